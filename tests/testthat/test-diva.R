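# Dispersal-vicariance optimization, S-DIVA frequencies, maxareas sensitivity.
# (The exhaustive oracle lives in helper-oracles.R.)

test_that("uniform tip ranges reconstruct to the same range at zero cost", {
  tr <- balanced4_tree()
  rec <- diva_optimize(tr, list(t1 = "a", t2 = "a", t3 = "a", t4 = "a"),
                       area_labels = c("a", "b"))
  expect_equal(rec$total_cost, 0)
  for (i in seq_len(nrow(rec$node_table))) {
    expect_equal(rec$node_table$sets[[i]], list("a"))
    expect_equal(rec$node_table$frequencies[[i]], 1)
  }
})

test_that("a cherry over two areas resolves to a zero-cost vicariance", {
  tr <- cherry_tree()
  rec <- diva_optimize(tr, list(t1 = "a", t2 = "b"))
  expect_equal(rec$total_cost, 0)
  sets <- vapply(rec$node_table$sets[[1]], paste, character(1), collapse = ",")
  expect_true("a,b" %in% sets)
})

test_that("random 4-tip instances match the exhaustive oracle", {
  set.seed(23)
  labels <- c("a", "b", "c")
  for (rep in 1:60) {
    tr <- if (rep %% 2 == 0) balanced4_tree() else
      ape::read.tree(text = "(((t1:1,t2:1):1,t3:2):1,t4:3);")
    tip_areas <- lapply(1:4, function(i)
      sample(labels, sample.int(2, 1)))
    names(tip_areas) <- tr$tip.label
    maxa <- sample(2:3, 1)
    strict <- rep %% 3 == 0
    rec <- diva_optimize(tr, tip_areas, maxareas = maxa,
                         area_labels = labels, strict = strict)
    ora <- oracle_diva(tr, tip_areas, labels, maxa, strict = strict)
    expect_equal(rec$total_cost, ora$cost)
    for (i in seq_len(nrow(rec$node_table))) {
      v <- rec$node_table$node[i]
      got <- sort(vapply(rec$node_table$sets[[i]], paste, character(1),
                         collapse = ","))
      want <- sort(vapply(ora$opt_sets[[v]], function(m)
        paste(mask_to_areas(m, labels), collapse = ","), character(1)))
      expect_equal(got, want)
      expect_equal(sum(rec$node_table$frequencies[[i]]), 1, tolerance = 1e-9)
    }
  }
})

test_that("total cost is non-increasing in maxareas", {
  set.seed(29)
  labels <- paste0("a", 1:4)
  cfg <- sim_config(seed = 131, n_species = 6)
  tr <- simulate_dated_tree(cfg)
  for (rep in 1:10) {
    tip_areas <- setNames(lapply(1:6, function(i)
      sample(labels, sample.int(2, 1))), tr$tip.label)
    costs <- vapply(2:4, function(m)
      diva_optimize(tr, tip_areas, maxareas = m,
                    area_labels = labels)$total_cost, numeric(1))
    expect_true(all(diff(costs) <= 0))
  }
})

test_that("reconstruction is equivariant under area relabelling", {
  set.seed(31)
  labels <- c("a", "b", "c")
  perm <- c(a = "c", b = "a", c = "b")
  tr <- balanced4_tree()
  tip_areas <- list(t1 = c("a", "b"), t2 = "c", t3 = "b", t4 = c("a", "c"))
  r1 <- diva_optimize(tr, tip_areas, area_labels = labels)
  tip2 <- lapply(tip_areas, function(v) unname(perm[v]))
  r2 <- diva_optimize(tr, tip2, area_labels = labels)
  expect_equal(r1$total_cost, r2$total_cost)
  for (i in seq_len(nrow(r1$node_table))) {
    s1 <- sort(vapply(r1$node_table$sets[[i]], function(s)
      paste(sort(unname(perm[s])), collapse = ","), character(1)))
    s2 <- sort(vapply(r2$node_table$sets[[i]], function(s)
      paste(sort(s), collapse = ","), character(1)))
    expect_equal(s1, s2)
  }
})

test_that("simulated low-event histories recover the true root range", {
  # zero extinction, rare dispersal, maxareas at the true root-range size
  # (unconstrained DIVA happily absorbs single dispersals into ever wider
  # cost-free ancestral ranges; the maxareas bound exists for precisely this)
  labels <- paste0("a", 1:5)
  pairs <- t(combn(labels, 2))
  ar <- area_system(labels, pairs)
  hits <- 0L; n <- 200L
  for (r in seq_len(n)) {
    cfg <- sim_config(seed = 3000 + r, n_species = 6, dispersal_rate = 0.02,
                      extinction_rate = 0)
    tr <- simulate_dated_tree(cfg, seed = 3000 + r)
    set.seed(123 + r)
    h <- simulate_biogeography(tr, ar, cfg, root_range = sample(labels, 2),
                               seed = 6000 + r)
    rec <- diva_optimize(tr, h$tip_areas, area_labels = labels,
                         maxareas = max(2L, max(lengths(h$tip_areas))))
    root_row <- which(rec$node_table$node == ape::Ntip(tr) + 1L)
    sets <- rec$node_table$sets[[root_row]]
    if (any(vapply(sets, setequal, logical(1),
                   h$node_range[[ape::Ntip(tr) + 1L]])))
      hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("single-tree S-DIVA frequencies are uniform and idempotent", {
  tr <- balanced4_tree()
  tip_areas <- list(t1 = "a", t2 = "b", t3 = "a", t4 = "c")
  one <- sdiva_frequencies(list(tr), tip_areas)
  two <- sdiva_frequencies(list(tr, tr), tip_areas)
  expect_equal(one, two)
  rec <- diva_optimize(tr, tip_areas)
  for (i in seq_len(nrow(rec$node_table))) {
    cl <- rec$node_table$clade[i]
    sub <- one[one$clade == cl, ]
    expect_equal(sum(sub$frequency), 1, tolerance = 1e-9)
    expect_equal(nrow(sub), length(rec$node_table$sets[[i]]))
  }
})

test_that("frequencies at an unstable clade scale with its occurrence", {
  # 10 trees: 7 contain clade (t1,t2), 3 the conflicting clade (t2,t3)
  t_a <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  t_b <- ape::read.tree(text = "(((t2:1,t3:1):0.5,t1:1.5):0.5,t4:2);")
  trees <- c(rep(list(t_a), 7), rep(list(t_b), 3))
  tip_areas <- list(t1 = "a", t2 = "b", t3 = "c", t4 = "c")
  fr <- sdiva_frequencies(trees, tip_areas)
  # hand tally: clade t1,t2 appears in 7/10 trees
  sub <- fr[fr$clade == "t1,t2", ]
  expect_equal(sum(sub$frequency), 0.7, tolerance = 1e-9)
  expect_equal(unique(sub$occurrence), 0.7)
  single <- sdiva_frequencies(list(t_a), tip_areas)
  ssub <- single[single$clade == "t1,t2", ]
  m <- merge(sub, ssub, by = "set")
  expect_equal(m$frequency.x, 0.7 * m$frequency.y, tolerance = 1e-9)
})

test_that("maxareas sensitivity flags constructed disagreements", {
  # all-single-area history: settings must agree
  tr <- balanced4_tree()
  uni <- list(t1 = "a", t2 = "a", t3 = "a", t4 = "a")
  rep1 <- maxareas_sensitivity(tr, uni, 2:3, area_labels = c("a", "b", "c"))
  expect_true(all(rep1$node_table$agree))
  # three single-area tips in distinct areas: maxareas = 3 admits the
  # zero-cost full split at the root, maxareas = 2 cannot
  tr3 <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  tips3 <- list(t1 = "a", t2 = "b", t3 = "c")
  rep2 <- maxareas_sensitivity(tr3, tips3, 2:3)
  expect_false(all(rep2$node_table$agree))
  expect_lt(rep2$costs["3"], rep2$costs["2"] + 1e-9)
  # report equals the pairwise diff of individual runs
  r2 <- diva_optimize(tr3, tips3, maxareas = 2)
  r3 <- diva_optimize(tr3, tips3, maxareas = 3)
  for (i in seq_len(nrow(rep2$node_table))) {
    s2 <- paste(sort(vapply(r2$node_table$sets[[i]], paste, character(1),
                            collapse = ",")), collapse = " | ")
    s3 <- paste(sort(vapply(r3$node_table$sets[[i]], paste, character(1),
                            collapse = ",")), collapse = " | ")
    expect_equal(rep2$node_table$agree[i], identical(s2, s3))
  }
  # settings below the largest tip set are reported as skipped
  wide <- list(t1 = c("a", "b", "c"), t2 = "a", t3 = "b")
  rep3 <- maxareas_sensitivity(tr3, wide, c(2, 3))
  expect_equal(rep3$settings_skipped, 2L)
})

test_that("bad inputs are rejected", {
  tr <- cherry_tree()
  expect_error(diva_optimize(tr, list(t1 = "a")), "without area")
  expect_error(diva_optimize(tr, list(t1 = character(0), t2 = "a")), "empty")
  expect_error(diva_optimize(tr, list(t1 = c("a", "b"), t2 = "c"),
                             maxareas = 1), "largest tip set")
})
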
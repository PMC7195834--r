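# PTP-style two-rate delimitation and cross-method concordance.

# exhaustive oracle: enumerate all species partitions (antichains of subtree
# roots covering the tips) and score with the same two-class rule
oracle_ptp_partitions <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  covers <- function(v) {
    # all ways to cover the tips below v with an antichain including or
    # excluding v itself
    own <- list(v)
    if (v <= ntip) return(own)
    ch <- kids(v)
    below <- lapply(covers(ch[1]), function(a)
      lapply(covers(ch[2]), function(b) c(a, b)))
    c(own, unlist(below, recursive = FALSE))
  }
  covers(root)
}

test_that("a star-like tree with long terminals keeps every tip its own species", {
  tr <- ape::read.tree(text = paste0(
    "(((t1:1.02,t2:0.98):0.012,t3:1.05):0.009,(t4:0.97,t5:1.01):0.013);"))
  p <- ptp_delimit(tr, n_starts = 20, seed = 2)
  expect_equal(p$n_clusters, 5L)
})

test_that("4-tip searches equal the exhaustive oracle", {
  set.seed(9)
  for (rep in 1:25) {
    tr <- if (rep %% 2 == 0) balanced4_tree() else
      ape::read.tree(text = "(((t1:1,t2:1):1,t3:2):1,t4:3);")
    tr$edge.length <- rexp(6, sample(c(2, 20), 6, replace = TRUE))
    parts <- oracle_ptp_partitions(tr)
    scores <- vapply(parts, function(r) pdmvic:::.ptp_score(tr, r), numeric(1))
    best <- max(scores)
    # oracle tie-break: more species among top scorers
    top <- parts[scores >= best - 1e-9]
    best_k <- max(lengths(top))
    got <- ptp_delimit(tr, n_starts = 15, seed = rep)
    expect_equal(attr(got, "loglik"), best, tolerance = 1e-9)
    expect_equal(attr(got, "n_species"), best_k)
  }
})

test_that("two-class branch-length draws: the search attains the ML score", {
  # iid exponential classes with a 10x mean separation substantially overlap,
  # so the exact-count ML recovery plateaus near 60%; the properties that
  # must hold are (a) the hill climb never returns a partition worse than the
  # truth and (b) recovery stays far above chance
  hits <- 0L
  for (r in 1:20) {
    cfg <- sim_config(seed = 9500 + r, n_species = 5,
                      haplotypes_per_species = 4, coalescent_depth = 0.25)
    sp <- simulate_dated_tree(cfg, seed = 9500 + r, min_internal_age = 1.5)
    ht <- simulate_haplotype_tree(sp, cfg, seed = 9600 + r)
    tr <- ht$tree
    set.seed(9700 + r)
    crowns <- vapply(unique(ht$tip_species), function(s)
      ape::getMRCA(tr, names(ht$tip_species)[ht$tip_species == s]),
      integer(1))
    within <- unlist(lapply(crowns, function(v)
      which(tr$edge[, 1] %in% c(v, pdmvic:::.descendants(tr, v)))))
    lens <- rexp(nrow(tr$edge), rate = 10)   # between, mean 0.1
    lens[within] <- rexp(length(within), rate = 100) # within, mean 0.01
    tr$edge.length <- lens
    p <- ptp_delimit(tr, n_starts = 50, seed = 9800 + r)
    expect_gte(attr(p, "loglik"),
               pdmvic:::.ptp_score(tr, unname(crowns)) - 1e-9)
    if (p$n_clusters == 5L) hits <- hits + 1L
  }
  expect_gte(hits, 10L)
})

test_that("delimitation is invariant to tip-label permutation", {
  set.seed(13)
  cfg <- sim_config(seed = 121, n_species = 4, haplotypes_per_species = 3)
  sp <- simulate_dated_tree(cfg, min_internal_age = 1)
  tr <- simulate_haplotype_tree(sp, cfg)$tree
  tr$edge.length <- tr$edge.length * 0.01
  p1 <- ptp_delimit(tr, n_starts = 25, seed = 3)
  perm <- sample(tr$tip.label)
  tr2 <- tr; tr2$tip.label <- perm
  p2 <- ptp_delimit(tr2, n_starts = 25, seed = 3)
  expect_equal(p2$n_clusters, p1$n_clusters)
  expect_equal(attr(p2, "loglik"), attr(p1, "loglik"), tolerance = 1e-9)
})

test_that("zero-length trees are rejected", {
  tr <- balanced4_tree()
  tr$edge.length[] <- 0
  expect_error(ptp_delimit(tr), "zero")
})

test_that("identical partitions agree on every reference species", {
  ref <- setNames(rep(sprintf("s%d", 1:8), each = 2),
                  sprintf("t%02d", 1:16))
  asg <- setNames(rep(1:8, each = 2), names(ref))
  parts <- list(delimitation_partition(asg, "m1"),
                delimitation_partition(asg, "m2"),
                delimitation_partition(asg, "m3"))
  rep_ <- concordance(parts, ref)
  expect_equal(rep_$consensus_count, 8L)
  expect_true(all(rep_$status == "exact"))
})

test_that("merges and splits reduce the consensus count arithmetically", {
  ref <- setNames(rep(sprintf("s%d", 1:5), each = 2), sprintf("t%02d", 1:10))
  exact <- setNames(rep(1:5, each = 2), names(ref))
  merged <- exact; merged[ref %in% c("s1", "s2")] <- 1L # A merges s1+s2
  split <- exact; split[c(5, 6)] <- c(3L, 6L)            # B splits s3
  rep_ <- concordance(list(delimitation_partition(merged, "A"),
                           delimitation_partition(split, "B")), ref)
  expect_equal(rep_$consensus_count, 5L - 3L)
  expect_equal(unname(rep_$status["s1", "A"]), "merged")
  expect_equal(unname(rep_$status["s3", "B"]), "split")
})

test_that("status reports match a brute-force per-species computation", {
  set.seed(17)
  tips <- sprintf("t%02d", 1:12)
  ref <- setNames(sample(sprintf("s%d", 1:4), 12, replace = TRUE), tips)
  while (length(unique(ref)) < 4)
    ref <- setNames(sample(sprintf("s%d", 1:4), 12, replace = TRUE), tips)
  for (rep in 1:10) {
    parts <- lapply(1:3, function(i)
      delimitation_partition(setNames(sample.int(5, 12, replace = TRUE), tips),
                             paste0("m", i)))
    got <- concordance(parts, ref)
    for (s in rownames(got$status)) for (j in 1:3) {
      asg <- parts[[j]]$assignment
      ts <- tips[ref == s]
      cl <- unique(asg[ts])
      expected <- if (length(cl) == 1) {
        if (sum(asg == cl) == length(ts)) "exact" else "merged"
      } else {
        outside <- any(vapply(cl, function(ci)
          any(ref[names(asg)[asg == ci]] != s), logical(1)))
        if (outside) "mixed" else "split"
      }
      expect_equal(unname(got$status[s, j]), expected)
    }
  }
})

test_that("partitions over different tip sets are rejected", {
  p1 <- delimitation_partition(c(a = 1, b = 1), "m1")
  p2 <- delimitation_partition(c(a = 1, c = 2), "m2")
  expect_error(concordance(list(p1, p2), c(a = "s", b = "s")), "tip set")
})
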
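#' Simulation configuration for the synthetic ground-truth generator
#'
#' Bundles all parameters of the synthetic-data module. Defaults emulate a
#' single-genus mitochondrial phylogeography dataset: a complete
#' protein-coding mtDNA marker of 1,137 sites for ~10 species with several
#' haplotypes each, tree depths on a 0--30 Ma scale, and a handful of endemic
#' areas arranged on an adjacency graph.
#'
#' @param n_species number of species (tree tips), >= 2.
#' @param haplotypes_per_species haplotypes sampled within each species (used
#'   by [simulate_haplotype_tree()]).
#' @param birth_rate,death_rate birth--death rates, events/Ma
#'   (`birth_rate > death_rate >= 0`).
#' @param root_age_bound reject simulated trees with root age above this (Ma).
#' @param clock_rate_mean mean substitution rate, substitutions/site/Ma.
#' @param clock_model `"strict"` or `"lognormal-relaxed"`.
#' @param relaxed_sd standard deviation of log branch rates under the relaxed
#'   clock (sdlog of the lognormal; the real-scale mean is `clock_rate_mean`).
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freqs stationary base frequencies, named A,C,G,T, summing to 1.
#' @param seq_length alignment length in sites (kept a multiple of 3 for the
#'   coding-frame check).
#' @param area_count number of endemic areas.
#' @param dispersal_rate,extinction_rate range-evolution rates on the area
#'   graph, events/lineage/Ma.
#' @param coalescent_depth within-species coalescent depth (Ma) for haplotype
#'   trees; should be well below typical species divergences.
#' @param seed integer seed; every generator consumes it deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L,
                       haplotypes_per_species = 3L,
                       birth_rate = 0.3,
                       death_rate = 0.1,
                       root_age_bound = 30,
                       clock_rate_mean = 0.01,
                       clock_model = c("strict", "lognormal-relaxed"),
                       relaxed_sd = 0.3,
                       kappa = 4,
                       base_freqs = c(A = 0.25, C = 0.30, G = 0.15, T = 0.30),
                       seq_length = 1137L,
                       area_count = 7L,
                       dispersal_rate = 0.05,
                       extinction_rate = 0.02,
                       coalescent_depth = 0.3,
                       seed = 1L) {
  clock_model <- match.arg(clock_model)
  .check_scalar(n_species, "n_species", lower = 2)
  .check_scalar(seq_length, "seq_length", lower = 1)
  for (nm in c("birth_rate", "death_rate", "clock_rate_mean", "relaxed_sd",
               "dispersal_rate", "extinction_rate"))
    .check_scalar(get(nm), nm, lower = 0)
  if (birth_rate <= death_rate) stop("birth_rate must exceed death_rate")
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  if (is.null(names(base_freqs))) names(base_freqs) <- c("A", "C", "G", "T")
  .check_scalar(seed, "seed", lower = 0, upper = 2^31 - 10)
  structure(list(
    n_species = as.integer(n_species),
    haplotypes_per_species = as.integer(haplotypes_per_species),
    birth_rate = birth_rate, death_rate = death_rate,
    root_age_bound = root_age_bound,
    clock_rate_mean = clock_rate_mean, clock_model = clock_model,
    relaxed_sd = relaxed_sd, kappa = kappa, base_freqs = base_freqs,
    seq_length = as.integer(seq_length), area_count = as.integer(area_count),
    dispersal_rate = dispersal_rate, extinction_rate = extinction_rate,
    coalescent_depth = coalescent_depth, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a dated species tree under a birth--death process
#'
#' Draws a rooted, binary, ultrametric tree with exactly `n_species` tips and
#' branch lengths in Ma, conditioning on the root age not exceeding
#' `root_age_bound` by rejection.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param max_attempts rejection budget before an error is raised.
#' @param min_internal_age additionally require every internal node to be at
#'   least this old (Ma); used to condition on clearly separated species for
#'   delimitation experiments.
#' @return An ultrametric `phylo` with tips `sp01, sp02, ...`.
#' @export
simulate_dated_tree <- function(config, seed = config$seed, max_attempts = 1000L,
                                min_internal_age = 0) {
  set.seed(seed)
  ntip <- config$n_species
  for (i in seq_len(max_attempts)) {
    tree <- ape::rphylo(config$n_species, birth = config$birth_rate,
                        death = config$death_rate)
    ages <- .node_ages(tree)
    if (max(ages) <= config$root_age_bound &&
        min(ages[(ntip + 1L):(2L * ntip - 1L)]) >= min_internal_age) {
      tree$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
      return(tree)
    }
  }
  stop(sprintf("no tree with root age <= %g obtained in %d attempts; ",
               config$root_age_bound, max_attempts),
       "the birth/death rates imply deeper trees")
}

#' Graft within-species haplotype subtrees onto a species tree
#'
#' Replaces each species tip by a small coalescent subtree of
#' `haplotypes_per_species` haplotypes whose depth is drawn uniformly on
#' `(0, coalescent_depth]`, giving the deep-between/shallow-within structure
#' single-locus species delimitation assumes.
#'
#' @param species_tree ultrametric `phylo` in Ma.
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return list with `tree` (ultrametric haplotype `phylo`, tips
#'   `spXX_hY`) and `tip_species` (named character vector tip -> species).
#' @export
simulate_haplotype_tree <- function(species_tree, config, seed = config$seed + 3L) {
  set.seed(seed)
  k <- config$haplotypes_per_species
  tree <- species_tree
  if (k > 1L) {
    for (sp in species_tree$tip.label) {
      tip_idx <- which(tree$tip.label == sp)
      stem_len <- tree$edge.length[tree$edge[, 2] == tip_idx]
      depth <- runif(1, 0.2, 1) * min(config$coalescent_depth, 0.9 * stem_len)
      labs <- paste0(sp, "_h", seq_len(k))
      sub <- ape::rcoal(k, tip.label = labs)
      dep <- ape::node.depth.edgelength(sub)
      sub$edge.length <- sub$edge.length * depth / max(dep)
      # graft the cluster at the tip, then shorten its stem so the haplotype
      # tips come back to age 0 (keeps the tree ultrametric)
      tree <- ape::bind.tree(tree, sub, where = tip_idx)
      crown <- ape::getMRCA(tree, labs)
      e <- which(tree$edge[, 2] == crown)
      tree$edge.length[e] <- tree$edge.length[e] - depth
    }
    dep <- ape::node.depth.edgelength(tree)
    tips <- seq_len(ape::Ntip(tree))
    stopifnot(max(dep[tips]) - min(dep[tips]) < 1e-8)
  }
  tip_species <- sub("_h[0-9]+$", "", tree$tip.label)
  names(tip_species) <- tree$tip.label
  list(tree = tree, tip_species = tip_species)
}

# Internal: evolve an area set along a branch, recording events.
# Returns list(set, events = data.frame)
.evolve_range <- function(set, node, t_start, t_end, areas, d_rate, e_rate) {
  dt <- t_start - t_end
  events <- list()
  n_ev <- rpois(1, (d_rate + e_rate) * dt)
  if (n_ev > 0) {
    times <- sort(runif(n_ev, t_end, t_start), decreasing = TRUE)
    for (tm in times) {
      is_disp <- runif(1) < d_rate / (d_rate + e_rate)
      if (is_disp) {
        nb <- areas$labels[colSums(areas$adj[set, , drop = FALSE]) > 0]
        cand <- setdiff(nb, set)
        if (length(cand) == 0) next
        a <- if (length(cand) == 1) cand else sample(cand, 1)
        set <- c(set, a)
        events[[length(events) + 1L]] <-
          data.frame(kind = "dispersal", node = node, age = tm, areas = a)
      } else {
        if (length(set) <= 1) next
        a <- sample(set, 1)
        set <- setdiff(set, a)
        events[[length(events) + 1L]] <-
          data.frame(kind = "extinction", node = node, age = tm, areas = a)
      }
    }
  }
  list(set = set, events = events)
}

#' Simulate a biogeographic history with known truth on a dated tree
#'
#' Evolves discrete ranges along the tree: dispersal adds a graph-adjacent
#' area, extinction removes an area (never emptying a range), and at each
#' speciation a multi-area range splits by vicariance (uniformly random
#' disjoint bipartition) while a single-area range duplicates into both
#' daughters.
#'
#' @param tree dated `phylo` (branch lengths in Ma).
#' @param areas an [area_system()]; its adjacency graph must be connected.
#' @param config a [sim_config()] (uses `dispersal_rate`, `extinction_rate`).
#' @param root_range optional character vector of areas for the root range;
#'   default a single uniformly drawn area.
#' @param seed optional seed.
#' @return An object of class `true_history`: list with `tree`, `node_range`
#'   (list indexed by node id), `edge_start_range` (range inherited at the top
#'   of each node's stem edge, indexed by child node id), `events`
#'   (data.frame: kind, node, age, areas), `tip_areas` (named list) and
#'   `tip_species`.
#' @export
simulate_biogeography <- function(tree, areas, config, root_range = NULL,
                                  seed = config$seed + 1L) {
  g <- .area_graph(areas)
  if (!igraph::is_connected(g)) stop("area adjacency graph must be connected")
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  ages <- .node_ages(tree)
  root <- ntip + 1L
  node_range <- vector("list", nnode)
  edge_start <- vector("list", nnode)
  events <- list()
  if (is.null(root_range)) {
    root_range <- sample(areas$labels, 1)
  } else {
    root_range <- as.character(root_range)
    if (!all(root_range %in% areas$labels)) stop("unknown areas in root_range")
  }
  node_range[[root]] <- root_range

  # preorder traversal
  ord <- rev(ape::postorder(tree))
  # process speciation at each internal node, then evolve along child edges
  split_range <- function(S) {
    if (length(S) == 1L) return(list(S, S, kind = "duplication"))
    repeat {
      side <- runif(length(S)) < 0.5
      if (any(side) && !all(side)) break
    }
    list(S[side], S[!side], kind = "vicariance")
  }
  # children edges in preorder: iterate edges such that parent's range known
  for (e in rev(ape::postorder(tree))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    if (is.null(edge_start[[chi]])) {
      # speciation at `par`: split its range between its two children now
      kids <- tree$edge[tree$edge[, 1] == par, 2]
      sp <- split_range(node_range[[par]])
      edge_start[[kids[1]]] <- sp[[1]]
      edge_start[[kids[2]]] <- sp[[2]]
      events[[length(events) + 1L]] <- data.frame(
        kind = sp$kind, node = par, age = ages[par],
        areas = paste0(kids[1], "=", paste(sp[[1]], collapse = ","), "|",
                       kids[2], "=", paste(sp[[2]], collapse = ",")))
    }
    ev <- .evolve_range(edge_start[[chi]], chi, ages[par], ages[chi], areas,
                        config$dispersal_rate, config$extinction_rate)
    node_range[[chi]] <- ev$set
    events <- c(events, ev$events)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), node = integer(), age = numeric(),
               areas = character())
  events <- events[order(-events$age), , drop = FALSE]
  rownames(events) <- NULL
  tip_areas <- setNames(node_range[seq_len(ntip)], tree$tip.label)
  structure(list(tree = tree, node_range = node_range,
                 edge_start_range = edge_start, events = events,
                 tip_areas = tip_areas,
                 tip_species = setNames(tree$tip.label, tree$tip.label),
                 areas = areas),
            class = "true_history")
}

#' Replay a recorded biogeographic event list
#'
#' Independently reconstructs every tip range from a `true_history`'s event
#' list alone (inherited ranges at speciations plus the per-branch dispersal
#' and extinction events), for validating that the recorded ranges and the
#' event log agree.
#'
#' @param history a `true_history` from [simulate_biogeography()].
#' @return named list of tip ranges implied by the event list.
#' @export
replay_history <- function(history) {
  tree <- history$tree
  ntip <- ape::Ntip(tree)
  ev <- history$events
  out <- vector("list", ntip + tree$Nnode)
  # parse speciation events to get inherited ranges
  start <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] %in% c("vicariance", "duplication")) {
      parts <- strsplit(ev$areas[i], "|", fixed = TRUE)[[1]]
      for (p in parts) {
        kv <- strsplit(p, "=", fixed = TRUE)[[1]]
        start[[as.integer(kv[1])]] <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
      }
    }
  }
  for (chi in seq_len(ntip + tree$Nnode)) {
    if (is.null(start[[chi]])) next
    set <- start[[chi]]
    branch_ev <- ev[ev$node == chi & ev$kind %in% c("dispersal", "extinction"), ]
    if (nrow(branch_ev)) {
      branch_ev <- branch_ev[order(-branch_ev$age), ]
      for (i in seq_len(nrow(branch_ev))) {
        set <- if (branch_ev$kind[i] == "dispersal") c(set, branch_ev$areas[i])
               else setdiff(set, branch_ev$areas[i])
      }
    }
    out[[chi]] <- set
  }
  setNames(out[seq_len(ntip)], tree$tip.label)
}

#' Simulate a clock-evolved coding alignment on a dated tree
#'
#' Evolves sequences under HKY with a strict or uncorrelated-lognormal relaxed
#' clock. The root sequence is drawn from the stationary base frequencies with
#' in-frame stop codons (vertebrate mitochondrial code, frame 0) resampled, so
#' the quality-control stage sees a clean reading frame at low divergence.
#'
#' @param tree dated `phylo`, branch lengths in Ma.
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return A character matrix (rows = tips, upper-case bases) of class
#'   `dna_alignment`, with attributes `branch_rates` (true per-edge rates,
#'   substitutions/site/Ma, in `tree$edge` order) and `root_sequence`.
#' @export
simulate_alignment <- function(tree, config, seed = config$seed + 2L) {
  set.seed(seed)
  nedge <- nrow(tree$edge)
  rates <- switch(config$clock_model,
    strict = rep(config$clock_rate_mean, nedge),
    `lognormal-relaxed` = rlnorm(nedge,
      meanlog = log(config$clock_rate_mean) - config$relaxed_sd^2 / 2,
      sdlog = config$relaxed_sd))
  rootseq <- .sample_coding_root(config$seq_length, config$base_freqs)
  tr <- tree
  tr$edge.length <- tree$edge.length * rates
  if (config$clock_rate_mean == 0 || all(tr$edge.length == 0)) {
    m <- matrix(rep(rootseq, ape::Ntip(tree)), nrow = ape::Ntip(tree),
                byrow = TRUE, dimnames = list(tree$tip.label, NULL))
  } else {
    bf <- config$base_freqs[c("A", "C", "G", "T")]
    sim <- phangorn::simSeq(tr, l = config$seq_length,
                            Q = c(1, config$kappa, 1, 1, config$kappa, 1),
                            bf = as.numeric(bf),
                            rootseq = tolower(rootseq), type = "DNA")
    m <- toupper(as.character(sim))
    m <- m[tree$tip.label, , drop = FALSE]
  }
  aln <- dna_alignment(m)
  attr(aln, "branch_rates") <- rates
  attr(aln, "root_sequence") <- rootseq
  aln
}

# Internal: root sequence from stationary frequencies, no internal stops
# (vertebrate mitochondrial code, frame 0)
.sample_coding_root <- function(len, bf) {
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, len, replace = TRUE, prob = bf[bases])
  stops <- c("TAA", "TAG", "AGA", "AGG")
  n_codon <- len %/% 3L
  if (n_codon > 1L) {
    repeat {
      idx <- 3L * (seq_len(n_codon - 1L) - 1L) # internal codons only
      codons <- paste0(seqv[idx + 1L], seqv[idx + 2L], seqv[idx + 3L])
      bad <- which(codons %in% stops)
      if (length(bad) == 0) break
      for (b in bad) {
        pos <- 3L * (b - 1L)
        seqv[pos + seq_len(3L)] <- sample(bases, 3L, replace = TRUE,
                                          prob = bf[bases])
      }
    }
  }
  seqv
}
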
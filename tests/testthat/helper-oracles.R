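# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: transition probabilities come from an eigen
# decomposition of the rate matrix, likelihoods from explicit summation over
# ancestral states, and set/graph questions from direct enumeration.

# HKY transition matrix by eigen decomposition (states A, C, G, T)
oracle_hky_pmat <- function(t, kappa, bf) {
  pur <- c(TRUE, FALSE, TRUE, FALSE)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- bf[j] * if (pur[i] == pur[j]) kappa else 1
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# Brute-force pruning oracle: sum over all internal-node state assignments.
# tree: rooted binary phylo; el: expected substitutions per edge (tree$edge
# order); aln: character matrix over ACGT.
oracle_loglik <- function(tree, aln, el, kappa, bf) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    oracle_hky_pmat(el[e], kappa, bf))
  states <- match(aln[tree$tip.label, , drop = FALSE], c("A", "C", "G", "T"))
  dim(states) <- c(ntip, ncol(aln))
  n_int <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  ll <- 0
  for (s in seq_len(ncol(aln))) {
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      st <- c(states[, s], grid[g, ])
      p <- bf[st[ntip + 1]]
      for (e in seq_len(nrow(tree$edge)))
        p <- p * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      lik <- lik + p
    }
    ll <- ll + log(lik)
  }
  ll
}

# Fixed small ultrametric trees
cherry_tree <- function(t = 1, labels = c("t1", "t2")) {
  tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", labels[1], t,
                                      labels[2], t))
  tr
}

balanced4_tree <- function(t1 = 1, t2 = 2) {
  ape::read.tree(text = sprintf(
    "((t1:%g,t2:%g):%g,(t3:%g,t4:%g):%g);", t1, t1, t2 - t1, t1, t1, t2 - t1))
}

# Random alignment of pure bases
random_alignment <- function(n, len, labels = sprintf("t%d", seq_len(n))) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len,
              dimnames = list(labels, NULL))
  dna_alignment(m)
}

# Random connected area system on k areas: random spanning tree plus extras
random_area_system <- function(k, extra_p = 0.3) {
  labels <- paste0("a", seq_len(k))
  pairs <- list()
  for (i in 2:k) pairs[[length(pairs) + 1L]] <- c(labels[sample.int(i - 1, 1)],
                                                  labels[i])
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    if (runif(1) < extra_p) pairs[[length(pairs) + 1L]] <- c(labels[i], labels[j])
  area_system(labels, unique(do.call(rbind, pairs)))
}

# Direct adjacency check between two area sets (independent of .sets_touch)
oracle_sets_touch <- function(A, B, areas) {
  for (a in A) for (b in B) {
    if (a == b) return(TRUE)
    if (areas$adj[a, b]) return(TRUE)
  }
  FALSE
}

# Exhaustive DIVA oracle: enumerate every assignment of ancestral sets to
# internal nodes and compute the cost with an explicit event model: at each
# internal node the ancestral set passes to the daughters by the cheapest
# allowed inheritance (vicariance bipartition / duplication / optional
# sympatric subset), then each branch pays one unit per area gained or lost.
oracle_diva <- function(tree, tip_areas, labels, maxareas, strict = FALSE) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  A <- length(labels)
  masks <- 1:(2^A - 1)
  pc <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:15)) > 0), numeric(1))
  valid <- masks[pc <= maxareas]
  to_mask <- function(v) sum(2^(match(v, labels) - 1))
  tipm <- vapply(tree$tip.label, function(l) to_mask(tip_areas[[l]]), numeric(1))
  sd2 <- function(a, b) sum(bitwAnd(bitwXor(a, b), 2^(0:15)) > 0)
  pair_cost <- function(D, Cl, Cr) {
    ndl <- sum(bitwAnd(D, 2^(0:15)) > 0)
    best <- Inf
    if (ndl == 1) best <- sd2(D, Cl) + sd2(D, Cr)
    else {
      sub <- bitwAnd(D - 1, D)
      while (sub > 0) {
        best <- min(best, sd2(sub, Cl) + sd2(bitwXor(D, sub), Cr),
                    sd2(sub, Cr) + sd2(bitwXor(D, sub), Cl))
        sub <- bitwAnd(sub - 1, D)
      }
      if (!strict) {
        sub <- D
        while (sub > 0) {
          best <- min(best, sd2(D, Cl) + sd2(sub, Cr),
                      sd2(sub, Cl) + sd2(D, Cr))
          sub <- bitwAnd(sub - 1, D)
        }
      }
    }
    best
  }
  internals <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(valid), length(internals))))
  best_cost <- Inf
  opt_sets <- vector("list", nn)
  for (g in seq_len(nrow(grid))) {
    assign <- numeric(nn)
    assign[seq_len(ntip)] <- tipm
    assign[internals] <- grid[g, ]
    cost <- 0
    for (v in internals) {
      ch <- tree$edge[tree$edge[, 1] == v, 2]
      cost <- cost + pair_cost(assign[v], assign[ch[1]], assign[ch[2]])
    }
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      opt_sets <- vector("list", nn)
    }
    if (cost <= best_cost + 1e-9)
      for (v in internals)
        opt_sets[[v]] <- union(opt_sets[[v]], assign[v])
  }
  list(cost = best_cost, opt_sets = opt_sets)
}

mask_to_areas <- function(m, labels)
  labels[bitwAnd(m, 2^(0:15))[seq_along(labels)] > 0]

# Random terrain: max of 1-4 Manhattan cones with summits above 160 m on a
# -50 m floor. Every local maximum is a summit, so for flood levels at or
# below 150 m the habitable superlevel sets only ever merge as the sea falls
# (no new component can be born below the lowest summit).
random_terrain <- function(nr = 10, nc = 10) {
  z <- matrix(-50, nr, nc)
  for (j in seq_len(sample(1:4, 1))) {
    pr <- sample.int(nr, 1); pc <- sample.int(nc, 1)
    h <- runif(1, 160, 200); slope <- runif(1, 15, 40)
    d <- abs(row(z) - pr) + abs(col(z) - pc)
    z <- pmax(z, h - slope * d)
  }
  z
}
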
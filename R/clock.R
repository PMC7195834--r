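#' Molecular clock model specification
#'
#' @param kind `"strict"` (one rate shared by all branches) or `"UCLN"`
#'   (uncorrelated lognormal relaxed clock: independent branch rates with a
#'   shared real-scale mean and log-scale SD, both estimated).
#' @param init_rate starting value for the (mean) rate, substitutions/site/Ma.
#' @param fixed_rate if not `NULL`, the strict-clock rate is fixed at this
#'   value instead of being sampled (useful for closed-form checks).
#' @return list of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "UCLN"), init_rate = 0.01,
                        fixed_rate = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, init_rate = init_rate, fixed_rate = fixed_rate),
            class = "clock_model")
}

#' MCMC settings for the node-dating sampler
#'
#' @param iterations number of sweeps (one sweep updates every age plus the
#'   clock and substitution parameters once).
#' @param burnin sweeps discarded.
#' @param thin keep every `thin`-th sweep.
#' @param sample_kappa sample the HKY kappa (multiplier move) or keep fixed.
#' @param kappa initial / fixed transition-transversion ratio.
#' @param gamma_alpha fixed discrete-gamma shape for site-rate heterogeneity,
#'   or `NULL` for homogeneous site rates.
#' @param gamma_categories gamma categories when `gamma_alpha` is set.
#' @param tree_prior `"yule"` (pure-birth density on node ages, the zero-death
#'   special case of the birth--death prior) or `"uniform"` (flat on ages
#'   subject to parent-older-than-child and `root_max`).
#' @param yule_rate birth rate of the Yule tree prior, events/Ma.
#' @param root_max upper truncation for the root age, Ma.
#' @param likelihood_power power on the likelihood (0 = prior-only sampling,
#'   1 = posterior; intermediate values are used by stepping-stone rungs).
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 4000L, burnin = 1000L, thin = 2L,
                          sample_kappa = TRUE, kappa = 4,
                          gamma_alpha = NULL, gamma_categories = 4L,
                          tree_prior = c("yule", "uniform"), yule_rate = 0.3,
                          root_max = 100, likelihood_power = 1) {
  tree_prior <- match.arg(tree_prior)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 sample_kappa = sample_kappa, kappa = kappa,
                 gamma_alpha = gamma_alpha,
                 gamma_categories = as.integer(gamma_categories),
                 tree_prior = tree_prior, yule_rate = yule_rate,
                 root_max = root_max, likelihood_power = likelihood_power),
            class = "mcmc_settings")
}

# Internal sampler state helpers ---------------------------------------------

# initial node ages consistent with parent > child, scaled to a root guess
.init_ages <- function(tree, root_age) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  depth <- integer(nn) # max number of nodes to a tip below
  for (e in seq_len(nrow(tree$edge))) { # postorder assumed
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    depth[par] <- max(depth[par], depth[chi] + 1L)
  }
  ages <- root_age * depth / max(depth)
  ages[seq_len(ntip)] <- 0
  ages
}

.log_prior_ages <- function(ages, tree_po, settings) {
  root <- ape::Ntip(tree_po) + 1L
  if (ages[root] > settings$root_max) return(-Inf)
  if (settings$tree_prior == "yule") {
    lam <- settings$yule_rate
    durations <- ages[tree_po$edge[, 1]] - ages[tree_po$edge[, 2]]
    tree_po$Nnode * log(lam) - lam * sum(durations)
  } else 0
}

.log_prior_calibrations <- function(ages, cal_nodes, cal_means, cal_sds) {
  if (!length(cal_nodes)) return(0)
  sum(dnorm(ages[cal_nodes], cal_means, cal_sds, log = TRUE))
}

#' Bayesian node-age estimation on a fixed rooted topology
#'
#' Metropolis-within-Gibbs sampling of internal node ages (constrained to
#' parent older than child, tips at 0 Ma), the clock rate(s) and the HKY
#' kappa. The likelihood is the pruning-algorithm HKY likelihood with branch
#' lengths `rate x duration`; the prior is a tree prior (Yule or uniform)
#' times truncated-normal calibration densities times diffuse (log-uniform /
#' exponential) hyperpriors.
#'
#' Proposal kernels: uniform sliding within the (child, parent) age bracket
#' for non-root nodes, a multiplier for the root age, a joint
#' scale-ages/counter-scale-rate move, multipliers for rate and kappa, and
#' normal log-rate slides per branch under the relaxed clock.
#'
#' @param aln a [dna_alignment()] whose labels match the topology's tips.
#' @param topology rooted binary `phylo`; edge lengths are ignored.
#' @param scheme a bound `calibration_scheme` (at least one constraint).
#' @param clock a [clock_model()].
#' @param mcmc an [mcmc_settings()].
#' @param seed integer seed.
#' @return An object of class `posterior_sample`: list with `ages` (draws x
#'   internal nodes matrix, column names = node ids), `rate` (strict rate or
#'   relaxed real-scale mean), `relaxed_sd`, `kappa`, `loglik`, `logprior`,
#'   `ess` (effective sample sizes), `cal_nodes`, `tree`, `accept` (rates).
#' @export
estimate_node_ages <- function(aln, topology, scheme, clock = clock_model(),
                               mcmc = mcmc_settings(), seed = 1L) {
  if (!inherits(aln, "dna_alignment")) aln <- dna_alignment(aln)
  if (!setequal(rownames(aln), topology$tip.label))
    stop("alignment labels and topology tips do not match")
  if (!length(scheme$constraints)) stop("at least one calibration required")
  set.seed(seed)

  tr <- ape::reorder.phylo(topology, "postorder")
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  root <- ntip + 1L
  internal <- (ntip + 1L):nn
  edge <- tr$edge
  nedge <- nrow(edge)
  parent_of <- integer(nn)
  parent_of[edge[, 2]] <- edge[, 1]
  children_of <- split(edge[, 2], factor(edge[, 1], levels = seq_len(nn)))
  edge_below <- integer(nn) # edge row whose child is the node
  edge_below[edge[, 2]] <- seq_len(nedge)

  cal_nodes <- .resolve_calibrations(scheme, tr)
  cal_means <- vapply(scheme$constraints, `[[`, numeric(1), "mean")
  cal_sds <- vapply(scheme$constraints, `[[`, numeric(1), "sd")

  pk <- .pack_patterns(aln, tr$tip.label)
  bf <- .empirical_base_freqs(aln)
  site_rates <- if (is.null(mcmc$gamma_alpha)) 1.0 else
    as.numeric(phangorn::discrete.gamma(mcmc$gamma_alpha,
                                        mcmc$gamma_categories))

  # state
  ages <- .init_ages(tr, root_age = min(1.2 * max(cal_means),
                                        0.9 * mcmc$root_max))
  # nudge all ages so no exact tie violates parent > child downstream moves
  rate <- if (!is.null(clock$fixed_rate)) clock$fixed_rate else clock$init_rate
  kappa <- mcmc$kappa
  relaxed <- clock$kind == "UCLN"
  branch_logrates <- rep(0, nedge) # log deviation from mean rate
  relaxed_sd <- 0.3

  beta <- mcmc$likelihood_power
  loglik_fn <- function(ages, rate, kappa, blr) {
    dur <- ages[edge[, 1]] - ages[edge[, 2]]
    el <- dur * rate * exp(blr)
    .loglik_hky_cpp(edge, el, pk$patterns, pk$weights, kappa, bf, site_rates)
  }
  logprior_fn <- function(ages, rate, kappa, blr, rsd) {
    lp <- .log_prior_ages(ages, tr, mcmc) +
      .log_prior_calibrations(ages, cal_nodes, cal_means, cal_sds)
    if (is.null(clock$fixed_rate)) {
      if (rate < 1e-8 || rate > 100) return(-Inf)
      lp <- lp - log(rate) # log-uniform
    }
    if (mcmc$sample_kappa) {
      if (kappa < 0.1 || kappa > 100) return(-Inf)
      lp <- lp - log(kappa)
    }
    if (relaxed) {
      lp <- lp + sum(dnorm(blr, -rsd^2 / 2, rsd, log = TRUE)) +
        dexp(rsd, rate = 2, log = TRUE)
      if (rsd <= 0) return(-Inf)
    }
    lp
  }

  cur_ll <- if (beta > 0) loglik_fn(ages, rate, kappa, branch_logrates) else 0
  cur_lp <- logprior_fn(ages, rate, kappa, branch_logrates, relaxed_sd)
  if (!is.finite(cur_lp)) stop("initial state has zero prior probability")

  n_keep <- (mcmc$iterations - mcmc$burnin) %/% mcmc$thin
  draws_ages <- matrix(NA_real_, n_keep, length(internal),
                       dimnames = list(NULL, internal))
  draws_rate <- draws_kappa <- draws_ll <- draws_lp <- draws_rsd <-
    numeric(n_keep)
  acc <- c(age = 0, scale = 0, rate = 0, kappa = 0, blr = 0)
  try_n <- c(age = 0, scale = 0, rate = 0, kappa = 0, blr = 0)
  k_out <- 0L

  mh <- function(new_ll, new_lp, cur_ll, cur_lp, log_hastings = 0) {
    if (!is.finite(new_lp)) return(FALSE)
    log(runif(1)) < beta * (new_ll - cur_ll) + (new_lp - cur_lp) + log_hastings
  }

  for (it in seq_len(mcmc$iterations)) {
    # --- node ages
    for (v in internal[sample.int(length(internal))]) {
      lo <- max(ages[children_of[[v]]])
      if (v == root) {
        u <- runif(1, -0.3, 0.3)
        newage <- ages[v] * exp(u)
        if (newage <= lo || newage > mcmc$root_max) next
        lhast <- u # log Jacobian of multiplier
      } else {
        hi <- ages[parent_of[v]]
        newage <- runif(1, lo, hi)
        lhast <- 0
      }
      try_n["age"] <- try_n["age"] + 1
      ages2 <- ages; ages2[v] <- newage
      new_ll <- if (beta > 0) loglik_fn(ages2, rate, kappa, branch_logrates) else 0
      new_lp <- logprior_fn(ages2, rate, kappa, branch_logrates, relaxed_sd)
      if (mh(new_ll, new_lp, cur_ll, cur_lp, lhast)) {
        ages <- ages2; cur_ll <- new_ll; cur_lp <- new_lp
        acc["age"] <- acc["age"] + 1
      }
    }
    # --- joint scale (ages up, rate down) keeps branch lengths ~constant
    if (is.null(clock$fixed_rate)) {
      try_n["scale"] <- try_n["scale"] + 1
      u <- runif(1, -0.15, 0.15); cs <- exp(u)
      ages2 <- ages; ages2[internal] <- ages[internal] * cs
      rate2 <- rate / cs
      lhast <- u * (length(internal) - 1)
      new_ll <- if (beta > 0) loglik_fn(ages2, rate2, kappa, branch_logrates) else 0
      new_lp <- logprior_fn(ages2, rate2, kappa, branch_logrates, relaxed_sd)
      if (mh(new_ll, new_lp, cur_ll, cur_lp, lhast)) {
        ages <- ages2; rate <- rate2; cur_ll <- new_ll; cur_lp <- new_lp
        acc["scale"] <- acc["scale"] + 1
      }
      # --- rate multiplier
      try_n["rate"] <- try_n["rate"] + 1
      u <- runif(1, -0.4, 0.4); rate2 <- rate * exp(u)
      new_ll <- if (beta > 0) loglik_fn(ages, rate2, kappa, branch_logrates) else 0
      new_lp <- logprior_fn(ages, rate2, kappa, branch_logrates, relaxed_sd)
      if (mh(new_ll, new_lp, cur_ll, cur_lp, u)) {
        rate <- rate2; cur_ll <- new_ll; cur_lp <- new_lp
        acc["rate"] <- acc["rate"] + 1
      }
    }
    # --- kappa
    if (mcmc$sample_kappa) {
      try_n["kappa"] <- try_n["kappa"] + 1
      u <- runif(1, -0.3, 0.3); kappa2 <- kappa * exp(u)
      new_ll <- if (beta > 0) loglik_fn(ages, rate, kappa2, branch_logrates) else 0
      new_lp <- logprior_fn(ages, rate, kappa2, branch_logrates, relaxed_sd)
      if (mh(new_ll, new_lp, cur_ll, cur_lp, u)) {
        kappa <- kappa2; cur_ll <- new_ll; cur_lp <- new_lp
        acc["kappa"] <- acc["kappa"] + 1
      }
    }
    # --- relaxed-clock branch rates and sd
    if (relaxed) {
      for (e in sample.int(nedge, max(1L, nedge %/% 2L))) {
        try_n["blr"] <- try_n["blr"] + 1
        blr2 <- branch_logrates
        blr2[e] <- blr2[e] + rnorm(1, 0, 0.3)
        new_ll <- if (beta > 0) loglik_fn(ages, rate, kappa, blr2) else 0
        new_lp <- logprior_fn(ages, rate, kappa, blr2, relaxed_sd)
        if (mh(new_ll, new_lp, cur_ll, cur_lp)) {
          branch_logrates <- blr2; cur_ll <- new_ll; cur_lp <- new_lp
          acc["blr"] <- acc["blr"] + 1
        }
      }
      u <- runif(1, -0.3, 0.3); rsd2 <- relaxed_sd * exp(u)
      new_lp <- logprior_fn(ages, rate, kappa, branch_logrates, rsd2)
      if (mh(cur_ll, new_lp, cur_ll, cur_lp, u)) {
        relaxed_sd <- rsd2; cur_lp <- new_lp
      }
    }
    # --- record
    if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
      k_out <- k_out + 1L
      draws_ages[k_out, ] <- ages[internal]
      draws_rate[k_out] <- rate
      draws_kappa[k_out] <- kappa
      draws_rsd[k_out] <- relaxed_sd
      draws_ll[k_out] <- cur_ll
      draws_lp[k_out] <- cur_lp
    }
  }

  ess <- c(apply(draws_ages, 2, .ess), rate = .ess(draws_rate))
  structure(list(ages = draws_ages[seq_len(k_out), , drop = FALSE],
                 rate = draws_rate[seq_len(k_out)],
                 relaxed_sd = if (relaxed) draws_rsd[seq_len(k_out)] else NULL,
                 kappa = draws_kappa[seq_len(k_out)],
                 loglik = draws_ll[seq_len(k_out)],
                 logprior = draws_lp[seq_len(k_out)],
                 ess = ess, ess_low = any(ess < 100),
                 cal_nodes = cal_nodes, tree = tr, clock = clock$kind,
                 accept = ifelse(try_n > 0, acc / pmax(try_n, 1), NA)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample:", nrow(x$ages), "draws,", ncol(x$ages),
      "internal node ages,", x$clock, "clock\n")
  cat("min ESS:", round(min(x$ess), 1),
      if (x$ess_low) "(low - consider longer chains)" else "", "\n")
  invisible(x)
}

# Internal: empirical base frequencies (A,C,G,T) with pseudocount
.empirical_base_freqs <- function(aln) {
  counts <- table(factor(as.vector(unclass(aln)), levels = c("A", "C", "G", "T")))
  f <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  f / sum(f)
}

# Internal: effective sample size via initial-positive-sequence autocorrelation
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  maxlag <- min(n - 2L, 200L)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Shortest (highest-density) credible interval
#'
#' @param x numeric draws.
#' @param prob interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) stop("empty sample")
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Summarize posterior node ages
#'
#' @param sample a `posterior_sample`.
#' @param nodes integer node ids (default: all internal nodes of the sample).
#' @param prob HPD mass.
#' @return data.frame with `node`, `median`, `hpd_lower`, `hpd_upper`.
#' @export
summarize_ages <- function(sample, nodes = NULL, prob = 0.95) {
  if (nrow(sample$ages) == 0) stop("empty posterior sample")
  if (is.null(nodes)) nodes <- as.integer(colnames(sample$ages))
  out <- lapply(nodes, function(v) {
    x <- sample$ages[, as.character(v)]
    h <- hpd_interval(x, prob)
    data.frame(node = v, median = median(x), hpd_lower = h[1], hpd_upper = h[2])
  })
  do.call(rbind, out)
}
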
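# Two-rate PTP-style species delimitation on substitution-scaled trees.
#
# A species partition is an antichain of "species root" nodes covering every
# tip exactly once. Edges strictly inside a species subtree form the
# within-species (coalescent) class; all remaining edges form the
# between-species (speciation) class. Branch lengths in each class are
# modelled as iid exponential draws with class-specific rates.

# Internal: list of edge indices strictly below node v
.edges_below <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(integer(0))
  desc <- .descendants(tree, v)
  which(tree$edge[, 1] %in% c(v, desc))
}

# Internal: all descendant node ids of v (excluding v)
.descendants <- function(tree, v) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == v, 2]
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, x)
    stack <- c(stack, tree$edge[tree$edge[, 1] == x, 2])
  }
  out
}

# Internal: single-class exponential max log-likelihood; empty class -> 0
.exp_ll <- function(x) {
  n <- length(x)
  if (n == 0) return(0)
  s <- max(sum(x), 1e-12)
  n * log(n / s) - n
}

# Internal: edge indices strictly below every node, computed once per tree
.edges_below_all <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(nn)) out[[i]] <- integer(0)
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    out[[par]] <- c(out[[par]], e, out[[chi]])
  }
  out
}

# Internal: score a species-root set. Within = edges strictly inside species
# subtrees; between = the rest. Identifiability: if both classes are nonempty
# but the between-class mean is below the within-class mean, the two-class
# model is collapsed to the single-class score. `below` may carry a
# precomputed .edges_below_all() list.
.ptp_score <- function(tree, roots, below = NULL) {
  within <- if (is.null(below))
    unlist(lapply(roots, .edges_below, tree = tree))
  else unlist(below[roots])
  lens <- tree$edge.length
  w <- lens[within]
  b <- if (length(within)) lens[-within] else lens
  if (length(w) && length(b) && mean(b) < mean(w)) return(.exp_ll(lens))
  .exp_ll(w) + .exp_ll(b)
}

# Internal: partition from species roots
.ptp_partition <- function(tree, roots) {
  ntip <- ape::Ntip(tree)
  assign <- integer(ntip)
  for (i in seq_along(roots)) {
    v <- roots[i]
    tips <- if (v <= ntip) v else
      Filter(function(x) x <= ntip, .descendants(tree, v))
    assign[unlist(tips)] <- i
  }
  delimitation_partition(setNames(assign, tree$tip.label), method = "ptp")
}

#' PTP-style two-rate species delimitation
#'
#' Searches over species partitions of a substitution-scaled tree (each
#' species a connected subtree) for the maximum-likelihood assignment of edges
#' to a between-species and a within-species exponential branch-length class,
#' by greedy hill climbing (merge two sister species / split a species at its
#' root) from multiple random restarts. Exact likelihood ties are broken
#' toward more species (absence of within-species signal does not merge).
#'
#' @param tree rooted binary `phylo`, branch lengths in expected
#'   substitutions; >= 3 tips, not all branch lengths zero.
#' @param n_starts number of random restarts.
#' @param seed integer seed for the restarts.
#' @return A [delimitation_partition()] with attributes `loglik` and
#'   `n_species`.
#' @export
ptp_delimit <- function(tree, n_starts = 50L, seed = 1L) {
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  if (all(tree$edge.length == 0)) stop("all branch lengths are zero")
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  below <- .edges_below_all(tree)

  climb <- function(roots) {
    cur <- .ptp_score(tree, roots, below)
    repeat {
      best_roots <- NULL; best <- cur; best_k <- length(roots)
      # split moves
      for (i in seq_along(roots)) {
        v <- roots[i]
        if (v <= ntip) next
        kids <- tree$edge[tree$edge[, 1] == v, 2]
        cand <- c(roots[-i], kids)
        sc <- .ptp_score(tree, cand, below)
        if (sc > best + 1e-9 ||
            (abs(sc - best) <= 1e-9 && length(cand) > best_k)) {
          best <- sc; best_roots <- cand; best_k <- length(cand)
        }
      }
      # merge moves: two species roots that are siblings
      if (length(roots) > 1) {
        pars <- parent_of[roots]
        for (p in unique(pars[duplicated(pars)])) {
          pair <- roots[pars == p]
          if (length(pair) == 2) {
            cand <- c(setdiff(roots, pair), p)
            sc <- .ptp_score(tree, cand, below)
            if (sc > best + 1e-9 ||
                (abs(sc - best) <= 1e-9 && length(cand) > best_k)) {
              best <- sc; best_roots <- cand; best_k <- length(cand)
            }
          }
        }
      }
      if (is.null(best_roots)) break
      roots <- best_roots; cur <- best
    }
    list(roots = roots, loglik = cur)
  }

  random_start <- function() {
    roots <- seq_len(ntip) # all singletons
    n_merge <- sample.int(ntip, 1) - 1L
    for (i in seq_len(n_merge)) {
      pars <- parent_of[roots]
      dup <- unique(pars[duplicated(pars)])
      if (!length(dup)) break
      p <- if (length(dup) == 1) dup else sample(dup, 1)
      roots <- c(setdiff(roots, roots[pars == p]), p)
    }
    roots
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- climb(if (s == 1L) seq_len(ntip) else
                 if (s == 2L) root else random_start())
    if (is.null(best) || res$loglik > best$loglik + 1e-9 ||
        (abs(res$loglik - best$loglik) <= 1e-9 &&
         length(res$roots) > length(best$roots)))
      best <- res
  }
  part <- .ptp_partition(tree, best$roots)
  attr(part, "loglik") <- best$loglik
  attr(part, "n_species") <- length(best$roots)
  part
}

#' Cross-method concordance of delimitation partitions
#'
#' Compares delimitation partitions against a reference species table: per
#' reference species and method the status is `"exact"` (recovered as exactly
#' one cluster), `"merged"` (contained in a larger cluster), `"split"`
#' (distributed over several clusters, none extending beyond the species) or
#' `"mixed"` (split with at least one cluster crossing the species boundary).
#'
#' @param partitions list of [delimitation_partition()] objects on the same
#'   tip set.
#' @param reference named character vector: tip -> species.
#' @return list of class `concordance_report`: `status` (species x method
#'   character matrix), `consensus_count` (species recovered exactly by every
#'   method), `n_reference`.
#' @export
concordance <- function(partitions, reference) {
  if (!length(partitions)) stop("no partitions supplied")
  tipsets <- lapply(partitions, function(p) sort(names(p$assignment)))
  if (length(unique(tipsets)) != 1L ||
      !setequal(tipsets[[1]], names(reference)))
    stop("all partitions and the reference must share one tip set")
  methods <- vapply(seq_along(partitions), function(i) {
    m <- partitions[[i]]$method
    if (is.null(m)) paste0("method", i) else m
  }, character(1))
  methods <- make.unique(methods)
  species <- sort(unique(reference))
  status <- matrix(NA_character_, length(species), length(partitions),
                   dimnames = list(species, methods))
  for (j in seq_along(partitions)) {
    asg <- partitions[[j]]$assignment
    for (s in species) {
      tips_s <- names(reference)[reference == s]
      cl <- unique(asg[tips_s])
      if (length(cl) == 1L) {
        extent <- names(asg)[asg == cl]
        status[s, j] <- if (setequal(extent, tips_s)) "exact" else "merged"
      } else {
        crosses <- any(vapply(cl, function(ci)
          !all(names(asg)[asg == ci] %in% tips_s), logical(1)))
        status[s, j] <- if (crosses) "mixed" else "split"
      }
    }
  }
  structure(list(status = status,
                 consensus_count = sum(apply(status == "exact", 1, all)),
                 n_reference = length(species)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance:", x$consensus_count, "of", x$n_reference,
      "reference species recovered exactly by every method\n")
  print(x$status)
  invisible(x)
}
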
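#' HKY85 transition probability matrix
#'
#' Closed-form transition probabilities under the HKY85 model with the rate
#' matrix normalised to one expected substitution per site per unit branch
#' length.
#'
#' @param t branch length in expected substitutions per site.
#' @param kappa transition/transversion rate ratio.
#' @param base_freqs stationary frequencies in A, C, G, T order.
#' @return 4x4 matrix `P[i, j] = P(j at end | i at start)`.
#' @export
hky_transition_matrix <- function(t, kappa, base_freqs) {
  bf <- as.numeric(base_freqs)
  stopifnot(length(bf) == 4, abs(sum(bf) - 1) < 1e-8, t >= 0, kappa > 0)
  P <- .hky_pmat_cpp(t, kappa, bf)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

#' Expected proportion of differing sites under HKY
#'
#' For two sequences separated by total path length `t` (expected
#' substitutions per site), the probability that a site differs.
#'
#' @inheritParams hky_transition_matrix
#' @return scalar expected p-distance.
#' @export
hky_expected_pdist <- function(t, kappa, base_freqs) {
  P <- hky_transition_matrix(t, kappa, base_freqs)
  1 - sum(as.numeric(base_freqs) * diag(P))
}

# Internal: pack an alignment into site patterns for the pruning kernel.
# Ambiguity codes and gaps are treated as missing data.
.pack_patterns <- function(aln, tip_order) {
  m <- unclass(aln)[tip_order, , drop = FALSE]
  code <- match(m, c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- -1L
  dim(code) <- dim(m)
  key <- apply(code, 2, paste, collapse = ",")
  ux <- !duplicated(key)
  list(patterns = code[, ux, drop = FALSE],
       weights = as.numeric(table(key)[key[ux]]))
}

#' Phylogenetic log-likelihood under HKY (+ discrete gamma)
#'
#' Felsenstein pruning over a rooted tree with branch lengths in expected
#' substitutions per site. Non-ACGT symbols are treated as missing data.
#'
#' @param tree rooted binary `phylo`.
#' @param aln a [dna_alignment()] covering all tips.
#' @param kappa transition/transversion ratio.
#' @param base_freqs stationary frequencies (A, C, G, T).
#' @param edge_lengths optional replacement for `tree$edge.length` (in
#'   `tree$edge` row order), used by the dating sampler.
#' @param gamma_alpha shape of the discrete-gamma site-rate distribution, or
#'   `NULL` for homogeneous rates.
#' @param gamma_categories number of rate categories.
#' @return log-likelihood (scalar).
#' @export
loglik_hky <- function(tree, aln, kappa, base_freqs, edge_lengths = NULL,
                       gamma_alpha = NULL, gamma_categories = 4L) {
  if (is.null(edge_lengths)) edge_lengths <- tree$edge.length
  tr <- ape::reorder.phylo(tree, "postorder")
  # reorder edge lengths to match the postorder edge matrix
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_po <- paste(tr$edge[, 1], tr$edge[, 2])
  el <- edge_lengths[match(key_po, key_in)]
  pk <- .pack_patterns(aln, tr$tip.label)
  rates <- if (is.null(gamma_alpha)) 1.0 else
    as.numeric(phangorn::discrete.gamma(gamma_alpha, gamma_categories))
  .loglik_hky_cpp(tr$edge, el, pk$patterns, pk$weights, kappa,
                  as.numeric(base_freqs), rates)
}
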
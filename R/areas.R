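#' Discrete geographic area system with adjacency
#'
#' Defines the biogeographic units (e.g. endemism areas of a river-basin
#' system) and which pairs of units share a border. Adjacency drives both the
#' synthetic dispersal process and the vicariance-versus-extinction rule; the
#' dispersal--vicariance optimization itself is adjacency-blind (see
#' [diva_optimize()]).
#'
#' @param labels character vector of unique area labels.
#' @param adjacency two-column matrix or data.frame of adjacent label pairs.
#'   Pairs are symmetrized; self-adjacency is an error.
#' @return An object of class `area_system`: a list with `labels` and a
#'   logical adjacency matrix `adj`.
#' @examples
#' area_system(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' @export
area_system <- function(labels, adjacency) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("area labels must be unique")
  if (length(labels) < 1L) stop("at least one area required")
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop("adjacency must have two columns")
  if (!all(adjacency %in% labels)) stop("adjacency refers to unknown areas")
  if (any(adjacency[, 1] == adjacency[, 2])) stop("adjacency must be irreflexive")
  adj <- matrix(FALSE, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (i in seq_len(nrow(adjacency))) {
    adj[adjacency[i, 1], adjacency[i, 2]] <- TRUE
    adj[adjacency[i, 2], adjacency[i, 1]] <- TRUE
  }
  structure(list(labels = labels, adj = adj), class = "area_system")
}

#' @export
print.area_system <- function(x, ...) {
  cat("Area system with", length(x$labels), "areas:",
      paste(x$labels, collapse = ", "), "\n")
  cat("Adjacent pairs:", sum(x$adj) / 2, "\n")
  invisible(x)
}

#' Linear chain of areas
#'
#' Convenience constructor for a path-graph area system (`a1 - a2 - ... - ak`),
#' the simplest geometry with non-trivial intervening areas.
#'
#' @param k number of areas.
#' @param labels optional labels (default `a1..ak`).
#' @return An `area_system`.
#' @export
chain_areas <- function(k, labels = paste0("a", seq_len(k))) {
  if (k < 2) stop("need at least 2 areas for a chain")
  area_system(labels, cbind(labels[-k], labels[-1]))
}

# Internal: igraph view of the adjacency
.area_graph <- function(areas) {
  igraph::graph_from_adjacency_matrix(areas$adj, mode = "undirected")
}

# Internal: TRUE if any area of A is adjacent to (or equal to) any area of B
.sets_touch <- function(A, B, areas) {
  if (length(intersect(A, B)) > 0) return(TRUE)
  any(areas$adj[A, B, drop = FALSE])
}
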
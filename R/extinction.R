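# The adjacency rule for postulating extinctions: where the two daughter
# ranges at a node overlap or directly neighbour each other, a vicariant
# event suffices; where they are separated, the split is explained by a
# dispersal followed by local extinction in the intervening area(s).

#' Intervening areas between two separated range sets
#'
#' The union of the interior areas of all shortest adjacency-graph paths
#' (measured in edges, at the minimal A-to-B distance) between any area of
#' `A` and any area of `B`. With `single_path = TRUE` only one deterministic
#' shortest path (the first in area-label order) contributes, for
#' minimal-extinction counting.
#'
#' @param A,B disjoint, non-adjacent, nonempty character vectors of areas.
#' @param areas an [area_system()].
#' @param single_path logical; see above.
#' @return character vector of intervening areas (possibly along several
#'   equally short corridors).
#' @export
intervening_areas <- function(A, B, areas, single_path = FALSE) {
  if (!length(A) || !length(B)) stop("empty area set")
  if (!all(c(A, B) %in% areas$labels)) stop("areas absent from the system")
  if (length(intersect(A, B))) stop("overlapping inputs: nothing intervenes")
  if (.sets_touch(A, B, areas)) stop("adjacent inputs: nothing intervenes")
  g <- .area_graph(areas)
  d <- igraph::distances(g, v = A, to = B)
  dmin <- min(d)
  if (!is.finite(dmin)) stop("no path between the two sets")
  interior <- character(0)
  for (a in A) for (b in B) {
    if (d[a, b] > dmin) next
    ps <- igraph::all_shortest_paths(g, from = a, to = b)$res
    for (p in ps) {
      nodes <- igraph::as_ids(p)
      interior <- c(interior, nodes[-c(1, length(nodes))])
      if (single_path) return(sort(unique(interior)))
    }
  }
  sort(unique(interior))
}

#' Classify a cladogenetic node: vicariance vs dispersal-with-extinction
#'
#' Applies the neighbouring-areas rule to one node given its two daughter
#' range sets: if the sets overlap or some area of one is graph-adjacent to
#' some area of the other, the split needs no extinction (vicariance);
#' otherwise it is classified dispersal-with-extinction and the intervening
#' areas are attached. When several equally optimal reconstructions are
#' supplied (lists of candidate sets per daughter) and they disagree, the
#' verdict is `"ambiguous"` with per-reconstruction verdicts attached.
#'
#' @param left_set,right_set character vectors (single reconstruction) or
#'   lists of character vectors (one per equally optimal reconstruction;
#'   combined pairwise by position if equal length, else by cross product).
#' @param areas an [area_system()].
#' @param node optional node id carried into the result.
#' @param single_path passed to [intervening_areas()].
#' @return list of class `event_classification`: `node`, `verdict`
#'   (`"vicariance"`, `"dispersal_with_extinction"` or `"ambiguous"`),
#'   `left_set`, `right_set`, `overlap`, `intervening`, and, when ambiguous,
#'   `per_reconstruction` (data.frame).
#' @export
classify_node <- function(left_set, right_set, areas, node = NA_integer_,
                          single_path = FALSE) {
  single <- function(L, R) {
    if (!length(L) || !length(R)) stop("empty daughter area set")
    if (!all(c(L, R) %in% areas$labels)) stop("areas absent from the system")
    if (.sets_touch(L, R, areas)) {
      list(verdict = "vicariance", overlap = intersect(L, R),
           intervening = character(0))
    } else {
      list(verdict = "dispersal_with_extinction",
           overlap = character(0),
           intervening = intervening_areas(L, R, areas,
                                           single_path = single_path))
    }
  }
  if (!is.list(left_set) && !is.list(right_set)) {
    r <- single(left_set, right_set)
    return(structure(list(node = node, verdict = r$verdict,
                          left_set = left_set, right_set = right_set,
                          overlap = r$overlap, intervening = r$intervening),
                     class = "event_classification"))
  }
  L <- if (is.list(left_set)) left_set else list(left_set)
  R <- if (is.list(right_set)) right_set else list(right_set)
  combos <- if (length(L) == length(R))
    lapply(seq_along(L), function(i) list(L[[i]], R[[i]]))
  else {
    cc <- expand.grid(i = seq_along(L), j = seq_along(R))
    lapply(seq_len(nrow(cc)), function(k) list(L[[cc$i[k]]], R[[cc$j[k]]]))
  }
  res <- lapply(combos, function(p) single(p[[1]], p[[2]]))
  verdicts <- vapply(res, `[[`, character(1), "verdict")
  if (length(unique(verdicts)) == 1L) {
    intv <- sort(unique(unlist(lapply(res, `[[`, "intervening"))))
    structure(list(node = node, verdict = verdicts[1],
                   left_set = L, right_set = R,
                   overlap = sort(unique(unlist(lapply(res, `[[`, "overlap")))),
                   intervening = intv),
              class = "event_classification")
  } else {
    per <- data.frame(
      left = vapply(combos, function(p) paste(p[[1]], collapse = ","), character(1)),
      right = vapply(combos, function(p) paste(p[[2]], collapse = ","), character(1)),
      verdict = verdicts)
    structure(list(node = node, verdict = "ambiguous",
                   left_set = L, right_set = R,
                   overlap = character(0), intervening = character(0),
                   per_reconstruction = per),
              class = "event_classification")
  }
}

#' @export
print.event_classification <- function(x, ...) {
  cat("Node", x$node, "verdict:", x$verdict)
  if (length(x$intervening))
    cat(" (intervening:", paste(x$intervening, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Classify every internal node of a reconstructed history
#'
#' Convenience wrapper: takes a DIVA reconstruction and applies
#' [classify_node()] at every internal node with two internal-or-tip daughter
#' ranges (using each node's equally optimal sets, so disagreements surface
#' as `"ambiguous"`).
#'
#' @param reconstruction an `area_reconstruction` from [diva_optimize()].
#' @param areas an [area_system()].
#' @param single_path passed down.
#' @return list of `event_classification` objects, one per internal node.
#' @export
classify_reconstruction <- function(reconstruction, areas, single_path = FALSE) {
  tr <- reconstruction$tree
  ntip <- ape::Ntip(tr)
  nt <- reconstruction$node_table
  sets_of <- function(v) {
    if (v <= ntip) {
      i <- which(reconstruction$canonical_events$node == v)
      return(list(strsplit(reconstruction$canonical_events$range[i], ",")[[1]]))
    }
    nt$sets[[which(nt$node == v)]]
  }
  out <- list()
  for (i in seq_len(nrow(nt))) {
    v <- nt$node[i]
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    out[[length(out) + 1L]] <- classify_node(sets_of(kids[1]),
                                             sets_of(kids[2]),
                                             areas, node = v,
                                             single_path = single_path)
  }
  out
}

#' Date postulated extinction events on the tree
#'
#' Every intervening-area extinction postulated at node `v` is assigned the
#' interval `[age(parent(v)), age(v)]`: the range must have been lost along
#' `v`'s stem branch, after the ancestral range demonstrably existed and
#' before the separated daughter ranges are observed (stem-branch
#' convention); for the root, the root age is the older bound.
#'
#' @param classifications list of `event_classification` (from
#'   [classify_node()] / [classify_reconstruction()]), with node ids referring
#'   to `dated_tree`.
#' @param dated_tree ultrametric `phylo` with branch lengths in Ma.
#' @return data.frame of class `extinction_events`: `area`, `older`,
#'   `younger`, `node`, one row per (node, intervening area).
#' @export
date_extinctions <- function(classifications, dated_tree) {
  if (is.null(dated_tree$edge.length)) stop("tree is not dated")
  ages <- .node_ages(dated_tree)
  root <- ape::Ntip(dated_tree) + 1L
  parent_of <- integer(length(ages))
  parent_of[dated_tree$edge[, 2]] <- dated_tree$edge[, 1]
  rows <- list()
  for (cl in classifications) {
    if (cl$verdict != "dispersal_with_extinction") next
    v <- cl$node
    if (is.na(v) || v > length(ages)) stop("classification node not in tree")
    younger <- ages[v]
    older <- if (v == root) ages[root] else ages[parent_of[v]]
    for (a in cl$intervening)
      rows[[length(rows) + 1L]] <- data.frame(area = a, older = older,
                                              younger = younger, node = v)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(area = character(), older = numeric(), younger = numeric(),
               node = integer())
  class(out) <- c("extinction_events", class(out))
  out
}
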
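# Event-based dispersal-vicariance (DIVA) optimization.
#
# Area sets are bitmasks over the area universe (exact subset dynamic
# program, practical for up to ~10-12 areas; masks support up to 16).
# Event costs: dispersal (area gained along a branch) and extinction (area
# lost along a branch) cost 1 per area; at a speciation the ancestral set is
# inherited at cost 0 by vicariance (disjoint nonempty bipartition),
# duplication (single-area ancestor copied to both daughters) or, unless
# `strict = TRUE`, a sympatric-subset split (one daughter keeps the full set,
# the other any nonempty subset).

.popcount16 <- local({
  tab <- vapply(0:65535, function(x) sum(bitwAnd(x, 2^(0:15)) > 0), numeric(1))
  function(x) tab[x + 1L]
})

# Internal: ordered inheritance pairs (list of 2-col matrix) for ancestral
# mask D at zero cost
.diva_splits <- function(D, strict) {
  pc <- .popcount16(D)
  if (pc == 1L) return(matrix(c(D, D), 1L, 2L))
  out <- list()
  # vicariance: ordered disjoint bipartitions
  sub <- bitwAnd(D - 1L, D)
  while (sub > 0L) {
    out[[length(out) + 1L]] <- c(sub, bitwXor(D, sub))
    sub <- bitwAnd(sub - 1L, D)
  }
  if (!strict) {
    # sympatric subset: one daughter = D, the other any nonempty subset
    sub <- D
    while (sub > 0L) {
      out[[length(out) + 1L]] <- c(D, sub)
      if (sub != D) out[[length(out) + 1L]] <- c(sub, D)
      sub <- bitwAnd(sub - 1L, D)
    }
  }
  do.call(rbind, out)
}

# Internal: normalise tip areas to a named list of character vectors
.norm_tip_areas <- function(tip_areas, tips) {
  if (is.character(tip_areas))
    tip_areas <- lapply(strsplit(tip_areas, ",", fixed = TRUE), trimws)
  missing <- setdiff(tips, names(tip_areas))
  if (length(missing)) stop("tips without area data: ",
                            paste(missing, collapse = ", "))
  if (any(lengths(tip_areas[tips]) == 0)) stop("tip with empty area set")
  tip_areas[tips]
}

#' Dispersal-vicariance ancestral-area optimization
#'
#' Sankoff-style dynamic program over all nonempty area sets of size at most
#' `maxareas`, minimising the number of dispersal and extinction events (one
#' per area gained or lost along a branch; vicariance and duplication are
#' free). Returns, per internal node, every ancestral set attained by at
#' least one globally minimum-cost reconstruction, with a uniform frequency
#' over those sets, plus the global minimal cost. Adjacency between areas is
#' deliberately not consulted (classic DIVA is adjacency-blind); geography
#' enters later via the extinction rule (see [classify_node()]).
#'
#' @param tree rooted binary `phylo`.
#' @param tip_areas named list of character vectors (or named character
#'   vector of comma-joined labels): tip -> occupied areas.
#' @param maxareas maximum ancestral set size; default = number of areas.
#' @param area_labels optional explicit area universe (default: union of tip
#'   areas, sorted).
#' @param strict if `TRUE`, disallow the zero-cost sympatric-subset
#'   inheritance for multi-area ancestors (vicariance/duplication only).
#' @return Object of class `area_reconstruction`: list with `total_cost`,
#'   `area_labels`, `maxareas`, `node_table` (one row per internal node:
#'   `node`, `clade` (sorted tip labels, comma-joined), `sets` (list of
#'   character vectors), `frequencies` (uniform, summing to 1)), and
#'   `canonical_events` (stem dispersal/extinction counts of one
#'   deterministically chosen optimal reconstruction).
#' @export
diva_optimize <- function(tree, tip_areas, maxareas = NULL,
                          area_labels = NULL, strict = FALSE) {
  ntip <- ape::Ntip(tree)
  tip_areas <- .norm_tip_areas(tip_areas, tree$tip.label)
  if (is.null(area_labels))
    area_labels <- sort(unique(unlist(tip_areas)))
  if (!all(unlist(tip_areas) %in% area_labels))
    stop("tip areas outside the area universe")
  A <- length(area_labels)
  if (A > 16) stop("more than 16 areas not supported by the subset DP")
  if (is.null(maxareas)) maxareas <- A
  if (maxareas < 1 || maxareas > A) stop("maxareas must be in 1..", A)
  largest_tip <- max(lengths(tip_areas))
  if (maxareas < largest_tip)
    stop("maxareas (", maxareas, ") below the largest tip set (",
         largest_tip, ")")

  masks <- seq_len(2^A - 1L)
  pc <- .popcount16(masks)
  valid <- masks[pc <= maxareas]
  nmask <- length(masks)
  to_mask <- function(v) sum(2L^(match(v, area_labels) - 1L))
  to_areas <- function(m) area_labels[bitwAnd(m, 2L^(seq_len(A) - 1L)) > 0]

  tr <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tr$Nnode
  root <- ntip + 1L
  kids <- split(tr$edge[, 2], factor(tr$edge[, 1], levels = seq_len(nn)))
  parent_of <- integer(nn); parent_of[tr$edge[, 2]] <- tr$edge[, 1]

  INF <- 1e9
  inside <- matrix(INF, nn, nmask)
  for (i in seq_len(ntip)) inside[i, to_mask(tip_areas[[i]])] <- 0
  # rows of tr$edge in postorder give children before parents
  M <- vector("list", nn) # M[[child]][S] = min_C sd(S, C) + inside[child, C]
  splits_cache <- lapply(valid, .diva_splits, strict = strict)
  names(splits_cache) <- valid

  min_transition <- function(child) {
    ins <- inside[child, ]
    fin <- which(ins < INF)
    out <- rep(INF, nmask)
    for (S in masks) {
      out[S] <- min(.popcount16(bitwXor(S, fin)) + ins[fin])
    }
    out
  }

  internal_po <- unique(tr$edge[, 1]) # postorder: children before parents
  for (v in internal_po) {
    ch <- kids[[v]]
    for (cchild in ch) if (is.null(M[[cchild]])) M[[cchild]] <- min_transition(cchild)
    Ml <- M[[ch[1]]]; Mr <- M[[ch[2]]]
    for (D in valid) {
      sp <- splits_cache[[as.character(D)]]
      inside[v, D] <- min(Ml[sp[, 1]] + Mr[sp[, 2]])
    }
  }
  G <- min(inside[root, valid])

  # outside pass (preorder)
  outside <- matrix(INF, nn, nmask)
  outside[root, valid] <- 0
  for (v in rev(internal_po)) {
    ch <- kids[[v]]
    for (side in 1:2) {
      cchild <- ch[side]; sib <- ch[3 - side]
      Ms <- M[[sib]]
      # O1[S] = min over D, splits with this child's side = S
      O1 <- rep(INF, nmask)
      for (D in valid) {
        if (outside[v, D] >= INF) next
        sp <- splits_cache[[as.character(D)]]
        Sc <- sp[, side]; Ss <- sp[, 3 - side]
        cand <- outside[v, D] + Ms[Ss]
        upd <- cand < O1[Sc]
        if (any(upd)) {
          for (r in which(upd)) O1[Sc[r]] <- min(O1[Sc[r]], cand[r])
        }
      }
      fin <- which(O1 < INF)
      oc <- rep(INF, nmask)
      for (C in masks)
        oc[C] <- min(O1[fin] + .popcount16(bitwXor(C, fin)))
      outside[cchild, ] <- oc
    }
  }

  clade_tips <- function(v) {
    if (v <= ntip) return(tr$tip.label[v])
    sort(tr$tip.label[Filter(function(x) x <= ntip, .descendants(tr, v))])
  }
  internal_nodes <- (ntip + 1L):nn
  node_rows <- lapply(internal_nodes, function(v) {
    opt <- valid[inside[v, valid] + outside[v, valid] == G]
    sets <- lapply(opt, to_areas)
    list(node = v, clade = paste(clade_tips(v), collapse = ","),
         sets = sets, frequencies = rep(1 / length(sets), length(sets)))
  })
  node_table <- data.frame(
    node = vapply(node_rows, `[[`, integer(1), "node"),
    clade = vapply(node_rows, `[[`, character(1), "clade"))
  node_table$sets <- lapply(node_rows, `[[`, "sets")
  node_table$frequencies <- lapply(node_rows, `[[`, "frequencies")

  # canonical optimal reconstruction (deterministic backtrack) for event
  # decomposition per stem branch
  choice <- integer(nn)
  choice[root] <- valid[which(inside[root, valid] == G)[1]]
  ev_rows <- list()
  for (v in rev(internal_po)) {
    D <- choice[v]
    ch <- kids[[v]]
    sp <- splits_cache[[as.character(D)]]
    tot <- M[[ch[1]]][sp[, 1]] + M[[ch[2]]][sp[, 2]]
    r <- which(tot == inside[v, D])[1]
    for (side in 1:2) {
      S <- sp[r, side]; cchild <- ch[side]
      fin <- which(inside[cchild, ] < INF)
      costs <- .popcount16(bitwXor(S, fin)) + inside[cchild, fin]
      C <- fin[which(costs == M[[cchild]][S])[1]]
      choice[cchild] <- C
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        node = cchild,
        inherited = paste(to_areas(S), collapse = ","),
        range = paste(to_areas(C), collapse = ","),
        dispersals = .popcount16(bitwAnd(C, bitwNot(S))),
        extinctions = .popcount16(bitwAnd(S, bitwNot(C))))
    }
  }
  canonical_events <- do.call(rbind, ev_rows)

  structure(list(total_cost = G, area_labels = area_labels,
                 maxareas = maxareas, strict = strict,
                 node_table = node_table,
                 canonical_events = canonical_events, tree = tr),
            class = "area_reconstruction")
}

#' @export
print.area_reconstruction <- function(x, ...) {
  cat("DIVA reconstruction: total cost", x$total_cost, "with maxareas",
      x$maxareas, "\n")
  for (i in seq_len(nrow(x$node_table))) {
    sets <- vapply(x$node_table$sets[[i]], paste, character(1), collapse = "")
    cat(sprintf("  node %d [%s]: %s\n", x$node_table$node[i],
                x$node_table$clade[i], paste(sets, collapse = " | ")))
  }
  invisible(x)
}

#' S-DIVA frequencies over a sample of trees
#'
#' Runs [diva_optimize()] on every tree, matches internal nodes across trees
#' by their clade (tip bipartition), and averages each tree's uniform
#' distribution over equally parsimonious sets. Frequencies are weighted by
#' bipartition occurrence: at a clade present in a fraction f of the trees,
#' the set frequencies sum to f.
#'
#' @param trees list of rooted `phylo` objects (or a `multiPhylo`) sharing one
#'   tip set.
#' @param tip_areas as in [diva_optimize()].
#' @param maxareas as in [diva_optimize()].
#' @param ... passed to [diva_optimize()].
#' @return data.frame: `clade`, `occurrence` (fraction of trees containing the
#'   clade), `set` (comma-joined areas), `frequency`.
#' @export
sdiva_frequencies <- function(trees, tip_areas, maxareas = NULL, ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree sample")
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(tipsets)) != 1L) stop("trees must share one tip set")
  n <- length(trees)
  acc <- list() # clade -> named numeric (set string -> freq sum)
  occ <- list()
  for (tr in trees) {
    rec <- diva_optimize(tr, tip_areas, maxareas, ...)
    for (i in seq_len(nrow(rec$node_table))) {
      clade <- rec$node_table$clade[i]
      sets <- vapply(rec$node_table$sets[[i]], paste, character(1),
                     collapse = ",")
      fr <- rec$node_table$frequencies[[i]]
      cur <- acc[[clade]]
      if (is.null(cur)) cur <- setNames(numeric(0), character(0))
      for (j in seq_along(sets))
        cur[sets[j]] <- (if (sets[j] %in% names(cur)) cur[sets[j]] else 0) + fr[j]
      acc[[clade]] <- cur
      occ[[clade]] <- (if (is.null(occ[[clade]])) 0 else occ[[clade]]) + 1L
    }
  }
  rows <- lapply(names(acc), function(cl) {
    data.frame(clade = cl, occurrence = occ[[cl]] / n,
               set = names(acc[[cl]]),
               frequency = as.numeric(acc[[cl]]) / n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of the reconstruction to the 'maxareas' constraint
#'
#' Re-runs the optimization under each requested `maxareas` value and reports,
#' per internal node, whether the optimal ancestral sets agree across all
#' (admissible) settings; where they differ the per-setting alternatives are
#' listed. Settings smaller than the largest tip set are inadmissible and
#' reported as skipped.
#'
#' @param tree rooted binary `phylo`.
#' @param tip_areas as in [diva_optimize()].
#' @param maxareas_values integer vector of settings (>= 2 values).
#' @param ... passed to [diva_optimize()].
#' @return list of class `maxareas_report`: `settings_used`,
#'   `settings_skipped`, `costs` (named total costs), and `node_table`
#'   (per node: `clade`, `agree`, one column per setting with the sets).
#' @export
maxareas_sensitivity <- function(tree, tip_areas, maxareas_values, ...) {
  if (length(maxareas_values) < 2) stop("need at least 2 maxareas settings")
  runs <- list(); skipped <- integer(0)
  for (m in sort(unique(maxareas_values))) {
    r <- tryCatch(diva_optimize(tree, tip_areas, maxareas = m, ...),
                  error = function(e) e)
    if (inherits(r, "error")) skipped <- c(skipped, m) else
      runs[[as.character(m)]] <- r
  }
  if (!length(runs)) stop("no admissible maxareas setting")
  set_strings <- function(rec, i)
    sort(vapply(rec$node_table$sets[[i]], paste, character(1), collapse = ","))
  base <- runs[[1]]
  nt <- data.frame(node = base$node_table$node, clade = base$node_table$clade)
  for (m in names(runs))
    nt[[paste0("maxareas_", m)]] <- vapply(seq_len(nrow(nt)), function(i)
      paste(set_strings(runs[[m]], i), collapse = " | "), character(1))
  setcols <- grep("^maxareas_", names(nt))
  nt$agree <- apply(nt[, setcols, drop = FALSE], 1,
                    function(r) length(unique(r)) == 1L)
  structure(list(settings_used = as.integer(names(runs)),
                 settings_skipped = skipped,
                 costs = vapply(runs, `[[`, numeric(1), "total_cost"),
                 node_table = nt),
            class = "maxareas_report")
}

#' @export
print.maxareas_report <- function(x, ...) {
  cat("maxareas sensitivity over settings",
      paste(x$settings_used, collapse = ", "),
      if (length(x$settings_skipped))
        paste0("(skipped: ", paste(x$settings_skipped, collapse = ", "), ")")
      else "", "\n")
  cat("Nodes in agreement:", sum(x$node_table$agree), "of",
      nrow(x$node_table), "\n")
  invisible(x)
}
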
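# Sea-level curves, elevation grids and concordance between dated intervals
# and high sea-level stands.

#' Sea-level curve
#'
#' @param age numeric vector of ages (Ma), strictly increasing.
#' @param level sea level (m relative to present) at each age.
#' @return data.frame of class `sealevel_curve`.
#' @export
sealevel_curve <- function(age, level) {
  if (length(age) != length(level)) stop("age and level lengths differ")
  if (any(diff(age) <= 0)) stop("ages must be strictly increasing")
  if (any(!is.finite(level))) stop("levels must be finite")
  structure(data.frame(age = age, level = level),
            class = c("sealevel_curve", "data.frame"))
}

#' Read a sea-level curve from CSV
#'
#' Expects columns `age` (Ma) and `level` (m); rows are sorted by age.
#'
#' @param path CSV path.
#' @return a [sealevel_curve()].
#' @examples
#' curve <- read_sealevel_csv(system.file("extdata", "sealevel_synthetic.csv",
#'                                        package = "pdmvic"))
#' extract_highstands(curve, 60)
#' @export
read_sealevel_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  df <- df[order(df$age), ]
  sealevel_curve(df$age, df$level)
}

#' Extract high-stand intervals from a sea-level curve
#'
#' Linearly interpolates the curve and returns the disjoint age intervals on
#' which the level is at or above `threshold`, with threshold-crossing ages
#' solved exactly on the segments. A curve lying entirely at the threshold
#' yields one full-domain interval.
#'
#' @param curve a [sealevel_curve()] (>= 2 points).
#' @param threshold sea level (m) defining a high stand.
#' @return data.frame of class `highstand_intervals` with `older`, `younger`
#'   (Ma, `older >= younger`), ordered from old to young, disjoint.
#' @export
extract_highstands <- function(curve, threshold) {
  if (nrow(curve) < 2) stop("need at least 2 curve points")
  age <- curve$age; lev <- curve$level
  above <- lev >= threshold
  bounds <- list()
  open_from <- if (above[1]) age[1] else NULL
  for (i in seq_len(length(age) - 1L)) {
    a1 <- age[i]; a2 <- age[i + 1]; l1 <- lev[i]; l2 <- lev[i + 1]
    if (above[i] == above[i + 1]) next
    tcross <- a1 + (threshold - l1) * (a2 - a1) / (l2 - l1)
    if (above[i]) { # falls below at tcross
      bounds[[length(bounds) + 1L]] <- c(open_from, tcross)
      open_from <- NULL
    } else open_from <- tcross
  }
  if (!is.null(open_from))
    bounds[[length(bounds) + 1L]] <- c(open_from, age[length(age)])
  if (!length(bounds))
    out <- data.frame(older = numeric(0), younger = numeric(0))
  else {
    m <- do.call(rbind, bounds)
    # stored young->old along the age axis; report as [older, younger]
    out <- data.frame(older = m[, 2], younger = m[, 1])
    out <- out[order(-out$older), ]
    rownames(out) <- NULL
  }
  class(out) <- c("highstand_intervals", class(out))
  out
}

#' Elevation grid (DEM)
#'
#' @param z numeric matrix of elevations (m a.s.l.); `NA` = no data.
#' @param cellsize grid cell size (arbitrary units).
#' @param nodata no-data marker used on write.
#' @return list of class `dem_grid`.
#' @export
dem_grid <- function(z, cellsize = 1, nodata = -9999) {
  if (!is.matrix(z) || !is.numeric(z)) stop("z must be a numeric matrix")
  structure(list(z = z, cellsize = cellsize, nodata = nodata),
            class = "dem_grid")
}

#' Read an ESRI-style ASCII grid
#'
#' Parses the plain-text header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by whitespace-separated rows, top row
#' first.
#'
#' @param path file path.
#' @return a [dem_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  z[z == nodata] <- NA
  dem_grid(z, cellsize = if (!is.null(hdr$cellsize)) hdr$cellsize else 1,
           nodata = nodata)
}

#' Write an ESRI-style ASCII grid
#'
#' @param grid a [dem_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  z <- grid$z
  z[is.na(z)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(z)), paste("nrows", nrow(z)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", grid$cellsize),
               paste("NODATA_value", grid$nodata)), con)
  for (r in seq_len(nrow(z))) writeLines(paste(z[r, ], collapse = " "), con)
  invisible(path)
}

#' Classify an elevation grid into three habitat categories
#'
#' Class 1: elevation below `sea_cut` (land flooded by the high stands the
#' study simulates); class 2: `sea_cut` up to and including `upland_cut`
#' (habitable lowland; the upper limit reflects the altitudinal ceiling of
#' the fish fauna); class 3: above `upland_cut` (uninhabitable upland). The
#' boundary handling is deliberately literal: `< sea_cut`, `<= upland_cut`,
#' `> upland_cut`.
#'
#' @param grid a [dem_grid()].
#' @param sea_cut flooded-land cutoff, m (default 60).
#' @param upland_cut upland cutoff, m (default 1000).
#' @return list of class `dem_classification`: `classes` (integer matrix with
#'   `NA` preserved) and `counts` (named cell counts).
#' @export
classify_dem <- function(grid, sea_cut = 60, upland_cut = 1000) {
  if (sea_cut >= upland_cut) stop("sea_cut must be below upland_cut")
  z <- grid$z
  if (all(is.na(z))) stop("all-no-data grid")
  cl <- ifelse(z < sea_cut, 1L, ifelse(z <= upland_cut, 2L, 3L))
  counts <- setNames(tabulate(cl, 3L),
                     c("below_sea_cut", "lowland", "upland"))
  structure(list(classes = cl, counts = counts,
                 sea_cut = sea_cut, upland_cut = upland_cut),
            class = "dem_classification")
}

#' Connectivity of habitable land at a given sea level
#'
#' Habitable cells are those with `sea_level <= elevation <= upland_cut`.
#' Connected components are computed under 4-connectivity by default
#' (lowland corridors are edge-sharing; diagonal touch does not connect), or
#' 8-connectivity on request.
#'
#' @param grid a [dem_grid()].
#' @param sea_level current sea level, m.
#' @param upland_cut upland cutoff, m.
#' @param connectivity 4 or 8.
#' @return list: `n_components`, `sizes` (descending cell counts).
#' @export
habitat_connectivity <- function(grid, sea_level, upland_cut = 1000,
                                 connectivity = 4) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  z <- grid$z
  hab <- !is.na(z) & z >= sea_level & z <= upland_cut
  idx <- which(hab)
  if (!length(idx)) return(list(n_components = 0L, sizes = integer(0)))
  nr <- nrow(z); nc <- ncol(z)
  id <- matrix(0L, nr, nc); id[idx] <- seq_along(idx)
  edges <- list()
  rc <- arrayInd(idx, dim(z))
  offs <- rbind(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- rbind(offs, c(1, 1), c(1, -1))
  for (k in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs[k, 1]; c2 <- rc[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- hab[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges[[length(edges) + 1L]] <-
        cbind(id[idx[ok]], id[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  list(n_components = as.integer(comp$no),
       sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Concordance between dated intervals and high sea-level stands
#'
#' Measures the overlap fraction (summed overlap length over summed target
#' length) between a set of target intervals (e.g. dated extinction windows)
#' and the high-stand intervals, and attaches a one-tailed permutation
#' p-value: each target interval is repositioned uniformly at random
#' (length-preserving) within `[0, root_bound]` and the fraction of null
#' overlap fractions at least as large as the observed one is reported. The
#' permutation test formalizes what is otherwise a visual correspondence
#' claim and is reported alongside, never instead of, the raw overlap.
#'
#' @param targets data.frame with columns `older`, `younger` (Ma).
#' @param highstands a `highstand_intervals` data.frame (or any data.frame
#'   with `older`/`younger`).
#' @param n_perm number of permutations (>= 100).
#' @param root_bound upper age bound (Ma) for random repositioning.
#' @param seed integer seed.
#' @return list of class `concordance_test`: `overlap_fraction`,
#'   `overlap_length`, `target_length`, `p_value`, `null_mean`, `n_perm`.
#' @export
interval_concordance <- function(targets, highstands, n_perm = 1000L,
                                 root_bound, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!nrow(targets)) stop("no target intervals")
  if (any(targets$older < targets$younger)) stop("older must be >= younger")
  if (any(targets$older > root_bound) || any(targets$younger < 0))
    stop("targets must lie within [0, root_bound]")
  set.seed(seed)
  ov_len <- function(t_old, t_young) {
    s <- 0
    for (i in seq_len(nrow(highstands)))
      s <- s + sum(pmax(0, pmin(t_old, highstands$older[i]) -
                           pmax(t_young, highstands$younger[i])))
    s
  }
  tlen <- sum(targets$older - targets$younger)
  if (tlen == 0) stop("zero total target length")
  obs <- ov_len(targets$older, targets$younger) / tlen
  lens <- targets$older - targets$younger
  null <- replicate(n_perm, {
    y <- runif(length(lens), 0, root_bound - lens)
    ov_len(y + lens, y) / tlen
  })
  structure(list(overlap_fraction = obs,
                 overlap_length = obs * tlen,
                 target_length = tlen,
                 p_value = mean(null >= obs - 1e-12),
                 null_mean = mean(null), n_perm = n_perm),
            class = "concordance_test")
}

#' @export
print.concordance_test <- function(x, ...) {
  cat(sprintf(paste0("Interval concordance: overlap fraction %.3f ",
                     "(null mean %.3f, one-tailed p = %.4g, %d permutations)\n"),
              x$overlap_fraction, x$null_mean, x$p_value, x$n_perm))
  invisible(x)
}
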
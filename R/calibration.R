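#' Node-age calibration constraint
#'
#' A normal prior (truncated at 0 Ma) on the age of the most recent common
#' ancestor of a set of tips.
#'
#' @param name short identifier.
#' @param mean,sd prior mean and standard deviation, Ma (`sd > 0`).
#' @param tips character vector of tip labels whose MRCA is constrained, or
#'   `NULL` for an unbound constraint (bind later with [bind_calibrations()]).
#' @return list of class `calibration`.
#' @export
calibration <- function(name, mean, sd, tips = NULL) {
  .check_scalar(mean, "mean", lower = 0)
  .check_scalar(sd, "sd")
  if (sd <= 0) stop("sd must be positive")
  structure(list(name = name, mean = mean, sd = sd, tips = tips),
            class = "calibration")
}

#' The five alternative calibration schemes
#'
#' Builds one of the five published calibration schemes for dating a Middle
#' American cichlid mitochondrial phylogeny:
#' \describe{
#'   \item{I}{fossil *Plesioheros chauliodus* (mean 44.25 Ma, SD 2.7) +
#'     Cuba--Hispaniola separation (22.5, 1.5) + Orinoco--Magdalena basin
#'     separation (10.95, 0.6).}
#'   \item{II}{scheme I without the fossil constraint.}
#'   \item{III}{the fossil constraint only.}
#'   \item{IV}{secondary calibration on the *Caquetaia* split (23, 2).}
#'   \item{V}{the geological Punta del Morro constraint only (mean 7.5 Ma;
#'     the source gives no SD, default 0.5, overridable via `pdm_sd`).}
#' }
#' Constraints are returned unbound; attach MRCA tip sets for a concrete
#' topology with [bind_calibrations()].
#'
#' @param id `"I"`, `"II"`, `"III"`, `"IV"` or `"V"`.
#' @param pdm_sd prior SD for the Punta del Morro constraint in scheme V.
#' @return list of class `calibration_scheme`: `id` plus a list `constraints`
#'   of [calibration()] objects.
#' @export
build_calibration_scheme <- function(id, pdm_sd = 0.5) {
  id <- as.character(id)
  fossil <- calibration("fossil_plesioheros", 44.25, 2.7)
  cuba <- calibration("cuba_hispaniola", 22.5, 1.5)
  orinoco <- calibration("orinoco_magdalena", 10.95, 0.6)
  caquetaia <- calibration("caquetaia_split", 23, 2)
  pdm <- calibration("punta_del_morro", 7.5, pdm_sd)
  constraints <- switch(id,
    I = list(fossil, cuba, orinoco),
    II = list(cuba, orinoco),
    III = list(fossil),
    IV = list(caquetaia),
    V = list(pdm),
    stop("unknown calibration scheme id: ", id))
  structure(list(id = id, constraints = constraints),
            class = "calibration_scheme")
}

#' Bind calibration constraints to MRCA tip sets
#'
#' @param scheme a `calibration_scheme`.
#' @param tips named list: constraint name -> character vector of tip labels.
#'   Every constraint of the scheme must be present.
#' @return The scheme with tip sets attached.
#' @export
bind_calibrations <- function(scheme, tips) {
  for (i in seq_along(scheme$constraints)) {
    nm <- scheme$constraints[[i]]$name
    if (is.null(tips[[nm]]))
      stop("no tip set supplied for constraint '", nm, "'")
    scheme$constraints[[i]]$tips <- tips[[nm]]
  }
  scheme
}

#' Construct an ad-hoc calibration scheme
#'
#' For synthetic experiments where the calibrations are placed at known true
#' node ages rather than at published geological events.
#'
#' @param ... [calibration()] objects.
#' @param id scheme identifier.
#' @return A `calibration_scheme`.
#' @export
calibration_scheme <- function(..., id = "custom") {
  constraints <- list(...)
  stopifnot(all(vapply(constraints, inherits, logical(1), "calibration")))
  structure(list(id = id, constraints = constraints),
            class = "calibration_scheme")
}

#' @export
print.calibration_scheme <- function(x, ...) {
  cat("Calibration scheme", x$id, "with", length(x$constraints),
      "constraint(s):\n")
  for (co in x$constraints)
    cat(sprintf("  %-20s N(%g, %g) Ma%s\n", co$name, co$mean, co$sd,
                if (is.null(co$tips)) "  [unbound]" else ""))
  invisible(x)
}

# Internal: resolve constraints to node ids on a topology
.resolve_calibrations <- function(scheme, tree) {
  vapply(scheme$constraints, function(co) {
    if (is.null(co$tips)) stop("constraint '", co$name, "' is unbound")
    missing <- setdiff(co$tips, tree$tip.label)
    if (length(missing)) stop("constraint '", co$name,
                              "' refers to unknown tips: ",
                              paste(missing, collapse = ", "))
    if (length(co$tips) == 1L) stop("constraint '", co$name,
                                    "' needs >= 2 tips to define an MRCA")
    ape::getMRCA(tree, co$tips)
  }, integer(1))
}
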
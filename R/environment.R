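#' Centred deme positions for an M-deme habitat
#'
#' Positions run from -(M/2 - 1) to M/2 for even M (e.g. -109..110 for
#' M = 220), and are centred analogously for odd M.
#'
#' @param M number of demes.
#' @return Integer vector of length M.
#' @export
demePositions <- function(M) {
  M <- as.integer(M)
  seq.int(-(M %/% 2L - 1L) - (M %% 2L), M %/% 2L)
}

newProfile <- function(positions, theta, kind, pars = list()) {
  new("EnvironmentProfile", positions = as.integer(positions),
      theta = as.numeric(theta), kind = kind, pars = pars)
}

#' Spatially steepening gradient of phenotypic optima
#'
#' Default family theta(x) = a * sinh(x / s): odd-symmetric about the
#' habitat centre, near-linear (slope a/s) at the centre, and increasingly
#' steep towards the edges. Defaults for the full 220-deme habitat anchor
#' the edge optimum (deme position 110) at 162.54 with s = 20; for other
#' habitat sizes, pass explicit shape parameters (see the methods vignette
#' for the scaled defaults used in tests).
#'
#' @param M number of demes (even).
#' @param a scale parameter (> 0), trait units.
#' @param s steepness length scale (> 0), demes.
#' @return An [EnvironmentProfile-class] of kind "steepening".
#' @examples
#' env <- steepeningProfile(220)
#' max(thetaOf(env))  # 162.54 at position 110
#' @export
steepeningProfile <- function(M, a = 162.54 / sinh(110 / s), s = 20) {
  force(s); force(a)
  if (!(a > 0) || !(s > 0)) stop("shape parameters a and s must be > 0")
  x <- demePositions(M)
  newProfile(x, a * sinh(x / s), "steepening", list(a = a, s = s))
}

#' Linearly changing gradient of phenotypic optima
#'
#' theta_i = b * x_i with x the centred deme position.
#'
#' @param M number of demes.
#' @param b slope (trait units per deme).
#' @return An [EnvironmentProfile-class] of kind "linear".
#' @export
linearProfile <- function(M, b) {
  x <- demePositions(M)
  newProfile(x, b * x, "linear", list(b = b))
}

#' User-tabulated profile
#'
#' @param positions integer deme positions.
#' @param theta optimal phenotype per deme.
#' @return An [EnvironmentProfile-class] of kind "table".
#' @export
tableProfile <- function(positions, theta) {
  newProfile(positions, theta, "table", list())
}

#' Fit shape parameters of a profile family to anchor points
#'
#' Least-squares fit of the chosen family to (deme position, theta) anchor
#' pairs; exact when the anchors are consistent with the family. For the
#' sinh family either both (a, s) are free, or s may be fixed, in which
#' case a has the closed form a = sum(th * sinh(x/s)) / sum(sinh(x/s)^2).
#'
#' @param anchors data.frame or matrix with columns (position, theta).
#' @param family "steepening" (sinh) or "linear".
#' @param s optional fixed steepness scale for the sinh family.
#' @return Named list of fitted shape parameters.
#' @examples
#' calibrateProfile(cbind(c(0, 110), c(0, 162.54)), "steepening", s = 20)
#' @export
calibrateProfile <- function(anchors, family = c("steepening", "linear"),
                             s = NULL) {
  family <- match.arg(family)
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 2L) stop("anchors must have two columns (position, theta)")
  x <- anchors[, 1]; th <- anchors[, 2]
  if (family == "linear") {
    if (all(x == 0)) stop("degenerate anchors: all positions zero")
    return(list(b = sum(th * x) / sum(x * x)))
  }
  fitA <- function(s) {
    sx <- sinh(x / s)
    if (all(sx == 0)) stop("degenerate anchors for the sinh family")
    sum(th * sx) / sum(sx * sx)
  }
  if (!is.null(s)) return(list(a = fitA(s), s = s))
  useful <- sum(x != 0)
  if (useful < 2L) stop("need >= 2 nonzero-position anchors to fit (a, s)")
  sse <- function(ls) {
    s <- exp(ls); a <- fitA(s); sum((th - a * sinh(x / s))^2)
  }
  opt <- stats::optimize(sse, interval = log(c(max(abs(x)) / 200, max(abs(x)) * 50)),
                         tol = 1e-12)
  s <- exp(opt$minimum)
  list(a = fitA(s), s = s)
}

#' @rdname steepeningProfile
#' @param object an `EnvironmentProfile`.
#' @export
thetaOf <- function(object) object@theta

#' Theta at given 1-based deme indices
#' @param object an `EnvironmentProfile`.
#' @param deme integer 1-based deme indices.
#' @export
thetaAt <- function(object, deme) object@theta[deme]

#' @rdname steepeningProfile
#' @export
profileKind <- function(object) object@kind

setMethod("show", "EnvironmentProfile", function(object) {
  cat(sprintf("EnvironmentProfile (%s): %d demes, positions %d..%d, theta [%.4g, %.4g]\n",
              object@kind, length(object@theta), min(object@positions),
              max(object@positions), min(object@theta), max(object@theta)))
})

#' Read / write a tabulated profile as two-column delimited text
#'
#' @param object an `EnvironmentProfile` (for writing).
#' @param path file path.
#' @return `readProfile` returns an [EnvironmentProfile-class] of kind
#'   "table"; `writeProfile` invisibly returns the path.
#' @export
writeProfile <- function(object, path) {
  utils::write.table(
    data.frame(deme_position = object@positions,
               theta = sprintf("%.17g", object@theta)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  tableProfile(tab$deme_position, tab$theta)
}
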
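#' Construct simulation parameters
#'
#' All arguments default to the headline study design (see
#' [SimParams-class]). `effectG` defaults to `2 / nLoci`, which at the
#' default L = 799 is 0.0025 to four decimals.
#'
#' @param nDemes number of demes M.
#' @param carryingCapacity local carrying capacity K.
#' @param growthRate maximal intrinsic growth rate r_m.
#' @param selectionWidth width of stabilizing selection V_S.
#' @param mutationRate per-allele-copy mutation probability mu.
#' @param nLoci loci per trait component L.
#' @param effectZ allele substitution effect alpha for the nonplastic
#'   component (per-allele effects are +/- alpha/2).
#' @param effectG allele substitution effect beta for plasticity.
#' @param dispersalSd dispersal kernel standard deviation sigma (demes).
#' @param costShape plasticity cost shape gamma.
#' @param costScale plasticity cost scale delta.
#' @param nGenerations generations to simulate T.
#' @param seed integer base seed.
#' @return A validated [SimParams-class] object.
#' @examples
#' p <- simParams()
#' effectG(p)           # 2/799
#' simParams(nDemes = 40, nLoci = 50)
#' @export
simParams <- function(nDemes = 220L,
                      carryingCapacity = 100L,
                      growthRate = 2,
                      selectionWidth = 2,
                      mutationRate = 1e-6,
                      nLoci = 799L,
                      effectZ = 0.1,
                      effectG = 2 / nLoci,
                      dispersalSd = 1,
                      costShape = 0.5,
                      costScale = 0.5,
                      nGenerations = 100000L,
                      seed = 1L) {
  new("SimParams",
      nDemes = as.integer(nDemes),
      carryingCapacity = as.integer(carryingCapacity),
      growthRate = as.numeric(growthRate),
      selectionWidth = as.numeric(selectionWidth),
      mutationRate = as.numeric(mutationRate),
      nLoci = as.integer(nLoci),
      effectZ = as.numeric(effectZ),
      effectG = as.numeric(effectG),
      dispersalSd = as.numeric(dispersalSd),
      costShape = as.numeric(costShape),
      costScale = as.numeric(costScale),
      nGenerations = as.integer(nGenerations),
      seed = as.integer(seed))
}

#' @rdname simParams
#' @param object,x a `SimParams` object.
#' @export
nDemes <- function(object) object@nDemes
#' @rdname simParams
#' @export
carryingCapacity <- function(object) object@carryingCapacity
#' @rdname simParams
#' @export
nLoci <- function(object) object@nLoci
#' @rdname simParams
#' @export
effectZ <- function(object) object@effectZ
#' @rdname simParams
#' @export
effectG <- function(object) object@effectG

setMethod("show", "SimParams", function(object) {
  cat("SimParams:",
      sprintf("M=%d K=%d r_m=%g V_S=%g mu=%g", object@nDemes,
              object@carryingCapacity, object@growthRate,
              object@selectionWidth, object@mutationRate),
      sprintf("L=%d alpha=%g beta=%g sigma=%g gamma=%g delta=%g T=%d seed=%d",
              object@nLoci, object@effectZ, object@effectG,
              object@dispersalSd, object@costShape, object@costScale,
              object@nGenerations, object@seed),
      sep = "\n  ")
})

# Deterministic per-stage seed stream: one user-facing seed is expanded into
# independent sub-seeds so adding realizations to a later stage never
# perturbs an earlier one. Kept below 2^31.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}
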
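#' @import methods
NULL

#' Simulation parameters
#'
#' Container for every constant of the individual-based model plus run
#' controls. Defaults are the headline parameterization of the study design:
#' a 220-deme habitat at carrying capacity 100, maximal intrinsic growth rate
#' 2, stabilizing-selection width 2, per-allele mutation rate 1e-6, 799
#' biallelic loci per trait component, allele effects alpha = 0.1 (nonplastic
#' component) and beta = 2/L (plasticity), unit dispersal standard deviation,
#' and a plasticity cost with shape 0.5 and scale 0.5, run for 1e5
#' generations.
#'
#' @slot nDemes integer, number of habitat demes (M).
#' @slot carryingCapacity integer, local carrying capacity (K).
#' @slot growthRate numeric, maximal intrinsic growth rate (r_m).
#' @slot selectionWidth numeric, width of stabilizing selection (V_S),
#'   in squared trait units.
#' @slot mutationRate numeric, per-allele-copy, per-generation flip
#'   probability (mu).
#' @slot nLoci integer, number of loci per trait component (L).
#' @slot effectZ numeric, per-homozygous-substitution effect on the
#'   nonplastic component (alpha); allele effects are +/- alpha/2.
#' @slot effectG numeric, per-homozygous-substitution effect on plasticity
#'   (beta); allele effects are +/- beta/2.
#' @slot dispersalSd numeric, standard deviation of the discretized Gaussian
#'   dispersal kernel (sigma), in demes.
#' @slot costShape numeric, shape parameter of the plasticity cost (gamma).
#' @slot costScale numeric, scale parameter of the plasticity cost (delta).
#' @slot nGenerations integer, number of generations to iterate (T).
#' @slot seed integer, base random seed for a run.
#' @export
setClass("SimParams", representation(
  nDemes = "integer",
  carryingCapacity = "integer",
  growthRate = "numeric",
  selectionWidth = "numeric",
  mutationRate = "numeric",
  nLoci = "integer",
  effectZ = "numeric",
  effectG = "numeric",
  dispersalSd = "numeric",
  costShape = "numeric",
  costScale = "numeric",
  nGenerations = "integer",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nDemes < 2L) msg <- c(msg, "nDemes (M) must be >= 2")
  if (object@carryingCapacity < 1L)
    msg <- c(msg, "carryingCapacity (K) must be >= 1")
  if (!(object@selectionWidth > 0))
    msg <- c(msg, "selectionWidth (V_S) must be > 0")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate (mu) must lie in [0, 1]")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci (L) must be >= 1")
  if (object@dispersalSd < 0) msg <- c(msg, "dispersalSd (sigma) must be >= 0")
  if (object@costScale < 0) msg <- c(msg, "costScale (delta) must be >= 0")
  if (!(object@costShape > 0)) msg <- c(msg, "costShape (gamma) must be > 0")
  if (object@nGenerations < 0L) msg <- c(msg, "nGenerations (T) must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-deme environmental profile of locally optimal phenotypes
#'
#' Holds the optimal phenotype theta_i for every deme of the one-dimensional
#' habitat. Deme positions are centred integers running from -(M/2 - 1) to
#' M/2 (so for M = 220, from -109 to 110). Profiles come in three kinds:
#' \code{"steepening"} (smooth, near-flat at the habitat centre, increasingly
#' steep towards the edges), \code{"linear"} (constant slope), and
#' \code{"table"} (arbitrary user-supplied values).
#'
#' @slot positions integer vector of centred deme positions.
#' @slot theta numeric vector of locally optimal phenotypes, one per deme.
#' @slot kind character, one of "steepening", "linear", "table".
#' @slot pars list of shape parameters of the generating family.
#' @export
setClass("EnvironmentProfile", representation(
  positions = "integer",
  theta = "numeric",
  kind = "character",
  pars = "list"
))

setValidity("EnvironmentProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@theta))
    msg <- c(msg, "positions and theta must have equal length")
  if (length(object@theta) < 2L) msg <- c(msg, "profile needs >= 2 demes")
  if (!object@kind %in% c("steepening", "linear", "table"))
    msg <- c(msg, "kind must be one of steepening/linear/table")
  if (any(!is.finite(object@theta))) msg <- c(msg, "theta must be finite")
  if (length(msg)) msg else TRUE
})

#' State of the simulated metapopulation
#'
#' All individuals' diploid bit-genomes for the two trait components, their
#' deme of residence, and the generation counter. Allele matrices are
#' n x L 0/1 matrices, one per homologous copy; the additive trait values
#' z and g, the realized phenotype u, and fitness W are derived quantities
#' (see [traitZ()], [traitG()], [phenotypes()], [fitnessValues()]).
#'
#' @slot zA1,zA2 integer matrices (n x L), the two homologous allele copies
#'   underlying the nonplastic component (1 = "+" allele).
#' @slot gA1,gA2 integer matrices (n x L), allele copies underlying
#'   plasticity.
#' @slot deme integer vector, 1-based deme index of residence per individual.
#' @slot generation integer, generation counter tau.
#' @slot env the [EnvironmentProfile-class] the population lives on.
#' @slot params the [SimParams-class] governing the run.
#' @slot extinct logical flag; TRUE marks a terminal extinct state.
#' @export
setClass("PopulationState", representation(
  zA1 = "matrix", zA2 = "matrix",
  gA1 = "matrix", gA2 = "matrix",
  deme = "integer",
  generation = "integer",
  env = "EnvironmentProfile",
  params = "SimParams",
  extinct = "logical"
))

setValidity("PopulationState", function(object) {
  msg <- character()
  n <- nrow(object@zA1)
  L <- ncol(object@zA1)
  dims <- vapply(list(object@zA2, object@gA1, object@gA2),
                 function(m) identical(dim(m), c(n, L)), logical(1))
  if (!all(dims)) msg <- c(msg, "allele matrices must share dimensions n x L")
  if (length(object@deme) != n)
    msg <- c(msg, "deme vector length must equal the number of individuals")
  M <- object@params@nDemes
  if (n > 0 && (any(object@deme < 1L) || any(object@deme > M)))
    msg <- c(msg, "deme indices must lie in [1, M]")
  if (length(object@env@theta) != M)
    msg <- c(msg, "environment profile length must equal nDemes")
  if (n > 0) {
    vals <- c(object@zA1[1, ], object@zA2[1, ], object@gA1[1, ], object@gA2[1, ])
    if (!all(vals %in% c(0L, 1L)))
      msg <- c(msg, "allele states must be binary 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Result of an in-silico reciprocal transplant experiment
#'
#' Phenotype measurements for the four (origin x measurement environment)
#' groups, replicated over independent sampling realizations drawn from the
#' same final population state. Each realization samples 10 mothers per deme,
#' forms 10 half-sib offspring per mother, and splits each family 5/5 between
#' the native and the new environment; the adaptive-trait phenotype u and the
#' fitness-indicator trait w are recorded for every offspring in its
#' assigned environment.
#'
#' @slot demePair integer(2), 1-based indices of the two origin demes.
#' @slot deltaTheta numeric, difference in local optima theta(b) - theta(a).
#' @slot data data.frame with columns realization, origin (1/2), native
#'   (logical), family, u, w.
#' @slot nRealizations integer.
#' @export
setClass("TransplantResult", representation(
  demePair = "integer",
  deltaTheta = "numeric",
  data = "data.frame",
  nRealizations = "integer"
))

#' Reaction-norm statistics for a transplant experiment
#'
#' Per-realization inferential results: Bonferroni-adjusted post hoc p-value
#' and signed Glass' delta for the native-vs-new contrast, per origin and per
#' trait, plus the qualitative outcome pattern of each realization and the
#' frequency of each pattern across realizations.
#'
#' @slot stats data.frame with columns realization, origin, trait
#'   ("adaptive"/"indicator"), pOmnibus, pAdj, delta, significant.
#' @slot patterns character vector, one outcome label per realization.
#' @slot frequencies named numeric, fraction of realizations per pattern.
#' @slot alpha numeric significance level used.
#' @export
setClass("ReactionNormStats", representation(
  stats = "data.frame",
  patterns = "character",
  frequencies = "numeric",
  alpha = "numeric"
))
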
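#' Additive trait value from a diploid allele matrix
#'
#' Each of the 2L allele copies contributes +effect/2 if it carries the "+"
#' state (coded 1) and -effect/2 otherwise, so the trait equals
#' effect * (S - L) where S is the number of "+" copies.
#'
#' @param alleles 2 x L binary matrix (rows = homologous copies).
#' @param effect per-homozygous-substitution effect size (alpha or beta).
#' @return Scalar trait value.
#' @examples
#' traitFromAlleles(matrix(1L, 2, 799), 0.1)  # 79.9
#' @export
traitFromAlleles <- function(alleles, effect) {
  if (!is.matrix(alleles) || nrow(alleles) != 2L)
    stop("alleles must be a 2 x L matrix (two homologous copies per locus)")
  if (!all(alleles %in% c(0, 1)))
    stop("allele states must be binary 0/1")
  effect * (sum(alleles) - ncol(alleles))
}

# Vectorized trait values for a whole population from its two copy matrices.
traitFromCopies <- function(a1, a2, effect) {
  effect * (rowSums(a1) + rowSums(a2) - ncol(a1))
}

#' Realized phenotype of the adaptive trait
#'
#' The phenotype is the sum of the nonplastic component and the plastic
#' component, the latter proportional to the locally optimal phenotype of
#' the environment the individual currently occupies: u = z + g * theta.
#' Plasticity is labile: on transplant, u is re-expressed with the theta of
#' the new environment.
#'
#' @param z nonplastic component (trait units).
#' @param g plasticity (dimensionless proportionality coefficient).
#' @param theta locally optimal phenotype of the environment of residence.
#' @return Phenotype u (vectorized over inputs).
#' @examples
#' phenotype(1, 0.5, 10)  # 6
#' @export
phenotype <- function(z, g, theta) z + g * theta

# Cost-related function 1 - delta*|g|^gamma, clamped at 0 so fitness stays a
# valid reproduction rate. |g| makes negative plasticity equally costly.
costFactor <- function(g, costScale, costShape) {
  pmax(0, 1 - costScale * abs(g)^costShape)
}

#' Fitness of an individual
#'
#' Density-dependent Gaussian stabilizing selection with a direct cost of
#' plasticity:
#' W = max(0, 1 - delta |g|^gamma) * exp(r_m (1 - N/K) - (theta - u)^2 / (2 V_S)).
#' The cost factor is clamped at zero (it would go negative for
#' |g| > (1/delta)^(1/gamma), far outside the evolved range), and the power
#' is taken of |g| so negative plasticity is costed symmetrically.
#'
#' @param u realized phenotype.
#' @param g plasticity.
#' @param theta local phenotypic optimum.
#' @param N local adult population size.
#' @param params a [SimParams-class].
#' @return Fitness W >= 0 (vectorized).
#' @examples
#' p <- simParams()
#' fitness(0, 0, 0, carryingCapacity(p), p)  # 1
#' fitness(0, 0, 0, 0, p)                    # e^2
#' @export
fitness <- function(u, g, theta, N, params) {
  costFactor(g, params@costScale, params@costShape) *
    exp(params@growthRate * (1 - N / params@carryingCapacity) -
          (theta - u)^2 / (2 * params@selectionWidth))
}

#' Fitness-indicator trait
#'
#' The phenotype-dependent component of fitness, i.e. [fitness()] with the
#' density term removed (N set to K):
#' w = max(0, 1 - delta |g|^gamma) * exp(-(theta - u)^2 / (2 V_S)).
#' Used as the measured "fitness-correlated" trait in transplant
#' experiments; lies in [0, 1].
#'
#' @inheritParams fitness
#' @return Indicator trait value w (vectorized).
#' @examples
#' fitnessIndicator(2, 0, 0, simParams())  # exp(-1)
#' @export
fitnessIndicator <- function(u, g, theta, params) {
  costFactor(g, params@costScale, params@costShape) *
    exp(-(theta - u)^2 / (2 * params@selectionWidth))
}

#' Share of the phenotype determined by the plastic component
#'
#' The plastic component g*theta expressed as a percentage of the full
#' phenotype z + g*theta.
#'
#' @inheritParams phenotype
#' @return Percentage in (typically) 0..100 (vectorized).
#' @examples
#' plasticShare(11.64, 0.530, 24.81)  # ~53
#' @export
plasticShare <- function(z, g, theta) {
  100 * g * theta / (z + g * theta)
}
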
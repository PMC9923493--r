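# Shared fixtures and oracles for the test suite. Heavy objects (evolved
# metapopulations) are built once per run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Scaled-down study conditions: a 40-deme habitat, 50 loci per component,
# K = 50, 2000 generations. The steepening gradient keeps the full model's
# relative shape (edge position / length-scale = 5.5) with edge optimum 30;
# the matched linear gradient shares the edge optimum.
scaledParams <- function(seed = 1L, nGenerations = 2000L) {
  simParams(nDemes = 40L, carryingCapacity = 50L, nLoci = 50L,
            nGenerations = nGenerations, seed = seed)
}

scaledSteepEnv <- function() steepeningProfile(40, a = 30 / sinh(5.5), s = 20 / 5.5)

scaledLinearEnv <- function() linearProfile(40, b = 30 / 20)

evolvedScaled <- function(seed = 1L, env = c("steepening", "linear")) {
  env <- match.arg(env)
  key <- paste0("evolved-", env, "-", seed)
  if (is.null(.fixtures[[key]])) {
    prof <- if (env == "steepening") scaledSteepEnv() else scaledLinearEnv()
    .fixtures[[key]] <- runExpansion(scaledParams(seed), prof)$final
  }
  .fixtures[[key]]
}

# Construct a deterministic population: every individual homozygous, with
# the given per-deme z and g values (must be representable with an even
# number of "+" alleles). Used for closed-form transplant checks.
uniformPop <- function(params, env, demes, zValues, gValues) {
  L <- nLoci(params)
  n <- length(demes)
  fillHomo <- function(trait, effect) {
    sPlus <- round(L + trait / effect)
    stopifnot(all(sPlus >= 0), all(sPlus <= 2 * L), all(sPlus %% 2 == 0))
    m <- matrix(0L, n, L)
    for (i in seq_len(n)) if (sPlus[i] > 0) m[i, seq_len(sPlus[i] / 2)] <- 1L
    m
  }
  zm <- fillHomo(zValues, effectZ(params))
  gm <- fillHomo(gValues, effectG(params))
  new("PopulationState", zA1 = zm, zA2 = zm, gA1 = gm, gA2 = gm,
      deme = as.integer(demes), generation = 0L, env = env, params = params,
      extinct = FALSE)
}

# Exhaustive-permutation p-value for the Kruskal-Wallis statistic on two
# groups: enumerates every assignment of the pooled values into groups of
# the observed sizes and counts assignments with H >= observed H.
permutationKWP <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(pooled), n1)
  hOf <- function(i1) kruskalWallis(list(pooled[i1], pooled[-i1]))$H
  hObs <- hOf(seq_len(n1))
  hAll <- apply(idx, 2, hOf)
  mean(hAll >= hObs - 1e-12)
}
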
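#' Found a population in a set of demes
#'
#' Each founder deme is filled to carrying capacity. Plasticity alleles are
#' balanced so every founder has g = 0 exactly (one copy all "+", the other
#' all "-"). The nonplastic component is either matched to the local optimum
#' ("adapted": the number of "+" alleles is the rounding of L + theta/alpha,
#' clipped to [0, 2L]) or set to zero ("blank").
#'
#' @param params a [SimParams-class].
#' @param env an [EnvironmentProfile-class] with `nDemes(params)` demes.
#' @param founderDemes integer vector of 1-based deme indices to occupy.
#' @param founderZMode "adapted" or "blank".
#' @return A [PopulationState-class] at generation 0.
#' @export
initializePopulation <- function(params, env,
                                 founderDemes,
                                 founderZMode = c("adapted", "blank")) {
  founderZMode <- match.arg(founderZMode)
  founderDemes <- as.integer(founderDemes)
  if (length(founderDemes) == 0L) stop("founderDemes must be nonempty")
  if (any(founderDemes < 1L) || any(founderDemes > params@nDemes))
    stop("founderDemes outside the habitat [1, M]")
  K <- params@carryingCapacity
  L <- params@nLoci
  n <- K * length(founderDemes)
  deme <- rep(founderDemes, each = K)

  # target "+" allele counts per individual for the z component
  sTarget <- if (founderZMode == "adapted") {
    th <- thetaAt(env, deme)
    pmin(2L * L, pmax(0L, as.integer(round(L + th / params@effectZ))))
  } else rep.int(L, n)

  fillCopies <- function(sCount) {
    # fill copy 1 first (up to L "+" alleles), overflow into copy 2
    a1 <- matrix(0L, n, L)
    a2 <- matrix(0L, n, L)
    k1 <- pmin(sCount, L)
    k2 <- sCount - k1
    csel <- sequence(k1)
    a1[cbind(rep(seq_len(n), k1), csel)] <- 1L
    csel2 <- sequence(k2)
    if (length(csel2))
      a2[cbind(rep(seq_len(n), k2), csel2)] <- 1L
    list(a1, a2)
  }
  z <- fillCopies(sTarget)
  g <- fillCopies(rep.int(L, n))  # g = 0 for every founder

  new("PopulationState", zA1 = z[[1]], zA2 = z[[2]],
      gA1 = g[[1]], gA2 = g[[2]],
      deme = deme, generation = 0L, env = env, params = params,
      extinct = FALSE)
}

#' Derived quantities of a population state
#'
#' `traitZ` and `traitG` are the additive sums over the 2L allele copies of
#' each component; `phenotypes` gives u = z + g*theta in each individual's
#' deme of residence; `fitnessValues` evaluates the fitness equation with
#' the current adult count of each deme.
#'
#' @param pop a [PopulationState-class].
#' @return Numeric vector, one value per individual (`demeCounts`: one count
#'   per deme).
#' @export
traitZ <- function(pop) traitFromCopies(pop@zA1, pop@zA2, pop@params@effectZ)

#' @rdname traitZ
#' @export
traitG <- function(pop) traitFromCopies(pop@gA1, pop@gA2, pop@params@effectG)

#' @rdname traitZ
#' @export
demeCounts <- function(pop) tabulate(pop@deme, nbins = pop@params@nDemes)

#' @rdname traitZ
#' @export
phenotypes <- function(pop) {
  th <- thetaAt(pop@env, pop@deme)
  phenotype(traitZ(pop), traitG(pop), th)
}

#' @rdname traitZ
#' @export
fitnessValues <- function(pop) {
  th <- thetaAt(pop@env, pop@deme)
  N <- demeCounts(pop)[pop@deme]
  z <- traitZ(pop); g <- traitG(pop)
  fitness(phenotype(z, g, th), g, th, N, pop@params)
}

#' @rdname traitZ
#' @export
nIndividuals <- function(pop) nrow(pop@zA1)

#' @rdname traitZ
#' @export
isExtinct <- function(pop) pop@extinct

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState: %d individuals in %d/%d demes, generation %d%s\n",
              nIndividuals(object), sum(demeCounts(object) > 0),
              object@params@nDemes, object@generation,
              if (object@extinct) " [EXTINCT]" else ""))
})

# ---- lifecycle internals ----------------------------------------------------

# Mate: per mother, Poisson(2W) offspring; father uniform from the mother's
# deme (selfing possible). Returns mother/father indices and natal demes.
matePairs <- function(pop, W) {
  nOff <- stats::rpois(length(W), 2 * W)
  total <- sum(nOff)
  if (total == 0L)
    return(list(mother = integer(), father = integer(), deme = integer()))
  mother <- rep.int(seq_along(nOff), nOff)
  natal <- pop@deme[mother]
  father <- integer(total)
  for (d in unique(natal)) {
    sel <- natal == d
    cand <- which(pop@deme == d)
    father[sel] <- cand[sample.int(length(cand), sum(sel), replace = TRUE)]
  }
  list(mother = mother, father = father, deme = natal)
}

# Free recombination: each transmitted haplotype picks, per locus
# independently, one of the parent's two copies.
gametes <- function(a1, a2, parent) {
  recombineCpp(a1, a2, as.integer(parent))
}

#' Reproduce one generation
#'
#' Every adult acts once as a mother: its offspring count is Poisson with
#' mean 2 W (W from the fitness equation with the deme's current adult
#' count); the father is drawn uniformly from the same deme, selfing
#' allowed. Offspring haplotypes are formed by free recombination. Adults
#' die after reproduction (the returned genomes are the juveniles).
#'
#' @param pop a [PopulationState-class].
#' @return List with allele matrices `zA1`, `zA2`, `gA1`, `gA2` and integer
#'   vector `deme` (natal demes) for the offspring.
#' @export
reproduce <- function(pop) {
  W <- fitnessValues(pop)
  mp <- matePairs(pop, W)
  list(zA1 = gametes(pop@zA1, pop@zA2, mp$mother),
       zA2 = gametes(pop@zA1, pop@zA2, mp$father),
       gA1 = gametes(pop@gA1, pop@gA2, mp$mother),
       gA2 = gametes(pop@gA1, pop@gA2, mp$father),
       deme = mp$deme)
}

#' Mutate allele matrices
#'
#' Each allele copy flips state independently with probability mu.
#'
#' @param genomes list with zA1, zA2, gA1, gA2 matrices (as from
#'   [reproduce()]).
#' @param mu per-copy flip probability.
#' @return The list with mutations applied.
#' @export
mutateGenomes <- function(genomes, mu) {
  if (mu <= 0) return(genomes)
  for (nm in c("zA1", "zA2", "gA1", "gA2")) {
    m <- genomes[[nm]]
    nFlip <- stats::rbinom(1L, length(m), mu)
    if (nFlip > 0L) {
      idx <- sample.int(length(m), nFlip)
      m[idx] <- 1L - m[idx]
      genomes[[nm]] <- m
    }
  }
  genomes
}

#' Discretized Gaussian dispersal with reflecting boundaries
#'
#' Integer displacements are drawn with probabilities proportional to the
#' mass of Normal(0, sigma) on (d - 1/2, d + 1/2] (i.e. the rounding of a
#' Gaussian draw); destinations beyond the habitat are reflected at the
#' edges until they fall inside.
#'
#' @param deme integer natal demes (1-based).
#' @param sigma dispersal standard deviation.
#' @param M number of demes.
#' @return Integer vector of destination demes in [1, M].
#' @export
disperse <- function(deme, sigma, M) {
  if (sigma <= 0 || length(deme) == 0L) return(deme)
  dest <- deme + as.integer(round(stats::rnorm(length(deme), 0, sigma)))
  # reflect about the habitat edges (boundaries at 0.5 and M + 0.5)
  repeat {
    below <- dest < 1L
    above <- dest > M
    if (!any(below) && !any(above)) break
    dest[below] <- 1L - dest[below]
    dest[above] <- 2L * M + 1L - dest[above]
  }
  dest
}

#' Advance the population by one generation
#'
#' Applies the lifecycle in fixed order: mating/recombination ->
#' mutation -> death of adults -> dispersal of juveniles. Trait values are
#' recomputed from genomes and phenotypes are expressed in the
#' post-dispersal deme (juveniles develop where they land). A population
#' with zero offspring is returned empty with the extinction flag set.
#'
#' @param pop a [PopulationState-class].
#' @return The successor [PopulationState-class] at generation tau + 1.
#' @export
stepPopulation <- function(pop) {
  if (pop@extinct || nIndividuals(pop) == 0L) {
    pop@extinct <- TRUE
    pop@generation <- pop@generation + 1L
    return(pop)
  }
  off <- reproduce(pop)
  off <- mutateGenomes(off, pop@params@mutationRate)
  deme <- disperse(off$deme, pop@params@dispersalSd, pop@params@nDemes)
  extinct <- length(deme) == 0L
  L <- pop@params@nLoci
  emptyM <- matrix(integer(), 0L, L)
  new("PopulationState",
      zA1 = if (extinct) emptyM else off$zA1,
      zA2 = if (extinct) emptyM else off$zA2,
      gA1 = if (extinct) emptyM else off$gA1,
      gA2 = if (extinct) emptyM else off$gA2,
      deme = as.integer(deme), generation = pop@generation + 1L,
      env = pop@env, params = pop@params, extinct = extinct)
}

#' Run a range-expansion simulation
#'
#' Iterates [stepPopulation()] for `nGenerations(params)` generations from a
#' founding population, optionally recording a per-deme time series of
#' occupancy and mean trait values.
#'
#' @param params a [SimParams-class] (its `seed` slot seeds the run).
#' @param env an [EnvironmentProfile-class].
#' @param founderDemes demes initially occupied; default: the two central
#'   demes.
#' @param founderZMode see [initializePopulation()].
#' @param checkpointEvery record a time-series row every this many
#'   generations (0 = final state only).
#' @return List with `final` (the final [PopulationState-class]) and
#'   `series` (data.frame: generation, deme, position, N, meanZ, meanG).
#' @export
runExpansion <- function(params, env,
                         founderDemes = centralDemes(params),
                         founderZMode = "adapted",
                         checkpointEvery = 0L) {
  set.seed(deriveSeed(params@seed, "expansion"))
  pop <- initializePopulation(params, env, founderDemes, founderZMode)
  rows <- list()
  record <- function(p) {
    s <- populationSummary(p)
    s$generation <- p@generation
    rows[[length(rows) + 1L]] <<- s[s$N > 0, ]
  }
  if (checkpointEvery > 0L) record(pop)
  T <- params@nGenerations
  if (T > 0L) for (tau in seq_len(T)) {
    pop <- stepPopulation(pop)
    if (pop@extinct) break
    if (checkpointEvery > 0L && tau %% checkpointEvery == 0L) record(pop)
  }
  series <- if (length(rows)) do.call(rbind, rows) else NULL
  list(final = pop, series = series)
}

#' @rdname runExpansion
#' @export
centralDemes <- function(params) {
  M <- params@nDemes
  as.integer(c(M %/% 2L, M %/% 2L + 1L))
}

#' Per-deme summary of a population state
#'
#' @param pop a [PopulationState-class].
#' @return data.frame with one row per deme: deme, position, theta, N,
#'   meanZ, meanG, meanU (NA for empty demes) and an `occupied` flag.
#' @export
populationSummary <- function(pop) {
  M <- pop@params@nDemes
  N <- demeCounts(pop)
  z <- traitZ(pop); g <- traitG(pop)
  u <- phenotype(z, g, thetaAt(pop@env, pop@deme))
  agg <- function(v) {
    s <- rep(NA_real_, M)
    if (length(v)) {
      m <- vapply(split(v, factor(pop@deme, levels = seq_len(M))),
                  function(x) if (length(x)) mean(x) else NA_real_, numeric(1))
      s <- unname(m)
    }
    s
  }
  data.frame(deme = seq_len(M), position = pop@env@positions,
             theta = pop@env@theta, N = N,
             meanZ = agg(z), meanG = agg(g), meanU = agg(u),
             occupied = N > 0L)
}
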
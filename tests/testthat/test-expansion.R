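smallParams <- function(...) {
  defaults <- list(nDemes = 10L, carryingCapacity = 20L, nLoci = 20L,
                   nGenerations = 5L)
  do.call(simParams, utils::modifyList(defaults, list(...)))
}

test_that("founding fills demes to capacity with balanced plasticity", {
  p <- simParams(nDemes = 20L, carryingCapacity = 100L, nLoci = 40L)
  env <- linearProfile(20, 0.5)
  pop <- initializePopulation(p, env, founderDemes = c(10L, 11L))
  expect_equal(nIndividuals(pop), 200)
  expect_setequal(unique(pop@deme), c(10L, 11L))
  expect_equal(traitG(pop), rep(0, 200))
  # adapted mode: z matches theta to the nearest achievable allele count
  expect_true(all(abs(traitZ(pop) - thetaAt(env, pop@deme)) <= effectZ(p)))
  # theta = 0 demes found with z exactly 0
  pop0 <- initializePopulation(p, linearProfile(20, 0), 5L)
  expect_equal(mean(traitZ(pop0)), 0)
  # blank mode
  popB <- initializePopulation(p, env, 10L, founderZMode = "blank")
  expect_equal(traitZ(popB), rep(0, 100))
  expect_error(initializePopulation(p, env, integer()), "nonempty")
  expect_error(initializePopulation(p, env, 99L), "habitat")
})

test_that("offspring numbers follow the Poisson(2W) reproduction rule", {
  # perfectly adapted lone mother at negligible density: mean ~ 2 e^2
  p <- smallParams(mutationRate = 0)
  draws <- 1e5
  set.seed(101)
  W <- fitness(0, 0, 0, N = 0, p)
  counts <- rpois(draws, 2 * W)
  expect_equal(mean(counts), 2 * exp(2), tolerance = 0.02)
  # a deme at carrying capacity, perfectly adapted: stationary mean ~ 2
  env <- linearProfile(10, 0)
  pop <- uniformPop(p, env, rep(3L, 20), zValues = rep(0, 20),
                    gValues = rep(0, 20))
  set.seed(202)
  tot <- replicate(300, length(reproduce(pop)$deme))
  expect_equal(mean(tot) / 20, 2, tolerance = 0.05)
  # W = 0 everywhere -> no offspring
  popFar <- uniformPop(p, linearProfile(10, 50), rep(1L, 20),
                       zValues = rep(0, 20), gValues = rep(0, 20))
  expect_length(reproduce(popFar)$deme, 0)
})

test_that("mutation flips alleles at the expected rate", {
  g <- list(zA1 = matrix(0L, 50, 40), zA2 = matrix(1L, 50, 40),
            gA1 = matrix(0L, 50, 40), gA2 = matrix(0L, 50, 40))
  expect_identical(mutateGenomes(g, 0), g)
  flipped <- mutateGenomes(g, 1)
  expect_true(all(flipped$zA1 == 1L) && all(flipped$zA2 == 0L))
  set.seed(5)
  mu <- 0.01
  nFlips <- replicate(200, sum(mutateGenomes(g, mu)$zA1))
  expect_equal(mean(nFlips), length(g$zA1) * mu, tolerance = 0.1)
})

test_that("dispersal is symmetric inside and reflecting at the edges", {
  expect_equal(disperse(rep(5L, 100), 0, 10), rep(5L, 100))
  set.seed(9)
  d <- disperse(rep(50L, 1e5), 1, 100) - 50L
  expect_equal(mean(d), 0, tolerance = 0.02)
  expect_equal(mean(d == 0), pnorm(0.5) - pnorm(-0.5), tolerance = 0.01)
  # boundary contract: never leaves the habitat
  left <- disperse(rep(1L, 1e4), 3, 10)
  expect_true(all(left >= 1L & left <= 10L))
  right <- disperse(rep(10L, 1e4), 3, 10)
  expect_true(all(right >= 1L & right <= 10L))
})

test_that("the generation step preserves structure and is deterministic", {
  p <- smallParams()
  env <- linearProfile(10, 0.2)
  pop <- initializePopulation(p, env, c(5L, 6L))
  set.seed(33); s1 <- stepPopulation(pop)
  set.seed(33); s2 <- stepPopulation(pop)
  expect_identical(s1@zA1, s2@zA1)
  expect_identical(s1@deme, s2@deme)
  expect_equal(s1@generation, 1L)
  expect_equal(ncol(s1@zA1), nLoci(p))
  expect_true(all(s1@deme >= 1L & s1@deme <= 10L))
  # empty population: flagged terminal state, not an error
  emptyPop <- new("PopulationState",
                  zA1 = matrix(integer(), 0, 20), zA2 = matrix(integer(), 0, 20),
                  gA1 = matrix(integer(), 0, 20), gA2 = matrix(integer(), 0, 20),
                  deme = integer(), generation = 0L, env = env, params = p,
                  extinct = FALSE)
  stepped <- stepPopulation(emptyPop)
  expect_true(isExtinct(stepped))
  expect_equal(nIndividuals(stepped), 0)
})

test_that("allele frequencies drift without directional bias when neutral", {
  # one isolated deme, no mutation, V_S -> inf, delta = 0: one-step allele
  # frequency change has expectation ~ 0 (Wright-Fisher-like neutrality)
  p <- simParams(nDemes = 2L, carryingCapacity = 40L, nLoci = 30L,
                 mutationRate = 0, selectionWidth = 1e12, costScale = 0,
                 dispersalSd = 0)
  env <- linearProfile(2, 0)
  set.seed(77)
  zA1 <- matrix(rbinom(40 * 30, 1, 0.5), 40, 30)
  zA2 <- matrix(rbinom(40 * 30, 1, 0.5), 40, 30)
  pop <- new("PopulationState", zA1 = zA1, zA2 = zA2,
             gA1 = matrix(0L, 40, 30), gA2 = matrix(1L, 40, 30),
             deme = rep(1L, 40), generation = 0L, env = env, params = p,
             extinct = FALSE)
  freq0 <- mean(zA1 + zA2) / 2
  set.seed(78)
  freqs <- replicate(200, {
    s <- stepPopulation(pop)
    mean(s@zA1 + s@zA2) / 2
  })
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - freq0), 3.5 * se + 1e-6)
})

test_that("density regulation holds a neutral deme at its stationary level", {
  # under Poisson(2W) reproduction the per-capita growth is 2 exp(r_m(1-N/K)),
  # so the stationary occupancy is K(1 + ln2/r_m), not K itself
  p <- simParams(nDemes = 2L, carryingCapacity = 50L, nLoci = 10L,
                 mutationRate = 0, selectionWidth = 1e12, costScale = 0,
                 dispersalSd = 0, nGenerations = 60L, seed = 4L)
  env <- linearProfile(2, 0)
  pop <- initializePopulation(p, env, 1L)
  set.seed(44)
  sizes <- numeric(400)
  for (i in seq_along(sizes)) {
    pop <- stepPopulation(pop)
    sizes[i] <- nIndividuals(pop)
  }
  expect_equal(mean(sizes[101:400]), 50 * (1 + log(2) / 2), tolerance = 0.1)
})

test_that("checkpoints round-trip bit-exactly and preserve dynamics", {
  p <- smallParams(seed = 3L)
  env <- steepeningProfile(10, a = 1.5, s = 2)
  pop <- runExpansion(p, env)$final
  path <- withr::local_tempfile(fileext = ".txt")
  writePopulation(pop, path)
  back <- readPopulation(path)
  expect_identical(back@zA1, pop@zA1)
  expect_identical(back@zA2, pop@zA2)
  expect_identical(back@gA1, pop@gA1)
  expect_identical(back@gA2, pop@gA2)
  expect_identical(back@deme, pop@deme)
  expect_identical(back@generation, pop@generation)
  expect_equal(thetaOf(back@env), thetaOf(pop@env))
  # stepping the reloaded state equals stepping the in-memory state
  set.seed(55); a <- stepPopulation(pop)
  set.seed(55); b <- stepPopulation(back)
  expect_identical(a@zA1, b@zA1)
  expect_identical(a@deme, b@deme)
})

test_that("population summaries aggregate per deme", {
  p <- smallParams(mutationRate = 0)
  env <- linearProfile(10, 1)
  pop <- uniformPop(p, env, c(2L, 2L, 7L), zValues = c(1, 1, 1) * 0.2,
                    gValues = c(0, 0, 0))
  s <- populationSummary(pop)
  expect_equal(nrow(s), 10)
  expect_equal(s$N[2], 2)
  expect_equal(s$meanZ[s$deme == 2], 0.2)
  expect_equal(s$meanG[s$deme == 7], 0)
  expect_true(all(is.na(s$meanZ[!s$occupied])))
  expect_equal(s$meanU, s$meanZ + s$meanG * s$theta)
})

test_that("runExpansion honours T = 0 and emits checkpoint series", {
  p <- smallParams(nGenerations = 0L)
  env <- linearProfile(10, 0.1)
  res <- runExpansion(p, env, founderDemes = 5L)
  expect_equal(res$final@generation, 0L)
  expect_equal(nIndividuals(res$final), carryingCapacity(p))
  p2 <- smallParams(nGenerations = 10L)
  res2 <- runExpansion(p2, env, founderDemes = 5L, checkpointEvery = 5L)
  expect_setequal(unique(res2$series$generation), c(0, 5, 10))
})
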
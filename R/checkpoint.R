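#' Write / read a population checkpoint as plain text
#'
#' A checkpoint is a self-contained text file: the first line is a JSON
#' header with the generation counter, the parameter set, and the
#' environment profile; each subsequent line holds one individual as
#' tab-separated fields: deme index and the four haplotypes as 0/1 strings
#' (z copy 1, z copy 2, g copy 1, g copy 2). Reading reconstructs a
#' [PopulationState-class] bit-identical in genomes, demes, generation,
#' parameters, and environment.
#'
#' @param pop a [PopulationState-class].
#' @param path file path.
#' @return `writePopulation` invisibly returns the path; `readPopulation`
#'   returns the reconstructed [PopulationState-class].
#' @export
writePopulation <- function(pop, path) {
  p <- pop@params
  header <- jsonlite::toJSON(list(
    format = "plastrange-checkpoint-1",
    generation = pop@generation,
    extinct = pop@extinct,
    params = list(M = p@nDemes, K = p@carryingCapacity, r_m = p@growthRate,
                  V_S = p@selectionWidth, mu = p@mutationRate, L = p@nLoci,
                  alpha = p@effectZ, beta = p@effectG, sigma = p@dispersalSd,
                  gamma = p@costShape, delta = p@costScale,
                  T = p@nGenerations, seed = p@seed),
    env = list(kind = pop@env@kind, positions = pop@env@positions,
               theta = pop@env@theta, pars = pop@env@pars)
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  if (nIndividuals(pop) > 0L) {
    packRows <- function(m) apply(m, 1L, paste, collapse = "")
    writeLines(paste(pop@deme,
                     packRows(pop@zA1), packRows(pop@zA2),
                     packRows(pop@gA1), packRows(pop@gA2),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writePopulation
#' @export
readPopulation <- function(path) {
  lines <- readLines(path)
  hd <- jsonlite::fromJSON(lines[1])
  if (!identical(hd$format, "plastrange-checkpoint-1"))
    stop("not a plastrange checkpoint file")
  pp <- hd$params
  params <- simParams(nDemes = pp$M, carryingCapacity = pp$K,
                      growthRate = pp$r_m, selectionWidth = pp$V_S,
                      mutationRate = pp$mu, nLoci = pp$L, effectZ = pp$alpha,
                      effectG = pp$beta, dispersalSd = pp$sigma,
                      costShape = pp$gamma, costScale = pp$delta,
                      nGenerations = pp$T, seed = pp$seed)
  env <- newProfile(hd$env$positions, hd$env$theta, hd$env$kind,
                    as.list(hd$env$pars))
  body <- lines[-1]
  L <- params@nLoci
  if (length(body) == 0L) {
    emptyM <- matrix(integer(), 0L, L)
    return(new("PopulationState", zA1 = emptyM, zA2 = emptyM,
               gA1 = emptyM, gA2 = emptyM, deme = integer(),
               generation = as.integer(hd$generation), env = env,
               params = params, extinct = isTRUE(hd$extinct)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  deme <- as.integer(vapply(parts, `[[`, character(1), 1L))
  unpack <- function(k) {
    s <- vapply(parts, `[[`, character(1), k)
    m <- matrix(as.integer(unlist(strsplit(s, "", fixed = TRUE))),
                nrow = length(s), ncol = L, byrow = TRUE)
    m
  }
  new("PopulationState", zA1 = unpack(2L), zA2 = unpack(3L),
      gA1 = unpack(4L), gA2 = unpack(5L), deme = deme,
      generation = as.integer(hd$generation), env = env, params = params,
      extinct = isTRUE(hd$extinct))
}
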
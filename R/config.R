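#' Load a validated simulation configuration
#'
#' Configurations are YAML (or JSON, which YAML subsumes) files whose keys
#' follow the model's standard notation: under `params`, the keys
#' M, K, r_m, V_S, mu, L, alpha, beta, sigma, gamma, delta, T, seed; under
#' `environment`, `kind` ("steepening", "linear" or "table") with the shape
#' parameters of the chosen family (`a`, `s` for steepening; `b` for
#' linear; `positions`/`theta` for table). An empty file (or missing
#' sections) yields the full default parameterization. Unknown keys are
#' rejected with an error naming the offending key, as are invariant
#' violations.
#'
#' @param path path to the configuration file.
#' @return List with elements `params` (a [SimParams-class]) and `env`
#'   (an [EnvironmentProfile-class]).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("params", "environment")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config section: ", paste(bad, collapse = ", "))

  p <- cfg$params
  if (is.null(p)) p <- list()
  keyMap <- c(M = "nDemes", K = "carryingCapacity", r_m = "growthRate",
              V_S = "selectionWidth", mu = "mutationRate", L = "nLoci",
              alpha = "effectZ", beta = "effectG", sigma = "dispersalSd",
              gamma = "costShape", delta = "costScale", T = "nGenerations",
              seed = "seed")
  bad <- setdiff(names(p), names(keyMap))
  if (length(bad))
    stop("unknown parameter key: ", paste(bad, collapse = ", "))
  args <- stats::setNames(p, keyMap[names(p)])
  params <- tryCatch(do.call(simParams, args), error = function(e)
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE))

  e <- cfg$environment
  if (is.null(e)) e <- list(kind = "steepening")
  if (is.null(e$kind)) e$kind <- "steepening"
  env <- switch(e$kind,
    steepening = {
      bad <- setdiff(names(e), c("kind", "a", "s"))
      if (length(bad)) stop("unknown environment key: ", paste(bad, collapse = ", "))
      args <- e[intersect(names(e), c("a", "s"))]
      do.call(steepeningProfile, c(list(M = params@nDemes), args))
    },
    linear = {
      bad <- setdiff(names(e), c("kind", "b"))
      if (length(bad)) stop("unknown environment key: ", paste(bad, collapse = ", "))
      if (is.null(e$b)) stop("linear environment requires slope b")
      linearProfile(params@nDemes, e$b)
    },
    table = {
      bad <- setdiff(names(e), c("kind", "positions", "theta"))
      if (length(bad)) stop("unknown environment key: ", paste(bad, collapse = ", "))
      tableProfile(e$positions, e$theta)
    },
    stop("unknown environment kind: ", e$kind))
  list(params = params, env = env)
}

#' Write a configuration file for a parameter set and environment
#'
#' Inverse of [loadConfig()]: `loadConfig(writeConfig(x, path))` restores
#' the same parameters and profile.
#'
#' @param params a [SimParams-class].
#' @param env an [EnvironmentProfile-class].
#' @param path output path (YAML).
#' @export
writeConfig <- function(params, env, path) {
  p <- params
  envSpec <- switch(env@kind,
                    steepening = c(list(kind = "steepening"), env@pars),
                    linear = c(list(kind = "linear"), env@pars),
                    table = list(kind = "table",
                                 positions = env@positions,
                                 theta = env@theta))
  yaml::write_yaml(list(
    params = list(M = p@nDemes, K = p@carryingCapacity, r_m = p@growthRate,
                  V_S = p@selectionWidth, mu = p@mutationRate, L = p@nLoci,
                  alpha = p@effectZ, beta = p@effectG, sigma = p@dispersalSd,
                  gamma = p@costShape, delta = p@costScale,
                  T = p@nGenerations, seed = p@seed),
    environment = envSpec), path, precision = 15)
  invisible(path)
}
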
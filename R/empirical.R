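#' Validate an empirical phenotype record table
#'
#' Expected columns: `population` ("high_salinity"/"low_salinity"),
#' `salinity_psu` (treatment salinity), `native` (logical), `weight_g`
#' (> 1 so ln(weight) > 0), `grazing_g` (control-corrected algal mass
#' consumed) and `respiration` (oxygen consumption rate). The native flag
#' must be consistent with the population-to-home-salinity mapping
#' (high_salinity at 16 psu, low_salinity at 8 psu by default).
#'
#' @param records data.frame of phenotype records.
#' @param homeSalinity named numeric mapping population to native salinity.
#' @return The records, invisibly, after validation.
#' @export
validateRecords <- function(records,
                            homeSalinity = c(high_salinity = 16,
                                             low_salinity = 8)) {
  need <- c("population", "salinity_psu", "native", "weight_g",
            "grazing_g", "respiration")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$population %in% names(homeSalinity)))
    stop("unknown population labels")
  if (any(records$weight_g <= 1))
    stop("weights must exceed 1 g so that ln(weight) is positive")
  expected <- records$salinity_psu == homeSalinity[records$population]
  if (!all(records$native == expected))
    stop("native flags inconsistent with the population/salinity mapping")
  invisible(records)
}

#' Standardize responses by body size
#'
#' Grazing and respiration covary with body weight, so both are divided by
#' the natural logarithm of the weight. The log10 of the standardized
#' respiration is also produced (respiration/weight values are
#' approximately log-normal, so ANOVA and plots work on the log10 scale).
#' An alternative convention, division by raw weight, is available via
#' `divisor = "weight"`.
#'
#' @param records validated phenotype records (see [validateRecords()]).
#' @param divisor "log" (ln weight, default) or "weight".
#' @return The records with added columns `grazing_std`, `respiration_std`,
#'   `log10_respiration_std`.
#' @export
standardizeRecords <- function(records, divisor = c("log", "weight")) {
  divisor <- match.arg(divisor)
  validateRecords(records)
  d <- if (divisor == "log") log(records$weight_g) else records$weight_g
  if (any(d <= 0)) stop("standardization divisor must be positive")
  records$grazing_std <- records$grazing_g / d
  records$respiration_std <- records$respiration / d
  records$log10_respiration_std <- log10(records$respiration_std)
  records
}

#' Control-corrected algal mass consumed
#'
#' Ungrazed algae pieces serve as controls for growth and water
#' accumulation: the expected end mass of an ungrazed piece is start mass
#' times the control growth factor (mean end/start ratio over controls),
#' so consumed = start * factor - end. Negative values (growth outpacing
#' grazing) are returned as-is with a warning.
#'
#' @param startMass,endMass algal wet masses (> 0), grams.
#' @param controlGrowthFactor mean(end/start) over ungrazed controls.
#' @return Consumed mass (vectorized), grams.
#' @examples
#' grazingCorrection(10, 9, 1.1)  # 2
#' @export
grazingCorrection <- function(startMass, endMass, controlGrowthFactor) {
  if (any(startMass <= 0) || any(endMass <= 0))
    stop("algal masses must be positive")
  if (any(controlGrowthFactor <= 0))
    stop("control growth factor must be positive")
  consumed <- startMass * controlGrowthFactor - endMass
  if (any(consumed < 0))
    warning("negative consumed mass: control growth outpaced grazing")
  consumed
}

#' Analyse an empirical reciprocal-transplant phenotype table
#'
#' The analysis pipeline for two populations x two treatment salinities:
#' (1) size-standardize responses; (2) on the untrimmed data, per trait, a
#' Kruskal-Wallis omnibus over the four (population x salinity) groups with
#' Dunn/Bonferroni native-vs-new post hoc contrasts per population, and
#' Glass' delta (new minus native, native spread); (3) Grubbs outlier
#' trimming (within each group, per trait) followed by a two-way ANOVA
#' (population x salinity, with interaction) on grazing_std and on
#' log10(respiration_std). Outlier removal affects only the ANOVA, never
#' the rank tests or effect sizes.
#'
#' @param records phenotype records (see [validateRecords()]).
#' @param alpha significance level.
#' @param m Bonferroni multiplier for the post hoc contrasts (default 2).
#' @param grubbsAlpha level for outlier detection (default 0.05).
#' @return List with `norms` (data.frame: population, trait, pOmnibus, pAdj,
#'   delta, significant), `anova` (data.frame: trait, term, F, p),
#'   `outliers` (integer row indices removed before the ANOVA), and
#'   `records` (the standardized table).
#' @export
analyzeEmpirical <- function(records, alpha = 0.05, m = 2L,
                             grubbsAlpha = 0.05) {
  records <- standardizeRecords(records)
  pops <- c("high_salinity", "low_salinity")
  if (!all(pops %in% records$population) ||
      length(unique(records$salinity_psu)) < 2L)
    stop("both populations and both treatments must be present")
  traits <- c(grazing = "grazing_std", respiration = "log10_respiration_std")

  # rank-based reaction norms on untrimmed data
  normRows <- list()
  for (tn in names(traits)) {
    v <- records[[traits[[tn]]]]
    grp <- list(
      v[records$population == pops[1] & records$native],
      v[records$population == pops[1] & !records$native],
      v[records$population == pops[2] & records$native],
      v[records$population == pops[2] & !records$native])
    kw <- kruskalWallis(grp)
    ph <- dunnBonferroni(grp, list(c(2L, 1L), c(4L, 3L)), m = m)
    for (i in 1:2) {
      delta <- glassDelta(grp[[2 * i]], grp[[2 * i - 1]])
      normRows[[length(normRows) + 1L]] <- data.frame(
        population = pops[i], trait = tn, pOmnibus = kw$p,
        pAdj = ph$pAdj[i], delta = delta,
        significant = kw$p < alpha && ph$pAdj[i] < alpha)
    }
  }
  norms <- do.call(rbind, normRows)

  # Grubbs trimming within groups, then two-way ANOVA per trait
  groupId <- interaction(records$population, records$salinity_psu)
  anovaRows <- list()
  allOut <- integer()
  for (tn in names(traits)) {
    v <- records[[traits[[tn]]]]
    out <- unlist(lapply(levels(groupId), function(gl) {
      idx <- which(groupId == gl)
      if (length(idx) >= 3L) idx[grubbsOutliers(v[idx], grubbsAlpha)]
      else integer()
    }))
    allOut <- union(allOut, out)
    keep <- setdiff(seq_along(v), out)
    tab <- twoWayAnova(v[keep], records$population[keep],
                       factor(records$salinity_psu[keep]))
    anovaRows[[length(anovaRows) + 1L]] <- data.frame(
      trait = tn,
      term = c("population", "salinity", "population:salinity"),
      F = tab$F, p = tab$p)
  }
  list(norms = norms, anova = do.call(rbind, anovaRows),
       outliers = sort(allOut), records = records)
}

#' Generate synthetic reciprocal-transplant phenotype records
#'
#' Emulates the structure of a two-population x two-salinity isopod
#' transplant dataset: group sizes default to about 75 per treatment for the
#' high-salinity population and 50 for the low-salinity population. Body
#' weights are drawn so that ln(weight) is positive; responses are Gaussian
#' on the standardized scale (grazing per ln weight; log10 respiration per
#' ln weight) and back-transformed through each individual's weight, so the
#' raw table carries the weight covariance the analysis must remove.
#' Treatment effects are specified per population as Glass' delta units of
#' the group spread (effect of the new environment relative to native).
#' Optional gross outliers multiply a random response by `outlierFactor`.
#'
#' @param n named integer vector, individuals per treatment for each
#'   population.
#' @param grazingMean,grazingSd mean and sd of the standardized grazing in
#'   the native environment (shared by both populations).
#' @param log10RespMean,log10RespSd native-group parameters of log10
#'   standardized respiration.
#' @param grazingDelta,respDelta named numeric, per-population effect of
#'   the new environment in control-sd units (grazing on the standardized
#'   scale, respiration on the log10 standardized scale).
#' @param weightMeanLog,weightSdLog parameters of ln(weight); draws are
#'   truncated so weight > 1.05 g.
#' @param nOutliers gross outliers to inject (default 0).
#' @param outlierFactor multiplier applied to an outlier's raw responses.
#' @param homeSalinity named numeric, native salinity per population.
#' @param seed integer seed.
#' @return A validated records data.frame (see [validateRecords()]).
#' @export
generateSyntheticRecords <- function(
    n = c(high_salinity = 75L, low_salinity = 50L),
    grazingMean = 0.5, grazingSd = 0.15,
    log10RespMean = 2, log10RespSd = 0.15,
    grazingDelta = c(high_salinity = 0, low_salinity = -0.5),
    respDelta = c(high_salinity = 0, low_salinity = 0.5),
    weightMeanLog = 1, weightSdLog = 0.3,
    nOutliers = 0L, outlierFactor = 8,
    homeSalinity = c(high_salinity = 16, low_salinity = 8),
    seed = 1L) {
  if (any(n < 2L)) stop("need n >= 2 per group")
  if (grazingSd <= 0 || log10RespSd <= 0 || weightSdLog <= 0)
    stop("spreads must be > 0")
  set.seed(deriveSeed(seed, "synthetic-records"))
  treatments <- sort(unique(homeSalinity))
  rows <- list()
  for (popName in names(n)) {
    for (sal in treatments) {
      native <- sal == homeSalinity[[popName]]
      ni <- n[[popName]]
      lw <- stats::rnorm(ni, weightMeanLog, weightSdLog)
      lw <- pmax(lw, log(1.05))
      weight <- exp(lw)
      gMu <- grazingMean + (!native) * grazingDelta[[popName]] * grazingSd
      rMu <- log10RespMean + (!native) * respDelta[[popName]] * log10RespSd
      grazingStd <- stats::rnorm(ni, gMu, grazingSd)
      log10RespStd <- stats::rnorm(ni, rMu, log10RespSd)
      rows[[length(rows) + 1L]] <- data.frame(
        population = popName, salinity_psu = sal, native = native,
        weight_g = weight,
        grazing_g = grazingStd * lw,
        respiration = 10^log10RespStd * lw)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (nOutliers > 0L) {
    idx <- sample.int(nrow(records), nOutliers)
    records$grazing_g[idx] <- records$grazing_g[idx] * outlierFactor
    records$respiration[idx] <- records$respiration[idx] * outlierFactor
  }
  validateRecords(records, homeSalinity)
  records
}

#' Read / write phenotype records as delimited text
#'
#' Tab-separated with header columns population, salinity_psu, native,
#' weight_g, grazing_g, respiration.
#'
#' @param records a phenotype records data.frame.
#' @param path file path.
#' @export
writeRecords <- function(records, path) {
  utils::write.table(records[, c("population", "salinity_psu", "native",
                                 "weight_g", "grazing_g", "respiration")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  rec$native <- as.logical(rec$native)
  validateRecords(rec)
  rec
}
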
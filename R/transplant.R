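#' Sample half-sib families from a deme
#'
#' `nParents` mothers are sampled without replacement among the adults of
#' the deme; each offspring's father is drawn uniformly from the same deme
#' (selfing possible, so families are half-sib with possible full sibs).
#' Offspring genomes are formed by the same free-recombination and mutation
#' rules as the simulator.
#'
#' @param pop a [PopulationState-class].
#' @param deme 1-based deme index to sample from.
#' @param nParents mothers per deme (default 10).
#' @param nOffspring offspring per mother (default 10).
#' @return List with offspring allele matrices `zA1`, `zA2`, `gA1`, `gA2`,
#'   the `family` index per offspring, and derived vectors `z`, `g`.
#' @export
sampleFamilies <- function(pop, deme, nParents = 10L, nOffspring = 10L) {
  resid <- which(pop@deme == deme)
  if (length(resid) < nParents)
    stop(sprintf("deme %d holds %d adults; %d parents requested",
                 deme, length(resid), nParents))
  mothers <- resid[sample.int(length(resid), nParents)]
  momIdx <- rep(mothers, each = nOffspring)
  total <- nParents * nOffspring
  fathers <- resid[sample.int(length(resid), total, replace = TRUE)]
  off <- list(zA1 = gametes(pop@zA1, pop@zA2, momIdx),
              zA2 = gametes(pop@zA1, pop@zA2, fathers),
              gA1 = gametes(pop@gA1, pop@gA2, momIdx),
              gA2 = gametes(pop@gA1, pop@gA2, fathers))
  off <- mutateGenomes(off, pop@params@mutationRate)
  off$family <- rep(seq_len(nParents), each = nOffspring)
  off$z <- traitFromCopies(off$zA1, off$zA2, pop@params@effectZ)
  off$g <- traitFromCopies(off$gA1, off$gA2, pop@params@effectG)
  off
}

#' Simulate a reciprocal transplant experiment
#'
#' For each realization, families are freshly sampled in both demes; within
#' every family, half the offspring (chosen uniformly at random) remain in
#' the native environment and the other half are transplanted. Each
#' offspring's adaptive-trait phenotype u is expressed with the theta of its
#' assigned environment (plasticity is labile), and the fitness-indicator
#' trait w is the phenotype-dependent fitness component in that
#' environment. No survival or density feedback acts during the
#' experiment.
#'
#' @param pop the evolved [PopulationState-class] (evolution is not re-run:
#'   realizations re-draw samples from this fixed state).
#' @param demeA,demeB 1-based origin demes.
#' @param nRealizations independent sampling realizations (default 1000).
#' @param nParents,nOffspring family design (default 10 x 10).
#' @param seed integer seed for the experiment stream.
#' @return A [TransplantResult-class].
#' @export
reciprocalTransplant <- function(pop, demeA, demeB, nRealizations = 1000L,
                                 nParents = 10L, nOffspring = 10L,
                                 seed = pop@params@seed) {
  set.seed(deriveSeed(seed, paste("transplant", demeA, demeB)))
  thA <- thetaAt(pop@env, demeA)
  thB <- thetaAt(pop@env, demeB)
  params <- pop@params
  nHalf <- nOffspring %/% 2L
  acc <- vector("list", nRealizations)
  for (r in seq_len(nRealizations)) {
    rows <- lapply(1:2, function(orig) {
      fam <- sampleFamilies(pop, if (orig == 1L) demeA else demeB,
                            nParents, nOffspring)
      thNative <- if (orig == 1L) thA else thB
      thNew <- if (orig == 1L) thB else thA
      # random half of each family stays native
      stay <- unlist(lapply(seq_len(nParents), function(f)
        sample.int(nOffspring, nHalf) + (f - 1L) * nOffspring))
      native <- logical(nParents * nOffspring)
      native[stay] <- TRUE
      th <- ifelse(native, thNative, thNew)
      u <- phenotype(fam$z, fam$g, th)
      w <- fitnessIndicator(u, fam$g, th, params)
      data.frame(realization = r, origin = orig, native = native,
                 family = fam$family, u = u, w = w)
    })
    acc[[r]] <- rbind(rows[[1]], rows[[2]])
  }
  new("TransplantResult", demePair = as.integer(c(demeA, demeB)),
      deltaTheta = thB - thA, data = do.call(rbind, acc),
      nRealizations = as.integer(nRealizations))
}

#' @rdname reciprocalTransplant
#' @param object a `TransplantResult`.
#' @export
transplantData <- function(object) object@data

#' @rdname reciprocalTransplant
#' @export
deltaTheta <- function(object) object@deltaTheta

setMethod("show", "TransplantResult", function(object) {
  cat(sprintf(
    "TransplantResult: demes (%d, %d), delta theta = %.4g, %d realizations, %d measurements\n",
    object@demePair[1], object@demePair[2], object@deltaTheta,
    object@nRealizations, nrow(object@data)))
})

#' Reaction-norm statistics of a transplant experiment
#'
#' Per realization and per trait (adaptive u; fitness indicator w): a
#' Kruskal-Wallis omnibus over the four (origin x environment) groups,
#' followed by Dunn-type native-vs-new post hoc contrasts per origin with
#' Bonferroni adjustment over `m` contrasts (adjusted p capped at 1), and
#' signed Glass' delta (new minus native, native spread as denominator).
#' A contrast is called significant when both the omnibus and its adjusted
#' post hoc p fall below `alpha`. Each realization is then classified into
#' the qualitative outcome pattern via [classifyPattern()].
#'
#' @param result a [TransplantResult-class].
#' @param alpha significance level.
#' @param m Bonferroni multiplier (default 2: the two native-vs-new
#'   contrasts per trait).
#' @param requireOmnibus gate post hoc significance on the omnibus test
#'   (default TRUE).
#' @return A [ReactionNormStats-class].
#' @export
analyzeTransplant <- function(result, alpha = 0.05, m = 2L,
                              requireOmnibus = TRUE) {
  dat <- result@data
  reals <- split(dat, dat$realization)
  traits <- c(adaptive = "u", indicator = "w")
  statRows <- vector("list", length(reals))
  patterns <- character(length(reals))
  for (k in seq_along(reals)) {
    d <- reals[[k]]
    sig <- matrix(FALSE, 2, 2, dimnames = list(NULL, names(traits)))
    rows <- list()
    for (tn in names(traits)) {
      v <- d[[traits[[tn]]]]
      groups <- list(v[d$origin == 1 & d$native], v[d$origin == 1 & !d$native],
                     v[d$origin == 2 & d$native], v[d$origin == 2 & !d$native])
      kw <- kruskalWallis(groups)
      ph <- dunnBonferroni(groups, list(c(2L, 1L), c(4L, 3L)), m = m)
      for (orig in 1:2) {
        ctrl <- groups[[2 * orig - 1]]
        trt <- groups[[2 * orig]]
        delta <- if (stats::sd(ctrl) > 0) glassDelta(trt, ctrl) else NaN
        pAdj <- ph$pAdj[orig]
        isSig <- pAdj < alpha && (!requireOmnibus || kw$p < alpha)
        sig[orig, tn] <- isSig
        rows[[length(rows) + 1L]] <- data.frame(
          realization = d$realization[1], origin = orig, trait = tn,
          pOmnibus = kw$p, pAdj = pAdj, delta = delta, significant = isSig)
      }
    }
    statRows[[k]] <- do.call(rbind, rows)
    patterns[k] <- classifyPattern(sig[, "adaptive"], sig[, "indicator"])
  }
  freq <- table(factor(patterns, levels = unique(patterns))) / length(patterns)
  new("ReactionNormStats", stats = do.call(rbind, statRows),
      patterns = patterns,
      frequencies = stats::setNames(as.numeric(freq), names(freq)),
      alpha = alpha)
}

#' @rdname analyzeTransplant
#' @param object a `ReactionNormStats`.
#' @export
normStats <- function(object) object@stats

#' @rdname analyzeTransplant
#' @export
outcomePatterns <- function(object) object@patterns

#' @rdname analyzeTransplant
#' @export
patternFrequencies <- function(object) object@frequencies

setMethod("show", "ReactionNormStats", function(object) {
  cat(sprintf("ReactionNormStats: %d realizations (alpha = %g)\n",
              length(object@patterns), object@alpha))
  f <- sort(object@frequencies, decreasing = TRUE)
  for (nm in names(f)) cat(sprintf("  %-28s %5.1f%%\n", nm, 100 * f[[nm]]))
})

#' Classify a transplant outcome into its qualitative plasticity pattern
#'
#' Maps the four significance flags (adaptive trait origins 1 and 2, then
#' fitness-indicator trait origins 1 and 2, with origin 1 the
#' lower-plasticity deme) onto the canonical outcome patterns observed
#' across the plasticity spectrum:
#' (No,No,Yes,Yes) very low, (No,Yes,Yes,Yes) low, (Yes,Yes,Yes,Yes)
#' intermediate, (Yes,Yes,Yes,No) high, (Yes,Yes,No,No) very high
#' plasticity; anything else is "unclassified".
#'
#' @param adaptiveSig logical(2), adaptive-trait significance per origin.
#' @param indicatorSig logical(2), indicator-trait significance per origin.
#' @return Character pattern label.
#' @examples
#' classifyPattern(c(FALSE, FALSE), c(TRUE, TRUE))  # "very low plasticity"
#' @export
classifyPattern <- function(adaptiveSig, indicatorSig) {
  key <- paste(c(adaptiveSig, indicatorSig), collapse = "")
  switch(key,
         "FALSEFALSETRUETRUE" = "very low plasticity",
         "FALSETRUETRUETRUE" = "low plasticity",
         "TRUETRUETRUETRUE" = "intermediate plasticity",
         "TRUETRUETRUEFALSE" = "high plasticity",
         "TRUETRUEFALSEFALSE" = "very high plasticity",
         "unclassified")
}

#' Direction concordance of a pair of reaction norms
#'
#' Significant reaction norms that share the same sign for both origins
#' behave like a fitness-indicator trait under sub-optimal buffering
#' (fitness drops in the new environment for both populations); opposite
#' signs are the signature of an adaptive trait tracking opposite optima.
#'
#' @param deltaOrigin1,deltaOrigin2 signed effect sizes for the two origins.
#' @param bothSignificant logical, are both reaction norms significant.
#' @return "fitness-indicator-like", "adaptive-like", or "indeterminate".
#' @export
directionConcordance <- function(deltaOrigin1, deltaOrigin2,
                                 bothSignificant) {
  if (!isTRUE(bothSignificant) || is.na(deltaOrigin1) || is.na(deltaOrigin2))
    return("indeterminate")
  s <- sign(deltaOrigin1) * sign(deltaOrigin2)
  if (s > 0) "fitness-indicator-like"
  else if (s < 0) "adaptive-like"
  else "indeterminate"
}

#' Scan transplants from a focal deme over alternative demes
#'
#' Runs one reciprocal transplant plus analysis per (focal, alternative)
#' pair and summarizes each pair for effect-size-versus-delta-theta curves.
#'
#' @param pop evolved [PopulationState-class].
#' @param focalDeme 1-based focal deme.
#' @param alternativeDemes integer vector of alternative demes.
#' @param nRealizations realizations per pair.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param ... passed to [reciprocalTransplant()].
#' @return List with `summary` (one row per pair x origin x trait:
#'   alternative, deltaTheta, meanDelta, fracSignificant, medianPAdj,
#'   ordered by deltaTheta) and `stats` (all per-realization rows with an
#'   `alternative` column).
#' @export
demeScan <- function(pop, focalDeme, alternativeDemes, nRealizations = 100L,
                     alpha = 0.05, seed = pop@params@seed, ...) {
  summaries <- list(); details <- list()
  for (alt in alternativeDemes) {
    tr <- reciprocalTransplant(pop, focalDeme, alt,
                               nRealizations = nRealizations,
                               seed = seed, ...)
    st <- normStats(analyzeTransplant(tr, alpha = alpha))
    st$alternative <- alt
    st$deltaTheta <- deltaTheta(tr)
    details[[length(details) + 1L]] <- st
    agg <- stats::aggregate(cbind(delta, significant, pAdj) ~ origin + trait,
                            data = st,
                            FUN = function(x) mean(x))
    med <- stats::aggregate(pAdj ~ origin + trait, data = st, FUN = stats::median)
    summaries[[length(summaries) + 1L]] <- data.frame(
      alternative = alt, deltaTheta = deltaTheta(tr),
      origin = agg$origin, trait = agg$trait, meanDelta = agg$delta,
      fracSignificant = agg$significant, medianPAdj = med$pAdj)
  }
  summary <- do.call(rbind, summaries)
  summary <- summary[order(summary$deltaTheta, summary$origin, summary$trait), ]
  rownames(summary) <- NULL
  list(summary = summary, stats = do.call(rbind, details))
}

#' Choose transplant deme pairs spanning the plasticity spectrum
#'
#' Encodes the sampling design of the in-silico experiments: five origin
#' pairs are placed along the evolved plasticity gradient (right habitat
#' half) so that qualitatively different transplant outcomes are expected,
#' from very low to very high local plasticity. With `gbar` the deme-mean
#' plasticity relative to its habitat maximum:
#' \describe{
#'   \item{veryLow}{both origins below 0.2 of the maximum; the pair spans
#'     the widest available optimum difference so the fitness-indicator
#'     signal is detectable while the adaptive trait stays flat.}
#'   \item{low}{a low-plasticity origin paired with one at 0.25-0.45 of
#'     the maximum (nearest deme above the centre).}
#'   \item{intermediate}{the two lowest-optimum demes with relative
#'     plasticity 0.45-0.65.}
#'   \item{high}{the 0.75-0.95 pair minimizing the difference in the
#'     nonplastic component (reaction norms driven by plasticity alone).}
#'   \item{veryHigh}{the two highest-optimum demes above 0.95.}
#' }
#' Each pair is ordered so origin 1 is the lower-plasticity deme. Windows
#' that contain too few demes fall back to the demes nearest the window.
#'
#' @param pop an evolved [PopulationState-class].
#' @param minN minimum deme occupancy for a sampling location.
#' @return data.frame with columns regime, deme1, deme2, theta1, theta2,
#'   g1, g2.
#' @export
pickTransplantPairs <- function(pop, minN = 15L) {
  s <- populationSummary(pop)
  sel <- s[s$occupied & s$N >= minN & s$position >= 0, ]
  if (nrow(sel) < 5L) stop("too few occupied demes to place experiments")
  rel <- sel$meanG / max(sel$meanG)
  inWin <- function(lo, hi) which(rel >= lo & rel < hi)
  nearest <- function(target, k, exclude = integer()) {
    ord <- order(abs(rel - target))
    setdiff(ord, exclude)[seq_len(k)]
  }
  win <- function(lo, hi, k) {
    idx <- inWin(lo, hi)
    if (length(idx) >= k) idx else nearest((lo + hi) / 2, k)
  }

  lowIdx <- win(0, 0.2, 2L)
  base <- lowIdx[which.min(sel$theta[lowIdx])]          # central low-g deme
  vlAlt <- lowIdx[which.max(sel$theta[lowIdx])]         # widest low-g span
  if (vlAlt == base) vlAlt <- nearest(0.1, 2L, exclude = base)[1]

  lowWin <- win(0.25, 0.45, 1L)
  lowAlt <- lowWin[which.min(sel$theta[lowWin])]

  midWin <- win(0.45, 0.65, 2L)
  mid <- midWin[order(sel$theta[midWin])][1:2]

  highWin <- win(0.75, 0.95, 2L)
  cmb <- utils::combn(highWin, 2L)
  dz <- abs(sel$meanZ[cmb[1, ]] - sel$meanZ[cmb[2, ]])
  high <- cmb[, which.min(dz)]

  vhWin <- win(0.95, Inf, 2L)
  vh <- vhWin[order(sel$theta[vhWin], decreasing = TRUE)][1:2]

  mk <- function(regime, i, j) {
    if (sel$meanG[i] > sel$meanG[j]) { t <- i; i <- j; j <- t }
    data.frame(regime = regime, deme1 = sel$deme[i], deme2 = sel$deme[j],
               theta1 = sel$theta[i], theta2 = sel$theta[j],
               g1 = sel$meanG[i], g2 = sel$meanG[j])
  }
  rbind(mk("veryLow", base, vlAlt),
        mk("low", base, lowAlt),
        mk("intermediate", mid[1], mid[2]),
        mk("high", high[1], high[2]),
        mk("veryHigh", vh[1], vh[2]))
}

#' Write per-realization reaction-norm statistics as tidy delimited text
#'
#' One row per realization x origin x trait with p-values, effect size and
#' significance flag.
#'
#' @param object a [ReactionNormStats-class].
#' @param path file path.
#' @export
writeNormStats <- function(object, path) {
  st <- object@stats
  st$pAdjPrinted <- formatPValue(st$pAdj)
  utils::write.table(st, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
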
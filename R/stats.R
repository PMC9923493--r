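#' Kruskal-Wallis omnibus test over k groups
#'
#' Tie-corrected rank test; H is referred to the chi-square law with k - 1
#' degrees of freedom (via [stats::kruskal.test()]). The degenerate case of
#' all values identical is reported as H = 0, p = 1 rather than an error.
#'
#' @param groups list of k >= 2 nonempty numeric vectors.
#' @return List with elements `H` and `p`.
#' @examples
#' kruskalWallis(list(1:3, 4:6))
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 numeric vectors")
  if (any(lengths(groups) == 0L)) stop("all groups must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  gfac <- factor(rep.int(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, gfac)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

# Tie-corrected variance building block for Dunn's z: the pooled mid-rank
# variance term N(N+1)/12 - sum(t^3 - t) / (12 (N - 1)).
dunnTieTerm <- function(pooled) {
  N <- length(pooled)
  t <- table(pooled)
  N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
}

#' Dunn-type post hoc contrasts with Bonferroni adjustment
#'
#' After a Kruskal-Wallis omnibus over all groups, selected pairwise
#' contrasts are tested on the pooled mid-ranks with Dunn's z statistic
#' (tie-corrected variance); two-sided normal p-values are multiplied by
#' `m` and capped at 1.
#'
#' @param groups list of numeric vectors (the omnibus groups).
#' @param contrasts list of integer pairs indexing `groups`.
#' @param m Bonferroni multiplier; defaults to the number of contrasts.
#' @return data.frame with columns i, j, z, pRaw, pAdj.
#' @export
dunnBonferroni <- function(groups, contrasts, m = length(contrasts)) {
  if (length(contrasts) == 0L)
    return(data.frame(i = integer(), j = integer(), z = numeric(),
                      pRaw = numeric(), pAdj = numeric()))
  if (m < length(contrasts)) stop("m must be >= number of contrasts")
  x <- unlist(groups, use.names = FALSE)
  gfac <- rep.int(seq_along(groups), lengths(groups))
  r <- rank(x)
  tie <- dunnTieTerm(x)
  meanR <- tapply(r, gfac, mean)
  n <- lengths(groups)
  out <- lapply(contrasts, function(ct) {
    i <- ct[1]; j <- ct[2]
    se <- sqrt(tie * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (meanR[[i]] - meanR[[j]]) / se else 0
    pRaw <- 2 * stats::pnorm(-abs(z))
    data.frame(i = i, j = j, z = z, pRaw = pRaw,
               pAdj = min(1, pRaw * m))
  })
  do.call(rbind, out)
}

#' Format an adjusted p-value the way transplant tables report it
#'
#' Values above 0.99 (including capped ones) print as ">0.99".
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
formatPValue <- function(p) {
  ifelse(p > 0.99, ">0.99", formatC(p, format = "g", digits = 2))
}

#' Glass' delta effect size
#'
#' Standardized mean difference using the control group's sample standard
#' deviation (n - 1 denominator): delta = (mean(treatment) - mean(control))
#' / sd(control). In transplant analyses the native group is the control and
#' the transplanted ("new environment") group the treatment, so the sign is
#' new minus native.
#'
#' @param treatment numeric vector.
#' @param control numeric vector (>= 2 values with nonzero spread).
#' @return Scalar delta; NaN with a warning when the control spread is zero.
#' @examples
#' glassDelta(c(1, 2, 3) + 1, c(1, 2, 3))  # +1
#' @export
glassDelta <- function(treatment, control) {
  if (length(control) < 2L) stop("control needs >= 2 values")
  s <- stats::sd(control)
  if (s == 0) {
    warning("zero control spread: Glass' delta undefined")
    return(NaN)
  }
  (mean(treatment) - mean(control)) / s
}

#' Qualitative magnitude category of an effect size
#'
#' Rule-of-thumb thresholds on |delta|: 0.2 small, 0.5 medium, 0.8 large,
#' 1.2 very large, 2.0 huge (boundaries inclusive); below 0.2 is
#' negligible. Sign is ignored.
#'
#' @param delta numeric vector of effect sizes.
#' @return Character vector of categories.
#' @examples
#' effectSizeCategory(c(0, 0.8, -3.7))
#' @export
effectSizeCategory <- function(delta) {
  a <- abs(delta)
  cut(a, breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, 2.0, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large", "very large",
                 "huge")) |> as.character()
}

#' Iterative two-sided Grubbs outlier test
#'
#' The Grubbs statistic G = max|x - mean(x)| / sd(x) is compared with the
#' t-based critical value ((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2)) with
#' t = qt(1 - alpha/(2n), n - 2); the most extreme point is removed and the
#' test repeated until no rejection (or fewer than 3 points remain).
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level per pass.
#' @return Integer indices (into `values`) of detected outliers, possibly
#'   empty.
#' @export
grubbsOutliers <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop("Grubbs test requires n >= 3")
  idx <- seq_along(values)
  out <- integer()
  repeat {
    n <- length(values)
    if (n < 3L) break
    s <- stats::sd(values)
    if (s == 0) break
    dev <- abs(values - mean(values))
    G <- max(dev) / s
    tq <- stats::qt(1 - alpha / (2 * n), n - 2L)
    crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= crit) break
    worst <- which.max(dev)
    out <- c(out, idx[worst])
    values <- values[-worst]
    idx <- idx[-worst]
  }
  out
}

#' Two-way factorial ANOVA
#'
#' Fits value ~ A * B. Balanced designs use the classical sequential
#' decomposition; unbalanced designs use type-III sums of squares (sum
#' contrasts, via [car::Anova()]). Both factors need >= 2 levels and the
#' interaction needs >= 2 replicates per cell.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (coerced).
#' @return data.frame with rows A, B, A:B and columns F and p.
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  A <- factor(factorA); B <- factor(factorB)
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need >= 2 levels")
  cells <- table(A, B)
  if (any(cells == 0L)) stop("empty design cells")
  dat <- data.frame(y = values, A = A, B = B)
  balanced <- length(unique(as.vector(cells))) == 1L
  if (balanced) {
    fit <- stats::aov(y ~ A * B, data = dat)
    tab <- summary(fit)[[1]]
    res <- data.frame(term = c("A", "B", "A:B"),
                      F = tab[["F value"]][1:3], p = tab[["Pr(>F)"]][1:3])
  } else {
    fit <- stats::lm(y ~ A * B, data = dat,
                     contrasts = list(A = "contr.sum", B = "contr.sum"))
    tab <- car::Anova(fit, type = 3)
    keep <- c("A", "B", "A:B")
    res <- data.frame(term = c("A", "B", "A:B"),
                      F = tab[keep, "F value"], p = tab[keep, "Pr(>F)"])
  }
  # an all-constant response has no variance anywhere: report F = 0, p = 1
  res$F[!is.finite(res$F)] <- 0
  res$p[!is.finite(res$p)] <- 1
  if (stats::var(values) == 0) { res$F[] <- 0; res$p[] <- 1 }
  rownames(res) <- res$term
  res
}

#' PCA on a genotype matrix of allele counts
#'
#' Columns (loci) are mean-centred and the centred matrix decomposed by
#' singular values; this is a PCA of the individual-by-individual genetic
#' covariance ("similarity") matrix over all loci, without allele-frequency
#' scaling.
#'
#' @param genotypes numeric matrix, individuals x loci, allele counts
#'   0/1/2 (any numeric dosage accepted).
#' @param nComponents retained components (default: all with positive
#'   variance).
#' @return List with `scores` (individuals x components),
#'   `explainedVariance` (fractions summing to 1 over all positive-variance
#'   components), `sdev`, and `monomorphic` flag (TRUE when no locus
#'   varies).
#' @export
pcaGenotypes <- function(genotypes, nComponents = NULL) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L) stop("need >= 2 individuals")
  centred <- scale(genotypes, center = TRUE, scale = FALSE)
  if (all(abs(centred) < 1e-12)) {
    return(list(scores = matrix(0, nrow(genotypes), 1),
                explainedVariance = 0, sdev = 0, monomorphic = TRUE))
  }
  pc <- stats::prcomp(genotypes, center = TRUE, scale. = FALSE)
  pos <- pc$sdev^2 > 1e-12 * pc$sdev[1]^2
  k <- if (is.null(nComponents)) sum(pos) else min(nComponents, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explainedVariance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       sdev = pc$sdev[seq_len(k)],
       monomorphic = FALSE)
}

#' Allele-count genotype matrix of a population's simulated loci
#'
#' Counts of the "+" allele (0/1/2) per individual at every locus of both
#' trait components, suitable for [pcaGenotypes()].
#'
#' @param pop a [PopulationState-class].
#' @param which individuals to include (default all).
#' @return Integer matrix, individuals x 2L loci.
#' @export
genotypeMatrix <- function(pop, which = seq_len(nIndividuals(pop))) {
  cbind(pop@zA1[which, , drop = FALSE] + pop@zA2[which, , drop = FALSE],
        pop@gA1[which, , drop = FALSE] + pop@gA2[which, , drop = FALSE])
}
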
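#' Floor-aware quantile normalization of a censored subpopulation
#'
#' Growth distributions under strong stresses are approximately normal with
#' a hard floor of no-growth strains. This maps every value onto a normal
#' whose parameters are estimated only from the portion well separated from
#' the floor: plotting positions `q_i = (rank_i - 0.5)/n` (midranks for
#' ties) are assigned over the full subpopulation, the observed values with
#' `value > floor_cut` are regressed on the standard-normal quantiles
#' `qnorm(q_i)` giving `mu` (intercept) and `sigma` (slope), and every
#' value is replaced by `mu + sigma * qnorm(q_i)`. Rank order is preserved
#' exactly; floored values are thereby imputed from the fitted normal.
#'
#' @param values numeric (optionally named) per-strain areas (mm^2) for one
#'   allele subpopulation.
#' @param floor_cut separation cutoff in mm^2 (default 5).
#' @return normalized values (same names/order), with attributes `mu` and
#'   `sigma` of the fitted normal.
#' @export
quantile_normalize_floored <- function(values, floor_cut = 5) {
  stopifnot(is.numeric(values))
  n <- length(values)
  above <- values > floor_cut
  if (sum(above) < 10L) {
    stop("need at least 10 values above the floor cutoff (have ",
         sum(above), ")")
  }
  q <- (rank(values) - 0.5) / n
  z <- qnorm(q)
  fit <- lm(values[above] ~ z[above])
  mu <- unname(coef(fit)[1])
  sigma <- unname(coef(fit)[2])
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate normal fit (sigma <= 0)")
  }
  out <- mu + sigma * z
  names(out) <- names(values)
  structure(out, mu = mu, sigma = sigma)
}

#' Broad-sense heritability from replicate measurements
#'
#' Estimates `H^2 = 1 - sigma2_e / sigma2_s`, where `sigma2_s` is the
#' variance of the population of segregant means and
#' `sigma2_e = sigma2_w / n_bar` is the sampling variance of those means:
#' the pooled within-segregant variance `sigma2_w` comes from a one-way
#' random-intercept model fitted by REML (or a method-of-moments pooled
#' variance), and `n_bar` is the mean number of retained measurements per
#' segregant. Only measurements above `min_area` from segregants with at
#' least `min_reps` such measurements enter the *within-variance* fit
#' (excluding the no-growth floor, where replicate noise reflects the
#' detection limit rather than growth); `sigma2_s` is taken over the full
#' population of per-strain means so that it is comparable with the
#' centered-subpopulation variance of [locus_variance()].
#'
#' @param data data.frame with columns `strain` and `area` (one row per
#'   replicate measurement, mm^2).
#' @param min_area retain measurements strictly above this (default 5).
#' @param min_reps minimum retained measurements per strain (default 2).
#' @param method `"reml"` (lme4 random-intercept fit, the default) or
#'   `"moments"` (pooled within-group variance).
#' @param strain_means optional named vector overriding the segregant means
#'   used for `sigma2_s` (e.g. quantile-normalized means).
#' @return object of class `variance_components` with `sigma2_s`,
#'   `sigma2_w`, `sigma2_e`, `n_bar`, `H2`, `n_strains`.
#' @export
heritability <- function(data, min_area = 5, min_reps = 2,
                         method = c("reml", "moments"),
                         strain_means = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("strain", "area") %in% names(data)))
  d <- data[!is.na(data$area) & data$area > min_area, c("strain", "area")]
  reps <- table(d$strain)
  keep <- names(reps)[reps >= min_reps]
  if (length(keep) < 2L) stop("fewer than 2 strains pass the filters")
  d <- d[d$strain %in% keep, ]
  d$strain <- factor(d$strain)

  sigma2_w <- if (method == "reml") {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(area ~ 1 + (1 | strain), data = d)))
    sigma(fit)^2
  } else {
    gm <- tapply(d$area, d$strain, mean)
    sum((d$area - gm[as.character(d$strain)])^2) /
      (nrow(d) - nlevels(d$strain))
  }
  n_bar <- nrow(d) / nlevels(d$strain)
  sigma2_e <- sigma2_w / n_bar

  means <- if (is.null(strain_means)) {
    all_ok <- data[!is.na(data$area), c("strain", "area")]
    tapply(all_ok$area, all_ok$strain, mean)
  } else {
    strain_means[!is.na(strain_means)]
  }
  if (length(means) < 2L) stop("fewer than 2 strains with a mean")
  sigma2_s <- var(as.numeric(means))
  if (sigma2_s == 0) stop("zero variance of segregant means: H2 undefined")
  structure(list(sigma2_s = sigma2_s, sigma2_w = sigma2_w,
                 sigma2_e = sigma2_e, n_bar = n_bar,
                 H2 = 1 - sigma2_e / sigma2_s,
                 n_strains = length(means)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("Variance components (%d strains): sigma2_s=%.3f, ",
                     "sigma2_w=%.3f, n_bar=%.2f, sigma2_e=%.3f, H2=%.3f\n"),
              x$n_strains, x$sigma2_s, x$sigma2_w, x$n_bar, x$sigma2_e,
              x$H2))
  invisible(x)
}

#' Genetic variance explained by one locus
#'
#' The two allele subpopulations are centered to mean zero; the variance of
#' the pooled centered segregant means `sigma2_ns` is what remains after
#' removing the locus effect, so the locus accounts for
#' `sigma2_s - sigma2_ns` of the phenotypic variance of segregant means.
#' The proportion of the *genetic* variance explained uses `H2 * sigma2_s`
#' as denominator. Negative explained variance (possible under the null by
#' sampling noise) is reported as-is with a warning, never clamped.
#'
#' @param segregant_means named numeric vector of per-strain means.
#' @param alleles parallel (named) vector of `"P1"`/`"P2"` calls at the
#'   locus; missing calls are dropped.
#' @param vc a `variance_components` object for the same condition.
#' @return object of class `locus_variance` with `sigma2_ns`, `explained`,
#'   `proportion_genetic`, `residual_genetic`.
#' @export
locus_variance <- function(segregant_means, alleles, vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (!is.null(names(segregant_means)) && !is.null(names(alleles))) {
    common <- intersect(names(segregant_means), names(alleles))
    segregant_means <- segregant_means[common]
    alleles <- alleles[common]
  }
  ok <- !is.na(segregant_means) & alleles %in% c("P1", "P2")
  m <- segregant_means[ok]
  a <- alleles[ok]
  if (length(m) == 0L) stop("no strains with both a mean and an allele call")
  if (length(unique(a)) < 2L) stop("one allele class is empty")
  centered <- m - tapply(m, a, mean)[a]
  sigma2_ns <- var(as.numeric(centered))
  explained <- vc$sigma2_s - sigma2_ns
  if (explained < 0) {
    warning("negative explained variance (", signif(explained, 3),
            "); reported unclamped")
  }
  structure(list(sigma2_ns = sigma2_ns, explained = explained,
                 proportion_genetic = explained / (vc$H2 * vc$sigma2_s),
                 residual_genetic = sigma2_ns - vc$sigma2_e),
            class = "locus_variance")
}

#' @export
print.locus_variance <- function(x, ...) {
  cat(sprintf(paste0("Locus variance: sigma2_ns=%.3f, explained=%.3f ",
                     "(%.1f%% of genetic), residual genetic=%.3f\n"),
              x$sigma2_ns, x$explained, 100 * x$proportion_genetic,
              x$residual_genetic))
  invisible(x)
}

#' Two-factor interaction ANOVA: locus allele x medium additive
#'
#' Fixed-effects two-way ANOVA with interaction on patch areas, testing
#' whether a medium additive changes the effect of the major-locus allele
#' beyond its rich-medium effect. Type II sums of squares accommodate
#' mildly unbalanced designs.
#'
#' @param area numeric response (mm^2), one value per observation.
#' @param allele factor (or vector) giving the locus allele per observation.
#' @param additive factor: presence/absence of the medium additive.
#' @return list with `F` and `p` for the interaction term and the full
#'   ANOVA `table`.
#' @export
interaction_anova <- function(area, allele, additive) {
  allele <- factor(allele)
  additive <- factor(additive)
  stopifnot(length(area) == length(allele), length(area) == length(additive))
  if (nlevels(allele) < 2 || nlevels(additive) < 2) {
    single <- if (nlevels(allele) < 2) "allele" else "additive"
    stop("empty design cell: factor '", single, "' has a single level")
  }
  cells <- table(allele, additive)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: allele=", rownames(cells)[empty[1]],
         ", additive=", colnames(cells)[empty[2]])
  }
  fit <- lm(area ~ allele * additive)
  tab <- car::Anova(fit, type = 2)
  i <- grep("allele:additive", rownames(tab))
  list(F = tab[i, "F value"], p = tab[i, "Pr(>F)"], table = tab)
}

#' Mann-Whitney U comparison of two groups of areas
#'
#' Nonparametric location comparison with midranks: exact two-sided p-value
#' by enumeration when both groups have fewer than 8 untied observations,
#' otherwise the tie-corrected normal approximation (no continuity
#' correction). The raw difference of group means (mm^2) is reported
#' alongside; multiple-testing correction across conditions is the
#' caller's responsibility.
#'
#' @param x,y numeric vectors of areas for the two groups.
#' @return list with `U`, `p`, `mean_diff` (`mean(x) - mean(y)`).
#' @export
group_difference_tests <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) < 8 && length(y) < 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       mean_diff = mean(x) - mean(y))
}

#' Pearson correlation of per-strain means between two conditions
#'
#' @param a,b named numeric vectors of per-strain means; strains present in
#'   both enter the correlation.
#' @return Pearson product-moment correlation coefficient.
#' @export
condition_correlation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) {
    stop("unnamed vectors must have equal length")
  }
  ok <- complete.cases(a, b)
  if (sum(ok) < 3L) stop("fewer than 3 complete strain pairs")
  if (var(a[ok]) == 0 || var(b[ok]) == 0) {
    stop("zero variance in one condition: correlation undefined")
  }
  cor(a[ok], b[ok])
}
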
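#' Natural-log transform of biomarker level columns
#'
#' Adds `log_<name>` columns for the named level columns, which must be
#' strictly positive (biomarker concentrations in mg/L or similar). Level
#' columns are retained so descriptive tables can keep reporting
#' untransformed means.
#'
#' @param cohort data.frame of per-individual covariates and biomarker
#'   levels.
#' @param columns character vector of level column names.
#' @return the cohort with `log_*` columns appended.
#' @export
log_transform <- function(cohort, columns) {
  missing_cols <- setdiff(columns, names(cohort))
  if (length(missing_cols)) {
    stop("column(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  }
  for (cl in columns) {
    x <- cohort[[cl]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("non-positive value in column '", cl, "' at row ", bad[1])
    }
    cohort[[paste0("log_", cl)]] <- log(x)
  }
  cohort
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of an outcome (usually a log-transformed
#' biomarker) on a genotype exposure plus confounding covariates, with an
#' intercept. Reports the exposure coefficient, its standard error, a
#' normal-approximation 95% CI (multiplier 1.96) and the two-sided t-test
#' p-value. Rows with a missing value in any used column are dropped
#' (complete-case per model).
#'
#' @param data data.frame holding all columns.
#' @param outcome outcome column name.
#' @param exposure exposure column name (dosage, indicator, or haplotype
#'   dosage).
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @return An object of class `association_result`: list with `outcome`,
#'   `exposure`, `estimate`, `se`, `ci` (length-2), `p`, `n`, `covariates`,
#'   `sigma` (residual SD), and the full coefficient table `coefficients`.
#' @export
fit_linear <- function(data, outcome, exposure, covariates = character()) {
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  n <- nrow(d)
  if (n <= length(cols) + 1L) stop("too few complete cases (n = ", n, ")")
  if (length(unique(d[[exposure]])) < 2L) {
    stop("exposure '", exposure, "' is constant on the analysis sample")
  }
  fm <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(fm, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  est <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  structure(list(outcome = outcome, exposure = exposure,
                 estimate = est, se = se,
                 ci = c(est - 1.96 * se, est + 1.96 * se),
                 p = sm[exposure, "Pr(>|t|)"],
                 n = n, covariates = covariates,
                 sigma = summary(fit)$sigma,
                 coefficients = sm),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s ~ %s%s (n = %d)\n", x$outcome, x$exposure,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + "))
              else "", x$n))
  cat(sprintf("  beta = %.4g (95%% CI %.4g to %.4g), SE = %.4g, p = %.3g\n",
              x$estimate, x$ci[1], x$ci[2], x$se, x$p))
  invisible(x)
}

#' Partial Pearson correlation
#'
#' Pearson correlation between two variables after removing linear
#' covariate effects from each: both are regressed on the covariates (with
#' intercept) and the residual vectors are correlated. The p-value uses the
#' t distribution with `n - k - 2` degrees of freedom, `k` the number of
#' covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of covariates.
#' @return list with `r`, `p`, `df`, `n`, and logical `degenerate` (TRUE
#'   when a residual vector has zero variance, in which case `r` is `NA`).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(1, length(x), 1)
    k <- 0L
  } else {
    covariates <- as.matrix(covariates)
    Z <- cbind(1, covariates)
    k <- ncol(covariates)
  }
  cc <- stats::complete.cases(cbind(x, y, Z))
  x <- x[cc]; y <- y[cc]; Z <- Z[cc, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2L) stop("too few complete cases for partial correlation")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  # residual variance at numerical zero (e.g. x is itself a covariate)
  degen <- function(r, v) stats::var(r) <= 1e-12 * max(stats::var(v), 1e-300)
  if (degen(rx, x) || degen(ry, y)) {
    return(list(r = NA_real_, p = NA_real_, df = n - k - 2L, n = n,
                degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = df, n = n,
       degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' Multiplies a p-value by the size of its test family. Unlike
#' `p.adjust(..., "bonferroni")` the product is deliberately not capped at
#' 1: adjusted values above 1 are conventionally reported as "NS" (see
#' [format_adjusted_p()]), and the uncapped value keeps the adjustment
#' exactly invertible.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m number of tests in the family (>= 1).
#' @return numeric vector `p * m` (may exceed 1).
#' @examples
#' bonferroni_adjust(4.94e-6, 5)
#' format_adjusted_p(bonferroni_adjust(0.5, 3))  # "NS"
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (any(m < 1)) stop("family size m must be >= 1")
  p * m
}

#' Report an adjusted p-value, with values above 1 as "NS"
#'
#' @param p_adj adjusted p-value(s) from [bonferroni_adjust()].
#' @param digits significant digits for formatting.
#' @return character vector.
#' @export
format_adjusted_p <- function(p_adj, digits = 3) {
  ifelse(is.na(p_adj), NA_character_,
         ifelse(p_adj > 1, "NS", formatC(signif(p_adj, digits),
                                         format = "g", digits = digits)))
}

#' Mediator-quartile subgroup analysis
#'
#' Splits the cohort at the empirical quartiles of a mediator level
#' (linear-interpolation quantiles; intervals are right-closed so ties go
#' to the lower quartile), refits the covariate-adjusted exposure-outcome
#' association within each quartile, and tests the trend in carrier
#' frequency across quartiles by a chi-square test on the 4 x 2 carrier
#' table.
#'
#' @param data data.frame with all columns.
#' @param mediator mediator level column (non-constant).
#' @param exposure genotype coding column (additive dosage or indicator);
#'   `carrier = exposure > 0` defines the trend table.
#' @param outcome outcome column.
#' @param covariates covariate column names.
#' @param min_per_quartile smallest admissible quartile size.
#' @return list with `fits` (list of four `association_result`s),
#'   `table` (data.frame of per-quartile estimates), `carrier_table`
#'   (4 x 2), `trend_chisq`, `trend_p`, `breaks`.
#' @export
quartile_subgroup <- function(data, mediator, exposure, outcome, covariates,
                              min_per_quartile = 8L) {
  cols <- c(mediator, exposure, outcome, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  med <- d[[mediator]]
  if (length(unique(med)) < 2L) stop("mediator '", mediator, "' is constant")
  qs <- stats::quantile(med, probs = c(0.25, 0.5, 0.75), type = 7,
                        names = FALSE)
  grp <- 1L + (med > qs[1]) + (med > qs[2]) + (med > qs[3])
  sizes <- tabulate(grp, 4L)
  if (any(sizes < min_per_quartile)) {
    stop("quartile with fewer than ", min_per_quartile, " individuals")
  }
  fits <- lapply(1:4, function(q) {
    fit_linear(d[grp == q, , drop = FALSE], outcome, exposure, covariates)
  })
  tab <- do.call(rbind, lapply(1:4, function(q) {
    f <- fits[[q]]
    data.frame(quartile = q, n = f$n, estimate = f$estimate, se = f$se,
               ci_lower = f$ci[1], ci_upper = f$ci[2], p = f$p)
  }))
  carrier <- factor(d[[exposure]] > 0, levels = c(FALSE, TRUE))
  ct <- table(quartile = grp, carrier = carrier)
  if (any(ct == 0)) warning("empty cell in the carrier trend table")
  chi <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
  list(fits = fits, table = tab, carrier_table = ct,
       trend_chisq = unname(chi$statistic), trend_p = chi$p.value,
       breaks = qs)
}

#' Two-group cohort description
#'
#' Mean +/- SD per group with a pooled-variance two-sided t-test for
#' continuous variables (run on the natural-log scale for designated
#' right-skewed markers, while untransformed means are displayed), and
#' proportions with a chi-square test for categorical indicators.
#' Medication-based exclusion rules can be attached per variable.
#'
#' @param cohort data.frame.
#' @param group binary grouping column name (e.g. sex indicator).
#' @param continuous character vector of continuous variable names.
#' @param categorical character vector of 0/1 indicator names.
#' @param log_scale subset of `continuous` whose test runs on log values.
#' @param exclusions named list: for variable `v`, `exclusions[[v]]` names
#'   an indicator column; rows with indicator 1 are excluded for that
#'   variable only.
#' @return data.frame with one row per variable: group summaries, p-value
#'   and test label.
#' @export
describe_cohort <- function(cohort, group, continuous,
                            categorical = character(),
                            log_scale = character(),
                            exclusions = list()) {
  g <- cohort[[group]]
  if (!all(stats::na.omit(g) %in% 0:1)) stop("group must be a 0/1 indicator")
  if (min(table(g)) < 2L) stop("each group needs at least 2 members")
  fmt <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  rows <- list()
  for (v in continuous) {
    d <- cohort
    if (!is.null(exclusions[[v]])) d <- d[d[[exclusions[[v]]]] == 0, ]
    ok <- !is.na(d[[v]]) & !is.na(d[[group]])
    x0 <- d[[v]][ok & d[[group]] == 0]
    x1 <- d[[v]][ok & d[[group]] == 1]
    tx0 <- if (v %in% log_scale) log(x0) else x0
    tx1 <- if (v %in% log_scale) log(x1) else x1
    p <- if (stats::var(c(tx0, tx1)) == 0) 1 else
      stats::t.test(tx0, tx1, var.equal = TRUE)$p.value
    rows[[v]] <- data.frame(variable = v, group0 = fmt(x0), group1 = fmt(x1),
                            p = p,
                            test = if (v %in% log_scale) "t (log scale)"
                                   else "t")
  }
  for (v in categorical) {
    d <- cohort
    if (!is.null(exclusions[[v]])) d <- d[d[[exclusions[[v]]]] == 0, ]
    ok <- !is.na(d[[v]]) & !is.na(d[[group]])
    tab <- table(d[[group]][ok], factor(d[[v]][ok], levels = 0:1))
    pr0 <- prop.table(tab, 1)
    identical_props <- all(abs(pr0[1, ] - pr0[2, ]) < 1e-12)
    p <- if (identical_props) 1 else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    pr <- prop.table(tab, 1)[, "1"] * 100
    rows[[v]] <- data.frame(variable = v,
                            group0 = sprintf("%.1f%%", pr[1]),
                            group1 = sprintf("%.1f%%", pr[2]),
                            p = p, test = "chi-square")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
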
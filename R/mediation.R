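#' Path regressions for a three-variable mediation model
#'
#' Fits the three covariate-adjusted OLS models of the classical
#' product-of-coefficients mediation framework on one common complete-case
#' sample:
#'
#' 1. `mediator ~ iv + covariates` giving the exposure-to-mediator path
#'    `alpha` (criterion 1: the independent variable must predict the
#'    mediator);
#' 2. `dv ~ mediator + iv + covariates` giving the mediator-to-outcome path
#'    `beta` adjusting for the exposure (criterion 2) and the direct effect
#'    `gamma_prime`;
#' 3. `dv ~ iv + covariates` giving the independently fitted total effect
#'    (criterion 3).
#'
#' The indirect (mediation) effect is the product `alpha * beta`, and on a
#' shared sample the OLS decomposition identity
#' `total = gamma_prime + alpha * beta` holds exactly; it is asserted to
#' 1e-8. Sobel-test fields are left unset; see [sobel_test()] and
#' [mediate()].
#'
#' @param data data.frame with all columns.
#' @param iv exposure column (genotype dosage, carrier indicator or
#'   haplotype dosage).
#' @param mediator mediator column (log biomarker level).
#' @param dv dependent-variable column (log biomarker level).
#' @param covariates covariate column names (age, sex, BMI, smoking,
#'   medication indicators in the canonical analysis).
#' @param level significance level for the criterion flags (default 0.05).
#' @return An object of class `mediation_result`; see [mediate()] for the
#'   field list. `sobel_se`, `sobel_z`, `sobel_p`, `criterion4` and
#'   `classification` are `NA` at this stage.
#' @export
mediation_paths <- function(data, iv, mediator, dv, covariates = character(),
                            level = 0.05) {
  cols <- c(iv, mediator, dv, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (length(unique(d[[iv]])) < 2L) stop("exposure '", iv, "' is constant")
  f1 <- fit_linear(d, mediator, iv, covariates)
  f2m <- fit_linear(d, dv, mediator, c(iv, covariates))
  f2i <- fit_linear(d, dv, iv, c(mediator, covariates))
  f3 <- fit_linear(d, dv, iv, covariates)
  if (!(f1$n == f2m$n && f1$n == f3$n)) {
    stop("path models did not use the same sample; ",
         "the decomposition identity requires shared complete cases")
  }
  indirect <- f1$estimate * f2m$estimate
  total <- f3$estimate
  if (abs(total - (f2i$estimate + indirect)) > 1e-8) {
    stop("OLS decomposition identity violated beyond 1e-8; ",
         "models are not on a shared sample/covariate set")
  }
  structure(list(
    iv = iv, mediator = mediator, dv = dv, covariates = covariates,
    n = f1$n, level = level,
    alpha = f1$estimate, se_alpha = f1$se, p_alpha = f1$p,
    beta = f2m$estimate, se_beta = f2m$se, p_beta = f2m$p,
    gamma_prime = f2i$estimate, se_gamma_prime = f2i$se,
    p_gamma_prime = f2i$p,
    indirect = indirect,
    total = total, se_total = f3$se, p_total = f3$p,
    criterion1 = f1$p < level,
    criterion2 = f2m$p < level,
    criterion3 = f3$p < level,
    criterion4 = NA,
    sobel_se = NA_real_, sobel_z = NA_real_, sobel_p = NA_real_,
    classification = NA_character_
  ), class = "mediation_result")
}

#' Sobel delta-method test of the indirect effect
#'
#' Tests `H0: alpha * beta = 0` with the first-order delta-method standard
#' error
#' \deqn{\delta_{\alpha\beta} = \sqrt{\delta_\alpha^2 \beta^2 +
#'       \delta_\beta^2 \alpha^2}}{se = sqrt(se_a^2 b^2 + se_b^2 a^2)}
#' and test ratio `Z = alpha * beta / se`, referred to the standard normal
#' (two-tailed). `+/-1.96` are the critical values at the 5% level. The
#' second-order variant adds `se_alpha^2 * se_beta^2` under the root; it is
#' off by default.
#'
#' @param alpha,se_alpha exposure-to-mediator coefficient and SE.
#' @param beta,se_beta mediator-to-outcome coefficient and SE (from the
#'   model adjusting for the exposure).
#' @param second_order add the second-order term to the variance.
#' @return list with `se`, `z`, `p` (two-tailed), and logical `degenerate`
#'   (TRUE when the SE is zero, in which case `z` and `p` are `NA`).
#' @examples
#' sobel_test(0.312, 0.071, 0.429, 0.040)  # p ~ 4.78e-5
#' @export
sobel_test <- function(alpha, se_alpha, beta, se_beta,
                       second_order = FALSE) {
  stopifnot(se_alpha >= 0, se_beta >= 0)
  v <- se_alpha^2 * beta^2 + se_beta^2 * alpha^2
  if (second_order) v <- v + se_alpha^2 * se_beta^2
  if (v == 0) {
    return(list(se = 0, z = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  se <- sqrt(v)
  z <- alpha * beta / se
  list(se = se, z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Classify an effect decomposition as mediation, suppression or neither
#'
#' Requires the Sobel test of the indirect effect to be significant
#' (criterion 4). Given that, the pattern is called *suppression* when the
#' direct and indirect effects have opposite signs and the direct effect
#' exceeds the total effect in magnitude (adjusting for the mediator
#' strengthens the exposure-outcome association), and *mediation* when the
#' signs agree and the total effect is at least as large in magnitude as
#' the direct effect. Anything else is `"none"`. Magnitude comparisons are
#' on absolute values.
#'
#' @param direct direct effect `gamma_prime`.
#' @param indirect indirect effect `alpha * beta`.
#' @param total total effect `gamma_prime + alpha * beta`.
#' @param sobel_p two-tailed Sobel p-value.
#' @param level significance level for criterion 4 (default 0.05).
#' @return one of `"mediation"`, `"suppression"`, `"none"`.
#' @examples
#' classify_suppression(0.017, -0.018, -0.002, 1e-9)  # "suppression"
#' @export
classify_suppression <- function(direct, indirect, total, sobel_p,
                                 level = 0.05) {
  stopifnot(is.finite(direct), is.finite(indirect), is.finite(total))
  if (is.na(sobel_p) || sobel_p >= level) return("none")
  opposite <- sign(indirect) != sign(direct) && sign(indirect) != 0
  if (opposite && abs(direct) > abs(total)) return("suppression")
  if (!opposite && abs(total) >= abs(direct)) return("mediation")
  "none"
}

#' Full mediation analysis for one exposure/mediator/outcome triple
#'
#' Convenience wrapper: [mediation_paths()], then [sobel_test()] on the
#' fitted `alpha`/`beta` paths, then [classify_suppression()].
#'
#' @inheritParams mediation_paths
#' @param second_order passed to [sobel_test()].
#' @return An object of class `mediation_result`: list with the path
#'   coefficients (`alpha`, `beta`, `gamma_prime`, each with SE and p),
#'   `indirect` (`alpha * beta`), `total` (independently fitted, with SE
#'   and p), criterion flags 1-4, `sobel_se`, `sobel_z`, `sobel_p`,
#'   `classification`, `covariates`, `n`.
#' @export
mediate <- function(data, iv, mediator, dv, covariates = character(),
                    level = 0.05, second_order = FALSE) {
  res <- mediation_paths(data, iv, mediator, dv, covariates, level)
  s <- sobel_test(res$alpha, res$se_alpha, res$beta, res$se_beta,
                  second_order = second_order)
  res$sobel_se <- s$se
  res$sobel_z <- s$z
  res$sobel_p <- s$p
  res$criterion4 <- !s$degenerate && s$p < level
  res$classification <- classify_suppression(res$gamma_prime, res$indirect,
                                             res$total, s$p, level)
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: %s -> %s -> %s (n = %d)\n",
              x$iv, x$mediator, x$dv, x$n))
  cat(sprintf("  alpha  = %8.4f (SE %.4f, p = %.3g)\n",
              x$alpha, x$se_alpha, x$p_alpha))
  cat(sprintf("  beta   = %8.4f (SE %.4f, p = %.3g)\n",
              x$beta, x$se_beta, x$p_beta))
  cat(sprintf("  direct = %8.4f (SE %.4f, p = %.3g)\n",
              x$gamma_prime, x$se_gamma_prime, x$p_gamma_prime))
  cat(sprintf("  indirect (alpha*beta) = %8.4f\n", x$indirect))
  cat(sprintf("  total  = %8.4f (SE %.4f, p = %.3g)\n",
              x$total, x$se_total, x$p_total))
  if (!is.na(x$sobel_z)) {
    cat(sprintf("  Sobel: SE %.4f, Z = %.3f, p = %.3g\n",
                x$sobel_se, x$sobel_z, x$sobel_p))
    cat(sprintf("  criteria: %s | classification: %s\n",
                paste(ifelse(c(x$criterion1, x$criterion2, x$criterion3,
                               x$criterion4), "+", "-"), collapse = ""),
                x$classification))
  }
  invisible(x)
}

#' Mediation scan over exposure/mediator/outcome triples
#'
#' Runs [mediate()] for each requested triple (both directions are
#' supported: genotype -> SAA -> CRP and genotype/haplotype -> CRP -> SAA)
#' and collects one row per triple.
#'
#' @param data data.frame with all exposure codings, haplotype dosages and
#'   log biomarker columns.
#' @param pairs list of triples; each element a named character vector or
#'   list with `iv`, `mediator`, `dv`.
#' @param covariates covariate column names, shared across triples.
#' @param level criterion significance level.
#' @param second_order passed to [sobel_test()].
#' @return data.frame with one row per triple and all `mediation_result`
#'   scalar fields; the full result objects are attached as
#'   `attr(, "results")`.
#' @export
run_mediation_scan <- function(data, pairs, covariates = character(),
                               level = 0.05, second_order = FALSE) {
  results <- lapply(pairs, function(pr) {
    pr <- as.list(pr)
    need <- c(pr$iv, pr$mediator, pr$dv)
    absent <- setdiff(need, names(data))
    if (length(absent)) {
      stop("unresolvable column(s) ", paste(absent, collapse = ", "),
           " in pair (", paste(need, collapse = ", "), ")")
    }
    mediate(data, pr$iv, pr$mediator, pr$dv, covariates,
            level = level, second_order = second_order)
  })
  scalar <- c("iv", "mediator", "dv", "n", "alpha", "se_alpha", "p_alpha",
              "beta", "se_beta", "p_beta", "gamma_prime", "se_gamma_prime",
              "p_gamma_prime", "indirect", "total", "se_total", "p_total",
              "criterion1", "criterion2", "criterion3", "criterion4",
              "sobel_se", "sobel_z", "sobel_p", "classification")
  out <- do.call(rbind, lapply(results, function(r) {
    as.data.frame(r[scalar], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Criteria-block report of a mediation scan
#'
#' Reshapes a scan into the conventional long report: one column per
#' exposure, blocks of rows for criterion 1 (alpha), criterion 2 (beta and
#' gamma_prime), criterion 3 (total effect) and criterion 4 (indirect
#' effect with Sobel p).
#'
#' @param scan output of [run_mediation_scan()].
#' @param digits coefficient rounding for display.
#' @return data.frame in block layout.
#' @export
mediation_table <- function(scan, digits = 3) {
  fmt_p <- function(p) ifelse(p < 1e-3, sprintf("%.3g", p),
                              sprintf("%.3f", p))
  block <- function(label, est, se = NULL, p = NULL) {
    rows <- list(data.frame(row = paste0(label, ": coefficient"),
                            t(round(est, digits))))
    if (!is.null(se)) rows <- c(rows, list(
      data.frame(row = paste0(label, ": SE"), t(round(se, digits)))))
    if (!is.null(p)) rows <- c(rows, list(
      data.frame(row = paste0(label, ": p"), t(fmt_p(p)))))
    rows
  }
  cols <- scan$iv
  rows <- c(block("criterion 1, alpha", scan$alpha, scan$se_alpha,
                  scan$p_alpha),
            block("criterion 2, beta", scan$beta, scan$se_beta,
                  scan$p_beta),
            block("criterion 2, gamma_prime", scan$gamma_prime,
                  scan$se_gamma_prime, scan$p_gamma_prime),
            block("criterion 3, total", scan$total, scan$se_total,
                  scan$p_total),
            block("criterion 4, indirect", scan$indirect, scan$sobel_se,
                  scan$sobel_p),
            list(data.frame(row = "classification", t(scan$classification))))
  out <- do.call(rbind, lapply(rows, function(r) {
    names(r) <- c("row", cols); r
  }))
  rownames(out) <- NULL
  out
}
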
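test_that("log transform is natural-log, round-trips, and rejects non-positive levels", {
  co <- data.frame(crp = c(1.0, exp(1), 2.5), saa = c(0.4, 5.3, 11.1))
  d <- log_transform(co, c("crp", "saa"))
  expect_equal(d$log_crp[1], 0)
  expect_equal(d$log_crp[2], 1)           # base-e convention
  expect_equal(exp(d$log_saa), co$saa, tolerance = 1e-12)
  expect_true(all(c("crp", "saa") %in% names(d)))  # levels retained

  co$crp[2] <- -0.1
  expect_error(log_transform(co, "crp"), "'crp' at row 2")
})

test_that("fit_linear interpolates exact data and matches cov/var with no covariates", {
  x <- c(0, 1, 2, 3, 4, 5)
  d <- data.frame(y = 2 * x + 1, x = x)
  f <- suppressWarnings(fit_linear(d, "y", "x"))
  expect_equal(f$estimate, 2, tolerance = 1e-12)
  expect_lt(f$sigma, 1e-12)
  expect_equal(f$ci, f$estimate + c(-1.96, 1.96) * f$se)

  set.seed(31)
  for (k in 1:10) {
    d <- data.frame(x = rnorm(30), y = rnorm(30))
    f <- fit_linear(d, "y", "x")
    expect_equal(f$estimate, stats::cov(d$x, d$y) / stats::var(d$x),
                 tolerance = 1e-10)
  }
})

test_that("fit_linear recovers the generating coefficient at large n", {
  sim <- simulate_cohort(sim_params(n_individuals = 5000, seed = 17))
  d <- log_transform(sim$cohort, c("crp", "saa"))
  f <- fit_linear(d, "log_saa", "x_snp", COVS)
  expect_lt(abs(f$estimate - (-0.040)), 2 * f$se)
})

test_that("fit_linear rejects degenerate designs with named columns", {
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  d$x2 <- d$x  # exact duplicate of the exposure
  expect_error(fit_linear(d, "y", "x", "x2"), "collinear.*x2")
  d$c <- 1
  expect_error(fit_linear(d, "y", "c"), "constant")
  expect_error(fit_linear(d, "y", "missing_col"), "not in data")
})

test_that("partial correlation equals the two-stage residual oracle", {
  set.seed(41)
  n <- 80
  Z <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  x <- 0.3 * Z$age + rnorm(n)
  y <- -0.2 * Z$age + 0.5 * x + rnorm(n)

  pc <- partial_correlation(x, y, Z)
  # independent residualization through lm()
  rx <- residuals(lm(x ~ age + sex, Z))
  ry <- residuals(lm(y ~ age + sex, Z))
  r_oracle <- cor(rx, ry)
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt((n - 4) / (1 - r_oracle^2))
  expect_equal(pc$p, 2 * pt(-abs(t_oracle), n - 4), tolerance = 1e-12)

  # no covariates: plain Pearson r
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # self-correlation
  expect_equal(partial_correlation(x, x)$r, 1)
  # degenerate residual flagged
  expect_true(partial_correlation(Z$age, y, Z)$degenerate)

  # sign agreement with the adjusted regression slope
  d <- cbind(Z, x = x, y = y)
  f <- fit_linear(d, "y", "x", c("age", "sex"))
  expect_equal(sign(pc$r), sign(f$estimate))
})

test_that("Bonferroni adjustment reproduces published examples and is monotone", {
  expect_equal(signif(bonferroni_adjust(9.1e-26, 32), 2), 2.9e-24)
  expect_equal(bonferroni_adjust(1.78e-26, 4), 7.12e-26, tolerance = 1e-15)
  expect_equal(bonferroni_adjust(0.5, 3), 1.5)
  expect_equal(format_adjusted_p(bonferroni_adjust(0.5, 3)), "NS")
  expect_equal(format_adjusted_p(0.032), "0.032")

  p <- sort(runif(20))
  expect_true(all(diff(bonferroni_adjust(p, 5)) >= 0))       # monotone in p
  expect_true(all(bonferroni_adjust(0.01, 1:10) ==
                    cummax(bonferroni_adjust(0.01, 1:10))))  # monotone in m
  expect_error(bonferroni_adjust(1.2, 3), "\\[0, 1\\]")
})

test_that("quartile subgroup analysis recovers a uniform within-quartile effect", {
  set.seed(51)
  n <- 800
  d <- data.frame(med = exp(rnorm(n, 1.2, 0.8)),
                  x = rbinom(n, 2, 0.4),
                  age = rnorm(n, 46, 10))
  d$y <- -0.1 * d$x + 0.01 * d$age + rnorm(n, 0, 0.2)
  qs <- quartile_subgroup(d, "med", "x", "y", "age")
  expect_equal(nrow(qs$table), 4)
  # no ties: quartile sizes differ by at most 1
  expect_lte(diff(range(table(findInterval(d$med, qs$breaks)))), 1)
  for (q in 1:4) {
    expect_lt(abs(qs$table$estimate[q] - (-0.1)), 2 * qs$table$se[q])
  }
  expect_true(is.finite(qs$trend_p))

  d$med <- 1
  expect_error(quartile_subgroup(d, "med", "x", "y", "age"), "constant")
})

test_that("carrier trend chi-square is null-calibrated (uniform p)", {
  set.seed(61)
  nrep <- 400
  pvals <- numeric(nrep)
  for (r in seq_len(nrep)) {
    n <- 400
    d <- data.frame(med = rnorm(n), x = rbinom(n, 2, 0.35))
    d$y <- rnorm(n)
    qs <- quartile_subgroup(d, "med", "x", "y", character(0))
    pvals[r] <- qs$trend_p
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort description reproduces closed-form tests and applies exclusions", {
  set.seed(71)
  n <- 120
  co <- data.frame(g = rep(0:1, each = n / 2),
                   bmi = rnorm(n, 24, 3),
                   crp = exp(rnorm(n, 0, 0.8)),
                   smoking = rbinom(n, 1, 0.2),
                   med_htn = rbinom(n, 1, 0.3))
  tab <- describe_cohort(co, "g", continuous = c("bmi", "crp"),
                         categorical = "smoking", log_scale = "crp",
                         exclusions = list(bmi = "med_htn"))
  # closed-form pooled t-test for the excluded-sample bmi comparison
  d <- co[co$med_htn == 0, ]
  x0 <- d$bmi[d$g == 0]; x1 <- d$bmi[d$g == 1]
  sp2 <- ((length(x0) - 1) * var(x0) + (length(x1) - 1) * var(x1)) /
    (length(x0) + length(x1) - 2)
  tt <- (mean(x0) - mean(x1)) / sqrt(sp2 * (1 / length(x0) + 1 / length(x1)))
  p_oracle <- 2 * pt(-abs(tt), length(x0) + length(x1) - 2)
  expect_equal(tab$p[tab$variable == "bmi"], p_oracle, tolerance = 1e-10)

  # identical groups: p = 1 throughout
  co2 <- data.frame(g = rep(0:1, each = 4), bmi = rep(c(20, 22, 24, 26), 2),
                    smoking = rep(c(0, 1, 0, 1), 2))
  tab2 <- describe_cohort(co2, "g", continuous = "bmi",
                          categorical = "smoking")
  expect_true(all(tab2$p == 1))

  # balanced 2x2 indicator table: chi-square 0
  co3 <- data.frame(g = rep(0:1, each = 100),
                    smoking = rep(rep(0:1, each = 50), 2))
  tab3 <- describe_cohort(co3, "g", continuous = character(0),
                          categorical = "smoking")
  expect_equal(tab3$p, 1)

  expect_error(describe_cohort(data.frame(g = c(0, 1), x = 1:2), "g",
                               "x"), "at least 2")
})
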
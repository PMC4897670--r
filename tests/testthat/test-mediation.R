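test_that("Sobel test reproduces published path-coefficient examples", {
  # CRP haplotype AAGCG: alpha 0.312 (SE 0.071), beta 0.429 (SE 0.040)
  s <- sobel_test(0.312, 0.071, 0.429, 0.040)
  expect_equal(signif(s$p, 3), 4.78e-5)
  expect_equal(s$se, sqrt(0.071^2 * 0.429^2 + 0.040^2 * 0.312^2),
               tolerance = 1e-12)

  # SAA1 rs4638289: alpha -0.040 (SE 0.004), beta 0.460 (SE 0.041)
  s <- sobel_test(-0.040, 0.004, 0.460, 0.041)
  expect_equal(abs(s$z), 7.4651, tolerance = 1e-3)
  expect_lt(s$p, 1e-8)
})

test_that("Sobel test edge cases and symmetry", {
  # zero product with a non-degenerate SE
  s <- sobel_test(0, 1, 0.5, 0.1)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)

  # |Z| = 1.96 anchors p = 0.05
  s <- sobel_test(1.96, 1, 1, 0)
  expect_equal(s$z, 1.96)
  expect_lt(abs(s$p - 0.05), 1e-3)

  # symmetric under swapping the two paths
  set.seed(81)
  for (k in 1:20) {
    a <- rnorm(1); b <- rnorm(1); sa <- runif(1); sb <- runif(1)
    s1 <- sobel_test(a, sa, b, sb)
    s2 <- sobel_test(b, sb, a, sa)
    expect_equal(s1$se, s2$se, tolerance = 1e-12)
    expect_equal(s1$z, s2$z, tolerance = 1e-12)
  }

  # second-order variant inflates the SE, shrinking |Z|
  s1 <- sobel_test(0.3, 0.1, 0.4, 0.1)
  s2 <- sobel_test(0.3, 0.1, 0.4, 0.1, second_order = TRUE)
  expect_gt(s2$se, s1$se)
  expect_lt(abs(s2$z), abs(s1$z))

  # degenerate SE flagged
  expect_true(sobel_test(0, 0, 0, 0)$degenerate)
})

test_that("suppression/mediation classification follows the four-criterion rules", {
  # published decomposition: direct 0.017, indirect -0.018, total -0.002
  expect_equal(classify_suppression(0.017, -0.018, -0.002, 1e-9),
               "suppression")
  # same-sign reinforcement
  expect_equal(classify_suppression(0.2, 0.1, 0.3, 0.001), "mediation")
  # criterion 4 fails
  expect_equal(classify_suppression(0.017, 0, 0.017, 1), "none")
  # sign opposition without |direct| > |total|
  expect_equal(classify_suppression(0.05, -0.2, -0.15, 0.001), "none")
  # suppression implies opposite signs by construction
  expect_equal(classify_suppression(-0.188, 0.134, -0.054, 4.78e-5),
               "suppression")
})

test_that("path regressions satisfy the OLS decomposition identity", {
  sim <- simulate_cohort(sim_params(n_individuals = 580, seed = 23))
  d <- log_transform(sim$cohort, c("crp", "saa"))
  m <- mediation_paths(d, "x_snp", "log_saa", "log_crp", COVS)
  expect_lt(abs(m$total - (m$gamma_prime + m$indirect)), 1e-8)
  expect_true(is.na(m$sobel_p))          # Sobel fields unset at this stage
  expect_true(is.na(m$classification))

  mm <- mediate(d, "x_snp", "log_saa", "log_crp", COVS)
  expect_identical(mm[c("alpha", "beta", "gamma_prime", "total")],
                   m[c("alpha", "beta", "gamma_prime", "total")])
  expect_false(is.na(mm$sobel_p))

  d$const <- 1
  expect_error(mediation_paths(d, "const", "log_saa", "log_crp", COVS),
               "constant")
  expect_error(mediation_paths(d, "nope", "log_saa", "log_crp", COVS),
               "not in data")
})

test_that("identity holds on the shared complete-case sample under missingness", {
  sim <- simulate_cohort(sim_params(n_individuals = 400, seed = 29))
  d <- log_transform(sim$cohort, c("crp", "saa"))
  d$x_snp[c(3, 50, 200)] <- NA
  d$log_saa[c(10, 60)] <- NA
  m <- mediate(d, "x_snp", "log_saa", "log_crp", COVS)
  expect_equal(m$n, 395)
  expect_lt(abs(m$total - (m$gamma_prime + m$indirect)), 1e-8)
})

test_that("criterion 1 and the Sobel test are calibrated under a null alpha", {
  nrep <- 300
  c1 <- logical(nrep); sob <- logical(nrep)
  for (r in seq_len(nrep)) {
    p <- sim_params(n_individuals = 300, seed = 60000 + r, alpha = 0)
    sim <- simulate_cohort(p)
    d <- log_transform(sim$cohort, c("crp", "saa"))
    m <- mediate(d, "x_snp", "log_saa", "log_crp", COVS)
    c1[r] <- m$criterion1
    sob[r] <- m$sobel_p < 0.05
  }
  # criterion 1 rejects at ~ the nominal 5% level
  expect_gte(mean(!c1), 0.90)
  expect_lte(mean(!c1), 0.99)
  # the Sobel test is conservative under alpha*beta = 0: bound only
  mc_se <- sqrt(0.05 * 0.95 / nrep)
  expect_lte(mean(sob), 0.05 + 2 * mc_se)
})

test_that("mediation scan runs both directions and is deterministic", {
  sim <- simulate_cohort(sim_params(n_individuals = 580, seed = 37))
  d <- log_transform(sim$cohort, c("crp", "saa"))
  pairs <- list(
    list(iv = "x_snp", mediator = "log_saa", dv = "log_crp"),
    list(iv = "x_hap", mediator = "log_crp", dv = "log_saa"))
  s1 <- run_mediation_scan(d, pairs, COVS)
  s2 <- run_mediation_scan(d, pairs, COVS)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2)
  expect_equal(s1$classification[1], "suppression")

  expect_error(run_mediation_scan(d, list(list(iv = "absent",
                                               mediator = "log_saa",
                                               dv = "log_crp")), COVS),
               "unresolvable column.*absent")

  tab <- mediation_table(s1)
  expect_true(any(grepl("criterion 4", tab$row)))
  expect_equal(ncol(tab), 3)  # row label + two exposures
})
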
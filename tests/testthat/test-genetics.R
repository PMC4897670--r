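test_that("HWE chi-square matches the closed form and flags degenerate sites", {
  # exact HWE proportions
  h <- hwe_test(c(25, 50, 25))
  expect_equal(h$chisq, 0)
  expect_equal(h$p, 1)

  # published-scale genotype counts: tiny deviation, clearly non-significant
  h <- hwe_test(c(237, 266, 75))
  expect_equal(h$chisq, 0.000721763, tolerance = 1e-6)
  expect_gt(h$p, 0.05)

  # complete heterozygote deficit: chi-square equals n
  h <- hwe_test(c(100, 0, 100))
  expect_equal(h$chisq, 200)
  expect_lt(h$p, 1e-10)

  # monomorphic site
  h <- hwe_test(c(50, 0, 0))
  expect_true(h$degenerate)
  expect_equal(h$p, 1)

  expect_error(hwe_test(c(-1, 2, 3)), "non-negative")
  expect_error(hwe_test(c(0, 0, 0)), ">= 1")
})

test_that("HWE statistic is label-swap invariant and equals the oracle", {
  set.seed(11)
  for (k in 1:50) {
    cnt <- stats::rmultinom(1, size = sample(50:500, 1),
                            prob = c(0.4, 0.45, 0.15))[, 1]
    if (any(cnt[c(1, 3)] == sum(cnt))) next
    h1 <- hwe_test(cnt)
    h2 <- hwe_test(rev(cnt))
    expect_equal(h1$chisq, h2$chisq, tolerance = 1e-12)
    expect_equal(h1$chisq, oracle_hwe_chisq(cnt), tolerance = 1e-12)
  }
})

test_that("single-site EM reduces to allele counting", {
  calls <- c(rep("A/A", 30), rep("A/G", 20), rep("G/G", 10))
  gm <- genotype_matrix(cbind(s1 = calls), data.frame(id = "s1", locus = "L"))
  h <- em_haplotypes(gm)
  expect_equal(unname(h$frequencies[c("A", "G")]), c(80, 40) / 120,
               tolerance = 1e-9)
  expect_true(h$converged)
  expect_true(all(abs(rowSums(h$dosages) - 2) < 1e-8))
})

test_that("EM equals direct counting when phase is unambiguous", {
  # every individual has at most one heterozygous site
  calls <- cbind(s1 = c("A/A", "A/G", "G/G", "A/A", "A/G"),
                 s2 = c("C/T", "C/C", "T/T", "C/C", "T/T"))
  gm <- genotype_matrix(calls, data.frame(id = c("s1", "s2"), locus = "L"))
  h <- em_haplotypes(gm)
  # resolve each individual by hand: AC/AT, AC/GC, GT/GT, AC/AC, AT/GT
  direct <- table(c("AC", "AT", "AC", "GC", "GT", "GT", "AC", "AC",
                    "AT", "GT")) / 10
  expect_equal(h$frequencies[names(direct)], c(direct),
               tolerance = 1e-8, ignore_attr = "names")
})

test_that("EM attains the exhaustive-likelihood maximum on a 3-site toy", {
  # 12 individuals including double heterozygotes (latent phase)
  calls <- cbind(
    s1 = c("A/G", "A/G", "A/A", "G/G", "A/G", "A/A", "A/G", "G/G",
           "A/A", "A/G", "A/G", "A/A"),
    s2 = c("C/T", "C/C", "C/T", "T/T", "C/T", "C/C", "T/T", "C/T",
           "C/C", "C/T", "C/C", "C/T"),
    s3 = c("A/A", "A/C", "A/C", "C/C", "A/A", "A/C", "A/C", "A/A",
           "C/C", "A/C", "A/A", "A/A"))
  gm <- genotype_matrix(calls,
                        data.frame(id = c("s1", "s2", "s3"), locus = "L"))
  h <- em_haplotypes(gm, tol = 1e-12, max_iter = 5000)
  ll_em <- h$loglik[length(h$loglik)]
  ll_star <- oracle_hap_max_loglik(calls, h$haplotypes)
  expect_lt(abs(ll_em - ll_star), 1e-6)
  # and the trace is the likelihood the oracle computes
  expect_equal(ll_em, oracle_hap_loglik(calls, h$haplotypes,
                                        unname(h$frequencies)),
               tolerance = 1e-9)
})

test_that("EM invariants hold across random datasets", {
  haps3 <- c("ACA", "ACC", "GTA", "GTC", "GCA")
  for (sd in 1:8) {
    gm <- random_toy_gm(40, haps3, seed = sd)
    h <- em_haplotypes(gm)
    expect_true(all(diff(h$loglik) > -1e-10))          # monotone loglik
    expect_equal(sum(h$frequencies), 1, tolerance = 1e-10)
    expect_true(all(abs(rowSums(h$dosages) - 2) < 1e-8))
  }
})

test_that("EM marginalizes missing calls and flags symmetric ridges", {
  calls <- cbind(s1 = c("A/G", NA, "A/A", "G/G"),
                 s2 = c("C/C", "C/T", "C/T", "T/T"))
  gm <- genotype_matrix(calls, data.frame(
    id = c("s1", "s2"), locus = "L",
    alleles = I(list(c("A", "G"), c("C", "T")))))
  h <- em_haplotypes(gm)
  expect_true(h$converged)
  expect_true(all(abs(rowSums(h$dosages) - 2) < 1e-8))

  # all double heterozygotes: AB/ab vs Ab/aB cannot be distinguished
  calls <- cbind(s1 = rep("A/G", 6), s2 = rep("C/T", 6))
  gm <- genotype_matrix(calls, data.frame(id = c("s1", "s2"), locus = "L"))
  h <- em_haplotypes(gm)
  expect_false(h$identifiable)

  gm_empty <- genotype_matrix(
    cbind(s1 = c(NA_character_, NA)),
    data.frame(id = "s1", locus = "L", alleles = I(list(c("A", "G")))))
  expect_error(em_haplotypes(gm_empty), "missing")
})

test_that("LD measures match direct arithmetic and respect their bounds", {
  # complete LD: only AB and ab
  l <- ld_pairwise(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(l$Dprime, 1)
  expect_equal(l$r2, 1)

  # independence
  f <- outer(c(0.3, 0.7), c(0.6, 0.4))
  l <- ld_pairwise(f)
  expect_equal(l$D, 0, tolerance = 1e-12)
  expect_equal(l$r2, 0, tolerance = 1e-12)

  set.seed(21)
  for (k in 1:40) {
    tab <- matrix(stats::runif(4), 2, 2)
    tab <- tab / sum(tab)
    l <- ld_pairwise(tab)
    o <- oracle_ld(tab)
    expect_equal(l$D, o$D, tolerance = 1e-12)
    expect_equal(l$Dprime, o$Dprime, tolerance = 1e-12)
    expect_equal(l$r2, o$r2, tolerance = 1e-12)
    expect_true(l$r2 >= 0 && l$r2 <= 1 + 1e-12)
    expect_true(abs(l$Dprime) <= 1 + 1e-12)
  }

  # monomorphic margin is flagged
  l <- ld_pairwise(matrix(c(0.6, 0.4, 0, 0), 2, 2))
  expect_true(l$degenerate)

  # genotype-matrix entry point: two-site EM then LD
  gm <- random_toy_gm(200, c("AC", "GT"), seed = 5)  # complete LD pool
  l <- ld_pairwise(gm, "s1", "s2")
  expect_equal(abs(l$Dprime), 1, tolerance = 1e-6)
  expect_equal(l$r2, 1, tolerance = 1e-6)
})

test_that("additive and dominant codings follow the MM/Mm/mm convention", {
  calls <- cbind(rs = c("A/A", "A/G", "G/G", NA, "A/A"))
  gm <- genotype_matrix(calls, data.frame(
    id = "rs", locus = "L", alleles = I(list(c("A", "G")))))
  # A is major (6 of 8 alleles), G minor
  expect_equal(gm$sites$minor, "G")
  expect_equal(unname(code_additive(gm, "rs")), c(0L, 1L, 2L, NA, 0L))
  expect_equal(unname(code_dominant(gm, "rs")), c(0L, 1L, 1L, NA, 0L))
  # pinning the counted allele flips the dosage
  expect_equal(unname(code_additive(gm, "rs", allele = "A")),
               c(2L, 1L, 0L, NA, 2L))
  expect_error(code_additive(gm, "rs", allele = "T"), "not in the alphabet")

  # additive dosage 0 <=> dominant indicator 0
  add <- code_additive(gm, "rs"); dom <- code_dominant(gm, "rs")
  expect_identical(unname(add == 0L), unname(dom == 0L))
})

test_that("triallelic recoding groups genotypes as specified", {
  calls <- cbind(rs3091244 = c("C/C", "A/A", "A/C", "A/T", "C/T", "T/T", NA))
  gm <- genotype_matrix(calls, data.frame(
    id = "rs3091244", locus = "CRP", alleles = I(list(c("A", "C", "T")))))
  rc <- recode_triallelic(gm, "rs3091244")
  classes <- rc$calls[, 1]
  hom_M <- paste(rc$sites$major[1], rc$sites$major[1], sep = "/")
  het <- paste(sort(c(rc$sites$major[1], rc$sites$minor[1])), collapse = "/")
  hom_m <- paste(rc$sites$minor[1], rc$sites$minor[1], sep = "/")
  # CC -> MM; AA, AC, AT -> Mm; CT, TT -> mm; missing propagates
  expect_equal(unname(classes),
               c(hom_M, het, het, het, hom_m, hom_m, NA))
  expect_length(rc$sites$alleles[[1]], 2L)
  # recoded site feeds the standard codings
  expect_equal(unname(code_additive(rc, "rs3091244", allele = rc$sites$minor[1])),
               c(0L, 1L, 1L, 1L, 2L, 2L, NA))

  expect_error(recode_triallelic(gm, "rs3091244",
                                 grouping = list(MM = "CC", Mm = "AA",
                                                 mm = "TT")),
               "absent from grouping")
  gm2 <- genotype_matrix(cbind(b = c("A/A", "A/G")),
                         data.frame(id = "b", locus = "L"))
  expect_error(recode_triallelic(gm2, "b"), "not triallelic")
})

test_that("genotype container validates alphabets and normalizes calls", {
  expect_error(genotype_matrix(cbind(s = c("A/X")), data.frame(
    id = "s", locus = "L", alleles = I(list(c("A", "G"))))),
    "outside alphabet")
  gm <- genotype_matrix(cbind(s = c("G/A", "A|G")),
                        data.frame(id = "s", locus = "L"))
  expect_equal(unname(gm$calls[, 1]), c("A/G", "A/G"))
  expect_equal(unname(genotype_counts(gm, "s")), c(0L, 2L, 0L))
})
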
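#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' `(MM, Mm, mm)` against the Hardy-Weinberg expectation
#' `n * (p^2, 2pq, q^2)`, where `q` is the minor allele frequency estimated
#' from the counts themselves. Monomorphic sites (q = 0 or 1) are reported
#' as degenerate with statistic 0 and p = 1.
#'
#' The statistic is symmetric in the homozygote labels, so swapping the
#' major/minor designation does not change the result.
#'
#' @param counts numeric vector of length 3: major homozygote, heterozygote,
#'   minor homozygote counts. Alternatively a [genotype_matrix()], in which
#'   case `site` must name a biallelic site.
#' @param site site id, when `counts` is a genotype matrix.
#' @return list with `chisq`, `p`, `maf` (minor allele frequency from the
#'   counts), `n`, and logical `degenerate`.
#' @examples
#' hwe_test(c(25, 50, 25))   # exact HWE proportions: chisq 0, p 1
#' hwe_test(c(237, 266, 75)) # p ~ 0.98
#' @export
hwe_test <- function(counts, site = NULL) {
  if (inherits(counts, "genotype_matrix")) {
    counts <- genotype_counts(counts, site)
  }
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0) || any(!is.finite(counts))) {
    stop("`counts` must be three non-negative genotype counts (MM, Mm, mm)")
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  q <- min(q, 1 - q)  # label-swap invariance
  if (q == 0) {
    return(list(chisq = 0, p = 1, maf = 0, n = n, degenerate = TRUE))
  }
  p <- 1 - q
  # orient expected counts to the observed ordering
  qq <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - qq)^2, 2 * qq * (1 - qq), qq^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       maf = q, n = n, degenerate = FALSE)
}

#' Pairwise linkage disequilibrium
#'
#' Computes the standard two-site LD summaries from haplotype frequencies:
#' `D = p_AB - p_A p_B`, the normalized `D'` (D divided by its
#' sign-dependent bound), and `r^2 = D^2 / (p_A p_a p_B p_b)`. Both sites
#' must be biallelic; when called on genotypes, a two-site EM fit
#' ([em_haplotypes()]) supplies the haplotype frequencies.
#'
#' @param x either a 2x2 numeric matrix of haplotype frequencies (rows =
#'   alleles at site 1, columns = alleles at site 2, summing to 1), or a
#'   [genotype_matrix()].
#' @param site1,site2 site ids when `x` is a genotype matrix.
#' @return list with `D`, `Dprime`, `r2`, the marginal allele frequencies
#'   `p1`, `p2` (frequency of the first row/column allele), and logical
#'   `degenerate` (TRUE when either site is monomorphic, in which case the
#'   LD measures are `NA`).
#' @examples
#' # complete LD: only AB and ab haplotypes
#' ld_pairwise(matrix(c(0.5, 0, 0, 0.5), 2, 2))
#' @export
ld_pairwise <- function(x, site1 = NULL, site2 = NULL) {
  if (inherits(x, "genotype_matrix")) {
    for (s in c(site1, site2)) {
      j <- match(s, x$sites$id)
      if (is.na(j)) stop("unknown site: ", s)
      if (length(x$sites$alleles[[j]]) != 2L) {
        stop("ld_pairwise() requires biallelic sites; recode ", s, " first")
      }
    }
    hs <- em_haplotypes(x, site_ids = c(site1, site2))
    a1 <- x$sites$alleles[[match(site1, x$sites$id)]]
    a2 <- x$sites$alleles[[match(site2, x$sites$id)]]
    f <- matrix(0, 2, 2, dimnames = list(a1, a2))
    al <- do.call(rbind, strsplit(hs$haplotypes, ""))
    for (k in seq_along(hs$haplotypes)) {
      f[al[k, 1], al[k, 2]] <- f[al[k, 1], al[k, 2]] + hs$frequencies[k]
    }
    x <- f
  }
  if (!is.matrix(x) || !all(dim(x) == 2)) {
    stop("haplotype frequencies must form a 2x2 matrix")
  }
  if (abs(sum(x) - 1) > 1e-8) stop("haplotype frequencies must sum to 1")
  pA <- sum(x[1, ]); pB <- sum(x[, 1])
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                p1 = pA, p2 = pB, degenerate = TRUE))
  }
  D <- x[1, 1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       Dprime = if (D == 0) 0 else D / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       p1 = pA, p2 = pB, degenerate = FALSE)
}

#' Locus-wide QC scan: HWE per site and LD for all site pairs
#'
#' Triallelic sites are skipped with a note (recode them first with
#' [recode_triallelic()] to include them).
#'
#' @param gm a [genotype_matrix()].
#' @return list with data.frames `hwe` (site, locus, maf, chisq, p,
#'   degenerate) and `ld` (site1, site2, locus, D, Dprime, r2).
#' @export
qc_scan <- function(gm) {
  bi <- vapply(gm$sites$alleles, length, 1L) == 2L
  hwe <- do.call(rbind, lapply(which(bi), function(j) {
    h <- hwe_test(gm, gm$sites$id[j])
    data.frame(site = gm$sites$id[j], locus = gm$sites$locus[j],
               maf = h$maf, chisq = h$chisq, p = h$p,
               degenerate = h$degenerate)
  }))
  ld <- NULL
  for (locus in unique(gm$sites$locus)) {
    ids <- gm$sites$id[bi & gm$sites$locus == locus]
    if (length(ids) < 2) next
    for (a in seq_len(length(ids) - 1)) for (b in (a + 1):length(ids)) {
      l <- ld_pairwise(gm, ids[a], ids[b])
      ld <- rbind(ld, data.frame(site1 = ids[a], site2 = ids[b],
                                 locus = locus, D = l$D,
                                 Dprime = l$Dprime, r2 = l$r2))
    }
  }
  list(hwe = hwe, ld = ld)
}
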
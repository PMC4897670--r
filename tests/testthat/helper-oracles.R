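# Independent oracles used across tests. These deliberately reimplement the
# quantities they check by a different route (direct enumeration, closed
# forms, generic optimisation) so they never share code with the package.

COVS <- c("age", "sex", "bmi", "smoking", "med_htn", "med_dm", "med_lipid")

# brute-force phase enumeration: per-individual H x H compatibility matrix
oracle_compat <- function(calls, haps) {
  hm <- do.call(rbind, strsplit(haps, ""))
  H <- length(haps)
  lapply(seq_len(nrow(calls)), function(i) {
    gi <- calls[i, ]
    C <- matrix(TRUE, H, H)
    for (a in seq_len(H)) for (b in seq_len(H)) {
      for (j in seq_along(gi)) {
        if (is.na(gi[j])) next
        pair <- paste(sort(c(hm[a, j], hm[b, j])), collapse = "/")
        if (pair != gi[j]) { C[a, b] <- FALSE; break }
      }
    }
    C
  })
}

# direct multinomial-phase log-likelihood: sum_i log(f' C_i f)
oracle_hap_loglik <- function(calls, haps, f, compat = NULL) {
  if (is.null(compat)) compat <- oracle_compat(calls, haps)
  informative <- rowSums(!is.na(calls)) > 0
  ff <- f %o% f
  sum(vapply(which(informative), function(i) log(sum(ff[compat[[i]]])),
             numeric(1)))
}

# maximized log-likelihood over the frequency simplex: multi-start BFGS on
# a softmax parameterization (grid-free "grid + polish" equivalent)
oracle_hap_max_loglik <- function(calls, haps, n_starts = 25, seed = 99) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  compat <- oracle_compat(calls, haps)
  best <- -Inf
  for (s in seq_len(n_starts)) {
    th0 <- stats::rnorm(length(haps))
    r <- stats::optim(th0, function(th) {
      f <- exp(th - max(th)); f <- f / sum(f)
      -oracle_hap_loglik(calls, haps, f, compat)
    }, method = "BFGS", control = list(maxit = 400, reltol = 1e-12))
    best <- max(best, -r$value)
  }
  best
}

# closed-form HWE chi-square recomputed independently
oracle_hwe_chisq <- function(cnt) {
  n <- sum(cnt)
  q <- (2 * cnt[3] + cnt[2]) / (2 * n)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  sum((cnt - e)^2 / e)
}

# direct LD arithmetic from a 2x2 haplotype frequency table
oracle_ld <- function(tab) {
  pA <- sum(tab[1, ]); pB <- sum(tab[, 1])
  D <- tab[1, 1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = if (D == 0) 0 else D / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# random small genotype matrix drawn from a random haplotype pool
random_toy_gm <- function(n, haps, locus = "L", seed = 1) {
  set.seed(seed)
  f <- stats::runif(length(haps)); f <- f / sum(f)
  hp <- matrix(sample(haps, 2 * n, replace = TRUE, prob = f), ncol = 2)
  a1 <- do.call(rbind, strsplit(hp[, 1], ""))
  a2 <- do.call(rbind, strsplit(hp[, 2], ""))
  sites <- paste0("s", seq_len(nchar(haps[1])))
  calls <- matrix(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"),
                  nrow = n, dimnames = list(NULL, sites))
  genotype_matrix(calls, data.frame(id = sites, locus = locus))
}
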
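#' Haplotype frequency estimation by EM from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a set of linked sites,
#' using the classical expectation-maximization scheme for unphased
#' multilocus genotypes. In the E-step every phase configuration consistent
#' with an individual's genotype is enumerated (missing sites are
#' marginalized over the site alphabet) and weighted by the product of
#' current haplotype frequencies; in the M-step frequencies are the
#' expected haplotype counts divided by `2 * n`. The observed-data
#' log-likelihood is non-decreasing across iterations and is asserted to be
#' so at every step.
#'
#' The candidate haplotype list is the union of haplotypes compatible with
#' at least one individual, and the initial frequency vector is uniform over
#' it. Symmetric likelihood ridges (for example a sample consisting only of
#' double heterozygotes) leave the uniform initial point unchanged; such
#' fits are flagged `identifiable = FALSE` rather than broken by an
#' arbitrary tie rule.
#'
#' Individuals with every call missing carry no information and are dropped
#' from the likelihood; their posterior dosages equal twice the final
#' frequencies. Identical multilocus genotypes are collapsed to unique
#' patterns internally, so large cohorts over a few sites cost no more than
#' the number of distinct genotypes.
#'
#' @param gm a [genotype_matrix()], normally restricted to one locus group.
#' @param site_ids sites to use (default: all sites in `gm`); at most 8.
#' @param tol convergence tolerance on the change in log-likelihood.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param n_starts number of EM starts: the first is uniform over the
#'   candidate haplotypes, the rest are seeded random frequency vectors
#'   (deterministic, and the caller's random number stream is untouched);
#'   the run with the best final log-likelihood is returned. Multiple
#'   starts guard against the local maxima the haplotype likelihood is
#'   known to have on small samples.
#' @return An object of class `haplotype_set`: list with `haplotypes`
#'   (allele strings, site order = `site_ids`), `frequencies` (simplex
#'   vector), `dosages` (individuals x haplotypes matrix of posterior
#'   expected copy counts; rows sum to 2), `loglik` (trace, one value per
#'   iteration), `converged`, `identifiable`, `iterations`, `n_used`,
#'   `sites`.
#' @examples
#' gm <- genotype_matrix(
#'   cbind(s1 = c("A/A", "A/G", "G/G"), s2 = c("T/T", "T/T", "C/T")),
#'   sites = data.frame(id = c("s1", "s2"), locus = "L")
#' )
#' em_haplotypes(gm)$frequencies
#' @export
em_haplotypes <- function(gm, site_ids = NULL, tol = 1e-8, max_iter = 1000L,
                          n_starts = 10L) {
  if (!inherits(gm, "genotype_matrix")) stop("`gm` must be a genotype_matrix")
  if (is.null(site_ids)) site_ids <- gm$sites$id
  jj <- match(site_ids, gm$sites$id)
  if (anyNA(jj)) stop("unknown site(s): ",
                      paste(site_ids[is.na(jj)], collapse = ", "))
  if (length(jj) > 8L) stop("EM enumeration is limited to 8 sites")
  calls <- gm$calls[, site_ids, drop = FALSE]
  alph <- gm$sites$alleles[jj]

  informative <- rowSums(!is.na(calls)) > 0L
  if (!any(informative)) stop("all genotype calls are missing")

  # collapse identical multilocus genotypes to unique patterns
  key <- apply(calls, 1, function(r) paste(ifelse(is.na(r), ".", r),
                                           collapse = ";"))
  upat <- !duplicated(key)
  pat_of <- match(key, key[upat])
  wts <- as.vector(table(factor(pat_of, levels = seq_len(sum(upat)))))
  pcalls <- calls[upat, , drop = FALSE]

  # per pattern: enumerate compatible ordered haplotype pairs
  pat_pairs <- lapply(seq_len(nrow(pcalls)), function(i) {
    h1 <- ""; h2 <- ""
    for (s in seq_along(site_ids)) {
      g <- pcalls[i, s]
      if (is.na(g)) {
        opts <- expand.grid(a = alph[[s]], b = alph[[s]],
                            stringsAsFactors = FALSE)
      } else {
        al <- strsplit(g, "/", fixed = TRUE)[[1]]
        opts <- if (al[1] == al[2]) data.frame(a = al[1], b = al[2])
                else data.frame(a = al, b = rev(al))
      }
      h1 <- as.vector(outer(h1, opts$a, paste0))
      h2 <- as.vector(outer(h2, opts$b, paste0))
      if (length(h1) > 262144L) stop("phase enumeration too large at pattern ", i)
    }
    # unordered pair de-duplication; multiplicity 2 for heterozygous pairs
    lo <- pmin(h1, h2); hi <- pmax(h1, h2)
    pk <- paste(lo, hi)
    keep <- !duplicated(pk)
    data.frame(h1 = lo[keep], h2 = hi[keep],
               mult = ifelse(lo[keep] == hi[keep], 1, 2))
  })

  haps <- sort(unique(c(unlist(lapply(pat_pairs, `[[`, "h1")),
                        unlist(lapply(pat_pairs, `[[`, "h2")))))
  H <- length(haps)

  # flatten pair lists for vectorized E-steps
  pat_id <- rep(seq_along(pat_pairs),
                vapply(pat_pairs, nrow, 1L))
  i1 <- match(unlist(lapply(pat_pairs, `[[`, "h1")), haps)
  i2 <- match(unlist(lapply(pat_pairs, `[[`, "h2")), haps)
  mult <- unlist(lapply(pat_pairs, `[[`, "mult"))
  pat_informative <- rowSums(!is.na(pcalls)) > 0L
  n_used <- sum(wts[pat_informative])
  use <- pat_informative[pat_id]   # drop all-missing patterns from likelihood
  w_pat <- wts[pat_id]

  # accumulate pair weights into haplotype counts
  accumulate <- function(w) {
    cnt <- numeric(H)
    t1 <- rowsum(w, i1); cnt[as.integer(rownames(t1))] <- t1[, 1]
    t2 <- rowsum(w, i2)
    cnt[as.integer(rownames(t2))] <- cnt[as.integer(rownames(t2))] + t2[, 1]
    cnt
  }

  em_run <- function(f) {
    ll_trace <- numeric(0)
    converged <- FALSE
    moved <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      lik <- f[i1] * f[i2] * mult
      s_pat <- as.vector(rowsum(lik, pat_id))        # per-pattern likelihood
      ll <- sum(wts[pat_informative] * log(s_pat[pat_informative]))
      if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-10) {
        stop("EM log-likelihood decreased; this is a bug")
      }
      ll_trace <- c(ll_trace, ll)
      # posterior weights and expected haplotype counts
      post <- lik / s_pat[pat_id] * w_pat
      post[!use] <- 0
      f_new <- accumulate(post) / (2 * n_used)
      if (max(abs(f_new - f)) > 1e-12) moved <- TRUE
      delta <- if (length(ll_trace) > 1)
        abs(ll_trace[length(ll_trace)] - ll_trace[length(ll_trace) - 1])
        else Inf
      f <- f_new
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    list(f = f, ll_trace = ll_trace, converged = converged, moved = moved,
         iterations = iter)
  }

  # first start: uniform over observed-compatible haplotypes (this run also
  # probes for symmetric likelihood ridges); further starts: seeded random
  # frequency vectors, best final likelihood wins
  runs <- vector("list", max(1L, n_starts))
  runs[[1]] <- em_run(rep(1 / H, H))
  if (n_starts > 1L) {
    seed_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(seed_state))
        assign(".Random.seed", seed_state, envir = globalenv())
    }, add = TRUE)
    set.seed(H * 10007L + nrow(pcalls))
    for (s in 2:n_starts) {
      f0 <- stats::rgamma(H, 1); f0 <- f0 / sum(f0)
      runs[[s]] <- em_run(f0)
    }
  }
  lls <- vapply(runs, function(r) r$ll_trace[length(r$ll_trace)], 0)
  best <- runs[[which.max(lls)]]
  f <- best$f
  ll_trace <- best$ll_trace
  converged <- best$converged
  moved <- runs[[1]]$moved
  iter <- best$iterations

  # ambiguous phase anywhere? (>= 2 het sites or any missing among informative)
  n_het <- rowSums(matrix(vapply(seq_along(pcalls), function(k) {
    g <- pcalls[k]
    if (is.na(g)) FALSE else {
      al <- strsplit(g, "/", fixed = TRUE)[[1]]; al[1] != al[2]
    }
  }, logical(1)), nrow = nrow(pcalls)))
  ambiguous <- any((n_het >= 2 | rowSums(is.na(pcalls)) > 0)[pat_informative])
  identifiable <- !(ambiguous && !moved && H > 1L)

  # final posterior dosages per pattern, expanded back to individuals
  lik <- f[i1] * f[i2] * mult
  s_all <- as.vector(rowsum(lik, pat_id))
  dos_pat <- matrix(0, nrow(pcalls), H)
  pw <- lik / s_all[pat_id]
  for (k in seq_along(pw)) {
    dos_pat[pat_id[k], i1[k]] <- dos_pat[pat_id[k], i1[k]] + pw[k]
    dos_pat[pat_id[k], i2[k]] <- dos_pat[pat_id[k], i2[k]] + pw[k]
  }
  dosages <- dos_pat[pat_of, , drop = FALSE]
  dimnames(dosages) <- list(gm$ids, haps)

  structure(list(haplotypes = haps, frequencies = stats::setNames(f, haps),
                 dosages = dosages, loglik = ll_trace,
                 converged = converged, identifiable = identifiable,
                 iterations = iter, n_used = n_used, sites = site_ids),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set over sites:", paste(x$sites, collapse = ", "), "\n")
  cat(sprintf("%d haplotypes, n = %d, %d EM iterations (%s)\n",
              length(x$haplotypes), x$n_used, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (!x$identifiable) cat("warning: frequencies not identifiable (symmetric ridge)\n")
  print(round(sort(x$frequencies, decreasing = TRUE), 4))
  invisible(x)
}

#' Haplotype frequency report with rare-haplotype pooling
#'
#' Haplotypes below the reporting floor are pooled into a single `rare`
#' row, mirroring the truncated haplotype tables usual in candidate-gene
#' reports.
#'
#' @param hs a `haplotype_set` from [em_haplotypes()].
#' @param floor pooling threshold on frequency (default 0.01).
#' @return data.frame with columns `haplotype`, `frequency`.
#' @export
haplotype_report <- function(hs, floor = 0.01) {
  f <- sort(hs$frequencies, decreasing = TRUE)
  keep <- f >= floor
  out <- data.frame(haplotype = names(f)[keep], frequency = unname(f[keep]))
  if (any(!keep) && sum(f[!keep]) > 1e-8) {
    out <- rbind(out, data.frame(haplotype = "rare",
                                 frequency = sum(f[!keep])))
  }
  out
}

#' Posterior expected haplotype dosage
#'
#' Per-individual expected copy count of one haplotype, for use as a
#' regression exposure. Expected (rather than best-guess) dosage keeps the
#' exposure unbiased under phase uncertainty.
#'
#' @param hs a `haplotype_set`.
#' @param haplotype allele string, e.g. `"GATT"`.
#' @return numeric vector named by individual.
#' @export
haplotype_dosage <- function(hs, haplotype) {
  k <- match(haplotype, hs$haplotypes)
  if (is.na(k)) stop("haplotype not in set: ", haplotype)
  hs$dosages[, k]
}
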
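#' Genotype matrix of unordered allele pairs
#'
#' Container for unphased genotype calls at candidate-gene sites. Each call
#' is an unordered allele pair such as `"A/C"` (stored with alleles sorted,
#' so `"C/A"` and `"A/C"` are the same genotype); missing calls are `NA`.
#' Sites carry an allele alphabet of two or three symbols and a locus group
#' label so that multi-site operations (haplotype inference, LD) can be
#' restricted to one linkage block.
#'
#' Major/minor allele designation follows the sample: the minor allele is
#' the less frequent one; an exact tie is broken lexicographically (the
#' alphabetically first allele is taken as major). For triallelic sites the
#' designation is left `NA` until the site is recoded (see
#' [recode_triallelic()]).
#'
#' @param calls character matrix, individuals in rows and sites in columns;
#'   entries like `"A/G"` (either allele order, `"/"` or `"|"` separator,
#'   phase is ignored) or `NA` for missing.
#' @param sites data.frame with columns `id` (site identifier, matching
#'   `colnames(calls)`), `locus` (block label, e.g. `"CRP"`/`"SAA1"`), and a
#'   list-column `alleles` giving each site's alphabet. If `alleles` is
#'   missing it is inferred from the observed calls.
#' @param ids individual identifiers; defaults to rownames of `calls` or
#'   `1..n`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (normalized matrix), `sites` (annotated site table with
#'   `major`/`minor` columns) and `ids`.
#' @examples
#' gm <- genotype_matrix(
#'   cbind(rs1 = c("A/A", "A/G", "G/G")),
#'   sites = data.frame(id = "rs1", locus = "CRP")
#' )
#' gm$sites$minor
#' @export
genotype_matrix <- function(calls, sites, ids = rownames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(colnames(calls))) colnames(calls) <- sites$id
  if (is.null(ids)) ids <- as.character(seq_len(nrow(calls)))
  sites <- as.data.frame(sites)
  if (!all(c("id", "locus") %in% names(sites))) {
    stop("`sites` must have columns `id` and `locus`")
  }
  sites$id <- as.character(sites$id)
  if (!identical(sort(colnames(calls)), sort(sites$id))) {
    stop("column names of `calls` must match `sites$id`")
  }
  calls <- calls[, sites$id, drop = FALSE]

  # normalize allele order and separator
  norm <- apply(calls, 2, function(col) {
    vapply(col, function(g) {
      if (is.na(g)) return(NA_character_)
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) != 2L) stop("malformed genotype call: ", g)
      paste(sort(al), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
  })
  if (!is.matrix(norm)) norm <- matrix(norm, nrow = nrow(calls),
                                       dimnames = dimnames(calls))
  rownames(norm) <- ids

  if (is.null(sites$alleles)) {
    sites$alleles <- lapply(seq_len(ncol(norm)), function(j) {
      sort(unique(unlist(strsplit(norm[, j][!is.na(norm[, j])], "/"))))
    })
  } else if (!is.list(sites$alleles)) {
    sites$alleles <- strsplit(as.character(sites$alleles), ",")
  }
  # alphabet size 1 is tolerated (monomorphic simulated sites); analyses
  # that need polymorphism flag or reject such sites themselves
  ok_size <- vapply(sites$alleles, length, 1L) %in% c(1L, 2L, 3L)
  if (!all(ok_size)) {
    stop("site alphabet must have 1-3 alleles: ",
         paste(sites$id[!ok_size], collapse = ", "))
  }
  for (j in seq_len(ncol(norm))) {
    obs <- unique(unlist(strsplit(norm[, j][!is.na(norm[, j])], "/")))
    bad <- setdiff(obs, sites$alleles[[j]])
    if (length(bad)) {
      stop("allele(s) outside alphabet at ", sites$id[j], ": ",
           paste(bad, collapse = ", "))
    }
  }

  gm <- structure(list(calls = norm, sites = sites, ids = as.character(ids)),
                  class = "genotype_matrix")
  gm$sites <- annotate_alleles(gm)
  gm
}

# sample-frequency major/minor designation (biallelic sites only)
annotate_alleles <- function(gm) {
  sites <- gm$sites
  sites$major <- NA_character_
  sites$minor <- NA_character_
  for (j in seq_len(ncol(gm$calls))) {
    alph <- sites$alleles[[j]]
    if (length(alph) != 2L) next
    cnt <- allele_counts(gm, sites$id[j])
    # ties: alphabetically first allele is major
    ord <- order(-cnt, names(cnt))
    sites$major[j] <- names(cnt)[ord[1]]
    sites$minor[j] <- names(cnt)[ord[2]]
  }
  sites
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x",
      nrow(x$sites), "sites\n")
  cat("loci:", paste(unique(x$sites$locus), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Allele counts at one site
#'
#' @param gm a [genotype_matrix()].
#' @param site site id.
#' @return named integer vector of allele counts over the site alphabet
#'   (missing calls excluded).
#' @export
allele_counts <- function(gm, site) {
  j <- match(site, gm$sites$id)
  if (is.na(j)) stop("unknown site: ", site)
  alph <- gm$sites$alleles[[j]]
  obs <- unlist(strsplit(gm$calls[, j][!is.na(gm$calls[, j])], "/"))
  cnt <- table(factor(obs, levels = alph))
  stats::setNames(as.integer(cnt), alph)
}

#' Genotype counts (MM, Mm, mm) at a biallelic site
#'
#' Counts individuals that are major-allele homozygous, heterozygous and
#' minor-allele homozygous, using the site's sample-derived major/minor
#' designation.
#'
#' @inheritParams allele_counts
#' @return named integer vector `c(MM, Mm, mm)`.
#' @export
genotype_counts <- function(gm, site) {
  j <- match(site, gm$sites$id)
  if (is.na(j)) stop("unknown site: ", site)
  if (length(gm$sites$alleles[[j]]) != 2L) {
    stop("genotype_counts() requires a biallelic site; recode ", site,
         " first (see recode_triallelic)")
  }
  M <- gm$sites$major[j]; m <- gm$sites$minor[j]
  g <- gm$calls[, j]
  g <- g[!is.na(g)]
  c(MM = sum(g == paste(M, M, sep = "/")),
    Mm = sum(g == paste(sort(c(M, m)), collapse = "/")),
    mm = sum(g == paste(m, m, sep = "/")))
}

#' Restrict a genotype matrix to one locus group
#'
#' @inheritParams allele_counts
#' @param locus locus group label.
#' @export
subset_locus <- function(gm, locus) {
  keep <- gm$sites$locus == locus
  if (!any(keep)) stop("no sites in locus group: ", locus)
  genotype_matrix(gm$calls[, gm$sites$id[keep], drop = FALSE],
                  gm$sites[keep, c("id", "locus", "alleles")],
                  ids = gm$ids)
}

# split "A/C" calls into a 2-column allele matrix (NA rows for missing)
split_calls <- function(g) {
  out <- matrix(NA_character_, length(g), 2)
  ok <- !is.na(g)
  if (any(ok)) {
    sp <- strsplit(g[ok], "/", fixed = TRUE)
    out[ok, 1] <- vapply(sp, `[`, "", 1L)
    out[ok, 2] <- vapply(sp, `[`, "", 2L)
  }
  out
}
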
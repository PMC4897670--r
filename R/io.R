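#' Read a cohort table
#'
#' Reads a delimited per-individual table (TSV or CSV) and validates unit
#' and coding conventions: biomarker level columns must be strictly
#' positive and indicator columns must be 0/1.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param level_columns columns checked for positivity (default
#'   `c("crp", "saa")`, intersected with what is present).
#' @param indicator_columns columns checked for 0/1 coding.
#' @return data.frame.
#' @export
read_cohort <- function(path, dialect = c("tsv", "csv"),
                        level_columns = c("crp", "saa"),
                        indicator_columns = c("sex", "smoking", "med_htn",
                                              "med_dm", "med_lipid")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- if (dialect == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  for (cl in intersect(level_columns, names(d))) {
    bad <- which(!is.na(d[[cl]]) & d[[cl]] <= 0)
    if (length(bad)) {
      stop("non-positive level in column '", cl, "' at data row ", bad[1])
    }
  }
  for (cl in intersect(indicator_columns, names(d))) {
    if (!all(stats::na.omit(d[[cl]]) %in% 0:1)) {
      stop("column '", cl, "' is not a 0/1 indicator")
    }
  }
  d
}

#' Write a cohort table as TSV
#'
#' @param cohort data.frame.
#' @param path output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV or minimal VCF
#'
#' TSV layout: one row per individual, an optional `id` column, and one
#' column per site holding calls such as `"A/T"` (phased `"A|T"` also
#' accepted; phase is discarded). VCF input is parsed with the vcfR
#' package; only the GT field is used, multi-ALT (triallelic) records give
#' three-symbol site alphabets, and both `/` and `|` separators are
#' accepted.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param locus_map named character vector mapping site id to locus group;
#'   sites absent from the map get locus `"unknown"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           locus_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    ids <- if ("id" %in% names(d)) d$id else as.character(seq_len(nrow(d)))
    d <- d[, setdiff(names(d), "id"), drop = FALSE]
    calls <- as.matrix(d)
    calls[calls %in% c("", ".", "./.", ".|.")] <- NA
    site_ids <- colnames(calls)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    site_ids <- fix[, "ID"]
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- colnames(gt)
    alleles_by_site <- lapply(seq_along(site_ids), function(k) {
      c(fix[k, "REF"], strsplit(fix[k, "ALT"], ",", fixed = TRUE)[[1]])
    })
    calls <- matrix(NA_character_, ncol(gt), nrow(gt),
                    dimnames = list(ids, site_ids))
    for (k in seq_along(site_ids)) {
      g <- gt[k, ]
      ok <- !is.na(g) & !grepl("\\.", g)
      idx <- strsplit(g[ok], "[/|]")
      calls[ok, k] <- vapply(idx, function(ii) {
        paste(alleles_by_site[[k]][as.integer(ii) + 1L], collapse = "/")
      }, character(1))
    }
  }
  rownames(calls) <- ids
  locus <- if (is.null(locus_map)) rep("unknown", length(site_ids)) else {
    out <- unname(locus_map[site_ids])
    out[is.na(out)] <- "unknown"
    out
  }
  genotype_matrix(calls, data.frame(id = site_ids, locus = locus),
                  ids = ids)
}

#' Write genotypes as TSV
#'
#' One row per individual, `id` column plus one `"A/T"`-style column per
#' site; missing calls are written as `"."`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(gm, path) {
  d <- as.data.frame(gm$calls, stringsAsFactors = FALSE)
  d[is.na(d)] <- "."
  d <- cbind(id = gm$ids, d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with the GT field only and unphased
#' `/` separators. The REF allele is the site's major allele when
#' designated, otherwise the first alphabet symbol; remaining alphabet
#' symbols become ALT alleles (two ALTs for a triallelic site). Positions
#' are synthetic unless supplied.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param chrom chromosome label(s), recycled over sites.
#' @param pos integer positions; default `1000 * site index`.
#' @export
write_vcf_minimal <- function(gm, path, chrom = "1",
                              pos = 1000L * seq_len(nrow(gm$sites))) {
  sites <- gm$sites
  chrom <- rep_len(chrom, nrow(sites))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$ids),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(sites))) {
    alph <- sites$alleles[[j]]
    ref <- if (!is.na(sites$major[j])) sites$major[j] else alph[1]
    alt <- setdiff(alph, ref)
    code <- stats::setNames(seq_along(c(ref, alt)) - 1L, c(ref, alt))
    gts <- vapply(gm$calls[, j], function(g) {
      if (is.na(g)) return("./.")
      al <- strsplit(g, "/", fixed = TRUE)[[1]]
      paste(sort(code[al]), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    writeLines(paste(c(chrom[j], pos[j], sites$id[j], ref,
                       paste(alt, collapse = ","), ".", "PASS", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
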
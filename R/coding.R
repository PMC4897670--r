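#' Additive genotype coding (minor-allele dosage)
#'
#' Codes each individual's genotype at a biallelic site as the number of
#' copies of the counted allele: 0 (MM), 1 (Mm) or 2 (mm). Missing calls
#' propagate as `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param site site id (must be biallelic; recode triallelic sites first).
#' @param allele allele to count; defaults to the site's sample-derived
#'   minor allele. Supplying the allele explicitly pins the sign convention
#'   of downstream regression coefficients.
#' @return integer vector of dosages in `{0, 1, 2}`, named by individual.
#' @export
code_additive <- function(gm, site, allele = NULL) {
  j <- match(site, gm$sites$id)
  if (is.na(j)) stop("unknown site: ", site)
  if (length(gm$sites$alleles[[j]]) != 2L) {
    stop("additive coding requires a biallelic site; recode ", site,
         " first (see recode_triallelic)")
  }
  if (is.null(allele)) allele <- gm$sites$minor[j]
  if (!allele %in% gm$sites$alleles[[j]]) {
    stop("allele ", allele, " not in the alphabet of ", site)
  }
  al <- split_calls(gm$calls[, j])
  stats::setNames((al[, 1] == allele) + (al[, 2] == allele), gm$ids)
}

#' Dominant genotype coding (carrier indicator)
#'
#' Codes major-allele homozygotes (MM) as 0 and carriers of at least one
#' counted allele (Mm or mm) as 1.
#'
#' @inheritParams code_additive
#' @return integer vector in `{0, 1}`, named by individual; `NA` for
#'   missing calls.
#' @export
code_dominant <- function(gm, site, allele = NULL) {
  d <- code_additive(gm, site, allele)
  stats::setNames(as.integer(d >= 1L), names(d))
}

#' Recode a triallelic site to a biallelic MM/Mm/mm classification
#'
#' Collapses the six unordered genotypes of a three-allele site into three
#' classes via an explicit grouping, and returns a genotype matrix in which
#' the site is replaced by a synthetic biallelic site with alleles `M`
#' (major) and `m` (minor), so that [code_additive()] and [code_dominant()]
#' apply directly.
#'
#' The default grouping is the one used for the triallelic CRP promoter
#' site rs3091244 (alleles A, C, T): `CC -> MM`; `AA, AC, AT -> Mm`;
#' `CT, TT -> mm`.
#'
#' @param gm a [genotype_matrix()].
#' @param site id of the triallelic site.
#' @param grouping named list with components `MM`, `Mm`, `mm`, each a
#'   character vector of unordered genotypes written as two-letter strings
#'   (allele order irrelevant). Every observed genotype must be covered.
#' @return a new [genotype_matrix()] with the site recoded; its calls at
#'   the site are `"M/M"`, `"M/m"` or `"m/m"`.
#' @examples
#' gm <- genotype_matrix(
#'   cbind(rs3091244 = c("C/C", "A/T", "T/T")),
#'   sites = data.frame(id = "rs3091244", locus = "CRP",
#'                      alleles = I(list(c("A", "C", "T"))))
#' )
#' recode_triallelic(gm, "rs3091244")$calls
#' @export
recode_triallelic <- function(gm, site,
                              grouping = list(MM = "CC",
                                              Mm = c("AA", "AC", "AT"),
                                              mm = c("CT", "TT"))) {
  j <- match(site, gm$sites$id)
  if (is.na(j)) stop("unknown site: ", site)
  if (length(gm$sites$alleles[[j]]) != 3L) {
    stop(site, " is not triallelic")
  }
  if (!setequal(names(grouping), c("MM", "Mm", "mm")) ||
      length(grouping) != 3L) {
    stop("`grouping` must have components MM, Mm, mm")
  }
  norm_pair <- function(x) {
    vapply(strsplit(x, ""), function(a) paste(sort(a), collapse = ""), "")
  }
  map <- c(stats::setNames(rep("M/M", length(grouping$MM)), norm_pair(grouping$MM)),
           stats::setNames(rep("M/m", length(grouping$Mm)), norm_pair(grouping$Mm)),
           stats::setNames(rep("m/m", length(grouping$mm)), norm_pair(grouping$mm)))
  g <- gm$calls[, j]
  key <- ifelse(is.na(g), NA, gsub("/", "", g, fixed = TRUE))
  uncovered <- setdiff(unique(key[!is.na(key)]), names(map))
  if (length(uncovered)) {
    stop("genotype(s) absent from grouping at ", site, ": ",
         paste(uncovered, collapse = ", "))
  }
  calls <- gm$calls
  calls[, j] <- unname(map[key])
  sites <- gm$sites[, c("id", "locus", "alleles")]
  sites$alleles[[j]] <- c("M", "m")
  out <- genotype_matrix(calls, sites, ids = gm$ids)
  # the grouping *defines* M as major: pin it rather than re-deriving from
  # sample frequency (the pooled Mm+mm class may well outnumber MM)
  out$sites$major[j] <- "M"
  out$sites$minor[j] <- "m"
  out
}
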
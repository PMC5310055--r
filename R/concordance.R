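# Concordance of exome genotypes against orthogonal platforms
# (Sanger / Taqman style calls).

#' Read orthogonal genotype calls
#'
#' Tab-delimited with header columns `subject_id`, `rsid`, `chrom`, `pos`,
#' `ref`, `alt`, `platform`, `genotype` (coded `0/0`, `0/1`, `1/1`, `1`,
#' `.`). One call per (subject, variant, platform).
#'
#' @param path Path to the TSV file.
#' @param subject_sexes Optional named `id -> "M"/"F"` map to decode male
#'   X/Y genotypes as hemizygous.
#' @return An `orthogonal_calls` data frame with decoded `zygosity` and `key`.
#' @export
read_orthogonal_calls <- function(path, subject_sexes = NULL) {
  oc <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  req <- c("subject_id", "rsid", "chrom", "pos", "ref", "alt", "platform",
           "genotype")
  miss <- setdiff(req, names(oc))
  if (length(miss))
    stop("orthogonal-calls table is missing column(s): ",
         paste(miss, collapse = ", "))
  oc$chrom <- .norm_chrom(oc$chrom)
  oc$pos <- as.integer(oc$pos)
  oc$ref <- toupper(oc$ref)
  oc$alt <- toupper(oc$alt)
  oc$key <- variant_key(oc$chrom, oc$pos, oc$ref, oc$alt)
  if (anyDuplicated(oc[c("subject_id", "key", "platform")]))
    stop("duplicate (subject, variant, platform) calls")
  male <- if (is.null(subject_sexes)) rep(FALSE, nrow(oc))
          else toupper(as.character(subject_sexes[oc$subject_id])) == "M"
  male[is.na(male)] <- FALSE
  oc$zygosity <- vapply(seq_len(nrow(oc)), function(i) {
    .decode_gt(oc$genotype[i], 1L, male[i] && .is_sex_chrom(oc$chrom[i]))
  }, character(1))
  class(oc) <- c("orthogonal_calls", "data.frame")
  oc
}

#' Compare exome genotypes against orthogonal calls
#'
#' Each call is resolved to a matrix cell by variant key, or, failing that,
#' to an extra-genotype record by rsID (for loci outside the exome capture).
#' By default a pair enters the denominator only when both sides are
#' non-missing (the strict mode `count_missing = TRUE` counts such pairs as
#' mismatches), and matching requires identical zygosity
#' (`hemi_equals_hom = TRUE` lets HEMI_ALT match HOM_ALT and HEMI_REF match
#' HOM_REF).
#'
#' @param matrix A [genotype_matrix()].
#' @param calls An `orthogonal_calls` data frame (or any data frame with
#'   columns `subject_id`, `key`, `rsid`, `platform`, `zygosity`).
#' @param extra_genotypes Optional [read_extra_genotypes()] table.
#' @param hemi_equals_hom Treat hemizygous as matching homozygous?
#' @param count_missing Count pairs with a missing side as mismatches?
#' @return A `concordance_report`: list with `platforms` (data frame
#'   `platform`, `n_compared`, `n_matched`, `rate_percent`), `n_compared`,
#'   `n_matched` and `rate_percent` overall.
#' @export
compare_genotypes <- function(matrix, calls, extra_genotypes = NULL,
                              hemi_equals_hom = FALSE, count_missing = FALSE) {
  if (!nrow(calls)) stop("no orthogonal calls supplied")
  unknown <- setdiff(unique(calls$subject_id), matrix$subjects$id)
  if (length(unknown))
    stop("orthogonal call(s) reference unknown subject(s): ",
         paste(unknown, collapse = ", "))
  mkeys <- matrix$variants$key
  wes <- vapply(seq_len(nrow(calls)), function(i) {
    k <- calls$key[i]
    if (k %in% mkeys)
      return(matrix$geno[calls$subject_id[i], k])
    if (!is.null(extra_genotypes)) {
      hit <- extra_genotypes$rsid == calls$rsid[i] &
        extra_genotypes$subject_id == calls$subject_id[i]
      if (any(hit)) return(extra_genotypes$zygosity[which(hit)[1L]])
    }
    stop("orthogonal call not resolvable to an exome or extra genotype: ",
         "subject ", calls$subject_id[i], ", variant ", k)
  }, character(1))

  canon <- function(z) {
    if (hemi_equals_hom)
      z <- c(HOM_REF = "HOM_REF", HET = "HET", HOM_ALT = "HOM_ALT",
             HEMI_REF = "HOM_REF", HEMI_ALT = "HOM_ALT", MISSING = "MISSING")[z]
    z
  }
  both_called <- wes != "MISSING" & calls$zygosity != "MISSING"
  compared <- if (count_missing) rep(TRUE, nrow(calls)) else both_called
  matched <- compared & both_called & canon(wes) == canon(calls$zygosity)

  platforms <- unique(calls$platform)
  per <- data.frame(
    platform = platforms,
    n_compared = vapply(platforms, function(p)
      sum(compared & calls$platform == p), integer(1)),
    n_matched = vapply(platforms, function(p)
      sum(matched & calls$platform == p), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  per$rate_percent <- ifelse(per$n_compared > 0,
                             100 * per$n_matched / per$n_compared, NA_real_)
  n_compared <- sum(compared)
  if (n_compared == 0L)
    stop("no comparable genotype pairs: all cells missing on one side")
  structure(list(platforms = per, n_compared = n_compared,
                 n_matched = sum(matched),
                 rate_percent = 100 * sum(matched) / n_compared),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report\n")
  print(x$platforms, row.names = FALSE)
  cat(sprintf("overall: %d/%d matched (%.1f%%)\n",
              x$n_matched, x$n_compared, x$rate_percent))
  invisible(x)
}
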
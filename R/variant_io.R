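# Genotype-matrix input/output: multi-sample VCF -> subjects x variants
# zygosity matrix, plus the per-variant annotation table that drives the
# downstream filters.

#' Build a variant key string
#'
#' A variant is identified throughout the package by the string
#' `"chrom:pos:ref:alt"` on 1-based GRCh37/hg19-style coordinates. The `"chr"`
#' prefix, if present, is stripped so that `"chr1"` and `"1"` name the same
#' chromosome.
#'
#' @param chrom Chromosome label (e.g. `"1"`, `"10"`, `"X"`).
#' @param pos 1-based base-pair position.
#' @param ref,alt Reference and alternate allele strings (uppercase A/C/G/T/N).
#' @return Character vector of keys.
#' @examples
#' variant_key("1", 171076936, "G", "T")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- .norm_chrom(chrom)
  if (any(grepl(":", chrom, fixed = TRUE)))
    stop("chromosome labels must not contain ':'")
  paste(chrom, as.integer(pos), toupper(ref), toupper(alt), sep = ":")
}

#' Parse variant key strings
#'
#' @param key Character vector of `"chrom:pos:ref:alt"` keys.
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(as.character(key), ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed variant key(s): ", paste(key[bad], collapse = ", "))
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos   = as.integer(vapply(parts, `[`, character(1), 2L)),
    ref   = vapply(parts, `[`, character(1), 3L),
    alt   = vapply(parts, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

#' Classify variants as SNP or INDEL
#'
#' A variant is a SNP exactly when both alleles have length one; any
#' insertion or deletion (either allele longer than one base) is an INDEL.
#'
#' @param ref Reference alleles, or variant key strings if `alt` is `NULL`.
#' @param alt Alternate alleles, or `NULL` to parse `ref` as keys.
#' @return Character vector, `"SNP"` or `"INDEL"`.
#' @examples
#' classify_variant("G", "T")          # SNP
#' classify_variant("A", "AT")         # insertion -> INDEL
#' classify_variant("2:100:AT:A")      # deletion  -> INDEL
#' @export
classify_variant <- function(ref, alt = NULL) {
  if (is.null(alt)) {
    k <- parse_variant_key(ref)
    ref <- k$ref
    alt <- k$alt
  }
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}

.validate_alleles <- function(ref, alt) {
  ok <- grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt)
  if (any(!ok))
    stop("alleles must be non-empty uppercase strings over {A,C,G,T,N}")
  if (any(ref == alt))
    stop("ref and alt alleles must differ")
}

#' Construct a genotype matrix
#'
#' The container that backs every filter: an ordered subject list, an ordered
#' variant list and one zygosity call per cell. Zygosity values are
#' `HOM_REF`, `HET`, `HOM_ALT`, `HEMI_REF`, `HEMI_ALT` or `MISSING`; `HEMI_*`
#' is only legal on X/Y cells of male subjects.
#'
#' @param geno Character matrix of zygosity calls, subjects in rows and
#'   variants in columns.
#' @param subjects Data frame with columns `id` (unique) and `sex`
#'   (`"M"`/`"F"`); extra columns (age, ancestry) are carried along.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `subjects`, `variants` (gains a `key` column) and `geno` (dimnames set to
#'   subject ids and variant keys).
#' @export
genotype_matrix <- function(geno, subjects, variants) {
  stopifnot(is.data.frame(subjects), is.data.frame(variants))
  subjects$id <- as.character(subjects$id)
  subjects$sex <- toupper(as.character(subjects$sex))
  if (anyDuplicated(subjects$id))
    stop("subject ids must be unique")
  if (!all(subjects$sex %in% c("M", "F")))
    stop("subject sex must be 'M' or 'F'")
  variants$chrom <- .norm_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  if (nrow(variants)) {
    if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
    .validate_alleles(variants$ref, variants$alt)
  }
  variants$key <- if (nrow(variants))
    variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  else character(0)
  if (anyDuplicated(variants$key))
    stop("variant keys must be unique within a matrix: ",
         paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  if (nrow(geno) != nrow(subjects) || ncol(geno) != nrow(variants))
    stop("geno must be |subjects| x |variants| (got ",
         nrow(geno), "x", ncol(geno), ")")
  if (length(geno) && !all(geno %in% .zygosity_levels))
    stop("invalid zygosity value(s): ",
         paste(unique(geno[!geno %in% .zygosity_levels]), collapse = ", "))
  hemi <- geno %in% c("HEMI_REF", "HEMI_ALT")
  if (any(hemi)) {
    allowed <- outer(subjects$sex == "M", .is_sex_chrom(variants$chrom), `&`)
    if (any(hemi & !allowed))
      stop("HEMI_* zygosity is only valid on X/Y cells of male subjects")
  }
  dimnames(geno) <- list(subjects$id, variants$key)
  structure(list(subjects = subjects, variants = variants, geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$subjects), " subjects x ",
      nrow(x$variants), " variants\n", sep = "")
  if (length(x$geno)) {
    tab <- table(factor(x$geno, levels = .zygosity_levels))
    cat("  cells:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Decode a single VCF GT string relative to one alt allele index.
# `hemi` marks male sex-chromosome cells, where single-allele and
# homozygous-coded genotypes become HEMI_* calls.
.decode_gt <- function(g, alt_index, hemi) {
  if (is.na(g) || g == "" || g == ".") return("MISSING")
  g <- gsub("|", "/", g, fixed = TRUE)
  al <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (!length(al) || any(al == ".")) return("MISSING")
  dose <- sum(al == as.character(alt_index))
  if (length(al) == 1L) {
    if (hemi) return(if (dose >= 1L) "HEMI_ALT" else "HEMI_REF")
    return(if (dose >= 1L) "HOM_ALT" else "HOM_REF")
  }
  if (hemi) {
    if (dose == length(al)) return("HEMI_ALT")
    if (all(al == "0")) return("HEMI_REF")
    return("HET")
  }
  if (dose == 0L) "HOM_REF" else if (dose == length(al)) "HOM_ALT" else "HET"
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Every record contributes one matrix column per alternate allele
#' (multiallelic records are split, and each cell's zygosity is counted
#' relative to that column's alt allele, so allele dosage is conserved across
#' the split columns). `./.` and partially missing genotypes become
#' `MISSING`. On X/Y, single-allele or homozygous-coded genotypes of male
#' subjects become `HEMI_REF`/`HEMI_ALT`.
#'
#' @param path Path to a VCF 4.x file with a GT FORMAT field.
#' @param subject_sexes Named character vector mapping every VCF sample name
#'   to `"M"` or `"F"` (or a data frame with columns `id` and `sex`).
#' @return A [genotype_matrix()].
#' @export
read_multisample_vcf <- function(path, subject_sexes) {
  stopifnot(is.character(path), length(path) == 1L)
  if (is.data.frame(subject_sexes))
    subject_sexes <- stats::setNames(as.character(subject_sexes$sex),
                                     as.character(subject_sexes$id))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(vcf@gt) < 2L)
    stop("VCF has no sample columns: ", path)
  samples <- colnames(vcf@gt)[-1L]
  no_sex <- setdiff(samples, names(subject_sexes))
  if (length(no_sex))
    stop("no sex provided for VCF sample(s): ", paste(no_sex, collapse = ", "))
  sex <- toupper(as.character(subject_sexes[samples]))
  if (!all(sex %in% c("M", "F")))
    stop("subject sexes must be 'M' or 'F'")

  chrom <- .norm_chrom(vcfR::getCHROM(vcf))
  pos <- vcfR::getPOS(vcf)
  ref <- toupper(vcfR::getREF(vcf))
  alt <- toupper(vcfR::getALT(vcf))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = length(chrom),
                 dimnames = list(NULL, samples))
  male <- sex == "M"

  v_chrom <- character(0); v_pos <- integer(0)
  v_ref <- character(0); v_alt <- character(0)
  cols <- list()
  for (i in seq_along(chrom)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    hemi <- male & .is_sex_chrom(chrom[i])
    for (a in seq_along(alts)) {
      v_chrom <- c(v_chrom, chrom[i])
      v_pos <- c(v_pos, pos[i])
      v_ref <- c(v_ref, ref[i])
      v_alt <- c(v_alt, alts[a])
      cols[[length(cols) + 1L]] <- vapply(
        seq_along(samples),
        function(s) .decode_gt(gt[i, s], a, hemi[s]),
        character(1)
      )
    }
  }
  geno <- if (length(cols)) do.call(cbind, cols)
          else matrix(character(0), nrow = length(samples), ncol = 0L)
  genotype_matrix(
    geno,
    subjects = data.frame(id = samples, sex = sex, stringsAsFactors = FALSE),
    variants = data.frame(chrom = v_chrom, pos = v_pos, ref = v_ref,
                          alt = v_alt, stringsAsFactors = FALSE)
  )
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCF 4.2 file with a GT FORMAT field; `HEMI_*` calls are
#' written as single-allele genotypes (`0`/`1`) and `MISSING` as `./.`.
#' Re-reading with [read_multisample_vcf()] and the same sex map reproduces
#' the matrix cell-by-cell.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  code <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
            HEMI_REF = "0", HEMI_ALT = "1", MISSING = "./.")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$subjects$id), collapse = "\t")
  )
  v <- x$variants
  rows <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], ".", v$ref[j], v$alt[j], ".", "PASS", ".",
            "GT", code[x$geno[, j]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.sift_vocab <- c("TOLERATED", "DELETERIOUS")
.polyphen_vocab <- c("BENIGN", "DAMAGING")

.validate_annotation <- function(ann) {
  req <- c("chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  opt <- c("rsid", "sift_score", "sift_call", "polyphen_score",
           "polyphen_call", "maf")
  for (col in setdiff(opt, names(ann))) ann[[col]] <- rep(NA, nrow(ann))
  ann <- ann[c(req, opt)]   # unknown columns ignored
  ann$chrom <- .norm_chrom(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  ann$ref <- toupper(as.character(ann$ref))
  ann$alt <- toupper(as.character(ann$alt))
  ann$gene <- as.character(ann$gene)
  ann$rsid <- as.character(ann$rsid)
  for (col in c("sift_score", "polyphen_score", "maf"))
    ann[[col]] <- as.numeric(ann[[col]])
  for (col in c("sift_call", "polyphen_call"))
    ann[[col]] <- toupper(as.character(ann[[col]]))
  ann$sift_call[ann$sift_call %in% c("NA", "")] <- NA
  ann$polyphen_call[ann$polyphen_call %in% c("NA", "")] <- NA
  bad <- !is.na(ann$sift_call) & !ann$sift_call %in% .sift_vocab
  if (any(bad))
    stop("invalid sift_call value(s): ", paste(unique(ann$sift_call[bad]), collapse = ", "))
  bad <- !is.na(ann$polyphen_call) & !ann$polyphen_call %in% .polyphen_vocab
  if (any(bad))
    stop("invalid polyphen_call value(s): ", paste(unique(ann$polyphen_call[bad]), collapse = ", "))
  score_bad <- function(x) !is.na(x) & (x < 0 | x > 1)
  if (any(score_bad(ann$sift_score)) || any(score_bad(ann$polyphen_score)))
    stop("predictor scores must lie in [0, 1]")
  if (any(!is.na(ann$maf) & (ann$maf < 0 | ann$maf > 0.5)))
    stop("MAF values must lie in [0, 0.5]")
  if (nrow(ann)) .validate_alleles(ann$ref, ann$alt)
  ann$key <- if (nrow(ann)) variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
             else character(0)
  if (anyDuplicated(ann$key))
    stop("duplicate variant rows in annotation table: ",
         paste(unique(ann$key[duplicated(ann$key)]), collapse = ", "))
  ann$variant_class <- classify_variant(ann$ref, ann$alt)
  class(ann) <- c("variant_annotation", "data.frame")
  ann
}

#' Read a per-variant annotation table
#'
#' Tab-delimited with header; required columns `chrom`, `pos`, `ref`, `alt`,
#' `gene`; optional columns `rsid`, `sift_score`, `sift_call`
#' (TOLERATED/DELETERIOUS), `polyphen_score`, `polyphen_call`
#' (BENIGN/DAMAGING), `maf`. `"."` marks missing values; unknown columns are
#' ignored. The variant class (SNP/INDEL) is derived from allele lengths.
#'
#' @param path Path to the TSV file.
#' @return A `variant_annotation` data frame keyed by `"chrom:pos:ref:alt"`.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c(".", ""), colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  .validate_annotation(ann)
}

#' Build an annotation table from a data frame
#'
#' In-memory counterpart of [read_annotation_table()], applying the same
#' validation (unique keys, MAF range, call vocabularies).
#'
#' @param df Data frame with the annotation columns.
#' @return A `variant_annotation` data frame.
#' @export
as_variant_annotation <- function(df) .validate_annotation(as.data.frame(df))

#' Read / write plain-text gene sets
#'
#' One gene symbol per line; blank lines and `#` comments are skipped.
#' Membership tests elsewhere in the package are case-insensitive.
#'
#' @param path File path.
#' @return `read_gene_set`: character vector of symbols.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname read_gene_set
#' @param genes Character vector of gene symbols.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
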
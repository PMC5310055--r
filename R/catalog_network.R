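# Known-variant catalog lookup and seed-gene interactome expansion over a
# pre-scored protein-interaction edge list.

#' Read a known-variant catalog
#'
#' Tab-delimited with header columns `rsid`, `chrom`, `pos`, `ref`, `alt`,
#' `gene`, and optional `maf`, `hgvs_c`, `hgvs_p`, `evidence`; `"."` marks
#' missing values. rsIDs and variant keys must be unique.
#'
#' @param path Path to the TSV file.
#' @return A `known_variant_catalog` data frame with a derived `key` column.
#' @export
read_known_variant_catalog <- function(path) {
  cat_df <- utils::read.delim(path, sep = "\t", header = TRUE,
                              na.strings = c(".", ""), colClasses = "character",
                              stringsAsFactors = FALSE)
  req <- c("rsid", "chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(req, names(cat_df))
  if (length(miss))
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("maf", "hgvs_c", "hgvs_p", "evidence"))
    if (!col %in% names(cat_df)) cat_df[[col]] <- NA
  cat_df$chrom <- .norm_chrom(cat_df$chrom)
  cat_df$pos <- as.integer(cat_df$pos)
  cat_df$ref <- toupper(cat_df$ref)
  cat_df$alt <- toupper(cat_df$alt)
  cat_df$maf <- as.numeric(cat_df$maf)
  cat_df$key <- variant_key(cat_df$chrom, cat_df$pos, cat_df$ref, cat_df$alt)
  if (anyDuplicated(cat_df$rsid))
    stop("catalog rsids must be unique")
  if (anyDuplicated(cat_df$key))
    stop("catalog variant keys must be unique")
  class(cat_df) <- c("known_variant_catalog", "data.frame")
  cat_df
}

#' Read extra (non-exome) genotype records
#'
#' Side-channel for variants genotyped outside the exome capture (e.g. an
#' intronic Taqman assay). Tab-delimited with header columns `subject_id`,
#' `rsid`, `chrom`, `pos`, `ref`, `alt`, optional `gene`, and `genotype`
#' coded VCF-style (`0/0`, `0/1`, `1/1`, `1`, `.`).
#'
#' @param path Path to the TSV file.
#' @param subject_sexes Optional named `id -> "M"/"F"` map; needed to decode
#'   male X/Y genotypes as hemizygous.
#' @return Data frame with a decoded `zygosity` column and a `key` column.
#' @export
read_extra_genotypes <- function(path, subject_sexes = NULL) {
  eg <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  req <- c("subject_id", "rsid", "chrom", "pos", "ref", "alt", "genotype")
  miss <- setdiff(req, names(eg))
  if (length(miss))
    stop("extra-genotype table is missing column(s): ",
         paste(miss, collapse = ", "))
  eg$chrom <- .norm_chrom(eg$chrom)
  eg$pos <- as.integer(eg$pos)
  eg$ref <- toupper(eg$ref)
  eg$alt <- toupper(eg$alt)
  eg$key <- variant_key(eg$chrom, eg$pos, eg$ref, eg$alt)
  male <- if (is.null(subject_sexes)) rep(FALSE, nrow(eg))
          else toupper(as.character(subject_sexes[eg$subject_id])) == "M"
  male[is.na(male)] <- FALSE
  eg$zygosity <- vapply(seq_len(nrow(eg)), function(i) {
    .decode_gt(eg$genotype[i], 1L, male[i] && .is_sex_chrom(eg$chrom[i]))
  }, character(1))
  eg
}

#' Look up known variants in a cohort
#'
#' For each catalog entry, emits one hit per subject carrying the alternate
#' allele (HET, HOM_ALT or HEMI_ALT), with its zygosity. Variants absent from
#' the matrix are resolved through `extra_genotypes` (matched by rsID), the
#' side-channel for loci not captured by the exome. A catalog position that
#' matches a matrix variant with different alleles triggers a warning.
#'
#' @param matrix A [genotype_matrix()].
#' @param catalog A [read_known_variant_catalog()] table.
#' @param extra_genotypes Optional [read_extra_genotypes()] table.
#' @return A `catalog_hits` data frame: `subject_id`, `rsid`, `gene`,
#'   `zygosity`.
#' @export
lookup_known_variants <- function(matrix, catalog, extra_genotypes = NULL) {
  empty <- data.frame(subject_id = character(0), rsid = character(0),
                      gene = character(0), zygosity = character(0),
                      stringsAsFactors = FALSE)
  hits <- list(empty)
  mkeys <- matrix$variants$key
  mpos <- paste(matrix$variants$chrom, matrix$variants$pos, sep = ":")
  for (i in seq_len(nrow(catalog))) {
    k <- catalog$key[i]
    if (k %in% mkeys) {
      zy <- matrix$geno[, k]
      carrier <- zy %in% .carrier_states
      if (any(carrier))
        hits[[length(hits) + 1L]] <- data.frame(
          subject_id = matrix$subjects$id[carrier], rsid = catalog$rsid[i],
          gene = catalog$gene[i], zygosity = unname(zy[carrier]),
          stringsAsFactors = FALSE)
      next
    }
    cp <- paste(catalog$chrom[i], catalog$pos[i], sep = ":")
    if (cp %in% mpos)
      warning("catalog entry ", catalog$rsid[i],
              " collides with a differently-annotated matrix variant at ", cp)
    if (!is.null(extra_genotypes)) {
      ex <- extra_genotypes[extra_genotypes$rsid == catalog$rsid[i] &
                              extra_genotypes$zygosity %in% .carrier_states, ,
                            drop = FALSE]
      if (nrow(ex))
        hits[[length(hits) + 1L]] <- data.frame(
          subject_id = ex$subject_id, rsid = catalog$rsid[i],
          gene = catalog$gene[i], zygosity = ex$zygosity,
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  class(out) <- c("catalog_hits", "data.frame")
  out
}

#' Tally catalog hits by rsID
#'
#' Counts heterozygous and homozygous carriers per catalog variant;
#' hemizygous-alt calls count as homozygous.
#'
#' @param hits A `catalog_hits` data frame from [lookup_known_variants()].
#' @return Data frame with columns `rsid`, `n_het`, `n_hom`.
#' @export
tally_catalog_hits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(rsid = character(0), n_het = integer(0),
                      n_hom = integer(0), stringsAsFactors = FALSE))
  rsids <- unique(hits$rsid)
  data.frame(
    rsid = rsids,
    n_het = vapply(rsids, function(r)
      sum(hits$rsid == r & hits$zygosity == "HET"), integer(1)),
    n_hom = vapply(rsids, function(r)
      sum(hits$rsid == r & hits$zygosity %in% .homalt_states), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a scored interaction-network edge list
#'
#' Tab-delimited with header columns `gene_a`, `gene_b`, `combined_score`.
#' Scores on the 0-1000 integer dialect are auto-detected (any score above 1)
#' and divided by 1000. Self-loops and duplicate unordered pairs are
#' rejected.
#'
#' @param path Path to the TSV file.
#' @return An `interaction_network` data frame: `gene_a`, `gene_b`, `score`.
#' @export
read_interaction_network <- function(path) {
  net <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("gene_a", "gene_b", "combined_score")
  miss <- setdiff(req, names(net))
  if (length(miss))
    stop("network table is missing column(s): ", paste(miss, collapse = ", "))
  score <- as.numeric(net$combined_score)
  if (any(is.na(score)))
    stop("non-numeric combined_score values")
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0 | score > 1))
    stop("interaction scores must lie in [0, 1] (or the 0-1000 dialect)")
  a <- toupper(net$gene_a)
  b <- toupper(net$gene_b)
  if (any(a == b))
    stop("self-loop edge(s) in network: ", paste(unique(a[a == b]), collapse = ", "))
  pair <- ifelse(a < b, paste(a, b), paste(b, a))
  if (anyDuplicated(pair))
    stop("duplicate edge(s) for unordered pair(s): ",
         paste(unique(pair[duplicated(pair)]), collapse = ", "))
  structure(data.frame(gene_a = a, gene_b = b, score = score,
                       stringsAsFactors = FALSE),
            class = c("interaction_network", "data.frame"))
}

#' Expand seed genes through an interaction network
#'
#' For each seed, takes its neighbors with score at least `min_score`,
#' ordered by descending score (ties at the cut broken lexicographically by
#' symbol), truncated to `max_interactors`; the union over seeds, with the
#' seeds themselves included, is returned. A seed absent from the network is
#' kept with zero interactors, with a warning.
#'
#' @param network An [read_interaction_network()] edge list.
#' @param seeds Character vector of seed gene symbols.
#' @param min_score Minimum interaction score (default 0.4).
#' @param max_interactors Maximum neighbors kept per seed (default 10).
#' @return Sorted character vector of uppercase gene symbols.
#' @export
expand_seed_genes <- function(network, seeds, min_score = 0.4,
                              max_interactors = 10L) {
  if (!length(seeds)) stop("at least one seed gene is required")
  a <- toupper(network$gene_a)
  b <- toupper(network$gene_b)
  out <- toupper(seeds)
  for (s in toupper(seeds)) {
    on_edge <- a == s | b == s
    if (!any(on_edge)) {
      warning("seed gene ", s, " is absent from the network")
      next
    }
    nb <- ifelse(a[on_edge] == s, b[on_edge], a[on_edge])
    sc <- network$score[on_edge]
    keep <- sc >= min_score
    nb <- nb[keep]
    sc <- sc[keep]
    ord <- order(-sc, nb)
    out <- c(out, nb[ord][seq_len(min(max_interactors, length(nb)))])
  }
  sort(unique(out))
}

#' Scan an interactome gene set for rare deleterious variants
#'
#' Keeps matrix variants annotated to a gene in the interactome set that have
#' at least one carrier of any zygosity (the sharing and homozygosity rules
#' of the cascade do not apply here) and that pass the pathogenicity and
#' rarity filters.
#'
#' @param matrix A [genotype_matrix()].
#' @param annotations A `variant_annotation` table.
#' @param interactome Character vector of gene symbols (e.g. from
#'   [expand_seed_genes()]).
#' @param config A [cascade_config()].
#' @return Character vector of surviving variant keys.
#' @export
interactome_variant_scan <- function(matrix, annotations, interactome,
                                     config = cascade_config()) {
  if (!length(interactome)) stop("interactome gene set is empty")
  keys <- intersect(matrix$variants$key, annotations$key)
  gene <- toupper(annotations$gene[match(keys, annotations$key)])
  keys <- keys[!is.na(gene) & gene %in% toupper(interactome)]
  keys <- keys[vapply(keys, function(k)
    any(matrix$geno[, k] %in% .carrier_states), logical(1))]
  keys <- pathogenicity_filter(keys, annotations, config)
  rarity_filter(keys, annotations, config)
}
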
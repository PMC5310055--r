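# The variant-prioritization cascade: a shared trunk (cohort homozygote
# presence, then in-silico deleteriousness) followed by two discovery
# branches -- oxidoreductase gene-set membership + rarity, and cross-subject
# sharing within genes outside the known TMA-metabolism set + rarity.

#' Cascade configuration
#'
#' @param maf_threshold Variants with MAF strictly below this are rare
#'   (default 0.05, the 1000 Genomes rarity convention).
#' @param sift_deleterious_max SIFT scores strictly below this count as
#'   deleterious when no categorical call is present (default 0.05, the
#'   tool's conventional cut-off).
#' @param polyphen_damaging_min PolyPhen-2 scores at or above this count as
#'   damaging when no categorical call is present (default 0.446, the tool's
#'   "possibly damaging" lower bound).
#' @param pathogenicity_rule `"EITHER"` (default; SIFT deleterious OR
#'   PolyPhen-2 damaging) or `"BOTH"`.
#' @param presence_rule `"ANY_SUBJECT"` (default) or `"ALL_SUBJECTS"` (every
#'   subject must be a non-missing carrier).
#' @param require_cohort_homozygote Require at least one HOM_ALT/HEMI_ALT
#'   subject at the presence step (default `TRUE`).
#' @param min_sharing_subjects Minimum subjects sharing a variant in the
#'   sharing branch (default 2).
#' @param sharing_zygosity Default sharing mode: `"ANY_CARRIER"` counts
#'   HET/HOM_ALT/HEMI_ALT, `"HOM_ALT_ONLY"` counts HOM_ALT/HEMI_ALT.
#' @param missing_maf_policy Variants without a MAF annotation are
#'   `"TREAT_AS_RARE"` (default; novel variants absent from reference panels
#'   are the cascade's explicit interest) or `"EXCLUDE"`d.
#' @param known_tma_genes Genes with a known role in TMA metabolism, excluded
#'   from the sharing branch (default FMO3, PYROXD2, DMGDH).
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(maf_threshold = 0.05,
                           sift_deleterious_max = 0.05,
                           polyphen_damaging_min = 0.446,
                           pathogenicity_rule = c("EITHER", "BOTH"),
                           presence_rule = c("ANY_SUBJECT", "ALL_SUBJECTS"),
                           require_cohort_homozygote = TRUE,
                           min_sharing_subjects = 2L,
                           sharing_zygosity = c("ANY_CARRIER", "HOM_ALT_ONLY"),
                           missing_maf_policy = c("TREAT_AS_RARE", "EXCLUDE"),
                           known_tma_genes = c("FMO3", "PYROXD2", "DMGDH")) {
  stopifnot(
    maf_threshold > 0, maf_threshold < 1,
    sift_deleterious_max > 0, sift_deleterious_max < 1,
    polyphen_damaging_min > 0, polyphen_damaging_min < 1,
    min_sharing_subjects >= 2
  )
  structure(list(
    maf_threshold = maf_threshold,
    sift_deleterious_max = sift_deleterious_max,
    polyphen_damaging_min = polyphen_damaging_min,
    pathogenicity_rule = match.arg(pathogenicity_rule),
    presence_rule = match.arg(presence_rule),
    require_cohort_homozygote = isTRUE(require_cohort_homozygote),
    min_sharing_subjects = as.integer(min_sharing_subjects),
    sharing_zygosity = match.arg(sharing_zygosity),
    missing_maf_policy = match.arg(missing_maf_policy),
    known_tma_genes = toupper(known_tma_genes)
  ), class = "cascade_config")
}

.check_keys_in_matrix <- function(matrix, keys) {
  bad <- setdiff(keys, matrix$variants$key)
  if (length(bad))
    stop("variant key(s) not in matrix: ", paste(bad, collapse = ", "))
}

#' Cohort presence filter
#'
#' Under the default `ANY_SUBJECT` rule with `require_cohort_homozygote`,
#' keeps variants for which at least one subject is homozygous (or
#' hemizygous) for the alternate allele; without the homozygote requirement,
#' any carrier suffices. Under `ALL_SUBJECTS`, every subject must additionally
#' be a non-missing carrier.
#'
#' @param matrix A [genotype_matrix()].
#' @param config A [cascade_config()].
#' @return Character vector of surviving variant keys (in matrix order).
#' @export
cohort_presence_filter <- function(matrix, config = cascade_config()) {
  g <- matrix$geno
  if (!ncol(g)) return(character(0))
  hom_any <- vapply(seq_len(ncol(g)),
                    function(j) any(g[, j] %in% .homalt_states), logical(1))
  carrier_any <- vapply(seq_len(ncol(g)),
                        function(j) any(g[, j] %in% .carrier_states), logical(1))
  keep <- if (config$require_cohort_homozygote) hom_any else carrier_any
  if (config$presence_rule == "ALL_SUBJECTS") {
    all_carrier <- vapply(seq_len(ncol(g)),
                          function(j) all(g[, j] %in% .carrier_states), logical(1))
    keep <- keep & all_carrier
  }
  matrix$variants$key[keep]
}

#' Pathogenicity filter (SIFT / PolyPhen-2)
#'
#' A variant is SIFT-deleterious when its categorical call is DELETERIOUS,
#' or, lacking a call, when its score is below `sift_deleterious_max`;
#' PolyPhen-2 damaging when its call is DAMAGING or its score is at least
#' `polyphen_damaging_min`. Categorical calls take precedence over scores.
#' A predictor with neither call nor score does not vote. Under the default
#' `EITHER` rule one positive predictor keeps the variant.
#'
#' @param keys Variant keys to filter.
#' @param annotations A `variant_annotation` table; every key must have a row.
#' @param config A [cascade_config()].
#' @return Surviving keys.
#' @export
pathogenicity_filter <- function(keys, annotations, config = cascade_config()) {
  if (!length(keys)) return(character(0))
  idx <- match(keys, annotations$key)
  if (anyNA(idx))
    stop("no annotation for variant(s): ",
         paste(keys[is.na(idx)], collapse = ", "))
  a <- annotations[idx, , drop = FALSE]
  sift_del <- ifelse(!is.na(a$sift_call), a$sift_call == "DELETERIOUS",
                     !is.na(a$sift_score) & a$sift_score < config$sift_deleterious_max)
  pp_dam <- ifelse(!is.na(a$polyphen_call), a$polyphen_call == "DAMAGING",
                   !is.na(a$polyphen_score) & a$polyphen_score >= config$polyphen_damaging_min)
  keep <- if (config$pathogenicity_rule == "EITHER") sift_del | pp_dam
          else sift_del & pp_dam
  keys[keep]
}

#' Gene-set membership filter
#'
#' `INCLUDE` keeps variants whose annotated gene is in the set; `EXCLUDE`
#' keeps those whose gene is not. Matching is case-insensitive. A variant
#' without a gene annotation cannot prove membership, so it is dropped under
#' `INCLUDE` and kept under `EXCLUDE`.
#'
#' @param keys Variant keys to filter.
#' @param annotations A `variant_annotation` table.
#' @param gene_set Character vector of gene symbols.
#' @param mode `"INCLUDE"` or `"EXCLUDE"`.
#' @return Surviving keys.
#' @export
gene_set_filter <- function(keys, annotations, gene_set,
                            mode = c("INCLUDE", "EXCLUDE")) {
  mode <- match.arg(mode)
  if (!length(keys)) return(character(0))
  gs <- toupper(gene_set)
  if (mode == "INCLUDE" && !length(gs)) {
    warning("empty gene set with INCLUDE mode: result is empty")
    return(character(0))
  }
  gene <- toupper(annotations$gene[match(keys, annotations$key)])
  inset <- !is.na(gene) & gene %in% gs
  keys[if (mode == "INCLUDE") inset else !inset]
}

#' Rarity filter (minor allele frequency)
#'
#' Keeps variants with annotated MAF strictly below `maf_threshold`.
#' Variants without a MAF (not observed in the reference panel) follow
#' `missing_maf_policy`.
#'
#' @inheritParams pathogenicity_filter
#' @return Surviving keys.
#' @export
rarity_filter <- function(keys, annotations, config = cascade_config()) {
  if (!length(keys)) return(character(0))
  maf <- annotations$maf[match(keys, annotations$key)]
  rare <- maf < config$maf_threshold
  rare[is.na(rare)] <- config$missing_maf_policy == "TREAT_AS_RARE"
  keys[rare]
}

#' Shared-variant filter
#'
#' Keeps variants carried by at least `min_sharing_subjects` subjects and
#' reports who shares them. `ANY_CARRIER` counts HET/HOM_ALT/HEMI_ALT;
#' `HOM_ALT_ONLY` counts HOM_ALT/HEMI_ALT (a hemizygous male satisfies a
#' homozygosity requirement: a one-allele genotype cannot be het).
#'
#' @param matrix A [genotype_matrix()].
#' @param keys Variant keys (must be columns of `matrix`).
#' @param config A [cascade_config()].
#' @param zygosity Sharing mode; defaults to `config$sharing_zygosity`.
#' @return Named list mapping each surviving key to the sorted ids of its
#'   sharing subjects.
#' @export
shared_variant_filter <- function(matrix, keys, config = cascade_config(),
                                  zygosity = config$sharing_zygosity) {
  zygosity <- match.arg(zygosity, c("ANY_CARRIER", "HOM_ALT_ONLY"))
  if (!length(keys)) return(stats::setNames(list(), character(0)))
  .check_keys_in_matrix(matrix, keys)
  states <- if (zygosity == "HOM_ALT_ONLY") .homalt_states else .carrier_states
  res <- lapply(keys, function(k) {
    sort(matrix$subjects$id[matrix$geno[, k] %in% states])
  })
  names(res) <- keys
  res[vapply(res, length, integer(1)) >= config$min_sharing_subjects]
}

#' Run the full variant-prioritization cascade
#'
#' Executes the MAIN trunk (cohort presence, then pathogenicity) and the two
#' discovery branches: OXIDOREDUCTASE (gene-set inclusion, then rarity) and
#' SHARED (exclusion of known TMA-metabolism genes, sharing by any carrier,
#' sharing restricted to homozygotes, then rarity). SNPs and indels are
#' tallied separately at every step; within a branch the survivor sets are
#' nested.
#'
#' @param matrix A [genotype_matrix()].
#' @param annotations A `variant_annotation` table covering the matrix
#'   variants that survive the presence step.
#' @param oxidoreductase_genes Character vector: the oxidoreductase /
#'   FMO3-pathway gene set.
#' @param config A [cascade_config()].
#' @return A `cascade_report`: list with `steps` (data frame `branch`,
#'   `label`, `snp_count`, `indel_count`), `survivors` (list of key vectors,
#'   one per step), `sharing` (terminal SHARED keys mapped to their sharing
#'   subjects) and `config`.
#' @export
run_cascade <- function(matrix, annotations, oxidoreductase_genes,
                        config = cascade_config()) {
  s_presence <- cohort_presence_filter(matrix, config)
  s_path <- pathogenicity_filter(s_presence, annotations, config)
  o_gene <- gene_set_filter(s_path, annotations, oxidoreductase_genes, "INCLUDE")
  o_rare <- rarity_filter(o_gene, annotations, config)
  h_excl <- gene_set_filter(s_path, annotations, config$known_tma_genes, "EXCLUDE")
  h_any <- shared_variant_filter(matrix, h_excl, config, zygosity = "ANY_CARRIER")
  h_hom <- shared_variant_filter(matrix, .names0(h_any), config,
                                 zygosity = "HOM_ALT_ONLY")
  h_rare <- rarity_filter(.names0(h_hom), annotations, config)

  survivors <- list(s_presence, s_path, o_gene, o_rare,
                    h_excl, .names0(h_any), .names0(h_hom), h_rare)
  steps <- data.frame(
    branch = c("MAIN", "MAIN", "OXIDOREDUCTASE", "OXIDOREDUCTASE",
               "SHARED", "SHARED", "SHARED", "SHARED"),
    label = c(
      if (config$require_cohort_homozygote) "cohort_homozygote_presence"
      else "cohort_carrier_presence",
      "pathogenic_sift_or_polyphen",
      "oxidoreductase_gene_set",
      sprintf("maf_lt_%g", config$maf_threshold),
      "exclude_known_tma_genes",
      sprintf("shared_any_carrier_ge_%d", config$min_sharing_subjects),
      sprintf("shared_homozygous_ge_%d", config$min_sharing_subjects),
      sprintf("maf_lt_%g", config$maf_threshold)
    ),
    snp_count = vapply(survivors, function(k) sum(classify_variant(k) == "SNP"),
                       integer(1)),
    indel_count = vapply(survivors,
                         function(k) sum(classify_variant(k) == "INDEL"),
                         integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(steps = steps, survivors = survivors,
                 sharing = h_hom[h_rare], config = config),
            class = "cascade_report")
}

#' Terminal survivor set of a cascade branch
#'
#' @param report A `cascade_report` from [run_cascade()].
#' @param branch `"OXIDOREDUCTASE"`, `"SHARED"` or `"MAIN"`.
#' @return Character vector of the branch's terminal variant keys.
#' @export
cascade_terminal <- function(report,
                             branch = c("OXIDOREDUCTASE", "SHARED", "MAIN")) {
  branch <- match.arg(branch)
  i <- max(which(report$steps$branch == branch))
  report$survivors[[i]]
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}
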
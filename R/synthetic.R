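# Synthetic cohorts with known truth: random background genotypes drawn from
# uniform MAFs under Hardy-Weinberg, plus planted variants that either satisfy
# a discovery branch's full criteria set or violate exactly one criterion
# (leave-one-out decoys), so filter-order bugs surface as exact mismatches.

#' Specify a planted variant
#'
#' A plant is written into the synthetic cohort exactly as specified: its
#' carriers and zygosities, gene, MAF, predictor calls and variant class. A
#' true plant (`fail_criterion = NULL`) satisfies every criterion of its
#' target branch; a decoy names the single criterion it violates (the caller
#' supplies field values consistent with that label - see
#' [default_plant_set()]).
#'
#' @param gene Gene symbol.
#' @param carriers Named character vector mapping subject ids to zygosities
#'   (`HET`, `HOM_ALT`, `HEMI_ALT`); may be empty.
#' @param target_branch `"OXIDOREDUCTASE"`, `"SHARED"`, `"INTERACTOME"`,
#'   `"CATALOG"` or `"NONE"`.
#' @param fail_criterion `NULL` for a true plant, or the name of the one
#'   violated criterion.
#' @param maf Annotated minor allele frequency (`NA` for novel).
#' @param variant_class `"SNP"` or `"INDEL"`.
#' @param sift_call,sift_score,polyphen_call,polyphen_score Predictor
#'   annotations.
#' @param chrom,pos,ref,alt Optional explicit coordinates; assigned
#'   deterministically by [generate_cohort()] when `NULL`.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(gene, carriers,
                       target_branch = c("OXIDOREDUCTASE", "SHARED",
                                         "INTERACTOME", "CATALOG", "NONE"),
                       fail_criterion = NULL, maf = 0.01,
                       variant_class = c("SNP", "INDEL"),
                       sift_call = "DELETERIOUS", sift_score = 0.01,
                       polyphen_call = "DAMAGING", polyphen_score = 0.95,
                       chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  target_branch <- match.arg(target_branch)
  variant_class <- match.arg(variant_class)
  carriers <- unlist(carriers)
  if (length(carriers)) {
    if (is.null(names(carriers)) || any(!nzchar(names(carriers))))
      stop("carriers must be a named id -> zygosity vector")
    if (!all(carriers %in% .carrier_states))
      stop("carrier zygosities must be HET, HOM_ALT or HEMI_ALT")
  }
  structure(list(gene = gene, carriers = carriers,
                 target_branch = target_branch,
                 fail_criterion = fail_criterion, maf = maf,
                 variant_class = variant_class,
                 sift_call = sift_call, sift_score = sift_score,
                 polyphen_call = polyphen_call,
                 polyphen_score = polyphen_score,
                 chrom = chrom, pos = pos, ref = ref, alt = alt),
            class = "plant_spec")
}

#' Default plant set: true plants plus leave-one-out decoys per branch
#'
#' For each discovery branch, builds `n_plants` variants satisfying the full
#' criteria set and `n_decoys` decoys each violating exactly one criterion,
#' cycling over the branch's criteria: OXIDOREDUCTASE - presence,
#' pathogenicity, gene_set, rarity; SHARED - pathogenicity, exclusion,
#' sharing, hom_sharing, rarity (a presence failure cannot be isolated there,
#' since two homozygous sharers imply a cohort homozygote); INTERACTOME -
#' gene_set, carrier, pathogenicity, rarity. Carriers cycle over the subject
#' ids.
#'
#' @param subject_ids Character vector of cohort subject ids.
#' @param n_plants True plants per branch (default 3).
#' @param n_decoys Decoys per branch (default 5).
#' @return List of [plant_spec()] objects.
#' @export
default_plant_set <- function(subject_ids, n_plants = 3L, n_decoys = 5L) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  stopifnot(n >= 3L)
  pick <- function(i, k = 1L)
    subject_ids[((i - 1L) + seq_len(k) - 1L) %% n + 1L]
  benign <- list(sift_call = "TOLERATED", sift_score = 0.62,
                 polyphen_call = "BENIGN", polyphen_score = 0.05)
  plants <- list()
  push <- function(p) plants[[length(plants) + 1L]] <<- p

  for (i in seq_len(n_plants))
    push(plant_spec(sprintf("OXGENE%02d", i),
                    stats::setNames("HOM_ALT", pick(i)), "OXIDOREDUCTASE"))
  oxcrit <- c("presence", "pathogenicity", "gene_set", "rarity")
  for (i in seq_len(n_decoys)) {
    crit <- oxcrit[(i - 1L) %% length(oxcrit) + 1L]
    push(switch(crit,
      presence = plant_spec(sprintf("OXDEC%02d", i),
                            stats::setNames("HET", pick(i)),
                            "OXIDOREDUCTASE", "presence"),
      pathogenicity = do.call(plant_spec, c(list(
        sprintf("OXDEC%02d", i), stats::setNames("HOM_ALT", pick(i)),
        "OXIDOREDUCTASE", "pathogenicity"), benign)),
      gene_set = plant_spec(sprintf("NEUTOX%02d", i),
                            stats::setNames("HOM_ALT", pick(i)),
                            "OXIDOREDUCTASE", "gene_set"),
      rarity = plant_spec(sprintf("OXDEC%02d", i),
                          stats::setNames("HOM_ALT", pick(i)),
                          "OXIDOREDUCTASE", "rarity", maf = 0.30)))
  }

  for (i in seq_len(n_plants))
    push(plant_spec(sprintf("SHGENE%02d", i),
                    stats::setNames(c("HOM_ALT", "HOM_ALT"), pick(i, 2L)),
                    "SHARED"))
  shcrit <- c("pathogenicity", "exclusion", "sharing", "hom_sharing", "rarity")
  for (i in seq_len(n_decoys)) {
    crit <- shcrit[(i - 1L) %% length(shcrit) + 1L]
    push(switch(crit,
      pathogenicity = do.call(plant_spec, c(list(
        sprintf("SHDEC%02d", i),
        stats::setNames(c("HOM_ALT", "HOM_ALT"), pick(i, 2L)),
        "SHARED", "pathogenicity"), benign)),
      exclusion = plant_spec("FMO3",
                             stats::setNames(c("HOM_ALT", "HOM_ALT"), pick(i, 2L)),
                             "SHARED", "exclusion"),
      sharing = plant_spec(sprintf("SHDEC%02d", i),
                           stats::setNames("HOM_ALT", pick(i)),
                           "SHARED", "sharing"),
      hom_sharing = plant_spec(sprintf("SHDEC%02d", i),
                               stats::setNames(c("HOM_ALT", "HET"), pick(i, 2L)),
                               "SHARED", "hom_sharing"),
      rarity = plant_spec(sprintf("SHDEC%02d", i),
                          stats::setNames(c("HOM_ALT", "HOM_ALT"), pick(i, 2L)),
                          "SHARED", "rarity", maf = 0.30)))
  }

  for (i in seq_len(n_plants))
    push(plant_spec(sprintf("INTGENE%02d", i),
                    stats::setNames("HET", pick(i)), "INTERACTOME"))
  incrit <- c("gene_set", "carrier", "pathogenicity", "rarity")
  for (i in seq_len(n_decoys)) {
    crit <- incrit[(i - 1L) %% length(incrit) + 1L]
    push(switch(crit,
      gene_set = plant_spec(sprintf("NEUTIN%02d", i),
                            stats::setNames("HET", pick(i)),
                            "INTERACTOME", "gene_set"),
      carrier = plant_spec(sprintf("INTDEC%02d", i), character(0),
                           "INTERACTOME", "carrier"),
      pathogenicity = do.call(plant_spec, c(list(
        sprintf("INTDEC%02d", i), stats::setNames("HET", pick(i)),
        "INTERACTOME", "pathogenicity"), benign)),
      rarity = plant_spec(sprintf("INTDEC%02d", i),
                          stats::setNames("HET", pick(i)),
                          "INTERACTOME", "rarity", maf = 0.30)))
  }
  plants
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Cohort size (default 10, the study design).
#' @param n_background_variants Autosomal background variants with uniform
#'   MAFs and Hardy-Weinberg genotypes (default 200).
#' @param missing_rate Fraction of background cells blanked to `MISSING`
#'   (default 0.19, the middle of the observed 15-23 percent SNP missingness
#'   band).
#' @param planted List of [plant_spec()] objects.
#' @param seed Integer RNG seed; the bundle is a deterministic function of
#'   the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 10L, n_background_variants = 200L,
                        missing_rate = 0.19, planted = list(), seed = 1L) {
  stopifnot(n_subjects >= 2L, n_background_variants >= 0L,
            missing_rate >= 0, missing_rate <= 1)
  if (length(planted) && !all(vapply(planted, inherits, logical(1), "plant_spec")))
    stop("planted must be a list of plant_spec objects")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_background_variants = as.integer(n_background_variants),
                 missing_rate = missing_rate, planted = planted,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort bundle
#'
#' Draws background variants with MAF uniform on (0, 0.5) and genotypes
#' binomial(2, MAF) per subject, blanks exactly
#' `round(missing_rate * n_subjects * n_background_variants)` background
#' cells to `MISSING`, and writes the planted variants verbatim. Background
#' variants are annotated non-deleterious, so the planted truth labels are
#' the exact expected output of every branch. The oxidoreductase gene set is
#' derived from the OXIDOREDUCTASE-branch specs (excluding `gene_set`
#' decoys), and the interaction network links the seed gene DMGDH to the
#' INTERACTOME-branch genes (excluding `gene_set` decoys) at score 0.9, plus
#' one sub-threshold edge.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, the standard files
#'   (`cohort.vcf`, `annotations.tsv`, `oxidoreductase_genes.txt`,
#'   `known_tma_genes.txt`, `network.tsv`, `truth.tsv`, `subjects.tsv`) are
#'   written there, byte-identically for identical specs.
#' @return List with `matrix` ([genotype_matrix()]), `annotations`,
#'   `truth` (data frame: key, gene, variant_class, target_branch,
#'   fail_criterion, is_plant), `oxidoreductase_genes`, `interactome_genes`,
#'   `network`, `seeds`, `subject_sexes`, `n_missing_injected` and (when
#'   `dir` is given) `paths`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  sex <- rep("F", n)
  if (n >= 4L) sex[c(n - 1L, n)] <- "M"
  for (p in spec$planted) {
    bad <- setdiff(names(p$carriers), ids)
    if (length(bad))
      stop("plant references unknown subject(s): ", paste(bad, collapse = ", "))
  }

  nb <- spec$n_background_variants
  res <- withr::with_seed(spec$seed, {
    alleles <- c("A", "C", "G", "T")
    bchrom <- as.character(sample(1:22, nb, replace = TRUE))
    bpos <- sort(sample.int(198000000L, nb)) + 2000000L
    bref <- sample(alleles, nb, replace = TRUE)
    balt <- vapply(bref, function(r) sample(setdiff(alleles, r), 1L),
                   character(1), USE.NAMES = FALSE)
    bmaf <- stats::runif(nb, 0, 0.5)
    dose <- matrix(stats::rbinom(n * nb, 2L, rep(bmaf, each = n)), nrow = n)
    bg <- matrix(c("HOM_REF", "HET", "HOM_ALT")[dose + 1L], nrow = n)
    n_missing <- round(spec$missing_rate * n * nb)
    if (n_missing > 0L)
      bg[sample.int(n * nb, n_missing)] <- "MISSING"
    list(bchrom = bchrom, bpos = bpos, bref = bref, balt = balt,
         bmaf = bmaf, bg = bg, n_missing = n_missing)
  })

  np <- length(spec$planted)
  pcols <- matrix("HOM_REF", nrow = n, ncol = np)
  pchrom <- character(np); ppos <- integer(np)
  pref <- character(np); palt <- character(np)
  for (i in seq_len(np)) {
    p <- spec$planted[[i]]
    pchrom[i] <- if (is.null(p$chrom)) as.character((i - 1L) %% 22L + 1L)
                 else .norm_chrom(p$chrom)
    ppos[i] <- if (is.null(p$pos)) 100000L + 97L * i else as.integer(p$pos)
    pref[i] <- if (is.null(p$ref)) "G" else p$ref
    palt[i] <- if (is.null(p$alt)) {
      if (p$variant_class == "INDEL") "GA" else "A"
    } else p$alt
    pcols[match(names(p$carriers), ids), i] <- p$carriers
  }

  geno <- cbind(res$bg, pcols)
  variants <- data.frame(
    chrom = c(res$bchrom, pchrom), pos = c(res$bpos, ppos),
    ref = c(res$bref, pref), alt = c(res$balt, palt),
    stringsAsFactors = FALSE)
  matrix <- genotype_matrix(
    geno,
    subjects = data.frame(id = ids, sex = sex, stringsAsFactors = FALSE),
    variants = variants)

  field <- function(name, default) vapply(spec$planted, function(p) {
    v <- p[[name]]
    if (is.null(v) || length(v) != 1L || is.na(v)) default else v
  }, default)
  ann <- as_variant_annotation(data.frame(
    chrom = c(res$bchrom, pchrom), pos = c(res$bpos, ppos),
    ref = c(res$bref, pref), alt = c(res$balt, palt),
    gene = c(sprintf("BG%04d", seq_len(nb)), field("gene", NA_character_)),
    rsid = NA_character_,
    sift_score = c(rep(0.62, nb), field("sift_score", NA_real_)),
    sift_call = c(rep("TOLERATED", nb), field("sift_call", NA_character_)),
    polyphen_score = c(rep(0.05, nb), field("polyphen_score", NA_real_)),
    polyphen_call = c(rep("BENIGN", nb), field("polyphen_call", NA_character_)),
    maf = c(res$bmaf, field("maf", NA_real_)),
    stringsAsFactors = FALSE))

  pkeys <- matrix$variants$key[nb + seq_len(np)]
  truth <- data.frame(
    key = pkeys,
    gene = field("gene", NA_character_),
    variant_class = field("variant_class", NA_character_),
    target_branch = field("target_branch", NA_character_),
    fail_criterion = vapply(spec$planted, function(p)
      if (is.null(p$fail_criterion)) NA_character_ else p$fail_criterion,
      character(1)),
    stringsAsFactors = FALSE)
  truth$is_plant <- is.na(truth$fail_criterion)

  branch_genes <- function(branch) {
    sel <- truth$target_branch == branch &
      (truth$is_plant | truth$fail_criterion != "gene_set")
    unique(truth$gene[sel])
  }
  oxi_genes <- branch_genes("OXIDOREDUCTASE")
  int_genes <- branch_genes("INTERACTOME")
  network <- data.frame(
    gene_a = "DMGDH",
    gene_b = c(int_genes, "SUBTHRESH1"),
    score = c(rep(0.9, length(int_genes)), 0.2),
    stringsAsFactors = FALSE)
  class(network) <- c("interaction_network", "data.frame")

  out <- list(matrix = matrix, annotations = ann, truth = truth,
              oxidoreductase_genes = oxi_genes, interactome_genes = int_genes,
              network = network, seeds = "DMGDH",
              subject_sexes = stats::setNames(sex, ids),
              n_missing_injected = res$n_missing, spec = spec)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      vcf = file.path(dir, "cohort.vcf"),
      annotations = file.path(dir, "annotations.tsv"),
      oxidoreductase_genes = file.path(dir, "oxidoreductase_genes.txt"),
      known_tma_genes = file.path(dir, "known_tma_genes.txt"),
      network = file.path(dir, "network.tsv"),
      truth = file.path(dir, "truth.tsv"),
      subjects = file.path(dir, "subjects.tsv"))
    write_matrix_vcf(matrix, paths[["vcf"]])
    ann_out <- ann[, c("chrom", "pos", "ref", "alt", "gene", "rsid",
                       "sift_score", "sift_call", "polyphen_score",
                       "polyphen_call", "maf")]
    utils::write.table(ann_out, paths[["annotations"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
    write_gene_set(oxi_genes, paths[["oxidoreductase_genes"]])
    write_gene_set(c("FMO3", "PYROXD2", "DMGDH"), paths[["known_tma_genes"]])
    net_out <- data.frame(gene_a = network$gene_a, gene_b = network$gene_b,
                          combined_score = network$score)
    utils::write.table(net_out, paths[["network"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    utils::write.table(matrix$subjects, paths[["subjects"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Generate orthogonal genotype calls from a matrix
#'
#' Samples non-missing matrix cells without replacement and flips the
#' zygosity of exactly `n_mismatches` of them, so the expected concordance is
#' `100 * (n_calls - n_mismatches) / n_calls` exactly.
#'
#' @param matrix A [genotype_matrix()].
#' @param n_calls Number of cells to sample.
#' @param n_mismatches Number of sampled calls to corrupt.
#' @param seed Integer RNG seed.
#' @param platform Platform label for the calls.
#' @param path Optional TSV output path (coded genotype column).
#' @return An `orthogonal_calls` data frame.
#' @export
generate_orthogonal_calls <- function(matrix, n_calls, n_mismatches = 0L,
                                      seed = 1L, platform = "synthetic",
                                      path = NULL) {
  cells <- which(matrix$geno != "MISSING", arr.ind = TRUE)
  if (n_calls > nrow(cells))
    stop("insufficient non-missing cells: ", nrow(cells), " available, ",
         n_calls, " requested")
  if (n_mismatches > n_calls)
    stop("n_mismatches must not exceed n_calls")
  flip <- c(HOM_REF = "HET", HET = "HOM_ALT", HOM_ALT = "HET",
            HEMI_REF = "HEMI_ALT", HEMI_ALT = "HEMI_REF")
  res <- withr::with_seed(seed, {
    pick <- cells[sample.int(nrow(cells), n_calls), , drop = FALSE]
    zy <- matrix$geno[pick]
    idx <- if (n_mismatches > 0L) sample.int(n_calls, n_mismatches)
           else integer(0)
    zy[idx] <- flip[zy[idx]]
    list(pick = pick, zy = zy)
  })
  v <- matrix$variants[res$pick[, 2L], , drop = FALSE]
  calls <- data.frame(
    subject_id = matrix$subjects$id[res$pick[, 1L]],
    rsid = NA_character_,
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    platform = platform, zygosity = unname(res$zy), key = v$key,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("orthogonal_calls", "data.frame")
  if (!is.null(path)) {
    code <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
              HEMI_REF = "0", HEMI_ALT = "1", MISSING = ".")
    tsv <- calls[, c("subject_id", "rsid", "chrom", "pos", "ref", "alt",
                     "platform")]
    tsv$genotype <- code[calls$zygosity]
    utils::write.table(tsv, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  calls
}
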
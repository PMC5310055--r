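# Shared test helpers: compact matrix/annotation builders, a random-case
# generator, and an independent brute-force cascade oracle (naive loops over
# the criteria truth table; shares no code with the package filters).

make_matrix <- function(zy, sex = NULL, chrom = NULL, pos = NULL) {
  zy <- as.matrix(zy)
  n <- nrow(zy)
  m <- ncol(zy)
  if (is.null(sex)) sex <- rep("F", n)
  if (is.null(chrom)) chrom <- as.character((seq_len(m) - 1L) %% 22L + 1L)
  if (is.null(pos)) pos <- 1000L + seq_len(m)
  genotype_matrix(
    zy,
    subjects = data.frame(id = sprintf("S%d", seq_len(n)), sex = sex),
    variants = data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A")
  )
}

make_ann <- function(gm, gene, sift_call = NA, sift_score = NA,
                     polyphen_call = NA, polyphen_score = NA, maf = NA) {
  v <- gm$variants
  as_variant_annotation(data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = gene, sift_call = sift_call, sift_score = sift_score,
    polyphen_call = polyphen_call, polyphen_score = polyphen_score,
    maf = maf, stringsAsFactors = FALSE
  ))
}

# Random genotype matrix + annotation pair for oracle-equivalence and
# permutation tests. Males get only HEMI_*/MISSING calls on X.
random_cascade_case <- function(seed, n_subj = 6L, n_var = 40L) {
  withr::with_seed(seed, {
    sex <- sample(c("M", "F"), n_subj, replace = TRUE)
    chrom <- sample(c(as.character(1:22), "X"), n_var, replace = TRUE)
    pos <- sample.int(1e7L, n_var)
    ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
    alt <- ifelse(runif(n_var) < 0.15, paste0(ref, "T"),
                  vapply(ref, function(r)
                    sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                    character(1)))
    zy <- matrix("HOM_REF", n_subj, n_var)
    for (j in seq_len(n_var)) {
      for (i in seq_len(n_subj)) {
        zy[i, j] <- if (sex[i] == "M" && chrom[j] == "X")
          sample(c("HEMI_REF", "HEMI_ALT", "MISSING"), 1L,
                 prob = c(0.5, 0.3, 0.2))
        else
          sample(c("HOM_REF", "HET", "HOM_ALT", "MISSING"), 1L,
                 prob = c(0.4, 0.25, 0.2, 0.15))
      }
    }
    gm <- genotype_matrix(
      zy,
      subjects = data.frame(id = sprintf("S%d", seq_len(n_subj)), sex = sex),
      variants = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt)
    )
    genes <- sample(c("OXA", "OXB", "NEU1", "NEU2", "FMO3", "PYROXD2", NA),
                    n_var, replace = TRUE)
    pick_or_na <- function(vals) {
      out <- sample(vals, n_var, replace = TRUE)
      out[runif(n_var) < 0.4] <- NA
      out
    }
    ann <- as_variant_annotation(data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = genes,
      sift_call = pick_or_na(c("TOLERATED", "DELETERIOUS")),
      sift_score = round(pick_or_na(runif(n_var)), 4),
      polyphen_call = pick_or_na(c("BENIGN", "DAMAGING")),
      polyphen_score = round(pick_or_na(runif(n_var)), 4),
      maf = round(pick_or_na(runif(n_var, 0, 0.5)), 5),
      stringsAsFactors = FALSE
    ))
    list(gm = gm, ann = ann, oxi = c("OXA", "OXB"))
  })
}

# Independent brute-force oracle: evaluates each criterion by direct set
# comprehension per variant and returns both branch terminal sets.
oracle_terminals <- function(gm, ann, oxi_genes, config) {
  hom_states <- c("HOM_ALT", "HEMI_ALT")
  car_states <- c("HET", "HOM_ALT", "HEMI_ALT")
  ox <- character(0)
  sh <- character(0)
  for (k in gm$variants$key) {
    col <- gm$geno[, k]
    i <- which(ann$key == k)
    if (!length(i)) next
    has_hom <- any(col %in% hom_states)
    n_car <- sum(col %in% car_states)
    n_hom <- sum(col %in% hom_states)
    sift <- if (!is.na(ann$sift_call[i])) ann$sift_call[i] == "DELETERIOUS"
            else if (!is.na(ann$sift_score[i]))
              ann$sift_score[i] < config$sift_deleterious_max
            else FALSE
    pp <- if (!is.na(ann$polyphen_call[i])) ann$polyphen_call[i] == "DAMAGING"
          else if (!is.na(ann$polyphen_score[i]))
            ann$polyphen_score[i] >= config$polyphen_damaging_min
          else FALSE
    patho <- if (config$pathogenicity_rule == "EITHER") sift || pp
             else sift && pp
    rare <- if (is.na(ann$maf[i])) config$missing_maf_policy == "TREAT_AS_RARE"
            else ann$maf[i] < config$maf_threshold
    gene <- toupper(ann$gene[i])
    in_oxi <- !is.na(gene) && gene %in% toupper(oxi_genes)
    in_known <- !is.na(gene) && gene %in% config$known_tma_genes
    if (has_hom && patho && in_oxi && rare) ox <- c(ox, k)
    if (has_hom && patho && !in_known &&
        n_car >= config$min_sharing_subjects &&
        n_hom >= config$min_sharing_subjects && rare) sh <- c(sh, k)
  }
  list(OXIDOREDUCTASE = ox, SHARED = sh)
}
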
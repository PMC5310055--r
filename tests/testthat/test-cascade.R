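test_that("cohort presence filter requires a homozygote by default", {
  zy <- cbind(
    v1 = c("HET", "HET", "HOM_ALT"),
    v2 = c("HET", "HET", "HET"),
    v3 = c("MISSING", "HOM_ALT", "HOM_REF"),
    v4 = c("HOM_REF", "HOM_REF", "HOM_REF")
  )
  gm <- make_matrix(zy)
  keys <- gm$variants$key
  expect_equal(cohort_presence_filter(gm), keys[c(1, 3)])
  # without the homozygote requirement any carrier suffices
  cfg <- cascade_config(require_cohort_homozygote = FALSE)
  expect_equal(cohort_presence_filter(gm, cfg), keys[1:3])
  # ALL_SUBJECTS additionally demands every subject be a non-missing carrier
  cfg_all <- cascade_config(presence_rule = "ALL_SUBJECTS")
  expect_equal(cohort_presence_filter(gm, cfg_all), keys[1])
})

test_that("pathogenicity is an OR of SIFT and PolyPhen with call precedence", {
  gm <- make_matrix(matrix("HOM_ALT", 1, 5))
  keys <- gm$variants$key
  ann <- make_ann(gm, gene = "G",
                  sift_call = c(NA, "TOLERATED", "TOLERATED", "DELETERIOUS", NA),
                  sift_score = c(0.01, NA, 0.5, 0.9, NA),
                  polyphen_call = c("BENIGN", NA, "BENIGN", NA, NA),
                  polyphen_score = c(NA, 0.9, 0.1, NA, NA))
  got <- pathogenicity_filter(keys, ann)
  # kept: sift score 0.01 (no call); polyphen 0.9; DELETERIOUS call overrides
  # its own (inconsistent) score
  expect_equal(got, keys[c(1, 2, 4)])
  # BOTH rule requires both predictors to vote deleterious
  both <- cascade_config(pathogenicity_rule = "BOTH")
  ann2 <- make_ann(gm, gene = "G",
                   sift_call = "DELETERIOUS", polyphen_call = c(
                     "DAMAGING", "BENIGN", "DAMAGING", "BENIGN", NA))
  expect_equal(pathogenicity_filter(keys, ann2, both), keys[c(1, 3)])
  expect_error(pathogenicity_filter("9:9:G:A", ann), "no annotation")
})

test_that("gene-set filter is case-insensitive and drops unprovable members", {
  gm <- make_matrix(matrix("HOM_ALT", 1, 3))
  keys <- gm$variants$key
  ann <- make_ann(gm, gene = c("Cp", "FMO3", NA))
  expect_equal(gene_set_filter(keys, ann, c("CP"), "INCLUDE"), keys[1])
  expect_equal(gene_set_filter(keys, ann, c("FMO3", "PYROXD2", "DMGDH"),
                               "EXCLUDE"), keys[c(1, 3)])
  # missing gene annotation cannot prove membership
  expect_equal(gene_set_filter(keys[3], ann, c("CP"), "INCLUDE"), character(0))
  expect_warning(out <- gene_set_filter(keys, ann, character(0), "INCLUDE"),
                 "empty gene set")
  expect_equal(out, character(0))
})

test_that("rarity filter applies MAF < 0.05 with a missing-MAF policy", {
  gm <- make_matrix(matrix("HOM_ALT", 1, 3))
  keys <- gm$variants$key
  ann <- make_ann(gm, gene = "G", maf = c(0.011, 0.383, NA))
  expect_equal(rarity_filter(keys, ann), keys[c(1, 3)])
  excl <- cascade_config(missing_maf_policy = "EXCLUDE")
  expect_equal(rarity_filter(keys, ann, excl), keys[1])
})

test_that("shared-variant filter counts carriers under the requested zygosity", {
  zy <- cbind(
    v1 = c("HOM_ALT", "HOM_ALT", "HOM_REF"),
    v2 = c("HOM_ALT", "HET", "HOM_REF"),
    v3 = c("HET", "HOM_REF", "HOM_REF")
  )
  gm <- make_matrix(zy)
  keys <- gm$variants$key
  cfg <- cascade_config()
  hom <- shared_variant_filter(gm, keys, cfg, zygosity = "HOM_ALT_ONLY")
  expect_equal(names(hom), keys[1])
  expect_equal(hom[[1]], c("S1", "S2"))
  any_c <- shared_variant_filter(gm, keys, cfg, zygosity = "ANY_CARRIER")
  expect_equal(names(any_c), keys[1:2])
  # hemizygous males count as homozygous sharers
  gmx <- make_matrix(cbind(vx = c("HEMI_ALT", "HEMI_ALT", "HOM_REF")),
                     sex = c("M", "M", "F"), chrom = "X")
  hx <- shared_variant_filter(gmx, gmx$variants$key, cfg,
                              zygosity = "HOM_ALT_ONLY")
  expect_equal(hx[[1]], c("S1", "S2"))
})

test_that("cascade matches the brute-force oracle on small random matrices", {
  cfgs <- list(
    cascade_config(),
    cascade_config(pathogenicity_rule = "BOTH"),
    cascade_config(missing_maf_policy = "EXCLUDE")
  )
  for (seed in 1:8) {
    case <- random_cascade_case(seed, n_subj = 6L, n_var = 40L)
    for (cfg in cfgs) {
      rep <- run_cascade(case$gm, case$ann, case$oxi, cfg)
      oracle <- oracle_terminals(case$gm, case$ann, case$oxi, cfg)
      expect_setequal(cascade_terminal(rep, "OXIDOREDUCTASE"),
                      oracle$OXIDOREDUCTASE)
      expect_setequal(cascade_terminal(rep, "SHARED"), oracle$SHARED)
    }
  }
})

test_that("survivor sets are nested along every branch", {
  for (seed in 1:5) {
    case <- random_cascade_case(seed)
    rep <- run_cascade(case$gm, case$ann, case$oxi)
    s <- rep$survivors
    b <- rep$steps$branch
    for (i in 2:length(s)) {
      parent <- if (b[i] == b[i - 1] || b[i - 1] == "MAIN") s[[i - 1]] else s[[2]]
      if (b[i] %in% c("OXIDOREDUCTASE", "SHARED") && b[i - 1] == "MAIN")
        parent <- s[[2]]
      expect_true(all(s[[i]] %in% parent))
    }
    # branch roots descend from the MAIN terminal set
    expect_true(all(s[[3]] %in% s[[2]]))
    expect_true(all(s[[5]] %in% s[[2]]))
  }
})

test_that("cascade counts are invariant to subject and variant order", {
  case <- random_cascade_case(3)
  gm <- case$gm
  base <- run_cascade(gm, case$ann, case$oxi)$steps
  withr::with_seed(9, {
    si <- sample(nrow(gm$subjects))
    vi <- sample(nrow(gm$variants))
  })
  perm <- genotype_matrix(gm$geno[si, vi, drop = FALSE],
                          gm$subjects[si, , drop = FALSE],
                          gm$variants[vi, c("chrom", "pos", "ref", "alt")])
  got <- run_cascade(perm, case$ann, case$oxi)$steps
  expect_equal(got$snp_count, base$snp_count)
  expect_equal(got$indel_count, base$indel_count)
})

test_that("an empty matrix yields an all-zero report", {
  gm <- genotype_matrix(matrix(character(0), 0, 0),
                        data.frame(id = character(0), sex = character(0)),
                        data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0)))
  ann <- as_variant_annotation(data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0)))
  rep <- run_cascade(gm, ann, c("CP"))
  expect_true(all(rep$steps$snp_count == 0L))
  expect_true(all(rep$steps$indel_count == 0L))
})
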
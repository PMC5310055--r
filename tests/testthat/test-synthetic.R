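test_that("generation is deterministic: same spec, byte-identical bundle", {
  spec <- cohort_spec(n_background_variants = 30L,
                      planted = default_plant_set(sprintf("S%02d", 1:10)),
                      seed = 17L)
  d1 <- tempfile("synth1")
  d2 <- tempfile("synth2")
  b1 <- generate_cohort(spec, d1)
  b2 <- generate_cohort(spec, d2)
  for (nm in names(b1$paths))
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]))
  expect_identical(b1$matrix$geno, b2$matrix$geno)
})

test_that("plants land exactly as specified and unknown carriers error", {
  p <- plant_spec("MYGENE", c(S03 = "HET", S05 = "HOM_ALT"), "SHARED")
  b <- generate_cohort(cohort_spec(n_background_variants = 5L,
                                   planted = list(p), seed = 2L))
  k <- b$truth$key[1]
  col <- b$matrix$geno[, k]
  expect_equal(unname(col[c("S03", "S05")]), c("HET", "HOM_ALT"))
  expect_true(all(col[setdiff(names(col), c("S03", "S05"))] == "HOM_REF"))
  expect_equal(b$annotations$gene[b$annotations$key == k], "MYGENE")

  bad <- plant_spec("G", c(NOSUCH = "HET"), "SHARED")
  expect_error(
    generate_cohort(cohort_spec(planted = list(bad))),
    "unknown subject")
})

test_that("cascade recovers planted truth exactly across seeds", {
  ids <- sprintf("S%02d", 1:10)
  plants <- default_plant_set(ids, n_plants = 3L, n_decoys = 5L)
  for (seed in c(1L, 9L, 23L, 101L, 400L)) {
    b <- generate_cohort(cohort_spec(n_background_variants = 40L,
                                     planted = plants, seed = seed))
    rep <- run_cascade(b$matrix, b$annotations, b$oxidoreductase_genes)
    truth <- b$truth
    expected <- function(branch)
      truth$key[truth$target_branch == branch & truth$is_plant]
    expect_setequal(cascade_terminal(rep, "OXIDOREDUCTASE"),
                    expected("OXIDOREDUCTASE"))
    expect_setequal(cascade_terminal(rep, "SHARED"), expected("SHARED"))
    interactome <- expand_seed_genes(b$network, b$seeds)
    scan <- interactome_variant_scan(b$matrix, b$annotations, interactome)
    expect_setequal(scan, expected("INTERACTOME"))
    # every leave-one-out decoy is rejected by its own branch
    for (i in which(!truth$is_plant)) {
      branch <- truth$target_branch[i]
      hit <- if (branch == "INTERACTOME") scan
             else cascade_terminal(rep, branch)
      expect_false(truth$key[i] %in% hit)
    }
  }
})

test_that("background genotype frequencies track their generating MAFs", {
  b <- generate_cohort(cohort_spec(n_subjects = 500L,
                                   n_background_variants = 30L,
                                   missing_rate = 0, seed = 31L))
  maf <- b$annotations$maf[seq_len(30L)]
  pvals <- vapply(seq_len(30L), function(j) {
    m <- maf[j]
    obs <- table(factor(b$matrix$geno[, j],
                        levels = c("HOM_REF", "HET", "HOM_ALT")))
    expect_hwe <- c((1 - m)^2, 2 * m * (1 - m), m^2)
    suppressWarnings(chisq.test(as.integer(obs), p = expect_hwe)$p.value)
  }, numeric(1))
  # Hardy-Weinberg holds by construction; allow the expected alpha-level
  # fraction of rejections
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("fixture genotypes reproduce the published zygosity marks", {
  fx <- paper_fixture()
  gm <- read_multisample_vcf(fx$paths[["vcf"]], fx$subject_sexes)
  zy <- function(key) gm$geno[, key]
  # five heterozygotes for the common FMO3 missense variant
  het5 <- zy("1:171076966:G:A")
  expect_setequal(names(het5)[het5 == "HET"], c("64", "98", "113", "114", "122"))
  # one nonsense-variant heterozygote
  expect_equal(sum(zy("1:171076936:G:T") == "HET"), 1L)
  expect_equal(unname(zy("1:171076936:G:T")["99"]), "HET")
  # oxidoreductase homozygotes
  expect_equal(unname(zy("3:148916215:C:T")["52"]), "HOM_ALT")
  expect_equal(unname(zy("10:102295637:A:AT")["114"]), "HOM_ALT")
  # X-linked variant hemizygous in both male sharers
  esx1 <- zy("X:103495552:C:T")
  expect_equal(unname(esx1[c("113", "114")]), c("HEMI_ALT", "HEMI_ALT"))
  expect_true(all(esx1[setdiff(names(esx1), c("113", "114"))] == "HOM_REF"))
  # shared insertion homozygous in its two carriers
  or6p1 <- zy("1:158533298:T:TA")
  expect_setequal(names(or6p1)[or6p1 == "HOM_ALT"], c("62", "122"))
})

test_that("orthogonal-call generation validates its sampling preconditions", {
  b <- generate_cohort(cohort_spec(n_subjects = 3L,
                                   n_background_variants = 4L,
                                   missing_rate = 0, seed = 8L))
  expect_error(generate_orthogonal_calls(b$matrix, 13L), "insufficient")
  expect_error(generate_orthogonal_calls(b$matrix, 5L, 6L),
               "must not exceed")
  path <- tempfile(fileext = ".tsv")
  calls <- generate_orthogonal_calls(b$matrix, 6L, 2L, seed = 1L, path = path)
  back <- read_orthogonal_calls(path, b$subject_sexes)
  expect_equal(nrow(back), 6L)
  expect_setequal(back$zygosity, calls$zygosity)
})
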
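write_vcf_text <- function(lines, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, lines), path)
  path
}

test_that("multiallelic records split into one column per alt allele", {
  samples <- sprintf("P%02d", 1:10)
  gts <- function(...) paste(c(...), collapse = "\t")
  path <- write_vcf_text(c(
    paste("1", 100, ".", "G", "A", ".", "PASS", ".", "GT",
          gts(rep("0/1", 10)), sep = "\t"),
    paste("2", 200, ".", "C", "A,T", ".", "PASS", ".", "GT",
          gts("1/2", "0/2", "2/2", "0/0", "1/1", rep("0/0", 5)), sep = "\t"),
    paste("3", 300, ".", "T", "TA", ".", "PASS", ".", "GT",
          gts(rep("0/0", 10)), sep = "\t")
  ), samples)
  sexes <- setNames(rep("F", 10), samples)
  gm <- read_multisample_vcf(path, sexes)
  expect_equal(nrow(gm$variants), 4L)
  expect_setequal(gm$variants$key[gm$variants$chrom == "2"],
                  c("2:200:C:A", "2:200:C:T"))

  # splitting conserves alt-allele dosage: per-sample dosages over the two
  # split columns sum to the allele counts of the original genotypes
  dose <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)
  d1 <- dose[gm$geno[, "2:200:C:A"]]
  d2 <- dose[gm$geno[, "2:200:C:T"]]
  expect_equal(unname(d1[1:5] + d2[1:5]), c(2L, 1L, 2L, 0L, 2L))
  expect_equal(unname(d1[1:5]), c(1L, 0L, 0L, 0L, 2L))
})

test_that("GT strings decode to the expected zygosity calls", {
  samples <- c("A", "B", "C", "D", "E")
  path <- write_vcf_text(
    paste("7", 50, ".", "G", "A", ".", "PASS", ".", "GT",
          paste(c("0/1", "1/1", "./.", "0|1", "0/0"), collapse = "\t"),
          sep = "\t"),
    samples)
  gm <- read_multisample_vcf(path, setNames(rep("F", 5), samples))
  expect_equal(unname(gm$geno[, 1]),
               c("HET", "HOM_ALT", "MISSING", "HET", "HOM_REF"))
})

test_that("male X genotypes become hemizygous calls", {
  samples <- c("113", "114", "52")
  path <- write_vcf_text(
    paste("X", 103495552, ".", "C", "T", ".", "PASS", ".", "GT",
          paste(c("1", "1/1", "0/0"), collapse = "\t"), sep = "\t"),
    samples)
  gm <- read_multisample_vcf(path, c("113" = "M", "114" = "M", "52" = "F"))
  expect_equal(unname(gm$geno[, 1]), c("HEMI_ALT", "HEMI_ALT", "HOM_REF"))
  # hemizygous satisfies the homozygous-alt requirement downstream
  expect_equal(cohort_presence_filter(gm), "X:103495552:C:T")
})

test_that("a VCF sample without a sex assignment is a configuration error", {
  samples <- c("A", "B")
  path <- write_vcf_text(
    paste("1", 10, ".", "G", "A", ".", "PASS", ".", "GT", "0/1\t0/0",
          sep = "\t"), samples)
  expect_error(read_multisample_vcf(path, c(A = "F")), "no sex provided.*B")
})

test_that("variant classification follows allele lengths", {
  expect_equal(classify_variant("A", "AT"), "INDEL")   # 1 bp insertion
  expect_equal(classify_variant("G", "T"), "SNP")
  expect_equal(classify_variant("AT", "A"), "INDEL")   # deletion
  expect_equal(classify_variant(c("10:102295637:A:AT", "1:171076936:G:T")),
               c("INDEL", "SNP"))
})

test_that("annotation tables validate keys, classes and MAF range", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tgene\trsid\tsift_score\tsift_call\tpolyphen_score\tpolyphen_call\tmaf",
    "1\t171076966\tG\tA\tFMO3\trs2266782\t0.34\tTOLERATED\t0.12\tBENIGN\t0.383",
    "2\t500\tC\tCA\tGENE2\t.\t.\t.\t.\t.\t."
  ), path)
  ann <- read_annotation_table(path)
  expect_s3_class(ann, "variant_annotation")
  expect_equal(ann$variant_class, c("SNP", "INDEL"))
  expect_equal(ann$gene[1], "FMO3")
  expect_equal(ann$maf[1], 0.383)
  expect_true(is.na(ann$maf[2]))

  dup <- rbind(ann[1, ], ann[1, ])
  expect_error(as_variant_annotation(dup), "duplicate")
  bad <- ann
  bad$maf[2] <- 0.7
  expect_error(as_variant_annotation(bad), "0, 0.5")
})

test_that("VCF round-trip reproduces a matrix cell-by-cell", {
  for (seed in 1:5) {
    case <- random_cascade_case(seed, n_subj = 5L, n_var = 20L)
    gm <- case$gm
    path <- tempfile(fileext = ".vcf")
    write_matrix_vcf(gm, path)
    back <- read_multisample_vcf(
      path, setNames(gm$subjects$sex, gm$subjects$id))
    expect_identical(back$geno, gm$geno)
    expect_identical(back$variants$key, gm$variants$key)
    expect_identical(back$subjects$id, gm$subjects$id)
  }
})

test_that("hemizygous calls are rejected outside male sex chromosomes", {
  zy <- matrix(c("HEMI_ALT", "HOM_REF"), nrow = 2, ncol = 1)
  expect_error(make_matrix(zy, sex = c("F", "F"), chrom = "X"), "HEMI")
  expect_error(make_matrix(zy, sex = c("M", "F"), chrom = "5"), "HEMI")
  expect_s3_class(make_matrix(zy, sex = c("M", "F"), chrom = "X"),
                  "genotype_matrix")
})

test_that("injected missingness is reproduced exactly", {
  spec <- cohort_spec(n_subjects = 10L, n_background_variants = 40L,
                      missing_rate = 0.19, seed = 11L)
  b <- generate_cohort(spec)
  expect_equal(sum(b$matrix$geno == "MISSING"), round(0.19 * 10 * 40))
  expect_equal(b$n_missing_injected, round(0.19 * 10 * 40))

  b0 <- generate_cohort(cohort_spec(n_background_variants = 40L,
                                    missing_rate = 0, seed = 11L))
  expect_false(any(b0$matrix$geno == "MISSING"))
})
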
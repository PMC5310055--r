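# Reference fixture: a ten-subject TMAU cohort transcribed from the study's
# printed tables -- choline-challenge ratios, the known FMO3/PYROXD2 variant
# catalog with per-subject zygosities, the novel oxidoreductase / interactome
# / shared variants with their MAFs and carriers -- plus leave-one-out decoy
# variants so each filter criterion is exercised, and orthogonal genotype
# calls drawn from the same genotypes. Urine concentrations are back-solved
# from the printed ratios (TMA = 100*(1-r), TMAO = 100*r), which is exact by
# scale-invariance of the oxidation ratio.

.fixture_subject_table <- function() {
  data.frame(
    id    = c("52", "114", "122", "35", "99", "64", "62", "113", "98", "56"),
    age   = c(78L, 18L, 64L, 45L, 59L, 51L, 51L, 47L, 44L, 70L),
    sex   = c("F", "M", "F", "F", "F", "F", "F", "M", "F", "F"),
    ratio = c(0.13, 0.37, 0.47, 0.54, 0.58, 0.61, 0.79, 0.79, 0.86, 0.87),
    stringsAsFactors = FALSE
  )
}

# chrom|pos|ref|alt|rsid|gene|maf|sift_score|sift_call|pp_score|pp_call|role|carriers
.fixture_variant_table <- function() {
  rows <- c(
    # known-catalog variants (common FMO3 missense plus one rare nonsense;
    # the nonsense variant carries no SIFT/PolyPhen annotation, as neither
    # tool scores protein-truncating alleles)
    "1|171076936|G|T|rs72549325|FMO3|8.236e-06|.|.|.|.|catalog|99=HET",
    "1|171076966|G|A|rs2266782|FMO3|0.383|0.34|TOLERATED|0.12|BENIGN|catalog|64=HET;98=HET;113=HET;114=HET;122=HET",
    "1|171080080|G|A|rs1736557|FMO3|0.080|0.41|TOLERATED|0.08|BENIGN|catalog|122=HET",
    "1|171083242|A|G|rs2266780|FMO3|0.153|0.28|TOLERATED|0.21|BENIGN|catalog|98=HET",
    # rare deleterious variants in oxidoreductase-pathway genes
    "3|148916215|C|T|rs61733458|CP|0.0110|0.01|DELETERIOUS|0.98|DAMAGING|oxidoreductase|52=HOM_ALT",
    "17|41002169|G|A|rs34625494|AOC2|0.0032|0.31|TOLERATED|0.97|DAMAGING|oxidoreductase|62=HOM_ALT",
    "18|9887167|T|C|rs7294759|TXNDC2|0.0179|0.02|DELETERIOUS|.|.|oxidoreductase|52=HOM_ALT",
    "19|41600254|C|T|rs116368403|CYP2A13|0.0046|0.01|.|0.10|BENIGN|oxidoreductase|122=HOM_ALT",
    "10|102295637|A|AT|.|HIF1AN|0.0200|.|.|0.92|DAMAGING|oxidoreductase|114=HOM_ALT",
    # rare deleterious SNPs in the DMGDH interactome (all carriers het)
    "5|78378644|C|T|rs58580238|BHMT2|0.000154|0.00|DELETERIOUS|0.99|DAMAGING|interactome|56=HET",
    "9|136584082|G|A|rs35664470|SARDH|0.00692|0.01|DELETERIOUS|0.95|DAMAGING|interactome|99=HET",
    "17|18243524|C|T|rs78909145|SHMT1|0.00701|0.02|DELETERIOUS|0.88|DAMAGING|interactome|98=HET",
    # rare deleterious variants homozygous in two subjects
    "3|196235191|G|A|rs73891273|SMCO1|0.0445|0.01|DELETERIOUS|0.91|DAMAGING|shared|62=HOM_ALT;99=HOM_ALT",
    "6|110679450|C|T|rs77469804|METTL24|0.0262|0.03|DELETERIOUS|0.85|DAMAGING|shared|114=HOM_ALT;122=HOM_ALT",
    "7|149462317|G|A|rs77749341|ZNF467|0.0142|0.02|DELETERIOUS|0.93|DAMAGING|shared|99=HOM_ALT;114=HOM_ALT",
    "10|1094906|A|G|rs7091756|IDI1|0.0207|0.04|DELETERIOUS|0.77|DAMAGING|shared|35=HOM_ALT;56=HOM_ALT",
    "12|93966693|C|T|rs7956250|SOCS2|0.0257|0.01|DELETERIOUS|0.89|DAMAGING|shared|99=HOM_ALT;122=HOM_ALT",
    "15|41803754|G|A|rs55739813|LTK|0.0367|0.02|DELETERIOUS|0.96|DAMAGING|shared|35=HOM_ALT;52=HOM_ALT",
    "19|17638121|C|T|rs138735905|FAM129C|0.0193|0.03|DELETERIOUS|0.82|DAMAGING|shared|64=HOM_ALT;98=HOM_ALT",
    "22|17265194|G|A|rs114989947|XKR3|0.0344|0.01|DELETERIOUS|0.90|DAMAGING|shared|99=HOM_ALT;113=HOM_ALT",
    "X|103495552|C|T|rs41305431|ESX1|0.0266|0.02|DELETERIOUS|0.94|DAMAGING|shared|113=HEMI_ALT;114=HEMI_ALT",
    "1|158533298|T|TA|.|OR6P1|0.0100|.|.|0.87|DAMAGING|shared|62=HOM_ALT;122=HOM_ALT",
    # leave-one-out decoys, each violating exactly one branch criterion
    "2|31557187|G|A|.|XDH|0.3000|0.01|DELETERIOUS|0.95|DAMAGING|decoy_oxi_rarity|35=HOM_ALT",
    "2|201450000|C|T|.|AOX1|0.0100|0.64|TOLERATED|0.05|BENIGN|decoy_oxi_pathogenicity|64=HOM_ALT",
    "4|88339000|G|A|.|NUDT9|0.0100|0.02|DELETERIOUS|0.90|DAMAGING|decoy_oxi_geneset|56=HOM_ALT",
    "17|46700000|C|T|.|TTLL6|0.0100|0.01|DELETERIOUS|0.92|DAMAGING|decoy_shared_homsharing|35=HOM_ALT;56=HET",
    "17|39500000|G|A|.|KRT33A|0.2500|0.02|DELETERIOUS|0.88|DAMAGING|decoy_shared_rarity|62=HOM_ALT;99=HOM_ALT",
    "1|248700000|C|T|.|OR2T1|0.0100|0.55|TOLERATED|0.10|BENIGN|decoy_shared_pathogenicity|52=HOM_ALT;114=HOM_ALT",
    "9|136585000|C|T|.|SARDH|0.0050|0.60|TOLERATED|0.12|BENIGN|decoy_interactome_pathogenicity|64=HET",
    "5|78379000|G|A|.|BHMT2|0.4000|0.01|DELETERIOUS|0.93|DAMAGING|decoy_interactome_rarity|35=HET",
    "12|121000000|G|A|.|CABP1|0.0100|0.01|DELETERIOUS|0.91|DAMAGING|decoy_presence_het_only|98=HET"
  )
  f <- do.call(rbind, strsplit(rows, "|", fixed = TRUE))
  v <- data.frame(
    chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 3], alt = f[, 4],
    rsid = f[, 5], gene = f[, 6], maf = f[, 7],
    sift_score = f[, 8], sift_call = f[, 9],
    polyphen_score = f[, 10], polyphen_call = f[, 11],
    role = f[, 12], carriers = f[, 13],
    stringsAsFactors = FALSE
  )
  for (col in c("rsid", "maf", "sift_score", "sift_call", "polyphen_score",
                "polyphen_call"))
    v[[col]][v[[col]] == "."] <- NA
  v$maf <- as.numeric(v$maf)
  v$sift_score <- as.numeric(v$sift_score)
  v$polyphen_score <- as.numeric(v$polyphen_score)
  v
}

.parse_carriers <- function(s) {
  if (!nzchar(s)) return(stats::setNames(character(0), character(0)))
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2L),
                  vapply(kv, `[`, character(1), 1L))
}

# extra-genotype records for the intronic PYROXD2 variant rs7072216,
# genotyped outside the exome capture (Taqman-style)
.fixture_extra_genotypes <- function(subjects) {
  gt <- stats::setNames(rep("0/0", nrow(subjects)), subjects$id)
  gt[c("52", "56")] <- "0/1"
  gt[c("35", "64", "113")] <- "1/1"
  data.frame(
    subject_id = subjects$id, rsid = "rs7072216", chrom = "10",
    pos = 100156853L, ref = "T", alt = "C", gene = "PYROXD2",
    genotype = unname(gt), stringsAsFactors = FALSE
  )
}

.fixture_catalog <- function() {
  data.frame(
    rsid = c("rs72549325", "rs2266782", "rs1736557", "rs2266780", "rs7072216"),
    chrom = c("1", "1", "1", "1", "10"),
    pos = c(171076936L, 171076966L, 171080080L, 171083242L, 100156853L),
    ref = c("G", "G", "G", "A", "T"),
    alt = c("T", "A", "A", "G", "C"),
    gene = c("FMO3", "FMO3", "FMO3", "FMO3", "PYROXD2"),
    maf = c(8.236e-06, 0.383, 0.080, 0.153, 0.4012),
    hgvs_c = c("c.442G>T", "c.472G>A", "c.769G>A", "c.923A>G", "c.625+249A>G"),
    hgvs_p = c("p.Gly148Ter", "p.Glu158Lys", "p.Val257Met", "p.Glu308Gly", "."),
    evidence = c("rare loss-of-function", "common decreased-function",
                 "common decreased-function", "common decreased-function",
                 "common, associated with urinary TMA"),
    stringsAsFactors = FALSE
  )
}

.fixture_network <- function() {
  data.frame(
    gene_a = c("DMGDH", "DMGDH", "DMGDH", "DMGDH", "DMGDH",
               "FMO3", "FMO3", "PYROXD2"),
    gene_b = c("BHMT", "SARDH", "BHMT2", "SHMT1", "XDH",
               "FMO1", "CYP1A2", "NDOR1"),
    combined_score = c(0.99, 0.95, 0.92, 0.90, 0.30, 0.95, 0.91, 0.62),
    stringsAsFactors = FALSE
  )
}

.fixture_oxidoreductase_genes <- function()
  c("CP", "AOC2", "TXNDC2", "CYP2A13", "HIF1AN",
    "XDH", "AOX1", "FMO1", "CYP1A2", "MAOA", "SUOX")

# urine collections: interval 2 carries the TMA peak at 100*(1-r) with TMAO
# measured as 100*r; intervals 1 and 3 have lower TMA and no TMAO
# measurement; interval 0 is the pre-challenge first-morning sample
.fixture_urine <- function(subjects) {
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    id <- subjects$id[i]
    r <- subjects$ratio[i]
    peak <- 100 * (1 - r)
    data.frame(
      subject_id = id, interval_index = 0:3,
      volume_ml = c(350, 420, 410, 380),
      tma_conc = c(5, 0.5 * peak, peak, 0.25 * peak),
      tmao_conc = c(NA, NA, 100 * r, NA),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.fixture_gt_codes <- c(HET = "0/1", HOM_ALT = "1/1", HEMI_ALT = "1")

.fixture_vcf_lines <- function(subjects, variants) {
  male <- subjects$sex == "M"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects$id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    gt <- ifelse(male & .is_sex_chrom(v$chrom), "0", "0/0")
    names(gt) <- subjects$id
    car <- .parse_carriers(v$carriers)
    gt[names(car)] <- .fixture_gt_codes[car]
    paste(c(v$chrom, v$pos, if (is.na(v$rsid)) "." else v$rsid, v$ref, v$alt,
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  c(hdr, body)
}

# orthogonal genotype calls mirroring the validation design: partial Sanger
# coverage of the FMO3 exons (29 genotypes) and Taqman typing of two FMO3
# variants plus the intronic PYROXD2 variant in all ten subjects (30
# genotypes); all calls are transcribed from the fixture genotypes, so the
# two platforms agree with the exome matrix everywhere
.fixture_orthogonal_calls <- function(subjects, variants, extra) {
  male <- stats::setNames(subjects$sex == "M", subjects$id)
  gt_of <- function(v, id) {
    car <- .parse_carriers(v$carriers)
    if (id %in% names(car)) .fixture_gt_codes[[car[[id]]]]
    else if (male[[id]] && .is_sex_chrom(v$chrom)) "0" else "0/0"
  }
  fmo3 <- variants[variants$gene == "FMO3", , drop = FALSE]
  fmo3 <- fmo3[order(fmo3$pos), , drop = FALSE]
  sanger <- do.call(rbind, lapply(seq_len(nrow(fmo3)), function(i) {
    v <- fmo3[i, ]
    data.frame(subject_id = subjects$id, rsid = v$rsid, chrom = v$chrom,
               pos = v$pos, ref = v$ref, alt = v$alt, platform = "sanger",
               genotype = vapply(subjects$id, gt_of, character(1), v = v),
               stringsAsFactors = FALSE)
  }))
  sanger <- utils::head(sanger, 29L)
  taq_vcf <- variants[variants$rsid %in% c("rs2266782", "rs2266780"), ,
                      drop = FALSE]
  taqman <- do.call(rbind, lapply(seq_len(nrow(taq_vcf)), function(i) {
    v <- taq_vcf[i, ]
    data.frame(subject_id = subjects$id, rsid = v$rsid, chrom = v$chrom,
               pos = v$pos, ref = v$ref, alt = v$alt, platform = "taqman",
               genotype = vapply(subjects$id, gt_of, character(1), v = v),
               stringsAsFactors = FALSE)
  }))
  taq_extra <- data.frame(
    subject_id = extra$subject_id, rsid = extra$rsid, chrom = extra$chrom,
    pos = extra$pos, ref = extra$ref, alt = extra$alt, platform = "taqman",
    genotype = extra$genotype, stringsAsFactors = FALSE)
  out <- rbind(sanger, taqman, taq_extra)
  rownames(out) <- NULL
  out
}

#' Build the reference TMAU cohort fixture
#'
#' Writes a complete, self-consistent analysis bundle for a ten-subject TMAU
#' cohort transcribed from the study's printed tables: choline-challenge
#' urine collections whose oxidation ratios reproduce the published per-
#' subject values exactly, a multi-sample VCF carrying the known FMO3
#' variants and the novel oxidoreductase / DMGDH-interactome / shared
#' variants with their published positions, MAFs and zygosities, leave-one-
#' out decoy variants that each violate a single filter criterion, the
#' known-variant catalog, extra (non-exome) genotypes for the intronic
#' PYROXD2 variant, a minimal scored interaction network around the FMO3 /
#' PYROXD2 / DMGDH seeds, the oxidoreductase gene set, and orthogonal
#' Sanger/Taqman-style genotype calls (29 + 30) transcribed from the same
#' genotypes.
#'
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @return List with `dir`, `paths` (named: `vcf`, `annotations`, `urine`,
#'   `catalog`, `extra_genotypes`, `network`, `oxidoreductase_genes`,
#'   `known_tma_genes`, `orthogonal_calls`, `subjects`), `subjects` (data
#'   frame with id, age, sex and published ratio) and `subject_sexes`
#'   (named vector for [read_multisample_vcf()]).
#' @export
paper_fixture <- function(dir = tempfile("tmau_fixture")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- .fixture_subject_table()
  variants <- .fixture_variant_table()
  extra <- .fixture_extra_genotypes(subjects)

  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    urine = file.path(dir, "urine.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    extra_genotypes = file.path(dir, "extra_genotypes.tsv"),
    network = file.path(dir, "network.tsv"),
    oxidoreductase_genes = file.path(dir, "oxidoreductase_genes.txt"),
    known_tma_genes = file.path(dir, "known_tma_genes.txt"),
    orthogonal_calls = file.path(dir, "orthogonal_calls.tsv"),
    subjects = file.path(dir, "subjects.tsv")
  )

  writeLines(.fixture_vcf_lines(subjects, variants), paths[["vcf"]])
  ann <- variants[, c("chrom", "pos", "ref", "alt", "gene", "rsid",
                      "sift_score", "sift_call", "polyphen_score",
                      "polyphen_call", "maf")]
  utils::write.table(ann, paths[["annotations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  utils::write.table(.fixture_urine(subjects), paths[["urine"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  utils::write.table(.fixture_catalog(), paths[["catalog"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  utils::write.table(extra, paths[["extra_genotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  utils::write.table(.fixture_network(), paths[["network"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_set(.fixture_oxidoreductase_genes(),
                 paths[["oxidoreductase_genes"]])
  write_gene_set(c("FMO3", "PYROXD2", "DMGDH"), paths[["known_tma_genes"]])
  utils::write.table(.fixture_orthogonal_calls(subjects, variants, extra),
                     paths[["orthogonal_calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  utils::write.table(subjects[, c("id", "sex", "age")], paths[["subjects"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(dir = dir, paths = paths, subjects = subjects,
       subject_sexes = stats::setNames(subjects$sex, subjects$id))
}

#' Run the full analysis pipeline on a fixture-style bundle
#'
#' Convenience wrapper reading the files produced by [paper_fixture()] and
#' running every stage: metabolic profiling, known-variant catalog lookup,
#' the filter cascade, interactome scans seeded at FMO3, PYROXD2 and DMGDH,
#' orthogonal-genotype concordance, and per-subject summaries.
#'
#' @param fixture The list returned by [paper_fixture()].
#' @param config A [cascade_config()].
#' @return List with `matrix`, `annotations`, `profiles`, `catalog_hits`,
#'   `catalog_tally`, `cascade`, `interactome_hits` (named by seed gene),
#'   `concordance` and `summaries`.
#' @export
run_fixture_pipeline <- function(fixture, config = cascade_config()) {
  sexes <- fixture$subject_sexes
  matrix <- read_multisample_vcf(fixture$paths[["vcf"]], sexes)
  ann <- read_annotation_table(fixture$paths[["annotations"]])
  urine <- read_urine_table(fixture$paths[["urine"]])
  catalog <- read_known_variant_catalog(fixture$paths[["catalog"]])
  extra <- read_extra_genotypes(fixture$paths[["extra_genotypes"]], sexes)
  network <- read_interaction_network(fixture$paths[["network"]])
  oxi <- read_gene_set(fixture$paths[["oxidoreductase_genes"]])
  calls <- read_orthogonal_calls(fixture$paths[["orthogonal_calls"]], sexes)

  profiles <- metabolic_profiles(urine)
  hits <- lookup_known_variants(matrix, catalog, extra)
  cascade <- run_cascade(matrix, ann, oxi, config)
  scans <- lapply(c(FMO3 = "FMO3", PYROXD2 = "PYROXD2", DMGDH = "DMGDH"),
                  function(seed) {
                    interactome_variant_scan(
                      matrix, ann, expand_seed_genes(network, seed), config)
                  })
  concordance <- compare_genotypes(matrix, calls, extra)
  summaries <- build_subject_summaries(profiles, hits, cascade,
                                       scans[["DMGDH"]], matrix)
  list(matrix = matrix, annotations = ann, profiles = profiles,
       catalog_hits = hits, catalog_tally = tally_catalog_hits(hits),
       cascade = cascade, interactome_hits = scans,
       concordance = concordance, summaries = summaries)
}
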
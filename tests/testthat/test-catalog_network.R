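fixture_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- paper_fixture()
      cache <<- list(fx = fx, res = run_fixture_pipeline(fx))
    }
    cache
  }
})

test_that("seed expansion applies the score cut, top-k truncation and union", {
  net <- data.frame(
    gene_a = c("DMGDH", "DMGDH", "DMGDH", "DMGDH"),
    gene_b = c("BHMT", "SARDH", "SHMT1", "XLOW"),
    score = c(0.9, 0.8, 0.5, 0.3))
  expect_equal(expand_seed_genes(net, "DMGDH"),
               sort(c("DMGDH", "BHMT", "SARDH", "SHMT1")))

  # 12 equal-score neighbors: seed + the 10 lexicographically first
  net12 <- data.frame(gene_a = "SEED", gene_b = sprintf("N%02d", 1:12),
                      score = 0.9)
  out <- expand_seed_genes(net12, "SEED")
  expect_equal(out, sort(c("SEED", sprintf("N%02d", 1:10))))

  # shared neighbor appears once in the union
  net2 <- data.frame(gene_a = c("A", "B"), gene_b = c("X", "X"),
                     score = c(0.9, 0.9))
  expect_equal(expand_seed_genes(net2, c("A", "B")), c("A", "B", "X"))

  expect_warning(miss <- expand_seed_genes(net, c("DMGDH", "GHOST")),
                 "GHOST.*absent")
  expect_true("GHOST" %in% miss)
})

test_that("seed expansion is bounded and monotone in min_score", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n_edges <- sample(5:30, 1)
      net <- data.frame(
        gene_a = "SEED",
        gene_b = sprintf("G%03d", sample(500, n_edges)),
        score = round(runif(n_edges), 3))
      lo <- expand_seed_genes(net, "SEED", min_score = 0.2)
      hi <- expand_seed_genes(net, "SEED", min_score = 0.6)
      expect_lte(length(lo), 1 * (10 + 1))
      expect_true(all(hi %in% lo))
    }
  })
})

test_that("network reader detects the 0-1000 score dialect and bad edges", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tcombined_score",
               "DMGDH\tBHMT\t990", "DMGDH\tSARDH\t400"), path)
  net <- read_interaction_network(path)
  expect_equal(net$score, c(0.99, 0.40))

  writeLines(c("gene_a\tgene_b\tcombined_score", "A\tA\t0.5"), path)
  expect_error(read_interaction_network(path), "self-loop")
  writeLines(c("gene_a\tgene_b\tcombined_score",
               "A\tB\t0.5", "B\tA\t0.7"), path)
  expect_error(read_interaction_network(path), "duplicate edge")
})

test_that("catalog lookup reproduces the known-variant zygosity tallies", {
  res <- fixture_once()$res
  tally <- res$catalog_tally
  expect_equal(tally$n_het[tally$rsid == "rs2266782"], 5L)
  expect_equal(tally$n_hom[tally$rsid == "rs2266782"], 0L)
  # intronic variant resolved through the extra-genotype side-channel
  expect_equal(tally$n_het[tally$rsid == "rs7072216"], 2L)
  expect_equal(tally$n_hom[tally$rsid == "rs7072216"], 3L)
  hits <- res$catalog_hits
  expect_setequal(hits$subject_id[hits$rsid == "rs2266782"],
                  c("64", "98", "113", "114", "122"))
})

test_that("catalog lookup emits no hits for non-carriers", {
  b <- generate_cohort(cohort_spec(n_background_variants = 30L, seed = 5L))
  v <- b$matrix$variants[1:10, ]
  catalog <- data.frame(rsid = sprintf("rs%d", 1:10), chrom = v$chrom,
                        pos = v$pos, ref = v$ref, alt = v$alt,
                        gene = "G", key = v$key)
  hits <- lookup_known_variants(b$matrix, catalog)
  expect_true(all(hits$zygosity %in% c("HET", "HOM_ALT", "HEMI_ALT")))
  for (i in seq_len(nrow(hits))) {
    cell <- b$matrix$geno[hits$subject_id[i],
                          catalog$key[catalog$rsid == hits$rsid[i]]]
    expect_equal(unname(cell), hits$zygosity[i])
  }
  empty <- lookup_known_variants(b$matrix, catalog[0, ])
  expect_equal(nrow(empty), 0L)
  # a single hemizygous hit tallies as homozygous
  single <- data.frame(rsid = "rsX", gene = "G", subject_id = "S1",
                       zygosity = "HEMI_ALT")
  expect_equal(tally_catalog_hits(single)$n_hom, 1L)
  expect_equal(tally_catalog_hits(single)$n_het, 0L)
})

test_that("interactome scan recovers the DMGDH hits and nothing for FMO3/PYROXD2", {
  res <- fixture_once()$res
  expect_setequal(res$interactome_hits$DMGDH,
                  c("5:78378644:C:T", "9:136584082:G:A", "17:18243524:C:T"))
  expect_length(res$interactome_hits$FMO3, 0L)
  expect_length(res$interactome_hits$PYROXD2, 0L)
  # all fixture interactome carriers are heterozygous
  gm <- res$matrix
  for (k in res$interactome_hits$DMGDH) {
    zy <- gm$geno[, k]
    expect_true(all(zy[zy != "HOM_REF"] == "HET"))
  }
})

test_that("interactome scan distributes over gene-set union", {
  res <- fixture_once()$res
  gm <- res$matrix
  ann <- res$annotations
  s1 <- c("BHMT2", "SARDH")
  s2 <- c("SHMT1", "CP")
  u <- interactome_variant_scan(gm, ann, union(s1, s2))
  expect_setequal(u, union(interactome_variant_scan(gm, ann, s1),
                           interactome_variant_scan(gm, ann, s2)))
  expect_equal(interactome_variant_scan(gm, ann, "NOTAGENE123"),
               character(0))
})
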
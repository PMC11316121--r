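test_that("impact classification separates LoF, qualifying missense and the rest", {
  cfg <- screen_config()
  expect_equal(classify_impact("stop_gained", NA, cfg), "lof")
  expect_equal(classify_impact("frameshift", NA, cfg), "lof")
  expect_equal(classify_impact("missense_variant", 15.0, cfg),
               "high_impact_missense")  # threshold is inclusive
  expect_equal(classify_impact("missense_variant", 14.9, cfg), "other")
  expect_equal(classify_impact("missense_variant", NA, cfg), "other")
  expect_equal(classify_impact("synonymous_variant", 30.0, cfg), "other")
  expect_error(classify_impact("nonsense_term", NA, cfg), "nonsense_term")
  # splice_region can be made CADD-dependent
  strict <- screen_config(splice_region_needs_cadd = TRUE)
  expect_equal(classify_impact("splice_region", NA, strict), "other")
  expect_equal(classify_impact("splice_region", 20, strict), "lof")
})

test_that("rarity filter is inclusive and lets population-absent alleles through", {
  cfg <- screen_config()
  expect_true(passes_rarity(NA, cfg))
  expect_true(passes_rarity(0.01, cfg))
  expect_false(passes_rarity(0.02, cfg))
  expect_false(passes_rarity(NA, screen_config(missing_af_passes = FALSE)))
  expect_error(passes_rarity(1.5, cfg), "pop_af")
})

test_that("diplotype resolution distinguishes homozygous, phased and unphased pairs", {
  hom <- resolve_diplotype("p", "G",
    data.frame(variant_id = "v1", zygosity = "hom_alt"))
  expect_equal(hom$status, "candidate")
  expect_equal(hom$candidates$phase, "homozygous")
  expect_true(is.na(hom$candidates$allele2))

  pc <- data.frame(patient = "p", variant_a = "v1", variant_b = "v2",
                   configuration = "trans", evidence = "trio")
  two <- resolve_diplotype("p", "G",
    data.frame(variant_id = c("v1", "v2"), zygosity = c("het", "het")), pc)
  expect_equal(two$candidates$phase, "trans_confirmed")
  expect_equal(two$candidates$evidence, "trio")

  # cis evidence rules the pair out entirely
  pc$configuration <- "cis"
  cis <- resolve_diplotype("p", "G",
    data.frame(variant_id = c("v1", "v2"), zygosity = c("het", "het")), pc)
  expect_equal(nrow(cis$candidates), 0L)
  expect_equal(nrow(cis$unphased), 0L)

  # no evidence: the pair is reported but needs confirmation
  un <- resolve_diplotype("p", "G",
    data.frame(variant_id = c("v1", "v2"), zygosity = c("het", "het")))
  expect_equal(nrow(un$candidates), 0L)
  expect_equal(un$unphased$phase, "unphased")

  one <- resolve_diplotype("p", "G",
    data.frame(variant_id = "v1", zygosity = "het"))
  expect_equal(one$status, "monoallelic")

  # >2 hets: all unordered pairs, flagged for review
  three <- resolve_diplotype("p", "G",
    data.frame(variant_id = c("v1", "v2", "v3"), zygosity = rep("het", 3)))
  expect_equal(nrow(three$unphased), 3L)
  expect_true(all(three$unphased$manual_review))
})

test_that("trans_confirmed is never emitted without phase evidence", {
  for (pc in list(NULL,
                  data.frame(patient = "q", variant_a = "v1",
                             variant_b = "v2", configuration = "trans",
                             evidence = "trio"),
                  data.frame(patient = "p", variant_a = "v1",
                             variant_b = "v2", configuration = "ambiguous",
                             evidence = "long_read"))) {
    res <- resolve_diplotype("p", "G",
      data.frame(variant_id = c("v1", "v2"), zygosity = c("het", "het")), pc)
    expect_false("trans_confirmed" %in% res$candidates$phase)
  }
})

test_that("cohort screen applies the full cascade on a hand-built cohort", {
  tc <- tiny_cohort()
  res <- screen_cohort(tc$variants, tc$calls, tc$panel,
                       phase_calls = tc$phase)
  # pt1 hom stop-gain (AF absent), pt2 confirmed comp het,
  # pt4 hom stop-gain at AF exactly 0.01 (inclusive boundary)
  expect_setequal(res$candidates$patient, c("pt1", "pt2", "pt4"))
  expect_equal(res$candidates$phase[res$candidates$patient == "pt2"],
               "trans_confirmed")
  # pt3 fails rarity, pt5 off panel, pt6 benign
  expect_false(any(c("pt3", "pt5", "pt6") %in% res$candidates$patient))

  # every returned allele re-passes the individual filters
  idx <- match(res$candidates$allele1, tc$variants$variant_id)
  expect_true(all(passes_rarity(tc$variants$pop_af[idx])))
  expect_true(all(classify_impact(tc$variants$consequence[idx],
                                  tc$variants$cadd[idx]) != "other"))

  expect_equal(nrow(screen_cohort(tc$variants, tc$calls,
                                  gene_panel("none", "ZZZ"))$candidates), 0L)
  bad_calls <- call_table("px", "chrZ:1:A:T", "hom_alt")
  expect_error(screen_cohort(tc$variants, bad_calls, tc$panel), "unknown variant")
})

test_that("multi-transcript annotations collapse to the most severe consequence", {
  v <- variant_table(chrom = c("chr1", "chr1", "chr1"), pos = c(10, 10, 10),
                     ref = "A", alt = "G", gene = "PIWIL1",
                     consequence = c("intron_variant", "stop_gained",
                                     "missense_variant"),
                     transcript = c("tx3", "tx2", "tx1"), cadd = 30)
  cl <- collapse_annotations(v)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$consequence, "stop_gained")
  # severity tie broken by lowest transcript id
  v2 <- variant_table(chrom = "chr1", pos = c(10, 10), ref = "A", alt = "G",
                      gene = "PIWIL1", consequence = "stop_gained",
                      transcript = c("txB", "txA"))
  expect_equal(collapse_annotations(v2)$transcript, "txA")
})

test_that("exclusion screen flags additional rare homozygous high-impact hits", {
  panel <- gene_panel("azoo", c("TEX11", "SYCP3"))
  mk <- function(consequence, cadd, af = NA, zyg = "hom_alt", gene = "TEX11") {
    v <- variant_table("chr2", 50, "C", "G", gene, consequence,
                       pop_af = af, cadd = cadd)
    list(v = v, c = call_table("p1", v$variant_id, zyg))
  }
  hit <- mk("stop_gained", NA)
  expect_equal(exclusion_screen(hit$v, hit$c, panel)$decision, "exclude")
  low <- mk("missense_variant", 19)
  expect_equal(exclusion_screen(low$v, low$c, panel)$decision, "keep")
  ok <- mk("missense_variant", 20)
  expect_equal(exclusion_screen(ok$v, ok$c, panel)$decision, "exclude")
  het <- mk("stop_gained", NA, zyg = "het")
  expect_equal(exclusion_screen(het$v, het$c, panel)$decision, "keep")
  off <- mk("stop_gained", NA, gene = "NOTINPANEL")
  expect_equal(exclusion_screen(off$v, off$c, panel)$decision, "keep")
})

test_that("discovery arm lists testis-preferential genes with homozygous LoF only", {
  v <- variant_table(chrom = "chr3", pos = c(1, 2, 3), ref = "A", alt = "T",
                     gene = c("GENEA", "GENEB", "GENEC"),
                     consequence = c("frameshift", "missense_variant",
                                     "frameshift"),
                     pop_af = c(0, 0.001, NA), cadd = c(NA, 35, NA))
  calls <- call_table(c("p1", "p2", "p3"), v$variant_id, "hom_alt")
  testis <- c("GENEA", "GENEB")
  got <- discovery_lof_genes(v, calls, testis)
  expect_equal(got, "GENEA")   # B is missense, C not testis-preferential
  expect_error(discovery_lof_genes(v, calls, character(0)), "non-empty")
})

test_that("tightening thresholds never enlarges the candidate set", {
  for (seed in 1:3) {
    co <- simulate_cohort(sim_config(n_patients = 60), seed)
    base <- screen_cohort(co$variants, co$calls, co$panel,
                          screen_config(), co$phase_calls)$candidates
    key <- function(df) paste(df$patient, df$gene, df$allele1, df$allele2)
    for (cfg in list(screen_config(max_maf = 0.001),
                     screen_config(cadd_min_panel = 25),
                     screen_config(max_maf = 0.005, cadd_min_panel = 30))) {
      tight <- screen_cohort(co$variants, co$calls, co$panel, cfg,
                             co$phase_calls)$candidates
      expect_true(all(key(tight) %in% key(base)))
    }
  }
})
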
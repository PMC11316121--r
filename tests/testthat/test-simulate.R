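test_that("generators are bit-reproducible under a fixed seed", {
  sim <- sim_config(n_patients = 30, depth = 200, genome_size = 6000,
                    n_loci = 4, locus_size = 400, n_blacklist = 2)
  expect_identical(simulate_cohort(sim, 7), simulate_cohort(sim, 7))
  a1 <- make_toy_genome(sim, 7); a2 <- make_toy_genome(sim, 7)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$spikes, a2$spikes)
  s1 <- simulate_smallrna_sample("case", sim, a1, 9)
  s2 <- simulate_smallrna_sample("case", sim, a2, 9)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  # and written artifacts are byte-identical
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(a1$genome, f1)
  Biostrings::writeXStringSet(a2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  b1 <- tempfile(fileext = ".bed"); b2 <- tempfile(fileext = ".bed")
  write_bed(a1$loci, b1); write_bed(a2$loci, b2)
  expect_identical(readLines(b1), readLines(b2))
})

test_that("the generators do not disturb the session RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_trio("trans", 5))
  invisible(make_toy_genome(sim_config(genome_size = 6000, n_loci = 4,
                                       locus_size = 300, n_blacklist = 2), 5))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("toy genome intervals are disjoint, in bounds and spike-free", {
  sim <- sim_config()
  assets <- make_toy_genome(sim, 3)
  all_iv <- c(assets$loci, assets$blacklist)
  expect_equal(length(assets$loci), sim$n_loci)
  expect_equal(length(assets$blacklist), sim$n_blacklist)
  ov <- GenomicRanges::findOverlaps(all_iv, drop.self = TRUE)
  expect_equal(length(ov), 0L)
  expect_true(all(GenomicRanges::start(all_iv) >= 1))
  expect_true(all(GenomicRanges::end(all_iv) <= sim$genome_size))
  g <- as.character(assets$genome[[1]])
  for (s in assets$spikes) {
    expect_false(grepl(s, g, fixed = TRUE))
    expect_false(grepl(oracle_revcomp(s), g, fixed = TRUE))
  }
})

test_that("planted cohort truth matches what the screen recovers", {
  sim <- sim_config(n_patients = 120)
  co <- simulate_cohort(sim, 13)
  expect_setequal(unique(co$truth$class),
                  intersect(unique(co$truth$class),
                            c("hom", "comphet", "cis_pair", "monoallelic",
                              "excluded_secondary", "background")))
  res <- screen_cohort(co$variants, co$calls, co$panel,
                       phase_calls = co$phase_calls)
  found <- paste(res$candidates$patient, res$candidates$gene)
  expected <- with(co$truth[co$truth$expected_candidate, ],
                   paste(patient, gene))
  expect_setequal(found, expected)
  # a planted cis pair is never confirmed as trans
  cis_pat <- co$truth$patient[co$truth$class == "cis_pair"]
  expect_false(any(res$candidates$patient %in% cis_pat))
  expect_false(any(res$needs_confirmation$patient %in% cis_pat))
  # monoallelic patients never yield candidates
  mono <- co$truth$patient[co$truth$class == "monoallelic"]
  expect_false(any(res$candidates$patient %in% mono))
  # exclusion screen removes exactly the planted secondary-finding carriers
  ex <- exclusion_screen(co$variants, co$calls, list(co$exclusion_panel))
  expect_setequal(ex$patient[ex$decision == "exclude"],
                  co$truth$patient[co$truth$expected_excluded])
})

test_that("small-RNA truth labels describe the generated reads", {
  sim <- sim_config(depth = 300, genome_size = 6000, n_loci = 4,
                    locus_size = 400, n_blacklist = 2)
  assets <- make_toy_genome(sim, 17)
  s <- simulate_smallrna_sample("control", sim, assets, 18)
  expect_equal(length(s$reads), nrow(s$truth))
  expect_equal(unname(nchar(as.character(s$reads))), s$truth$length)
  expect_true(all(s$truth$origin[s$truth$length <= 23] %in%
                    c("mirna", "spike")))
  # spike reads are literal spike sequences
  sp <- as.character(s$reads)[s$truth$origin == "spike"]
  expect_true(all(sp %in% assets$spikes))
  # case depletion removes most piRNA reads
  ctrl_n <- sum(s$truth$origin == "pirna")
  case <- simulate_smallrna_sample("case", sim, assets, 18)
  case_n <- sum(case$truth$origin == "pirna")
  expect_lt(case_n, ctrl_n * (1 - sim$depletion) * 3)
})

test_that("case samples lose piRNA-locus signal at every window length", {
  sim <- sim_config(depth = 1500, genome_size = 8000, n_loci = 5,
                    locus_size = 500, n_blacklist = 3)
  assets <- make_toy_genome(sim, 23)
  run1 <- function(group, seed) {
    s <- simulate_smallrna_sample(group, sim, assets, seed)
    run_spectrum_pipeline(s$reads, assets$genome, assets$loci,
                          assets$blacklist, sample_id = group,
                          group = group)$spectrum
  }
  ctrl <- run1("control", 31)
  case <- run1("case", 32)
  expect_true(all(case$normalized < ctrl$normalized))
  # control modal length falls in the expected pachytene peak
  modal <- as.integer(names(which.max(ctrl$counts)))
  expect_true(modal >= 28 && modal <= 31)
})
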
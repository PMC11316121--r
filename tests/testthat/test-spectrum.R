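place <- function(start, end, chrom = "toychr", strand = "+") {
  data.frame(read_id = paste0("p", seq_along(start)), chrom = chrom,
             start = start, end = end, strand = strand,
             mismatches = 0L, pass = 1L, stringsAsFactors = FALSE)
}
iv <- function(start, end, label = paste0("iv", seq_along(start)),
               chrom = "toychr") {
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

test_that("length filter keeps the 25-45 nt band inclusively", {
  cfg <- spectrum_config()
  reads <- c(mir = strrep("A", 22), lo = strrep("C", 25),
             hi = strrep("G", 45), over = strrep("T", 46))
  kept <- length_filter(reads, cfg)
  expect_setequal(names(kept), c("lo", "hi"))
})

test_that("blacklist subtraction uses half-open >= 1 base overlap", {
  bl <- iv(120, 140)
  expect_equal(nrow(subtract_known_sncrna(place(100, 130), bl)), 0L)
  # abutting interval: no overlap under half-open arithmetic
  expect_equal(nrow(subtract_known_sncrna(place(100, 130), iv(130, 150))), 1L)
  expect_equal(nrow(subtract_known_sncrna(place(100, 130), iv(0, 0)[0, ])), 1L)
  # single-base overlap is enough
  expect_equal(nrow(subtract_known_sncrna(place(100, 130), iv(129, 150))), 0L)
})

test_that("interval overlap decisions match direct arithmetic on random pairs", {
  set.seed(21)
  for (i in 1:200) {
    ps <- sample(0:500, 1); pe <- ps + sample(20:40, 1)
    bs <- sample(0:500, 1); be <- bs + sample(5:200, 1)
    removed <- nrow(subtract_known_sncrna(place(ps, pe), iv(bs, be))) == 0L
    overlaps <- (max(ps, bs) < min(pe, be))   # half-open intersection
    expect_equal(removed, overlaps,
                 info = sprintf("[%d,%d) vs [%d,%d)", ps, pe, bs, be))
  }
})

test_that("locus assignment counts straddling placements once in the spectrum", {
  loci <- iv(c(100, 160), c(160, 220), label = c("L1", "L2"))
  inside <- assign_to_pirna_loci(place(110, 140), loci)
  expect_equal(nrow(inside$assigned), 1L)
  expect_equal(unname(inside$locus_counts), c(1L, 0L))

  outside <- assign_to_pirna_loci(place(300, 330), loci)
  expect_equal(nrow(outside$assigned), 0L)

  straddle <- assign_to_pirna_loci(place(150, 180), loci)
  expect_equal(nrow(straddle$assigned), 1L)          # once in the spectrum
  expect_equal(unname(straddle$locus_counts), c(1L, 1L))  # both loci credited
})

test_that("length spectrum tallies the window and normalizes per million", {
  cfg <- spectrum_config()
  pls <- place(start = rep(0, 5), end = c(28, 28, 28, 30, 30))
  sp <- length_spectrum(pls, cfg, "s1", "control", denominator = 1000L)
  expect_equal(unname(sp$counts), c(0L, 0L, 3L, 0L, 2L, 0L))
  expect_equal(names(sp$counts), as.character(26:31))
  expect_equal(unname(sp$normalized["28"]), 3 / 1000 * 1e6)
  empty <- length_spectrum(pls[0, ], cfg, "s0", "case", denominator = 10L)
  expect_true(all(empty$counts == 0L))
  # out-of-window lengths are excluded
  wide <- length_spectrum(place(0, 40), cfg, "s2", "control", 10L)
  expect_equal(sum(wide$counts), 0L)
})

test_that("spike-in QC requires every expected spike", {
  spikes <- c(s1 = "ACGTACGTACGTACGTACGTAC", s2 = "TTGGCCAATTGGCCAATTGGCC")
  reads <- c(spikes[["s1"]], spikes[["s1"]], spikes[["s2"]], "AAAA")
  qc <- spikein_qc(reads, spikes)
  expect_true(qc$pass)
  expect_equal(unname(qc$counts), c(2L, 1L))
  expect_false(spikein_qc(c(spikes[["s1"]]), spikes)$pass)
  zero <- spikein_qc(character(0), spikes)
  expect_false(zero$pass)
  expect_equal(unname(zero$counts), c(0L, 0L))
  expect_false(spikein_qc(reads, spikes, min_count = 3)$pass)
})

test_that("case group equal to control group yields p = 1", {
  cfg <- spectrum_config()
  mk <- function(id, group, counts) {
    pls <- place(start = rep(0, sum(counts)),
                 end = rep(26:31, counts))
    length_spectrum(pls, cfg, id, group, denominator = 500L)
  }
  counts <- c(2, 5, 9, 12, 8, 3)
  spectra <- list(mk("c1", "control", counts), mk("c2", "control", counts + 1),
                  mk("k1", "case", counts), mk("k2", "case", counts + 1))
  cmp <- compare_case_control(spectra, cfg)
  expect_equal(cmp$p_two_sided, 1)
  expect_equal(cmp$n_a, cmp$n_b)
})

test_that("one sample per group and a single length uses the exact two-value test", {
  cfg <- spectrum_config(window_min = 28, window_max = 28)
  mk <- function(id, group, n) {
    pls <- place(start = rep(0, n), end = rep(28, n))
    length_spectrum(pls, cfg, id, group, denominator = 100L)
  }
  cmp <- compare_case_control(list(mk("c", "control", 9), mk("k", "case", 2)),
                              cfg)
  expect_equal(cmp$method, "exact")
  expect_equal(cmp$p_two_sided, 1)   # two labelings only
  # normality is not assessable at n = 1, reported as NA with a reason
  expect_true(is.na(cmp$normality$control$W))
  expect_match(cmp$normality$control$reason, "n < 3")
  expect_error(compare_case_control(list(mk("c", "control", 5)), cfg),
               "at least one")
})

test_that("the cascade conserves reads stage by stage", {
  sim <- sim_config(depth = 300, genome_size = 8000, n_loci = 5,
                    locus_size = 500, n_blacklist = 3)
  assets <- make_toy_genome(sim, 11)
  s <- simulate_smallrna_sample("control", sim, assets, 12)
  res <- run_spectrum_pipeline(s$reads, assets$genome, assets$loci,
                               assets$blacklist, spikes = assets$spikes,
                               sample_id = "c1", group = "control")
  sc <- res$stage_counts
  al <- res$align_stats
  expect_equal(unname(sc["n_input"]), length(s$reads))
  expect_equal(unname(al["n_input"]), unname(sc["n_retained"]))
  expect_equal(unname(sc["n_placed"]),
               unname(al["n_pass1"] + al["n_pass2"]))
  expect_lte(sc[["n_after_blacklist"]], sc[["n_placed"]])
  expect_lte(sc[["n_assigned"]], sc[["n_after_blacklist"]])
  expect_lte(sum(res$spectrum$counts), sc[["n_assigned"]])
  expect_true(res$qc$pass)
  expect_equal(res$spectrum$denominator, unname(sc["n_retained"]))
})
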
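test_that("trio phasing resolves textbook inheritance patterns", {
  # each parent carries one of the two variants: alleles must be in trans
  trans <- trio_phase(list(mother_a = "het", mother_b = "ref_ref",
                           father_a = "ref_ref", father_b = "het"))
  expect_equal(trans$configuration, "trans")
  expect_equal(trans$evidence, "trio")

  # one parent carries both variants, the other neither: single maternal
  # haplotype carries both alternates
  cis <- trio_phase(list(mother_a = "het", mother_b = "het",
                         father_a = "ref_ref", father_b = "ref_ref"))
  expect_equal(cis$configuration, "cis")

  amb <- trio_phase(list(mother_a = "het", mother_b = "het",
                         father_a = "missing", father_b = "missing"))
  expect_equal(amb$configuration, "ambiguous")

  # child alt allele absent from both parents
  expect_error(trio_phase(list(mother_a = "ref_ref", mother_b = "het",
                               father_a = "ref_ref", father_b = "het")),
               "Mendelian")
})

test_that("trio phasing agrees with brute-force transmission enumeration", {
  gts <- c("ref_ref", "het", "hom_alt")
  grid <- expand.grid(ma = gts, mb = gts, fa = gts, fb = gts,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 81L)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    want <- oracle_trio_enumerate(g$ma, g$mb, g$fa, g$fb)
    got <- tryCatch(
      trio_phase(list(mother_a = g$ma, mother_b = g$mb,
                      father_a = g$fa, father_b = g$fb))$configuration,
      error = function(e) "inconsistent")
    expect_equal(got, want,
                 info = paste("genotypes:", g$ma, g$mb, g$fa, g$fb))
  }
})

test_that("fragment phasing tallies consistent fragments and applies thresholds", {
  frag <- function(a, b, n) data.frame(allele_a = rep(a, n),
                                       allele_b = rep(b, n))
  obs <- rbind(frag("alt", "ref", 6), frag("ref", "alt", 5))
  pc <- read_phase(obs, min_support = 5, max_conflict_fraction = 0.1)
  expect_equal(pc$configuration, "trans")
  expect_equal(c(pc$n_trans, pc$n_cis), c(11L, 0L))

  expect_equal(read_phase(frag("alt", "alt", 10))$configuration, "cis")
  tie <- read_phase(rbind(frag("alt", "alt", 5), frag("alt", "ref", 5)))
  expect_equal(tie$configuration, "ambiguous")

  empty <- read_phase(data.frame(allele_a = character(),
                                 allele_b = character()))
  expect_equal(empty$configuration, "ambiguous")
  expect_equal(c(empty$n_trans, empty$n_cis), c(0L, 0L))

  # support below min_support, or too much conflict -> ambiguous
  expect_equal(read_phase(frag("alt", "ref", 2),
                          min_support = 3)$configuration, "ambiguous")
  noisy <- rbind(frag("alt", "ref", 7), frag("alt", "alt", 3))
  expect_equal(read_phase(noisy, max_conflict_fraction = 0.2)$configuration,
               "ambiguous")
  # fragments missing one site are dropped from the tally
  miss <- rbind(frag("alt", "missing", 4), frag("alt", "alt", 4))
  expect_equal(read_phase(miss)$configuration, "cis")
})

test_that("fragment phasing is symmetric in site labels and fragment order", {
  for (seed in 1:5) {
    fr <- simulate_fragments(if (seed %% 2) "trans" else "cis",
                             n = 25, seed = seed)
    base <- read_phase(fr)
    swapped <- data.frame(allele_a = fr$allele_b, allele_b = fr$allele_a)
    expect_equal(read_phase(swapped)$configuration, base$configuration)
    expect_equal(read_phase(swapped)$n_trans, base$n_trans)
    shuffled <- fr[sample.int(nrow(fr)), ]
    expect_equal(read_phase(shuffled)$configuration, base$configuration)
  }
})

test_that("simulated trios and fragments recover the planted configuration", {
  for (seed in 1:30) {
    tr <- simulate_trio("trans", seed)
    expect_equal(trio_phase(tr)$configuration, "trans")
    ci <- simulate_trio("cis", seed)
    got <- trio_phase(ci)$configuration
    expect_true(got %in% c("cis", "ambiguous"))
  }
  for (seed in 1:20) {
    for (cfg in c("trans", "cis")) {
      fr <- simulate_fragments(cfg, n = 30, error_rate = 0.03, seed = seed)
      pc <- read_phase(fr)
      if (pc$configuration != "ambiguous") expect_equal(pc$configuration, cfg)
      # ambiguity is only allowed when the thresholds genuinely failed
      if (pc$configuration == "ambiguous") {
        maj <- max(pc$n_trans, pc$n_cis)
        tot <- pc$n_trans + pc$n_cis
        expect_true(maj < 3 || (tot - maj) / tot > 0.2 ||
                      pc$n_trans == pc$n_cis)
      }
    }
  }
})
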
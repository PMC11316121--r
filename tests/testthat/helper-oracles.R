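# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive enumerations / exhaustive scans, structured
# differently from the package code paths they verify.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
}

# every placement of `read` on `refs` (named character vector) with at most
# `max_mm` substitutions, by scanning every offset on both strands
oracle_align_scan <- function(read, refs, max_mm = 1L) {
  out <- NULL
  w <- nchar(read)
  for (chrom in names(refs)) {
    g <- refs[[chrom]]
    n <- nchar(g)
    if (n < w) next
    for (p in 1:(n - w + 1L)) {
      window <- substr(g, p, p + w - 1L)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") read else oracle_revcomp(read)
        mm <- sum(strsplit(q, NULL)[[1]] != strsplit(window, NULL)[[1]])
        if (mm <= max_mm)
          out <- rbind(out, data.frame(chrom = chrom, start = p - 1L,
                                       strand = strand, mm = mm,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# what the two-pass aligner must report for one read, per the oracle scan
oracle_align_expect <- function(read, refs) {
  hits <- oracle_align_scan(read, refs, max_mm = 1L)
  if (is.null(hits)) return(list(status = "unmapped"))
  exact <- hits[hits$mm == 0L, , drop = FALSE]
  if (nrow(exact) == 1L) return(list(status = "placed", pass = 1L, hit = exact))
  if (nrow(exact) > 1L) return(list(status = "multimapped"))
  mm1 <- hits[hits$mm == 1L, , drop = FALSE]
  if (nrow(mm1) == 1L) return(list(status = "placed", pass = 2L, hit = mm1))
  if (nrow(mm1) > 1L) return(list(status = "multimapped"))
  list(status = "unmapped")
}

# trio phasing by brute force over explicit parental haplotype 4-tuples:
# each parent is assigned an ordered pair of two-site haplotypes from
# {00, 01, 10, 11}; keep assignments matching the observed genotypes, then
# enumerate the four transmissions
oracle_trio_enumerate <- function(mother_a, mother_b, father_a, father_b) {
  haps <- expand.grid(a = 0:1, b = 0:1)
  gt_of <- function(x1, x2) c("ref_ref", "het", "hom_alt")[x1 + x2 + 1L]
  consistent <- function(h1, h2, za, zb) {
    (za == "missing" || gt_of(haps$a[h1], haps$a[h2]) == za) &&
    (zb == "missing" || gt_of(haps$b[h1], haps$b[h2]) == zb)
  }
  configs <- character(0)
  for (m1 in 1:4) for (m2 in 1:4) {
    if (!consistent(m1, m2, mother_a, mother_b)) next
    for (f1 in 1:4) for (f2 in 1:4) {
      if (!consistent(f1, f2, father_a, father_b)) next
      for (tm in c(m1, m2)) for (tf in c(f1, f2)) {
        child_a <- haps$a[tm] + haps$a[tf]
        child_b <- haps$b[tm] + haps$b[tf]
        if (child_a != 1L || child_b != 1L) next
        cis <- (haps$a[tm] == 1L && haps$b[tm] == 1L) ||
               (haps$a[tf] == 1L && haps$b[tf] == 1L)
        configs <- c(configs, if (cis) "cis" else "trans")
      }
    }
  }
  configs <- unique(configs)
  if (!length(configs)) return("inconsistent")
  if (length(configs) > 1L) return("ambiguous")
  configs
}

# P(overlap >= k) by enumerating every n-subset of 1..N with 1..K annotated
oracle_hyper_enum <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k == 0L))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# exact two-sided Mann-Whitney p by enumerating group labelings and counting
# pairwise wins (0.5 per tie) rather than via ranks
oracle_mwu_exact <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  u_of <- function(ia) {
    xa <- x[ia]; xb <- x[-ia]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  labelings <- utils::combn(length(x), na)
  u_all <- apply(labelings, 2L, u_of)
  mu <- na * length(b) / 2
  one <- if (u_obs <= mu) mean(u_all <= u_obs) else mean(u_all >= u_obs)
  min(1, 2 * one)
}

# a small hand-built cohort: two clear candidates among assorted decoys
tiny_cohort <- function() {
  v <- variant_table(
    chrom = rep("chr1", 8), pos = c(100, 200, 300, 400, 500, 600, 700, 800),
    ref = rep("A", 8), alt = rep("T", 8),
    gene = c("PIWIL1", "PIWIL1", "TDRD9", "TDRD9", "PIWIL1", "GPAT2",
             "OFFPANEL", "GPAT2"),
    consequence = c("stop_gained", "missense_variant", "missense_variant",
                    "frameshift", "missense_variant", "stop_gained",
                    "stop_gained", "synonymous_variant"),
    pop_af = c(NA, 0.001, 0.005, NA, 0.02, 0.01, NA, 0.001),
    cadd = c(NA, 25, 22, NA, 30, NA, 35, 3))
  ids <- v$variant_id
  calls <- call_table(
    patient = c("pt1", "pt2", "pt2", "pt3", "pt4", "pt5", "pt6"),
    variant_id = c(ids[1], ids[3], ids[4], ids[5], ids[6], ids[7], ids[8]),
    zygosity = c("hom_alt", "het", "het", "hom_alt", "hom_alt", "hom_alt",
                 "hom_alt"))
  phase <- data.frame(patient = "pt2", variant_a = ids[3], variant_b = ids[4],
                      configuration = "trans", evidence = "trio",
                      stringsAsFactors = FALSE)
  list(variants = v, calls = calls, phase = phase,
       panel = gene_panel("toy", c("PIWIL1", "TDRD9", "GPAT2")))
}
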
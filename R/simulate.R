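# run expr with a local, restored RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# default panels used by the simulator: the 14 genes of the published cohort
# plus ten canonical piRNA-pathway factors (synthetic stand-in for the
# 24-gene screen panel), and an illustrative azoospermia exclusion panel
.DEFAULT_PIRNA_PANEL <- c(
  "DDX4", "FKBP6", "GPAT2", "GTSF1", "HENMT1", "MAEL", "MOV10L1", "PIWIL1",
  "PIWIL2", "PLD6", "PNLDC1", "TDRD1", "TDRD9", "TDRD12",
  "PIWIL3", "PIWIL4", "ASZ1", "TDRKH", "TDRD5", "TDRD6", "TDRD7", "RNF17",
  "EXD1", "SPOCD1")
.DEFAULT_EXCLUSION_GENES <- c(
  "TEX11", "TEX14", "SYCP3", "MEIOB", "STAG3", "TERB1", "M1AP", "FANCM",
  "DMRT1", "NR5A1")

#' Simulation configuration
#'
#' Study-condition parameters for the seedable generators. Cohort fractions
#' give, per patient, the probability of each planted class; the remainder of
#' the cohort carries only decoy variants. Small-RNA parameters describe read
#' depth, the control piRNA length distribution (modal length inside
#' 28-31 nt), the case depletion factor and contaminant fractions.
#'
#' @param n_patients Cohort size (default 200).
#' @param frac_hom,frac_comphet,frac_cis,frac_monoallelic,frac_excluded
#'   Planted-class fractions (defaults 0.10, 0.06, 0.05, 0.05, 0.04).
#' @param depth Reads per small-RNA sample before case depletion (default
#'   2000).
#' @param depletion Fraction of piRNA-locus reads removed from case samples
#'   (default 0.9).
#' @param frac_pirna,frac_mirna,frac_blacklist,frac_spike,frac_junk Read
#'   composition of a sample (defaults 0.60, 0.15, 0.13, 0.02, 0.10).
#' @param pirna_length_weights Named numeric weights over the 26-31 nt
#'   window for piRNA read lengths.
#' @param tail_frac Fraction of piRNA reads drawn instead from a 32-36 nt
#'   tail (default 0.08).
#' @param mismatch_frac Fraction of genome-derived reads carrying one planted
#'   substitution (exercises alignment pass 2; default 0.10).
#' @param genome_size,n_loci,locus_size,n_blacklist,blacklist_size Toy-genome
#'   geometry (defaults 20000, 8, 600, 5, 120).
#' @param panel_genes,exclusion_genes,background_genes Gene symbol sets used
#'   by the cohort simulator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L,
                       frac_hom = 0.10, frac_comphet = 0.06, frac_cis = 0.05,
                       frac_monoallelic = 0.05, frac_excluded = 0.04,
                       depth = 2000L, depletion = 0.9,
                       frac_pirna = 0.60, frac_mirna = 0.15,
                       frac_blacklist = 0.13, frac_spike = 0.02,
                       frac_junk = 0.10,
                       pirna_length_weights = c(`26` = 0.05, `27` = 0.10,
                                                `28` = 0.20, `29` = 0.30,
                                                `30` = 0.25, `31` = 0.10),
                       tail_frac = 0.08, mismatch_frac = 0.10,
                       genome_size = 20000L, n_loci = 8L, locus_size = 600L,
                       n_blacklist = 5L, blacklist_size = 120L,
                       panel_genes = .DEFAULT_PIRNA_PANEL,
                       exclusion_genes = .DEFAULT_EXCLUSION_GENES,
                       background_genes = paste0("BG", 1:40)) {
  fr <- c(frac_hom, frac_comphet, frac_cis, frac_monoallelic, frac_excluded)
  stopifnot(all(fr >= 0), sum(fr) <= 1, depth > 0,
            depletion >= 0, depletion <= 1,
            genome_size >= n_loci * locus_size + n_blacklist * blacklist_size)
  structure(list(
    n_patients = as.integer(n_patients),
    frac_hom = frac_hom, frac_comphet = frac_comphet, frac_cis = frac_cis,
    frac_monoallelic = frac_monoallelic, frac_excluded = frac_excluded,
    depth = as.integer(depth), depletion = depletion,
    frac_pirna = frac_pirna, frac_mirna = frac_mirna,
    frac_blacklist = frac_blacklist, frac_spike = frac_spike,
    frac_junk = frac_junk,
    pirna_length_weights = pirna_length_weights,
    tail_frac = tail_frac, mismatch_frac = mismatch_frac,
    genome_size = as.integer(genome_size), n_loci = as.integer(n_loci),
    locus_size = as.integer(locus_size),
    n_blacklist = as.integer(n_blacklist),
    blacklist_size = as.integer(blacklist_size),
    panel_genes = panel_genes, exclusion_genes = exclusion_genes,
    background_genes = background_genes), class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

# one random variant annotation row (list), qualifying or decoy by kind
.sim_variant <- function(gene, kind, env) {
  env$pos_counter <- env$pos_counter + 1L
  pos <- env$pos_counter * 101L + sample.int(100L, 1L)
  ref <- sample(.BASES, 1L)
  alt <- sample(setdiff(.BASES, ref), 1L)
  lof <- sample(DISCOVERY_LOF_CLASSES, 1L)
  out <- switch(kind,
    qualifying = {
      if (stats::runif(1) < 0.5)
        list(consequence = lof, cadd = stats::runif(1, 20, 40))
      else
        list(consequence = "missense_variant", cadd = stats::runif(1, 20, 35))
    },
    qualifying_lof = list(consequence = lof, cadd = stats::runif(1, 20, 40)),
    common = list(consequence = lof, cadd = stats::runif(1, 20, 40)),
    low_cadd = list(consequence = "missense_variant",
                    cadd = stats::runif(1, 0, 14.5)),
    benign = list(consequence = "synonymous_variant",
                  cadd = stats::runif(1, 0, 10)))
  af <- if (kind == "common") stats::runif(1, 0.02, 0.30)
        else if (stats::runif(1) < 0.5) NA_real_ else stats::runif(1, 0, 0.01)
  list(chrom = paste0("chr", sample.int(22L, 1L)), pos = pos,
       ref = ref, alt = alt, gene = gene,
       consequence = out$consequence, pop_af = af, cadd = out$cadd)
}

#' Simulate a cohort with planted biallelic candidates and decoys
#'
#' Every patient receives background decoy variants (a common allele, a
#' low-CADD missense, an off-panel LoF and a benign synonymous variant, all
#' homozygous except where noted). On top of this, planted classes add:
#' `hom` (a qualifying homozygous panel variant), `comphet` (two qualifying
#' hets with trans phase evidence), `cis_pair` (two qualifying hets with cis
#' evidence), `monoallelic` (one qualifying het), `excluded_secondary` (a
#' qualifying homozygous panel variant plus a rare homozygous LoF in an
#' exclusion-panel gene). Truth labels record which patients must be
#' recovered by [screen_cohort()] and which must be removed by
#' [exclusion_screen()].
#'
#' @param sim A [sim_config()].
#' @param seed Integer seed; output is bit-reproducible given (sim, seed).
#' @return A list: `variants` ([variant_table()]), `calls` ([call_table()]),
#'   `phase_calls` (data.frame), `panel` ([gene_panel()]),
#'   `exclusion_panel`, `truth` (per-patient data.frame with `class`,
#'   `gene`, `allele1`, `allele2`, `expected_candidate`,
#'   `expected_excluded`).
#' @export
simulate_cohort <- function(sim = sim_config(), seed = 1L) {
  .with_seed(seed, {
    env <- new.env()
    env$pos_counter <- 0L
    classes <- c("hom", "comphet", "cis_pair", "monoallelic",
                 "excluded_secondary", "background")
    probs <- c(sim$frac_hom, sim$frac_comphet, sim$frac_cis,
               sim$frac_monoallelic, sim$frac_excluded,
               1 - sim$frac_hom - sim$frac_comphet - sim$frac_cis -
                 sim$frac_monoallelic - sim$frac_excluded)
    pats <- sprintf("P%04d", seq_len(sim$n_patients))
    cls <- sample(classes, sim$n_patients, replace = TRUE, prob = probs)
    vrows <- list(); crows <- list(); prows <- list(); trows <- list()
    add_var <- function(v) { vrows[[length(vrows) + 1L]] <<- v }
    add_call <- function(p, v, z)
      crows[[length(crows) + 1L]] <<- list(patient = p, variant_id = .vid(v),
                                           zygosity = z)
    .vid <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    for (i in seq_along(pats)) {
      p <- pats[i]
      # background decoys for everyone
      v <- .sim_variant(sample(sim$panel_genes, 1L), "common", env)
      add_var(v); add_call(p, v, "hom_alt")
      v <- .sim_variant(sample(sim$panel_genes, 1L), "low_cadd", env)
      add_var(v); add_call(p, v, "hom_alt")
      v <- .sim_variant(sample(sim$background_genes, 1L), "qualifying_lof", env)
      add_var(v); add_call(p, v, "hom_alt")
      v <- .sim_variant(sample(sim$panel_genes, 1L), "benign", env)
      add_var(v); add_call(p, v, "het")
      g <- sample(sim$panel_genes, 1L)
      a1 <- a2 <- NA_character_
      if (cls[i] == "hom" || cls[i] == "excluded_secondary") {
        v <- .sim_variant(g, "qualifying", env)
        add_var(v); add_call(p, v, "hom_alt")
        a1 <- .vid(v)
        if (cls[i] == "excluded_secondary") {
          ev <- .sim_variant(sample(sim$exclusion_genes, 1L),
                             "qualifying_lof", env)
          add_var(ev); add_call(p, ev, "hom_alt")
        }
      } else if (cls[i] %in% c("comphet", "cis_pair")) {
        v1 <- .sim_variant(g, "qualifying", env)
        v2 <- .sim_variant(g, "qualifying", env)
        add_var(v1); add_var(v2)
        add_call(p, v1, "het"); add_call(p, v2, "het")
        a1 <- .vid(v1); a2 <- .vid(v2)
        prows[[length(prows) + 1L]] <- list(
          patient = p, variant_a = a1, variant_b = a2,
          configuration = if (cls[i] == "comphet") "trans" else "cis",
          evidence = sample(c("trio", "long_read"), 1L))
      } else if (cls[i] == "monoallelic") {
        v <- .sim_variant(g, "qualifying", env)
        add_var(v); add_call(p, v, "het")
        a1 <- .vid(v)
      } else {
        g <- NA_character_
      }
      trows[[i]] <- list(patient = p, class = cls[i], gene = g,
                         allele1 = a1, allele2 = a2,
                         expected_candidate =
                           cls[i] %in% c("hom", "comphet",
                                         "excluded_secondary"),
                         expected_excluded = cls[i] == "excluded_secondary")
    }
    bind <- function(rows) do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    vdf <- bind(vrows)
    variants <- variant_table(vdf$chrom, vdf$pos, vdf$ref, vdf$alt, vdf$gene,
                              vdf$consequence, vdf$pop_af, vdf$cadd)
    cdf <- bind(crows)
    pdf <- if (length(prows)) bind(prows) else
      data.frame(patient = character(), variant_a = character(),
                 variant_b = character(), configuration = character(),
                 evidence = character(), stringsAsFactors = FALSE)
    list(variants = variants,
         calls = call_table(cdf$patient, cdf$variant_id, cdf$zygosity),
         phase_calls = pdf,
         panel = gene_panel("pirna_panel", sim$panel_genes),
         exclusion_panel = gene_panel("exclusion_panel", sim$exclusion_genes),
         truth = bind(trows))
  })
}

#' Simulate trio genotypes with a planted cis or trans configuration
#'
#' For `trans`, one parent carries the site-A alternate allele (het or
#' homozygous) and is reference at site B, and vice versa for the other
#' parent, which forces the two child alleles onto different transmitted
#' haplotypes. For `cis`, one parent is heterozygous at both sites (the two
#' alternates on one haplotype by construction) and the other parent is
#' reference at both sites, occasionally heterozygous at one site (which can
#' render the trio ambiguous, never trans).
#'
#' @param configuration `"trans"` or `"cis"`.
#' @param seed Integer seed.
#' @return A trio genotype list consumable by [trio_phase()], with the
#'   planted `configuration` attached as an attribute.
#' @export
simulate_trio <- function(configuration = c("trans", "cis"), seed = 1L) {
  configuration <- match.arg(configuration)
  .with_seed(seed, {
    zyg_carrier <- function() sample(c("het", "hom_alt"), 1L, prob = c(0.8, 0.2))
    if (configuration == "trans") {
      mother_first <- stats::runif(1) < 0.5
      if (mother_first)
        trio <- list(mother_a = zyg_carrier(), mother_b = "ref_ref",
                     father_a = "ref_ref", father_b = zyg_carrier())
      else
        trio <- list(mother_a = "ref_ref", mother_b = zyg_carrier(),
                     father_a = zyg_carrier(), father_b = "ref_ref")
    } else {
      other <- if (stats::runif(1) < 0.3)
        sample(c("het_a", "het_b"), 1L) else "ref"
      carrier_is_mother <- stats::runif(1) < 0.5
      oa <- if (other == "het_a") "het" else "ref_ref"
      ob <- if (other == "het_b") "het" else "ref_ref"
      trio <- if (carrier_is_mother)
        list(mother_a = "het", mother_b = "het", father_a = oa, father_b = ob)
      else
        list(mother_a = oa, mother_b = ob, father_a = "het", father_b = "het")
    }
    attr(trio, "configuration") <- configuration
    trio
  })
}

#' Simulate long-read fragment observations for a planted configuration
#'
#' @param configuration `"trans"` or `"cis"`.
#' @param n Number of fragments (default 20).
#' @param error_rate Per-fragment probability that one allele is misread
#'   (default 0.05).
#' @param missing_rate Per-fragment probability that one allele is missing
#'   (default 0.05).
#' @param seed Integer seed.
#' @return data.frame consumable by [read_phase()], planted configuration as
#'   an attribute.
#' @export
simulate_fragments <- function(configuration = c("trans", "cis"), n = 20L,
                               error_rate = 0.05, missing_rate = 0.05,
                               seed = 1L) {
  configuration <- match.arg(configuration)
  .with_seed(seed, {
    hap <- sample(0:1, n, replace = TRUE)   # which haplotype the fragment reads
    if (configuration == "trans") {
      a <- ifelse(hap == 0L, "alt", "ref")
      b <- ifelse(hap == 0L, "ref", "alt")
    } else {
      a <- ifelse(hap == 0L, "alt", "ref")
      b <- a
    }
    err <- stats::runif(n) < error_rate
    site <- sample(c("a", "b"), n, replace = TRUE)
    flip <- function(x) ifelse(x == "alt", "ref", "alt")
    a[err & site == "a"] <- flip(a[err & site == "a"])
    b[err & site == "b"] <- flip(b[err & site == "b"])
    miss <- stats::runif(n) < missing_rate
    msite <- sample(c("a", "b"), n, replace = TRUE)
    a[miss & msite == "a"] <- "missing"
    b[miss & msite == "b"] <- "missing"
    out <- data.frame(fragment = sprintf("frag%03d", seq_len(n)),
                      allele_a = a, allele_b = b, stringsAsFactors = FALSE)
    attr(out, "configuration") <- configuration
    out
  })
}

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

#' Build a toy genome with piRNA loci, a small-ncRNA blacklist and spike-ins
#'
#' A random reference sequence carrying non-overlapping labelled piRNA loci
#' and blacklist intervals, plus spike-in sequences verified absent from the
#' genome (both strands).
#'
#' @param sim A [sim_config()] (geometry fields).
#' @param seed Integer seed.
#' @return A list: `genome` (`DNAStringSet`, one sequence named `toychr`),
#'   `loci` (`GRanges` named `pi_1..`), `blacklist` (`GRanges` named
#'   `snc_1..`), `spikes` (named character vector).
#' @export
make_toy_genome <- function(sim = sim_config(), seed = 1L) {
  .with_seed(seed, {
    gsize <- sim$genome_size
    genome_seq <- .random_dna(gsize)
    n_int <- sim$n_loci + sim$n_blacklist
    widths <- c(rep(sim$locus_size, sim$n_loci),
                rep(sim$blacklist_size, sim$n_blacklist))
    kind <- sample(rep(c("locus", "snc"),
                       c(sim$n_loci, sim$n_blacklist)))
    widths <- ifelse(kind == "locus", sim$locus_size, sim$blacklist_size)
    slack <- gsize - sum(widths)
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, n_int + 1L)))
    starts0 <- cumsum(gaps[seq_len(n_int)] + c(0L, widths[-n_int]))
    ends0 <- starts0 + widths
    lab <- character(n_int)
    lab[kind == "locus"] <- paste0("pi_", seq_len(sim$n_loci))
    lab[kind == "snc"] <- paste0("snc_", seq_len(sim$n_blacklist))
    gr <- GenomicRanges::GRanges("toychr",
                                 IRanges::IRanges(start = starts0 + 1L,
                                                  end = ends0))
    names(gr) <- lab
    spikes <- character(0)
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, "toychr"))
    while (length(spikes) < 2L) {
      s <- .random_dna(22L)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      if (!grepl(s, genome_seq, fixed = TRUE) &&
          !grepl(rc, genome_seq, fixed = TRUE))
        spikes <- c(spikes, s)
    }
    names(spikes) <- c("spike_cel_mir39_like", "spike_ath_mir159a_like")
    list(genome = genome,
         loci = gr[kind == "locus"],
         blacklist = gr[kind == "snc"],
         spikes = spikes)
  })
}

.substr_read <- function(genome_seq, start1, len, minus) {
  s <- substr(genome_seq, start1, start1 + len - 1L)
  if (minus)
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.mutate1 <- function(s) {
  i <- sample.int(nchar(s), 1L)
  old <- substr(s, i, i)
  substr(s, i, i) <- sample(setdiff(.BASES, old), 1L)
  s
}

#' Simulate one small-RNA sample (FASTQ-ready reads plus per-read truth)
#'
#' Draws piRNA-locus reads with lengths from the configured control
#' distribution (modal length within 28-31 nt), ~22 nt miRNA-like reads,
#' blacklist-interval reads, spike-in reads and unmappable junk. Case samples
#' drop each piRNA-locus read with probability `depletion`. A configurable
#' fraction of genome-derived reads carries one substitution so that the
#' aligner's second pass is exercised.
#'
#' @param group `"control"` or `"case"`.
#' @param sim A [sim_config()].
#' @param assets Output of [make_toy_genome()].
#' @param seed Integer seed.
#' @return A list with `reads` (named `DNAStringSet`) and `truth`
#'   (data.frame: `read_id`, `origin`, `locus`, `length`, `strand`,
#'   `mutated`).
#' @export
simulate_smallrna_sample <- function(group = c("control", "case"),
                                     sim = sim_config(),
                                     assets, seed = 1L) {
  group <- match.arg(group)
  .with_seed(seed, {
    genome_seq <- as.character(assets$genome[[1L]])
    n <- sim$depth
    origins <- sample(c("pirna", "mirna", "blacklist", "spike", "junk"), n,
                      replace = TRUE,
                      prob = c(sim$frac_pirna, sim$frac_mirna,
                               sim$frac_blacklist, sim$frac_spike,
                               sim$frac_junk))
    if (group == "case") {
      drop <- origins == "pirna" & stats::runif(n) < sim$depletion
      origins <- origins[!drop]
      n <- length(origins)
    }
    win <- as.integer(names(sim$pirna_length_weights))
    seqs <- character(n); loc <- rep(NA_character_, n)
    lens <- integer(n); strands <- character(n); mut <- logical(n)
    for (i in seq_len(n)) {
      o <- origins[i]
      minus <- stats::runif(1) < 0.5
      if (o == "pirna") {
        len <- if (stats::runif(1) < sim$tail_frac) sample(32:36, 1L)
               else sample(win, 1L, prob = sim$pirna_length_weights)
        li <- sample.int(length(assets$loci), 1L)
        loc[i] <- names(assets$loci)[li]
        lo <- GenomicRanges::start(assets$loci)[li]
        hi <- GenomicRanges::end(assets$loci)[li]
        st <- sample(lo:(hi - len + 1L), 1L)
        s <- .substr_read(genome_seq, st, len, minus)
      } else if (o == "mirna") {
        len <- sample(21:23, 1L)
        st <- sample.int(nchar(genome_seq) - len, 1L)
        s <- .substr_read(genome_seq, st, len, minus)
      } else if (o == "blacklist") {
        len <- sample(28:36, 1L)
        bi <- sample.int(length(assets$blacklist), 1L)
        lo <- GenomicRanges::start(assets$blacklist)[bi]
        hi <- GenomicRanges::end(assets$blacklist)[bi]
        st <- sample(lo:(hi - len + 1L), 1L)
        s <- .substr_read(genome_seq, st, len, minus)
      } else if (o == "spike") {
        s <- unname(sample(assets$spikes, 1L))
        len <- nchar(s); minus <- FALSE
      } else {
        len <- sample(25:40, 1L)
        s <- .random_dna(len)
      }
      if (o %in% c("pirna", "mirna", "blacklist") &&
          stats::runif(1) < sim$mismatch_frac) {
        s <- .mutate1(s)
        mut[i] <- TRUE
      }
      seqs[i] <- s; lens[i] <- len
      strands[i] <- if (minus) "-" else "+"
    }
    ids <- sprintf("%s_r%05d", group, seq_len(n))
    truth <- data.frame(read_id = ids, origin = origins, locus = loc,
                        length = lens, strand = strands, mutated = mut,
                        stringsAsFactors = FALSE)
    list(reads = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
         truth = truth)
  })
}
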
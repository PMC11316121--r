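---
title: "Methods: biallelic piRNA-pathway variant screening and piRNA length spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biallelic piRNA-pathway variant screening and piRNA length spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnascreen)
```

## Scope and model

PIWI-interacting RNAs (piRNAs) are 26–31 nt germline small RNAs required for
transposon silencing and spermatogenesis. Biallelic loss of piRNA-biogenesis
genes is an autosomal-recessive cause of severe spermatogenic failure in men.
`pirnascreen` implements, as testable components, the computational analyses
such a study rests on:

1. **cohort screen** — a filter cascade that turns annotated variant tables
   into biallelic high-impact candidates within a gene panel, plus a
   homozygous-LoF discovery lister and a secondary-findings exclusion screen;
2. **phasing** — cis/trans resolution of two heterozygous variants from trio
   genotypes or long-read fragment observations;
3. **GO over-representation** — a one-sided hypergeometric (Fisher exact)
   test per term with Bonferroni control;
4. **piRNA length spectra** — a small-RNA read-processing cascade
   (length filter, two-pass alignment, ncRNA blacklist subtraction, piRNA
   locus assignment) ending in a case/control comparison with Shapiro–Wilk
   and Mann–Whitney U statistics;
5. **seedable simulators** providing every input with planted truth, since
   the corresponding patient-level sequencing data are access-restricted;
6. **reporting** — parsing and summarising the packaged carrier table.

Upstream read alignment at genome scale, variant calling, VEP-style
annotation and population-frequency lookup are consumed as *input fields*,
never recomputed.

## The variant filter cascade

A variant allele qualifies for the panel screen when all of the following
hold:

* **rarity**: population allele frequency ≤ `max_maf` (default 0.01,
  inclusive). Alleles absent from the reference population pass by default
  (`missing_af_passes`), because a recessive-disease screen must retain
  alleles never observed in population databases. Both behaviours are
  configurable.
* **impact**: the consequence is a structural high-impact class
  (stop-gain, start-loss, splice acceptor/donor/region, frameshift, in-frame
  indel), or missense with CADD ≥ `cadd_min_panel` (default 15, inclusive).
* **biallelic state**: the patient is homozygous, or carries two distinct
  qualifying heterozygous variants in the same gene whose *trans*
  configuration is confirmed by phase evidence. Unconfirmed pairs are
  reported separately as "requires confirmation"; pairs with *cis* evidence
  are dropped.

The discovery arm lists genes with rare homozygous variants in a stricter
loss-of-function class set (stop-gain, start-loss, splice acceptor/donor,
frameshift — no splice-region or in-frame indels), restricted to
testis-preferential genes. The two class sets differ deliberately and are
both overridable in `screen_config()`.

The exclusion screen removes patients carrying an *additional* rare
homozygous LoF or missense (CADD ≥ 20) variant in any exclusion-panel gene,
so that a competing genetic diagnosis disqualifies the candidate.

Design choices where the underlying procedure was ambiguous:

* The rarity threshold is taken **inclusive** (≤ 0.01); an exact-boundary
  allele passes.
* Multi-transcript annotations collapse to the most severe consequence,
  ties broken by the lexicographically lowest transcript id. Real pipelines
  would use a canonical transcript; the collapse rule makes the behaviour
  deterministic when several rows are supplied.
* With more than two qualifying heterozygous variants in one gene, all
  unordered pairs are emitted and the patient is flagged for manual review —
  the screen does not guess which pair is real.
* Whether splice-region variants additionally require a CADD threshold is
  exposed as `splice_region_needs_cadd` (default off).
* Output ordering is fixed at (patient, gene, position) so outputs are
  byte-stable under a fixed seed.

## Phasing

`trio_phase()` enumerates every parental two-site haplotype configuration
consistent with the parents' genotypes and every no-de-novo transmission
producing a het/het child. If all consistent transmissions place the two
alternate alleles on different transmitted haplotypes the call is `trans`;
if all place them together it is `cis`; otherwise `ambiguous`. A child
alternate allele attributable to neither parent raises a Mendelian
inconsistency error rather than being silently absorbed. The test suite
checks all 81 parental genotype combinations against an independent
brute-force enumeration.

`read_phase()` tallies fragments covering both sites: `alt/alt` and
`ref/ref` support *cis*; `alt/ref` and `ref/alt` support *trans*. The
majority configuration is called when it has at least `min_support = 3`
fragments and the conflicting minority is at most
`max_conflict_fraction = 0.2` of informative fragments. No numeric evidence
thresholds exist in the underlying wet protocol; these defaults are
explicitly arbitrary, conservative, and configurable. Sequencing-error
fragments count toward conflict rather than being discarded.

## Term over-representation

For a query of `n` genes in a universe of `N`, a term annotating `K` genes
and overlapping the query in `k`, the one-sided over-representation p-value
is the hypergeometric upper tail `P(X >= k)`, computed in log space. The
Bonferroni factor `m` counts all terms with at least one annotated gene in
the universe (configurable to overlap-only), because the procedure being
modelled corrects over every tested term. The universe defaults to the union
of annotated genes; whether the original analysis used all human genes or
annotated genes only is unknowable from the text, so the universe is an
explicit input. Significance is strict (`p_adj < 0.05`). Semantic clustering
and hierarchy visualisation of terms are out of scope.

## The small-RNA cascade

Reads are assumed adapter-trimmed. The stages:

1. **length filter** — keep reads of 25–45 nt inclusive (discards ~22 nt
   miRNAs). "Between 25 and 45 bases" is taken inclusive.
2. **two-pass alignment** — pass 1 admits only perfect matches on either
   strand; reads unmapped in pass 1 are retried allowing exactly one
   substitution. Reads with several best placements are discarded as
   multi-mapping (default) or optionally assigned one placement at random
   (`multi = "random_one"`, seedable). Candidates are found via hashed
   k-mer anchors at the read start and the half-read offset — a one-mismatch
   placement must be exact over one half of the read — then verified base by
   base, so the procedure is exhaustively correct at toy-reference scale
   while staying fast. The test suite compares every placement against a
   naive full offset/strand scan.
3. **blacklist subtraction** — placements overlapping a known non-piRNA
   small-ncRNA interval by ≥ 1 base (half-open arithmetic, strand-agnostic)
   are removed. Strand-aware and full-containment variants are switchable;
   any-overlap/strand-agnostic is the default because the original
   intersection settings are unstated.
4. **locus assignment** — placements overlapping a piRNA locus by ≥ 1 base
   are assigned; a placement straddling two loci counts once toward the
   spectrum and once per locus in per-locus counts.
5. **length spectrum** — counts per read length over the 26–31 nt window,
   normalised to counts per million length-filter-retained reads by default
   (raw counts available). The y-axis units of the figure being modelled are
   unspecified; per-million is the field's convention.

`compare_case_control()` pools the per-sample, per-length normalised window
values into one value set per group, reports Shapiro–Wilk normality per
group, and compares groups with a two-sided Mann–Whitney U test. Normality
is reported as `NA` with a reason when a group has fewer than three values
or is constant (the rank test still runs); this keeps single-sample,
single-length comparisons well-defined.

### Statistics primitives

The three statistics are implemented in the package and cross-checked in
tests against independent references (`stats::phyper`/enumeration,
`stats::wilcox.test`/labeling enumeration, `stats::shapiro.test`):

* `hypergeom_tail()` — log-space upper tail.
* `mann_whitney_u()` — midrank U; exact p by full enumeration of
  `choose(n_a + n_b, n_a)` labelings when the pooled sample is ≤ 20 with no
  ties, else a normal approximation with tie and continuity corrections;
  two-sided p is twice the smaller tail, capped at 1.
* `shapiro_wilk()` — Royston's (1995) AS R94 approximation for weights and
  p-value, valid for 3 ≤ n ≤ 5000; constant samples are an error.

## What the simulators emulate — and what they do not

`simulate_cohort()` plants, per patient, one of: a qualifying homozygous
panel variant, a trans-confirmed compound heterozygote, a *cis* pair, a
single (monoallelic) het, or a homozygous candidate plus a secondary
exclusion-panel hit; every patient additionally carries decoys (a common
allele, a low-CADD missense, an off-panel LoF, a benign synonymous variant).
Planted effect sizes are deliberately strong — missense CADD is drawn from
20–35, well above the threshold — so that screen recovery is a sharp
correctness check (precision = recall = 1), not a power study. Weak-effect
exploration is possible by adjusting `sim_config()`.

`make_toy_genome()` builds a random reference (default 20 kb) with
non-overlapping labelled piRNA loci and blacklist intervals and two spike-in
sequences verified absent from both strands. `simulate_smallrna_sample()`
draws piRNA-locus reads with lengths weighted over 26–31 nt (weights 0.05,
0.10, 0.20, 0.30, 0.25, 0.10 — modal length 29, within the expected
28–31 nt pachytene peak), a 32–36 nt tail (8%), ~22 nt miRNA-like reads,
blacklist reads, spike-ins and unmappable junk; 10% of genome-derived reads
carry one substitution to exercise alignment pass 2. Case samples drop each
piRNA-locus read with probability `depletion` (default 0.9, matching a
near-complete loss of pachytene piRNAs).

The simulators do **not** emulate realistic human exome backgrounds, linkage
structure, sequencing-error profiles beyond single substitutions, locus
expression heterogeneity, or adapter artefacts. Passing tests therefore
demonstrate the *correctness of the procedures* on data with known truth,
not performance on real sequencing data; in particular, the headline
p-value of the original case/control comparison depends on
access-restricted data and exact per-sample pooling, and is reproduced as a
procedure, not as a number.

## Problem sizes and numerical choices

* Screen recovery runs at 200 patients × 10 seeds; each run takes about a
  second.
* The case/control power property uses 3 control vs 3 case samples at 300
  reads per sample on a 6 kb toy genome with 6 loci, 100 seeded replicates —
  the package's chosen demonstration scale, at which the planted 90%
  depletion is rejected at α = 0.05 in ≥ 95/100 replicates with large
  margin (typical per-replicate p ≈ 1e-4).
* All generators restore the session RNG state (`.Random.seed`) after use
  and are bit-reproducible given (config, seed).
* Interval arithmetic is half-open 0-based at the placement level and
  converted once to 1-based closed coordinates for `GenomicRanges`;
  abutting intervals do not overlap.
* Bonferroni adjustment is clamped at 1; `-log10(p_adj)` is reported for
  plotting parity.
* Degenerate inputs are errors, not guesses: empty groups in the rank test,
  constant samples in Shapiro–Wilk, genotype calls referencing unknown
  variants, query genes outside the universe.

## Known limitations

* The toy aligner allows substitutions only (no indels) and is intended for
  references of tens of kilobases; it is not a genome-scale aligner.
* Trio phasing covers two sites and assumes no de novo events at those
  sites, mirroring the inheritance arguments it models.
* The packaged 24-gene screening panel and the exclusion panel are synthetic
  stand-ins (the curated originals are not publicly redistributable);
  analyses of real cohorts should supply their own panels.
* The cohort summary computes counts exactly as printed in the packaged
  table; it does not attempt to reconcile cohort-size discrepancies in the
  narrative surrounding that table.
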
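#' Spectrum configuration
#'
#' Length bounds of the small-RNA cascade: reads are retained when their
#' length lies in `[keep_min, keep_max]` (inclusive; discards ~22 nt miRNAs),
#' and the piRNA length spectrum is tallied over `[window_min, window_max]`,
#' the expected pachytene piRNA range.
#'
#' @param keep_min,keep_max Inclusive retained-read length bounds (nt),
#'   defaults 25 and 45.
#' @param window_min,window_max Inclusive spectrum window (nt), defaults 26
#'   and 31.
#' @param normalization `"per_million_retained"` (counts per million reads
#'   retained by the length filter; default) or `"raw"`.
#' @return An object of class `spectrum_config`.
#' @export
spectrum_config <- function(keep_min = 25L, keep_max = 45L,
                            window_min = 26L, window_max = 31L,
                            normalization = c("per_million_retained", "raw")) {
  normalization <- match.arg(normalization)
  stopifnot(keep_min <= window_min, window_min <= window_max,
            window_max <= keep_max, keep_min > 0)
  structure(list(keep_min = as.integer(keep_min),
                 keep_max = as.integer(keep_max),
                 window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 normalization = normalization),
            class = "spectrum_config")
}

#' Length filter on small-RNA reads
#'
#' Retains reads whose length is within `[keep_min, keep_max]` inclusive.
#'
#' @param reads Character vector or `DNAStringSet`.
#' @param config A [spectrum_config()].
#' @return The retained subset, same type as the input.
#' @export
length_filter <- function(reads, config = spectrum_config()) {
  len <- if (methods::is(reads, "XStringSet")) Biostrings::width(reads)
         else nchar(reads)
  reads[len >= config$keep_min & len <= config$keep_max]
}

# placements data.frame (0-based half-open) -> GRanges
.placements_gr <- function(placements) {
  GenomicRanges::GRanges(
    seqnames = placements$chrom,
    ranges = IRanges::IRanges(start = placements$start + 1L,
                              end = placements$end),
    strand = if ("strand" %in% names(placements)) placements$strand else "*")
}

# intervals: GRanges, or data.frame with chrom/start/end (0-based half-open)
.intervals_gr <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x) && !all(is.na(x$strand)))
      x$strand else "*")
}

.overlap_hits <- function(placements, intervals, strand_aware, containment) {
  GenomicRanges::findOverlaps(
    .placements_gr(placements), .intervals_gr(intervals),
    type = if (containment) "within" else "any",
    minoverlap = 1L, ignore.strand = !strand_aware)
}

#' Remove placements overlapping known non-piRNA small ncRNAs
#'
#' Drops any placement overlapping a blacklist interval by at least one base
#' (half-open arithmetic: intervals that merely abut do not overlap).
#' Strand-agnostic by default.
#'
#' @param placements Placement data.frame from [two_pass_align()].
#' @param blacklist Blacklist intervals: a `GRanges` (e.g. from
#'   [read_bed()]) or data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param strand_aware Require matching strand? Default `FALSE`.
#' @param containment Remove only placements fully contained in a blacklist
#'   interval? Default `FALSE` (any overlap).
#' @return The retained placements.
#' @export
subtract_known_sncrna <- function(placements, blacklist,
                                  strand_aware = FALSE, containment = FALSE) {
  if (!nrow(placements)) return(placements)
  if (is.null(blacklist) ||
      (methods::is(blacklist, "GRanges") && !length(blacklist)) ||
      (is.data.frame(blacklist) && !nrow(blacklist)))
    return(placements)
  hits <- .overlap_hits(placements, blacklist, strand_aware, containment)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- placements[setdiff(seq_len(nrow(placements)), drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign placements to piRNA loci
#'
#' A placement is assigned when it overlaps at least one locus by one base.
#' A placement straddling several loci counts once toward the spectrum but
#' increments each overlapped locus's counter.
#'
#' @inheritParams subtract_known_sncrna
#' @param loci piRNA locus intervals (`GRanges` or 0-based half-open
#'   data.frame; names/labels used for the per-locus counts).
#' @return A list with `assigned` (the assigned placements) and
#'   `locus_counts` (named integer vector, one entry per locus).
#' @export
assign_to_pirna_loci <- function(placements, loci,
                                 strand_aware = FALSE, containment = FALSE) {
  gr <- .intervals_gr(loci)
  labels <- if (!is.null(names(gr))) names(gr)
            else if (!is.null(gr$name)) gr$name
            else paste0("locus", seq_along(gr))
  counts <- stats::setNames(integer(length(gr)), labels)
  if (!nrow(placements))
    return(list(assigned = placements, locus_counts = counts))
  hits <- .overlap_hits(placements, loci, strand_aware, containment)
  tab <- table(S4Vectors::subjectHits(hits))
  counts[as.integer(names(tab))] <- as.integer(tab)
  keep <- unique(S4Vectors::queryHits(hits))
  assigned <- placements[sort(keep), , drop = FALSE]
  rownames(assigned) <- NULL
  list(assigned = assigned, locus_counts = counts)
}

#' Tally a piRNA length spectrum
#'
#' Counts assigned placements per read length over the spectrum window
#' (lengths outside the window are excluded). Normalized values are counts
#' per million retained reads when the configuration asks for it.
#'
#' @param assigned Assigned placements (from [assign_to_pirna_loci()]).
#' @param config A [spectrum_config()].
#' @param sample_id Sample label.
#' @param group `"control"` or `"case"`.
#' @param denominator Retained-read count after the length filter (used for
#'   per-million normalization).
#' @return An object of class `length_spectrum`: list with `sample`, `group`,
#'   `counts` (named integer vector over the window), `normalized`,
#'   `denominator`.
#' @export
length_spectrum <- function(assigned, config = spectrum_config(),
                            sample_id = "sample", group = c("control", "case"),
                            denominator = NA_integer_) {
  group <- match.arg(group)
  lens <- config$window_min:config$window_max
  counts <- stats::setNames(integer(length(lens)), lens)
  if (nrow(assigned)) {
    rl <- assigned$end - assigned$start
    tab <- table(rl[rl >= config$window_min & rl <= config$window_max])
    counts[names(tab)] <- as.integer(tab)
  }
  normalized <- switch(config$normalization,
    raw = as.numeric(counts),
    per_million_retained = {
      if (is.na(denominator) || denominator <= 0)
        rep(NA_real_, length(counts))
      else as.numeric(counts) / denominator * 1e6
    })
  structure(list(sample = sample_id, group = group,
                 counts = counts,
                 normalized = stats::setNames(normalized, lens),
                 denominator = denominator),
            class = "length_spectrum")
}

#' @export
print.length_spectrum <- function(x, ...) {
  cat(sprintf("piRNA length spectrum: sample %s (%s), %d reads in window, denominator %s\n",
              x$sample, x$group, sum(x$counts),
              ifelse(is.na(x$denominator), "-", x$denominator)))
  print(x$counts)
  invisible(x)
}

#' Compare case and control piRNA length spectra
#'
#' Pools the per-sample, per-length normalized counts over the spectrum
#' window into one value set per group, assesses each group's normality with
#' the Shapiro-Wilk test, and compares the groups with a two-sided
#' Mann-Whitney U test. Normality is reported as `NA` (with a reason) when a
#' group has fewer than 3 values or is constant; the rank test runs
#' regardless.
#'
#' @param spectra A list of [length_spectrum()] objects, at least one per
#'   group.
#' @param config A [spectrum_config()]; its `normalization` selects raw or
#'   per-million values.
#' @return An object of class `group_comparison`: `U`, `p_two_sided`,
#'   `method`, `n_a`/`n_b` (control/case pooled value counts), `normality`
#'   (per-group `W`, `p` or `NA` + reason) and the pooled `values`.
#' @export
compare_case_control <- function(spectra, config = spectrum_config()) {
  groups <- vapply(spectra, function(s) s$group, character(1))
  if (!any(groups == "control") || !any(groups == "case"))
    stop("need at least one control and one case spectrum")
  vals <- function(g) {
    unlist(lapply(spectra[groups == g], function(s) {
      v <- if (config$normalization == "raw") as.numeric(s$counts)
           else s$normalized
      stats::setNames(v, paste(s$sample, names(s$counts), sep = ":"))
    }))
  }
  a <- vals("control"); b <- vals("case")
  norm_of <- function(x) {
    if (length(x) < 3L)
      return(list(W = NA_real_, p = NA_real_, reason = "n < 3"))
    if (max(x) - min(x) <= 0)
      return(list(W = NA_real_, p = NA_real_, reason = "constant sample"))
    c(shapiro_wilk(x)[c("W", "p")], list(reason = NA_character_))
  }
  mw <- mann_whitney_u(a, b)
  structure(list(U = mw$U, p_two_sided = mw$p_two_sided, method = mw$method,
                 n_a = mw$n_a, n_b = mw$n_b,
                 normality = list(control = norm_of(a), case = norm_of(b)),
                 values = list(control = a, case = b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Case/control comparison of piRNA length spectra\n")
  fmt_norm <- function(nm, v) {
    if (is.na(v$W)) sprintf("  Shapiro-Wilk (%s): not assessed (%s)\n", nm, v$reason)
    else sprintf("  Shapiro-Wilk (%s): W = %.4f, p = %.4g\n", nm, v$W, v$p)
  }
  cat(fmt_norm("control", x$normality$control))
  cat(fmt_norm("case", x$normality$case))
  cat(sprintf("  Mann-Whitney U = %g (n = %d vs %d, %s), two-sided p = %.6g\n",
              x$U, x$n_a, x$n_b, x$method, x$p_two_sided))
  invisible(x)
}

#' Spike-in quality control
#'
#' Counts raw reads exactly matching each expected spike-in sequence; the
#' library passes when every spike is seen at least `min_count` times. No
#' normalization is applied.
#'
#' @param reads Character vector or `DNAStringSet` of raw (trimmed) reads.
#' @param spikes Named character vector of expected spike-in sequences.
#' @param min_count Minimum count per spike (default 1).
#' @return A list with `pass` (logical) and `counts` (named integer vector).
#' @export
spikein_qc <- function(reads, spikes, min_count = 1L) {
  if (!length(spikes)) stop("expected spike sequences must be supplied")
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  counts <- vapply(spikes, function(s) sum(reads == s), integer(1))
  list(pass = all(counts >= min_count), counts = counts)
}

#' Run the full small-RNA spectrum cascade on one sample
#'
#' length filter -> two-pass alignment -> blacklist subtraction -> piRNA
#' locus assignment -> length spectrum, with per-stage read accounting.
#'
#' @param reads Raw (adapter-trimmed) reads, character or `DNAStringSet`.
#' @param reference Toy reference (`DNAStringSet` or named character).
#' @param loci,blacklist Interval sets (see [assign_to_pirna_loci()],
#'   [subtract_known_sncrna()]).
#' @param config A [spectrum_config()].
#' @param sample_id,group Labels for the resulting spectrum.
#' @param spikes Optional named spike sequences for [spikein_qc()].
#' @param strand_aware,containment Overlap switches, see
#'   [subtract_known_sncrna()].
#' @return A list with `spectrum`, `locus_counts`, `qc` (or `NULL`),
#'   `align_stats` and `stage_counts` (reads entering/leaving each stage).
#' @export
run_spectrum_pipeline <- function(reads, reference, loci, blacklist,
                                  config = spectrum_config(),
                                  sample_id = "sample",
                                  group = c("control", "case"),
                                  spikes = NULL,
                                  strand_aware = FALSE, containment = FALSE) {
  group <- match.arg(group)
  qc <- if (!is.null(spikes)) spikein_qc(reads, spikes) else NULL
  retained <- length_filter(reads, config)
  aln <- two_pass_align(retained, reference)
  kept <- subtract_known_sncrna(aln$placements, blacklist,
                                strand_aware, containment)
  asg <- assign_to_pirna_loci(kept, loci, strand_aware, containment)
  spec <- length_spectrum(asg$assigned, config, sample_id, group,
                          denominator = length(retained))
  list(spectrum = spec, locus_counts = asg$locus_counts, qc = qc,
       align_stats = aln$stats,
       stage_counts = c(n_input = length(reads),
                        n_retained = length(retained),
                        n_placed = nrow(aln$placements),
                        n_after_blacklist = nrow(kept),
                        n_assigned = nrow(asg$assigned)))
}

#' Read intervals from a BED file
#'
#' BED3+ (0-based half-open on disk); returned as a `GRanges` whose names are
#' the BED name column when present.
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write intervals to a BED file
#'
#' @param gr A `GRanges` (names become the BED name column).
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  if (!is.null(names(gr)) && is.null(gr$name)) gr$name <- names(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Qualities are ignored; format is inferred from the file extension
#' (`.fq`/`.fastq` = FASTQ, otherwise FASTA).
#'
#' @param path File path.
#' @return A `DNAStringSet`.
#' @export
read_smallrna_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Write reads to FASTQ (constant dummy qualities) or FASTA
#'
#' @param reads A `DNAStringSet` (named).
#' @param path Output path; extension selects the format as in
#'   [read_smallrna_reads()].
#' @export
write_smallrna_reads <- function(reads, path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  if (fmt == "fastq") {
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  vapply(Biostrings::width(reads),
                                         function(w) strrep("I", w),
                                         character(1))))
  } else {
    Biostrings::writeXStringSet(reads, path, format = "fasta")
  }
  invisible(path)
}
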
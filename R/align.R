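#' Two-pass toy-scale read alignment
#'
#' Places small-RNA reads on a toy reference the way a short-read aligner at
#' genome scale would: a first pass admitting only perfect matches, then a
#' second pass re-trying unmapped reads with at most one substitution
#' (no indels). Both strands are searched; minus-strand placements report
#' forward-strand coordinates of the reverse complement match. Reads with
#' more than one best placement are discarded as multi-mapping by default.
#' Coordinates are 0-based half-open.
#'
#' Candidate placements are located through hashed k-mer anchors at the read
#' start and at the half-read offset — a placement with at most one
#' substitution must match the reference exactly over one of the two read
#' halves, hence over one anchor — and verified base by base.
#'
#' @param reads Named character vector or `DNAStringSet` of read sequences
#'   over A/C/G/T. Reads with other symbols are skipped with a warning.
#' @param reference Named `DNAStringSet` (or named character vector) of
#'   reference sequences.
#' @param multi How to handle multi-mapping reads: `"discard"` (default) or
#'   `"random_one"` (keep one best placement chosen uniformly; seed the
#'   session RNG for reproducibility).
#' @return A list with `placements` (data.frame: `read_id`, `chrom`, `start`,
#'   `end`, `strand`, `mismatches`, `pass`) and `stats` (named integer
#'   vector: `n_input`, `n_skipped`, `n_pass1`, `n_pass2`, `n_multimapped`,
#'   `n_unmapped`).
#' @export
two_pass_align <- function(reads, reference, multi = c("discard", "random_one")) {
  multi <- match.arg(multi)
  if (!length(reference)) stop("reference must be non-empty")
  if (methods::is(reference, "DNAStringSet")) {
    nm <- names(reference)
    reference <- as.character(reference)
    names(reference) <- nm
  }
  if (is.null(names(reference)))
    names(reference) <- paste0("ref", seq_along(reference))
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)) && length(reads))
    names(reads) <- paste0("read", seq_along(reads))
  n_input <- length(reads)
  ok <- grepl("^[ACGT]+$", reads)
  if (any(!ok))
    warning(sum(!ok), " read(s) with non-ACGT symbols skipped")
  reads <- reads[ok]
  n_skipped <- n_input - length(reads)

  ref_int <- lapply(reference, utf8ToInt)
  ref_len <- vapply(reference, nchar, integer(1))

  # hashed k-mer index per (chromosome, k): kmer string -> start positions
  idx_cache <- new.env(parent = emptyenv())
  kmer_index <- function(ci, k) {
    key <- paste0(ci, "_", k)
    e <- idx_cache[[key]]
    if (!is.null(e)) return(e)
    n <- ref_len[ci]
    e <- new.env(hash = TRUE, parent = emptyenv())
    if (n >= k) {
      km <- substring(reference[[ci]], 1:(n - k + 1L), k:n)
      list2env(split(seq_len(n - k + 1L), km), envir = e)
    }
    idx_cache[[key]] <- e
    e
  }
  lookup <- function(ci, k, s) {
    v <- kmer_index(ci, k)[[s]]
    if (is.null(v)) integer(0) else v
  }

  rc_all <- if (length(reads))
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(unname(reads)))) else character(0)

  res_id <- character(0); res_chrom <- character(0)
  res_start <- integer(0); res_strand <- character(0)
  res_mm <- integer(0); res_pass <- integer(0); res_w <- integer(0)
  n_p1 <- 0L; n_p2 <- 0L; n_multi <- 0L; n_unmapped <- 0L

  for (i in seq_along(reads)) {
    w <- nchar(reads[[i]])
    w1 <- w %/% 2L
    k <- min(12L, w1)
    hit_chrom <- integer(0); hit_pos <- integer(0)
    hit_strand <- character(0); hit_mm <- integer(0)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") reads[[i]] else rc_all[[i]]
      qi <- utf8ToInt(q)
      for (ci in seq_along(reference)) {
        n <- ref_len[ci]
        if (n < w) next
        cand <- if (k >= 1L) {
          unique(c(lookup(ci, k, substr(q, 1L, k)),
                   lookup(ci, k, substr(q, w1 + 1L, w1 + k)) - w1))
        } else seq_len(n - w + 1L)     # degenerate 1 nt reads: full scan
        cand <- cand[cand >= 1L & cand + w - 1L <= n]
        for (p in cand) {
          mm <- sum(qi != ref_int[[ci]][p:(p + w - 1L)])
          if (mm <= 1L) {
            hit_chrom <- c(hit_chrom, ci); hit_pos <- c(hit_pos, p)
            hit_strand <- c(hit_strand, strand); hit_mm <- c(hit_mm, mm)
          }
        }
      }
    }
    best <- if (any(hit_mm == 0L)) 0L else 1L
    sel <- which(hit_mm == best)
    if (!length(sel)) { n_unmapped <- n_unmapped + 1L; next }
    if (length(sel) > 1L) {
      if (multi == "discard") { n_multi <- n_multi + 1L; next }
      sel <- sel[sample.int(length(sel), 1L)]
    }
    pass <- best + 1L
    if (pass == 1L) n_p1 <- n_p1 + 1L else n_p2 <- n_p2 + 1L
    res_id <- c(res_id, names(reads)[i])
    res_chrom <- c(res_chrom, names(reference)[hit_chrom[sel]])
    res_start <- c(res_start, hit_pos[sel] - 1L)
    res_strand <- c(res_strand, hit_strand[sel])
    res_mm <- c(res_mm, best)
    res_pass <- c(res_pass, pass)
    res_w <- c(res_w, w)
  }

  placements <- data.frame(
    read_id = res_id, chrom = res_chrom, start = res_start,
    end = res_start + res_w, strand = res_strand,
    mismatches = res_mm, pass = res_pass, stringsAsFactors = FALSE)
  list(placements = placements,
       stats = c(n_input = n_input, n_skipped = n_skipped,
                 n_pass1 = n_p1, n_pass2 = n_p2,
                 n_multimapped = n_multi, n_unmapped = n_unmapped))
}
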
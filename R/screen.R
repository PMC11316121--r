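#' Classify a variant's impact for the panel screen
#'
#' The panel screen admits two classes of alleles: structural high-impact
#' consequences (stop-gain, start-loss, splice site/region, frameshift and
#' in-frame indels), labelled `"lof"`, and missense variants at or above the
#' CADD threshold, labelled `"high_impact_missense"`. Everything else is
#' `"other"`. Thresholds are inclusive.
#'
#' @param consequence Consequence term(s) from [CONSEQUENCE_TERMS].
#' @param cadd CADD phred score(s); `NA` when unscored.
#' @param config A [screen_config()].
#' @return Character vector over `{"lof", "high_impact_missense", "other"}`.
#' @export
classify_impact <- function(consequence, cadd = NA_real_,
                            config = screen_config()) {
  .check_consequence(consequence)
  n <- max(length(consequence), length(cadd))
  consequence <- rep_len(consequence, n)
  cadd <- rep_len(as.numeric(cadd), n)
  out <- rep("other", n)
  structural <- consequence %in% config$high_impact_classes
  if (config$splice_region_needs_cadd) {
    sr <- consequence == "splice_region"
    structural[sr] <- !is.na(cadd[sr]) & cadd[sr] >= config$cadd_min_panel
  }
  out[structural] <- "lof"
  mis <- consequence == "missense_variant" &
    !is.na(cadd) & cadd >= config$cadd_min_panel
  out[mis] <- "high_impact_missense"
  out
}

#' Rarity filter on population allele frequency
#'
#' A variant passes when its population AF is at most `max_maf` (inclusive),
#' or when it is absent from the reference population (`NA`) and
#' `missing_af_passes` is set.
#'
#' @param pop_af Numeric vector of allele frequencies; `NA` = absent.
#' @param config A [screen_config()].
#' @return Logical vector.
#' @export
passes_rarity <- function(pop_af, config = screen_config()) {
  pop_af <- as.numeric(pop_af)
  bad <- !is.na(pop_af) & (pop_af < 0 | pop_af > 1)
  if (any(bad)) stop("pop_af outside [0, 1]")
  ifelse(is.na(pop_af), config$missing_af_passes, pop_af <= config$max_maf)
}

.empty_candidates <- function() {
  data.frame(patient = character(), gene = character(),
             allele1 = character(), allele2 = character(),
             diplotype = character(), phase = character(),
             evidence = character(), manual_review = logical(),
             stringsAsFactors = FALSE)
}

.lookup_phase <- function(phase_calls, patient, id_a, id_b) {
  if (is.null(phase_calls) || !nrow(phase_calls)) return(NULL)
  hit <- phase_calls$patient == patient &
    ((phase_calls$variant_a == id_a & phase_calls$variant_b == id_b) |
     (phase_calls$variant_a == id_b & phase_calls$variant_b == id_a))
  if (!any(hit)) return(NULL)
  phase_calls[which(hit)[1L], , drop = FALSE]
}

#' Resolve a patient-by-gene genotype set into a diplotype
#'
#' A homozygous alternate call is biallelic by itself. Two or more
#' heterozygous calls form candidate pairs whose phase is taken from the
#' supplied phase calls: `trans` evidence confirms a compound heterozygote,
#' `cis` rules the pair out, and absent/ambiguous evidence leaves the pair
#' `unphased` (requires confirmation). A single het is monoallelic. With more
#' than two qualifying hets all unordered pairs are emitted and the patient
#' is flagged for manual review.
#'
#' @param patient,gene Identifiers shared by all calls.
#' @param calls data.frame with `variant_id`, `zygosity` for this
#'   patient-gene.
#' @param phase_calls Optional data.frame with columns `patient`,
#'   `variant_a`, `variant_b`, `configuration` (`trans`/`cis`/`ambiguous`)
#'   and `evidence` (`trio`/`long_read`).
#' @return A list with `status` (`"candidate"`, `"monoallelic"` or `"none"`),
#'   `candidates` (confirmed biallelic rows) and `unphased` (het pairs
#'   lacking phase evidence).
#' @export
resolve_diplotype <- function(patient, gene, calls, phase_calls = NULL) {
  cand <- .empty_candidates()
  unph <- .empty_candidates()
  if (!nrow(calls))
    return(list(status = "none", candidates = cand, unphased = unph))
  hom <- calls$variant_id[calls$zygosity == "hom_alt"]
  het <- calls$variant_id[calls$zygosity == "het"]
  for (h in hom)
    cand[nrow(cand) + 1L, ] <- list(patient, gene, h, NA_character_,
                                    "homozygous", "homozygous", "none", FALSE)
  review <- length(het) > 2L
  if (length(het) >= 2L) {
    pairs <- utils::combn(sort(het), 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      pc <- .lookup_phase(phase_calls, patient, a, b)
      if (!is.null(pc) && pc$configuration == "trans") {
        cand[nrow(cand) + 1L, ] <- list(patient, gene, a, b, "compound_het",
                                        "trans_confirmed", pc$evidence, review)
      } else if (!is.null(pc) && pc$configuration == "cis") {
        # same haplotype: not biallelic, drop
      } else {
        unph[nrow(unph) + 1L, ] <- list(patient, gene, a, b, "compound_het",
                                        "unphased", "none", review)
      }
    }
  }
  status <- if (nrow(cand) || nrow(unph)) "candidate"
            else if (length(het) == 1L) "monoallelic" else "none"
  list(status = status, candidates = cand, unphased = unph)
}

.order_candidates <- function(df, variants) {
  if (!nrow(df)) return(df)
  pos <- variants$pos[match(df$allele1, variants$variant_id)]
  df <- df[order(df$patient, df$gene, pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Screen a cohort for biallelic high-impact variants in a gene panel
#'
#' The filter cascade: restrict to panel genes, keep alleles that pass the
#' rarity filter and classify as `lof` or `high_impact_missense`, then
#' resolve each patient-gene genotype set into a diplotype. Confirmed
#' biallelic candidates (homozygous, or compound het with trans phase
#' evidence) are returned in `candidates`; het pairs without phase evidence
#' are returned separately in `needs_confirmation`.
#'
#' @param variants A [variant_table()] (multi-transcript rows are collapsed
#'   to the most severe consequence first).
#' @param calls A [call_table()].
#' @param panel A [gene_panel()].
#' @param config A [screen_config()].
#' @param phase_calls Optional phase-call data.frame (see
#'   [resolve_diplotype()]).
#' @return A list with `candidates` and `needs_confirmation` data.frames,
#'   ordered by (patient, gene, position).
#' @export
screen_cohort <- function(variants, calls, panel, config = screen_config(),
                          phase_calls = NULL) {
  variants <- collapse_annotations(validate_variant_table(variants))
  missing_ids <- setdiff(calls$variant_id, variants$variant_id)
  if (length(missing_ids))
    stop("genotype call(s) reference unknown variant(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  idx <- match(calls$variant_id, variants$variant_id)
  gene <- variants$gene[idx]
  ok <- gene %in% panel$genes &
    passes_rarity(variants$pop_af[idx], config) &
    classify_impact(variants$consequence[idx], variants$cadd[idx],
                    config) != "other"
  qual <- calls[ok, , drop = FALSE]
  qual$gene <- gene[ok]
  cand <- list(.empty_candidates())
  unph <- list(.empty_candidates())
  if (nrow(qual)) {
    for (grp in split(qual, list(qual$patient, qual$gene), drop = TRUE)) {
      res <- resolve_diplotype(grp$patient[1L], grp$gene[1L], grp,
                               phase_calls)
      cand[[length(cand) + 1L]] <- res$candidates
      unph[[length(unph) + 1L]] <- res$unphased
    }
  }
  list(candidates = .order_candidates(do.call(rbind, cand), variants),
       needs_confirmation = .order_candidates(do.call(rbind, unph), variants))
}

#' Secondary-findings exclusion screen
#'
#' A patient is excluded when they carry an additional rare homozygous
#' high-impact variant (loss-of-function, or missense with CADD at or above
#' `cadd_min_exclusion`) in any exclusion panel gene.
#'
#' @param variants A [variant_table()].
#' @param calls A [call_table()] (any number of patients).
#' @param exclusion_panels A list of [gene_panel()]s.
#' @param config A [screen_config()].
#' @return data.frame with one row per patient in `calls`: `patient`,
#'   `decision` (`keep`/`exclude`) and `reasons` (semicolon-joined
#'   `panel:gene:variant` strings; empty when kept).
#' @export
exclusion_screen <- function(variants, calls, exclusion_panels,
                             config = screen_config()) {
  variants <- collapse_annotations(validate_variant_table(variants))
  if (inherits(exclusion_panels, "gene_panel"))
    exclusion_panels <- list(exclusion_panels)
  idx <- match(calls$variant_id, variants$variant_id)
  csq <- variants$consequence[idx]
  cadd <- variants$cadd[idx]
  harmful <- csq %in% config$lof_classes |
    (csq == "missense_variant" & !is.na(cadd) & cadd >= config$cadd_min_exclusion)
  hit <- calls$zygosity == "hom_alt" & harmful &
    passes_rarity(variants$pop_af[idx], config)
  patients <- sort(unique(calls$patient))
  reasons <- vapply(patients, function(p) {
    rs <- character()
    for (pan in exclusion_panels) {
      sel <- hit & calls$patient == p & variants$gene[idx] %in% pan$genes
      if (any(sel))
        rs <- c(rs, paste(pan$name, variants$gene[idx][sel],
                          calls$variant_id[sel], sep = ":"))
    }
    paste(rs, collapse = ";")
  }, character(1))
  data.frame(patient = patients,
             decision = ifelse(nzchar(reasons), "exclude", "keep"),
             reasons = reasons, stringsAsFactors = FALSE, row.names = NULL)
}

#' Discovery arm: genes with rare homozygous LoF variants in
#' testis-preferential genes
#'
#' Lists genes in which at least one patient carries a rare homozygous
#' variant whose consequence is in the discovery loss-of-function class set
#' (stop-gain, start-loss, splice acceptor/donor, frameshift), restricted to
#' genes preferentially expressed in the testis.
#'
#' @param variants A [variant_table()].
#' @param calls A [call_table()].
#' @param testis_preferential Character vector of testis-preferential gene
#'   symbols (non-empty).
#' @param config A [screen_config()].
#' @return Sorted character vector of unique gene symbols.
#' @export
discovery_lof_genes <- function(variants, calls, testis_preferential,
                                config = screen_config()) {
  if (!length(testis_preferential))
    stop("testis_preferential gene set must be non-empty")
  variants <- collapse_annotations(validate_variant_table(variants))
  idx <- match(calls$variant_id, variants$variant_id)
  keep <- calls$zygosity == "hom_alt" &
    passes_rarity(variants$pop_af[idx], config) &
    variants$consequence[idx] %in% config$lof_classes &
    variants$gene[idx] %in% testis_preferential
  sort(unique(variants$gene[idx][keep]))
}
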
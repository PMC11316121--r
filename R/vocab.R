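#' Consequence vocabulary and impact class sets
#'
#' Sequence-Ontology-style consequence terms recognised by the screen, and the
#' two class sets used by its two arms: the panel screen admits any
#' "high-impact structural" consequence (stop-gain, start-loss, splice
#' acceptor/donor/region, frameshift, in-frame indels) plus missense above a
#' CADD threshold, while the discovery arm (homozygous LoF lister) uses the
#' stricter loss-of-function set (stop-gain, start-loss, splice
#' acceptor/donor, frameshift).
#'
#' @format Character vectors of consequence terms.
#' @name consequence_vocabulary
NULL

#' @rdname consequence_vocabulary
#' @export
CONSEQUENCE_TERMS <- c(
  "stop_gained", "start_lost", "splice_acceptor", "splice_donor",
  "splice_region", "frameshift", "inframe_insertion", "inframe_deletion",
  "missense_variant", "synonymous_variant", "intron_variant",
  "utr_variant", "upstream_variant", "downstream_variant",
  "intergenic_variant", "stop_lost"
)

#' @rdname consequence_vocabulary
#' @export
PANEL_HIGH_IMPACT_CLASSES <- c(
  "stop_gained", "start_lost", "splice_acceptor", "splice_donor",
  "splice_region", "frameshift", "inframe_insertion", "inframe_deletion"
)

#' @rdname consequence_vocabulary
#' @export
DISCOVERY_LOF_CLASSES <- c(
  "stop_gained", "start_lost", "splice_acceptor", "splice_donor", "frameshift"
)

# severity ranking used to collapse multi-transcript annotations
# (most severe first; ties between transcripts broken on transcript id)
.CONSEQUENCE_SEVERITY <- c(
  "stop_gained", "frameshift", "start_lost", "stop_lost",
  "splice_acceptor", "splice_donor", "splice_region",
  "inframe_insertion", "inframe_deletion", "missense_variant",
  "synonymous_variant", "utr_variant", "intron_variant",
  "upstream_variant", "downstream_variant", "intergenic_variant"
)

#' Screening configuration
#'
#' Thresholds and class sets for the biallelic high-impact screen. The MAF
#' cut-off is inclusive (a variant at exactly `max_maf` passes) and variants
#' with no population frequency pass the rarity filter by default, matching a
#' screen that retains alleles absent from the reference population. CADD
#' thresholds are inclusive phred-scaled scores.
#'
#' @param max_maf Maximum population minor allele frequency (default 0.01).
#' @param cadd_min_panel Minimum CADD for missense in the panel screen
#'   (default 15).
#' @param cadd_min_exclusion Minimum CADD for missense in the
#'   secondary-findings exclusion screen (default 20).
#' @param lof_classes Consequence terms counted as loss-of-function in the
#'   discovery arm.
#' @param high_impact_classes Consequence terms admitted by the panel screen
#'   without a CADD requirement.
#' @param missing_af_passes Should a variant with no population AF pass the
#'   rarity filter? Default `TRUE`.
#' @param splice_region_needs_cadd Should splice_region variants additionally
#'   require `cadd >= cadd_min_panel`? Default `FALSE` (treated like the other
#'   structural classes).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(max_maf = 0.01,
                          cadd_min_panel = 15,
                          cadd_min_exclusion = 20,
                          lof_classes = DISCOVERY_LOF_CLASSES,
                          high_impact_classes = PANEL_HIGH_IMPACT_CLASSES,
                          missing_af_passes = TRUE,
                          splice_region_needs_cadd = FALSE) {
  stopifnot(is.numeric(max_maf), length(max_maf) == 1L,
            max_maf > 0, max_maf <= 1,
            is.numeric(cadd_min_panel), cadd_min_panel >= 0,
            is.numeric(cadd_min_exclusion), cadd_min_exclusion >= 0)
  if (!all(lof_classes %in% CONSEQUENCE_TERMS))
    stop("unknown consequence term(s) in lof_classes: ",
         paste(setdiff(lof_classes, CONSEQUENCE_TERMS), collapse = ", "))
  if (!all(high_impact_classes %in% CONSEQUENCE_TERMS))
    stop("unknown consequence term(s) in high_impact_classes: ",
         paste(setdiff(high_impact_classes, CONSEQUENCE_TERMS), collapse = ", "))
  structure(
    list(max_maf = max_maf,
         cadd_min_panel = cadd_min_panel,
         cadd_min_exclusion = cadd_min_exclusion,
         lof_classes = lof_classes,
         high_impact_classes = high_impact_classes,
         missing_af_passes = isTRUE(missing_af_passes),
         splice_region_needs_cadd = isTRUE(splice_region_needs_cadd)),
    class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Biallelic high-impact screen configuration\n")
  cat(sprintf("  max MAF (inclusive):        %g\n", x$max_maf))
  cat(sprintf("  CADD >= (panel missense):   %g\n", x$cadd_min_panel))
  cat(sprintf("  CADD >= (exclusion screen): %g\n", x$cadd_min_exclusion))
  cat(sprintf("  missing AF passes rarity:   %s\n", x$missing_af_passes))
  cat("  panel high-impact classes:  ",
      paste(x$high_impact_classes, collapse = ", "), "\n")
  cat("  discovery LoF classes:      ",
      paste(x$lof_classes, collapse = ", "), "\n")
  invisible(x)
}

.check_consequence <- function(consequence) {
  bad <- setdiff(unique(consequence), CONSEQUENCE_TERMS)
  if (length(bad))
    stop("unknown consequence term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(consequence)
}
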
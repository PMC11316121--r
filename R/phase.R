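#' Phase-call object
#'
#' @param configuration `"trans"`, `"cis"` or `"ambiguous"`.
#' @param n_trans,n_cis Numbers of supporting fragments (0 for trio calls).
#' @param evidence `"trio"` or `"long_read"`.
#' @return An object of class `phase_call`.
#' @export
phase_call <- function(configuration, n_trans = 0L, n_cis = 0L,
                       evidence = c("trio", "long_read")) {
  configuration <- match.arg(configuration, c("trans", "cis", "ambiguous"))
  structure(list(configuration = configuration,
                 n_trans = as.integer(n_trans), n_cis = as.integer(n_cis),
                 evidence = match.arg(evidence)),
            class = "phase_call")
}

#' @export
print.phase_call <- function(x, ...) {
  cat(sprintf("phase call: %s (evidence: %s", x$configuration, x$evidence))
  if (x$evidence == "long_read")
    cat(sprintf(", %d trans- / %d cis-consistent fragments",
                x$n_trans, x$n_cis))
  cat(")\n")
  invisible(x)
}

.ZYG <- c("ref_ref", "het", "hom_alt", "missing")

# allele multisets per genotype (0 = ref, 1 = alt); "missing" enumerates all
.genotype_alleles <- function(z) {
  switch(z,
         ref_ref = list(c(0L, 0L)),
         het = list(c(0L, 1L)),
         hom_alt = list(c(1L, 1L)),
         missing = list(c(0L, 0L), c(0L, 1L), c(1L, 1L)),
         stop("unknown zygosity: ", z))
}

# all two-site haplotype pairs (each haplotype = c(alleleA, alleleB))
# consistent with one parent's genotypes at A and B
.parent_haplotype_pairs <- function(zA, zB) {
  out <- list()
  for (aa in .genotype_alleles(zA)) for (bb in .genotype_alleles(zB)) {
    # two ways to couple the A alleles with the B alleles
    out[[length(out) + 1L]] <- list(c(aa[1L], bb[1L]), c(aa[2L], bb[2L]))
    out[[length(out) + 1L]] <- list(c(aa[1L], bb[2L]), c(aa[2L], bb[1L]))
  }
  out
}

#' Phase two heterozygous sites from trio genotypes
#'
#' Enumerates every parental haplotype configuration consistent with the
#' parents' genotypes at the two sites and every transmission (one haplotype
#' per parent, no de novo events) that yields a child heterozygous at both
#' sites. If all consistent transmissions place the two alternate alleles on
#' different transmitted haplotypes the configuration is `trans`; if all
#' place them on the same haplotype it is `cis`; otherwise (including missing
#' parental genotypes that leave both possible) it is `ambiguous`.
#'
#' @param trio A list/data.frame-like with genotypes
#'   `mother_a`, `mother_b`, `father_a`, `father_b`, each one of
#'   `"ref_ref"`, `"het"`, `"hom_alt"`, `"missing"`. The child is
#'   heterozygous at both sites by precondition.
#' @return A [phase_call()] with evidence `"trio"`.
#' @export
trio_phase <- function(trio) {
  z <- c(trio$mother_a, trio$mother_b, trio$father_a, trio$father_b)
  if (!all(z %in% .ZYG)) stop("genotypes must be one of: ",
                              paste(.ZYG, collapse = ", "))
  configs <- character()
  for (mh in .parent_haplotype_pairs(trio$mother_a, trio$mother_b)) {
    for (fh in .parent_haplotype_pairs(trio$father_a, trio$father_b)) {
      for (mi in 1:2) for (fi in 1:2) {
        hm <- mh[[mi]]; hf <- fh[[fi]]     # transmitted haplotypes
        if (hm[1L] + hf[1L] != 1L) next    # child het at A
        if (hm[2L] + hf[2L] != 1L) next    # child het at B
        same <- (hm[1L] == 1L && hm[2L] == 1L) ||
                (hf[1L] == 1L && hf[2L] == 1L)
        configs <- c(configs, if (same) "cis" else "trans")
      }
    }
  }
  configs <- unique(configs)
  if (!length(configs))
    stop("Mendelian inconsistency: no parental transmission explains a ",
         "het/het child under these parental genotypes")
  conf <- if (length(configs) == 1L) configs else "ambiguous"
  phase_call(conf, evidence = "trio")
}

#' Phase two heterozygous sites from long-read fragment observations
#'
#' Each fragment reports the allele it carries at the two sites. Fragments
#' covering both sites are tallied as cis-consistent (`alt/alt` or
#' `ref/ref`) or trans-consistent (`alt/ref` or `ref/alt`); fragments with a
#' missing allele at either site are dropped. The majority configuration is
#' called when its support reaches `min_support` fragments and the conflicting
#' fraction is at most `max_conflict_fraction`; otherwise the call is
#' `ambiguous`.
#'
#' @param fragments data.frame with columns `allele_a`, `allele_b`, each in
#'   `{"ref", "alt", "missing"}` (an optional `fragment` id column is
#'   ignored).
#' @param min_support Minimum fragments supporting the majority configuration
#'   (default 3).
#' @param max_conflict_fraction Maximum fraction of informative fragments
#'   supporting the minority configuration (default 0.2).
#' @return A [phase_call()] with evidence `"long_read"`.
#' @export
read_phase <- function(fragments, min_support = 3L,
                       max_conflict_fraction = 0.2) {
  if (is.null(fragments) || !nrow(fragments))
    return(phase_call("ambiguous", 0L, 0L, "long_read"))
  a <- fragments$allele_a
  b <- fragments$allele_b
  ok <- a %in% c("ref", "alt") & b %in% c("ref", "alt")
  a <- a[ok]; b <- b[ok]
  n_cis <- sum(a == b)
  n_trans <- sum(a != b)
  total <- n_cis + n_trans
  conf <- "ambiguous"
  if (total > 0L && n_trans != n_cis) {
    maj <- max(n_trans, n_cis)
    if (maj >= min_support && (total - maj) / total <= max_conflict_fraction)
      conf <- if (n_trans > n_cis) "trans" else "cis"
  }
  phase_call(conf, n_trans, n_cis, "long_read")
}

#' Read trio genotypes from TSV
#'
#' Expected columns: `person` (`child`/`mother`/`father`), `site` (`A`/`B`),
#' `genotype` (`ref_ref`/`het`/`hom_alt`/`missing`).
#'
#' @param path TSV file path.
#' @return A list usable by [trio_phase()] (child genotypes included and
#'   checked to be het at both sites).
#' @export
read_trio_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  get <- function(person, site) {
    v <- df$genotype[df$person == person & df$site == site]
    if (length(v) != 1L) "missing" else v
  }
  if (get("child", "A") != "het" || get("child", "B") != "het")
    stop("trio phasing requires a child heterozygous at both sites")
  list(mother_a = get("mother", "A"), mother_b = get("mother", "B"),
       father_a = get("father", "A"), father_b = get("father", "B"))
}

#' Read fragment allele observations from TSV
#'
#' Expected columns: `fragment`, `allele_a`, `allele_b` with alleles in
#' `{"ref", "alt", "missing"}`.
#'
#' @param path TSV file path.
#' @return data.frame usable by [read_phase()].
#' @export
read_fragments_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  bad <- !(df$allele_a %in% c("ref", "alt", "missing")) |
         !(df$allele_b %in% c("ref", "alt", "missing"))
  if (any(bad)) stop("fragment alleles must be ref/alt/missing")
  if (any(df$allele_a == "missing" & df$allele_b == "missing"))
    stop("fragments must carry at least one observed allele")
  df
}
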
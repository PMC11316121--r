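.SEMEN_TOKENS <- c(Azoo = "azoo", Crypto = "crypto", ExtOligo = "extoligo",
                   SevOligo = "sevoligo")
.HISTOLOGY_TOKENS <- c(SCO = "SCO", SpgA = "SpgA", MeiA = "MeiA",
                       RsA = "RsA", `ES+` = "ESplus")

# normalize a c.-notation allele: strip whitespace and a leading "c." prefix
.norm_cnot <- function(x) sub("^c\\.", "", gsub("[[:space:]]+", "", x))

.split_genotype <- function(g, row_label) {
  m <- regmatches(g, regexec("^\\s*\\[(.+?)\\]\\s*;\\s*\\[(.+?)\\]\\s*$", g))[[1L]]
  if (length(m) != 3L)
    stop("malformed genotype string in row ", row_label, ": ", g)
  .norm_cnot(m[2:3])
}

.parse_phenotype <- function(s) {
  out <- list(semen = "unknown", histology = "unknown", tese = "not_done")
  tokens <- trimws(strsplit(s, "[;,]")[[1L]])
  for (tok in tokens) {
    if (!nzchar(tok)) next
    if (grepl("TESE", tok)) {
      out$tese <- if (grepl("negative", tok, ignore.case = TRUE))
        "negative" else "positive"
      tok <- trimws(gsub("(positive|negative)\\s*TESE", "", tok,
                         ignore.case = TRUE))
      if (!nzchar(tok)) next
    }
    if (tok %in% names(.SEMEN_TOKENS)) out$semen <- .SEMEN_TOKENS[[tok]]
    else if (tok %in% names(.HISTOLOGY_TOKENS))
      out$histology <- .HISTOLOGY_TOKENS[[tok]]
  }
  out
}

#' Parse a cohort variant-carrier table
#'
#' Reads the documented cohort TSV layout (columns `id`, `gene`,
#' `variant_c`, `variant_p`, `phenotype`; `#` comment lines skipped). The
#' genotype string `"[x];[y]"` is split into two alleles, with whitespace and
#' a redundant `c.` prefix normalized away; the phenotype string is split on
#' `;`/`,` into semen phenotype, histology and TESE tokens.
#'
#' @param path TSV file path.
#' @return A data.frame of class `cohort_records`, one row per patient:
#'   `id`, `gene`, `allele1`, `allele2`, `protein1`, `protein2`,
#'   `semen_phenotype`, `histology`, `tese`, `phenotype_raw`.
#' @export
parse_cohort_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "gene", "variant_c", "variant_p", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    out <- data.frame(id = character(), gene = character(),
                      allele1 = character(), allele2 = character(),
                      protein1 = character(), protein2 = character(),
                      semen_phenotype = character(), histology = character(),
                      tese = character(), phenotype_raw = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cohort_records", class(out))
    return(out)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    al <- .split_genotype(df$variant_c[i], df$id[i])
    pr <- tryCatch(.split_genotype(df$variant_p[i], df$id[i]),
                   error = function(e) c(NA_character_, NA_character_))
    ph <- .parse_phenotype(df$phenotype[i])
    data.frame(id = df$id[i], gene = df$gene[i],
               allele1 = al[1L], allele2 = al[2L],
               protein1 = pr[1L], protein2 = pr[2L],
               semen_phenotype = ph$semen, histology = ph$histology,
               tese = ph$tese, phenotype_raw = df$phenotype[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_records", class(out))
  out
}

#' Serialize parsed cohort records back to the table layout
#'
#' Inverse of [parse_cohort_table()] modulo whitespace normalization:
#' re-parsing the output reproduces the records.
#'
#' @param records A `cohort_records` data.frame.
#' @param path Optional output TSV path; when `NULL` the data.frame is
#'   returned instead.
#' @return The serialized data.frame (invisibly when written to `path`).
#' @export
format_cohort_table <- function(records, path = NULL) {
  df <- data.frame(
    id = records$id, gene = records$gene,
    variant_c = sprintf("[%s];[%s]", records$allele1, records$allele2),
    variant_p = ifelse(is.na(records$protein1), "[.];[.]",
                       sprintf("[%s];[%s]", records$protein1,
                               records$protein2)),
    phenotype = records$phenotype_raw, stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Summarize a cohort table
#'
#' Computes the headline counts of a biallelic variant-carrier table:
#' patients, distinct genes, distinct (gene, c.-notation) variants across
#' both alleles, homozygous vs compound-heterozygous rows, semen-phenotype
#' and histology tallies, and per-gene carrier counts.
#'
#' @param records Output of [parse_cohort_table()].
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  alleles <- rbind(data.frame(gene = records$gene, cnot = records$allele1),
                   data.frame(gene = records$gene, cnot = records$allele2))
  distinct <- unique(alleles)
  semen_levels <- c(unname(.SEMEN_TOKENS), "unknown")
  hist_levels <- c(unname(.HISTOLOGY_TOKENS), "unknown")
  structure(list(
    n_patients = nrow(records),
    n_genes = length(unique(records$gene)),
    n_distinct_variants = nrow(distinct),
    n_homozygous = sum(records$allele1 == records$allele2),
    n_compound_het = sum(records$allele1 != records$allele2),
    semen_counts = vapply(semen_levels,
                          function(l) sum(records$semen_phenotype == l),
                          integer(1)),
    histology_counts = vapply(hist_levels,
                              function(l) sum(records$histology == l),
                              integer(1)),
    gene_carriers = if (nrow(records))
      sort(table(records$gene), decreasing = TRUE) else table(character(0))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  patients:                 %d\n", x$n_patients))
  cat(sprintf("  genes:                    %d\n", x$n_genes))
  cat(sprintf("  distinct (gene, c.) vars: %d\n", x$n_distinct_variants))
  cat(sprintf("  homozygous rows:          %d\n", x$n_homozygous))
  cat(sprintf("  compound-het rows:        %d\n", x$n_compound_het))
  cat("  semen phenotypes:\n")
  for (nm in names(x$semen_counts))
    if (x$semen_counts[[nm]] > 0)
      cat(sprintf("    %-9s %d\n", nm, x$semen_counts[[nm]]))
  cat("  histology:\n")
  for (nm in names(x$histology_counts))
    if (x$histology_counts[[nm]] > 0)
      cat(sprintf("    %-9s %d\n", nm, x$histology_counts[[nm]]))
  cat("  carriers per gene:\n")
  for (nm in names(x$gene_carriers))
    cat(sprintf("    %-9s %d\n", nm, x$gene_carriers[[nm]]))
  invisible(x)
}

#' Path to the packaged cohort table
#'
#' The packaged transcription of the published table of biallelic
#' piRNA-pathway variant carriers.
#'
#' @return File path inside the installed package.
#' @export
cohort_table_path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "pirnascreen",
              mustWork = TRUE)
}
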
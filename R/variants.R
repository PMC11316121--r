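#' Build a validated annotated-variant table
#'
#' One row per alternate allele of one variant, carrying the annotation fields
#' the screen consumes: gene symbol, consequence term, population allele
#' frequency (`NA` when the allele is absent from the reference population)
#' and CADD phred score (`NA` when unscored). A `variant_id` key
#' (`chrom:pos:ref:alt`) is derived and used by genotype calls.
#'
#' @param chrom,pos,ref,alt Coordinates and alleles; `pos` is 1-based.
#' @param gene Gene symbol.
#' @param consequence Consequence term from [CONSEQUENCE_TERMS].
#' @param pop_af Population allele frequency in `[0, 1]`, or `NA`.
#' @param cadd Non-negative CADD phred score, or `NA`.
#' @param transcript,cdna,protein Optional annotation strings.
#' @return A `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gene, consequence,
                          pop_af = NA_real_, cadd = NA_real_,
                          transcript = NA_character_,
                          cdna = NA_character_, protein = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), transcript = as.character(transcript),
    cdna = as.character(cdna), protein = as.character(protein),
    consequence = as.character(consequence),
    pop_af = as.numeric(pop_af), cadd = as.numeric(cadd),
    stringsAsFactors = FALSE)
  df$variant_id <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  validate_variant_table(df)
}

#' @rdname variant_table
#' @param df A data.frame with the `variant_table` columns.
#' @export
validate_variant_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "pop_af", "cadd", "variant_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  bad_af <- !is.na(df$pop_af) & (df$pop_af < 0 | df$pop_af > 1)
  if (any(bad_af)) stop("pop_af outside [0, 1] for variant(s): ",
                        paste(df$variant_id[bad_af], collapse = ", "))
  if (any(!is.na(df$cadd) & df$cadd < 0)) stop("cadd must be non-negative")
  .check_consequence(df$consequence)
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Build a genotype-call table
#'
#' One row per (patient, variant) observation, with zygosity `het` or
#' `hom_alt`.
#'
#' @param patient Patient identifiers.
#' @param variant_id Keys into a [variant_table()].
#' @param zygosity `"het"` or `"hom_alt"`.
#' @return A `data.frame` with class `call_table`.
#' @export
call_table <- function(patient, variant_id, zygosity) {
  df <- data.frame(patient = as.character(patient),
                   variant_id = as.character(variant_id),
                   zygosity = as.character(zygosity),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$zygosity), c("het", "hom_alt"))
  if (length(bad)) stop("unknown zygosity value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[c("patient", "variant_id")]))
    stop("duplicate (patient, variant) genotype calls")
  class(df) <- unique(c("call_table", class(df)))
  df
}

#' Collapse multi-transcript annotations to one row per variant
#'
#' When a variant carries one annotation row per transcript, keep the most
#' severe consequence; ties are broken by the lexicographically lowest
#' transcript identifier.
#'
#' @param variants A [variant_table()] possibly containing several rows with
#'   the same `variant_id`.
#' @return A `variant_table` with unique `variant_id`s.
#' @export
collapse_annotations <- function(variants) {
  sev <- match(variants$consequence, .CONSEQUENCE_SEVERITY)
  tx <- ifelse(is.na(variants$transcript), "~", variants$transcript)
  ord <- order(variants$variant_id, sev, tx)
  v <- variants[ord, , drop = FALSE]
  v <- v[!duplicated(v$variant_id), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Read variants and genotype calls from a TSV file
#'
#' The documented tabular exchange format: one row per (patient, allele) with
#' columns `patient, chrom, pos, ref, alt, gene, transcript, cdna, protein,
#' consequence, pop_af, cadd, zygosity`. Empty strings and `.` in `pop_af` /
#' `cadd` are read as missing.
#'
#' @param path TSV file path (`#` comment lines are skipped).
#' @return A list with elements `variants` ([variant_table()]) and `calls`
#'   ([call_table()]).
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  num <- function(x) {
    x[x %in% c("", ".", "NA")] <- NA
    as.numeric(x)
  }
  variants <- variant_table(
    chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
    gene = df$gene, consequence = df$consequence,
    pop_af = num(df$pop_af), cadd = num(df$cadd),
    transcript = if ("transcript" %in% names(df)) df$transcript else NA,
    cdna = if ("cdna" %in% names(df)) df$cdna else NA,
    protein = if ("protein" %in% names(df)) df$protein else NA)
  variants <- variants[!duplicated(variants$variant_id), , drop = FALSE]
  calls <- call_table(df$patient,
                      paste(df$chrom, as.integer(df$pos), df$ref, df$alt,
                            sep = ":"),
                      df$zygosity)
  calls <- calls[!duplicated(calls[c("patient", "variant_id")]), , drop = FALSE]
  list(variants = validate_variant_table(variants), calls = calls)
}

#' Read variants and single-sample genotypes from a minimal VCF
#'
#' Accepts the minimal VCF v4.2 dialect with one sample, a `GT` FORMAT field
#' and INFO keys `GENE`, `CSQ` (consequence term), `AF_POP` and `CADD`.
#' Requires the VariantAnnotation package.
#'
#' @param path VCF file path.
#' @param patient Patient id to assign; defaults to the sample name in the
#'   VCF header.
#' @return As [read_variant_tsv()].
#' @export
read_variant_vcf <- function(path, patient = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_variant_vcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  if (is.null(patient)) patient <- colnames(vcf)[1L]
  unlist1 <- function(x) vapply(x, function(e)
    if (length(e)) as.character(e[[1L]]) else NA_character_, character(1))
  af <- info$AF_POP
  cadd <- info$CADD
  if (is.list(af) || methods::is(af, "List"))
    af <- vapply(af, function(e) if (length(e)) as.numeric(e[[1L]]) else NA_real_,
                 numeric(1))
  if (is.list(cadd) || methods::is(cadd, "List"))
    cadd <- vapply(cadd, function(e) if (length(e)) as.numeric(e[[1L]]) else NA_real_,
                   numeric(1))
  variants <- variant_table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a[[1L]]), character(1)),
    gene = if (is.list(info$GENE)) unlist1(info$GENE) else as.character(info$GENE),
    consequence = if (is.list(info$CSQ)) unlist1(info$CSQ) else as.character(info$CSQ),
    pop_af = as.numeric(af), cadd = as.numeric(cadd))
  zyg <- ifelse(gt %in% c("1/1", "1|1"), "hom_alt",
         ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"), "het", NA))
  keep <- !is.na(zyg)
  list(variants = variants[keep, , drop = FALSE],
       calls = call_table(patient, variants$variant_id[keep], zyg[keep]))
}

#' Read a gene panel from a one-symbol-per-line text file
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @param name Panel label (defaults to the file name).
#' @return A list with `name` and the unique, sorted `genes`.
#' @export
read_gene_panel <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- unique(lines[nzchar(lines)])
  if (!length(genes)) stop("gene panel is empty: ", path)
  gene_panel(if (is.null(name)) basename(path) else name, genes)
}

#' @rdname read_gene_panel
#' @param genes Character vector of gene symbols.
#' @export
gene_panel <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene panel symbols must be unique")
  structure(list(name = name, genes = sort(genes)), class = "gene_panel")
}
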
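#' Read term annotations from a two-column TSV
#'
#' Format: `term_id <TAB> gene` with an optional third column `term_name`.
#' Lines starting with `#` are skipped.
#'
#' @param path TSV file path.
#' @return A list with `terms` (named list of character gene vectors) and
#'   `names` (named character vector of term names, possibly empty).
#' @export
read_term_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation file needs at least two columns")
  terms <- lapply(split(df[[2L]], df[[1L]]), unique)
  nm <- character(0)
  if (ncol(df) >= 3L) {
    nm <- tapply(df[[3L]], df[[1L]], function(x) x[1L])
    nm <- stats::setNames(as.character(nm), names(nm))
  }
  list(terms = terms, names = nm)
}

#' Term over-representation with Bonferroni control
#'
#' For each annotation term, tests whether the query gene set overlaps the
#' term's gene set more than expected under hypergeometric sampling from the
#' universe (one-sided Fisher exact test), then applies Bonferroni correction
#' over the number of tested terms.
#'
#' @param query Character vector of query genes (must be a subset of the
#'   universe).
#' @param annotations Named list mapping term id to a character vector of
#'   annotated genes, or the result of [read_term_annotations()].
#' @param universe Character vector of universe genes. Defaults to the union
#'   of all annotated genes.
#' @param alpha Significance level on the adjusted p (strict `<`), default
#'   0.05.
#' @param correct_over Which terms count toward the Bonferroni factor `m`:
#'   `"annotated"` (all terms with at least one annotated gene in the
#'   universe; default) or `"overlapping"` (terms with overlap k >= 1).
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   term, sorted by (adjusted p, term id), with columns `term`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`, `significant`, `neg_log10_adj`.
#' @export
enrich <- function(query, annotations, universe = NULL, alpha = 0.05,
                   correct_over = c("annotated", "overlapping")) {
  correct_over <- match.arg(correct_over)
  if (is.list(annotations) && !is.null(annotations$terms))
    annotations <- annotations$terms
  if (is.null(universe))
    universe <- unique(unlist(annotations, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(as.character(query))
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  ann <- lapply(annotations, function(g) intersect(unique(g), universe))
  Kv <- vapply(ann, length, integer(1))
  ann <- ann[Kv >= 1L]
  kv <- vapply(ann, function(g) length(intersect(g, query)), integer(1))
  if (correct_over == "overlapping") {
    ann <- ann[kv >= 1L]
    kv <- kv[kv >= 1L]
  }
  m <- length(ann)
  if (!m)
    return(structure(data.frame(term = character(), k = integer(),
                                K = integer(), n = integer(), N = integer(),
                                p = numeric(), p_adj = numeric(),
                                significant = logical(),
                                neg_log10_adj = numeric()),
                     class = c("enrichment_result", "data.frame")))
  Kv <- vapply(ann, length, integer(1))
  p <- mapply(function(k, K) hypergeom_tail(k, K, n, N), kv, Kv)
  p_adj <- pmin(1, m * p)
  res <- data.frame(term = names(ann), k = as.integer(kv), K = as.integer(Kv),
                    n = n, N = N, p = p, p_adj = p_adj,
                    significant = p_adj < alpha,
                    neg_log10_adj = -log10(p_adj),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_adj, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Term over-representation: %d term(s) tested, query n = %s, universe N = %s\n",
              nrow(x), if (nrow(x)) x$n[1L] else "-",
              if (nrow(x)) x$N[1L] else "-"))
  NextMethod()
}
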
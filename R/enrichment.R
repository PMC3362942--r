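## Hypergeometric over-representation of gene sets against a GO-style
## annotation table.

#' Load an annotation table
#'
#' Builds a term -> gene-set annotation from a two-column mapping
#' (gene, term_id). Terms annotating fewer than `min_genes` genes are
#' discarded at load time (default 2).
#'
#' @param mapping data.frame (or TSV path) with columns `gene` and
#'   `term_id`.
#' @param term_names Optional data.frame (`term_id`, `term_name`).
#' @param min_genes Minimum genes per retained term (default 2).
#' @return List of class `AnnotationTable`: `terms` (named list of gene
#'   vectors), `term_names` (named character).
#' @export
readAnnotation <- function(mapping, term_names = NULL, min_genes = 2L) {
  if (is.character(mapping))
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term_id") %in% names(mapping)))
  terms <- lapply(split(mapping$gene, mapping$term_id), unique)
  terms <- terms[vapply(terms, length, 1L) >= min_genes]
  nm <- setNames(character(0), character(0))
  if (!is.null(term_names)) {
    if (is.character(term_names))
      term_names <- utils::read.delim(term_names, stringsAsFactors = FALSE)
    nm <- setNames(term_names$term_name, term_names$term_id)
  }
  structure(list(terms = terms, term_names = nm),
            class = "AnnotationTable")
}

#' Hypergeometric over-representation test
#'
#' For every annotation term, the upper-tail hypergeometric probability of
#' observing at least the seen overlap when drawing `|gene_set|` genes
#' from the universe, with the term's genes (intersected with the
#' universe) as successes. One-sided over-representation only; no
#' multiple-testing correction is applied by default (an optional
#' Bonferroni/BH adjustment can be requested).
#'
#' @param gene_set Character vector of genes of interest (must lie inside
#'   `universe`).
#' @param annotation An `AnnotationTable` from [readAnnotation()].
#' @param universe Character vector of all testable genes (e.g. every
#'   gene on the expression matrix).
#' @param alpha Significance level for the `enriched` flag (default 0.01).
#' @param adjust P-value adjustment method (default `"none"`).
#' @return data.frame: `term_id`, `term_name`, `set_count`, `term_count`,
#'   `overlap`, `p`, `enriched`.
#' @examples
#' ann <- readAnnotation(data.frame(gene = c("g1", "g2", "g3"),
#'                                  term_id = "T1"))
#' hypergeomEnrich(c("g1", "g2"), ann, paste0("g", 1:10))
#' @export
hypergeomEnrich <- function(gene_set, annotation, universe, alpha = 0.01,
                            adjust = "none") {
  stopifnot(inherits(annotation, "AnnotationTable"))
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!length(universe)) stop("empty universe")
  if (!length(gene_set)) stop("empty gene set")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(annotation$terms), function(tid) {
    term_genes <- intersect(annotation$terms[[tid]], universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, gene_set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = if (tid %in% names(annotation$term_names))
                 annotation$term_names[[tid]] else NA_character_,
               set_count = n, term_count = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$enriched <- out$p_adj < alpha
  rownames(out) <- NULL
  out[order(out$p), ]
}
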
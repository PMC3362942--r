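## Tab-separated interchange formats: genotype + map, expression + sample
## metadata, strain lifespans.

#' Write / read a GenotypePanel as TSV
#'
#' Genotypes are written strains x markers (values -1/1, first column
#' `strain`); the map as (`marker`, `chromosome`, `position_cM`).
#'
#' @param panel A [GenotypePanel-class].
#' @param geno_file,map_file Output/input paths.
#' @param parents Character(2) for reading: +1-coded then -1-coded parent.
#' @return `writeGenotypePanel` the paths (invisibly);
#'   `readGenotypePanel` a `GenotypePanel`.
#' @export
writeGenotypePanel <- function(panel, geno_file, map_file) {
  al <- alleles(panel)
  df <- data.frame(strain = rownames(al), al, check.names = FALSE)
  utils::write.table(df, geno_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(geneticMapOf(panel), map_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(geno_file, map_file))
}

#' @rdname writeGenotypePanel
#' @export
readGenotypePanel <- function(geno_file, map_file,
                              parents = c("N2", "CB4856")) {
  g <- utils::read.delim(geno_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  map <- utils::read.delim(map_file, stringsAsFactors = FALSE)
  al <- as.matrix(g[, -1L, drop = FALSE])
  rownames(al) <- g$strain
  GenotypePanel(al, geneticMap(map$marker, map$chromosome,
                               map$position_cM), parents = parents)
}

#' Write / read an ExpressionStudy as TSV
#'
#' Expression is written genes x samples (first column `gene`); sample
#' metadata as (`sample_id`, `strain`, `age_hours`, `age_group`,
#' `replicate`, `is_parent`). Masked values are written as `NA`.
#'
#' @param study An [ExpressionStudy-class].
#' @param expr_file,meta_file Output/input paths.
#' @param lifespans Optional lifespan data.frame (or TSV path) used to
#'   recompute physiological age when reading.
#' @return `writeExpressionStudy` the paths (invisibly);
#'   `readExpressionStudy` an `ExpressionStudy`.
#' @export
writeExpressionStudy <- function(study, expr_file, meta_file) {
  e <- exprMatrix(study)
  utils::write.table(data.frame(gene = rownames(e), e, check.names = FALSE),
                     expr_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  info <- sampleInfo(study)
  info$sample_id <- rownames(info)
  cols <- c("sample_id", "strain", "age_hours", "age_group", "replicate",
            "is_parent")
  utils::write.table(info[, cols], meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_file, meta_file))
}

#' @rdname writeExpressionStudy
#' @export
readExpressionStudy <- function(expr_file, meta_file, lifespans = NULL) {
  e <- utils::read.delim(expr_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  expr <- as.matrix(e[, -1L, drop = FALSE])
  rownames(expr) <- e$gene
  info <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  rownames(info) <- info$sample_id
  info <- info[colnames(expr), ]
  if (is.character(lifespans)) lifespans <- readLifespans(lifespans)
  mask <- !is.na(expr)
  ExpressionStudy(expr, info, lifespans = lifespans, mask = mask)
}

#' Read / write a strain lifespan table (TSV: strain, mean_lifespan_hours)
#'
#' @param file Path.
#' @param lifespans data.frame with `strain` and `mean_lifespan_hours`.
#' @return data.frame / the path (invisibly).
#' @export
readLifespans <- function(file) {
  ls <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "mean_lifespan_hours") %in% names(ls)))
  if (anyDuplicated(ls$strain)) stop("strains must be unique")
  if (any(ls$mean_lifespan_hours <= 0)) stop("lifespans must be positive")
  ls
}

#' @rdname readLifespans
#' @export
writeLifespans <- function(lifespans, file) {
  utils::write.table(lifespans, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
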
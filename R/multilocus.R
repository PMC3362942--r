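## Forward/backward stepwise selection with BIC over a reduced marker set,
## all pairwise marker interactions, physiological age and marker x age
## products. BIC = n*log(RSS/n) + k*log(n) with k counting every
## coefficient including the intercept.

#' Select spread-out candidate markers for multi-locus modelling
#'
#' Per chromosome, picks `per_chrom` markers maximizing the minimum
#' pairwise genetic distance (exhaustive search over combinations;
#' deterministic, ties broken by the lexicographically smallest position
#' vector, then marker id). With the default 4 per chromosome on a
#' 6-chromosome map this yields the 24-marker candidate set.
#'
#' @param map A [geneticMap()].
#' @param per_chrom Markers to keep per chromosome (default 4).
#' @return List of class `CandidateTermSet`: `markers` (character),
#'   `pairs` (2-row character matrix of all unordered pairs), `map`.
#' @examples
#' length(selectCandidateMarkers(defaultGeneticMap())$markers)  # 24
#' @export
selectCandidateMarkers <- function(map, per_chrom = 4L) {
  validateGeneticMap(map)
  sel <- unlist(lapply(unique(map$chromosome), function(chr) {
    sub <- map[map$chromosome == chr, ]
    m <- nrow(sub)
    if (m < per_chrom)
      stop("chromosome ", chr, " has fewer than ", per_chrom, " markers")
    if (m == per_chrom) return(sub$marker)
    combos <- utils::combn(m, per_chrom)
    score <- apply(combos, 2L, function(ix) min(dist(sub$position_cM[ix])))
    best <- which(score >= max(score) - 1e-12)
    if (length(best) > 1L) {
      # lexicographically smallest position vector, then marker ids
      keys <- vapply(best, function(b)
        paste(sprintf("%015.8f", sub$position_cM[combos[, b]]),
              paste(sub$marker[combos[, b]], collapse = ","),
              collapse = "|"), character(1))
      best <- best[order(keys)][1L]
    }
    sub$marker[combos[, best]]
  }))
  structure(list(markers = sel,
                 pairs = utils::combn(sel, 2L),
                 map = map),
            class = "CandidateTermSet")
}

## Canonical term codes and their design columns.
candidateTermTable <- function(candidates) {
  mk <- candidates$markers
  pairs <- candidates$pairs
  data.frame(
    code = c("A",
             paste0("M:", mk),
             paste0("I:", pairs[1L, ], "*", pairs[2L, ]),
             paste0("AxM:", mk)),
    type = c("A", rep("M", length(mk)), rep("I", ncol(pairs)),
             rep("AxM", length(mk))),
    stringsAsFactors = FALSE)
}

termColumns <- function(codes, geno, phys_age) {
  cols <- lapply(codes, function(code) {
    if (code == "A") return(phys_age)
    type <- sub(":.*", "", code)
    body <- sub("^[^:]+:", "", code)
    if (type == "M") geno[, body]
    else if (type == "AxM") geno[, body] * phys_age
    else {
      ms <- strsplit(body, "*", fixed = TRUE)[[1L]]
      geno[, ms[1L]] * geno[, ms[2L]]
    }
  })
  do.call(cbind, cols)
}

termMarkers <- function(codes) {
  codes <- codes[codes != "A"]
  unique(unlist(lapply(codes, function(code) {
    body <- sub("^[^:]+:", "", code)
    strsplit(body, "*", fixed = TRUE)[[1L]]
  })))
}

bicOf <- function(rss, n, k, floor_rss) {
  n * log(max(rss, floor_rss) / n) + k * log(n)
}

#' Forward/backward BIC selection of a gene's multi-locus model
#'
#' Starting from the physiological-age-only model, each step either adds
#' the candidate term (marker main effect, marker-pair product, or
#' marker x age product; age itself is also a removable term) giving the
#' largest BIC decrease, or removes the selected term whose removal most
#' decreases BIC, whichever is better. Interactions are admissible without
#' their main effects (no heredity constraint), so purely epistatic
#' regulation can enter first. Selection stops when no move decreases BIC,
#' after `max_steps` steps, or when the model holds `max_terms` terms and
#' no removal helps. Ties prefer removal over addition, then the earlier
#' term in the canonical candidate order.
#'
#' @param expr_gene Expression values over the window's samples.
#' @param geno Samples x markers allele matrix (columns must cover the
#'   candidate markers).
#' @param phys_age Physiological age per sample.
#' @param candidates A `CandidateTermSet` from [selectCandidateMarkers()].
#' @param max_terms Maximum number of explanatory terms, age included
#'   (default 6).
#' @param max_steps Step budget (default 2000).
#' @return List of class `MultiLocusModel`: `selected_terms` (term codes,
#'   e.g. `M:c2m03`, `I:c2m03*c4m01`, `A`, `AxM:c2m03`), `bic`,
#'   `start_bic`, `n_markers`, `has_epistasis`, `n_steps_used`, `n`.
#' @export
stepwiseBic <- function(expr_gene, geno, phys_age, candidates,
                        max_terms = 6L, max_steps = 2000L) {
  ok <- !is.na(expr_gene) & !is.na(phys_age)
  y <- expr_gene[ok]
  geno <- geno[ok, , drop = FALSE]
  a <- phys_age[ok]
  n <- length(y)
  if (n < max_terms + 2L) stop("need at least max_terms + 2 samples")
  tab <- candidateTermTable(candidates)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    return(structure(list(selected_terms = character(0),
                          bic = NA_real_, start_bic = NA_real_,
                          n_markers = 0L, has_epistasis = FALSE,
                          n_steps_used = 0L, n = n),
                     class = "MultiLocusModel"))
  }
  floor_rss <- max(tss * 1e-12, 1e-300)
  C <- termColumns(tab$code, geno, a)     # n x n_candidates
  colnames(C) <- tab$code

  fitRss <- function(codes) {
    X <- cbind(rep(1, n), C[, codes, drop = FALSE])
    f <- .lm.fit(X, y)
    sum(f$residuals^2)
  }

  selected <- "A"
  rss <- fitRss(selected)
  start_bic <- bicOf(rss, n, 1L + length(selected), floor_rss)
  bic <- start_bic
  steps <- 0L
  repeat {
    if (steps >= max_steps) break
    k_cur <- 1L + length(selected)
    best_add <- NULL
    if (length(selected) < max_terms) {
      pool <- setdiff(tab$code, selected)
      X <- cbind(rep(1, n), C[, selected, drop = FALSE])
      qx <- qr(X)
      r <- qr.resid(qx, y)
      Z <- qr.resid(qx, C[, pool, drop = FALSE])
      zz <- colSums(Z^2)
      gain <- ifelse(zz > 1e-10, colSums(Z * r)^2 / zz, 0)
      rss_add <- pmax(rss - gain, 0)
      bic_add <- bicOf_vec(rss_add, n, k_cur + 1L, floor_rss)
      i <- which.min(bic_add)      # ties: earlier candidate order
      best_add <- list(code = pool[i], bic = bic_add[i], rss = rss_add[i])
    }
    best_rem <- NULL
    if (length(selected) >= 1L) {
      rss_rem <- vapply(seq_along(selected), function(i)
        fitRss(selected[-i]), 1)
      bic_rem <- bicOf_vec(rss_rem, n, k_cur - 1L, floor_rss)
      i <- which.min(bic_rem)
      best_rem <- list(idx = i, bic = bic_rem[i], rss = rss_rem[i])
    }
    cand_bics <- c(if (!is.null(best_rem)) best_rem$bic else Inf,
                   if (!is.null(best_add)) best_add$bic else Inf)
    if (min(cand_bics) >= bic - 1e-10) break
    steps <- steps + 1L
    if (cand_bics[1L] <= cand_bics[2L] + 1e-10 &&
        cand_bics[1L] < bic - 1e-10) {   # prefer removal on ties
      selected <- selected[-best_rem$idx]
      rss <- best_rem$rss
      bic <- best_rem$bic
    } else {
      selected <- c(selected, best_add$code)
      rss <- best_add$rss
      bic <- best_add$bic
    }
  }
  rss <- fitRss(selected)   # exact refit of the final model
  bic <- bicOf(rss, n, 1L + length(selected), floor_rss)
  mk <- termMarkers(selected)
  structure(list(selected_terms = selected, bic = bic,
                 start_bic = start_bic, n_markers = length(mk),
                 has_epistasis = any(startsWith(selected, "I:")),
                 n_steps_used = steps, n = n),
            class = "MultiLocusModel")
}

bicOf_vec <- function(rss, n, k, floor_rss) {
  n * log(pmax(rss, floor_rss) / n) + k * log(n)
}

#' @export
print.MultiLocusModel <- function(x, ...) {
  cat("MultiLocusModel:", if (length(x$selected_terms))
        paste(x$selected_terms, collapse = " + ") else "(null model)",
      "\n  BIC", sprintf("%.2f", x$bic), "| markers", x$n_markers,
      "| epistasis", x$has_epistasis, "| steps", x$n_steps_used, "\n")
  invisible(x)
}

#' Multi-locus models for every gene of a study window
#'
#' Runs [stepwiseBic()] on the RIL samples of a two-age window for every
#' gene.
#'
#' @param study An [ExpressionStudy-class].
#' @param panel A [GenotypePanel-class].
#' @param window `"developing"` or `"aging"`.
#' @param candidates Optional `CandidateTermSet` (default: 4 per
#'   chromosome from the panel's map).
#' @param per_chrom,max_terms,max_steps See [selectCandidateMarkers()] and
#'   [stepwiseBic()].
#' @return data.frame: `gene`, `window`, `selected_terms`
#'   (semicolon-joined codes), `bic`, `n_markers`, `has_epistasis`,
#'   `n_steps_used`.
#' @export
multilocusModels <- function(study, panel, window = "developing",
                             candidates = NULL, per_chrom = 4L,
                             max_terms = 6L, max_steps = 2000L) {
  groups <- windowAges(window)
  if (length(groups) != 2L) stop("multi-locus models use a two-age window")
  if (is.null(candidates))
    candidates <- selectCandidateMarkers(geneticMapOf(panel), per_chrom)
  info <- sampleInfo(study)
  cols <- which(!info$is_parent & info$age_group %in% groups &
                  info$strain %in% rilNames(panel))
  if (!length(cols)) stop("no RIL samples in window")
  expr <- exprMatrix(study)[, cols, drop = FALSE]
  geno <- alleles(panel)[info$strain[cols], candidates$markers,
                         drop = FALSE]
  a <- info$phys_age[cols]
  rows <- lapply(rownames(expr), function(g) {
    m <- stepwiseBic(expr[g, ], geno, a, candidates, max_terms, max_steps)
    data.frame(gene = g, window = window,
               selected_terms = paste(m$selected_terms, collapse = ";"),
               bic = m$bic, n_markers = m$n_markers,
               has_epistasis = m$has_epistasis,
               n_steps_used = m$n_steps_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polygenic regulation summary by heritability bin
#'
#' Bins genes by heritability and reports, per bin and window, the
#' percentage of genes whose selected multi-locus model contains at least
#' one marker term, exactly one distinct marker, two or more distinct
#' markers, and any epistatic (marker-pair) term -- the machine-readable
#' analogue of an eQTL-by-heritability profile.
#'
#' @param models data.frame from [multilocusModels()].
#' @param h2 data.frame from [heritabilityTable()] (same window(s)).
#' @param bins Numeric bin edges for h2 (default `c(-Inf, 0.1..0.9, 1)`).
#' @return data.frame with one row per window x bin: `n_genes`,
#'   `pct_any_marker`, `pct_one_marker`, `pct_multi_marker`,
#'   `pct_epistasis` (NA for empty bins).
#' @export
polygenicSummary <- function(models, h2,
                             bins = c(-Inf, seq(0.1, 0.9, by = 0.1), 1)) {
  merged <- merge(models, h2[, c("gene", "window", "h2")],
                  by = c("gene", "window"))
  merged <- merged[!is.na(merged$h2), ]
  merged$bin <- cut(merged$h2, bins, include.lowest = TRUE)
  out <- expand.grid(window = unique(models$window),
                     bin = levels(merged$bin), stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(out)), function(i) {
    d <- merged[merged$window == out$window[i] & merged$bin == out$bin[i], ]
    if (!nrow(d))
      return(c(n_genes = 0, pct_any_marker = NA, pct_one_marker = NA,
               pct_multi_marker = NA, pct_epistasis = NA))
    c(n_genes = nrow(d),
      pct_any_marker = 100 * mean(d$n_markers >= 1),
      pct_one_marker = 100 * mean(d$n_markers == 1),
      pct_multi_marker = 100 * mean(d$n_markers >= 2),
      pct_epistasis = 100 * mean(d$has_epistasis))
  })
  cbind(out, do.call(rbind, stats))
}
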
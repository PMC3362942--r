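## Permutation nulls, genome-wide FDR at a score threshold, and the
## joint-FDR for parental differential expression overlapping eQTL.

#' Permute sample labels of a study
#'
#' Relabels whole sample columns, never values within a gene, so the
#' among-gene covariance structure is untouched. Scheme `"model1"`
#' permutes the sample-to-strain assignment; `"model2"` additionally
#' permutes the sample-to-age assignment, independently. Physiological age
#' is recomputed from the permuted strain/age pairs and the study's
#' lifespan table.
#'
#' @param study An [ExpressionStudy-class].
#' @param scheme `"model1"` or `"model2"`.
#' @param seed Optional seed; with `NULL` the current RNG stream is used
#'   (as inside permutation loops).
#' @return The permuted study.
#' @export
permuteLabels <- function(study, scheme = c("model1", "model2"),
                          seed = NULL) {
  scheme <- match.arg(scheme)
  doperm <- function() {
    info <- colData(study)
    n <- nrow(info)
    ps <- sample.int(n)
    info$strain <- info$strain[ps]
    info$is_parent <- info$is_parent[ps]
    if (scheme == "model2") {
      pa <- sample.int(n)
      info$age_hours <- info$age_hours[pa]
      info$age_group <- info$age_group[pa]
    }
    ls <- lifespanTable(study)
    if (!is.null(ls)) {
      lsv <- setNames(ls$mean_lifespan_hours, ls$strain)
      info$phys_age <- physiologicalAge(info$age_hours, lsv[info$strain])
    }
    colData(study) <- info
    study
  }
  if (is.null(seed)) doperm() else withr::with_seed(seed, doperm())
}

#' Build a permutation null distribution of per-gene peak scores
#'
#' Repeatedly permutes the study's sample labels ([permuteLabels()];
#' strain only for model 1, strain and age independently for model 2),
#' rescans the genome with [mapGenome()], and records every gene's peak
#' score per term.
#'
#' @param study,panel,model,window,subjects As in [mapGenome()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the whole permutation stream.
#' @return A `PermutationNull`: list with `term` peak-score matrices
#'   (genes x permutations) in `$perm_peaks`, plus scan metadata.
#' @export
permutationNull <- function(study, panel, model = 1, window,
                            subjects = c("rils", "parents"),
                            n_perm = 100L, seed = 1L) {
  subjects <- match.arg(subjects)
  scheme <- if (model == 1) "model1" else "model2"
  terms <- if (model == 1) "marker"
           else c("marker", "age", "marker_by_age")
  # permute labels only among the samples the scan actually uses
  info <- sampleInfo(study)
  strains <- if (subjects == "rils") rilNames(panel) else parentNames(panel)
  keep <- info$age_group %in% windowAges(window) & info$strain %in% strains
  study <- study[, keep]
  G <- nrow(study)
  peaks <- lapply(terms, function(t)
    matrix(NA_real_, G, n_perm,
           dimnames = list(rownames(study), NULL)))
  names(peaks) <- terms
  run <- function() {
    for (b in seq_len(n_perm)) {
      ps <- permuteLabels(study, scheme)
      scan <- mapGenome(ps, panel, model = model, window = window,
                        subjects = subjects, threshold = Inf)
      for (t in terms) peaks[[t]][, b] <- peakScores(scan, t)[rownames(study)]
    }
    peaks
  }
  peaks <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(perm_peaks = peaks, model = model, window = window,
                 subjects = subjects, n_perm = n_perm, seed = seed),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat("PermutationNull: model", x$model, "window", x$window, "(",
      x$subjects, "),", x$n_perm, "permutations x",
      nrow(x$perm_peaks[[1]]), "genes\n")
  invisible(x)
}

fdrRow <- function(term, window, threshold, n_obs, false_counts, n_perm,
                   seed) {
  mean_false <- mean(false_counts)
  fdr <- if (n_obs == 0 && mean_false > 0) 1
         else if (n_obs == 0) NA_real_
         else min(mean_false / n_obs, 1)
  data.frame(term = term, window = window, threshold = threshold,
             n_observed = n_obs, mean_false = mean_false,
             sd_false = sd(false_counts), fdr = fdr, n_perm = n_perm,
             seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}

#' Permutation plug-in FDR at a score threshold
#'
#' Estimates the false discovery rate of calling genes whose peak score
#' reaches `threshold` as (mean permuted count of genes at or above the
#' threshold) / (observed count), clipped to 1. Reported as 1 when nothing
#' is observed but permutations call genes, and as `NA` when both counts
#' are zero.
#'
#' @param observed_peaks Named numeric vector of observed per-gene peak
#'   scores (see [peakScores()]).
#' @param null A `PermutationNull` built on the same model/window/subjects.
#' @param threshold -log10 p calling threshold.
#' @param term Term of the null to use.
#' @return One-row data.frame (`FdrEstimate`): term, window, threshold,
#'   `n_observed`, `mean_false`, `sd_false`, `fdr`, `n_perm`, `seed`.
#' @export
estimateFdr <- function(observed_peaks, null, threshold, term = "marker") {
  stopifnot(inherits(null, "PermutationNull"))
  if (!term %in% names(null$perm_peaks))
    stop("null has no term '", term, "'")
  perm <- null$perm_peaks[[term]]
  common <- intersect(names(observed_peaks), rownames(perm))
  if (!length(common)) stop("observed and null gene universes are disjoint")
  obs <- observed_peaks[common]
  perm <- perm[common, , drop = FALSE]
  fdrRow(term, null$window, threshold, sum(obs >= threshold),
         colSums(perm >= threshold), null$n_perm, null$seed)
}

#' Joint-FDR: genes parent-differential and with an eQTL by chance
#'
#' Estimates the probability of a gene passing both the parental
#' differential-expression threshold and the RIL eQTL threshold by chance,
#' using independently drawn permutation nulls for the two datasets: the
#' numerator averages, over all pairs of a parental and a RIL permutation,
#' the number of genes passing both permuted thresholds; the denominator
#' is the observed number passing both. The independence-based product
#' rule value (universe size x marginal pass rates) is attached as
#' attribute `product_rule` for comparison.
#'
#' @param parent_peaks,ril_peaks Named per-gene peak scores of the
#'   parental contrast and the RIL scan.
#' @param parent_null,ril_null `PermutationNull` objects for the two
#'   datasets (defaults in the emulated study: 30 permutations each).
#' @param thresholds Numeric pair `c(parent, ril)`; default `c(2, 3)`.
#' @param term Model term (both nulls must carry it).
#' @return One-row `FdrEstimate` data.frame with attribute
#'   `product_rule`.
#' @export
jointFdr <- function(parent_peaks, ril_peaks, parent_null, ril_null,
                     thresholds = c(parent = 2, ril = 3),
                     term = "marker") {
  stopifnot(inherits(parent_null, "PermutationNull"),
            inherits(ril_null, "PermutationNull"))
  if (!identical(parent_null$window, ril_null$window))
    stop("nulls were built on different windows")
  genes <- Reduce(intersect, list(names(parent_peaks), names(ril_peaks),
                                  rownames(parent_null$perm_peaks[[term]]),
                                  rownames(ril_null$perm_peaks[[term]])))
  if (!length(genes)) stop("gene universes are disjoint")
  po <- parent_peaks[genes] >= thresholds[1L]
  ro <- ril_peaks[genes] >= thresholds[2L]
  n_obs <- sum(po & ro)
  A <- parent_null$perm_peaks[[term]][genes, , drop = FALSE] >= thresholds[1L]
  B <- ril_null$perm_peaks[[term]][genes, , drop = FALSE] >= thresholds[2L]
  # mean over all permutation pairs of the joint count decomposes into
  # per-gene products of marginal permutation pass rates
  pair_counts_mean <- sum(rowMeans(A) * rowMeans(B))
  fdr <- if (n_obs == 0 && pair_counts_mean > 0) 1
         else if (n_obs == 0) NA_real_
         else min(pair_counts_mean / n_obs, 1)
  out <- data.frame(term = term, window = parent_null$window,
                    threshold_parent = thresholds[1L],
                    threshold_ril = thresholds[2L], n_observed = n_obs,
                    mean_false = pair_counts_mean, fdr = fdr,
                    n_perm_parent = parent_null$n_perm,
                    n_perm_ril = ril_null$n_perm,
                    stringsAsFactors = FALSE)
  attr(out, "product_rule") <- length(genes) * mean(A) * mean(B)
  out
}
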
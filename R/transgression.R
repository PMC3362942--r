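## Transgressive segregation: RILs expressing beyond the parental range.
## Bounds are mean + 2 SD of the higher-mean parent (upper) and
## mean - 2 SD of the lower-mean parent (lower), each parent contributing
## its own replicate SD; a gene is transgressive when at least k_min RILs
## fall strictly outside a bound (at both ages of a two-age window).

transgressionBounds <- function(parent_expr, sd_mult) {
  m <- vapply(parent_expr, function(v) mean(v, na.rm = TRUE), 1)
  s <- vapply(parent_expr, function(v) sd(v, na.rm = TRUE), 1)
  n <- vapply(parent_expr, function(v) sum(!is.na(v)), 1L)
  if (any(n < 2L)) stop("each parent needs >= 2 replicates (SD undefined)")
  hi <- which.max(m); lo <- which.min(m)
  c(lower = m[[lo]] - sd_mult * s[[lo]], upper = m[[hi]] + sd_mult * s[[hi]])
}

transgressionRow <- function(gene, window, n_high, n_low, k_min) {
  significant <- n_high >= k_min || n_low >= k_min
  direction <- if (n_high >= k_min && n_low >= k_min) "both"
    else if (n_high >= k_min) "high"
    else if (n_low >= k_min) "low"
    else "none"
  data.frame(gene = gene, window = window, n_high = n_high, n_low = n_low,
             direction = direction, significant = significant,
             stringsAsFactors = FALSE)
}

#' Transgressive segregation of one gene at one age
#'
#' @param ril_expr One expression value per RIL.
#' @param parent_expr List of two parental replicate vectors at this age.
#' @param k_min Minimum number of transgressive RILs to call a gene
#'   significant (default 6).
#' @param sd_mult SD multiplier for the parental bounds (default 2).
#' @param gene,window Labels copied into the result row.
#' @return One-row data.frame: `gene`, `window`, `n_high`, `n_low`,
#'   `direction` (high/low/both/none), `significant`.
#' @examples
#' transgressionSingleAge(c(rep(12, 6), rep(10, 10)),
#'                        list(rnorm(6, 10, 0.5), rnorm(6, 9, 0.5)))
#' @export
transgressionSingleAge <- function(ril_expr, parent_expr, k_min = 6L,
                                   sd_mult = 2, gene = NA_character_,
                                   window = NA_character_) {
  b <- transgressionBounds(parent_expr, sd_mult)
  n_high <- sum(ril_expr > b[["upper"]], na.rm = TRUE)
  n_low <- sum(ril_expr < b[["lower"]], na.rm = TRUE)
  transgressionRow(gene, window, n_high, n_low, k_min)
}

#' Transgressive segregation of expression change over a two-age window
#'
#' A RIL counts as transgressive only when it exceeds the age-specific
#' upper bound at both ages (or falls below the age-specific lower bound
#' at both ages); crossing opposite bounds at the two ages counts toward
#' neither direction.
#'
#' @param ril_expr Matrix RILs x 2 ages.
#' @param parent_expr List of two parents, each a list of two replicate
#'   vectors (one per age).
#' @param k_min,sd_mult,gene,window As in [transgressionSingleAge()].
#' @return One-row data.frame as in [transgressionSingleAge()].
#' @export
transgressionOverTime <- function(ril_expr, parent_expr, k_min = 6L,
                                  sd_mult = 2, gene = NA_character_,
                                  window = NA_character_) {
  ril_expr <- as.matrix(ril_expr)
  stopifnot(ncol(ril_expr) == 2L)
  b1 <- transgressionBounds(lapply(parent_expr, `[[`, 1L), sd_mult)
  b2 <- transgressionBounds(lapply(parent_expr, `[[`, 2L), sd_mult)
  hi <- ril_expr[, 1L] > b1[["upper"]] & ril_expr[, 2L] > b2[["upper"]]
  lo <- ril_expr[, 1L] < b1[["lower"]] & ril_expr[, 2L] < b2[["lower"]]
  transgressionRow(gene, window,
                   sum(hi, na.rm = TRUE), sum(lo, na.rm = TRUE), k_min)
}

## Vectorized per-gene parental bounds at one age group given an
## assignment of samples to strains; returns G x 2 (lower, upper).
boundsForGroup <- function(expr, info, group, parents, sd_mult) {
  stats <- lapply(parents, function(p) {
    cols <- which(info$strain == p & info$age_group == group)
    P <- expr[, cols, drop = FALSE]
    n <- rowSums(!is.na(P))
    if (any(n < 2L)) stop("each parent needs >= 2 replicates (SD undefined)")
    m <- rowMeans(P, na.rm = TRUE)
    s <- sqrt(rowSums((P - m)^2, na.rm = TRUE) / (n - 1))
    list(m = m, s = s)
  })
  m1 <- stats[[1L]]$m; m2 <- stats[[2L]]$m
  s1 <- stats[[1L]]$s; s2 <- stats[[2L]]$s
  hi_is_1 <- m1 >= m2
  upper <- ifelse(hi_is_1, m1 + sd_mult * s1, m2 + sd_mult * s2)
  lower <- ifelse(hi_is_1, m2 - sd_mult * s2, m1 - sd_mult * s1)
  cbind(lower = lower, upper = upper)
}

transgressionCounts <- function(expr, info, window, parents, k_min,
                                sd_mult) {
  groups <- windowAges(window)
  ril_strains <- unique(info$strain[!info$is_parent])
  per_age <- lapply(groups, function(gr) {
    b <- boundsForGroup(expr, info, gr, parents, sd_mult)
    cols <- which(!info$is_parent & info$age_group == gr)
    R <- expr[, cols, drop = FALSE]
    colnames(R) <- info$strain[cols]
    R <- R[, ril_strains, drop = FALSE]
    list(hi = R > b[, "upper"], lo = R < b[, "lower"])
  })
  hi <- Reduce(`&`, lapply(per_age, `[[`, "hi"))
  lo <- Reduce(`&`, lapply(per_age, `[[`, "lo"))
  list(n_high = rowSums(hi, na.rm = TRUE), n_low = rowSums(lo, na.rm = TRUE))
}

#' Gene-wise transgression table for a study window
#'
#' Vectorized application of [transgressionSingleAge()] /
#' [transgressionOverTime()] to every gene.
#'
#' @param study An [ExpressionStudy-class].
#' @param window `"t1"`, `"t2"`, `"t3"`, `"developing"` or `"aging"`.
#' @param k_min,sd_mult See [transgressionSingleAge()].
#' @return data.frame with one row per gene.
#' @export
transgressionTable <- function(study, window, k_min = 6L, sd_mult = 2) {
  info <- sampleInfo(study)
  parents <- unique(info$strain[info$is_parent])
  if (length(parents) != 2L) stop("study must contain exactly 2 parents")
  cnt <- transgressionCounts(exprMatrix(study), info, window, parents,
                             k_min, sd_mult)
  out <- do.call(rbind, lapply(seq_along(cnt$n_high), function(i)
    transgressionRow(rownames(study)[i], window, cnt$n_high[i],
                     cnt$n_low[i], k_min)))
  rownames(out) <- NULL
  out
}

#' Permutation FDR for the transgressive-RIL count threshold
#'
#' Per permutation the sample-to-strain assignment (and with it the
#' RIL-vs-parent role) is shuffled within each age group, and the number
#' of significant transgressive genes recomputed. The FDR is the mean
#' permuted count divided by the observed count (`NA` when nothing is
#' observed).
#'
#' @param study An [ExpressionStudy-class].
#' @param window Analysis window.
#' @param k_min,sd_mult See [transgressionSingleAge()].
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed.
#' @return One-row data.frame: `window`, `k_min`, `n_observed`,
#'   `mean_false`, `sd_false`, `fdr`, `n_perm`, `seed`.
#' @export
transgressionFdr <- function(study, window, k_min = 6L, sd_mult = 2,
                             n_perm = 100L, seed = 1L) {
  info <- sampleInfo(study)
  parents <- unique(info$strain[info$is_parent])
  expr <- exprMatrix(study)
  cnt <- transgressionCounts(expr, info, window, parents, k_min, sd_mult)
  n_obs <- sum(cnt$n_high >= k_min | cnt$n_low >= k_min)
  run <- function() {
    vapply(seq_len(n_perm), function(b) {
      pinfo <- info
      for (gr in unique(info$age_group)) {
        idx <- which(info$age_group == gr)
        ps <- idx[sample.int(length(idx))]
        pinfo$strain[idx] <- info$strain[ps]
        pinfo$is_parent[idx] <- info$is_parent[ps]
      }
      pc <- transgressionCounts(expr, pinfo, window, parents, k_min,
                                sd_mult)
      sum(pc$n_high >= k_min | pc$n_low >= k_min)
    }, 1)
  }
  false_counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mean_false <- mean(false_counts)
  fdr <- if (n_obs == 0) NA_real_ else min(mean_false / n_obs, 1)
  data.frame(window = window, k_min = k_min, n_observed = n_obs,
             mean_false = mean_false, sd_false = sd(false_counts),
             fdr = fdr, n_perm = n_perm,
             seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}
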
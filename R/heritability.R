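## Broad-sense heritability of transcript abundance:
## H2 = (V_RIL - V_P) / V_RIL, with V_RIL the variance among RILs and V_P
## the pooled within-line variance of the two parents.

rowVarsNA <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / (n - 1)
  v[n < 2L] <- NA_real_
  v
}

h2FromVariances <- function(v_ril, v_p) {
  h2 <- (v_ril - v_p) / v_ril
  h2[!is.na(v_ril) & v_ril == 0] <- NA_real_
  h2
}

#' Broad-sense heritability at a single age
#'
#' `V_RIL` is the sample variance (n-1 denominator) across the RIL values;
#' `V_P` pools the two parents' within-strain replicate variances weighted
#' by their replicate degrees of freedom. `H2 = (V_RIL - V_P)/V_RIL` is at
#' most 1 and may be negative (negative values are retained, not clipped);
#' it is undefined (`NA`) when `V_RIL` is zero.
#'
#' @param ril_expr One expression value per RIL.
#' @param parent_expr List of two numeric vectors: the replicate values of
#'   each parent (>= 2 replicates each).
#' @return One-row data.frame: `v_ril`, `v_p`, `h2`.
#' @examples
#' heritabilitySingleAge(rnorm(10), list(rnorm(6), rnorm(6)))
#' @export
heritabilitySingleAge <- function(ril_expr, parent_expr) {
  ril_expr <- ril_expr[!is.na(ril_expr)]
  if (length(ril_expr) < 3L) stop("need at least 3 RIL values")
  parent_expr <- lapply(parent_expr, function(v) v[!is.na(v)])
  if (length(parent_expr) != 2L ||
      any(vapply(parent_expr, length, 1L) < 2L))
    stop("need >= 2 replicates for each of the two parents")
  v_ril <- var(ril_expr)
  dfs <- vapply(parent_expr, length, 1L) - 1L
  v_p <- sum(dfs * vapply(parent_expr, var, 1)) / sum(dfs)
  data.frame(v_ril = v_ril, v_p = v_p, h2 = h2FromVariances(v_ril, v_p))
}

#' Broad-sense heritability of expression over a two-age window
#'
#' Measures the genotype main effect across two ages while excluding the
#' genotype-by-age interaction: `V_RIL` is the variance across RILs of each
#' RIL's two-age mean (the age main effect cancels in the comparison, and a
#' pure crossing interaction leaves all two-age means equal, so it
#' contributes nothing). `V_P` is the matching environmental variance of a
#' two-age mean: half the pooled within-parent variance of age-centered
#' replicate residuals.
#'
#' @param ril_expr Matrix RILs x 2 ages (one value per RIL per age).
#' @param parent_expr List of two parents, each a list of two replicate
#'   vectors (one per age).
#' @return One-row data.frame: `v_ril`, `v_p`, `h2`.
#' @export
heritabilityOverTime <- function(ril_expr, parent_expr) {
  ril_expr <- as.matrix(ril_expr)
  stopifnot(ncol(ril_expr) == 2L)
  ok <- complete.cases(ril_expr)
  if (sum(ok) < 3L) stop("need at least 3 RILs observed at both ages")
  v_ril <- var(rowMeans(ril_expr[ok, , drop = FALSE]))
  ssq <- 0; df <- 0L
  for (p in parent_expr) {
    for (age_vals in p) {
      v <- age_vals[!is.na(age_vals)]
      if (length(v) < 2L) stop("need >= 2 parental replicates per age")
      ssq <- ssq + sum((v - mean(v))^2)
      df <- df + length(v) - 1L
    }
  }
  v_p <- (ssq / df) / 2
  data.frame(v_ril = v_ril, v_p = v_p, h2 = h2FromVariances(v_ril, v_p))
}

## Gene-wise building blocks shared by heritabilityTable and the
## permutation cutoff; all vectorized over genes.
h2Vector <- function(expr, info, window, parents) {
  groups <- windowAges(window)
  ril_strains <- unique(info$strain[!info$is_parent])
  if (length(groups) == 1L) {
    rcols <- which(!info$is_parent & info$age_group == groups)
    R <- expr[, rcols, drop = FALSE]
    v_ril <- rowVarsNA(R)
    ssq <- 0; dfm <- 0
    for (p in parents) {
      pc <- which(info$strain == p & info$age_group == groups)
      P <- expr[, pc, drop = FALSE]
      n <- rowSums(!is.na(P))
      ssq <- ssq + rowSums((P - rowMeans(P, na.rm = TRUE))^2, na.rm = TRUE)
      dfm <- dfm + pmax(n - 1, 0)
    }
    v_p <- ssq / dfm
    v_p[dfm < 2] <- NA_real_
  } else {
    # per-RIL two-age means; strains must be observed at both ages
    M <- vapply(groups, function(gr) {
      cols <- which(!info$is_parent & info$age_group == gr)
      m <- expr[, cols, drop = FALSE]
      colnames(m) <- info$strain[cols]
      m[, ril_strains, drop = FALSE]
    }, FUN.VALUE = matrix(0, nrow(expr), length(ril_strains)))
    means <- matrix((M[, , 1L] + M[, , 2L]) / 2, nrow = nrow(expr))
    v_ril <- rowVarsNA(means)
    ssq <- 0; dfm <- 0
    for (p in parents) {
      for (gr in groups) {
        pc <- which(info$strain == p & info$age_group == gr)
        P <- expr[, pc, drop = FALSE]
        n <- rowSums(!is.na(P))
        ssq <- ssq + rowSums((P - rowMeans(P, na.rm = TRUE))^2, na.rm = TRUE)
        dfm <- dfm + pmax(n - 1, 0)
      }
    }
    v_p <- (ssq / dfm) / 2
    v_p[dfm < 2] <- NA_real_
  }
  data.frame(gene = rownames(expr), window = window, v_ril = v_ril,
             v_p = v_p, h2 = h2FromVariances(v_ril, v_p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-wise heritability table for a study window
#'
#' Applies [heritabilitySingleAge()] (single-age windows) or
#' [heritabilityOverTime()] (developing/aging) to every gene, vectorized.
#'
#' @param study An [ExpressionStudy-class] with parental replicates.
#' @param window `"t1"`, `"t2"`, `"t3"`, `"developing"` or `"aging"`.
#' @param cutoff Optional high-heritability cutoff; when given, a
#'   `high_h2` flag is added.
#' @return data.frame: `gene`, `window`, `v_ril`, `v_p`, `h2`
#'   (and `high_h2`).
#' @export
heritabilityTable <- function(study, window, cutoff = NULL) {
  info <- sampleInfo(study)
  parents <- unique(info$strain[info$is_parent])
  if (length(parents) != 2L) stop("study must contain exactly 2 parents")
  tab <- h2Vector(exprMatrix(study), info, window, parents)
  if (!is.null(cutoff)) tab$high_h2 <- !is.na(tab$h2) & tab$h2 > cutoff
  tab
}

#' Permutation cutoff for highly heritable genes
#'
#' Per permutation, the sample-to-strain assignment is shuffled within
#' each age group (whole sample columns are relabeled) and the full
#' heritability vector recomputed. The cutoff is the smallest observed h2
#' value `t` such that (mean permuted count of genes with h2 >= t) /
#' (observed count with h2 >= t) is at most `fdr`.
#'
#' @param study An [ExpressionStudy-class].
#' @param window Analysis window.
#' @param fdr Target false-positive fraction (default 0.01).
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed.
#' @return List: `cutoff` (`NA` when no observed value attains the target
#'   rate), `fdr`, `n_perm`, `seed`, `observed_h2`, `n_flagged`.
#' @export
highH2Cutoff <- function(study, window, fdr = 0.01, n_perm = 100L,
                         seed = 1L) {
  info <- sampleInfo(study)
  parents <- unique(info$strain[info$is_parent])
  expr <- exprMatrix(study)
  obs <- h2Vector(expr, info, window, parents)$h2
  obs_f <- sort(obs[is.finite(obs)], decreasing = TRUE)
  if (!length(obs_f)) stop("no finite observed heritability values")
  run <- function() {
    perm_all <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      pinfo <- info
      for (gr in unique(info$age_group)) {
        idx <- which(info$age_group == gr)
        ps <- idx[sample.int(length(idx))]
        pinfo$strain[idx] <- info$strain[ps]
        pinfo$is_parent[idx] <- info$is_parent[ps]
      }
      perm_all[[b]] <- h2Vector(expr, pinfo, window, parents)$h2
    }
    perm_all
  }
  perm_all <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  perm_sorted <- sort(unlist(perm_all)[is.finite(unlist(perm_all))])
  # candidate thresholds: the observed values (descending); counts >= t by
  # rank (observed) and binary search (permuted pool)
  obs_count <- seq_along(obs_f)
  perm_ge <- length(perm_sorted) -
    findInterval(obs_f - 1e-12, perm_sorted)
  fdr_at <- (perm_ge / n_perm) / obs_count
  ok <- which(fdr_at <= fdr)
  cutoff <- if (length(ok)) min(obs_f[ok]) else NA_real_
  list(cutoff = cutoff, fdr = fdr, n_perm = n_perm, seed = seed,
       observed_h2 = obs,
       n_flagged = if (is.na(cutoff)) 0L else sum(obs >= cutoff,
                                                  na.rm = TRUE))
}
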
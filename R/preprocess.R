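## Physiological age and the two outlier-removal procedures.

#' Physiological age
#'
#' Chronological age divided by the strain's mean lifespan: a dimensionless
#' fraction of life lived, which puts strains with different absolute
#' lifespans on a common ageing scale.
#'
#' @param age_hours Age at sampling (hours, > 0). Vectorized.
#' @param lifespan_hours Mean lifespan of the strain (hours, > 0).
#' @return `age_hours / lifespan_hours`.
#' @examples
#' physiologicalAge(40, 16 * 24)    # N2 sampled at 40 h
#' physiologicalAge(214, 13 * 24)   # CB4856 sampled at 214 h
#' @export
physiologicalAge <- function(age_hours, lifespan_hours) {
  if (any(lifespan_hours <= 0, na.rm = TRUE))
    stop("lifespan must be positive")
  if (any(age_hours <= 0, na.rm = TRUE))
    stop("age must be positive")
  unname(age_hours / lifespan_hours)
}

#' Flag replicate values beyond k standard deviations of their mean
#'
#' Single-pass screen used per gene and age group: values outside
#' `mean +/- k * SD` (mean and SD over the supplied replicates, `NA`s
#' ignored) are flagged. With fewer than 3 usable values nothing is
#' flagged and a warning is raised.
#'
#' @param values Numeric replicate vector (one gene, one age group).
#' @param k SD multiplier (default 2).
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @examples
#' maskSdOutliers(c(0, 0, 0, 0, 0, 10))
#' @export
maskSdOutliers <- function(values, k = 2) {
  out <- rep(FALSE, length(values))
  ok <- !is.na(values)
  if (sum(ok) < 3L) {
    warning("fewer than 3 values; no outlier screening performed")
    return(out)
  }
  m <- mean(values[ok])
  s <- sd(values[ok])
  out[ok] <- abs(values[ok] - m) > k * s
  out
}

## Externally studentized residuals for a two-level (age-group) factor fit,
## computed in closed form: residual e_i about the group mean, leverage
## h_i = 1/n_group, deletion variance s2_(i) = (RSS - e_i^2/(1-h_i))/(df-1).
studentizedGroupResiduals <- function(values, group) {
  gm <- tapply(values, group, mean)
  ng <- tapply(values, group, length)
  e <- values - gm[group]
  h <- 1 / ng[group]
  n <- length(values)
  p <- length(gm)
  df <- n - p
  rss <- sum(e^2)
  s2i <- (rss - e^2 / (1 - h)) / (df - 1)
  t <- e / sqrt(s2i * (1 - h))
  t[s2i <= 0 | h >= 1 - 1e-12] <- NaN
  list(t = as.numeric(t), df_del = df - 1)
}

#' Recursive regression-based outlier removal across two age groups
#'
#' Fits expression on the two-level age-group factor for one genotype,
#' removes the single most extreme value whose externally studentized
#' residual falls outside the two-sided `conf` interval of its reference t
#' distribution, refits, and repeats until no value qualifies or
#' `max_removed` values have been removed.
#'
#' @param values Numeric vector of replicate expression values.
#' @param age_group Factor/character with exactly two levels, aligned with
#'   `values`.
#' @param conf Two-sided confidence level of the studentized-residual
#'   interval (default 0.995).
#' @param max_removed Hard cap on removals (default 6).
#' @return List with `keep` (logical retention mask) and `removed`
#'   (indices in removal order).
#' @examples
#' v <- c(rnorm(6), rnorm(6) + 1); v[3] <- 25
#' recursiveRegressionOutliers(v, rep(c("t1", "t2"), each = 6))$removed
#' @export
recursiveRegressionOutliers <- function(values, age_group, conf = 0.995,
                                        max_removed = 6L) {
  age_group <- as.character(age_group)
  stopifnot(length(values) == length(age_group))
  keep <- !is.na(values)
  removed <- integer(0)
  if (sum(keep) < 4L) {
    warning("fewer than 4 values; no outlier removal performed")
    return(list(keep = keep, removed = removed))
  }
  if (length(unique(age_group[keep])) != 2L)
    stop("exactly two age groups with data are required")
  cut_p <- 1 - (1 - conf) / 2
  while (length(removed) < max_removed) {
    idx <- which(keep)
    if (length(idx) < 4L ||
        length(unique(age_group[idx])) < 2L) break
    st <- studentizedGroupResiduals(values[idx], age_group[idx])
    if (st$df_del < 1L || all(!is.finite(st$t))) break
    worst <- which.max(abs(st$t))
    if (!is.finite(st$t[worst])) break
    if (abs(st$t[worst]) <= qt(cut_p, st$df_del)) break
    keep[idx[worst]] <- FALSE
    removed <- c(removed, idx[worst])
  }
  list(keep = keep, removed = removed)
}

#' Apply the replicate SD screen to a study's parental samples
#'
#' Runs [maskSdOutliers()] per gene, age group and strain over the
#' replicated samples of the selected subjects and records flagged values
#' in the study's retention mask.
#'
#' @param study An [ExpressionStudy-class].
#' @param subjects `"parents"` (default; the replicated samples) or
#'   `"all"`.
#' @param k SD multiplier.
#' @return The study with an updated `mask` assay.
#' @export
applySdOutlierMask <- function(study, subjects = c("parents", "all"),
                               k = 2) {
  subjects <- match.arg(subjects)
  info <- sampleInfo(study)
  expr <- assay(study, "expr")
  mask <- assay(study, "mask")
  cols <- if (subjects == "parents") which(info$is_parent)
          else seq_len(nrow(info))
  groups <- split(cols, paste(info$strain[cols], info$age_group[cols]))
  for (gcols in groups) {
    if (length(gcols) < 3L) next
    vals <- expr[, gcols, drop = FALSE]
    vals[!mask[, gcols, drop = FALSE]] <- NA
    m <- rowMeans(vals, na.rm = TRUE)
    s <- apply(vals, 1L, sd, na.rm = TRUE)
    n_ok <- rowSums(!is.na(vals))
    flag <- abs(vals - m) > k * s & n_ok >= 3L
    flag[is.na(flag)] <- FALSE
    mask[, gcols] <- mask[, gcols, drop = FALSE] & !flag
  }
  assays(study)$mask <- mask
  study
}

#' Apply recursive regression outlier removal to a study's parents
#'
#' For every gene and parental strain, runs
#' [recursiveRegressionOutliers()] on the developing (t1 + t2) and aging
#' (t2 + t3) sample pairs. A t2 value is treated as an outlier when either
#' run removes it (union of the two masks); t1 and t3 values only by their
#' own run.
#'
#' @param study An [ExpressionStudy-class].
#' @param conf,max_removed Passed to [recursiveRegressionOutliers()].
#' @return The study with an updated `mask` assay.
#' @export
applyRegressionOutlierMask <- function(study, conf = 0.995,
                                       max_removed = 6L) {
  info <- sampleInfo(study)
  expr <- assay(study, "expr")
  mask <- assay(study, "mask")
  windows <- list(c("t1", "t2"), c("t2", "t3"))
  for (strain in unique(info$strain[info$is_parent])) {
    for (w in windows) {
      cols <- which(info$strain == strain & info$age_group %in% w)
      if (length(cols) < 4L || length(unique(info$age_group[cols])) < 2L)
        next
      grp <- info$age_group[cols]
      for (gi in seq_len(nrow(expr))) {
        v <- expr[gi, cols]
        v[!mask[gi, cols]] <- NA
        if (sum(!is.na(v)) < 4L) next
        res <- suppressWarnings(
          recursiveRegressionOutliers(v, grp, conf, max_removed))
        if (length(res$removed))
          mask[gi, cols[res$removed]] <- FALSE
      }
    }
  }
  assays(study)$mask <- mask
  study
}
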
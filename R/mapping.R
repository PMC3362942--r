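## Single-marker (per-age) and two-age marker x physiological-age linear
## models, for RIL eQTL mapping and the parental strain contrast.

SCORE_CAP <- 300

scoreFromP <- function(p) pmin(-log10(pmax(p, 1e-310)), SCORE_CAP)

untestableRow <- function(term, n) {
  data.frame(term = term, effect = NA_real_, score = 0, n_used = n,
             testable = FALSE, stringsAsFactors = FALSE)
}

#' Single-marker linkage model at one age
#'
#' Ordinary least squares of expression on a two-level marker genotype
#' (coded -1/+1), equivalent to the pooled-variance two-sample t test.
#' `effect` is the regression slope on the allele coding (half the
#' between-group mean difference); `score` is -log10 of the two-sided
#' p-value of the marker term, capped at 300.
#'
#' Conventions for degenerate inputs: a monomorphic marker or fewer than 3
#' usable samples is untestable (`score` 0, `effect` `NA`); zero
#' between-group difference with zero residual variance scores 0; nonzero
#' group separation with zero residual variance scores at the cap.
#'
#' @param expr_gene Expression values (one gene) across strains; `NA`s are
#'   dropped pairwise.
#' @param geno_marker Alleles (-1/+1) aligned with `expr_gene`.
#' @return One-row data.frame: `term`, `effect`, `score`, `n_used`,
#'   `testable`.
#' @examples
#' fitModel1(c(1, 2, 1, 2, 5, 6, 5, 6), rep(c(-1, 1), each = 4))
#' @export
fitModel1 <- function(expr_gene, geno_marker) {
  ok <- !is.na(expr_gene) & !is.na(geno_marker)
  y <- expr_gene[ok]
  g <- geno_marker[ok]
  n <- length(y)
  if (n < 3L || length(unique(g)) < 2L)
    return(cbind(untestableRow("marker", n)))
  i1 <- g > 0
  n1 <- sum(i1); n0 <- n - n1
  m1 <- mean(y[i1]); m0 <- mean(y[!i1])
  rss <- sum((y[i1] - m1)^2) + sum((y[!i1] - m0)^2)
  tss <- sum((y - mean(y))^2)
  effect <- (m1 - m0) / 2
  if (tss <= 0) {
    return(data.frame(term = "marker", effect = 0, score = 0, n_used = n,
                      testable = TRUE, stringsAsFactors = FALSE))
  }
  if (rss <= tss * 1e-24) {
    score <- if (abs(m1 - m0) > 0) SCORE_CAP else 0
    if (score == 0) effect <- 0
    return(data.frame(term = "marker", effect = effect, score = score,
                      n_used = n, testable = TRUE, stringsAsFactors = FALSE))
  }
  sp2 <- rss / (n - 2)
  tval <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- 2 * pt(-abs(tval), n - 2)
  data.frame(term = "marker", effect = effect, score = scoreFromP(p),
             n_used = n, testable = TRUE, stringsAsFactors = FALSE)
}

#' Two-age model: marker + physiological age + interaction
#'
#' Ordinary least squares of expression on marker genotype, continuous
#' physiological age, and their product, fitted over the samples of a
#' two-age window. Per term, `score` is -log10 of the two-sided p-value of
#' the coefficient's t statistic (capped at 300).
#'
#' If physiological age is constant the age and interaction terms are
#' untestable and the marker term is the [fitModel1()] fit on the pooled
#' samples; any other rank deficiency makes all terms untestable.
#'
#' @param expr_gene Expression values across samples.
#' @param geno_marker Alleles (-1/+1) per sample (repeated per strain
#'   across ages).
#' @param phys_age Physiological age per sample.
#' @return Three-row data.frame (terms `marker`, `age`, `marker_by_age`)
#'   with `effect`, `score`, `n_used`, `testable`.
#' @export
fitModel2 <- function(expr_gene, geno_marker, phys_age) {
  ok <- !is.na(expr_gene) & !is.na(geno_marker) & !is.na(phys_age)
  y <- expr_gene[ok]; g <- geno_marker[ok]; a <- phys_age[ok]
  n <- length(y)
  terms <- c("marker", "age", "marker_by_age")
  if (n < 5L || length(unique(g)) < 2L)
    return(do.call(rbind, lapply(terms, untestableRow, n = n)))
  if (length(unique(a)) < 2L) {
    m1 <- fitModel1(y, g)
    m1$term <- "marker"
    return(rbind(m1, untestableRow("age", n),
                 untestableRow("marker_by_age", n)))
  }
  X <- cbind(1, g, a, g * a)
  qx <- qr(X)
  if (qx$rank < 4L)
    return(do.call(rbind, lapply(terms, untestableRow, n = n)))
  b <- qr.coef(qx, y)
  res <- y - X %*% b
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  xtx_inv <- chol2inv(qr.R(qx))
  eff <- b[2:4]
  if (tss <= 0) {
    return(data.frame(term = terms, effect = 0, score = 0, n_used = n,
                      testable = TRUE, stringsAsFactors = FALSE))
  }
  if (rss <= tss * 1e-20) {
    # exact fit: coefficients distinguishable from rounding noise score at
    # the cap, the rest at 0
    scale_j <- sqrt(tss / n) / apply(X[, 2:4, drop = FALSE], 2L, sd)
    score <- ifelse(abs(eff) > 1e-8 * scale_j, SCORE_CAP, 0)
    eff[score == 0] <- 0
    return(data.frame(term = terms, effect = unname(eff), score = score,
                      n_used = n, testable = TRUE, stringsAsFactors = FALSE))
  }
  sigma2 <- rss / (n - 4L)
  se <- sqrt(sigma2 * diag(xtx_inv)[2:4])
  tval <- eff / se
  p <- 2 * pt(-abs(tval), n - 4L)
  data.frame(term = terms, effect = unname(eff),
             score = unname(scoreFromP(p)), n_used = n, testable = TRUE,
             stringsAsFactors = FALSE)
}

## Vectorized single-marker scan: Y genes x samples, g alleles per sample.
## Returns effect and score vectors across genes; falls back to fitModel1
## per gene when missing values are present.
scanModel1Marker <- function(Y, g) {
  G <- nrow(Y)
  effect <- rep(NA_real_, G); score <- rep(0, G)
  has_na <- anyNA(Y)
  if (length(unique(g)) < 2L || length(g) < 3L)
    return(list(effect = effect, score = score))
  if (!has_na) {
    i1 <- g > 0
    n1 <- sum(i1); n0 <- sum(!i1); n <- n1 + n0
    m1 <- rowMeans(Y[, i1, drop = FALSE])
    m0 <- rowMeans(Y[, !i1, drop = FALSE])
    rss <- rowSums((Y[, i1, drop = FALSE] - m1)^2) +
           rowSums((Y[, !i1, drop = FALSE] - m0)^2)
    tss <- rowSums((Y - rowMeans(Y))^2)
    effect <- (m1 - m0) / 2
    tval <- (m1 - m0) / sqrt(rss / (n - 2) * (1 / n1 + 1 / n0))
    p <- 2 * pt(-abs(tval), n - 2)
    score <- scoreFromP(p)
    zero_res <- rss <= tss * 1e-24
    score[zero_res] <- ifelse(abs(m1 - m0)[zero_res] > 0, SCORE_CAP, 0)
    effect[zero_res & score == 0] <- 0
    zero_tot <- tss <= 0
    score[zero_tot] <- 0; effect[zero_tot] <- 0
  } else {
    for (gi in seq_len(G)) {
      f <- fitModel1(Y[gi, ], g)
      effect[gi] <- f$effect; score[gi] <- f$score
    }
  }
  list(effect = effect, score = score)
}

## Vectorized two-age scan at one marker. Returns per-term effect/score
## matrices (genes x 3).
scanModel2Marker <- function(Y, g, a) {
  G <- nrow(Y)
  terms <- c("marker", "age", "marker_by_age")
  eff <- matrix(NA_real_, G, 3L, dimnames = list(NULL, terms))
  sco <- matrix(0, G, 3L, dimnames = list(NULL, terms))
  if (anyNA(Y)) {
    for (gi in seq_len(G)) {
      f <- fitModel2(Y[gi, ], g, a)
      eff[gi, ] <- f$effect; sco[gi, ] <- f$score
    }
    return(list(effect = eff, score = sco))
  }
  n <- ncol(Y)
  X <- cbind(1, g, a, g * a)
  qx <- qr(X)
  if (qx$rank < 4L || n < 5L || length(unique(g)) < 2L) {
    for (gi in seq_len(G)) {
      f <- fitModel2(Y[gi, ], g, a)
      eff[gi, ] <- f$effect; sco[gi, ] <- f$score
    }
    return(list(effect = eff, score = sco))
  }
  xtx_inv <- chol2inv(qr.R(qx))
  B <- Y %*% X %*% xtx_inv            # G x 4 coefficients
  fitted_ss <- rowSums((Y %*% X) * B)
  rss <- pmax(rowSums(Y^2) - fitted_ss, 0)
  tss <- rowSums((Y - rowMeans(Y))^2)
  sigma2 <- rss / (n - 4L)
  eff[] <- B[, 2:4]
  se <- sqrt(outer(sigma2, diag(xtx_inv)[2:4]))
  tval <- eff / se
  p <- 2 * pt(-abs(tval), n - 4L)
  sco[] <- scoreFromP(p)
  zero_res <- rss <= tss * 1e-20
  if (any(zero_res)) {
    scale_j <- sqrt(tss / n) %o% (1 / apply(X[, 2:4, drop = FALSE], 2L, sd))
    capsc <- ifelse(abs(eff) > 1e-8 * scale_j, SCORE_CAP, 0)
    sco[zero_res, ] <- capsc[zero_res, ]
    eff[zero_res, ][sco[zero_res, ] == 0] <- 0
  }
  zero_tot <- tss <= 0
  sco[zero_tot, ] <- 0; eff[zero_tot, ] <- 0
  list(effect = eff, score = sco)
}

#' Genome scan: fit a model at every marker for every gene
#'
#' Applies [fitModel1()] (single-age window) or [fitModel2()] (two-age
#' window) at every marker for every gene of the study, and calls an eQTL
#' per gene and term at the peak marker when the peak score reaches the
#' threshold. With `subjects = "parents"` the scan reduces to the parental
#' strain-identity contrast (one pseudo-marker, `parental_genotype`),
#' reusing the same model code path.
#'
#' @param study An [ExpressionStudy-class].
#' @param panel A [GenotypePanel-class] sharing strains with the study.
#' @param model 1 (per-age marker model) or 2 (marker + physiological age +
#'   interaction).
#' @param window `"t1"`, `"t2"`, `"t3"` for model 1; `"developing"` or
#'   `"aging"` for model 2.
#' @param subjects `"rils"` (linkage mapping, default threshold 3) or
#'   `"parents"` (differential expression, default threshold 2).
#' @param threshold -log10 p calling threshold; defaults as above.
#' @return List of class `MappingScan`: `results` (gene x marker x term
#'   table), `peaks` (per gene x term peak marker and score), `calls`
#'   (peaks passing the threshold), plus the scan settings.
#' @examples
#' d <- studyDesign(n_rils = 12, seed = 1)
#' p <- simulateGenotypes(d)
#' s <- simulateExpression(p, d, categoryArchitectures("A", n = 2, seed = 2))
#' mapGenome(s, p, model = 1, window = "t1")$calls
#' @export
mapGenome <- function(study, panel, model = 1, window,
                      subjects = c("rils", "parents"), threshold = NULL) {
  subjects <- match.arg(subjects)
  stopifnot(model %in% c(1, 2))
  groups <- windowAges(window)
  if (model == 1 && length(groups) != 1L)
    stop("model 1 uses a single-age window (t1, t2 or t3)")
  if (model == 2 && length(groups) != 2L)
    stop("model 2 uses a two-age window (developing or aging)")
  if (is.null(threshold)) threshold <- if (subjects == "rils") 3 else 2

  info <- sampleInfo(study)
  strains <- if (subjects == "rils") rilNames(panel) else parentNames(panel)
  cols <- which(info$age_group %in% groups & info$strain %in% strains)
  if (!length(cols)) stop("study and panel share no usable strains")
  if (length(unique(info$strain[cols])) < 3L && subjects == "rils")
    stop("mapping needs at least 3 RIL strains with samples in the window")

  Y <- exprMatrix(study)[, cols, drop = FALSE]
  a <- info$phys_age[cols]
  genes <- rownames(Y)
  if (subjects == "rils") {
    geno <- alleles(panel)[info$strain[cols], , drop = FALSE]
    markers <- colnames(geno)
  } else {
    geno <- matrix(ifelse(info$strain[cols] == parentNames(panel)[1L],
                          1, -1), ncol = 1L,
                   dimnames = list(NULL, "parental_genotype"))
    markers <- "parental_genotype"
  }

  res <- vector("list", length(markers))
  for (mi in seq_along(markers)) {
    g <- geno[, mi]
    if (model == 1) {
      f <- scanModel1Marker(Y, g)
      res[[mi]] <- data.frame(gene = genes, marker = markers[mi],
                              term = "marker", effect = f$effect,
                              score = f$score, n_used = ncol(Y),
                              stringsAsFactors = FALSE)
    } else {
      f <- scanModel2Marker(Y, g, a)
      res[[mi]] <- data.frame(
        gene = rep(genes, 3L), marker = markers[mi],
        term = rep(colnames(f$score), each = length(genes)),
        effect = as.vector(f$effect), score = as.vector(f$score),
        n_used = ncol(Y), stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)

  peaks <- do.call(rbind, lapply(split(results, results$term), function(d) {
    sp <- split(d, d$gene)
    do.call(rbind, lapply(sp, function(dd) {
      i <- which.max(dd$score)   # ties: first marker in map order
      dd[i, c("gene", "marker", "term", "score"), drop = FALSE]
    }))
  }))
  names(peaks)[names(peaks) == "marker"] <- "peak_marker"
  peaks$window <- window
  rownames(peaks) <- NULL
  calls <- peaks[peaks$score >= threshold, , drop = FALSE]
  if (nrow(calls)) calls$threshold_used <- threshold
  else calls$threshold_used <- numeric(0)
  structure(list(results = results, peaks = peaks, calls = calls,
                 model = model, window = window, subjects = subjects,
                 threshold = threshold),
            class = "MappingScan")
}

#' @export
print.MappingScan <- function(x, ...) {
  cat("MappingScan: model", x$model, "window", x$window, "(", x$subjects,
      ")\n  genes:", length(unique(x$results$gene)),
      " markers:", length(unique(x$results$marker)),
      "\n  calls at -log10 p >=", x$threshold, ":", nrow(x$calls), "\n")
  invisible(x)
}

#' Per-gene peak scores from a mapping scan
#'
#' @param scan A `MappingScan` from [mapGenome()].
#' @param term Model term to extract (`"marker"`, `"age"`,
#'   `"marker_by_age"`).
#' @return Named numeric vector of per-gene peak scores.
#' @export
peakScores <- function(scan, term = "marker") {
  p <- scan$peaks[scan$peaks$term == term, ]
  setNames(p$score, p$gene)
}
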
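## Overlap categories (parental differential expression vs eQTL),
## heritability profiles, and the end-to-end pipeline driver.

#' Classify genes by parental differential expression vs eQTL status
#'
#' Exact set arithmetic on a shared gene universe: category A = genes both
#' parent-differential and with an eQTL; B = parent-differential without
#' an eQTL; C = eQTL without parental difference. The additivity
#' identities A + B = parent-differential count and A + C = eQTL count
#' hold by construction.
#'
#' @param parent_genes Genes called differentially expressed between the
#'   parents (character vector, or a calls data.frame with a `gene`
#'   column).
#' @param ril_genes Genes with an eQTL (same forms accepted).
#' @param universe All analyzed genes.
#' @param window,effect_term Labels copied into the count row.
#' @return List: `counts` (one-row data.frame with `n_eqtl`,
#'   `n_parent_diff`, `A`, `B`, `C`) and `sets` (the three gene vectors).
#' @examples
#' categorizeGenes(c("g1", "g2"), c("g2", "g3"), paste0("g", 1:5))$counts
#' @export
categorizeGenes <- function(parent_genes, ril_genes, universe,
                            window = NA_character_,
                            effect_term = NA_character_) {
  asGenes <- function(x) {
    if (is.data.frame(x)) {
      if (anyDuplicated(x$gene)) stop("duplicate gene entries in calls")
      x <- x$gene
    } else if (anyDuplicated(x)) {
      stop("duplicate gene entries in calls")
    }
    as.character(x)
  }
  parent_genes <- asGenes(parent_genes)
  ril_genes <- asGenes(ril_genes)
  if (!all(c(parent_genes, ril_genes) %in% universe))
    stop("calls must lie inside the gene universe")
  A <- intersect(parent_genes, ril_genes)
  B <- setdiff(parent_genes, ril_genes)
  C <- setdiff(ril_genes, parent_genes)
  counts <- data.frame(window = window, effect_term = effect_term,
                       n_eqtl = length(ril_genes),
                       n_parent_diff = length(parent_genes),
                       A = length(A), B = length(B), C = length(C),
                       stringsAsFactors = FALSE)
  list(counts = counts, sets = list(A = A, B = B, C = C))
}

#' Percentage of genes with an eQTL per heritability bin
#'
#' @param h2 data.frame from [heritabilityTable()].
#' @param call_genes Genes with a call (character vector or calls
#'   data.frame).
#' @param bins Numeric bin edges for h2.
#' @return data.frame per bin: `n_genes`, `n_with_call`, `pct_with_call`.
#' @export
h2EqtlProfile <- function(h2, call_genes,
                          bins = c(-Inf, seq(0.1, 0.9, by = 0.1), 1)) {
  if (is.data.frame(call_genes)) call_genes <- call_genes$gene
  d <- h2[!is.na(h2$h2), ]
  d$bin <- cut(d$h2, bins, include.lowest = TRUE)
  d$called <- d$gene %in% call_genes
  out <- do.call(rbind, lapply(levels(d$bin), function(b) {
    dd <- d[d$bin == b, ]
    data.frame(bin = b, n_genes = nrow(dd),
               n_with_call = sum(dd$called),
               pct_with_call = if (nrow(dd)) 100 * mean(dd$called)
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with the defaults of the
#' emulated study: calling thresholds (-log10 p) of 3 for RIL eQTL, 2 for
#' the parental contrast and the model-2 marker/interaction terms, 8/6 for
#' the physiological-age term in the developing/aging windows; 100
#' permutations for genome-wide FDRs, 30 for the joint-FDR; transgression
#' with at least 6 RILs beyond 2 parental SDs; heritability cutoff at 1%
#' false positives; 4 candidate markers per chromosome and at most 6 terms
#' in 2000 stepwise steps.
#'
#' @param n_genes Number of simulated genes per category (A, B, C) when
#'   the pipeline simulates its input.
#' @param seed Master seed.
#' @param ... Overrides for any listed default.
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(n_genes = c(A = 30L, B = 30L, C = 30L),
                           seed = 1L, ...) {
  cfg <- list(
    design = studyDesign(seed = seed),
    map = defaultGeneticMap(),
    n_genes = n_genes,
    seed = seed,
    thresholds = list(ril = 3, parent = 2,
                      age = c(developing = 8, aging = 6)),
    n_perm = list(fdr = 100L, joint = 30L, h2 = 100L,
                  transgression = 100L),
    k_min = 6L, sd_mult = 2,
    h2_fdr = 0.01,
    per_chrom = 4L, max_terms = 6L, max_steps = 2000L,
    h2_bins = c(-Inf, seq(0.1, 0.9, by = 0.1), 1),
    sd_outlier_k = 2, outlier_conf = 0.995, outlier_max_removed = 6L,
    run_outlier_removal = TRUE,
    windows = c("developing", "aging"),
    annotation = NULL,
    out_dir = NULL
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

writeStageTable <- function(tab, out_dir, name, cfg_hash) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", cfg_hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full age-aware eQTL pipeline
#'
#' Simulates a labeled study (categories A, B and C), applies the outlier
#' procedures, maps models 1 and 2 for RILs and parents across all
#' windows, estimates permutation and joint FDRs, computes heritability
#' with permutation cutoffs, transgression with its FDR, fits multi-locus
#' models, and assembles the category and heritability-profile tables.
#' With `out_dir` set, every table is written as TSV along with a run
#' manifest (configuration echo and seed) so a rerun with the same
#' configuration reproduces the outputs.
#'
#' @param config A [pipelineConfig()].
#' @return List of class `PipelineResult` with elements `panel`, `study`,
#'   `scans`, `fdr`, `joint_fdr`, `heritability`, `h2_cutoffs`,
#'   `transgression`, `transgression_fdr`, `multilocus`, `categories`,
#'   `profiles`, `polygenic`, `enrichment`, `config`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg_text <- paste(deparse(unclass(
    config[setdiff(names(config), c("annotation", "map"))])),
    collapse = "")
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(cfg_text) *
                                    seq_along(utf8ToInt(cfg_text))) %%
                               .Machine$integer.max)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  panel <- stage("simulate", simulateGenotypes(config$design, config$map))
  archs <- stage("simulate", withr::with_seed(config$seed + 1L, c(
    categoryArchitectures("A", config$map, config$n_genes[["A"]]),
    categoryArchitectures("B", config$map, config$n_genes[["B"]]),
    categoryArchitectures("C", config$map, config$n_genes[["C"]]))))
  names(archs) <- sprintf("gene%04d", seq_along(archs))
  study <- stage("simulate",
                 simulateExpression(panel, config$design, archs,
                                    seed = config$seed + 2L))
  if (isTRUE(config$run_outlier_removal)) {
    study <- stage("preprocess", applySdOutlierMask(
      study, "parents", k = config$sd_outlier_k))
    study <- stage("preprocess", applyRegressionOutlierMask(
      study, conf = config$outlier_conf,
      max_removed = config$outlier_max_removed))
  }

  single_windows <- AGE_GROUPS[seq_along(config$design$ages_hours)]
  scans <- list()
  for (w in single_windows) {
    scans[[paste0("m1_ril_", w)]] <- stage("mapping",
      mapGenome(study, panel, 1, w, "rils", config$thresholds$ril))
    scans[[paste0("m1_parent_", w)]] <- stage("mapping",
      mapGenome(study, panel, 1, w, "parents", config$thresholds$parent))
  }
  for (w in config$windows) {
    scans[[paste0("m2_ril_", w)]] <- stage("mapping",
      mapGenome(study, panel, 2, w, "rils", config$thresholds$ril))
    scans[[paste0("m2_parent_", w)]] <- stage("mapping",
      mapGenome(study, panel, 2, w, "parents", config$thresholds$parent))
  }

  fdr_rows <- list(); joint_rows <- list()
  for (w in config$windows) {
    ril_null <- stage("thresholds", permutationNull(
      study, panel, 2, w, "rils", n_perm = config$n_perm$fdr,
      seed = config$seed + 10L))
    parent_null <- stage("thresholds", permutationNull(
      study, panel, 2, w, "parents", n_perm = config$n_perm$joint,
      seed = config$seed + 11L))
    ril_scan <- scans[[paste0("m2_ril_", w)]]
    parent_scan <- scans[[paste0("m2_parent_", w)]]
    for (term in c("marker", "marker_by_age", "age")) {
      th <- if (term == "age") config$thresholds$age[[w]]
            else config$thresholds$ril
      fdr_rows[[paste(w, term)]] <- stage("thresholds", estimateFdr(
        peakScores(ril_scan, term), ril_null, th, term))
    }
    for (term in c("marker", "marker_by_age")) {
      joint_rows[[paste(w, term)]] <- stage("thresholds", jointFdr(
        peakScores(parent_scan, term), peakScores(ril_scan, term),
        parent_null, ril_null,
        thresholds = c(config$thresholds$parent, config$thresholds$ril),
        term = term))
    }
  }

  herit <- list(); cutoffs <- list()
  for (w in config$windows) {
    cut <- stage("heritability", highH2Cutoff(
      study, w, fdr = config$h2_fdr, n_perm = config$n_perm$h2,
      seed = config$seed + 20L))
    herit[[w]] <- stage("heritability",
                        heritabilityTable(study, w, cutoff = cut$cutoff))
    cutoffs[[w]] <- data.frame(window = w, fdr = config$h2_fdr,
                               cutoff = cut$cutoff, n_perm = cut$n_perm,
                               seed = cut$seed)
  }

  trans <- list(); trans_fdr <- list()
  for (w in c(single_windows, config$windows)) {
    trans[[w]] <- stage("transgression", transgressionTable(
      study, w, k_min = config$k_min, sd_mult = config$sd_mult))
    trans_fdr[[w]] <- stage("transgression", transgressionFdr(
      study, w, k_min = config$k_min, sd_mult = config$sd_mult,
      n_perm = config$n_perm$transgression, seed = config$seed + 30L))
  }

  candidates <- stage("multilocus",
                      selectCandidateMarkers(config$map, config$per_chrom))
  ml <- lapply(config$windows, function(w)
    stage("multilocus", multilocusModels(
      study, panel, w, candidates, max_terms = config$max_terms,
      max_steps = config$max_steps)))
  names(ml) <- config$windows

  categories <- list(); profiles <- list(); polygenic <- list()
  universe <- rownames(study)
  for (w in config$windows) {
    for (term in c("marker", "marker_by_age")) {
      pg <- scans[[paste0("m2_parent_", w)]]$calls
      rg <- scans[[paste0("m2_ril_", w)]]$calls
      cat_res <- stage("report", categorizeGenes(
        pg$gene[pg$term == term], rg$gene[rg$term == term], universe,
        window = w,
        effect_term = if (term == "marker") "genotype"
                      else "age_by_genotype"))
      categories[[paste(w, term)]] <- cat_res$counts
      profiles[[paste(w, term)]] <- cbind(
        window = w, term = term,
        stage("report", h2EqtlProfile(
          herit[[w]], rg$gene[rg$term == term], bins = config$h2_bins)))
    }
    polygenic[[w]] <- stage("report",
                            polygenicSummary(ml[[w]], herit[[w]],
                                             bins = config$h2_bins))
  }

  enr <- NULL
  if (!is.null(config$annotation)) {
    eqtl_genes <- unique(unlist(lapply(config$windows, function(w) {
      calls <- scans[[paste0("m2_ril_", w)]]$calls
      calls$gene[calls$term == "marker"]
    })))
    if (length(eqtl_genes))
      enr <- stage("enrichment",
                   hypergeomEnrich(eqtl_genes, config$annotation, universe))
  }

  result <- list(panel = panel, study = study, scans = scans,
                 fdr = do.call(rbind, fdr_rows),
                 joint_fdr = do.call(rbind, joint_rows),
                 heritability = do.call(rbind, herit),
                 h2_cutoffs = do.call(rbind, cutoffs),
                 transgression = trans,
                 transgression_fdr = do.call(rbind, trans_fdr),
                 multilocus = ml,
                 categories = do.call(rbind, categories),
                 profiles = do.call(rbind, profiles),
                 polygenic = polygenic,
                 enrichment = enr,
                 config = config)
  if (!is.null(out_dir)) {
    stage("report", {
      writeGenotypePanel(panel, file.path(out_dir, "genotypes.tsv"),
                         file.path(out_dir, "map.tsv"))
      writeExpressionStudy(study, file.path(out_dir, "expression.tsv"),
                           file.path(out_dir, "samples.tsv"))
      writeLifespans(lifespanTable(study),
                     file.path(out_dir, "lifespans.tsv"))
      for (nm in names(scans)) {
        writeStageTable(scans[[nm]]$results, out_dir,
                        paste0("scores_", nm), cfg_hash)
        writeStageTable(scans[[nm]]$calls, out_dir,
                        paste0("calls_", nm), cfg_hash)
      }
      writeStageTable(result$fdr, out_dir, "fdr", cfg_hash)
      writeStageTable(result$joint_fdr, out_dir, "joint_fdr", cfg_hash)
      writeStageTable(result$heritability, out_dir, "heritability",
                      cfg_hash)
      writeStageTable(result$h2_cutoffs, out_dir, "h2_cutoffs", cfg_hash)
      for (w in names(trans))
        writeStageTable(trans[[w]], out_dir, paste0("transgression_", w),
                        cfg_hash)
      writeStageTable(result$transgression_fdr, out_dir,
                      "transgression_fdr", cfg_hash)
      for (w in names(ml))
        writeStageTable(ml[[w]], out_dir, paste0("multilocus_", w),
                        cfg_hash)
      writeStageTable(result$categories, out_dir, "categories", cfg_hash)
      writeStageTable(result$profiles, out_dir, "h2_eqtl_profile",
                      cfg_hash)
      manifest <- c(paste0("seed: ", config$seed),
                    paste0("n_genes: ", paste(config$n_genes,
                                              collapse = ",")),
                    paste0("n_rils: ", config$design$n_rils),
                    paste0("package_version: ",
                           as.character(utils::packageVersion("wormAgeQTL"))))
      writeLines(manifest, file.path(out_dir, "manifest.txt"))
    })
  }
  structure(result, class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:", nrow(x$study), "genes,",
      length(rilNames(x$panel)), "RILs\n  category counts:\n")
  print(x$categories, row.names = FALSE)
  invisible(x)
}
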
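# Shared fixture builders; everything is generated in code.

tinyMap <- function(n_per_chrom = 6L, n_chrom = 2L, length_cM = 50) {
  pieces <- lapply(seq_len(n_chrom), function(i)
    data.frame(marker = sprintf("c%dm%02d", i, seq_len(n_per_chrom)),
               chromosome = paste0("chr", i),
               position_cM = seq(0, length_cM, length.out = n_per_chrom)))
  m <- do.call(rbind, pieces)
  geneticMap(m$marker, m$chromosome, m$position_cM)
}

# A study built directly from matrices: one age group per entry of `ages`,
# RILs with one sample each, two parents with `reps` replicates each.
manualStudy <- function(ril_vals, parent_vals, ages = c(t1 = 40),
                        lifespan = 384) {
  # ril_vals: list age_group -> genes x RIL matrix
  # parent_vals: list age_group -> list(P1 = genes x reps, P2 = ...)
  samples <- NULL
  blocks <- list()
  for (gr in names(ages)) {
    R <- ril_vals[[gr]]
    n_ril <- ncol(R)
    P1 <- parent_vals[[gr]][[1]]
    P2 <- parent_vals[[gr]][[2]]
    blocks[[gr]] <- cbind(R, P1, P2)
    samples <- rbind(samples, data.frame(
      strain = c(sprintf("RIL%03d", seq_len(n_ril)),
                 rep("P1", ncol(P1)), rep("P2", ncol(P2))),
      age_hours = ages[[gr]], age_group = gr,
      replicate = c(rep(1L, n_ril), seq_len(ncol(P1)), seq_len(ncol(P2))),
      is_parent = c(rep(FALSE, n_ril), rep(TRUE, ncol(P1) + ncol(P2)))))
  }
  expr <- do.call(cbind, blocks)
  colnames(expr) <- paste0(samples$strain, "_", samples$age_group, "_r",
                           samples$replicate)
  rownames(expr) <- if (is.null(rownames(expr)))
    sprintf("g%03d", seq_len(nrow(expr))) else rownames(expr)
  strains <- unique(samples$strain)
  lifespans <- data.frame(strain = strains,
                          mean_lifespan_hours = lifespan)
  ExpressionStudy(expr, samples, lifespans = lifespans)
}

# Simulated study with all-null architectures (RILs and parents
# exchangeable apart from lifespan differences unless equalized).
nullStudy <- function(n_genes = 50L, n_rils = 20L, noise_sd = 0.3,
                      seed = 1L, equal_lifespans = FALSE) {
  ls <- if (equal_lifespans) c(N2 = 350, CB4856 = 350)
        else c(N2 = 16 * 24, CB4856 = 13 * 24)
  d <- studyDesign(n_rils = n_rils, seed = seed,
                   parent_lifespans_hours = ls,
                   ril_lifespan_range_hours = if (equal_lifespans)
                     c(350, 350) else NULL)
  panel <- simulateGenotypes(d)
  archs <- replicate(n_genes, architectureSpec(noise_sd = noise_sd),
                     simplify = FALSE)
  list(design = d, panel = panel,
       study = simulateExpression(panel, d, archs, seed = seed + 1L))
}
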
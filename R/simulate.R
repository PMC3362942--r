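## Synthetic RIL panels and expression phenotypes.
##
## Genotypes follow a per-chromosome Markov chain over {-1, +1}: with the
## Haldane map function the recombination fraction between adjacent markers
## d cM apart is r = (1 - exp(-2d/100))/2, and repeated selfing expands it
## to an observed switch probability R = 2r/(1 + 2r) between fixed RIL
## genotypes.

rilSwitchProb <- function(d_cM) {
  r <- (1 - exp(-2 * d_cM / 100)) / 2
  2 * r / (1 + 2 * r)
}

#' Simulate RIL genotypes for a two-parent cross
#'
#' Draws fully inbred RIL genomes marker by marker along each chromosome:
#' the first marker of a chromosome is -1 or +1 with equal probability and
#' each subsequent marker switches parental type with probability
#' `2r/(1+2r)`, where `r` is the Haldane recombination fraction for the
#' inter-marker distance (the map expansion expected after repeated
#' selfing). Chromosomes are independent. The two parents are appended as
#' the constant rows +1 and -1.
#'
#' @param design A [studyDesign()] (supplies `n_rils`, parent names and the
#'   default seed).
#' @param map A [geneticMap()]; defaults to [defaultGeneticMap()].
#' @param seed RNG seed; defaults to `design$seed`.
#' @return A [GenotypePanel-class] object.
#' @examples
#' panel <- simulateGenotypes(studyDesign(n_rils = 5, seed = 1))
#' alleles(panel)[1:3, 1:4]
#' @export
simulateGenotypes <- function(design, map = defaultGeneticMap(),
                              seed = design$seed) {
  stopifnot(inherits(design, "StudyDesign"))
  validateGeneticMap(map)
  draw <- function() {
    n <- design$n_rils
    out <- matrix(NA_real_, n, nrow(map),
                  dimnames = list(sprintf("RIL%03d", seq_len(n)),
                                  map$marker))
    for (chr in unique(map$chromosome)) {
      idx <- which(map$chromosome == chr)
      pos <- map$position_cM[idx]
      out[, idx[1L]] <- sample(c(-1, 1), n, replace = TRUE)
      if (length(idx) > 1L) {
        R <- rilSwitchProb(diff(pos))
        for (j in seq_along(R)) {
          flip <- rbinom(n, 1L, R[j])
          out[, idx[j + 1L]] <- out[, idx[j]] * (1 - 2 * flip)
        }
      }
    }
    out
  }
  rils <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  parents <- names(design$parent_lifespans_hours)
  al <- rbind(rils,
              matrix(rep(c(1, -1), each = nrow(map)), 2L, nrow(map),
                     byrow = TRUE, dimnames = list(parents, map$marker)))
  GenotypePanel(al, map, parents = parents)
}

geneticValues <- function(spec, al) {
  g <- rep(spec$baseline, nrow(al))
  for (m in names(spec$additive)) g <- g + spec$additive[[m]] * al[, m]
  for (pp in names(spec$epistatic)) {
    ms <- strsplit(pp, ":", fixed = TRUE)[[1L]]
    g <- g + spec$epistatic[[pp]] * al[, ms[1L]] * al[, ms[2L]]
  }
  g
}

ageSlopes <- function(spec, al) {
  s <- rep(spec$age_slope, nrow(al))
  for (m in names(spec$age_by_marker))
    s <- s + spec$age_by_marker[[m]] * al[, m]
  s
}

#' Simulate log2 expression for a genotyped panel
#'
#' For each gene, strain and age the expected log2 expression is
#' `baseline + sum(additive * allele) + sum(epistatic * allele_i * allele_j)
#' + (age_slope + sum(age_by_marker * allele)) * physAge`, with independent
#' Gaussian residual noise. Physiological age is chronological age divided
#' by the strain's mean lifespan; parental lifespans come from the design
#' and RIL lifespans are drawn uniformly from the design's range. Parents
#' receive `parent_replicates_per_age` independent replicates per age, RILs
#' one sample per age.
#'
#' @param panel A [GenotypePanel-class].
#' @param design A [studyDesign()].
#' @param architectures List of [architectureSpec()] objects, one per gene
#'   (names become gene ids; unnamed lists get `gene0001`, ...).
#' @param seed RNG seed; defaults to `design$seed`.
#' @return An [ExpressionStudy-class] whose metadata records the design and
#'   the true architectures.
#' @examples
#' d <- studyDesign(n_rils = 5, seed = 1)
#' p <- simulateGenotypes(d)
#' s <- simulateExpression(p, d, list(architectureSpec(noise_sd = 0.1)))
#' @export
simulateExpression <- function(panel, design, architectures,
                               seed = design$seed) {
  stopifnot(is(panel, "GenotypePanel"), inherits(design, "StudyDesign"))
  al <- alleles(panel)
  bad <- setdiff(unique(unlist(lapply(architectures, architectureMarkers))),
                 colnames(al))
  if (length(bad))
    stop("architectures reference unknown markers: ",
         paste(bad, collapse = ", "))
  if (is.null(names(architectures)))
    names(architectures) <- sprintf("gene%04d", seq_along(architectures))

  rils <- rilNames(panel)
  parents <- parentNames(panel)
  ages <- design$ages_hours
  groups <- AGE_GROUPS[seq_along(ages)]

  samples <- do.call(rbind, lapply(seq_along(ages), function(ai) {
    rbind(
      data.frame(strain = rils, age_hours = ages[ai], age_group = groups[ai],
                 replicate = 1L, is_parent = FALSE),
      data.frame(strain = rep(parents,
                              each = design$parent_replicates_per_age),
                 age_hours = ages[ai], age_group = groups[ai],
                 replicate = rep(seq_len(design$parent_replicates_per_age),
                                 times = 2L),
                 is_parent = TRUE)
    )
  }))
  samples$sample_id <- paste(samples$strain, samples$age_group,
                             sprintf("r%02d", samples$replicate), sep = "_")
  rownames(samples) <- samples$sample_id

  build <- function() {
    ril_ls <- runif(length(rils), design$ril_lifespan_range_hours[1L],
                    design$ril_lifespan_range_hours[2L])
    lifespans <- data.frame(
      strain = c(rils, parents),
      mean_lifespan_hours = c(ril_ls, unname(design$parent_lifespans_hours))
    )
    ls_by_strain <- setNames(lifespans$mean_lifespan_hours, lifespans$strain)
    pa <- physiologicalAge(samples$age_hours, ls_by_strain[samples$strain])
    G <- length(architectures)
    S <- nrow(samples)
    expr <- matrix(NA_real_, G, S,
                   dimnames = list(names(architectures), samples$sample_id))
    al_sample <- al[samples$strain, , drop = FALSE]
    for (gi in seq_len(G)) {
      spec <- architectures[[gi]]
      mu <- geneticValues(spec, al_sample) + ageSlopes(spec, al_sample) * pa
      expr[gi, ] <- mu + rnorm(S, 0, spec$noise_sd)
    }
    list(expr = expr, lifespans = lifespans, phys_age = pa)
  }
  parts <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  samples$phys_age <- parts$phys_age
  ExpressionStudy(parts$expr, samples, lifespans = parts$lifespans,
                  metadata = list(design = design,
                                  architectures = architectures,
                                  parents = parents))
}

#' Generate architectures for the three parental/RIL contrast scenarios
#'
#' Three canonical genetic architectures relate parental differential
#' expression to eQTL detectability:
#' \describe{
#'   \item{A}{a single strong-effect locus -- parents differ and the locus
#'     maps in the RILs;}
#'   \item{B}{many small same-direction loci -- parents differ (effects
#'     accumulate in the constant parental genomes) but no single locus is
#'     detectable in the panel;}
#'   \item{C}{loci whose effects cancel in the parents -- either a pure
#'     epistatic marker pair (both parents carry the +1 product) or two
#'     opposite-sign additive loci; parental expectations are equal, yet
#'     the RILs segregate and often transgress.}
#' }
#'
#' Default effect sizes (in log2 units, residual SD 0.2): A = one locus of
#' 1.0; B = 20 loci of +0.0125 each, spread as evenly as possible over the
#' chromosomes; C = one pair with product effect 1.0 (or two opposite loci
#' of 0.5 when `c_style = "opposite"`).
#'
#' The B default is a power-analysis construction: the summed 0.5
#' log2-unit parental gap sits near the detection limit of 6 + 6 parental
#' replicates at residual SD 0.2, while balancing the loci across
#' chromosomes caps every chromosome's aggregate allele effect at about
#' 0.04 -- far below what a 36-line panel can map at a single marker. On
#' chromosome-scale linkage (tens of cM), clustered small effects would
#' otherwise merge into one mappable pseudo-locus and turn the scenario
#' into category A.
#'
#' @param kind `"A"`, `"B"` or `"C"`.
#' @param map Genetic map the loci are drawn from.
#' @param n Number of architectures to generate.
#' @param effect Per-locus effect size (total product effect for C).
#' @param n_loci Number of loci for kind B (default 20, allocated
#'   round-robin over shuffled chromosomes).
#' @param c_style For kind C: `"epistatic"` (marker-pair product) or
#'   `"opposite"` (two additive loci of opposite sign, each `effect/2`).
#' @param noise_sd,baseline Passed to [architectureSpec()].
#' @param seed Optional RNG seed (otherwise the current RNG stream is used).
#' @return List of `ArchitectureSpec` with the scenario in `$category`.
#' @examples
#' specs <- categoryArchitectures("A", n = 2, seed = 1)
#' specs[[1]]$additive
#' @export
categoryArchitectures <- function(kind, map = defaultGeneticMap(), n = 1L,
                                  effect = NULL, n_loci = 20L,
                                  c_style = c("epistatic", "opposite"),
                                  noise_sd = 0.2, baseline = 6,
                                  seed = NULL) {
  kind <- match.arg(kind, c("A", "B", "C"))
  c_style <- match.arg(c_style)
  if (is.null(effect)) effect <- switch(kind, A = 1.0, B = 0.0125, C = 1.0)
  chroms <- unique(map$chromosome)
  one <- function() {
    switch(kind,
      A = architectureSpec(
        baseline = baseline, noise_sd = noise_sd, category = "A",
        additive = setNames(effect, sample(map$marker, 1L))),
      B = {
        # loci balanced across chromosomes so no chromosome-level
        # aggregate becomes a mappable pseudo-locus
        alloc <- table(rep(sample(chroms), length.out = n_loci))
        picks <- unlist(lapply(names(alloc), function(ch)
          sample(map$marker[map$chromosome == ch], alloc[[ch]])))
        architectureSpec(
          baseline = baseline, noise_sd = noise_sd, category = "B",
          additive = setNames(rep(effect, n_loci), picks))
      },
      C = {
        chr2 <- sample(chroms, 2L)
        m <- vapply(chr2, function(ch)
          sample(map$marker[map$chromosome == ch], 1L), character(1))
        if (c_style == "epistatic") {
          architectureSpec(
            baseline = baseline, noise_sd = noise_sd, category = "C",
            epistatic = setNames(effect, paste(m, collapse = ":")))
        } else {
          architectureSpec(
            baseline = baseline, noise_sd = noise_sd, category = "C",
            additive = setNames(c(effect, -effect) / 2, m))
        }
      })
  }
  gen <- function() replicate(n, one(), simplify = FALSE)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' True architectures stored with a simulated study
#'
#' @param study An [ExpressionStudy-class] produced by
#'   [simulateExpression()].
#' @return Named list of `ArchitectureSpec`, or `NULL` for non-simulated
#'   studies.
#' @export
architectureTruth <- function(study) metadata(study)$architectures
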
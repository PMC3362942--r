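#' @import methods
#' @importFrom stats var sd rnorm rbinom runif qt pt phyper setNames
#'   complete.cases
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

AGE_GROUPS <- c("t1", "t2", "t3")

#' Two-age analysis windows
#'
#' Named age-group windows used throughout the package: the three single
#' sampling ages and the two-age windows `developing` (t1 + t2) and
#' `aging` (t2 + t3).
#'
#' @param window Window name, one of `"t1"`, `"t2"`, `"t3"`,
#'   `"developing"`, `"aging"`.
#' @return Character vector of age-group labels covered by the window.
#' @examples
#' windowAges("developing")
#' @export
windowAges <- function(window) {
  window <- match.arg(window, c("t1", "t2", "t3", "developing", "aging"))
  switch(window,
    t1 = "t1", t2 = "t2", t3 = "t3",
    developing = c("t1", "t2"),
    aging = c("t2", "t3")
  )
}

## ---------------------------------------------------------------------------
## GeneticMap: a validated data.frame (marker, chromosome, position_cM)
## ---------------------------------------------------------------------------

#' Construct a genetic map
#'
#' A genetic map is a data.frame with columns `marker`, `chromosome` and
#' `position_cM`. Positions must be nonnegative and nondecreasing within
#' each chromosome; marker ids must be unique.
#'
#' @param marker Character vector of unique marker ids.
#' @param chromosome Chromosome label per marker.
#' @param position_cM Genetic position in centiMorgan.
#' @return A `data.frame` of class `GeneticMap`.
#' @examples
#' geneticMap(c("m1", "m2"), c("I", "I"), c(0, 10))
#' @export
geneticMap <- function(marker, chromosome, position_cM) {
  map <- data.frame(
    marker = as.character(marker),
    chromosome = as.character(chromosome),
    position_cM = as.numeric(position_cM),
    stringsAsFactors = FALSE
  )
  validateGeneticMap(map)
  class(map) <- c("GeneticMap", "data.frame")
  map
}

validateGeneticMap <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker", "chromosome", "position_cM") %in% names(map)))
  if (anyDuplicated(map$marker))
    stop("marker ids must be unique")
  if (any(map$position_cM < 0) || anyNA(map$position_cM))
    stop("positions must be nonnegative and non-missing")
  for (chr in unique(map$chromosome)) {
    pos <- map$position_cM[map$chromosome == chr]
    if (length(pos) < 1L) stop("each chromosome needs at least one marker")
    if (is.unsorted(pos))
      stop("marker positions must be nondecreasing within chromosome ", chr)
  }
  invisible(map)
}

#' Default genetic map emulating the N2 x CB4856 marker panel
#'
#' 121 markers spread over six chromosomes (21 on chromosome I, 20 on each
#' of the others), evenly spaced along 50 cM per chromosome -- the marker
#' density of the C. elegans RIL panel this package emulates.
#'
#' @param markers_per_chrom Integer vector of marker counts per chromosome.
#' @param chrom_length_cM Genetic length of each chromosome in cM.
#' @return A `GeneticMap`.
#' @examples
#' map <- defaultGeneticMap()
#' nrow(map)  # 121
#' @export
defaultGeneticMap <- function(markers_per_chrom = c(21L, rep(20L, 5L)),
                              chrom_length_cM = 50) {
  chroms <- c("I", "II", "III", "IV", "V", "X")[seq_along(markers_per_chrom)]
  pieces <- lapply(seq_along(markers_per_chrom), function(i) {
    m <- markers_per_chrom[i]
    data.frame(
      marker = sprintf("c%dm%02d", i, seq_len(m)),
      chromosome = chroms[i],
      position_cM = seq(0, chrom_length_cM, length.out = m),
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  geneticMap(map$marker, map$chromosome, map$position_cM)
}

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' Describe a RIL aging-expression study design
#'
#' Captures the sampling layout of the emulated study: number of RILs, the
#' sampling ages, parental replication, and strain mean lifespans used to
#' convert chronological to physiological age.
#'
#' @param n_rils Number of recombinant inbred lines (>= 2).
#' @param ages_hours Strictly increasing sampling ages in hours.
#' @param parent_replicates_per_age Independent parental replicates per age.
#' @param parent_lifespans_hours Named numeric of length 2: mean lifespan of
#'   the two parents in hours. Defaults to 16 d (N2) and 13 d (CB4856).
#' @param ril_lifespan_range_hours Range the RIL mean lifespans are drawn
#'   from (uniformly); defaults to the interval spanned by the parents.
#' @param seed Optional RNG seed stored with the design.
#' @return A list of class `StudyDesign`.
#' @examples
#' studyDesign(n_rils = 10)
#' @export
studyDesign <- function(n_rils = 36L,
                        ages_hours = c(40, 96, 214),
                        parent_replicates_per_age = 6L,
                        parent_lifespans_hours = c(N2 = 16 * 24,
                                                   CB4856 = 13 * 24),
                        ril_lifespan_range_hours = NULL,
                        seed = NULL) {
  if (n_rils < 2L) stop("n_rils must be >= 2")
  if (length(ages_hours) < 1L || is.unsorted(ages_hours, strictly = TRUE))
    stop("ages_hours must be strictly increasing")
  if (length(ages_hours) > length(AGE_GROUPS))
    stop("at most ", length(AGE_GROUPS), " sampling ages are supported")
  if (length(parent_lifespans_hours) != 2L ||
      is.null(names(parent_lifespans_hours)))
    stop("parent_lifespans_hours must be a named numeric of length 2")
  if (is.null(ril_lifespan_range_hours))
    ril_lifespan_range_hours <- range(parent_lifespans_hours)
  if (any(c(parent_lifespans_hours, ril_lifespan_range_hours) <=
          max(ages_hours)))
    stop("all lifespans must exceed the oldest sampling age")
  design <- list(
    n_rils = as.integer(n_rils),
    ages_hours = as.numeric(ages_hours),
    parent_replicates_per_age = as.integer(parent_replicates_per_age),
    parent_lifespans_hours = parent_lifespans_hours,
    ril_lifespan_range_hours = as.numeric(ril_lifespan_range_hours),
    seed = seed
  )
  class(design) <- "StudyDesign"
  design
}

#' @export
print.StudyDesign <- function(x, ...) {
  cat("StudyDesign:", x$n_rils, "RILs +", length(x$parent_lifespans_hours),
      "parents (", paste(names(x$parent_lifespans_hours), collapse = ", "),
      ")\n  ages (h):", paste(x$ages_hours, collapse = ", "),
      "\n  parental replicates/age:", x$parent_replicates_per_age, "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## ArchitectureSpec
## ---------------------------------------------------------------------------

#' Specify a gene's genetic architecture for simulation
#'
#' Encodes how one simulated transcript responds to genotype and
#' physiological age: additive marker effects, epistatic (marker-pair
#' product) effects, a physiological-age slope, marker-by-age interaction
#' slopes, a baseline log2 level and a Gaussian residual SD.
#'
#' Epistatic effects are named by the two marker ids joined with `":"`.
#'
#' @param baseline Mean log2 expression level.
#' @param additive Named numeric, marker id -> additive effect (log2 units
#'   per allele unit on the -1/+1 coding).
#' @param epistatic Named numeric, `"m1:m2"` -> product effect.
#' @param age_slope Effect of physiological age (log2 units per unit).
#' @param age_by_marker Named numeric, marker id -> interaction slope.
#' @param noise_sd Residual SD on the log2 scale (> 0).
#' @param category Optional label (e.g. `"A"`, `"B"`, `"C"`) recording the
#'   scenario a gene was generated under.
#' @return A list of class `ArchitectureSpec`.
#' @examples
#' architectureSpec(additive = c(c1m05 = 1), noise_sd = 0.2)
#' @export
architectureSpec <- function(baseline = 6,
                             additive = numeric(0),
                             epistatic = numeric(0),
                             age_slope = 0,
                             age_by_marker = numeric(0),
                             noise_sd = 0.2,
                             category = NA_character_) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("noise_sd must be a single positive number")
  for (nm in c("additive", "epistatic", "age_by_marker")) {
    v <- get(nm)
    if (length(v) && is.null(names(v)))
      stop(nm, " effects must be named by marker id")
  }
  spec <- list(baseline = baseline, additive = additive,
               epistatic = epistatic, age_slope = age_slope,
               age_by_marker = age_by_marker, noise_sd = noise_sd,
               category = category)
  class(spec) <- "ArchitectureSpec"
  spec
}

architectureMarkers <- function(spec) {
  epi <- if (length(spec$epistatic))
    unlist(strsplit(names(spec$epistatic), ":", fixed = TRUE))
  else character(0)
  unique(c(names(spec$additive), epi, names(spec$age_by_marker)))
}

## ---------------------------------------------------------------------------
## GenotypePanel (S4)
## ---------------------------------------------------------------------------

#' GenotypePanel: RIL + parent allele matrix with a genetic map
#'
#' Strains-by-markers allele matrix coded -1/+1 (CB4856-type / N2-type
#' alleles), with the two parents stored as the constant rows +1 and -1,
#' plus the genetic map of the markers.
#'
#' @slot alleles Numeric matrix, strains x markers, entries in {-1, +1}.
#' @slot map A `GeneticMap` data.frame describing the marker columns.
#' @slot parents Character vector of length 2: the strain carrying the +1
#'   alleles, then the strain carrying the -1 alleles.
#' @export
setClass("GenotypePanel",
  representation(alleles = "matrix", map = "data.frame",
                 parents = "character"))

setValidity("GenotypePanel", function(object) {
  al <- object@alleles
  msgs <- character(0)
  if (!all(al %in% c(-1, 1)))
    msgs <- c(msgs, "alleles must be coded -1/+1 (fully inbred lines)")
  if (is.null(rownames(al)) || anyDuplicated(rownames(al)))
    msgs <- c(msgs, "strains must be uniquely named")
  if (!identical(colnames(al), object@map$marker))
    msgs <- c(msgs, "allele columns must match the genetic map markers")
  if (length(object@parents) != 2L ||
      !all(object@parents %in% rownames(al))) {
    msgs <- c(msgs, "parents must name two strains in the panel")
  } else {
    if (!all(al[object@parents[1L], ] == 1))
      msgs <- c(msgs, "first parent must carry all +1 alleles")
    if (!all(al[object@parents[2L], ] == -1))
      msgs <- c(msgs, "second parent must carry all -1 alleles")
  }
  ok <- tryCatch({ validateGeneticMap(object@map); TRUE },
                 error = function(e) e$message)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' @param alleles Strains x markers matrix coded -1/+1 with strain rownames
#'   and marker colnames matching `map$marker`.
#' @param map A `GeneticMap`.
#' @param parents Character(2): the +1-coded parent then the -1-coded parent.
#' @return A `GenotypePanel` object.
#' @seealso [simulateGenotypes()]
#' @export
GenotypePanel <- function(alleles, map, parents = c("N2", "CB4856")) {
  new("GenotypePanel", alleles = alleles, map = as.data.frame(map),
      parents = parents)
}

#' @describeIn GenotypePanel-class Allele matrix (strains x markers).
#' @param object,x A `GenotypePanel`.
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @export
setMethod("alleles", "GenotypePanel", function(x) x@alleles)

#' @describeIn GenotypePanel-class The genetic map data.frame.
#' @export
setGeneric("geneticMapOf", function(x) standardGeneric("geneticMapOf"))

#' @export
setMethod("geneticMapOf", "GenotypePanel", function(x) x@map)

#' @describeIn GenotypePanel-class Names of the two parental strains.
#' @export
setGeneric("parentNames", function(x) standardGeneric("parentNames"))

#' @export
setMethod("parentNames", "GenotypePanel", function(x) x@parents)

#' @describeIn GenotypePanel-class Names of the RIL strains.
#' @export
setGeneric("rilNames", function(x) standardGeneric("rilNames"))

#' @export
setMethod("rilNames", "GenotypePanel", function(x)
  setdiff(rownames(x@alleles), x@parents))

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", length(rilNames(object)), "RILs + parents",
      paste(object@parents, collapse = "/"), "\n ",
      ncol(object@alleles), "markers on",
      length(unique(object@map$chromosome)), "chromosomes\n")
  freq <- colMeans(object@alleles[rilNames(object), , drop = FALSE] == 1)
  cat("  RIL +1 allele frequency: ",
      sprintf("%.2f-%.2f", min(freq), max(freq)), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ExpressionStudy (S4, extends SummarizedExperiment)
## ---------------------------------------------------------------------------

#' ExpressionStudy: log2 expression with aging-study sample metadata
#'
#' A `SummarizedExperiment` with assays `expr` (log2 intensities,
#' genes x samples) and `mask` (logical, `TRUE` = value retained), and
#' column metadata `strain`, `age_hours`, `age_group` (t1/t2/t3),
#' `replicate`, `is_parent` and `phys_age` (age divided by the strain's
#' mean lifespan). The strain lifespan table lives in
#' `metadata(x)$lifespans`.
#'
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msgs <- character(0)
  if (!all(c("expr", "mask") %in% names(assays(object))))
    msgs <- c(msgs, "assays 'expr' and 'mask' are required")
  need <- c("strain", "age_hours", "age_group", "replicate", "is_parent")
  missing_cols <- setdiff(need, colnames(colData(object)))
  if (length(missing_cols))
    msgs <- c(msgs, paste("missing sample metadata:",
                          paste(missing_cols, collapse = ", ")))
  if (!length(msgs)) {
    if (!all(colData(object)$age_group %in% AGE_GROUPS))
      msgs <- c(msgs, "age_group must be one of t1/t2/t3")
    if (!is.logical(assay(object, "mask")))
      msgs <- c(msgs, "mask assay must be logical")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param expr Genes x samples numeric matrix of log2 intensities.
#' @param samples data.frame of per-sample metadata with columns `strain`,
#'   `age_hours`, `age_group`, `replicate`, `is_parent` (rows aligned with
#'   the columns of `expr`).
#' @param lifespans Optional data.frame (`strain`, `mean_lifespan_hours`)
#'   used to compute physiological age; when supplied every sample's strain
#'   must be present.
#' @param mask Optional logical matrix of retained values (default all
#'   `TRUE`).
#' @param metadata Extra metadata list entries.
#' @return An `ExpressionStudy`.
#' @seealso [simulateExpression()], [physiologicalAge()]
#' @export
ExpressionStudy <- function(expr, samples, lifespans = NULL, mask = NULL,
                            metadata = list()) {
  expr <- as.matrix(expr)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  }
  samples <- as.data.frame(samples)
  if (nrow(samples) != ncol(expr))
    stop("samples must have one row per expression column")
  if (is.null(samples$phys_age)) {
    if (!is.null(lifespans)) {
      ls <- setNames(lifespans$mean_lifespan_hours, lifespans$strain)
      if (!all(samples$strain %in% names(ls)))
        stop("every sample strain needs a lifespan entry")
      samples$phys_age <- physiologicalAge(samples$age_hours,
                                           ls[samples$strain])
    } else {
      samples$phys_age <- NA_real_
    }
  }
  md <- c(list(lifespans = lifespans), metadata)
  se <- SummarizedExperiment(
    assays = list(expr = expr, mask = mask),
    colData = DataFrame(samples, row.names = colnames(expr)),
    metadata = md
  )
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy-class Expression matrix; by default masked
#'   values are returned as `NA`.
#' @param x An `ExpressionStudy`.
#' @param masked Apply the retention mask (masked entries become `NA`)?
#' @export
exprMatrix <- function(x, masked = TRUE) {
  e <- assay(x, "expr")
  if (masked) e[!assay(x, "mask")] <- NA_real_
  e
}

#' @describeIn ExpressionStudy-class Sample metadata as a plain data.frame.
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

#' @describeIn ExpressionStudy-class Per-sample physiological age.
#' @export
physAge <- function(x) colData(x)$phys_age

#' @describeIn ExpressionStudy-class Strain lifespan table.
#' @export
lifespanTable <- function(x) metadata(x)$lifespans

setMethod("show", "ExpressionStudy", function(object) {
  info <- sampleInfo(object)
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n",
      " strains:", length(unique(info$strain)),
      "(", sum(!info$is_parent[!duplicated(info$strain)]), "RILs )\n",
      " ages (h):", paste(sort(unique(info$age_hours)), collapse = ", "),
      "\n  masked values:", sum(!assay(object, "mask")), "\n")
})
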
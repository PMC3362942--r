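test_that("candidate markers maximize the minimum pairwise spacing", {
  # chromosome with exactly 4 markers: all are forced in
  m4 <- geneticMap(sprintf("m%d", 1:4), rep("c1", 4), c(0, 5, 20, 30))
  expect_setequal(selectCandidateMarkers(m4)$markers, m4$marker)
  # the emulated panel: 4 per chromosome x 6 chromosomes = 24
  cand <- selectCandidateMarkers(defaultGeneticMap())
  expect_length(cand$markers, 24L)
  expect_equal(ncol(cand$pairs), choose(24, 2))
  # 21 equally spaced markers: exhaustive oracle over C(21, 4); several
  # sets tie at the optimal minimum distance and the deterministic
  # tie-break picks the lexicographically smallest position vector
  m21 <- geneticMap(sprintf("m%02d", 1:21), rep("c1", 21), seq(0, 50, 2.5))
  sel <- selectCandidateMarkers(m21)$markers
  combos <- combn(21, 4)
  minds <- apply(combos, 2, function(ix) min(dist(m21$position_cM[ix])))
  expect_equal(min(dist(m21$position_cM[match(sel, m21$marker)])),
               max(minds))
  expect_identical(sel, selectCandidateMarkers(m21)$markers)
  expect_true("m01" %in% sel)   # smallest tied set starts at the left end
  expect_error(selectCandidateMarkers(tinyMap(n_per_chrom = 3)),
               "fewer than")
})

makeStepwiseFixture <- function(n_rils = 36, seed = 70) {
  d <- studyDesign(n_rils = n_rils, seed = seed)
  map <- defaultGeneticMap()
  panel <- simulateGenotypes(d, map)
  cand <- selectCandidateMarkers(map)
  list(design = d, map = map, panel = panel, cand = cand)
}

stepwiseInputs <- function(fx, study) {
  info <- sampleInfo(study)
  cols <- which(!info$is_parent & info$age_group %in% c("t1", "t2"))
  list(cols = cols,
       geno = alleles(fx$panel)[info$strain[cols], fx$cand$markers],
       a = info$phys_age[cols])
}

test_that("stepwise BIC recovers a strong single locus near a candidate", {
  fx <- makeStepwiseFixture()
  # place the causal locus on a candidate marker so recovery is exact
  causal <- fx$cand$markers[7]
  st <- simulateExpression(fx$panel, fx$design, list(
    g = architectureSpec(additive = setNames(1.0, causal),
                         noise_sd = 0.2)), seed = 71)
  inp <- stepwiseInputs(fx, st)
  m <- stepwiseBic(exprMatrix(st)[1, inp$cols], inp$geno, inp$a, fx$cand)
  expect_true(paste0("M:", causal) %in% m$selected_terms)
  expect_lte(m$bic, m$start_bic)
  expect_lte(length(m$selected_terms), 6L)
  expect_lte(m$n_steps_used, 2000L)
})

test_that("a pure epistatic pair enters as an interaction term", {
  fx <- makeStepwiseFixture(seed = 72)
  pair <- c(fx$cand$markers[2], fx$cand$markers[10])  # different chromosomes
  st <- simulateExpression(fx$panel, fx$design, list(
    g = architectureSpec(epistatic = setNames(1.0, paste(pair, collapse = ":")),
                         noise_sd = 0.2)), seed = 73)
  inp <- stepwiseInputs(fx, st)
  m <- stepwiseBic(exprMatrix(st)[1, inp$cols], inp$geno, inp$a, fx$cand)
  expect_true(m$has_epistasis)
  expect_true(any(grepl(pair[1], m$selected_terms) &
                    grepl(pair[2], m$selected_terms)))
})

test_that("stepwise selection is deterministic and respects its budgets", {
  fx <- makeStepwiseFixture(seed = 74)
  st <- simulateExpression(fx$panel, fx$design,
                           replicate(3, architectureSpec(noise_sd = 0.3),
                                     simplify = FALSE), seed = 75)
  inp <- stepwiseInputs(fx, st)
  for (gi in 1:3) {
    y <- exprMatrix(st)[gi, inp$cols]
    m1 <- stepwiseBic(y, inp$geno, inp$a, fx$cand)
    m2 <- stepwiseBic(y, inp$geno, inp$a, fx$cand)
    expect_identical(m1$selected_terms, m2$selected_terms)
    expect_lte(m1$bic, m1$start_bic)
    expect_lte(length(m1$selected_terms), 6L)
  }
  # tighter budgets bind
  y <- exprMatrix(st)[1, inp$cols]
  m3 <- stepwiseBic(y, inp$geno, inp$a, fx$cand, max_terms = 2L)
  expect_lte(length(m3$selected_terms), 2L)
  m0 <- stepwiseBic(y, inp$geno, inp$a, fx$cand, max_steps = 0L)
  expect_identical(m0$selected_terms, "A")
})

test_that("constant expression returns the null model", {
  fx <- makeStepwiseFixture(seed = 76)
  st <- simulateExpression(fx$panel, fx$design,
                           list(architectureSpec(noise_sd = 0.3)),
                           seed = 77)
  inp <- stepwiseInputs(fx, st)
  m <- stepwiseBic(rep(4, length(inp$cols)), inp$geno, inp$a, fx$cand)
  expect_length(m$selected_terms, 0L)
  expect_equal(m$n_markers, 0L)
  expect_false(m$has_epistasis)
})

test_that("stepwise BIC equals a direct lm refit of the selected terms", {
  fx <- makeStepwiseFixture(seed = 78)
  st <- simulateExpression(fx$panel, fx$design, list(
    architectureSpec(additive = setNames(0.8, fx$cand$markers[3]),
                     age_slope = 1, noise_sd = 0.25)), seed = 79)
  inp <- stepwiseInputs(fx, st)
  y <- exprMatrix(st)[1, inp$cols]
  m <- stepwiseBic(y, inp$geno, inp$a, fx$cand)
  X <- wormAgeQTL:::termColumns(m$selected_terms, inp$geno, inp$a)
  fit <- lm(y ~ X)
  n <- length(y)
  k <- length(m$selected_terms) + 1L
  expect_equal(m$bic, n * log(sum(resid(fit)^2) / n) + k * log(n),
               tolerance = 1e-8)
})

test_that("multilocusModels and polygenicSummary wire genes through", {
  fx <- makeStepwiseFixture(seed = 80)
  archs <- c(categoryArchitectures("A", fx$map, n = 3, seed = 81),
             replicate(3, architectureSpec(noise_sd = 0.3),
                       simplify = FALSE))
  st <- simulateExpression(fx$panel, fx$design, archs, seed = 82)
  ml <- multilocusModels(st, fx$panel, "developing", fx$cand)
  expect_equal(nrow(ml), 6L)
  expect_true(all(ml$n_steps_used <= 2000L))
  h2 <- heritabilityTable(st, "developing")
  ps <- polygenicSummary(ml, h2, bins = c(-Inf, 0.5, 1))
  expect_true(all(c("pct_any_marker", "pct_epistasis") %in% names(ps)))
  # strong single-locus genes sit in the upper heritability bin with
  # at least one selected marker
  top <- ps[ps$bin == "(0.5,1]", ]
  expect_equal(unique(ml$window), "developing")
  expect_gte(sum(top$n_genes), 3)
})
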
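test_that("RIL genotypes are inbred, parents constant, seed-reproducible", {
  d <- studyDesign(n_rils = 10, seed = 7)
  panel <- simulateGenotypes(d, tinyMap())
  al <- alleles(panel)
  expect_true(all(al %in% c(-1, 1)))
  expect_true(all(al["N2", ] == 1))
  expect_true(all(al["CB4856", ] == -1))
  expect_identical(rilNames(panel), sprintf("RIL%03d", 1:10))
  panel2 <- simulateGenotypes(d, tinyMap())
  expect_identical(alleles(panel), alleles(panel2))
  panel3 <- simulateGenotypes(studyDesign(n_rils = 10, seed = 8), tinyMap())
  expect_false(identical(alleles(panel), alleles(panel3)))
})

test_that("zero map distance gives uniform chromosomes (no recombinants)", {
  m <- geneticMap(sprintf("m%d", 1:5), rep("chr1", 5), rep(3, 5))
  panel <- simulateGenotypes(studyDesign(n_rils = 30, seed = 1), m)
  al <- alleles(panel)[rilNames(panel), ]
  expect_true(all(apply(al, 1L, function(r) length(unique(r)) == 1L)))
})

test_that("non-monotone map positions are rejected", {
  expect_error(geneticMap(c("a", "b"), c("chr1", "chr1"), c(10, 5)),
               "nondecreasing")
})

test_that("allele frequency at a single marker is binomial around 1/2", {
  m <- geneticMap("m1", "chr1", 0)
  panel <- simulateGenotypes(studyDesign(n_rils = 2000, seed = 11), m)
  n1 <- sum(alleles(panel)[rilNames(panel), 1] == 1)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.5)
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])
})

test_that("adjacent-marker switch fraction matches the selfed-RIL map expansion", {
  d_cM <- 10
  r <- (1 - exp(-2 * d_cM / 100)) / 2
  R <- 2 * r / (1 + 2 * r)
  m <- geneticMap(c("m1", "m2"), c("chr1", "chr1"), c(0, d_cM))
  panel <- simulateGenotypes(studyDesign(n_rils = 2000, seed = 3), m)
  al <- alleles(panel)[rilNames(panel), ]
  obs <- mean(al[, 1] != al[, 2])
  se <- sqrt(R * (1 - R) / 2000)
  expect_lt(abs(obs - R), 3 * se)
})

test_that("null architecture reproduces baseline with chi-square-consistent noise", {
  d <- studyDesign(n_rils = 10, seed = 2)
  panel <- simulateGenotypes(d, tinyMap())
  sd0 <- 0.25
  st <- simulateExpression(panel, d, list(
    g1 = architectureSpec(baseline = 5, noise_sd = sd0)))
  vals <- exprMatrix(st)[1, ]
  n <- length(vals)
  expect_lt(abs(mean(vals) - 5), 4 * sd0 / sqrt(n))
  stat <- (n - 1) * var(vals) / sd0^2
  expect_gt(stat, qchisq(0.005, n - 1))
  expect_lt(stat, qchisq(0.995, n - 1))
  # near-zero noise: everything collapses onto the baseline
  st0 <- simulateExpression(panel, d, list(
    g1 = architectureSpec(baseline = 5, noise_sd = 1e-9)))
  expect_equal(unname(exprMatrix(st0)[1, ]), rep(5, n), tolerance = 1e-6)
})

test_that("an additive effect a separates RIL allele groups by 2a", {
  d <- studyDesign(n_rils = 30, seed = 4)
  panel <- simulateGenotypes(d, tinyMap())
  a <- 0.7
  st <- simulateExpression(panel, d, list(
    g1 = architectureSpec(additive = c(c1m03 = a), noise_sd = 1e-9)))
  info <- sampleInfo(st)
  cols <- which(!info$is_parent & info$age_group == "t1")
  al <- alleles(panel)[info$strain[cols], "c1m03"]
  v <- exprMatrix(st)[1, cols]
  expect_equal(mean(v[al > 0]) - mean(v[al < 0]), 2 * a, tolerance = 1e-6)
})

test_that("pure epistasis leaves single-marker marginal means near zero", {
  d <- studyDesign(n_rils = 500, seed = 5)
  m <- tinyMap(n_per_chrom = 2L, n_chrom = 2L)
  panel <- simulateGenotypes(d, m)
  st <- simulateExpression(panel, d, list(
    g1 = architectureSpec(epistatic = c("c1m01:c2m01" = 1), noise_sd = 0.01)))
  info <- sampleInfo(st)
  cols <- which(!info$is_parent & info$age_group == "t1")
  v <- exprMatrix(st)[1, cols]
  for (mk in c("c1m01", "c2m01")) {
    al <- alleles(panel)[info$strain[cols], mk]
    gap <- mean(v[al > 0]) - mean(v[al < 0])
    expect_lt(abs(gap), 3 * 2 / sqrt(length(v) / 2))
  }
})

test_that("physiological age enters through the strain lifespan", {
  d <- studyDesign(n_rils = 5, seed = 6)
  panel <- simulateGenotypes(d, tinyMap())
  st <- simulateExpression(panel, d, list(
    g1 = architectureSpec(age_slope = 3, noise_sd = 1e-9)))
  info <- sampleInfo(st)
  expect_equal(unname(exprMatrix(st)[1, ]),
               unname(6 + 3 * info$phys_age), tolerance = 1e-6)
  ls <- lifespanTable(st)
  expect_equal(ls$mean_lifespan_hours[ls$strain == "N2"], 384)
  expect_equal(ls$mean_lifespan_hours[ls$strain == "CB4856"], 312)
})

test_that("category architectures have the intended parental contrasts", {
  map <- tinyMap()
  # parents are the constant +1 / -1 genomes; pair products are +1 in
  # both, so only additive effects contribute to the parental gap
  parent_gap <- function(spec) 2 * sum(spec$additive)
  a <- categoryArchitectures("A", map, n = 1, seed = 1)[[1]]
  expect_length(a$additive, 1L)
  expect_equal(parent_gap(a), 2 * sum(a$additive))
  b <- categoryArchitectures("B", map, n = 1, effect = 0.05, n_loci = 10,
                             seed = 2)[[1]]
  expect_length(b$additive, 10L)
  expect_equal(parent_gap(b), 1.0)          # 2 * 10 * 0.05
  expect_equal(unname(b$additive[1]) * 2, 0.1)  # per-marker group gap
  # default B: 20 loci balanced over chromosomes, parental gap 0.5
  b_def <- categoryArchitectures("B", defaultGeneticMap(), n = 1,
                                 seed = 3)[[1]]
  expect_length(b_def$additive, 20L)
  expect_equal(parent_gap(b_def), 0.5)
  chrom_of <- defaultGeneticMap()$chromosome[
    match(names(b_def$additive), defaultGeneticMap()$marker)]
  expect_true(all(table(chrom_of) <= 4))
  ce <- categoryArchitectures("C", map, n = 1, seed = 3)[[1]]
  expect_length(ce$epistatic, 1L)
  expect_equal(parent_gap(ce), 0)
  co <- categoryArchitectures("C", map, n = 1, c_style = "opposite",
                              seed = 4)[[1]]
  expect_equal(sum(co$additive), 0)
  expect_error(categoryArchitectures("D", map), "arg")
})

test_that("expression simulation is bit-reproducible under a fixed seed", {
  d <- studyDesign(n_rils = 8, seed = 9)
  panel <- simulateGenotypes(d, tinyMap())
  archs <- categoryArchitectures("A", tinyMap(), n = 3, seed = 10)
  s1 <- simulateExpression(panel, d, archs, seed = 11)
  s2 <- simulateExpression(panel, d, archs, seed = 11)
  expect_identical(exprMatrix(s1), exprMatrix(s2))
  expect_identical(sampleInfo(s1)$phys_age, sampleInfo(s2)$phys_age)
})

test_that("architectures referencing unknown markers are rejected", {
  d <- studyDesign(n_rils = 5, seed = 1)
  panel <- simulateGenotypes(d, tinyMap())
  expect_error(simulateExpression(panel, d, list(
    architectureSpec(additive = c(nope = 1)))), "unknown markers")
})
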
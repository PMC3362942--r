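test_that("single-age heritability follows (V_RIL - V_P)/V_RIL exactly", {
  # v_ril = 4 (RIL values -2, 0, 2), pooled parental variance 0.5
  h <- heritabilitySingleAge(c(-2, 0, 2),
                             list(c(5.5, 6.5), c(3.5, 4.5)))
  expect_equal(h$v_ril, 4)
  expect_equal(h$v_p, 0.5)
  expect_equal(h$h2, (4 - 0.5) / 4)
  # replicate-identical parents: V_P = 0 -> h2 = 1
  h1 <- heritabilitySingleAge(c(1, 2, 3), list(c(7, 7, 7), c(4, 4, 4)))
  expect_equal(h1$h2, 1)
  # V_P > V_RIL -> negative heritability is retained
  hn <- heritabilitySingleAge(c(-1, 0, 1), list(c(-2, 0), c(0, 2)))
  expect_equal(hn$v_ril, 1)
  expect_equal(hn$v_p, 2)
  expect_equal(hn$h2, -1)
  # pooled V_P weights parents by replicate degrees of freedom
  hw <- heritabilitySingleAge(c(-2, 0, 2),
                              list(c(0, 2), c(1, 1, 1, 1, 1, 3)))
  expect_equal(hw$v_p, (1 * 2 + 5 * var(c(1, 1, 1, 1, 1, 3))) / 6)
  expect_error(heritabilitySingleAge(c(1, 2), list(c(1, 2), c(1, 2))),
               "3 RIL")
  expect_error(heritabilitySingleAge(c(1, 2, 3), list(c(1), c(1, 2))),
               "2 replicates")
})

test_that("h2 is invariant to shifting and scaling expression", {
  set.seed(50)
  rils <- rnorm(10); p1 <- rnorm(4); p2 <- rnorm(4)
  h <- heritabilitySingleAge(rils, list(p1, p2))$h2
  expect_equal(heritabilitySingleAge(rils + 5, list(p1 + 5, p2 + 5))$h2, h,
               tolerance = 1e-12)
  expect_equal(heritabilitySingleAge(3 * rils, list(3 * p1, 3 * p2))$h2, h,
               tolerance = 1e-12)
  expect_lte(h, 1)
})

test_that("over-time heritability isolates the genotype main effect", {
  # stable strain offsets, noiseless parents -> h2 = 1
  offs <- c(-1, 0, 1, 2)
  ril2 <- cbind(offs + 0.5, offs + 1.5)     # same offset at both ages
  par2 <- list(list(c(3, 3), c(4, 4)), list(c(2, 2), c(3, 3)))
  h <- heritabilityOverTime(ril2, par2)
  expect_equal(h$h2, 1)
  # a pure crossing interaction (two-age means equal) with parental noise
  # cannot look heritable
  inter <- cbind(c(-1, 1, -1, 1), c(1, -1, 1, -1)) +
    matrix(rnorm(8, 0, 1e-4), 4)
  par_noise <- list(list(rnorm(4, 3, 0.3), rnorm(4, 3, 0.3)),
                    list(rnorm(4, 2, 0.3), rnorm(4, 2, 0.3)))
  h2i <- heritabilityOverTime(inter, par_noise)$h2
  expect_lte(h2i, 0)
  # an age main effect common to every strain changes nothing
  h_shift <- heritabilityOverTime(cbind(ril2[, 1], ril2[, 2] + 10), par2)
  expect_equal(h_shift$h2, h$h2, tolerance = 1e-12)
})

test_that("over-time V_P is the environmental variance of a two-age mean", {
  set.seed(51)
  p11 <- rnorm(6); p12 <- rnorm(6); p21 <- rnorm(6); p22 <- rnorm(6)
  h <- heritabilityOverTime(cbind(rnorm(5), rnorm(5)),
                            list(list(p11, p12), list(p21, p22)))
  pooled <- (var(p11) + var(p12) + var(p21) + var(p22)) * 5 / 20
  expect_equal(h$v_p, pooled / 2, tolerance = 1e-12)
})

test_that("study-level table matches the per-gene estimators", {
  fx <- nullStudy(n_genes = 8, n_rils = 6, seed = 52)
  st <- fx$study
  info <- sampleInfo(st)
  e <- exprMatrix(st)
  tab1 <- heritabilityTable(st, "t1")
  rils <- e[3, which(!info$is_parent & info$age_group == "t1")]
  pr <- lapply(c("N2", "CB4856"), function(p)
    e[3, which(info$strain == p & info$age_group == "t1")])
  expect_equal(tab1$h2[3], heritabilitySingleAge(rils, pr)$h2,
               tolerance = 1e-12)

  tabD <- heritabilityTable(st, "developing")
  ril_strains <- unique(info$strain[!info$is_parent])
  m <- sapply(c("t1", "t2"), function(gr) {
    cols <- which(!info$is_parent & info$age_group == gr)
    v <- e[3, cols]; names(v) <- info$strain[cols]
    v[ril_strains]
  })
  pr2 <- lapply(c("N2", "CB4856"), function(p)
    lapply(c("t1", "t2"), function(gr)
      e[3, which(info$strain == p & info$age_group == gr)]))
  expect_equal(tabD$h2[3], heritabilityOverTime(m, pr2)$h2,
               tolerance = 1e-12)
})

test_that("permutation cutoff: fdr = 1 admits the minimum observed h2", {
  fx <- nullStudy(n_genes = 30, n_rils = 10, seed = 53)
  cut <- highH2Cutoff(fx$study, "t1", fdr = 1, n_perm = 5, seed = 54)
  obs <- cut$observed_h2
  expect_equal(cut$cutoff, min(obs[is.finite(obs)]))
})

test_that("permutation cutoff separates spiked from null heritability", {
  d <- studyDesign(n_rils = 36, seed = 55)
  map <- tinyMap()
  panel <- simulateGenotypes(d, map)
  # 20% of genes carry strong genetic signal (true h2 about 0.9)
  n_spike <- 30; n_null <- 120
  archs <- c(categoryArchitectures("A", map, n = n_spike, effect = 0.6,
                                   noise_sd = 0.2, seed = 56),
             replicate(n_null, architectureSpec(noise_sd = 0.2),
                       simplify = FALSE))
  st <- simulateExpression(panel, d, archs, seed = 57)
  cut <- highH2Cutoff(st, "t1", fdr = 0.01, n_perm = 20, seed = 58)
  expect_false(is.na(cut$cutoff))
  expect_gt(cut$cutoff, 0.4)
  expect_lt(cut$cutoff, 0.9)
  spiked_h2 <- cut$observed_h2[seq_len(n_spike)]
  expect_gte(mean(spiked_h2 >= cut$cutoff), 0.8)
})

test_that("pure-null studies admit no high-heritability cutoff below the max", {
  fx <- nullStudy(n_genes = 60, n_rils = 12, seed = 59)
  cut <- highH2Cutoff(fx$study, "t1", fdr = 0.01, n_perm = 20, seed = 60)
  obs_max <- max(cut$observed_h2[is.finite(cut$observed_h2)])
  expect_true(is.na(cut$cutoff) || cut$cutoff >= obs_max - 1e-9 ||
                cut$n_flagged <= 3L)
})
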
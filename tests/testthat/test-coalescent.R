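# Scenario grammar and simulator correctness. Heavy distributional checks
# (10^4-replicate closed forms) live in the acceptance suite; here we use
# smaller replicate counts plus an independent plain-R coalescent oracle.

tplParams <- studyTemplate()$params

test_that("scenario codes build the documented event structure", {
  b3 <- buildScenario("B3", tplParams)
  expect_identical(b3@mode, "peripatric")
  expect_match(paste(b3@events$event, collapse = "; "), "founded from deme 1")
  expect_match(paste(b3@events$event, collapse = "; "), "N1b -> N1")
  expect_true(all(diff(b3@events$time) >= 0))
  expect_equal(unname(b3@migrationWindows[1, ]), c(0, tplParams@t0))

  a1 <- buildScenario("A1", tplParams)
  expect_identical(nrow(a1@migrationWindows), 0L)
  expect_identical(a1@mode, "peripatric")
  d <- peripagen:::scenarioEpochs(a1)
  expect_true(all(d$m12 == 0) && all(d$m21 == 0))

  expect_identical(buildScenario("C2", scenarioParams(
    N1 = 1e4, N2 = 1e3, N2f = 100, NAnc = 1e4,
    t0 = 500, t1 = 600, t2 = 800, t3 = 1000, m12 = 1e-6))@mode, "complex")

  expect_error(buildScenario("E1", tplParams), "unknown scenario code")
  expect_error(buildScenario("C1", tplParams), "t2")
  expect_error(scenarioParams(N1 = 1e4, N2 = 1e3, t0 = 2000, t1 = 500,
                              t3 = 1000), "t0 < t3")
})

test_that("epoch table encodes sizes and migration windows faithfully", {
  d <- peripagen:::scenarioEpochs(buildScenario("B3", tplParams))
  expect_equal(d$brk, c(0, tplParams@t0, tplParams@t1, tplParams@t3))
  expect_equal(d$N1, c(tplParams@N1, tplParams@N1b, tplParams@N1b,
                       tplParams@NAnc))
  expect_equal(d$N2, c(tplParams@N2, tplParams@N2, tplParams@N2f,
                       tplParams@N2f))
  expect_equal(d$m12, c(tplParams@m12, 0, 0, 0))  # recent window only
  expect_equal(d$tMerge, tplParams@t3)
})

test_that("simulation is deterministic in the seed", {
  d <- peripagen:::scenarioEpochs(buildScenario("A1", tplParams))
  g1 <- peripagen:::simLocusMatrix(d, 20, 10, 1e-4, 42)
  g2 <- peripagen:::simLocusMatrix(d, 20, 10, 1e-4, 42)
  g3 <- peripagen:::simLocusMatrix(d, 20, 10, 1e-4, 43)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
})

test_that("single-lineage genealogy is empty and n = 2 TMRCA is calibrated", {
  g0 <- simulateGenealogy(peripagen:::constantDemography(100), 1, 0, seed = 1)
  expect_identical(g0$n, 1L)
  expect_equal(g0$time, 0)

  N <- 800
  tm <- vapply(1:3000, function(i)
    max(simulateGenealogy(peripagen:::constantDemography(N), 2, 0,
                          seed = i)$time), 1)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
})

test_that("total branch length matches 4N sum(1/i) at n = 10", {
  N <- 500
  tl <- vapply(1:3000, function(i) {
    g <- simulateGenealogy(peripagen:::constantDemography(N), 10, 0,
                           seed = 5000 + i)
    sum(g$time[g$parent[1:18]] - g$time[1:18])
  }, 1)
  se <- sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - 4 * N * sum(1 / (1:9))), 3 * se)
})

test_that("dropMutations obeys the infinite-sites contract", {
  g <- simulateGenealogy(peripagen:::constantDemography(200), 8, 0, seed = 9)
  z <- dropMutations(g, lengthBp = 100, mu = 0, seed = 1)
  expect_identical(ncol(z$genotypes), 0L)
  z2 <- dropMutations(g, lengthBp = 500, mu = 1e-4, seed = 2)
  expect_identical(ncol(z2$genotypes), length(z2$positions))
  expect_false(any(duplicated(z2$positions)))
  expect_true(all(z2$positions >= 0 & z2$positions < 500))
  # overflow guard: enormous rate on a tiny locus cannot map to fresh sites
  expect_error(dropMutations(g, lengthBp = 2, mu = 1, seed = 3),
               "overflow")
  # agreement with the compiled mutation dropper on E[S] (both near
  # theta * a1(8) = 12.96)
  muL <- 5 / (4 * 200)
  sR <- vapply(1:800, function(i)
    ncol(dropMutations(simulateGenealogy(peripagen:::constantDemography(200),
                                         8, 0, seed = i),
                       lengthBp = 1000, mu = muL / 1000,
                       seed = i)$genotypes), 1)
  sC <- vapply(1:800, function(i)
    ncol(peripagen:::simLocusMatrix(peripagen:::constantDemography(200),
                                    8, 0, muL, 1e6 + i)), 1)
  se <- sqrt(var(sR) / 800 + var(sC) / 800)
  expect_lt(abs(mean(sR) - mean(sC)), 3 * se)
})

test_that("engine agrees with the plain-R oracle on A1 and C1", {
  set.seed(99)
  nrep <- 600
  muL <- 2e-4
  for (code in c("A1", "C1")) {
    p <- scenarioParams(N1 = 2000, N2 = 800, N2f = 150, NAnc = 2000,
                        t0 = 500, t1 = 700,
                        t2 = if (code == "C1") 2000 else NA, t3 = 4000)
    d <- peripagen:::scenarioEpochs(buildScenario(code, p))
    eng <- vapply(seq_len(nrep), function(i) {
      m <- peripagen:::simLocusMatrix(d, 8, 6, muL, 7e5 + i)
      c(S = ncol(m), pi = nucleotideDiversity(m, perSite = FALSE),
        phist = peripagen:::locusStatRow(m, 8, 6, 1)[["phist"]])
    }, numeric(3))
    orc <- vapply(seq_len(nrep), function(i) {
      m <- oracleLocus(8, 6, d, muL)
      c(S = ncol(m), pi = nucleotideDiversity(m, perSite = FALSE),
        phist = peripagen:::locusStatRow(m, 8, 6, 1)[["phist"]])
    }, numeric(3))
    for (k in 1:3) {
      se <- sqrt(var(eng[k, ]) / nrep + var(orc[k, ]) / nrep)
      expect_lt(abs(mean(eng[k, ]) - mean(orc[k, ])), 3 * se)
    }
  }
})

test_that("deeper divergence increases PhiST monotonically in the mean", {
  muL <- 3e-4
  mean_phist <- vapply(c(500, 4000, 30000), function(t3) {
    p <- scenarioParams(N1 = 2000, N2 = 1000, N2f = 400,
                        t0 = t3 / 4, t1 = t3 / 4, t3 = t3)
    d <- peripagen:::scenarioEpochs(buildScenario("A1", p))
    mean(vapply(1:400, function(i) {
      m <- peripagen:::simLocusMatrix(d, 10, 10, muL, 3e5 + i)
      peripagen:::locusStatRow(m, 10, 10, 1)[["phist"]]
    }, 1))
  }, 1)
  expect_true(all(diff(mean_phist) > 0))
  expect_gt(mean_phist[3], 0.8)  # deep-divergence limit approaches 1
})

test_that("expected joint SFS respects symmetry and neutral marginals", {
  # symmetric two-deme scenario: spectrum symmetric under deme swap
  p <- scenarioParams(N1 = 1000, N2 = 1000, N2f = 1000, NAnc = 1000,
                      t0 = 100, t1 = 100, t3 = 200, m12 = 1e-3, m21 = 1e-3)
  scn <- buildScenario("A5", p)
  loci <- data.frame(locus = "l", length = 1000L, mu = 1e-6, ploidy = 1)
  js <- expectedJointSFS(scn, loci, 6, 6, nSims = 4000, seed = 10)
  M <- js@M
  expect_equal(peripagen:::sumPolymorphic(M), 1, tolerance = 1e-9)
  asym <- max(abs(M - t(M)))
  expect_lt(asym, 0.02)
  # merged single deme: marginal spectrum proportional to 1/i
  p2 <- scenarioParams(N1 = 1000, N2 = 1000, N2f = 1000, NAnc = 1000,
                       t0 = 1, t1 = 1, t3 = 2)
  js2 <- expectedJointSFS(buildScenario("A1", p2), loci, 8, 0,
                          nSims = 4000, seed = 11)
  marg <- rowSums(js2@M)[2:8]
  expect_equal(marg / marg[1], (1 / 1:7) / 1, tolerance = 0.08)
  # zero mutation rate is flagged
  loci0 <- data.frame(locus = "l", length = 1000L, mu = 0, ploidy = 1)
  expect_error(expectedJointSFS(scn, loci0, 6, 6, nSims = 10, seed = 1),
               "zero")
})
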
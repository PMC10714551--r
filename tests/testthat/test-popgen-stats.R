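# Statistics are checked against hand enumeration on the canonical toys
# and against brute-force oracles on randomized inputs.

t4 <- peripagen:::t4Fixture()

test_that("T4 toy matches hand-enumerated values exactly", {
  expect_identical(segregatingSites(t4), 2L)
  hs <- haplotypeSummary(t4)
  expect_identical(hs$Nh, 3L)
  expect_equal(hs$Hd, (4 / 3) * (1 - (0.25^2 + 0.25^2 + 0.5^2)))
  expect_equal(nucleotideDiversity(t4), (7 / 6) / 10)
  expect_equal(wattersonTheta(t4), 2 / ((11 / 6) * 10))
  # Tajima's D by direct constant evaluation (independent re-derivation)
  n <- 4; S <- 2; piL <- 7 / 6
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  Dexp <- (piL - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimaD(t4), Dexp)
  expect_equal(round(Dexp, 2), 0.59)
  # Fay & Wu H: xi = (0, 1, 1) against the all-A outgroup
  sfs <- unfoldedSFS(t4)
  expect_identical(sfs$counts, c(0L, 1L, 1L))
  expect_equal(fayWuH(t4), 7 / 6 - 26 / 12)
  expect_equal(fayWuH(t4, perSite = TRUE), -0.1)
  # joint SFS with populations {s1}, {s2}
  pm <- data.frame(sample_id = c("s1", "s2"), population = c("f", "y"))
  M <- jointSFS(t4, pm)@M
  expect_equal(M[0 + 1, 2 + 1], 1)
  expect_equal(M[1 + 1, 2 + 1], 1)
  expect_equal(sum(M), 2)
})

test_that("degenerate and boundary cases behave as documented", {
  mono <- matrix("A", 4, 10)
  expect_identical(segregatingSites(mono), 0L)
  expect_equal(nucleotideDiversity(mono), 0)
  expect_true(is.na(tajimaD(mono)))
  expect_true(is.na(fuLiStar(mono)[["Dstar"]]))
  expect_true(is.na(fuFS(mono)))
  hs <- haplotypeSummary(mono)
  expect_identical(hs$Nh, 1L)
  expect_equal(hs$Hd, 0)
  # all distinct haplotypes: Hd = 1
  dist4 <- matrix(c("A", "C", "G", "T"), 4, 3)
  expect_equal(haplotypeSummary(dist4)$Hd, 1)
  # n = 2 closed forms
  m2 <- matrix(c("A", "T"), 2, 1)
  expect_equal(wattersonTheta(m2, perSite = FALSE), 1)  # a1 = 1
  expect_equal(fuFS(m2), 0)                             # S' = theta/(1+theta) = 1/2
  expect_equal(fayWuH(m2, outgroup = matrix("A", 1, 1)), 0)  # pi = thetaH at n = 2
  # outgroup with a third allele: site skipped
  m3 <- matrix(c("A", "A", "T", "T"), 4, 1)
  sfs3 <- unfoldedSFS(m3, outgroup = matrix("G", 1, 1))
  expect_identical(sum(sfs3$counts), 0L)
  expect_identical(sfs3$nSkipped, 1L)
})

test_that("Fu's FS matches exact Ewens enumeration at n = 3", {
  # toy: 3 sequences, 2 haplotypes, pi_L = 4/3
  m <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L))
  expect_identical(haplotypeSummary(m)$Nh, 2L)
  theta <- nucleotideDiversity(m, perSite = FALSE)
  expect_equal(theta, 4 / 3)
  # Ewens, n = 3: |s(3,k)| = 2, 3, 1
  denom <- theta * (theta + 1) * (theta + 2)
  pk <- c(2 * theta, 3 * theta^2, theta^3) / denom
  expect_equal(sum(pk), 1)
  Sprime <- sum(pk[2:3])
  expect_equal(fuFS(m), log(Sprime / (1 - Sprime)))
})

test_that("excess singletons force Fu & Li's D* negative", {
  n <- 30
  m <- diag(1L, n)  # every mutation a singleton
  fl <- fuLiStar(m)
  expect_lt(fl[["Dstar"]], 0)
  expect_lt(fl[["Fstar"]], 0)
})

test_that("Rm lower bound matches the exhaustive stabbing oracle", {
  expect_identical(minRecombination(matrix(c(0L, 0L, 1L, 1L), 4, 1)), 0L)
  fg <- peripagen:::fourGameteFixture()
  expect_identical(minRecombination(fg), 1L)
  # three mutually incompatible sites reduce to 2 events
  tri <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  storage.mode(tri) <- "integer"
  expect_identical(bruteForceRm(tri), 2L)
  expect_identical(minRecombination(tri), 2L)
  # randomized agreement with the brute-force oracle
  set.seed(31)
  for (rep in 1:40) {
    m <- randomToy(n = sample(5:9, 1), S = sample(2:7, 1))
    expect_identical(minRecombination(m), bruteForceRm(m),
                     info = paste("rep", rep))
  }
})

test_that("SFS-pi identity holds exactly on random toys", {
  set.seed(17)
  for (rep in 1:100) {
    m <- randomToy()
    n <- nrow(m)
    piBrute <- bruteForcePi(m)
    expect_equal(nucleotideDiversity(m), piBrute, tolerance = 1e-12)
    sfs <- unfoldedSFS(m, outgroup = matrix("0", 1, ncol(m)))
    expect_equal(sfsPi(sfs$counts, n, ncol(m)), piBrute, tolerance = 1e-12)
  }
})

test_that("statistic bounds hold on random toys", {
  set.seed(23)
  for (rep in 1:50) {
    m <- randomToy()
    hs <- haplotypeSummary(m)
    expect_gte(hs$Hd, 0); expect_lte(hs$Hd, 1 + 1e-12)
    expect_gte(nucleotideDiversity(m), 0)
    expect_gte(wattersonTheta(m), 0)
    expect_gte(minRecombination(m), 0L)
  }
})

test_that("PhiST is 1 for fixed demes, near 0 for identical demes", {
  fixed <- rbind(matrix(0L, 5, 4), matrix(1L, 5, 4))
  r <- phiSt(fixed, rep(c("a", "b"), each = 5), nPerm = 99, seed = 1)
  expect_equal(r$phiST, 1)
  expect_lt(r$p, 0.05)
  expect_equal(r$hudsonFst, 1)

  same <- rbind(diag(1L, 4), diag(1L, 4))
  r0 <- phiSt(same, rep(c("a", "b"), each = 4), nPerm = 199, seed = 2)
  expect_lt(abs(r0$phiST), 0.35)
  expect_gt(r0$p, 0.05)
})

test_that("permutation p-values are uniform under the null", {
  # homogeneous data: p over repeated datasets should be ~ U(0,1); enough
  # sites are needed for the permutation distribution to be effectively
  # continuous (with very few sites ties make the test conservative)
  set.seed(41)
  pvals <- replicate(400, {
    m <- matrix(rbinom(12 * 40, 1, 0.4), 12, 40)
    phiSt(m, rep(c("a", "b"), each = 6), nPerm = 199,
          seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("private and shared site classification is correct", {
  # site 1: private to pop1; site 2: shared; site 3: fixed difference
  m <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L),
             c(0L, 0L, 1L), c(0L, 1L, 1L))
  ps <- privateSharedSites(m, rep(c("a", "b"), each = 2))
  expect_identical(unname(ps["private1"]), 1L)
  expect_identical(unname(ps["shared"]), 1L)
  expect_identical(unname(ps["fixedDiff"]), 1L)
  expect_identical(unname(ps["private2"]), 0L)
})

test_that("locusStatsTable emits per-population and pooled rows", {
  tpl <- smallTemplate(nLoci = 3L, totalBp = 1200L, nInd1 = 5L, nInd2 = 4L)
  ds <- generateDataset(tpl, seed = 11)
  tab <- locusStatsTable(ds)
  expect_setequal(unique(tab$population), c("pop1", "pop2", "pooled"))
  expect_identical(nrow(tab), 4L * 3L)  # 3 loci + cpDNA, 3 rows each
  expect_true(all(tab$pi >= 0))
  expect_true(all(tab$Hd >= 0 & tab$Hd <= 1 + 1e-12, na.rm = TRUE))
  # undefined statistics are NA, never silently zero: monomorphic check
  mono <- tab[tab$S == 0, ]
  if (nrow(mono) > 0) expect_true(all(is.na(mono$tajimaD)))
})
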
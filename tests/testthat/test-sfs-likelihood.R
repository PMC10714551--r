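test_that("composite log-likelihood arithmetic and oracles agree", {
  # single polymorphic entry: m = 10, p = 0.1 -> 10 log10(0.1) = -10
  Mo <- matrix(0, 3, 3); Mo[2, 1] <- 10
  Me <- matrix(0, 3, 3); Me[2, 1] <- 0.1; Me[3, 1] <- 0.9
  expect_equal(compositeLogLik(Mo, Me, Z = 1e9), -10)

  # brute-force agreement on random spectra
  set.seed(3)
  for (rep in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    Mo <- matrix(rpois((n1 + 1) * (n2 + 1), 2), n1 + 1, n2 + 1)
    Mo[1, 1] <- 0; Mo[n1 + 1, n2 + 1] <- 0
    Me <- matrix(runif((n1 + 1) * (n2 + 1)), n1 + 1, n2 + 1)
    Me[1, 1] <- 0; Me[n1 + 1, n2 + 1] <- 0
    if (sum(Mo) == 0) next
    poly <- Me; poly <- poly / peripagen:::sumPolymorphic(poly)
    direct <- sum(Mo * log10(pmax(poly, 1e-300)), na.rm = TRUE) -
      Mo[1, 1] * log10(pmax(poly[1, 1], 1e-300))
    expect_equal(compositeLogLik(Mo, Me, Z = 1e12), direct, tolerance = 1e-9)
  }
})

test_that("composite likelihood is maximized at empirical frequencies", {
  set.seed(4)
  Mo <- matrix(rpois(16, 3), 4, 4); Mo[1, 1] <- 0; Mo[4, 4] <- 0
  emp <- Mo / peripagen:::sumPolymorphic(Mo)
  clEmp <- compositeLogLik(Mo, emp, Z = 1e12)
  for (rep in 1:20) {
    alt <- matrix(runif(16), 4, 4); alt[1, 1] <- 0; alt[4, 4] <- 0
    expect_gte(clEmp, compositeLogLik(Mo, alt, Z = 1e12))
  }
  # log-linearity: scaling counts scales the likelihood
  expect_equal(compositeLogLik(3 * Mo, emp, Z = 1e12), 3 * clEmp)
})

test_that("AIC identities hold", {
  expect_equal(aic(-1000, 7), 14 + 2000 * log(10))
  expect_equal(round(aic(-1000, 7), 2), 4619.17)
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-50, 4) - aic(-50, 3), 2)
})

test_that("point bounds return the point; fits are seed-deterministic", {
  truth <- scenarioParams(N1 = 2e4, N2 = 5e3, N2f = 500, t0 = 1000,
                          t1 = 1500, t3 = 8000)
  scn <- buildScenario("A1", truth)
  loci <- data.frame(locus = "l", length = 2000L, mu = 1e-6, ploidy = 1)
  mats <- peripagen:::simLociMatrices(peripagen:::scenarioEpochs(scn),
                                      10, 10, 2e-3, 5)
  obs <- peripagen:::jsfsFromMatrices(mats, 10, 10)

  pt <- priorSpec(data.frame(
    param = c("N1", "N2", "N2f", "t1", "t3"),
    min = c(2e4, 5e3, 500, 1500, 8000),
    max = c(2e4, 5e3, 500, 1500, 8000),
    log = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  fit <- fitScenario(obs, "A1", bounds = pt, loci = loci, nSims = 300,
                     nLoops = 2, nRestarts = 1, evalsPerLoop = 5, seed = 6)
  expect_equal(unname(fit$free["t3"]), 8000)
  expect_equal(unname(fit$free["N1"]), 2e4)
  expect_true(is.finite(fit$maxLog10CL))
  expect_equal(fit$aic, aic(fit$maxLog10CL, 5))

  fit2 <- fitScenario(obs, "A1", bounds = pt, loci = loci, nSims = 300,
                      nLoops = 2, nRestarts = 1, evalsPerLoop = 5, seed = 6)
  expect_identical(fit$maxLog10CL, fit2$maxLog10CL)
  expect_identical(fit$free, fit2$free)
})

test_that("scenario comparison dedupes codes and ranks by AIC", {
  truth <- scenarioParams(N1 = 2e4, N2 = 5e3, N2f = 500, t0 = 1000,
                          t1 = 1500, t3 = 8000)
  loci <- data.frame(locus = "l", length = 2000L, mu = 1e-6, ploidy = 1)
  mats <- peripagen:::simLociMatrices(
    peripagen:::scenarioEpochs(buildScenario("A1", truth)), 10, 10, 2e-3, 7)
  obs <- peripagen:::jsfsFromMatrices(mats, 10, 10)
  expect_warning(
    cmp <- compareScenarios(obs, c("A1", "A1"), loci = loci, seed = 2,
                            nSims = 200, nLoops = 1, nRestarts = 1,
                            evalsPerLoop = 5),
    "duplicate")
  expect_identical(nrow(cmp$table), 1L)
  expect_equal(cmp$table$dAIC, 0)
})

test_that("bootstrap CIs bracket a stable MLE on a smoke run", {
  loci <- data.frame(locus = "l", length = 2000L, mu = 1e-6, ploidy = 1)
  pt <- priorSpec(data.frame(
    param = c("N1", "N2", "N2f", "t1", "t3"),
    min = c(1e4, 2e3, 200, 800, 4000),
    max = c(4e4, 1e4, 2000, 3000, 16000),
    log = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  truth <- scenarioParams(N1 = 2e4, N2 = 5e3, N2f = 500, t0 = 1000,
                          t1 = 1500, t3 = 8000)
  mats <- peripagen:::simLociMatrices(
    peripagen:::scenarioEpochs(buildScenario("A1", truth)), 10, 10, 2e-3, 8)
  obs <- peripagen:::jsfsFromMatrices(mats, 10, 10)
  fit <- fitScenario(obs, "A1", bounds = pt, loci = loci, nSims = 300,
                     nLoops = 2, nRestarts = 2, evalsPerLoop = 10, seed = 9)
  bc <- bootstrapCI(fit, loci, 10, 10, nBoot = 2, seed = 10, bounds = pt,
                    nSims = 300, nLoops = 1, nRestarts = 1,
                    evalsPerLoop = 8)
  expect_identical(dim(bc$ci), c(5L, 2L))
  expect_true(all(bc$ci[, "lo"] <= bc$ci[, "hi"]))
  expect_identical(nrow(bc$estimates), 2L)
})
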
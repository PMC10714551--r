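test_that("prior draws respect bounds, constraints, and log-uniformity", {
  sp <- priorSpec(data.frame(param = "x", min = 0, max = 1, log = FALSE))
  d <- samplePriors(sp, 1e4, seed = 1)
  expect_true(all(d$x >= 0 & d$x <= 1))
  expect_lt(abs(mean(d$x) - 0.5), 3 * sd(d$x) / sqrt(1e4))

  spc <- priorSpec(data.frame(param = c("t0", "t3"),
                              min = c(0, 0), max = c(10, 10),
                              log = c(FALSE, FALSE)),
                   constraints = "t0 < t3")
  dc <- samplePriors(spc, 5000, seed = 2)
  expect_true(all(dc$t0 < dc$t3))

  spl <- priorSpec(data.frame(param = "N", min = 1e3, max = 1e6, log = TRUE))
  dl <- samplePriors(spl, 2e4, seed = 3)
  expect_lt(abs(log10(median(dl$N)) - 4.5), 0.05)

  tight <- priorSpec(data.frame(param = c("a", "b"), min = c(0, 0),
                                max = c(1, 1), log = c(FALSE, FALSE)),
                     constraints = "a > b + 0.9999")
  expect_error(samplePriors(tight, 10, seed = 4), "acceptance rate")
})

test_that("rejection matches an exhaustive distance sort", {
  set.seed(8)
  stats <- cbind(s1 = rnorm(200), s2 = rnorm(200, sd = 4))
  tab <- toyReferenceTable(stats, rep(c("X", "Y"), each = 100))
  obs <- c(s1 = 0.2, s2 = -1)
  idx <- abcReject(obs, tab, tolerance = 0.1)
  # brute force: standardize, sort
  z <- sweep(sweep(stats, 2, tab@center), 2, tab@scale, "/")
  zo <- (obs - tab@center) / tab@scale
  d <- sqrt(colSums((t(z) - zo)^2))
  expect_identical(as.integer(idx), order(d)[1:20])
  expect_equal(unname(attr(idx, "distance")), sort(d)[1:20])
  # tolerance = 1 retains everything; exact self-match comes first
  expect_identical(length(abcReject(obs, tab, tolerance = 1)), 200L)
  obsRow <- stats[57, ]
  expect_identical(as.integer(abcReject(obsRow, tab, tolerance = 1 / 200)[1]),
                   57L)
})

test_that("rescaling a raw statistic leaves retained sets unchanged", {
  set.seed(9)
  stats <- cbind(a = rnorm(150), b = runif(150))
  tab <- toyReferenceTable(stats, rep(c("X", "Y", "Z"), each = 50))
  obs <- c(a = 0.3, b = 0.6)
  idx1 <- abcReject(obs, tab, 0.05)
  stats2 <- stats
  stats2[, "b"] <- stats2[, "b"] * 1000
  tab2 <- toyReferenceTable(stats2, tab@scenario)
  obs2 <- obs; obs2["b"] <- obs2["b"] * 1000
  idx2 <- abcReject(obs2, tab2, 0.05)
  expect_identical(as.integer(idx1), as.integer(idx2))
})

test_that("direct posterior is the retained scenario frequency", {
  stats <- cbind(s = c(rep(0, 6), rep(10, 4)))
  tab <- toyReferenceTable(stats, c(rep("B1", 6), rep("A1", 4)))
  idx <- suppressWarnings(abcReject(c(s = 0), tab, tolerance = 0.6))
  p <- posteriorDirect(tab, idx)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["B1"]), 1)
  # hand-count on a mixed retained set
  p2 <- posteriorDirect(tab, c(1L, 2L, 7L, 8L))
  expect_equal(unname(p2["B1"]), 0.5)
  expect_equal(unname(p2["A1"]), 0.5)
})

test_that("logistic posterior tracks the signal and an independent fit", {
  set.seed(11)
  # no signal: stats independent of label -> close to direct frequencies
  stats <- cbind(s1 = rnorm(400), s2 = rnorm(400))
  lab <- rep(c("X", "Y"), times = c(240, 160))
  tab <- toyReferenceTable(stats, lab)
  obs <- c(s1 = 0, s2 = 0)
  idx <- abcReject(obs, tab, tolerance = 1)
  pl <- posteriorLogistic(tab, idx, obs)
  pd <- posteriorDirect(tab, idx)
  expect_equal(unname(pl$posterior["X"]), unname(pd["X"]), tolerance = 0.08)
  expect_equal(sum(pl$posterior), 1, tolerance = 1e-9)

  # perfectly separated: probability -> 1 for the matching scenario
  statsSep <- cbind(s1 = c(rnorm(100, -6), rnorm(100, 6)))
  tabSep <- toyReferenceTable(statsSep, rep(c("X", "Y"), each = 100))
  obsSep <- c(s1 = -6)
  idxS <- abcReject(obsSep, tabSep, tolerance = 1)
  plS <- posteriorLogistic(tabSep, idxS, obsSep)
  expect_gt(unname(plS$posterior["X"]), 0.98)

  # two-class Gaussian toy against an independent binomial GLM
  set.seed(12)
  x <- c(rnorm(300, 0.6), rnorm(300, -0.6))
  tab2 <- toyReferenceTable(cbind(s1 = x), rep(c("X", "Y"), each = 300))
  obs2 <- c(s1 = 0.25)
  idx2 <- abcReject(obs2, tab2, tolerance = 1)
  pl2 <- posteriorLogistic(tab2, idx2, obs2)
  xs <- (x - obs2) / tab2@scale
  gfit <- glm(I(rep(c(0, 1), each = 300)) ~ xs, family = binomial())
  pY <- plogis(coef(gfit)[1])
  expect_equal(unname(pl2$posterior["Y"]), unname(pY), tolerance = 1e-4)
  expect_true(all(pl2$ci[, "lo"] <= pl2$posterior + 1e-9))
  expect_true(all(pl2$ci[, "hi"] >= pl2$posterior - 1e-9))
})

test_that("local-linear adjustment recovers a linear generating value", {
  set.seed(13)
  n <- 400
  param <- runif(n, 0, 10)
  stat <- 2 * param + rnorm(n, sd = 0.3)
  tab <- new("ReferenceTable", scenario = rep("A1", n),
             params = data.frame(theta = param),
             stats = cbind(s = stat),
             center = median(stat), scale = mad(stat),
             config = list(priors = list(A1 = priorSpec(
               data.frame(param = "theta", min = 0, max = 10,
                          log = FALSE)))))
  names(tab@center) <- names(tab@scale) <- "s"
  truth <- 4.2
  obs <- c(s = 2 * truth)
  idx <- abcReject(obs, tab, tolerance = 0.5)
  adj <- adjustParamsLocLinear(tab, idx, obs, code = "A1")
  expect_lt(abs(adj$summary["theta", "q50"] - truth), 0.25)
  expect_lt(adj$summary["theta", "q97.5"] - adj$summary["theta", "q2.5"], 2)
  # CI brackets the median
  expect_lt(adj$summary["theta", "q2.5"], adj$summary["theta", "q50"])
  expect_gt(adj$summary["theta", "q97.5"], adj$summary["theta", "q50"])

  # stat uncorrelated with the parameter: adjusted ~ raw retained draws
  stat0 <- rnorm(n)
  tab0 <- tab
  tab0@stats <- cbind(s = stat0)
  tab0@center <- setNames(median(stat0), "s")
  tab0@scale <- setNames(mad(stat0), "s")
  idx0 <- abcReject(c(s = 0), tab0, tolerance = 0.5)
  adj0 <- adjustParamsLocLinear(tab0, idx0, c(s = 0), code = "A1")
  raw <- param[idx0]
  expect_lt(abs(median(adj0$samples$theta) - median(raw)), 0.6)
})

test_that("confidence evaluation yields a stochastic confusion matrix", {
  tpl <- smallTemplate(nLoci = 4L, totalBp = 1600L, nInd1 = 6L, nInd2 = 5L)
  tab <- buildReferenceTable(c("A1", "C1"), R = 60, loci = tpl$loci,
                             n1 = tpl$n1, n2 = tpl$n2, seed = 21)
  cf <- suppressWarnings(evaluateConfidence(tab, nPods = 8, tolerance = 0.1,
                                            seed = 22))
  expect_equal(unname(rowSums(cf$confusion)), c(1, 1))
  expect_true(all(cf$typeI >= 0 & cf$typeI <= 1))
  expect_true(all(cf$typeII >= 0 & cf$typeII <= 1))
})

test_that("reference tables are consistent with independent statistics", {
  tpl <- smallTemplate(nLoci = 4L, totalBp = 1600L, nInd1 = 6L, nInd2 = 5L)
  tab <- buildReferenceTable("A1", R = 10, loci = tpl$loci,
                             n1 = tpl$n1, n2 = tpl$n2, seed = 33)
  expect_identical(nrow(tab@stats), 10L)
  expect_false(anyNA(tab@stats))
  expect_identical(colnames(tab@stats)[1], "Nh1_mean")
})
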
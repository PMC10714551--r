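test_that("study template reproduces the design shape", {
  tpl <- studyTemplate()
  nuc <- tpl$loci[tpl$loci$ploidy >= 1, ]
  expect_identical(sum(nuc$length), 6077L)
  expect_identical(nrow(nuc), 14L)
  expect_identical(tpl$n1, 224L)
  expect_identical(tpl$n2, 126L)
  expect_identical(tpl$loci$length[tpl$loci$locus == "cpdna"], 1589L)
  expect_identical(tpl$scenario, "B3")
  p <- tpl$params
  expect_equal(p@t3, 146000)   # 3.65 Ma at 25 y/generation
  expect_equal(p@t0, 24400)
  expect_equal(p@t1, 26000)
  expect_equal(tpl$loci$mu[1], 5.58e-9)
})

test_that("generated datasets validate and are seed-reproducible on disk", {
  tpl <- smallTemplate()
  d1 <- file.path(tempdir(), "gen1")
  d2 <- file.path(tempdir(), "gen2")
  unlink(c(d1, d2), recursive = TRUE)
  ds1 <- generateDataset(tpl, seed = 7, outdir = d1)
  ds2 <- generateDataset(tpl, seed = 7, outdir = d2)
  expect_length(validateDataset(ds1), 0L)
  f1 <- list.files(d1)
  expect_true(all(c("popmap.tsv", "provenance.json", "cpdna.fasta") %in% f1))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  ds3 <- generateDataset(tpl, seed = 8)
  expect_false(identical(
    as.character(haplotypes(ds1@nuclearLoci[[1]])),
    as.character(haplotypes(ds3@nuclearLoci[[1]]))))
  # cpDNA is haploid: one haplotype per individual
  expect_identical(length(ds1@cpdna), tpl$nInd1 + tpl$nInd2)
})

test_that("zero mutation rate yields monomorphic loci", {
  tpl <- smallTemplate(nLoci = 3L, totalBp = 900L, nInd1 = 4L, nInd2 = 3L)
  tpl$loci$mu <- 0
  ds <- generateDataset(tpl, seed = 2, withOutgroup = FALSE)
  for (aln in ds@nuclearLoci)
    expect_identical(segregatingSites(aln), 0L)
})

test_that("simulated-matrix statistics equal statistics from the FASTA", {
  tpl <- smallTemplate(nLoci = 5L, totalBp = 2000L, nInd1 = 8L, nInd2 = 6L)
  seed <- 19
  ds <- generateDataset(tpl, seed = seed, withOutgroup = TRUE)
  # reconstruct the generator's per-locus substreams to get raw matrices
  scn <- buildScenario(tpl$scenario, tpl$params)
  demog <- peripagen:::scenarioEpochs(scn)
  seeds <- peripagen:::childSeeds(seed, 2L * nrow(tpl$loci))
  nuc <- which(tpl$loci$ploidy >= 1)
  mats <- lapply(nuc, function(l)
    peripagen:::simLocusMatrix(demog, tpl$n1, tpl$n2,
                               tpl$loci$mu[l] * tpl$loci$length[l],
                               seeds[l]))
  fast <- datasetStats(mats, tpl$n1, tpl$n2, tpl$loci$length[nuc])
  slow <- observedStats(ds)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("divergence raises PhiST relative to a panmictic control", {
  tpl <- smallTemplate(nLoci = 5L, totalBp = 2000L, nInd1 = 8L, nInd2 = 6L)
  shallow <- tpl$params
  shallow@t3 <- 30; shallow@t0 <- 10; shallow@t1 <- 10
  phis <- function(params, seedBase) {
    mean(vapply(1:12, function(i) {
      ds <- generateDataset(tpl, params = params, seed = seedBase + i,
                            withOutgroup = FALSE)
      obs <- observedStats(ds)
      obs[["phist_mean"]]
    }, 1))
  }
  expect_gt(phis(tpl$params, 100), phis(shallow, 200))
})

test_that("micro-fixtures are written, stable, and self-consistent", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- makeFixtures(d1)
  p2 <- makeFixtures(d2)
  expect_true(all(file.exists(p1)))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  t4 <- peripagen:::splitOutgroupRecords(
    readAlignment(file.path(d1, "t4.fasta")))
  expect_identical(segregatingSites(t4), 2L)
  expect_equal(nucleotideDiversity(t4), 0.11667, tolerance = 1e-4)
  expect_equal(haplotypeSummary(t4)$Hd, 0.8333, tolerance = 1e-4)
  expect_match(readLines(file.path(d1, "README.md"))[1], "fixtures")
  hka <- read.table(file.path(d1, "hka_toy.tsv"), header = TRUE)
  expect_identical(nrow(hka), 2L)
})

test_that("pipeline closure: stats, ABC, and SFS fit run on one dataset", {
  tpl <- smallTemplate(nLoci = 4L, totalBp = 1600L, nInd1 = 6L, nInd2 = 5L)
  ds <- generateDataset(tpl, seed = 55, withOutgroup = TRUE)
  expect_length(validateDataset(ds), 0L)
  obs <- observedStats(ds)
  tab <- buildReferenceTable(c("A1", "B1"), R = 40, loci = tpl$loci,
                             n1 = tpl$n1, n2 = tpl$n2, seed = 56)
  post <- posteriorDirect(tab, suppressWarnings(abcReject(obs, tab, 0.25)))
  expect_equal(sum(post), 1)
  js <- observedJointSFS(ds)
  expect_s4_class(js, "JointSFS")
  fit <- fitScenario(js, "A1", loci = tpl$loci, nSims = 150, nLoops = 1,
                     nRestarts = 1, evalsPerLoop = 6, seed = 57)
  expect_true(is.finite(fit$aic))
})
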
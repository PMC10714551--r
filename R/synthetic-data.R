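# Study-shaped synthetic datasets: the package's end-to-end testbed.

#' The study template: sampling design and generating point estimates
#'
#' Shapes the synthetic data after the study design this pipeline targets:
#' 14 phased nuclear loci totalling 6,077 bp (433 bp x 13 + 448 bp x 1 by
#' default; per-locus lengths are configurable), 112 + 63 diploid
#' individuals in two populations (224 + 126 phased haplotypes), and one
#' haploid organellar locus of 1,589 bp (901 + 688 bp regions
#' concatenated) carried by every individual. The default generating
#' scenario is B3 -- deme 2 founded from deme 1 at t3 with recent
#' asymmetric migration during the deme-1 expansion -- at the point
#' estimates N1 = 5.17e5, N2 = 3.63e4, t3 = 3.65 Ma, t0 = 0.61 Ma,
#' t1 = 0.65 Ma, m12 = 1.91e-7, m21 = 8.37e-7, mu = 5.58e-9 per site per
#' generation, generation time 25 years. The pre-expansion and founder
#' sizes (not identified by point estimates) default to N1/10 and N2/10;
#' the outgroup calibration depth defaults to 16.7 Ma.
#'
#' @param nLoci number of nuclear loci.
#' @param totalBp total nuclear length.
#' @param nInd1,nInd2 diploid individuals per population.
#' @return list with `loci` (locus table: `locus`, `length`, `mu`,
#'   `ploidy`), `n1`, `n2` (haplotype counts), `nInd1`, `nInd2`,
#'   `scenario` (code), `params` ([ScenarioParams-class]),
#'   `generationTime`, `tOutgroup` (generations).
#' @export
studyTemplate <- function(nLoci = 14L, totalBp = 6077L, nInd1 = 112L,
                          nInd2 = 63L) {
  base <- totalBp %/% nLoci
  lens <- rep(base, nLoci)
  lens[nLoci] <- totalBp - base * (nLoci - 1L)
  rc <- rateConstants()
  loci <- data.frame(
    locus = c(sprintf("nuc%02d", seq_len(nLoci)), "cpdna"),
    length = c(lens, 1589L),
    mu = rc$muPerGen,
    ploidy = c(rep(1, nLoci), 0.5),
    stringsAsFactors = FALSE)
  gt <- rc$generationTime
  params <- scenarioParams(
    N1 = 5.17e5, N2 = 3.63e4,
    N1b = 5.17e4, N2f = 3.63e3, NAnc = 5.17e5,
    t0 = yearsToGenerations(0.61e6, gt),
    t1 = yearsToGenerations(0.65e6, gt),
    t3 = yearsToGenerations(3.65e6, gt),
    m12 = 1.91e-7, m21 = 8.37e-7)
  list(loci = loci, n1 = 2L * nInd1, n2 = 2L * nInd2,
       nInd1 = nInd1, nInd2 = nInd2,
       scenario = "B3", params = params, generationTime = gt,
       tOutgroup = yearsToGenerations(16.7e6, gt))
}

#' Generate a study-shaped dataset on disk
#'
#' Simulates a [StudyDataset-class] under the template (or a chosen
#' scenario/parameter set), writes one FASTA per locus (outgroup records
#' included), the popmap TSV, and a provenance JSON (code, parameters,
#' seed). Byte-identical for identical seeds.
#'
#' @param template from [studyTemplate()].
#' @param scenarioCode scenario code (default the template's).
#' @param params a [ScenarioParams-class] (default the template's).
#' @param seed integer seed.
#' @param outdir output directory (created); NULL keeps the dataset in
#'   memory only.
#' @param withOutgroup simulate outgroup divergence at the template's
#'   calibration depth.
#' @return the [StudyDataset-class] (invisibly if written to disk).
#' @export
generateDataset <- function(template = studyTemplate(),
                            scenarioCode = template$scenario,
                            params = template$params, seed = 1L,
                            outdir = NULL, withOutgroup = TRUE) {
  scn <- buildScenario(scenarioCode, params)
  nm <- list(pop1 = sprintf("F%03d", seq_len(template$nInd1)),
             pop2 = sprintf("Y%03d", seq_len(template$nInd2)))
  ds <- simulateDataset(scn, template$loci, template$n1, template$n2,
                        seed = seed,
                        tOutgroup = if (withOutgroup) template$tOutgroup else 0,
                        sampleNames = nm)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (aln in ds@nuclearLoci)
      writeAlignment(aln, file.path(outdir, paste0(locusId(aln), ".fasta")),
                     withOutgroup = TRUE)
    if (!is.null(ds@cpdna))
      writeAlignment(ds@cpdna, file.path(outdir, "cpdna.fasta"),
                     withOutgroup = TRUE)
    writePopMap(ds@popmap, file.path(outdir, "popmap.tsv"))
    prov <- list(scenario = scenarioCode,
                 params = paramsAsList(params),
                 seed = unbox0(seed),
                 nLoci = nrow(template$loci),
                 n1 = template$n1, n2 = template$n2)
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(ds))
  }
  ds
}

paramsAsList <- function(p) {
  list(N1 = p@N1, N2 = p@N2, N1b = p@N1b, N2f = p@N2f, NAnc = p@NAnc,
       t0 = p@t0, t1 = p@t1, t2 = p@t2, t3 = p@t3, m12 = p@m12, m21 = p@m21)
}

unbox0 <- function(x) as.vector(x)[1]

#' Write deterministic micro-fixtures for unit testing
#'
#' Creates, under `outdir`:
#' \itemize{
#' \item `t4.fasta` -- the 4-haplotype x 10 bp toy whose statistics are
#'   known by hand enumeration (S = 2, Nh = 3, Hd = 0.8333,
#'   pi = 0.11667 per site, theta_w = 0.10909 per site, Tajima's D =
#'   0.5916, Fay and Wu's H = -1 against the all-A outgroup).
#' \item `fourgamete.fasta` -- 4 haplotypes whose two sites show all four
#'   gametes (Rm = 1).
#' \item `hka_toy.tsv` -- a 2-locus HKA input.
#' \item `abc_toy.tsv` -- a 60-row, 2-scenario reference table with
#'   well-separated Gaussian statistics.
#' \item `README.md` -- every expected value with the oracle that
#'   produced it.
#' }
#'
#' @param outdir output directory (created).
#' @return character vector of written paths.
#' @export
makeFixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  t4 <- t4Fixture()
  p <- file.path(outdir, "t4.fasta")
  writeAlignment(t4, p, withOutgroup = TRUE)
  paths <- c(paths, p)
  fg <- fourGameteFixture()
  p <- file.path(outdir, "fourgamete.fasta")
  writeAlignment(fg, p)
  paths <- c(paths, p)
  hka <- data.frame(locus = c("L1", "L2"), S = c(4L, 10L), D = c(6.0, 14.0),
                    n = c(8L, 8L), L = c(500L, 500L))
  p <- file.path(outdir, "hka_toy.tsv")
  write.table(hka, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  abc <- abcToyTable()
  p <- file.path(outdir, "abc_toy.tsv")
  write.table(abc, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  readme <- c(
    "# Micro-fixtures",
    "",
    "## t4.fasta",
    "4 haplotypes x 10 bp (2 samples x 2 haplotypes) + all-A outgroup.",
    "Hand-enumerated values (6 sequence pairs; differences 1,2,2,1,1,0):",
    "S = 2; Nh = 3; Hd = (4/3)(1 - (0.25^2 + 0.25^2 + 0.5^2)) = 0.83333;",
    "pi = (7/6)/10 = 0.11667/site; theta_w = 2/(11/6 x 10) = 0.10909/site;",
    "Tajima's D = 0.59158 (direct constant evaluation, a1 = 11/6);",
    "unfolded SFS xi = (0, 1, 1); Fay & Wu H = 7/6 - 26/12 = -1 per locus.",
    "Joint SFS for pops {s1}, {s2}: M[0,2] and M[1,2] each 1.",
    "",
    "## fourgamete.fasta",
    "Sites 1 and 10 carry gametes AA/AT/TA/TT: Rm = 1 (four-gamete test).",
    "",
    "## hka_toy.tsv",
    "Two-locus HKA input; expected chi2 equals the brute-force grid",
    "minimization over (theta1, theta2, T) computed in the test suite.",
    "",
    "## abc_toy.tsv",
    "60 rows, scenarios X/Y, two Gaussian statistics separated by 4 sd;",
    "rejection retained sets must match an exhaustive distance sort.")
  p <- file.path(outdir, "README.md")
  writeLines(readme, p)
  c(paths, p)
}

# the canonical 4-haplotype toy (2 diploid samples), all-A outgroup
t4Fixture <- function() {
  newLocusAlignment(
    "t4",
    c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT", "AAAAAAAATT"),
    sampleId = c("s1", "s1", "s2", "s2"),
    haplotypeIndex = c(1L, 2L, 1L, 2L),
    outgroup = "AAAAAAAAAA")
}

fourGameteFixture <- function() {
  newLocusAlignment(
    "fourgamete",
    c("AAAAAAAAAA", "AAAAAAAAAT", "TAAAAAAAAA", "TAAAAAAAAT"),
    sampleId = c("s1", "s1", "s2", "s2"),
    haplotypeIndex = c(1L, 2L, 1L, 2L))
}

abcToyTable <- function() {
  set <- expand.grid(row = 1:30, scen = c("X", "Y"),
                     stringsAsFactors = FALSE)
  withSeed(4242, {
    mu <- ifelse(set$scen == "X", 0, 4)
    data.frame(scenario = set$scen,
               s1 = round(rnorm(nrow(set), mu, 1), 4),
               s2 = round(rnorm(nrow(set), -mu, 1), 4),
               stringsAsFactors = FALSE)
  })
}
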
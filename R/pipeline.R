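# Pipeline orchestration: stats -> neutrality/HKA -> ABC scenario choice
# -> SFS fitting, from a single validated config with one master seed
# fanned out to per-stage substreams.

#' Default run configuration
#'
#' Desk-scale settings; every field can be overridden by the `config`
#' argument of the run functions (unknown keys are rejected).
#'
#' @return nested list of settings.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    input = NULL,                      # directory of FASTA + popmap.tsv
    synth = list(scenario = "B3", nLoci = 14L, totalBp = 6077L,
                 nInd1 = 112L, nInd2 = 63L, withOutgroup = TRUE),
    stats = list(nPerm = 999L),
    hka = list(populations = NULL),    # NULL: every population
    abc = list(codes = c("A1", "B1", "C1", "D1"), R = 500L,
               tolerance = 0.01, nPods = 0L),
    sfs = list(codes = c("B1", "B3"), nSims = 1000L, nLoops = 3L,
               nRestarts = 2L, evalsPerLoop = 30L, nBoot = 0L),
    rates = list(muPerGen = 5.58e-9, generationTime = 25)
  )
}

# validate user config against the default schema and merge
resolveConfig <- function(config = list()) {
  def <- defaultRunConfig()
  checkKeys <- function(user, ref, path = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(user))
      if (is.list(ref[[k]]) && is.list(user[[k]]))
        checkKeys(user[[k]], ref[[k]], paste0(path, k, "."))
  }
  checkKeys(config, def)
  modifyList(def, config)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return resolved config list.
#' @export
readRunConfig <- function(path) {
  resolveConfig(yaml::read_yaml(path))
}

# obtain the dataset: read from config$input or synthesize
configDataset <- function(cfg, seed) {
  if (!is.null(cfg$input)) {
    files <- sort(list.files(cfg$input, pattern = "\\.fasta$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no FASTA files in ", cfg$input)
    pm <- readPopMap(file.path(cfg$input, "popmap.tsv"))
    alns <- lapply(files, readAlignment)
    isCp <- vapply(alns, function(a) grepl("^cp", locusId(a)), TRUE)
    # split off outgroup records carried in the FASTA
    alns <- lapply(alns, splitOutgroupRecords)
    newStudyDataset(alns[!isCp], pm,
                    cpdna = if (any(isCp)) alns[isCp][[1]] else NULL)
  } else {
    tpl <- studyTemplate(nLoci = cfg$synth$nLoci, totalBp = cfg$synth$totalBp,
                         nInd1 = cfg$synth$nInd1, nInd2 = cfg$synth$nInd2)
    generateDataset(tpl, scenarioCode = cfg$synth$scenario, seed = seed,
                    withOutgroup = cfg$synth$withOutgroup)
  }
}

splitOutgroupRecords <- function(aln) {
  og <- grepl("^outgroup", aln@sampleId)
  if (!any(og)) return(aln)
  newLocusAlignment(aln@locusId,
                    as.character(aln@seqs)[!og],
                    aln@sampleId[!og], aln@haplotypeIndex[!og],
                    outgroup = as.character(aln@seqs)[og])
}

# per-locus 13-statistic row from an alignment (same definitions as the
# fast simulated-matrix path, so observed and simulated vectors are
# directly comparable)
locusStatRowAln <- function(m, idx1, idx2) {
  m1 <- m[idx1, , drop = FALSE]
  m2 <- m[idx2, , drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  s1 <- siteSummary(m1); s2 <- siteSummary(m2)
  seg1 <- s1$nAlleles >= 2L
  seg2 <- s2$nAlleles >= 2L
  piL1 <- corePiTotal(s1); piL2 <- corePiTotal(s2)
  W1 <- withinPairDiffSum(m1)
  W2 <- withinPairDiffSum(m2)
  B <- betweenPairDiffSum(m1, m2)
  N <- n1 + n2
  SSt <- (W1 + W2 + B) / N
  SSw <- W1 / n1 + W2 / n2
  sigW <- SSw / (N - 2)
  nc <- (N - (n1^2 + n2^2) / N)
  sigA <- ((SSt - SSw) - sigW) / nc
  phi <- if (sigA + sigW <= 0) 0 else sigA / (sigA + sigW)
  D1 <- coreTajimaD(sum(seg1), piL1, n1)
  D2 <- coreTajimaD(sum(seg2), piL2, n2)
  L <- ncol(m)
  c(Nh1 = haplotypeSummary(m1)$Nh,
    S1 = sum(seg1), pi1 = piL1 / L, D1 = if (is.na(D1)) 0 else D1,
    priv1 = sum(seg1 & !seg2),
    Nh2 = haplotypeSummary(m2)$Nh,
    S2 = sum(seg2), pi2 = piL2 / L, D2 = if (is.na(D2)) 0 else D2,
    priv2 = sum(seg2 & !seg1),
    phist = phi, dxy = B / (n1 * n2 * L), sharedS = sum(seg1 & seg2))
}

#' ABC summary-statistic vector of a StudyDataset
#'
#' The observed-side counterpart of [datasetStats()]: identical statistic
#' definitions computed from the nuclear alignments.
#'
#' @param ds a [StudyDataset-class].
#' @return named numeric vector of 26 statistics.
#' @export
observedStats <- function(ds) {
  pops <- unique(ds@popmap$population)
  per <- vapply(ds@nuclearLoci, function(aln) {
    m <- alnMatrix(aln)
    pop <- ds@popmap$population[match(aln@sampleId, ds@popmap$sample_id)]
    locusStatRowAln(m, which(pop == pops[1]), which(pop == pops[2]))
  }, numeric(13))
  out <- c(rowMeans(per), apply(per, 1, var))
  names(out) <- c(paste0(rownames(per), "_mean"), paste0(rownames(per), "_var"))
  out
}

#' Observed joint SFS of a StudyDataset
#'
#' Sums the outgroup-polarized per-locus joint spectra of the nuclear
#' loci.
#'
#' @param ds a [StudyDataset-class] with outgroup sequences attached.
#' @return a [JointSFS-class] in counts mode.
#' @export
observedJointSFS <- function(ds) {
  Ms <- lapply(ds@nuclearLoci, function(aln)
    jointSFS(aln, popmap = ds@popmap)@M)
  new("JointSFS", M = Reduce(`+`, Ms), mode = "counts")
}

#' Run the summary-statistics stage
#'
#' @param config (partial) run config; see [defaultRunConfig()].
#' @param dataset optionally, a pre-built [StudyDataset-class] (skips the
#'   input/synthesis step).
#' @param outdir if non-NULL, write `stats.tsv` and `phist.json` there.
#' @return list with `table` (per-locus stats), `phiST` (multi-locus
#'   AMOVA over concatenated nuclear loci), `dataset`.
#' @export
runStats <- function(config = list(), dataset = NULL, outdir = NULL) {
  cfg <- resolveConfig(config)
  seeds <- childSeeds(cfg$seed, 5L)
  ds <- dataset %||% configDataset(cfg, seeds[1])
  tabl <- locusStatsTable(ds)
  cat14 <- concatenateLoci(ds@nuclearLoci, locusId = "nuclear_concat")
  ph <- phiSt(cat14, ds@popmap, nPerm = cfg$stats$nPerm, seed = seeds[2])
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(tabl, file.path(outdir, "stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ph, file.path(outdir, "phist.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tabl, phiST = ph, dataset = ds)
}

#' Run the multilocus HKA stage
#'
#' @inheritParams runStats
#' @return list of [hkaFit()] results, one per population.
#' @export
runHka <- function(config = list(), dataset = NULL, outdir = NULL) {
  cfg <- resolveConfig(config)
  seeds <- childSeeds(cfg$seed, 5L)
  ds <- dataset %||% configDataset(cfg, seeds[1])
  pops <- cfg$hka$populations %||% unique(ds@popmap$population)
  out <- lapply(setNames(pops, pops), function(p)
    hkaFit(hkaInputFromDataset(ds, population = p)))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      lapply(out, function(r) r[c("theta", "T", "chi2", "df", "p")]),
      file.path(outdir, "hka.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the ABC scenario-choice stage
#'
#' @inheritParams runStats
#' @return list with `observed`, `table` ([ReferenceTable-class]),
#'   `retained`, `direct`, `logistic`, `best`, `paramsPosterior`, and
#'   `confidence` (when `abc$nPods > 0`).
#' @export
runAbc <- function(config = list(), dataset = NULL, outdir = NULL) {
  cfg <- resolveConfig(config)
  seeds <- childSeeds(cfg$seed, 5L)
  ds <- dataset %||% configDataset(cfg, seeds[1])
  obs <- observedStats(ds)
  tpl <- studyTemplate(nLoci = cfg$synth$nLoci, totalBp = cfg$synth$totalBp,
                       nInd1 = cfg$synth$nInd1, nInd2 = cfg$synth$nInd2)
  tab <- buildReferenceTable(cfg$abc$codes, priors = NULL, R = cfg$abc$R,
                             loci = tpl$loci, n1 = tpl$n1, n2 = tpl$n2,
                             seed = seeds[3])
  ret <- abcReject(obs, tab, tolerance = cfg$abc$tolerance)
  direct <- posteriorDirect(tab, ret)
  logistic <- tryCatch(posteriorLogistic(tab, ret, obs),
                       error = function(e) NULL)
  best <- names(direct)[which.max(direct)]
  pp <- tryCatch(adjustParamsLocLinear(tab, ret, obs, code = best),
                 error = function(e) NULL)
  confid <- if (cfg$abc$nPods > 0)
    evaluateConfidence(tab, cfg$abc$nPods, tolerance = cfg$abc$tolerance,
                       seed = seeds[4]) else NULL
  out <- list(observed = obs, table = tab, retained = ret, direct = direct,
              logistic = logistic, best = best, paramsPosterior = pp,
              confidence = confid)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(direct = as.list(direct),
           logistic = if (!is.null(logistic)) as.list(logistic$posterior),
           best = best,
           paramsPosterior = if (!is.null(pp)) as.data.frame(pp$summary)),
      file.path(outdir, "abc.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the SFS composite-likelihood stage
#'
#' @inheritParams runStats
#' @return list with `observed` ([JointSFS-class]) and the
#'   [compareScenarios()] result.
#' @export
runSfs <- function(config = list(), dataset = NULL, outdir = NULL) {
  cfg <- resolveConfig(config)
  seeds <- childSeeds(cfg$seed, 5L)
  ds <- dataset %||% configDataset(cfg, seeds[1])
  obs <- observedJointSFS(ds)
  tpl <- studyTemplate(nLoci = cfg$synth$nLoci, totalBp = cfg$synth$totalBp,
                       nInd1 = cfg$synth$nInd1, nInd2 = cfg$synth$nInd2)
  cmp <- compareScenarios(obs, cfg$sfs$codes, loci = tpl$loci,
                          seed = seeds[5], nSims = cfg$sfs$nSims,
                          nLoops = cfg$sfs$nLoops,
                          nRestarts = cfg$sfs$nRestarts,
                          evalsPerLoop = cfg$sfs$evalsPerLoop)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(cmp$table, file.path(outdir, "sfs_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeJointSFS(obs, file.path(outdir, "observed_jsfs.tsv"))
  }
  list(observed = obs, comparison = cmp)
}

#' Run the full pipeline
#'
#' stats -> HKA -> ABC -> SFS fitting on one dataset, with the master
#' seed fanned out to stage substreams; rerunning with the same resolved
#' config reproduces identical numbers.
#'
#' @inheritParams runStats
#' @return list with elements `stats`, `hka`, `abc`, `sfs`, `config`.
#' @export
runAll <- function(config = list(), dataset = NULL, outdir = NULL) {
  cfg <- resolveConfig(config)
  seeds <- childSeeds(cfg$seed, 5L)
  ds <- dataset %||% configDataset(cfg, seeds[1])
  st <- runStats(cfg, dataset = ds, outdir = outdir)
  hk <- runHka(cfg, dataset = ds, outdir = outdir)
  ab <- runAbc(cfg, dataset = ds, outdir = outdir)
  sf <- runSfs(cfg, dataset = ds, outdir = outdir)
  if (!is.null(outdir))
    yaml::write_yaml(cfg, file.path(outdir, "resolved_config.yaml"))
  list(stats = st[c("table", "phiST")], hka = hk,
       abc = ab[setdiff(names(ab), "table")], sfs = sf, config = cfg)
}

#' Write a joint SFS in the package's TSV dialect
#'
#' First line: `#jsfs<TAB>mode<TAB>n1<TAB>n2`; then a header row `d2_0 ..
#' d2_n2` and one row per deme-1 derived count `d1_i` -- a minimal,
#' self-describing variant of the fastsimcoal2 `.obs` layout.
#'
#' @param jsfs a [JointSFS-class].
#' @param path output path.
#' @export
writeJointSFS <- function(jsfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n1 <- nrow(jsfs@M) - 1L
  n2 <- ncol(jsfs@M) - 1L
  writeLines(sprintf("#jsfs\t%s\t%d\t%d", jsfs@mode, n1, n2), con)
  M <- jsfs@M
  dimnames(M) <- list(paste0("d1_", 0:n1), paste0("d2_", 0:n2))
  write.table(M, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a joint SFS written by [writeJointSFS()]
#' @param path input path.
#' @return a [JointSFS-class].
#' @export
readJointSFS <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (hdr[1] != "#jsfs") stop("not a jsfs TSV: ", path)
  M <- as.matrix(read.table(path, sep = "\t", skip = 1L, header = TRUE,
                            row.names = 1, check.names = FALSE))
  dimnames(M) <- NULL
  new("JointSFS", M = M, mode = hdr[2])
}
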
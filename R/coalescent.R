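# R-level interface to the structured-coalescent engine. Heavy lifting
# (genealogy simulation, mutation dropping, branch-length JSFS
# accumulation) is compiled; these wrappers handle demography encoding,
# seeding, and container types.

demogOf <- function(scenario) {
  if (is(scenario, "DemographicScenario")) scenarioEpochs(scenario)
  else scenario  # already a list(brk, N1, N2, m12, m21, tMerge)
}

# single-deme constant-size demography (used by tests and null models)
constantDemography <- function(N) {
  list(brk = 0, N1 = N, N2 = N, m12 = 0, m21 = 0, tMerge = 0)
}

#' Simulate a genealogy under a two-deme scenario
#'
#' Standard structured coalescent: within a deme of current diploid size N
#' the pair-coalescence rate is k(k-1)/(4 N ploidy) per generation,
#' lineages migrate at the epoch-active backward rates, and at the
#' divergence time all deme-2 lineages move into deme 1 (whose size then
#' follows the ancestral epoch).
#'
#' @param scenario a [DemographicScenario-class] (or an epoch list as
#'   produced internally).
#' @param n1,n2 numbers of sampled haplotypes per deme.
#' @param seed integer seed.
#' @param ploidy ploidy factor (1 diploid nuclear, 0.5 haploid
#'   organellar).
#' @return list with `parent` (1-based parent pointers, NA at the root),
#'   `time` (node times in generations; tips first, internal nodes in
#'   coalescence order) and `n` (number of tips).
#' @export
simulateGenealogy <- function(scenario, n1, n2 = 0L, seed = 1L, ploidy = 1) {
  d <- demogOf(scenario)
  .sim_genealogy_cpp(as.integer(n1), as.integer(n2), d$brk, d$N1, d$N2,
                     d$m12, d$m21, d$tMerge, ploidy, as.double(seed))
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Each branch receives Poisson(mu * L * length) mutations; every mutation
#' hits a fresh position in `[0, L)` (positions drawn without
#' replacement), giving biallelic 0/1 sites.
#'
#' @param genealogy output of [simulateGenealogy()].
#' @param lengthBp locus length L in sites.
#' @param mu per-site per-generation mutation rate.
#' @param seed integer seed.
#' @return list with `genotypes` (0/1 matrix, rows = tips, columns in
#'   position order) and `positions` (0-based site positions).
#' @export
dropMutations <- function(genealogy, lengthBp, mu, seed = 1L) {
  n <- genealogy$n
  if (n < 2L) return(list(genotypes = matrix(0L, n, 0), positions = integer()))
  parent <- genealogy$parent
  tm <- genealogy$time
  nb <- 2L * n - 2L
  len <- tm[parent[seq_len(nb)]] - tm[seq_len(nb)]
  withSeed(seed, {
    nm <- rpois(nb, mu * lengthBp * len)
    S <- sum(nm)
    if (S > lengthBp)
      stop("mutation overflow: ", S, " mutations exceed locus length ",
           lengthBp, "; infinite-sites mapping impossible")
    geno <- matrix(0L, n, S)
    if (S > 0L) {
      children <- vector("list", 2L * n - 1L)
      for (i in seq_len(nb))
        children[[parent[i]]] <- c(children[[parent[i]]], i)
      col <- 0L
      for (i in which(nm > 0L)) {
        # tips below node i
        stack <- i
        tips <- integer()
        while (length(stack)) {
          nd <- stack[length(stack)]
          stack <- stack[-length(stack)]
          if (nd <= n) tips <- c(tips, nd)
          else stack <- c(stack, children[[nd]])
        }
        for (k in seq_len(nm[i])) {
          col <- col + 1L
          geno[tips, col] <- 1L
        }
      }
      pos <- sort(sample.int(lengthBp, S) - 1L)
      ord <- sample.int(S)  # random assignment of mutations to positions
      geno <- geno[, ord, drop = FALSE]
    } else pos <- integer()
    list(genotypes = geno, positions = pos)
  })
}

# fast path: one locus as a 0/1 matrix straight from the engine
simLocusMatrix <- function(demog, n1, n2, muL, seed, ploidy = 1) {
  .sim_locus_cpp(as.integer(n1), as.integer(n2), demog$brk, demog$N1,
                 demog$N2, demog$m12, demog$m21, demog$tMerge, ploidy,
                 muL, as.double(seed))
}

simLociMatrices <- function(demog, n1, n2, muLs, seed, ploidy = 1) {
  .sim_loci_cpp(as.integer(n1), as.integer(n2), demog$brk, demog$N1,
                demog$N2, demog$m12, demog$m21, demog$tMerge, ploidy,
                muLs, as.double(seed))
}

#' Simulate a multi-locus dataset under a scenario
#'
#' Independent genealogies per locus (no recombination within loci, free
#' recombination between loci); deterministic given the seed, with
#' per-locus substreams so locus results do not depend on execution
#' order. Sequences are encoded ancestral = A, derived = T at
#' uniformly-placed sites.
#'
#' @param scenario a [DemographicScenario-class].
#' @param loci data.frame with columns `locus`, `length`, `mu`, `ploidy`
#'   (see [studyTemplate()]).
#' @param n1,n2 sampled haplotype counts (per deme) for diploid loci;
#'   haploid loci sample half as many (one per individual).
#' @param seed integer seed.
#' @param tOutgroup if > 0, an outgroup sequence per locus is generated by
#'   dropping Poisson(2 mu L tOutgroup) extra mutations on the
#'   ingroup-root-to-outgroup path (generations).
#' @param sampleNames optional list with `pop1`, `pop2` character vectors
#'   of individual ids.
#' @return a [StudyDataset-class] (popmap populations `pop1`, `pop2`
#'   unless names are given).
#' @export
simulateDataset <- function(scenario, loci, n1, n2, seed = 1L,
                            tOutgroup = 0, sampleNames = NULL) {
  demog <- demogOf(scenario)
  nLoci <- nrow(loci)
  seeds <- childSeeds(seed, 2L * nLoci)
  nInd1 <- n1 %/% 2L
  nInd2 <- n2 %/% 2L
  if (is.null(sampleNames))
    sampleNames <- list(pop1 = sprintf("P1_%03d", seq_len(nInd1)),
                        pop2 = sprintf("P2_%03d", seq_len(nInd2)))
  popmap <- data.frame(
    sample_id = c(sampleNames$pop1, sampleNames$pop2),
    population = rep(c("pop1", "pop2"), c(nInd1, nInd2)),
    stringsAsFactors = FALSE)
  alns <- vector("list", nLoci)
  cp <- NULL
  for (l in seq_len(nLoci)) {
    pl <- loci$ploidy[l]
    haploid <- pl < 1
    h1 <- if (haploid) nInd1 else n1
    h2 <- if (haploid) nInd2 else n2
    g <- simLocusMatrix(demog, h1, h2, loci$mu[l] * loci$length[l],
                        seeds[l], ploidy = pl)
    aln <- encodeAlignment(g, loci$length[l], loci$locus[l],
                           sampleNames, haploid = haploid,
                           tOutgroup = tOutgroup, mu = loci$mu[l],
                           seed = seeds[nLoci + l])
    if (haploid) cp <- aln else alns[[l]] <- aln
  }
  alns <- Filter(Negate(is.null), alns)
  newStudyDataset(alns, popmap, cpdna = cp,
                  cpdnaPloidy = if (is.null(cp)) 0.5 else
                    loci$ploidy[loci$ploidy < 1][1])
}

# turn a 0/1 genotype matrix into a FASTA-backed LocusAlignment
# (ancestral A, derived T, positions uniform without replacement); the
# optional outgroup accumulates its own divergence mutations at fresh
# positions
encodeAlignment <- function(geno, lengthBp, locus, sampleNames,
                            haploid = FALSE, tOutgroup = 0, mu = 0,
                            seed = 1L) {
  n <- nrow(geno)
  S <- ncol(geno)
  withSeed(seed, {
    nOut <- if (tOutgroup > 0) rpois(1, 2 * mu * lengthBp * tOutgroup) else 0L
    if (S + nOut > lengthBp)
      stop("mutation overflow on locus ", locus)
    pos <- sample.int(lengthBp, S + nOut)
    seqMat <- matrix("A", n, lengthBp)
    if (S > 0)
      for (s in seq_len(S)) seqMat[geno[, s] == 1L, pos[s]] <- "T"
    ogSeq <- rep("A", lengthBp)
    if (nOut > 0) ogSeq[pos[S + seq_len(nOut)]] <- "T"
    seqs <- apply(seqMat, 1, paste, collapse = "")
    og <- if (tOutgroup > 0) paste(ogSeq, collapse = "") else NULL
    ids <- c(sampleNames$pop1, sampleNames$pop2)
    nInd <- length(ids)
    if (haploid) {
      sampleId <- ids
      hapIdx <- rep(1L, nInd)
    } else {
      sampleId <- rep(ids, each = 2L)
      hapIdx <- rep(c(1L, 2L), nInd)
    }
    stopifnot(length(sampleId) == n)
    newLocusAlignment(locus, seqs, sampleId, hapIdx, outgroup = og)
  })
}

#' Monte-Carlo expected joint SFS under a scenario
#'
#' Averages, over simulated genealogies, the expected number of mutations
#' on branches subtending each (i, j) descendant-count class, i.e. the
#' branch-length measure scaled by the total mutation rate. Returned in
#' probabilities mode (normalized over polymorphic entries); the
#' expected-SNP total Z before normalization is attached as attribute
#' `"Z"` (scaled by nSims to an expected per-dataset count).
#'
#' @param scenario a [DemographicScenario-class].
#' @param loci locus table (`length`, `mu`, `ploidy`); haploid loci are
#'   excluded (the JSFS is a nuclear summary here).
#' @param n1,n2 sampled haplotype counts.
#' @param nSims number of Monte-Carlo genealogies.
#' @param seed integer seed.
#' @return a [JointSFS-class] in probabilities mode.
#' @export
expectedJointSFS <- function(scenario, loci, n1, n2, nSims = 2000L,
                             seed = 1L) {
  demog <- demogOf(scenario)
  nuc <- loci[loci$ploidy >= 1, , drop = FALSE]
  muL <- sum(nuc$mu * nuc$length)
  if (muL <= 0) stop("degenerate locus set: total mutation rate is zero")
  M <- .sim_jsfs_cpp(as.integer(n1), as.integer(n2), demog$brk, demog$N1,
                     demog$N2, demog$m12, demog$m21, demog$tMerge, 1,
                     muL, as.integer(nSims), as.double(seed))
  Z <- sumPolymorphic(M)
  if (Z <= 0) stop("no expected polymorphism accumulated")
  P <- M / Z
  P[1, 1] <- 0
  P[nrow(P), ncol(P)] <- 0
  out <- new("JointSFS", M = P, mode = "probabilities")
  attr(out, "Z") <- Z / nSims
  out
}
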
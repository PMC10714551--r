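# Exported per-locus statistics and neutrality tests. Generics dispatch on
# LocusAlignment (FASTA-backed) and plain matrices (rows = haplotypes;
# character A/C/G/T/N/- or numeric 0/1 derived-allele codes).

statM <- function(x) {
  if (is(x, "LocusAlignment")) alnMatrix(x) else x
}

#' Number of segregating sites
#'
#' Counts alignment columns carrying at least two observed alleles among
#' the ingroup sequences (gap-masked input expected; N treated as missing).
#'
#' @param x a [LocusAlignment-class] or haplotype matrix.
#' @return integer count.
#' @export
setGeneric("segregatingSites", function(x) standardGeneric("segregatingSites"))

#' @rdname segregatingSites
setMethod("segregatingSites", "ANY", function(x) {
  coreS(siteSummary(statM(x)))
})

#' Total number of mutations (eta)
#'
#' Sum over columns of (observed alleles - 1).
#' @inheritParams segregatingSites
#' @return integer count.
#' @export
setGeneric("totalMutations", function(x) standardGeneric("totalMutations"))

#' @rdname totalMutations
setMethod("totalMutations", "ANY", function(x) {
  coreEta(siteSummary(statM(x)))
})

#' Haplotype count and haplotype diversity
#'
#' Haplotypes are distinct full sequences. Diversity uses the
#' sample-corrected estimator Hd = n (1 - sum p_k^2) / (n - 1).
#'
#' @inheritParams segregatingSites
#' @return list with elements `Nh` (integer) and `Hd` (numeric; NA when
#'   n < 2).
#' @export
setGeneric("haplotypeSummary", function(x) standardGeneric("haplotypeSummary"))

#' @rdname haplotypeSummary
setMethod("haplotypeSummary", "ANY", function(x) {
  m <- statM(x)
  n <- nrow(m)
  key <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  tab <- table(key)
  Nh <- length(tab)
  Hd <- if (n < 2L) NA_real_ else {
    p <- as.numeric(tab) / n
    n * (1 - sum(p^2)) / (n - 1)
  }
  list(Nh = as.integer(Nh), Hd = Hd)
})

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise difference per comparable site; sites where either
#' sequence is missing are skipped pairwise but the column still counts in
#' the length L.
#'
#' @inheritParams segregatingSites
#' @param perSite if FALSE, return the per-locus mean number of pairwise
#'   differences (pi_L) instead.
#' @return numeric; NA when n < 2.
#' @export
setGeneric("nucleotideDiversity",
           function(x, perSite = TRUE) standardGeneric("nucleotideDiversity"),
           signature = "x")

#' @rdname nucleotideDiversity
setMethod("nucleotideDiversity", "ANY", function(x, perSite = TRUE) {
  m <- statM(x)
  if (nrow(m) < 2L) return(NA_real_)
  ss <- siteSummary(m)
  piL <- corePiTotal(ss)
  if (perSite) piL / ss$L else piL
})

#' Watterson's theta per site
#'
#' theta_w = S / (a1 L) with a1 the harmonic number of n - 1.
#'
#' @inheritParams nucleotideDiversity
#' @return numeric; NA when n < 2.
#' @export
setGeneric("wattersonTheta",
           function(x, perSite = TRUE) standardGeneric("wattersonTheta"),
           signature = "x")

#' @rdname wattersonTheta
setMethod("wattersonTheta", "ANY", function(x, perSite = TRUE) {
  m <- statM(x)
  if (nrow(m) < 2L) return(NA_real_)
  ss <- siteSummary(m)
  th <- coreS(ss) / harmonicA1(nrow(m))
  if (perSite) th / ss$L else th
})

#' Minimum number of recombination events (Hudson-Kaplan Rm)
#'
#' Lower bound from four-gamete violations among biallelic sites, after
#' interval reduction (drop intervals containing another incompatible
#' interval, then count a maximal set of non-overlapping intervals).
#'
#' @inheritParams segregatingSites
#' @return integer lower bound.
#' @export
setGeneric("minRecombination", function(x) standardGeneric("minRecombination"))

#' @rdname minRecombination
setMethod("minRecombination", "ANY", function(x) {
  m <- statM(x)
  ss <- siteSummary(m)
  bi <- which(ss$nAlleles == 2L)
  if (length(bi) < 2L) return(0L)
  # recode biallelic columns to 0/1/NA
  rec <- vapply(bi, function(c) {
    col <- m[, c]
    alle <- rownames(ss$counts)[ss$counts[, c] > 0]
    out <- rep(NA_integer_, length(col))
    out[col == alle[1]] <- 0L
    out[col == alle[2]] <- 1L
    out
  }, integer(nrow(m)))
  B <- length(bi)
  ivl <- NULL
  for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    ok <- !is.na(rec[, i]) & !is.na(rec[, j])
    g <- unique(rec[ok, c(i, j), drop = FALSE])
    if (nrow(g) == 4L) ivl <- rbind(ivl, c(i, j))
  }
  if (is.null(ivl)) return(0L)
  # drop intervals that contain another interval
  keep <- rep(TRUE, nrow(ivl))
  for (k in seq_len(nrow(ivl))) {
    inside <- ivl[, 1] >= ivl[k, 1] & ivl[, 2] <= ivl[k, 2]
    inside[k] <- FALSE
    if (any(inside)) keep[k] <- FALSE
  }
  ivl <- ivl[keep, , drop = FALSE]
  ivl <- ivl[order(ivl[, 2]), , drop = FALSE]
  rm <- 0L
  lastRight <- -Inf
  for (k in seq_len(nrow(ivl))) {
    if (ivl[k, 1] >= lastRight) {
      rm <- rm + 1L
      lastRight <- ivl[k, 2]
    }
  }
  rm
})

#' Tajima's D
#'
#' D = (pi_L - S/a1) / sqrt(e1 S + e2 S (S - 1)) with the Tajima (1989)
#' constants. Undefined (NA) when S = 0.
#'
#' @inheritParams segregatingSites
#' @return numeric, or NA when undefined.
#' @export
setGeneric("tajimaD", function(x) standardGeneric("tajimaD"))

#' @rdname tajimaD
setMethod("tajimaD", "ANY", function(x) {
  m <- statM(x)
  ss <- siteSummary(m)
  coreTajimaD(coreS(ss), corePiTotal(ss), nrow(m))
})

#' Fu and Li's D* and F* (no outgroup needed)
#'
#' Starred statistics contrasting total mutations with singleton mutations
#' (D*) and with mean pairwise differences (F*), using the corrected
#' variance constants of the DnaSP/libsequence lineage. Undefined (NA)
#' when eta = 0 or n < 3.
#'
#' @inheritParams segregatingSites
#' @return named numeric vector `c(Dstar =, Fstar =)`.
#' @export
setGeneric("fuLiStar", function(x) standardGeneric("fuLiStar"))

#' @rdname fuLiStar
setMethod("fuLiStar", "ANY", function(x) {
  m <- statM(x)
  ss <- siteSummary(m)
  coreFuLiStar(coreEta(ss), coreEtaS(ss), corePiTotal(ss), nrow(m))
})

#' Fu's FS
#'
#' FS = ln(S'/(1 - S')) with S' = P(K >= k_obs) under the Ewens sampling
#' distribution at theta-hat = pi_L (mean pairwise differences), computed
#' with log-space unsigned Stirling numbers. Undefined (NA) when the
#' sample is monomorphic or has a single haplotype.
#'
#' @inheritParams segregatingSites
#' @return numeric, or NA when undefined.
#' @export
setGeneric("fuFS", function(x) standardGeneric("fuFS"))

#' @rdname fuFS
setMethod("fuFS", "ANY", function(x) {
  m <- statM(x)
  ss <- siteSummary(m)
  hs <- haplotypeSummary(m)
  coreFuFS(nrow(m), hs$Nh, corePiTotal(ss))
})

#' Fay and Wu's H (unnormalized)
#'
#' H = pi_L - theta_H over outgroup-polarizable sites (original 2000
#' definition, as reported by DnaSP). Sites where the outgroup is missing,
#' ambiguous, or carries an allele absent from the ingroup are skipped, as
#' are ingroup tri-allelic sites.
#'
#' @inheritParams segregatingSites
#' @param outgroup outgroup haplotype matrix (character); defaults to the
#'   outgroup carried by the `LocusAlignment`.
#' @param perSite divide by alignment length.
#' @return numeric, or NA when no site can be polarized.
#' @export
setGeneric("fayWuH",
           function(x, outgroup = NULL, perSite = FALSE)
             standardGeneric("fayWuH"), signature = "x")

#' @rdname fayWuH
setMethod("fayWuH", "ANY", function(x, outgroup = NULL, perSite = FALSE) {
  sfs <- unfoldedSFS(x, outgroup)
  h <- coreFayWuH(sfs$counts, sfs$n)
  if (perSite && !is.na(h)) h / sfs$L else h
})

#' Unfolded (outgroup-polarized) site frequency spectrum
#'
#' @inheritParams fayWuH
#' @return list with `counts` (xi_i, i = 1..n-1), `n`, `polarized`,
#'   `nFixedDerived`, `nSkipped` (polymorphic sites that could not be
#'   polarized) and `L`.
#' @export
setGeneric("unfoldedSFS",
           function(x, outgroup = NULL) standardGeneric("unfoldedSFS"),
           signature = "x")

#' @rdname unfoldedSFS
setMethod("unfoldedSFS", "ANY", function(x, outgroup = NULL) {
  m <- statM(x)
  if (is.null(outgroup) && is(x, "LocusAlignment")) outgroup <- outgroupMatrix(x)
  if (is.null(outgroup)) stop("outgroup required to polarize the spectrum")
  if (!is.matrix(outgroup)) outgroup <- matrix(outgroup, nrow = 1)
  ss <- siteSummary(m)
  anc <- ancestralAlleles(outgroup)
  der <- polarizedDerivedCounts(ss, anc)
  n <- nrow(m)
  xi <- tabulate(der[!is.na(der) & der >= 1L & der <= n - 1L], nbins = n - 1L)
  nSeg <- ss$nAlleles >= 2L
  list(counts = xi, n = n, polarized = TRUE,
       nFixedDerived = sum(der == n, na.rm = TRUE),
       nSkipped = sum(is.na(der) & nSeg), L = ss$L)
})

#' Joint (two-population) site frequency spectrum
#'
#' Counts polarizable sites by the pair (derived count in population 1,
#' derived count in population 2). Monomorphic-ancestral sites are not
#' counted; fixed-derived sites land in the (n1, n2) corner.
#'
#' @inheritParams fayWuH
#' @param popmap data.frame `sample_id`, `population`; population levels
#'   are taken in first-appearance order.
#' @return a [JointSFS-class] in counts mode.
#' @export
setGeneric("jointSFS",
           function(x, popmap = NULL, outgroup = NULL)
             standardGeneric("jointSFS"), signature = "x")

#' @rdname jointSFS
setMethod("jointSFS", "ANY", function(x, popmap = NULL, outgroup = NULL) {
  m <- statM(x)
  if (is.null(outgroup) && is(x, "LocusAlignment")) outgroup <- outgroupMatrix(x)
  if (is.null(outgroup)) stop("outgroup required to polarize the spectrum")
  if (!is.matrix(outgroup)) outgroup <- matrix(outgroup, nrow = 1)
  if (is.null(popmap)) stop("popmap required")
  idx <- popSplit(x, popmap)
  m1 <- m[idx[[1]], , drop = FALSE]
  m2 <- m[idx[[2]], , drop = FALSE]
  anc <- ancestralAlleles(outgroup)
  d1 <- polarizedDerivedCounts(siteSummary(m1), anc)
  d2 <- polarizedDerivedCounts(siteSummary(m2), anc)
  # a site polarizes for the joint spectrum only if it does in both samples
  # and in the pooled sample (tri-allelic rule on the pool)
  dp <- polarizedDerivedCounts(siteSummary(m), anc)
  ok <- !is.na(d1) & !is.na(d2) & !is.na(dp)
  n1 <- nrow(m1); n2 <- nrow(m2)
  M <- matrix(0, n1 + 1, n2 + 1)
  for (c in which(ok)) {
    if (d1[c] == 0L && d2[c] == 0L) next
    M[d1[c] + 1L, d2[c] + 1L] <- M[d1[c] + 1L, d2[c] + 1L] + 1
  }
  new("JointSFS", M = M, mode = "counts")
})

# split haplotype rows by population; returns list of row-index vectors in
# popmap population order (first appearance)
popSplit <- function(x, popmap) {
  if (is(x, "LocusAlignment")) {
    pops <- unique(popmap$population)
    pop <- popmap$population[match(x@sampleId, popmap$sample_id)]
    if (anyNA(pop)) stop("unmapped samples in alignment")
    lapply(pops, function(p) which(pop == p))
  } else {
    # matrix input: popmap may be a grouping vector over rows
    if (is.data.frame(popmap)) stop("matrix input needs a grouping vector")
    pops <- unique(popmap)
    lapply(pops, function(p) which(popmap == p))
  }
}

#' AMOVA-based PhiST with permutation test
#'
#' Distance-based fixation index from pairwise-difference distances
#' between haplotypes (Excoffier et al. 1992 variance components), with a
#' permutation test shuffling haplotypes across populations. Hudson's
#' estimator 1 - Hw/Hb is reported alongside for cross-checking.
#'
#' @inheritParams segregatingSites
#' @param popmap data.frame (`sample_id`, `population`) for alignments, or
#'   a grouping vector over matrix rows.
#' @param nPerm number of label permutations (0 skips the test).
#' @param seed integer seed for the permutations.
#' @return list with `phiST`, `p` (NA if nPerm = 0), `hudsonFst`,
#'   `sigmaAmong`, `sigmaWithin`, `nPerm`.
#' @export
setGeneric("phiSt",
           function(x, popmap, nPerm = 999L, seed = 1L)
             standardGeneric("phiSt"), signature = "x")

#' @rdname phiSt
setMethod("phiSt", "ANY", function(x, popmap, nPerm = 999L, seed = 1L) {
  m <- statM(x)
  idx <- popSplit(x, popmap)
  if (length(idx) != 2L) stop("exactly two populations required")
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]])
  if (n1 < 2L || n2 < 2L) stop("each population needs at least 2 sequences")
  ord <- c(idx[[1]], idx[[2]])
  d <- pairwiseDiffMatrix(m[ord, , drop = FALSE])
  groups <- rep(c(1L, 2L), c(n1, n2))
  obs <- amovaPhi(d, groups)
  hw <- (sum(d[groups == 1, groups == 1]) / (n1 * (n1 - 1)) +
         sum(d[groups == 2, groups == 2]) / (n2 * (n2 - 1))) / 2
  hb <- sum(d[groups == 1, groups == 2]) / (n1 * n2)
  hudson <- if (hb > 0) 1 - hw / hb else 0
  p <- NA_real_
  if (nPerm > 0L) {
    exceed <- withSeed(seed, {
      cnt <- 0L
      for (b in seq_len(nPerm)) {
        g <- sample(groups)
        if (amovaPhi(d, g)$phi >= obs$phi) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (exceed + 1) / (nPerm + 1)
  }
  list(phiST = obs$phi, p = p, hudsonFst = hudson,
       sigmaAmong = obs$sigmaAmong, sigmaWithin = obs$sigmaWithin,
       nPerm = as.integer(nPerm))
})

#' Private and shared polymorphic sites between two populations
#'
#' @inheritParams phiSt
#' @return named integer vector: `private1`, `private2`, `shared`,
#'   `fixedDiff`.
#' @export
privateSharedSites <- function(x, popmap) {
  m <- statM(x)
  idx <- popSplit(x, popmap)
  s1 <- siteSummary(m[idx[[1]], , drop = FALSE])
  s2 <- siteSummary(m[idx[[2]], , drop = FALSE])
  p1 <- s1$nAlleles >= 2L
  p2 <- s2$nAlleles >= 2L
  mono1 <- s1$nAlleles == 1L
  mono2 <- s2$nAlleles == 1L
  fixedDiff <- mono1 & mono2 &
    (apply(s1$counts > 0, 2, which.max) != apply(s2$counts > 0, 2, which.max))
  c(private1 = sum(p1 & mono2), private2 = sum(p2 & mono1),
    shared = sum(p1 & p2), fixedDiff = sum(fixedDiff))
}

#' Per-locus summary-statistics table for a dataset
#'
#' One row per locus per population plus a pooled row, with S, eta, Nh,
#' Hd, pi, theta_w, Rm, Tajima's D, Fu and Li's D*/F*, Fu's FS and (when an
#' outgroup is attached) Fay and Wu's H.
#'
#' @param ds a [StudyDataset-class].
#' @param lociOnly restrict to these locus ids.
#' @return data.frame.
#' @export
locusStatsTable <- function(ds, lociOnly = NULL) {
  pops <- unique(ds@popmap$population)
  rows <- list()
  loci <- ds@nuclearLoci
  if (!is.null(ds@cpdna)) loci <- c(loci, list(ds@cpdna))
  for (aln in loci) {
    if (!is.null(lociOnly) && !(locusId(aln) %in% lociOnly)) next
    m <- alnMatrix(aln)
    og <- outgroupMatrix(aln)
    pop <- ds@popmap$population[match(aln@sampleId, ds@popmap$sample_id)]
    parts <- c(as.list(pops), list(NULL))
    for (p in parts) {
      sub <- if (is.null(p)) m else m[pop == p, , drop = FALSE]
      ss <- siteSummary(sub)
      hs <- haplotypeSummary(sub)
      fl <- coreFuLiStar(coreEta(ss), coreEtaS(ss), corePiTotal(ss), nrow(sub))
      h <- if (!is.null(og)) {
        sfs <- unfoldedSFS(sub, og)
        coreFayWuH(sfs$counts, sfs$n)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locusId(aln), population = if (is.null(p)) "pooled" else p,
        n = nrow(sub), L = ss$L, S = coreS(ss), eta = coreEta(ss),
        Nh = hs$Nh, Hd = hs$Hd, pi = corePiTotal(ss) / ss$L,
        thetaW = coreS(ss) / harmonicA1(nrow(sub)) / ss$L,
        Rm = minRecombination(sub),
        tajimaD = coreTajimaD(coreS(ss), corePiTotal(ss), nrow(sub)),
        fuLiDstar = fl[["Dstar"]], fuLiFstar = fl[["Fstar"]],
        fuFS = coreFuFS(nrow(sub), hs$Nh, corePiTotal(ss)),
        fayWuH = h, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
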
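# Internal machinery for per-locus statistics. Everything is computed from
# per-column allele counts so the same code path serves FASTA alignments
# (character matrices over A/C/G/T with N and - as missing) and simulated
# 0/1 derived-allele matrices.

# allele-count matrix: rows = alleles, cols = alignment columns
countsOf <- function(m) {
  if (is.numeric(m)) {
    c1 <- colSums(m == 1)
    rbind("0" = nrow(m) - c1, "1" = c1)
  } else {
    rbind(A = colSums(m == "A"), C = colSums(m == "C"),
          G = colSums(m == "G"), T = colSums(m == "T"))
  }
}

# summary of column-wise allele structure
siteSummary <- function(m) {
  cn <- countsOf(m)
  nEff <- colSums(cn)
  nAll <- colSums(cn > 0)
  list(counts = cn, nEff = nEff, nAlleles = nAll, L = ncol(m), n = nrow(m))
}

# number of segregating (>= 2 allele) columns
coreS <- function(ss) sum(ss$nAlleles >= 2L)

# total number of mutations (alleles - 1 per segregating column)
coreEta <- function(ss) sum(pmax(ss$nAlleles - 1L, 0L))

# singleton mutations: alleles observed once; when every allele at a column
# is a singleton the column carries nAlleles - 1 mutations, all external
coreEtaS <- function(ss) {
  seg <- ss$nAlleles >= 2L
  if (!any(seg)) return(0L)
  cn <- ss$counts[, seg, drop = FALSE]
  ones <- colSums(cn == 1L)
  allOnes <- colSums(cn > 0L) == ones
  sum(ifelse(allOnes, ones - 1L, ones))
}

# per-column heterozygosity (probability two sequences differ at the column)
coreColDiv <- function(ss) {
  cn <- ss$counts
  ne <- ss$nEff
  d <- rep(0, ss$L)
  ok <- ne >= 2L
  if (any(ok)) {
    same <- colSums(cn[, ok, drop = FALSE] * (cn[, ok, drop = FALSE] - 1L))
    d[ok] <- 1 - same / (ne[ok] * (ne[ok] - 1))
  }
  d
}

# mean number of pairwise differences over the locus (pi_L)
corePiTotal <- function(ss) sum(coreColDiv(ss))

# Tajima (1989) variance constants
tajimaConstants <- function(n) {
  a1 <- harmonicA1(n)
  a2 <- harmonicA2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

coreTajimaD <- function(S, piL, n) {
  if (S < 1L || n < 2L) return(NA_real_)
  k <- tajimaConstants(n)
  (piL - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# Fu & Li (1993) starred statistics, with the corrected variance constants
# used by DnaSP/libsequence
fuLiStarConstants <- function(n) {
  a <- harmonicA1(n)
  b <- harmonicA2(n)
  an1 <- a + 1 / n               # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * a) / n^2 - 8 * b / n) / (a^2 + b)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) / (3 * n * (n - 1))) / a - vF
  list(a = a, uD = uD, vD = vD, uF = uF, vF = vF)
}

coreFuLiStar <- function(eta, etaS, piL, n) {
  if (n < 3L || eta < 1L)
    return(c(Dstar = NA_real_, Fstar = NA_real_))
  k <- fuLiStarConstants(n)
  Dstar <- ((n / (n - 1)) * eta - k$a * etaS) /
    sqrt(k$uD * eta + k$vD * eta^2)
  Fstar <- (piL - ((n - 1) / n) * etaS) /
    sqrt(k$uF * eta + k$vF * eta^2)
  c(Dstar = Dstar, Fstar = Fstar)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n), cached
.stirlingCache <- new.env(parent = emptyenv())
logStirlingRow <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirlingCache[[key]])) return(.stirlingCache[[key]])
  ls <- 0  # row 1: |s(1,1)| = 1
  if (n > 1) {
    for (m in 2:n) {
      left <- c(-Inf, ls)                  # |s(m-1, k-1)|
      right <- c(ls, -Inf) + log(m - 1)    # (m-1) |s(m-1, k)|
      hi <- pmax(left, right)
      ls <- hi + log1p(exp(-abs(left - right)))
      ls[is.infinite(hi)] <- -Inf
    }
  }
  .stirlingCache[[key]] <- ls
  ls
}

# Ewens sampling distribution of the number of alleles K given theta
ewensLogProbK <- function(n, theta) {
  if (theta <= 0) return(c(0, rep(-Inf, n - 1)))  # K = 1 surely
  ls <- logStirlingRow(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  lp - logSumExp(lp)  # normalize away residual rounding
}

# Fu's FS from observed haplotype count and mean pairwise differences
coreFuFS <- function(n, kObs, piL) {
  if (n < 2L || piL <= 0 || kObs <= 1L) return(NA_real_)
  lp <- ewensLogProbK(n, piL)
  lS <- logSumExp(lp[kObs:n])            # log S' = log P(K >= kObs)
  Sprime <- exp(lS)
  if (Sprime >= 1 || Sprime <= 0) return(NA_real_)
  log(Sprime) - log1p(-Sprime)
}

# --- outgroup polarization -------------------------------------------------

# per-column ancestral allele from an outgroup matrix: majority over
# non-missing outgroup residues; ties and all-missing are unpolarizable (NA)
ancestralAlleles <- function(ogm) {
  apply(ogm, 2, function(col) {
    col <- col[!col %in% c("N", "-")]
    if (length(col) == 0L) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return(NA_character_)
    names(tab)[1]
  })
}

# derived-allele counts per column; NA where the site cannot be polarized
# (missing/ambiguous outgroup, outgroup allele absent from the ingroup, or
# ingroup with > 2 alleles). Sites with missing ingroup data are skipped.
polarizedDerivedCounts <- function(ss, anc) {
  L <- ss$L
  out <- rep(NA_integer_, L)
  cn <- ss$counts
  for (c in seq_len(L)) {
    a <- anc[c]
    if (is.na(a)) next
    if (ss$nEff[c] < ss$n) next                  # missing ingroup data
    if (ss$nAlleles[c] > 2L) next                # tri-allelic: excluded
    ancCount <- if (a %in% rownames(cn)) cn[a, c] else 0L
    if (ancCount == 0L) {
      if (ss$nAlleles[c] == 1L) { out[c] <- ss$n; next }  # fixed derived
      next  # polymorphic but outgroup carries a third allele: skip
    }
    out[c] <- ss$n - ancCount
  }
  out
}

# unnormalized Fay & Wu H from the unfolded SFS (per locus):
# H = pi_L - theta_H over polarizable sites, computed through the SFS
# identities pi = sum 2 xi_i i (n - i) / (n (n-1)),
# theta_H = sum 2 xi_i i^2 / (n (n-1))
coreFayWuH <- function(xi, n) {
  if (sum(xi) == 0) return(NA_real_)
  i <- seq_len(n - 1)
  sum(2 * xi * (i * (n - i) - i^2)) / (n * (n - 1))
}

# --- pairwise-difference sums from column counts ---------------------------

# sum over unordered within-group pairs of their per-column differences
withinPairDiffSum <- function(m) {
  ss <- siteSummary(m)
  ne <- ss$nEff
  tot <- ne * (ne - 1) / 2
  same <- colSums(ss$counts * (ss$counts - 1)) / 2
  sum(tot - same)
}

betweenPairDiffSum <- function(m1, m2) {
  c1 <- countsOf(m1)
  c2 <- countsOf(m2)
  if (!identical(rownames(c1), rownames(c2))) {
    alle <- union(rownames(c1), rownames(c2))
    f <- function(cc) {
      out <- matrix(0, length(alle), ncol(cc), dimnames = list(alle, NULL))
      out[rownames(cc), ] <- cc
      out
    }
    c1 <- f(c1); c2 <- f(c2)
  }
  n1 <- colSums(c1); n2 <- colSums(c2)
  sum(n1 * n2 - colSums(c1 * c2))
}

# pairwise difference-count distance matrix (rows of m); comparisons with
# missing residues (N, -) are skipped pairwise
pairwiseDiffMatrix <- function(m) {
  if (is.numeric(m)) return(as.matrix(dist(m, method = "manhattan")))
  okM <- matrix(as.numeric(!(m %in% c("N", "-"))), nrow(m), ncol(m))
  valid <- okM %*% t(okM)
  same <- matrix(0, nrow(m), nrow(m))
  for (a in c("A", "C", "G", "T")) {
    Xa <- matrix(as.numeric(m == a), nrow(m), ncol(m))
    same <- same + Xa %*% t(Xa)
  }
  valid - same
}

# AMOVA variance components and PhiST from a squared-distance matrix
# (pairwise difference counts) and a two-level grouping
amovaPhi <- function(d, groups) {
  glev <- unique(groups)
  N <- nrow(d)
  P <- length(glev)
  total <- sum(d) / 2
  SSt <- total / N
  SSw <- 0
  np <- numeric(P)
  for (i in seq_len(P)) {
    idx <- which(groups == glev[i])
    np[i] <- length(idx)
    SSw <- SSw + sum(d[idx, idx]) / 2 / np[i]
  }
  SSa <- SSt - SSw
  sigW <- SSw / (N - P)
  nc <- (N - sum(np^2) / N) / (P - 1)
  sigA <- (SSa / (P - 1) - sigW) / nc
  phi <- if (sigA + sigW <= 0) 0 else sigA / (sigA + sigW)
  list(phi = phi, sigmaAmong = sigA, sigmaWithin = sigW,
       SSamong = SSa, SSwithin = SSw)
}
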
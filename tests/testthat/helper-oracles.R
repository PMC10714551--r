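# Independent oracles used across the suite. These re-derive expectations
# by routes separate from the package implementation: a plain-R
# structured-coalescent simulator, brute-force pairwise statistics, an
# exhaustive recombination-interval stabbing search, and direct Ewens /
# HKA objective evaluations.

# --- plain-R structured coalescent (independent of the compiled engine) ---

oracleGenealogy <- function(n1, n2, demog, ploidy = 1) {
  n <- n1 + n2
  deme <- c(rep(1L, n1), rep(2L, n2))
  active <- seq_len(n)
  parent <- rep(NA_integer_, 2L * n - 1L)
  tm <- rep(0, 2L * n - 1L)
  t <- 0
  nxt <- n + 1L
  merged <- demog$tMerge <= 0
  if (merged) deme[] <- 1L
  brk <- demog$brk
  while (length(active) > 1L) {
    e <- findInterval(t, brk)
    k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    rates <- c(
      if (k1 > 1) k1 * (k1 - 1) / (4 * demog$N1[e] * ploidy) else 0,
      if (k2 > 1) k2 * (k2 - 1) / (4 * demog$N2[e] * ploidy) else 0,
      if (merged) 0 else k1 * demog$m12[e],
      if (merged) 0 else k2 * demog$m21[e])
    tot <- sum(rates)
    nb <- if (e < length(brk)) brk[e + 1] else Inf
    dt <- if (tot > 0) rexp(1, tot) else Inf
    if (t + dt >= nb) {
      if (!is.finite(nb)) stop("oracle: degenerate demography")
      t <- nb
      if (!merged && demog$tMerge <= t) { deme[] <- 1L; merged <- TRUE }
      next
    }
    t <- t + dt
    ev <- sample.int(4L, 1L, prob = rates / tot)
    if (ev <= 2L) {
      pool <- which(deme == ev)
      pick <- sample(pool, 2L)
      node <- nxt; nxt <- nxt + 1L
      parent[active[pick]] <- node
      tm[node] <- t
      keepDeme <- deme[pick[1]]
      active <- c(active[-pick], node)
      deme <- c(deme[-pick], keepDeme)
    } else {
      pool <- which(deme == (ev - 2L))
      pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
      deme[pick] <- if (ev == 3L) 2L else 1L
    }
  }
  list(parent = parent, time = tm, n = n)
}

oracleLocus <- function(n1, n2, demog, muL, ploidy = 1) {
  g <- oracleGenealogy(n1, n2, demog, ploidy)
  n <- g$n
  nb <- 2L * n - 2L
  len <- g$time[g$parent[seq_len(nb)]] - g$time[seq_len(nb)]
  nm <- rpois(nb, muL * len)
  S <- sum(nm)
  geno <- matrix(0L, n, S)
  if (S > 0L) {
    children <- vector("list", 2L * n - 1L)
    for (i in seq_len(nb))
      children[[g$parent[i]]] <- c(children[[g$parent[i]]], i)
    col <- 0L
    for (i in which(nm > 0L)) {
      stack <- i; tips <- integer()
      while (length(stack)) {
        nd <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (nd <= n) tips <- c(tips, nd) else stack <- c(stack, children[[nd]])
      }
      for (k in seq_len(nm[i])) { col <- col + 1L; geno[tips, col] <- 1L }
    }
  }
  geno
}

# --- brute-force statistics -----------------------------------------------

bruteForcePi <- function(m) {
  # mean pairwise difference per site, counting columns with missing data
  # pairwise (same convention as the package)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- m[i, ]; b <- m[j, ]
    if (is.numeric(m)) {
      tot <- tot + sum(a != b)
    } else {
      ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
      tot <- tot + sum(a[ok] != b[ok])
    }
  }
  tot / choose(n, 2) / ncol(m)
}

sfsPi <- function(xi, n, L) {
  i <- seq_len(n - 1)
  sum(2 * xi * i * (n - i)) / (n * (n - 1)) / L
}

# exhaustive minimum interval stabbing: minimal number of points, each
# strictly inside an interval, hitting all incompatible-pair intervals
bruteForceRm <- function(m) {
  stopifnot(is.numeric(m))
  B <- ncol(m)
  if (B < 2) return(0L)
  ivl <- NULL
  for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    g <- unique(m[, c(i, j), drop = FALSE])
    if (nrow(g) == 4L) ivl <- rbind(ivl, c(i, j))
  }
  if (is.null(ivl)) return(0L)
  gaps <- seq_len(B - 1)  # point between site g and g+1
  covers <- function(pts) {
    all(vapply(seq_len(nrow(ivl)), function(k)
      any(pts >= ivl[k, 1] & pts < ivl[k, 2]), TRUE))
  }
  for (sz in 1:length(gaps)) {
    combos <- utils::combn(gaps, sz)
    for (c in seq_len(ncol(combos))) if (covers(combos[, c])) return(sz)
  }
  length(gaps)
}

# random 0/1 toy matrices with at least one segregating site
randomToy <- function(n = NULL, S = NULL) {
  n <- n %||% sample(4:12, 1)
  S <- S %||% sample(1:15, 1)
  repeat {
    m <- matrix(rbinom(n * S, 1, runif(1, 0.1, 0.9)), n, S)
    cs <- colSums(m)
    if (any(cs > 0 & cs < n)) return(m)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- HKA -------------------------------------------------------------------

# brute-force solve of the HKA moment system by nested grid refinement
# over (theta1, theta2, T): minimizes the summed squared residuals of the
# three moment equations, then evaluates the chi-square statistic at the
# solution. Independent of the package's closed-form 1-D reduction.
hkaGridOracle <- function(S, D, n, thetaLim = c(0.1, 10), Tlim = c(0.1, 20),
                          passes = 6L, pts = 15L) {
  a1 <- vapply(n, function(x) sum(1 / seq_len(x - 1)), 1)
  a2 <- vapply(n, function(x) sum(1 / seq_len(x - 1)^2), 1)
  lo <- c(thetaLim[1], thetaLim[1], Tlim[1])
  hi <- c(thetaLim[2], thetaLim[2], Tlim[2])
  best <- NULL
  for (pass in seq_len(passes)) {
    g1 <- seq(lo[1], hi[1], length.out = pts)
    g2 <- seq(lo[2], hi[2], length.out = pts)
    g3 <- seq(lo[3], hi[3], length.out = pts)
    grid <- expand.grid(t1 = g1, t2 = g2, Tv = g3)
    r1 <- S[1] + D[1] - grid$t1 * (a1[1] + grid$Tv + 1)
    r2 <- S[2] + D[2] - grid$t2 * (a1[2] + grid$Tv + 1)
    r3 <- sum(D) - (grid$Tv + 1) * (grid$t1 + grid$t2)
    obj <- r1^2 + r2^2 + r3^2
    k <- which.min(obj)
    best <- list(th = c(grid$t1[k], grid$t2[k]), T = grid$Tv[k],
                 obj = obj[k])
    step <- (hi - lo) / (pts - 1)
    ctr <- c(best$th, best$T)
    lo <- pmax(ctr - 1.5 * step, 1e-6)
    hi <- ctr + 1.5 * step
  }
  th <- best$th; Tv <- best$T
  ES <- th * a1; ED <- th * (Tv + 1)
  VS <- th * a1 + th^2 * a2
  VD <- th * (Tv + 1) + th^2
  list(chi2 = sum((S - ES)^2 / VS + (D - ED)^2 / VD), T = Tv, theta = th)
}

# --- small builders --------------------------------------------------------

smallTemplate <- function(nLoci = 6L, totalBp = 2400L, nInd1 = 10L,
                          nInd2 = 8L) {
  studyTemplate(nLoci = nLoci, totalBp = totalBp, nInd1 = nInd1,
                nInd2 = nInd2)
}

# hand-built ReferenceTable around given stats (for rejection tests)
toyReferenceTable <- function(stats, scenario, params = NULL) {
  if (is.null(params))
    params <- data.frame(p = seq_len(nrow(stats)))
  new("ReferenceTable", scenario = scenario, params = params,
      stats = stats,
      center = apply(stats, 2, median), scale = apply(stats, 2, mad),
      config = list())
}
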
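# Composite-likelihood fitting of demographic scenarios to the observed
# joint SFS, AIC comparison, and parametric-bootstrap confidence
# intervals.

#' Composite log10-likelihood of an observed joint SFS
#'
#' CL = sum over polymorphic entries of m_e log10(p_e), with the expected
#' probabilities renormalized over polymorphic entries. Zero expected
#' probabilities are floored at 1/(10 Z) -- Z being the simulated
#' expected-SNP total behind the expectation -- and the vector is
#' renormalized, so unobserved-in-simulation cells stay finite.
#'
#' @param obs a [JointSFS-class] in counts mode (or a counts matrix).
#' @param expected a [JointSFS-class] in probabilities mode (or a matrix);
#'   its `"Z"` attribute supplies Z unless given explicitly.
#' @param Z simulated expected-SNP total used for the floor (default from
#'   `attr(expected, "Z")`, else the observed SNP total).
#' @return log10 composite likelihood (numeric scalar).
#' @export
compositeLogLik <- function(obs, expected, Z = NULL) {
  Mo <- if (is(obs, "JointSFS")) obs@M else obs
  Me <- if (is(expected, "JointSFS")) expected@M else expected
  if (!all(dim(Mo) == dim(Me))) stop("observed/expected shapes differ")
  if (is.null(Z)) Z <- attr(expected, "Z") %||% sumPolymorphic(Mo)
  poly <- matrix(TRUE, nrow(Mo), ncol(Mo))
  poly[1, 1] <- FALSE
  poly[nrow(Mo), ncol(Mo)] <- FALSE
  m <- Mo[poly]
  if (sum(m) < 1) stop("observed spectrum has no polymorphic entries")
  p <- Me[poly]
  if (sum(p) <= 0) stop("expected spectrum is all zero")
  p <- p / sum(p)
  floorP <- 1 / (10 * max(Z, 1))
  p[p < floorP] <- floorP
  p <- p / sum(p)
  sum(m * log10(p))
}

#' Akaike information criterion from a log10 likelihood
#'
#' AIC = 2 k - 2 ln(10) maxlog10L.
#'
#' @param maxLog10L maximized log10 (composite) likelihood.
#' @param k number of free parameters, >= 0.
#' @export
aic <- function(maxLog10L, k) {
  stopifnot(k >= 0)
  2 * k - 2 * log(10) * maxLog10L
}

# map optimizer coordinates in R^k to bounded parameters (logistic box
# transform; log-uniform parameters are transformed on the log scale)
boxTransform <- function(z, tb) {
  v <- numeric(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    u <- stats::plogis(z[i])
    v[i] <- if (tb$log[i]) exp(log(tb$min[i]) + u * (log(tb$max[i]) - log(tb$min[i])))
            else tb$min[i] + u * (tb$max[i] - tb$min[i])
  }
  setNames(v, tb$param)
}

boxInverse <- function(v, tb) {
  z <- numeric(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    if (tb$max[i] <= tb$min[i]) { z[i] <- 0; next }  # point bounds
    u <- if (tb$log[i]) (log(v[i]) - log(tb$min[i])) / (log(tb$max[i]) - log(tb$min[i]))
         else (v[i] - tb$min[i]) / (tb$max[i] - tb$min[i])
    u <- min(max(u, 1e-8), 1 - 1e-8)
    z[i] <- stats::qlogis(u)
  }
  z
}

#' Fit a scenario to an observed joint SFS by composite likelihood
#'
#' Nelder-Mead search over box-transformed parameters. Each evaluation
#' re-estimates the expected JSFS by Monte Carlo with common random
#' numbers within a loop (the same simulation seed for every evaluation,
#' refreshed between loops) so the stochastic likelihood surface is
#' smooth enough to climb. The objective adds a Poisson log-likelihood on
#' the total polymorphic-site count, which carries the absolute scale
#' (the joint-SFS shape alone is invariant to rescaling all sizes and
#' times).
#'
#' @param obs observed [JointSFS-class] in counts mode.
#' @param code scenario code.
#' @param bounds a [PriorSpec-class] giving box bounds per free parameter
#'   (default [defaultPriors()]).
#' @param loci locus table (for total mutation rate).
#' @param nSims Monte-Carlo genealogies per likelihood evaluation.
#' @param nLoops seed-refresh loops of the maximization.
#' @param nRestarts independent restarts from random prior draws.
#' @param evalsPerLoop Nelder-Mead evaluation budget per loop.
#' @param seed integer seed.
#' @param useTotalS include the Poisson term on the SNP total
#'   (recommended; without it the absolute scale is unidentifiable).
#' @return a `FitResult` list: `code`, `mle` (full parameter set),
#'   `free` (fitted free parameters), `maxLog10CL`, `k`, `aic`, `nSims`,
#'   `loops`, `restarts`.
#' @export
fitScenario <- function(obs, code, bounds = defaultPriors(code), loci,
                        nSims = 2000L, nLoops = 10L, nRestarts = 5L,
                        evalsPerLoop = 40L, seed = 1L, useTotalS = TRUE) {
  tb <- bounds@table
  n1 <- nrow(obs@M) - 1L
  n2 <- ncol(obs@M) - 1L
  Sobs <- sumPolymorphic(obs@M)
  nuc <- loci[loci$ploidy >= 1, , drop = FALSE]
  muL <- sum(nuc$mu * nuc$length)
  seeds <- childSeeds(seed, nRestarts * (nLoops + 1L))
  dim(seeds) <- c(nRestarts, nLoops + 1L)

  objective <- function(z, simSeed) {
    v <- boxTransform(z, tb)
    p <- tryCatch(paramsFromVector(code, as.list(v)), error = function(e) NULL)
    if (is.null(p)) return(-1e18)
    ok <- tryCatch({ validObject(p); TRUE }, error = function(e) FALSE)
    if (!ok) return(-1e18)
    scn <- tryCatch(buildScenario(code, p), error = function(e) NULL)
    if (is.null(scn)) return(-1e18)
    d <- scenarioEpochs(scn)
    M <- .sim_jsfs_cpp(n1, n2, d$brk, d$N1, d$N2, d$m12, d$m21,
                       d$tMerge, 1, muL, as.integer(nSims), as.double(simSeed))
    Z <- sumPolymorphic(M)
    if (Z <= 0) return(-1e18)
    P <- M / Z
    cl <- compositeLogLik(obs@M, P, Z = Z / nSims)
    if (useTotalS)
      cl <- cl + dpois(round(Sobs), Z / nSims, log = TRUE) / log(10)
    cl
  }

  best <- NULL
  for (r in seq_len(nRestarts)) {
    start <- samplePriors(bounds, 1, seed = seeds[r, nLoops + 1L])
    z <- boxInverse(as.numeric(start[1, tb$param]), tb)
    val <- -Inf
    for (l in seq_len(nLoops)) {
      simSeed <- seeds[r, l]
      opt <- stats::optim(z, function(zz) objective(zz, simSeed),
                          method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = evalsPerLoop))
      z <- opt$par
      val <- opt$value
    }
    if (is.null(best) || val > best$val) best <- list(z = z, val = val, restart = r)
  }
  if (!is.finite(best$val)) stop("optimizer failed on all restarts")
  free <- boxTransform(best$z, tb)
  full <- paramsFromVector(code, as.list(free))
  k <- nrow(tb)
  list(code = code, mle = full, free = free,
       maxLog10CL = best$val, k = k, aic = aic(best$val, k),
       nSims = nSims, loops = nLoops, restarts = nRestarts,
       bestRestart = best$restart)
}

#' Fit and rank several scenarios by AIC
#'
#' @inheritParams fitScenario
#' @param codes scenario codes (duplicates dropped with a warning).
#' @param ... further arguments passed to [fitScenario()].
#' @return list with `table` (data.frame ranked by AIC ascending, with
#'   dAIC) and `fits` (named list of FitResults).
#' @export
compareScenarios <- function(obs, codes, loci, seed = 1L, ...) {
  if (anyDuplicated(codes)) {
    warning("duplicate scenario codes dropped")
    codes <- unique(codes)
  }
  seeds <- childSeeds(seed, length(codes))
  fits <- lapply(seq_along(codes), function(i)
    fitScenario(obs, codes[i], loci = loci, seed = seeds[i], ...))
  names(fits) <- codes
  tabl <- data.frame(
    code = codes,
    k = vapply(fits, `[[`, 1, "k"),
    maxLog10CL = vapply(fits, `[[`, 1, "maxLog10CL"),
    AIC = vapply(fits, `[[`, 1, "aic"))
  tabl <- tabl[order(tabl$AIC), , drop = FALSE]
  tabl$dAIC <- tabl$AIC - tabl$AIC[1]
  rownames(tabl) <- NULL
  list(table = tabl, fits = fits)
}

# observed-style JSFS counts from simulated 0/1 matrices
jsfsFromMatrices <- function(mats, n1, n2) {
  M <- matrix(0, n1 + 1, n2 + 1)
  for (g in mats) {
    if (ncol(g) == 0) next
    i <- colSums(g[seq_len(n1), , drop = FALSE])
    j <- colSums(g[n1 + seq_len(n2), , drop = FALSE])
    for (s in seq_along(i)) M[i[s] + 1, j[s] + 1] <- M[i[s] + 1, j[s] + 1] + 1
  }
  new("JointSFS", M = M, mode = "counts")
}

#' Parametric-bootstrap confidence intervals for a fitted scenario
#'
#' Simulates `nBoot` datasets at the MLE, refits each (at the supplied
#' settings), and reports 2.5/97.5 percentile intervals per free
#' parameter.
#'
#' @param fit a FitResult from [fitScenario()].
#' @param loci locus table used for simulation and refitting.
#' @param n1,n2 haplotype counts.
#' @param nBoot bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param ... refit settings forwarded to [fitScenario()] (use reduced
#'   ones: the bootstrap multiplies their cost).
#' @return list with `ci` (matrix param x c(lo, hi)), `estimates`
#'   (nBoot x k matrix of refitted parameters).
#' @export
bootstrapCI <- function(fit, loci, n1, n2, nBoot = 100L, seed = 1L, ...) {
  stopifnot(nBoot >= 2)
  code <- fit$code
  scn <- buildScenario(code, fit$mle)
  demog <- scenarioEpochs(scn)
  nuc <- loci[loci$ploidy >= 1, , drop = FALSE]
  muLs <- nuc$mu * nuc$length
  seeds <- childSeeds(seed, 2L * nBoot)
  est <- matrix(NA_real_, nBoot, length(fit$free),
                dimnames = list(NULL, names(fit$free)))
  for (b in seq_len(nBoot)) {
    mats <- simLociMatrices(demog, n1, n2, muLs, seeds[b])
    obsB <- jsfsFromMatrices(mats, n1, n2)
    rf <- fitScenario(obsB, code, loci = loci, seed = seeds[nBoot + b], ...)
    est[b, ] <- rf$free[colnames(est)]
  }
  ci <- t(apply(est, 2, quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("lo", "hi")
  list(ci = ci, estimates = est)
}
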
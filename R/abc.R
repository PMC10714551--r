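# DIYABC-style scenario choice: reference-table simulation, rejection,
# direct and logistic-regression posteriors, local-linear parameter
# adjustment, and pseudo-observed-dataset confidence evaluation.

# deterministic pseudo-random projection weights for fast distinct-row
# counting (LCG with a multiplier small enough for exact double arithmetic)
hashWeights <- function(S) {
  x <- 987654321
  w <- numeric(S)
  for (k in seq_len(S)) {
    x <- (69069 * x + 1) %% 2147483648
    w[k] <- x / 2147483648 + 0.25
  }
  w
}

nDistinctRows <- function(m) {
  if (ncol(m) == 0L) return(1L)
  length(unique(as.numeric(m %*% hashWeights(ncol(m)))))
}

# per-locus raw quantities from a 0/1 derived matrix, by population
locusStatRow <- function(g, n1, n2, L) {
  i1 <- seq_len(n1)
  i2 <- n1 + seq_len(n2)
  c1 <- if (ncol(g)) colSums(g[i1, , drop = FALSE]) else numeric()
  c2 <- if (ncol(g)) colSums(g[i2, , drop = FALSE]) else numeric()
  seg1 <- c1 > 0L & c1 < n1
  seg2 <- c2 > 0L & c2 < n2
  S1 <- sum(seg1); S2 <- sum(seg2)
  piL1 <- sum(2 * c1 * (n1 - c1)) / (n1 * (n1 - 1))
  piL2 <- sum(2 * c2 * (n2 - c2)) / (n2 * (n2 - 1))
  W1 <- sum(c1 * (n1 - c1))              # within-pop differing pairs
  W2 <- sum(c2 * (n2 - c2))
  B <- sum(c1 * (n2 - c2) + (n1 - c1) * c2)  # between-pop differing pairs
  # AMOVA variance components from pair sums
  N <- n1 + n2
  SSt <- (W1 + W2 + B) / N
  SSw <- W1 / n1 + W2 / n2
  sigW <- SSw / (N - 2)
  nc <- (N - (n1^2 + n2^2) / N)
  sigA <- ((SSt - SSw) - sigW) / nc
  phi <- if (sigA + sigW <= 0) 0 else sigA / (sigA + sigW)
  D1 <- coreTajimaD(S1, piL1, n1)
  D2 <- coreTajimaD(S2, piL2, n2)
  c(Nh1 = nDistinctRows(g[i1, , drop = FALSE]),
    S1 = S1, pi1 = piL1 / L, D1 = if (is.na(D1)) 0 else D1,
    priv1 = sum(seg1 & !seg2),
    Nh2 = nDistinctRows(g[i2, , drop = FALSE]),
    S2 = S2, pi2 = piL2 / L, D2 = if (is.na(D2)) 0 else D2,
    priv2 = sum(seg2 & !seg1),
    phist = phi, dxy = B / (n1 * n2 * L), sharedS = sum(seg1 & seg2))
}

#' Summary-statistic vector of a simulated multi-locus dataset
#'
#' The fixed, versioned statistic set used for ABC: per population
#' (haplotype count, S, pi, Tajima's D, private S) and between populations
#' (per-locus PhiST, mean between-population pairwise difference per site,
#' shared S), each summarized as mean and variance across loci.
#' Undefined per-locus values (monomorphic loci) enter as 0 so the vector
#' never contains missing entries.
#'
#' @param mats list of per-locus 0/1 derived matrices (rows: n1 then n2
#'   haplotypes).
#' @param n1,n2 haplotype counts per population.
#' @param L per-locus lengths (recycled).
#' @return named numeric vector of 26 statistics.
#' @export
datasetStats <- function(mats, n1, n2, L) {
  L <- rep_len(L, length(mats))
  per <- vapply(seq_along(mats),
                function(i) locusStatRow(mats[[i]], n1, n2, L[i]),
                numeric(13))
  mu <- rowMeans(per)
  va <- apply(per, 1, var)
  out <- c(mu, va)
  names(out) <- c(paste0(rownames(per), "_mean"), paste0(rownames(per), "_var"))
  out
}

#' Build an ABC reference table
#'
#' Draws parameters from the prior of each scenario, simulates a
#' study-shaped multi-locus dataset per draw with the coalescent engine,
#' and records the summary-statistic vector. Standardization constants
#' (median/MAD per statistic) are computed over the whole table.
#'
#' @param codes character vector of scenario codes.
#' @param priors a [PriorSpec-class], a named list of one spec per code,
#'   or NULL for [defaultPriors()] per code.
#' @param R number of simulations per scenario.
#' @param loci locus table (`locus`, `length`, `mu`, `ploidy`); haploid
#'   rows are ignored.
#' @param n1,n2 sampled haplotype counts.
#' @param seed integer seed.
#' @return a [ReferenceTable-class].
#' @export
buildReferenceTable <- function(codes, priors = NULL, R, loci, n1, n2,
                                seed = 1L) {
  codes <- unique(codes)
  nuc <- loci[loci$ploidy >= 1, , drop = FALSE]
  muLs <- nuc$mu * nuc$length
  specOf <- function(code) {
    if (is.null(priors)) defaultPriors(code)
    else if (is(priors, "PriorSpec")) priors
    else priors[[code]]
  }
  seeds <- childSeeds(seed, 2L * length(codes))
  allStats <- NULL
  allParams <- list()
  allScen <- character()
  for (ci in seq_along(codes)) {
    code <- codes[ci]
    spec <- specOf(code)
    draws <- samplePriors(spec, R, seed = seeds[ci])
    simSeeds <- childSeeds(seeds[length(codes) + ci], R)
    stats <- matrix(NA_real_, R, 26L)
    for (r in seq_len(R)) {
      scn <- buildScenario(code, paramsFromVector(code, draws[r, ]))
      demog <- scenarioEpochs(scn)
      mats <- simLociMatrices(demog, n1, n2, muLs, simSeeds[r])
      stats[r, ] <- datasetStats(mats, n1, n2, nuc$length)
    }
    allStats <- rbind(allStats, stats)
    draws$.code <- code
    allParams[[code]] <- draws
    allScen <- c(allScen, rep(code, R))
  }
  colnames(allStats) <- names(datasetStats(
    list(matrix(0L, n1 + n2, 0)), n1, n2, 1))
  params <- do.call(rbind, lapply(allParams, function(d) {
    miss <- setdiff(unique(unlist(lapply(allParams, names))), names(d))
    for (m in miss) d[[m]] <- NA_real_
    d
  }))
  rownames(params) <- NULL
  ctr <- apply(allStats, 2, median)
  scl <- apply(allStats, 2, mad)
  new("ReferenceTable", scenario = allScen, params = params,
      stats = allStats, center = ctr, scale = scl,
      config = list(codes = codes, R = R, loci = loci, n1 = n1, n2 = n2,
                    priors = lapply(setNames(codes, codes), specOf)))
}

#' ABC rejection step
#'
#' Euclidean distance on median/MAD-standardized statistics; retains the
#' `ceiling(tolerance * nrow)` closest simulations. Statistics with zero
#' MAD are dropped from the distance with a warning. Ties are broken by
#' row index.
#'
#' @param observed named statistic vector (same set as the table).
#' @param table a [ReferenceTable-class].
#' @param tolerance retained fraction (the classic "closest 1\%" is 0.01).
#' @return integer vector of retained row indices, closest first, with
#'   the distances as attribute `"distance"`.
#' @export
abcReject <- function(observed, table, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  scl <- table@scale
  usable <- scl > 0
  if (any(!usable))
    warning("dropping zero-MAD statistics from the distance: ",
            paste(names(scl)[!usable], collapse = ", "))
  ctr <- table@center[usable]
  scl <- scl[usable]
  obs <- (observed[names(ctr)] - ctr) / scl
  Z <- sweep(sweep(table@stats[, usable, drop = FALSE], 2, ctr), 2, scl, "/")
  d <- sqrt(rowSums(sweep(Z, 2, obs)^2))
  nKeep <- ceiling(tolerance * nrow(Z))
  idx <- order(d)[seq_len(nKeep)]
  attr(idx, "distance") <- d[idx]
  idx
}

#' Direct (rejection) scenario posterior
#'
#' Scenario frequencies among the retained simulations, over all
#' scenarios present in the table.
#'
#' @param table a [ReferenceTable-class].
#' @param retained indices from [abcReject()].
#' @return named numeric vector summing to 1.
#' @export
posteriorDirect <- function(table, retained) {
  stopifnot(length(retained) > 0)
  lev <- unique(table@scenario)
  tab <- base::table(factor(table@scenario[retained], levels = lev))
  setNames(as.numeric(tab) / length(retained), lev)
}

#' Logistic-regression scenario posterior
#'
#' Multinomial logistic regression of the scenario label on the
#' (standardized) statistic offsets from the observed vector over the
#' retained simulations, evaluated at zero offset. Ridge-regularized
#' (weight decay) so complete separation degrades gracefully; 95\%
#' intervals via the delta method on the intercepts.
#'
#' @inheritParams posteriorDirect
#' @param observed observed statistic vector.
#' @param decay ridge penalty passed to [nnet::multinom()].
#' @return list with `posterior` (named, sums to 1), `ci` (2-column
#'   matrix, possibly NA when the Hessian is unusable), `fit`.
#' @export
posteriorLogistic <- function(table, retained, observed, decay = 1e-6) {
  lev <- unique(table@scenario[retained])
  if (length(lev) < 2L)
    stop("logistic posterior needs >= 2 scenarios among retained rows")
  usable <- table@scale > 0
  ctr <- table@center[usable]
  scl <- table@scale[usable]
  X <- sweep(sweep(table@stats[retained, usable, drop = FALSE], 2,
                   observed[names(ctr)]), 2, scl, "/")
  # drop collinear/constant columns for stability
  keep <- apply(X, 2, function(cc) sd(cc) > 1e-10)
  X <- X[, keep, drop = FALSE]
  df <- data.frame(.scen = factor(table@scenario[retained],
                                  levels = sort(lev)), X, check.names = TRUE)
  fit <- tryCatch(
    nnet::multinom(.scen ~ ., data = df, decay = decay, trace = FALSE,
                   maxit = 500),
    error = function(e) NULL)
  levs <- sort(lev)
  if (is.null(fit)) {
    warning("multinomial fit failed; falling back to direct frequencies")
    p <- posteriorDirect(table, retained)
    return(list(posterior = p[levs] / sum(p[levs]),
                ci = matrix(NA_real_, length(levs), 2,
                            dimnames = list(levs, c("lo", "hi"))),
                fit = NULL))
  }
  nd <- as.data.frame(matrix(0, 1, ncol(X)))
  names(nd) <- colnames(X)
  p <- stats::predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(p))) {
    # two-class fit returns P(second level)
    p <- c(1 - p, p)
  }
  p <- setNames(as.numeric(p), levs)
  ci <- tryCatch({
    V <- stats::vcov(fit)
    cf <- coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                       dimnames = list(levs[2], names(cf)))
    K <- length(levs)
    eta <- c(0, cf[, "(Intercept)"])
    pr <- exp(eta) / sum(exp(eta))
    # d p_k / d eta_j for j = 2..K (intercept block)
    Jm <- matrix(0, K, K - 1)
    for (k in seq_len(K)) for (j in 2:K)
      Jm[k, j - 1] <- pr[k] * ((k == j) - pr[j])
    inames <- grep("(Intercept)", colnames(V), fixed = TRUE, value = TRUE)
    Vi <- V[inames, inames, drop = FALSE]
    se <- sqrt(pmax(diag(Jm %*% Vi %*% t(Jm)), 0))
    cbind(lo = pmax(p - 1.96 * se, 0), hi = pmin(p + 1.96 * se, 1))
  }, error = function(e)
    matrix(NA_real_, length(levs), 2, dimnames = list(levs, c("lo", "hi"))))
  list(posterior = p / sum(p), ci = ci, fit = fit)
}

weightedQuantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1] %||% length(x)], 1)
}

#' Local-linear (Beaumont) parameter-posterior adjustment
#'
#' Weighted linear regression of each parameter on the standardized
#' statistic offsets among the retained rows of the best scenario
#' (Epanechnikov weights on the rejection distance), with the regression
#' prediction subtracted so the adjusted draws condition on the observed
#' statistics. Adjusted values are clipped to the prior support.
#'
#' @inheritParams posteriorLogistic
#' @param code scenario whose retained rows to adjust (default: the most
#'   frequent among retained).
#' @return list with `samples` (data.frame of adjusted draws), `weights`,
#'   `summary` (2.5/50/97.5 weighted percentiles per parameter), `code`.
#' @export
adjustParamsLocLinear <- function(table, retained, observed, code = NULL) {
  if (is.null(code)) {
    p <- posteriorDirect(table, retained)
    code <- names(p)[which.max(p)]
  }
  sel <- retained[table@scenario[retained] == code]
  if (length(sel) < 50L)
    stop("need >= 50 retained rows of scenario ", code, "; got ", length(sel))
  d <- attr(retained, "distance")
  if (is.null(d)) stop("retained indices must come from abcReject()")
  d <- d[match(sel, retained)]
  delta <- max(d) * (1 + 1e-12)
  w <- pmax(1 - (d / delta)^2, 1e-12)
  usable <- table@scale > 0
  ctr <- table@center[usable]
  scl <- table@scale[usable]
  X <- sweep(sweep(table@stats[sel, usable, drop = FALSE], 2,
                   observed[names(ctr)]), 2, scl, "/")
  keep <- apply(X, 2, function(cc) sd(cc) > 1e-10)
  X <- X[, keep, drop = FALSE]
  spec <- table@config$priors[[code]]
  pn <- intersect(names(table@params), spec@table$param)
  samples <- table@params[sel, pn, drop = FALSE]
  for (par in pn) {
    y <- samples[[par]]
    tb <- spec@table[spec@table$param == par, ]
    lg <- tb$log
    ty <- if (lg) log(y) else y
    fit <- tryCatch(lm(ty ~ X, weights = w), error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit))) {
      warning("singular design for ", par, "; returning unadjusted draws")
      adj <- ty
    } else {
      adj <- coef(fit)[1] + stats::residuals(fit)
    }
    if (lg) adj <- exp(adj)
    samples[[par]] <- pmin(pmax(adj, tb$min), tb$max)
  }
  summ <- t(vapply(pn, function(par)
    weightedQuantile(samples[[par]], w, c(0.025, 0.5, 0.975)), numeric(3)))
  colnames(summ) <- c("q2.5", "q50", "q97.5")
  list(samples = samples, weights = w, summary = summ, code = code)
}

#' Confidence evaluation with pseudo-observed datasets
#'
#' Draws `nPods` parameter sets per scenario from its prior, simulates a
#' dataset for each, classifies it against the reference table
#' (rejection + direct posterior argmax) and reports the confusion
#' matrix, per-scenario type-I error (true scenario not chosen) and
#' type-II error (scenario chosen when false).
#'
#' @param table a [ReferenceTable-class] (carries its simulation config).
#' @param nPods pseudo-observed datasets per scenario.
#' @param tolerance rejection tolerance.
#' @param seed integer seed.
#' @return list with `confusion` (rows: true scenario; rows sum to 1),
#'   `typeI`, `typeII`.
#' @export
evaluateConfidence <- function(table, nPods, tolerance = 0.01, seed = 1L) {
  stopifnot(nPods >= 1)
  cfg <- table@config
  codes <- cfg$codes
  nuc <- cfg$loci[cfg$loci$ploidy >= 1, , drop = FALSE]
  muLs <- nuc$mu * nuc$length
  seeds <- childSeeds(seed, 2L * length(codes))
  conf <- matrix(0, length(codes), length(codes),
                 dimnames = list(true = codes, chosen = codes))
  for (ci in seq_along(codes)) {
    code <- codes[ci]
    draws <- samplePriors(cfg$priors[[code]], nPods, seed = seeds[ci])
    podSeeds <- childSeeds(seeds[length(codes) + ci], nPods)
    for (r in seq_len(nPods)) {
      scn <- buildScenario(code, paramsFromVector(code, draws[r, ]))
      mats <- simLociMatrices(scenarioEpochs(scn), cfg$n1, cfg$n2, muLs,
                              podSeeds[r])
      obs <- datasetStats(mats, cfg$n1, cfg$n2, nuc$length)
      post <- posteriorDirect(table, abcReject(obs, table, tolerance))
      pick <- names(post)[which.max(post)]
      conf[code, pick] <- conf[code, pick] + 1
    }
  }
  conf <- conf / nPods
  typeI <- 1 - diag(conf)
  typeII <- vapply(seq_along(codes), function(j)
    mean(conf[-j, j]), 1)
  names(typeII) <- codes
  list(confusion = conf, typeI = setNames(typeI, codes), typeII = typeII)
}
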
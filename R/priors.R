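#' PriorSpec: independent uniform/log-uniform priors with order constraints
#'
#' @slot table data.frame with columns `param`, `min`, `max`, `log`
#'   (log-uniform flag).
#' @slot constraints character vector of cross-parameter inequalities
#'   evaluated on draws (e.g. `"t0 < t3"`).
#'
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(table = "data.frame", constraints = "character"))

setValidity("PriorSpec", function(object) {
  msg <- character()
  tb <- object@table
  if (!all(c("param", "min", "max", "log") %in% names(tb)))
    msg <- c(msg, "table needs columns param, min, max, log")
  else {
    if (any(tb$min > tb$max)) msg <- c(msg, "need min <= max for every parameter")
    if (any(tb$log & tb$min <= 0)) msg <- c(msg, "log-uniform needs min > 0")
    if (anyDuplicated(tb$param)) msg <- c(msg, "duplicate parameter names")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec:\n")
  print(object@table, row.names = FALSE)
  if (length(object@constraints))
    cat("constraints:", paste(object@constraints, collapse = ", "), "\n")
})

#' Construct a PriorSpec
#'
#' @param table data.frame with columns `param`, `min`, `max`, `log`.
#' @param constraints character vector of inequalities among parameters.
#' @return a [PriorSpec-class].
#' @export
priorSpec <- function(table, constraints = character()) {
  new("PriorSpec", table = table, constraints = constraints)
}

# free parameters of a scenario code
freeParamNames <- function(code) {
  fam <- substr(code, 1, 1)
  suf <- as.integer(substr(code, 2, 2))
  p <- c("N1", "N2", "N2f", "t1", "t3")
  if (fam %in% c("B", "D")) p <- c(p, "N1b", "t0")
  if (fam %in% c("C", "D")) p <- c(p, "NAnc", "t2")
  if (suf %in% c(3L, 4L) && !"t0" %in% p) p <- c(p, "t0")
  if (suf >= 2L) p <- c(p, "m12", "m21")
  p
}

#' Default desk-scale priors for a scenario code
#'
#' Uniform times (generations), log-uniform sizes and migration rates,
#' with the definitional order constraints of the scenario grammar:
#' `t0 < t3`, `t1 < t3`, `t1 <= t2 < t3` (C/D), `N1b < N1` (an
#' expansion), `N2f < N2` and (C/D) `N2f < NAnc` (a founder event or
#' bottleneck).
#'
#' @param code scenario code (`"A1"` .. `"D5"`).
#' @return a [PriorSpec-class] over the code's free parameters.
#' @export
defaultPriors <- function(code) {
  all <- data.frame(
    param = c("N1", "N2", "N1b", "N2f", "NAnc", "t3", "t0", "t1", "t2",
              "m12", "m21"),
    min = c(1e4, 1e3, 1e3, 1e2, 1e4, 2e4, 1e3, 1e3, 1e3, 1e-8, 1e-8),
    max = c(1e6, 1e5, 1e5, 1e4, 1e6, 4e5, 1e5, 1e5, 2e5, 1e-5, 1e-5),
    log = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
            TRUE, TRUE),
    stringsAsFactors = FALSE)
  free <- freeParamNames(code)
  tb <- all[all$param %in% free, , drop = FALSE]
  cs <- c("t1 < t3", "N2f < N2")
  if ("t0" %in% free) cs <- c(cs, "t0 < t3")
  if ("N1b" %in% free) cs <- c(cs, "N1b < N1")
  if ("t2" %in% free) cs <- c(cs, "t1 <= t2", "t2 < t3")
  if ("NAnc" %in% free) cs <- c(cs, "N2f < NAnc")
  priorSpec(tb, cs)
}

#' Draw parameter vectors from a PriorSpec
#'
#' Independent uniform (or log-uniform) draws, with order constraints
#' enforced by rejection resampling.
#'
#' @param spec a [PriorSpec-class].
#' @param R number of draws.
#' @param seed integer seed.
#' @return data.frame with R rows, one column per parameter.
#' @export
samplePriors <- function(spec, R, seed = 1L) {
  stopifnot(R >= 1)
  tb <- spec@table
  drawBlock <- function(nn) {
    out <- lapply(seq_len(nrow(tb)), function(i) {
      if (tb$log[i]) exp(runif(nn, log(tb$min[i]), log(tb$max[i])))
      else runif(nn, tb$min[i], tb$max[i])
    })
    names(out) <- tb$param
    as.data.frame(out)
  }
  okRows <- function(df) {
    ok <- rep(TRUE, nrow(df))
    for (cs in spec@constraints)
      ok <- ok & eval(parse(text = cs), envir = df)
    ok
  }
  withSeed(seed, {
    acc <- NULL
    tried <- 0
    kept <- 0
    while (is.null(acc) || nrow(acc) < R) {
      blk <- drawBlock(max(R, 1000L))
      tried <- tried + nrow(blk)
      blk <- blk[okRows(blk), , drop = FALSE]
      kept <- kept + nrow(blk)
      if (tried >= 1e4 && kept / tried < 1e-4)
        stop("prior constraint acceptance rate below 1e-4; priors unsatisfiable")
      acc <- if (is.null(acc)) blk else rbind(acc, blk)
    }
    acc <- acc[seq_len(R), , drop = FALSE]
    rownames(acc) <- NULL
    acc
  })
}

# complete a free-parameter vector into ScenarioParams for a code
paramsFromVector <- function(code, v) {
  v <- as.list(v)
  fam <- substr(code, 1, 1)
  N1 <- v$N1
  scenarioParams(
    N1 = N1, N2 = v$N2,
    N1b = v$N1b %||% N1,
    N2f = v$N2f %||% v$N2,
    NAnc = v$NAnc %||% N1,
    t0 = v$t0 %||% (v$t3 / 2),
    t1 = v$t1,
    t2 = if (fam %in% c("C", "D")) v$t2 else NA_real_,
    t3 = v$t3,
    m12 = v$m12 %||% 0, m21 = v$m21 %||% 0)
}
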
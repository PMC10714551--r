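#' Construct ScenarioParams
#'
#' @param N1,N2 current diploid sizes of deme 1 and deme 2.
#' @param N1b pre-expansion size of deme 1 (defaults to N1: no change).
#' @param N2f founder/bottleneck size of deme 2 (defaults to N2).
#' @param NAnc ancestral size (defaults to N1: the ancestral-range deme).
#' @param t0 deme-1 expansion time / recent-migration window end
#'   (generations).
#' @param t1 deme-2 recovery time.
#' @param t2 deme-2 bottleneck onset (C/D families; NA otherwise).
#' @param t3 divergence time.
#' @param m12,m21 backward per-lineage migration rates (deme 1 -> 2 and
#'   2 -> 1).
#' @return a [ScenarioParams-class].
#' @export
scenarioParams <- function(N1, N2, N1b = N1, N2f = N2, NAnc = N1,
                           t0, t1, t2 = NA_real_, t3, m12 = 0, m21 = 0) {
  new("ScenarioParams", N1 = N1, N2 = N2, N1b = N1b, N2f = N2f,
      NAnc = NAnc, t0 = t0, t1 = t1, t2 = as.numeric(t2), t3 = t3,
      m12 = m12, m21 = m21)
}

scenarioModes <- c(
  A1 = "peripatric", A3 = "peripatric", B1 = "peripatric", B3 = "peripatric",
  C1 = "vicariant", C3 = "vicariant", D1 = "vicariant", D3 = "vicariant",
  A2 = "parapatric", A4 = "parapatric", B2 = "parapatric", B4 = "parapatric",
  A5 = "complex", B5 = "complex", C2 = "complex", C4 = "complex",
  C5 = "complex", D2 = "complex", D4 = "complex", D5 = "complex")

#' Build a demographic scenario from its code
#'
#' The scenario family letter sets the population-size history (backward
#' in time, generations before present):
#' \itemize{
#' \item A: deme 2 founded from deme 1 at `t3` at size `N2f`, recovering
#'   to `N2` at `t1`; deme 1 constant at `N1`.
#' \item B: as A, plus a deme-1 size change `N1b -> N1` at `t0` (recent
#'   expansion of the ancestral-range deme).
#' \item C: both demes split from an ancestor of size `NAnc` at `t3`;
#'   deme 2 passes through a bottleneck at size `N2f` during
#'   `(t1, t2)`.
#' \item D: as C, plus the deme-1 expansion at `t0`.
#' }
#' The numeric suffix sets the migration epochs: 1 none; 2 initial only
#' (`[t1, t3]`, the early phase of divergence); 3 recent only (`[0, t0]`,
#' during the deme-1 expansion); 4 both windows; 5 ongoing (`[0, t3]`).
#'
#' @param code scenario code, e.g. `"B3"`.
#' @param params a [ScenarioParams-class]; time ordering appropriate to
#'   the family is validated (C/D require `t2`).
#' @return a [DemographicScenario-class].
#' @export
buildScenario <- function(code, params) {
  code <- toupper(code)
  if (!grepl("^[ABCD][1-5]$", code))
    stop("unknown scenario code: ", code)
  fam <- substr(code, 1, 1)
  suf <- as.integer(substr(code, 2, 2))
  p <- params
  validObject(p)
  if (fam %in% c("C", "D") && is.na(p@t2))
    stop("scenario ", code, " requires t2 (bottleneck onset), with t1 <= t2 < t3")
  ev <- data.frame(time = p@t3,
                   event = if (fam %in% c("A", "B")) "deme2 founded from deme 1 (size N2f)"
                           else "demes split from ancestor (size NAnc)")
  ev <- rbind(ev, data.frame(time = p@t1,
                             event = "deme 2 size change to N2 (recovery)"))
  if (fam %in% c("C", "D"))
    ev <- rbind(ev, data.frame(time = p@t2, event = "deme 2 bottleneck onset (size N2f)"))
  if (fam %in% c("B", "D"))
    ev <- rbind(ev, data.frame(time = p@t0, event = "deme 1 size change N1b -> N1 (expansion)"))
  ev <- ev[order(ev$time), , drop = FALSE]
  win <- switch(suf,
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end"))),
    matrix(c(p@t1, p@t3), 1, 2, dimnames = list(NULL, c("start", "end"))),
    matrix(c(0, p@t0), 1, 2, dimnames = list(NULL, c("start", "end"))),
    matrix(c(0, p@t1, p@t0, p@t3), 2, 2, dimnames = list(NULL, c("start", "end"))),
    matrix(c(0, p@t3), 1, 2, dimnames = list(NULL, c("start", "end"))))
  if (suf > 1 && p@m12 == 0 && p@m21 == 0)
    warning("scenario ", code, " has migration epochs but zero rates")
  new("DemographicScenario", code = code,
      mode = unname(scenarioModes[code]), params = p, events = ev,
      migrationWindows = win)
}

# piecewise-constant epochs for the simulator: breakpoints, per-epoch
# sizes and active migration rates, and the merge time
scenarioEpochs <- function(scn) {
  p <- scn@params
  fam <- substr(scn@code, 1, 1)
  times <- c(0, p@t1, p@t3)
  if (fam %in% c("B", "D")) times <- c(times, p@t0)
  if (fam %in% c("C", "D")) times <- c(times, p@t2)
  win <- scn@migrationWindows
  if (nrow(win) > 0) times <- c(times, as.vector(win))
  brk <- sort(unique(times))
  brk <- brk[brk <= p@t3]
  nE <- length(brk)
  mid <- brk + c(diff(brk) / 2, Inf)  # representative time inside epoch
  # deme 1 size per epoch
  N1 <- rep(p@N1, nE)
  if (fam %in% c("B", "D")) N1[mid > p@t0] <- p@N1b
  N1[mid > p@t3] <- p@NAnc
  # deme 2 size per epoch (unused after the merge)
  N2 <- rep(p@N2, nE)
  if (fam %in% c("A", "B")) {
    N2[mid > p@t1] <- p@N2f
  } else {
    N2[mid > p@t1 & mid <= p@t2] <- p@N2f
  }
  active <- rep(FALSE, nE)
  if (nrow(win) > 0) {
    for (w in seq_len(nrow(win)))
      active <- active | (mid > win[w, 1] & mid <= win[w, 2])
  }
  list(brk = brk, N1 = N1, N2 = N2,
       m12 = ifelse(active, p@m12, 0), m21 = ifelse(active, p@m21, 0),
       tMerge = p@t3)
}
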
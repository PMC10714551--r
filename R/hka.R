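#' Multilocus Hudson-Kreitman-Aguade (HKA) neutrality test
#'
#' One-taxon configuration: within-taxon polymorphism (S_i) at L loci is
#' contrasted with mean divergence to an outgroup (D_i) under a neutral
#' model with locus-specific theta_i and a shared scaled divergence time T
#' (units of 2N generations, ancestral size assumed equal to the ingroup
#' size). Moment expectations are
#' \deqn{E[S_i] = \theta_i a_1(n_i), \quad E[D_i] = \theta_i (T + 1)}
#' with variances \eqn{Var[S_i] = \theta_i a_1 + \theta_i^2 a_2} and
#' \eqn{Var[D_i] = \theta_i (T+1) + \theta_i^2} (Hudson et al. 1987,
#' including the ancestral coalescent variance term). The moment system
#' reduces to a single monotone equation in T, solved by Brent's method;
#' locus thetas follow as theta_i = (S_i + D_i) / (a_1(n_i) + T + 1),
#' which conserves the observed totals by construction.
#'
#' The goodness-of-fit statistic is
#' X^2 = sum_i (S_i - E S_i)^2 / Var S_i + (D_i - E D_i)^2 / Var D_i,
#' referred to a chi-square distribution with (L - 1) degrees of freedom.
#'
#' @param input data.frame with columns `locus`, `S` (segregating sites),
#'   `D` (mean ingroup-outgroup differences), `n` (ingroup haplotypes);
#'   an `L` column (sites) may be present and is carried through.
#' @param tol relative convergence tolerance of the root solve.
#' @return list with `theta` (named per-locus estimates), `T` (scaled
#'   divergence time), `chi2`, `df`, `p`, and the per-locus expectation
#'   table `fit`.
#' @export
hkaFit <- function(input, tol = 1e-10) {
  stopifnot(all(c("locus", "S", "D", "n") %in% names(input)))
  L <- nrow(input)
  if (L < 2L) stop("HKA needs at least 2 loci")
  if (any(input$S < 0) || any(input$D < 0)) stop("S and D must be >= 0")
  if (any(input$n < 2)) stop("each locus needs n >= 2 ingroup haplotypes")
  a1 <- vapply(input$n, harmonicA1, 1)
  a2 <- vapply(input$n, harmonicA2, 1)
  tot <- input$S + input$D
  sumD <- sum(input$D)
  if (sumD <= 0) stop("no divergence observed; T is unidentifiable")
  # residual of the divergence moment equation; strictly increasing in T
  g <- function(T) sum(tot * (T + 1) / (a1 + T + 1)) - sumD
  hi <- 1
  while (g(hi) < 0) hi <- hi * 2
  That <- uniroot(g, c(-1 + 1e-12, hi), tol = tol)$root
  theta <- tot / (a1 + That + 1)
  ES <- theta * a1
  ED <- theta * (That + 1)
  VS <- theta * a1 + theta^2 * a2
  VD <- theta * (That + 1) + theta^2
  chi2 <- sum((input$S - ES)^2 / VS + (input$D - ED)^2 / VD)
  df <- L - 1L
  if (df < 1L) stop("non-positive degrees of freedom")
  fit <- data.frame(locus = input$locus, S = input$S, D = input$D,
                    n = input$n, theta = theta, ES = ES, ED = ED,
                    varS = VS, varD = VD)
  list(theta = setNames(theta, input$locus), T = That, chi2 = chi2,
       df = df, p = chisqUpperTail(chi2, df), fit = fit)
}

#' Upper-tail chi-square probability
#'
#' @param x statistic value, >= 0.
#' @param df degrees of freedom, >= 1.
#' @return P(X >= x) for X ~ chi-square(df).
#' @export
chisqUpperTail <- function(x, df) {
  if (df < 1) stop("df must be >= 1")
  if (any(x < 0)) stop("statistic must be >= 0")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Assemble HKA input from a dataset with outgroup sequences
#'
#' Computes per-locus S within the chosen population and mean pairwise
#' divergence D to the locus outgroup (mean over all ingroup x outgroup
#' sequence pairs, pairwise-deletion).
#'
#' @param ds a [StudyDataset-class] whose loci carry outgroup sequences.
#' @param population population label to test (NULL pools all samples).
#' @return data.frame suitable for [hkaFit()].
#' @export
hkaInputFromDataset <- function(ds, population = NULL) {
  rows <- lapply(ds@nuclearLoci, function(aln) {
    og <- outgroupMatrix(aln)
    if (is.null(og)) stop("locus ", locusId(aln), " has no outgroup")
    m <- alnMatrix(aln)
    if (!is.null(population)) {
      pop <- ds@popmap$population[match(aln@sampleId, ds@popmap$sample_id)]
      m <- m[pop == population, , drop = FALSE]
    }
    nb <- betweenPairDiffSum(m, og) / (nrow(m) * nrow(og))
    data.frame(locus = locusId(aln), S = segregatingSites(m), D = nb,
               n = nrow(m), L = ncol(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
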
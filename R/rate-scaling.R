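# Mutation-rate derivation and unit conversions. All conversions are exact
# arithmetic; round trips hold to machine precision.

#' Mutation rate per year from silent-site divergence
#'
#' mu = Ks / (2 T): Ks is the average silent-site divergence (proportion)
#' to a calibrating outgroup taxon and T the calibration split time in
#' years, so each lineage accumulated Ks/2 substitutions per site over T
#' years.
#'
#' @param Ks silent-site divergence, >= 0.
#' @param Tyears calibration time in years, > 0.
#' @return per-site per-year mutation rate.
#' @export
muFromKs <- function(Ks, Tyears) {
  if (Tyears <= 0) stop("calibration time must be > 0")
  if (Ks < 0) stop("Ks must be >= 0")
  Ks / (2 * Tyears)
}

#' Convert a per-year rate to a per-generation rate
#' @param muPerYear per-site per-year mutation rate.
#' @param generationTime generation time in years (default 25, a
#'   long-lived conifer).
#' @return per-site per-generation rate.
#' @export
perYearToPerGen <- function(muPerYear, generationTime = 25) {
  stopifnot(muPerYear > 0, generationTime > 0)
  muPerYear * generationTime
}

#' Convert a per-generation rate to a per-year rate
#' @param muPerGen per-site per-generation mutation rate.
#' @inheritParams perYearToPerGen
#' @export
perGenToPerYear <- function(muPerGen, generationTime = 25) {
  stopifnot(muPerGen > 0, generationTime > 0)
  muPerGen / generationTime
}

#' Population-scaled migration 2Nm
#'
#' Expected effective migrant lineages per generation in the receiving
#' deme.
#'
#' @param Ne diploid effective size of the receiving deme, > 0.
#' @param m per-lineage per-generation migration rate, >= 0.
#' @export
scaled2Nm <- function(Ne, m) {
  stopifnot(Ne > 0, m >= 0)
  2 * Ne * m
}

#' Convert years to generations
#' @param tYears time in years.
#' @inheritParams perYearToPerGen
#' @export
yearsToGenerations <- function(tYears, generationTime = 25) {
  stopifnot(tYears > 0, generationTime > 0)
  tYears / generationTime
}

#' Convert generations to years
#' @param tGen time in generations.
#' @inheritParams perYearToPerGen
#' @export
generationsToYears <- function(tGen, generationTime = 25) {
  stopifnot(tGen > 0, generationTime > 0)
  tGen * generationTime
}

#' Default rate constants
#'
#' The package-wide defaults: per-generation rate 5.58e-9 per site
#' (geometric-average nuclear rate scaled by the 25-year generation time
#' from a per-year rate of 2.23e-10), generation time 25 years.
#'
#' @return named list `muPerGen`, `muPerYear`, `generationTime`.
#' @export
rateConstants <- function() {
  list(muPerGen = 5.58e-9, muPerYear = 2.23e-10, generationTime = 25)
}
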
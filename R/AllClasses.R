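#' @include peripagen-package.R
NULL

#' LocusAlignment: phased haplotype alignment for one locus
#'
#' Holds the aligned, equal-length haplotype sequences of one locus, the
#' sample each haplotype belongs to, and (optionally) aligned outgroup
#' sequences used for polarizing derived alleles.
#'
#' @slot locusId single locus identifier.
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width haplotype
#'   sequences (alphabet A, C, G, T, -, N).
#' @slot sampleId character, one sample id per haplotype.
#' @slot haplotypeIndex integer, haplotype index within sample (1 for
#'   haploid loci, 1/2 for diploid phased loci).
#' @slot outgroup a [Biostrings::DNAStringSet] of aligned outgroup
#'   sequences (may be empty).
#'
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  representation(
    locusId = "character",
    seqs = "DNAStringSet",
    sampleId = "character",
    haplotypeIndex = "integer",
    outgroup = "DNAStringSet"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  ns <- length(object@seqs)
  if (ns < 1L) msg <- c(msg, "alignment must contain at least one sequence")
  w <- unique(Biostrings::width(object@seqs))
  if (length(w) > 1L)
    msg <- c(msg, sprintf("ragged alignment: sequence widths %s",
                          paste(w, collapse = ", ")))
  if (length(object@outgroup) > 0L &&
      length(unique(c(w, Biostrings::width(object@outgroup)))) > 1L)
    msg <- c(msg, "outgroup width differs from alignment width")
  if (length(object@sampleId) != ns || length(object@haplotypeIndex) != ns)
    msg <- c(msg, "sampleId/haplotypeIndex must match number of sequences")
  key <- paste(object@sampleId, object@haplotypeIndex)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (sample, haplotype) identifiers")
  if (length(object@locusId) != 1L) msg <- c(msg, "locusId must be length 1")
  af <- Biostrings::alphabetFrequency(object@seqs, collapse = TRUE)
  allowed <- c("A", "C", "G", "T", "-", "N")
  extra <- af[setdiff(names(af)[af > 0], allowed)]
  if (length(extra) > 0L)
    msg <- c(msg, sprintf("disallowed characters in alignment: %s",
                          paste(names(extra), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' StudyDataset: multi-locus dataset with population map
#'
#' @slot nuclearLoci list of [LocusAlignment] (diploid phased loci).
#' @slot cpdna a [LocusAlignment] for the concatenated organellar locus, or
#'   NULL.
#' @slot popmap data.frame with columns `sample_id`, `population`.
#' @slot ploidy named numeric ploidy factor per locus (1 nuclear diploid,
#'   0.5 haploid organellar by default).
#'
#' @exportClass StudyDataset
setClass("StudyDataset",
  representation(
    nuclearLoci = "list",
    cpdna = "ANY",
    popmap = "data.frame",
    ploidy = "numeric"
  )
)

#' ScenarioParams: parameters of the two-deme demographic scenario family
#'
#' Sizes are current diploid effective sizes; times are in generations
#' before present. `NAnc` is the ancestral size (demes A/B default it to
#' `N1`, the ancestral-range deme). Migration rates are backward
#' per-lineage per-generation rates: `m12` moves a deme-1 lineage into
#' deme 2 (i.e. forward migration 2 to 1), `m21` the reverse.
#'
#' @slot N1,N2 current sizes of deme 1 (large ancestral-range variety) and
#'   deme 2 (derived/peripheral variety).
#' @slot N1b pre-expansion size of deme 1 (B/D families).
#' @slot N2f founder or bottleneck size of deme 2.
#' @slot NAnc ancestral population size (older than `t3`).
#' @slot t0 deme-1 expansion time; also the end of the "recent" migration
#'   window.
#' @slot t1 deme-2 recovery time.
#' @slot t2 deme-2 bottleneck-onset time (C/D families only; NA otherwise).
#' @slot t3 divergence time.
#' @slot m12,m21 epoch-restricted migration rates (which epochs are active
#'   is set by the scenario code suffix).
#'
#' @exportClass ScenarioParams
setClass("ScenarioParams",
  representation(
    N1 = "numeric", N2 = "numeric", N1b = "numeric", N2f = "numeric",
    NAnc = "numeric", t0 = "numeric", t1 = "numeric", t2 = "numeric",
    t3 = "numeric", m12 = "numeric", m21 = "numeric"
  ),
  prototype(t2 = NA_real_, m12 = 0, m21 = 0)
)

setValidity("ScenarioParams", function(object) {
  msg <- character()
  sizes <- c(N1 = object@N1, N2 = object@N2, N1b = object@N1b,
             N2f = object@N2f, NAnc = object@NAnc)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    msg <- c(msg, "all population sizes must be finite and > 0")
  if (!is.finite(object@t3) || object@t3 <= 0) msg <- c(msg, "t3 must be > 0")
  if (!is.finite(object@t0) || object@t0 <= 0 || object@t0 >= object@t3)
    msg <- c(msg, "need 0 < t0 < t3")
  if (!is.finite(object@t1) || object@t1 <= 0 || object@t1 >= object@t3)
    msg <- c(msg, "need 0 < t1 < t3")
  if (!is.na(object@t2) &&
      (object@t2 < object@t1 || object@t2 >= object@t3))
    msg <- c(msg, "need t1 <= t2 < t3")
  if (object@m12 < 0 || object@m21 < 0)
    msg <- c(msg, "migration rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DemographicScenario: an instantiated scenario code A1--D5
#'
#' @slot code scenario code, family letter A--D plus migration suffix 1--5.
#' @slot mode speciation-mode tag: peripatric (A1, A3, B1, B3), vicariant
#'   (C1, C3, D1, D3), parapatric (A2, A4, B2, B4) or complex.
#' @slot params a [ScenarioParams].
#' @slot events data.frame of backward-time events (time, event), sorted by
#'   time.
#' @slot migrationWindows numeric matrix with columns `start`, `end`
#'   (generations) during which migration is active; zero rows for
#'   suffix-1 codes.
#'
#' @exportClass DemographicScenario
setClass("DemographicScenario",
  representation(
    code = "character",
    mode = "character",
    params = "ScenarioParams",
    events = "data.frame",
    migrationWindows = "matrix"
  )
)

#' JointSFS: two-population joint site frequency spectrum
#'
#' @slot M numeric matrix, entry (i+1, j+1) for derived-allele count i in
#'   population 1 (0..n1) and j in population 2 (0..n2).
#' @slot mode `"counts"` (observed SNP counts) or `"probabilities"`
#'   (normalized over polymorphic entries).
#'
#' @exportClass JointSFS
setClass("JointSFS",
  representation(M = "matrix", mode = "character")
)

setValidity("JointSFS", function(object) {
  msg <- character()
  if (!object@mode %in% c("counts", "probabilities"))
    msg <- c(msg, "mode must be 'counts' or 'probabilities'")
  if (any(object@M < 0)) msg <- c(msg, "entries must be >= 0")
  if (object@mode == "probabilities") {
    s <- sumPolymorphic(object@M)
    if (abs(s - 1) > 1e-6)
      msg <- c(msg, "probabilities must sum to 1 over polymorphic entries")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceTable: simulated (scenario, parameters, statistics) records
#'
#' The simulated training table for ABC rejection and regression, plus the
#' median/MAD standardization constants of each summary statistic.
#'
#' @slot scenario character, scenario code per row.
#' @slot params data.frame of drawn parameters per row.
#' @slot stats numeric matrix of summary statistics per row.
#' @slot center,scale named numeric standardization constants (median and
#'   MAD per statistic).
#' @slot config the simulation settings (priors, locus table, sample
#'   sizes) the table was built with, so pseudo-observed datasets can be
#'   drawn under identical conditions.
#'
#' @exportClass ReferenceTable
setClass("ReferenceTable",
  representation(
    scenario = "character",
    params = "data.frame",
    stats = "matrix",
    center = "numeric",
    scale = "numeric",
    config = "list"
  )
)

setValidity("ReferenceTable", function(object) {
  msg <- character()
  if (length(object@scenario) != nrow(object@stats))
    msg <- c(msg, "scenario labels and stats rows differ in length")
  if (anyNA(object@stats)) msg <- c(msg, "missing values in statistics")
  if (any(table(object@scenario) < 1)) msg <- c(msg, "empty scenario")
  if (length(msg)) msg else TRUE
})

# -- show methods -------------------------------------------------------

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment '%s': %d haplotypes x %d bp (%d outgroup)\n",
              object@locusId, length(object@seqs),
              if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0L,
              length(object@outgroup)))
})

setMethod("show", "StudyDataset", function(object) {
  cat(sprintf("StudyDataset: %d nuclear loci, cpDNA %s, %d samples, %d populations\n",
              length(object@nuclearLoci),
              if (is.null(object@cpdna)) "absent" else "present",
              nrow(object@popmap), length(unique(object@popmap$population))))
})

setMethod("show", "DemographicScenario", function(object) {
  cat(sprintf("DemographicScenario %s (%s)\n", object@code, object@mode))
  cat("events (backward time, generations):\n")
  print(object@events, row.names = FALSE)
  if (nrow(object@migrationWindows) > 0) {
    cat("migration windows:\n")
    print(object@migrationWindows)
  }
})

setMethod("show", "JointSFS", function(object) {
  cat(sprintf("JointSFS (%s): %d x %d (n1 = %d, n2 = %d haplotypes), total %g\n",
              object@mode, nrow(object@M), ncol(object@M),
              nrow(object@M) - 1L, ncol(object@M) - 1L, sum(object@M)))
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d rows, %d statistics, scenarios: %s\n",
              nrow(object@stats), ncol(object@stats),
              paste(sprintf("%s (%d)", names(table(object@scenario)),
                            table(object@scenario)), collapse = ", ")))
})

# -- accessors ----------------------------------------------------------

#' @describeIn LocusAlignment-class locus identifier
#' @param x,object a `LocusAlignment`
#' @export
locusId <- function(x) x@locusId

#' @describeIn LocusAlignment-class haplotype sequences as DNAStringSet
#' @export
haplotypes <- function(x) x@seqs

#' @describeIn LocusAlignment-class sample ids (one per haplotype)
#' @export
sampleIds <- function(x) x@sampleId

#' @describeIn LocusAlignment-class outgroup sequences
#' @export
outgroup <- function(x) x@outgroup

#' @describeIn LocusAlignment-class alignment length in sites
#' @export
lengthBp <- function(x) {
  if (length(x@seqs) == 0L) 0L else Biostrings::width(x@seqs)[1]
}

#' Number of haplotype sequences in an alignment
#' @param x a `LocusAlignment`
#' @export
setMethod("length", "LocusAlignment", function(x) length(x@seqs))

# sum of a JSFS matrix over polymorphic entries (drops (0,0) and (n1,n2))
sumPolymorphic <- function(M) {
  sum(M) - M[1, 1] - M[nrow(M), ncol(M)]
}
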
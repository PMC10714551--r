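#' Construct a LocusAlignment
#'
#' @param locusId locus identifier.
#' @param seqs character vector or [Biostrings::DNAStringSet] of aligned,
#'   equal-length haplotype sequences.
#' @param sampleId sample id per haplotype; defaults to sequence names or
#'   `h1..hn`.
#' @param haplotypeIndex integer haplotype index within sample; defaults to
#'   a running index within each sample.
#' @param outgroup optional character vector/DNAStringSet of aligned
#'   outgroup sequences.
#' @return a [LocusAlignment-class] object.
#' @export
newLocusAlignment <- function(locusId, seqs, sampleId = NULL,
                              haplotypeIndex = NULL, outgroup = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (is.null(sampleId)) {
    sampleId <- names(seqs) %||% paste0("h", seq_along(seqs))
    if (is.null(names(seqs))) names(seqs) <- sampleId
  }
  if (is.null(haplotypeIndex)) {
    haplotypeIndex <- stats::ave(seq_along(sampleId), sampleId,
                                 FUN = seq_along)
  }
  if (is.null(outgroup)) outgroup <- Biostrings::DNAStringSet()
  if (is.character(outgroup)) outgroup <- Biostrings::DNAStringSet(toupper(outgroup))
  new("LocusAlignment", locusId = as.character(locusId), seqs = seqs,
      sampleId = as.character(sampleId),
      haplotypeIndex = as.integer(haplotypeIndex), outgroup = outgroup)
}

#' Read a FASTA alignment into a LocusAlignment
#'
#' Record names of the form `sample_2` are split into sample id `sample`
#' and haplotype index 2; names without a trailing `_<number>` get a
#' running haplotype index within each sample. Sequences are uppercased and
#' validated (equal lengths, alphabet A/C/G/T/-/N, unique ids).
#'
#' @param path path to a FASTA file.
#' @param locusId locus identifier; defaults to the file name without
#'   extension.
#' @param format only `"fasta"` is supported.
#' @return a [LocusAlignment-class].
#' @export
readAlignment <- function(path, locusId = NULL, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e) stop("FASTA parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA parse error: no records in ", path)
  if (length(unique(Biostrings::width(seqs))) > 1L)
    stop("alignment error: unequal sequence lengths in ", path)
  if (anyDuplicated(names(seqs)))
    stop("validation error: duplicate sequence ids in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (is.null(locusId)) locusId <- sub("\\.[^.]*$", "", basename(path))
  nm <- names(seqs)
  hasIdx <- grepl("_[0-9]+$", nm)
  sampleId <- ifelse(hasIdx, sub("_[0-9]+$", "", nm), nm)
  hapIdx <- ifelse(hasIdx, as.integer(sub("^.*_([0-9]+)$", "\\1", nm)), NA)
  if (anyNA(hapIdx)) {
    hapIdx <- stats::ave(seq_along(sampleId), sampleId, FUN = seq_along)
  }
  newLocusAlignment(locusId, seqs, sampleId, as.integer(hapIdx))
}

#' Write a LocusAlignment to FASTA
#'
#' Record names are `sample_<haplotypeIndex>`; outgroup records (if any)
#' are appended with names `outgroup_<i>`.
#'
#' @param aln a [LocusAlignment-class].
#' @param path output file path.
#' @param withOutgroup append outgroup records.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path, withOutgroup = FALSE) {
  seqs <- aln@seqs
  names(seqs) <- paste(aln@sampleId, aln@haplotypeIndex, sep = "_")
  if (withOutgroup && length(aln@outgroup) > 0L) {
    og <- aln@outgroup
    names(og) <- paste0("outgroup_", seq_along(og))
    seqs <- c(seqs, og)
  }
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Remove alignment columns containing gaps
#'
#' Columns containing `-` in any ingroup (or, if present, outgroup)
#' sequence are excluded from nucleotide analyses, matching the treatment
#' of indels as non-substitution events. The unmasked original should be
#' kept where haplotypes are counted with indels coded as single events
#' (see `collapseGaps`).
#'
#' @param aln a [LocusAlignment-class].
#' @param collapseGaps if TRUE, each maximal run of gap columns is
#'   re-coded as one binary presence/absence character (appended as a
#'   single pseudo-site column with alleles A/T) so that a contiguous
#'   indel counts as one event in haplotype analyses.
#' @return list with elements `alignment` (masked [LocusAlignment-class])
#'   and `nRemoved` (number of columns removed).
#' @export
maskIndelColumns <- function(aln, collapseGaps = FALSE) {
  m <- alnMatrix(aln)
  ogm <- outgroupMatrix(aln)
  gapCol <- apply(m == "-", 2, any)
  if (!is.null(ogm)) gapCol <- gapCol | apply(ogm == "-", 2, any)
  nRemoved <- sum(gapCol)
  keep <- !gapCol
  m2 <- m[, keep, drop = FALSE]
  ogm2 <- if (!is.null(ogm)) ogm[, keep, drop = FALSE] else NULL
  if (collapseGaps && nRemoved > 0L) {
    runs <- rle(gapCol)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      block <- m[, starts[r]:ends[r], drop = FALSE]
      present <- ifelse(apply(block == "-", 1, all), "T", "A")
      m2 <- cbind(m2, present)
    }
  }
  seqs <- Biostrings::DNAStringSet(apply(m2, 1, paste, collapse = ""))
  names(seqs) <- paste(aln@sampleId, aln@haplotypeIndex, sep = "_")
  ogSet <- if (!is.null(ogm2))
    Biostrings::DNAStringSet(apply(ogm2, 1, paste, collapse = ""))
  else Biostrings::DNAStringSet()
  out <- new("LocusAlignment", locusId = aln@locusId, seqs = seqs,
             sampleId = aln@sampleId, haplotypeIndex = aln@haplotypeIndex,
             outgroup = ogSet)
  list(alignment = out, nRemoved = as.integer(nRemoved))
}

#' Concatenate loci sharing the same samples into one alignment
#'
#' Used to join organellar regions (e.g. two chloroplast spacers) into a
#' single haploid locus. All inputs must cover exactly the same
#' (sample, haplotype) set; per-sample order of the first input is kept.
#'
#' @param alns list of [LocusAlignment-class].
#' @param locusId identifier for the concatenated locus.
#' @return a [LocusAlignment-class] of width equal to the summed widths.
#' @export
concatenateLoci <- function(alns, locusId = "concatenated") {
  stopifnot(length(alns) >= 1L)
  if (length(alns) == 1L) return(alns[[1]])
  ref <- alns[[1]]
  key <- function(a) paste(a@sampleId, a@haplotypeIndex)
  refKey <- key(ref)
  seqMat <- lapply(alns, function(a) {
    if (!setequal(key(a), refKey))
      stop("sample mismatch between loci ", ref@locusId, " and ", a@locusId)
    as.character(a@seqs)[match(refKey, key(a))]
  })
  joined <- do.call(paste0, seqMat)
  og <- if (all(vapply(alns, function(a) length(a@outgroup), 1L) ==
               length(ref@outgroup)) && length(ref@outgroup) > 0L) {
    Biostrings::DNAStringSet(do.call(paste0, lapply(alns, function(a)
      as.character(a@outgroup))))
  } else Biostrings::DNAStringSet()
  newLocusAlignment(locusId, joined, ref@sampleId, ref@haplotypeIndex,
                    outgroup = og)
}

#' Read a sample-to-population map
#'
#' Expects a two-column TSV `sample_id<TAB>population` (no header).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id`, `population`.
#' @export
readPopMap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample_id", "population"),
                   colClasses = "character")
  if (anyDuplicated(pm$sample_id)) stop("duplicate sample ids in popmap")
  pm
}

#' Write a population map TSV
#' @param popmap data.frame with columns `sample_id`, `population`.
#' @param path output path.
#' @export
writePopMap <- function(popmap, path) {
  write.table(popmap[, c("sample_id", "population")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a StudyDataset
#'
#' @param nuclearLoci list of [LocusAlignment-class] (phased diploid).
#' @param popmap data.frame `sample_id`, `population`.
#' @param cpdna optional haploid [LocusAlignment-class].
#' @param cpdnaPloidy ploidy factor for the organellar locus relative to
#'   nuclear diploid (default 0.5).
#' @return a [StudyDataset-class].
#' @export
newStudyDataset <- function(nuclearLoci, popmap, cpdna = NULL,
                            cpdnaPloidy = 0.5) {
  ploidy <- setNames(rep(1, length(nuclearLoci)),
                     vapply(nuclearLoci, locusId, ""))
  if (!is.null(cpdna)) ploidy[locusId(cpdna)] <- cpdnaPloidy
  new("StudyDataset", nuclearLoci = nuclearLoci, cpdna = cpdna,
      popmap = popmap, ploidy = ploidy)
}

#' Validate a StudyDataset
#'
#' Checks ploidy (nuclear haplotypes = 2 x mapped individuals per locus,
#' cpDNA haplotypes = mapped individuals), that every aligned sample is in
#' the population map, and that exactly two populations are present for
#' two-deme analyses. Returns a report rather than raising; the dataset is
#' valid iff the report is empty.
#'
#' @param ds a [StudyDataset-class].
#' @return character vector of violations (empty if valid).
#' @export
validateDataset <- function(ds) {
  report <- character()
  pops <- unique(ds@popmap$population)
  if (length(pops) != 2L)
    report <- c(report, sprintf("expected 2 populations, found %d", length(pops)))
  mapped <- ds@popmap$sample_id
  for (aln in ds@nuclearLoci) {
    un <- setdiff(unique(aln@sampleId), mapped)
    if (length(un) > 0L)
      report <- c(report, sprintf("locus %s: unmapped samples: %s",
                                  aln@locusId, paste(un, collapse = ", ")))
    tab <- table(aln@sampleId)
    if (any(tab != 2L))
      report <- c(report, sprintf(
        "locus %s: ploidy violation, samples without 2 haplotypes: %s",
        aln@locusId, paste(names(tab)[tab != 2L], collapse = ", ")))
  }
  if (!is.null(ds@cpdna)) {
    aln <- ds@cpdna
    un <- setdiff(unique(aln@sampleId), mapped)
    if (length(un) > 0L)
      report <- c(report, sprintf("cpDNA: unmapped samples: %s",
                                  paste(un, collapse = ", ")))
    if (any(table(aln@sampleId) != 1L))
      report <- c(report, "cpDNA: ploidy violation, expected 1 haplotype per sample")
  }
  report
}

# character matrix view of the haplotype sequences (rows = haplotypes)
alnMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln@seqs), ""))
  rownames(m) <- paste(aln@sampleId, aln@haplotypeIndex, sep = "_")
  m
}

# outgroup character matrix or NULL
outgroupMatrix <- function(aln) {
  if (length(aln@outgroup) == 0L) return(NULL)
  do.call(rbind, strsplit(as.character(aln@outgroup), ""))
}
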
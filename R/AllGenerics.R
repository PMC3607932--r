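#' Total fluorescence of a peak profile
#'
#' The total fluorescence of a profile is the sum of its peak heights. It is
#' a proxy for the amount of DNA loaded on the capillary gel and is used as
#' a replicate quality-control gate and as the denominator of relative
#' abundances.
#'
#' @param x A [TRFProfile-class] or [ConsensusProfile-class].
#' @return A single number (fluorescence units).
#' @examples
#' p <- trfProfile("S1", "AluI", "1",
#'                 data.frame(size = c(100, 200), height = c(60, 70),
#'                            area = c(60, 70)))
#' totalFluorescence(p)  # 130
#' @export
setGeneric("totalFluorescence", function(x) standardGeneric("totalFluorescence"))

#' @rdname totalFluorescence
#' @export
setMethod("totalFluorescence", "TRFProfile",
          function(x) sum(x@peaks$height))

#' @rdname totalFluorescence
#' @export
setMethod("totalFluorescence", "ConsensusProfile",
          function(x) sum(x@bins$height))

#' Peak table of a profile
#'
#' @param x A [TRFProfile-class].
#' @return The `data.frame` of peaks (`size`, `height`, `area`).
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname peaks
#' @export
setMethod("peaks", "TRFProfile", function(x) x@peaks)

#' Consensus profile bins
#'
#' @param x A [ConsensusProfile-class].
#' @return The `data.frame` of bins (`bin_size`, `height`, `area`,
#'   `rel_abundance`).
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' @rdname profileBins
#' @export
setMethod("profileBins", "ConsensusProfile", function(x) x@bins)

#' OTU membership and abundances of a partition
#'
#' `otuMembership()` returns the named integer vector mapping each sequence
#' to its OTU; `otuAbundances()` returns per-OTU clone counts sorted by OTU
#' number.
#'
#' @param x An [OTUPartition-class].
#' @return An integer vector.
#' @export
setGeneric("otuMembership", function(x) standardGeneric("otuMembership"))

#' @rdname otuMembership
#' @export
setMethod("otuMembership", "OTUPartition", function(x) x@membership)

#' @rdname otuMembership
#' @export
setGeneric("otuAbundances", function(x) standardGeneric("otuAbundances"))

#' @rdname otuMembership
#' @export
setMethod("otuAbundances", "OTUPartition", function(x) {
  tab <- table(x@membership)
  setNames(as.integer(tab), names(tab))
})

#' Relative-abundance matrix and dates of a profile series
#'
#' @param x A [ProfileSeries-class].
#' @return For `abundanceMatrix()`, the bins x dates matrix of relative
#'   abundances (rownames are bin sizes); for `seriesDates()`, the sampling
#'   dates.
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @rdname abundanceMatrix
#' @export
setMethod("abundanceMatrix", "ProfileSeries", function(x) {
  m <- x@abundance
  dimnames(m) <- list(format(x@binSizes, trim = TRUE),
                      as.character(x@dates))
  m
})

#' @rdname abundanceMatrix
#' @export
setGeneric("seriesDates", function(x) standardGeneric("seriesDates"))

#' @rdname abundanceMatrix
#' @export
setMethod("seriesDates", "ProfileSeries", function(x) x@dates)

#' Ground-truth TRF lengths of a reference community
#'
#' @param x A [ReferenceCommunity-class].
#' @return The taxa `data.frame` with taxon ids, names and `trf_<enzyme>`
#'   columns holding true fragment lengths.
#' @export
setGeneric("referenceTaxa", function(x) standardGeneric("referenceTaxa"))

#' @rdname referenceTaxa
#' @export
setMethod("referenceTaxa", "ReferenceCommunity", function(x) x@taxa)

setMethod("show", "ReferenceCommunity", function(object) {
  cat(sprintf("ReferenceCommunity with %d taxa\n", nrow(object@taxa)))
  enz <- grep("^trf_", names(object@taxa), value = TRUE)
  cat("  enzymes:", paste(sub("^trf_", "", enz), collapse = ", "), "\n")
  cat("  sequence widths:",
      paste(range(Biostrings::width(object@sequences)), collapse = "-"), "\n")
})

setMethod("show", "CommunityScenario", function(object) {
  cat(sprintf(
    "CommunityScenario: %d taxa, drift %g bases, noiseSd %g, %d replicates (seed %d)\n",
    nrow(object@reference@taxa), object@drift, object@noiseSd,
    object@nReplicates, object@seed))
})

setMethod("show", "TRFProfile", function(object) {
  cat(sprintf("TRFProfile %s / %s / replicate %s: %d peaks, TF = %.1f FU\n",
              object@sampleId, object@enzyme, object@replicateId,
              nrow(object@peaks), totalFluorescence(object)))
})

setMethod("show", "BinnedProfileSet", function(object) {
  cat(sprintf("BinnedProfileSet (%s): %d bins x %d profiles\n",
              object@enzyme, length(object@binCenters),
              length(object@sampleIds)))
})

setMethod("show", "ConsensusProfile", function(object) {
  cat(sprintf("ConsensusProfile %s / %s: %d bins, TF = %.1f FU\n",
              object@sampleId, object@enzyme, nrow(object@bins),
              totalFluorescence(object)))
  if (nrow(object@bins)) {
    print(head(object@bins, 5L), row.names = FALSE)
    if (nrow(object@bins) > 5L) cat("  ...\n")
  }
})

setMethod("show", "ProfileSeries", function(object) {
  cat(sprintf("ProfileSeries (%s): %d TRF bins x %d dates (%s to %s)\n",
              object@enzyme, length(object@binSizes), length(object@dates),
              min(object@dates), max(object@dates)))
})

setMethod("show", "OTUPartition", function(object) {
  ab <- otuAbundances(object)
  cat(sprintf("OTUPartition at %.1f%% similarity: %d sequences in %d OTUs\n",
              100 * object@threshold, length(object@membership), length(ab)))
})

setMethod("show", "LabelImageSet", function(object) {
  d <- dim(object@channels$EUB)
  cat(sprintf("LabelImageSet %s: %d x %d pixels, channels EUB/ARC915/MX825\n",
              object@imageId, d[1], d[2]))
})
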
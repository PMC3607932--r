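#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAString DNAStringSet matchPattern width
#'   readDNAStringSet writeXStringSet
#' @importFrom BiocGenerics start
#' @importFrom stats approx cor median pt rnorm rpois runif sd setNames
#'   as.dist cutree hclust rmultinom complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' Reference community of taxa with known terminal restriction fragments
#'
#' Container for a set of reference 16S rRNA gene sequences, each carrying
#' the forward-primer site and a known (self-consistent) terminal
#' restriction fragment (TRF) length per restriction enzyme. It stands in
#' for a curated digest database: every downstream prediction on these
#' sequences can be checked against the recorded ground truth.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of reference sequences,
#'   named by taxon identifier.
#' @slot taxa A `data.frame` with columns `taxon_id`, `name` and one
#'   `trf_<enzyme>` column per enzyme holding the true labeled-fragment
#'   length in bases.
#'
#' @seealso [makeReferenceTaxa()], [digestDatabase()]
#' @export
setClass("ReferenceCommunity",
  slots = c(sequences = "DNAStringSet", taxa = "data.frame"),
  validity = function(object) {
    msg <- character()
    ids <- object@taxa$taxon_id
    if (is.null(ids) || anyDuplicated(ids)) {
      msg <- c(msg, "taxon_id must be present and unique")
    }
    if (length(object@sequences) != nrow(object@taxa)) {
      msg <- c(msg, "one sequence per taxon required")
    }
    if (!identical(names(object@sequences), as.character(ids))) {
      msg <- c(msg, "sequence names must equal taxa$taxon_id")
    }
    if (length(object@sequences) && any(Biostrings::width(object@sequences) < 200L)) {
      msg <- c(msg, "all sequences must be at least 200 bases long")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Simulation scenario for a T-RFLP community fingerprinting experiment
#'
#' Bundles a reference community with the ground-truth relative abundances
#' and the observation model used to render replicate electropherograms:
#' a size-calling drift (observed fragments run shorter than predicted),
#' multiplicative peak-height noise and a replicate count.
#'
#' @slot reference A [ReferenceCommunity-class].
#' @slot weights Non-negative per-taxon proportions summing to 1.
#' @slot drift Integer number of bases subtracted from the true TRF length
#'   when rendering observed peaks (predicted minus observed size).
#' @slot noiseSd Relative standard deviation of peak-height noise.
#' @slot nReplicates Number of replicate profiles per enzyme.
#' @slot seed Integer seed making the scenario fully reproducible.
#'
#' @seealso [communityScenario()], [renderElectropherograms()]
#' @export
setClass("CommunityScenario",
  slots = c(reference = "ReferenceCommunity", weights = "numeric",
            drift = "numeric", noiseSd = "numeric",
            nReplicates = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    w <- object@weights
    if (length(w) != nrow(object@reference@taxa)) {
      msg <- c(msg, "one weight per reference taxon required")
    }
    if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
    if (abs(sum(w) - 1) > 1e-9) msg <- c(msg, "weights must sum to 1 (tol 1e-9)")
    if (object@drift < 0) msg <- c(msg, "drift must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' One replicate T-RFLP peak profile
#'
#' A single replicate's list of detected electrophoresis peaks for one
#' sample and one restriction enzyme, as exported by fragment-analysis
#' software: fragment size in bases (fractional, from size calling), peak
#' height and peak area in fluorescence units.
#'
#' @slot sampleId Sample identifier.
#' @slot enzyme Restriction enzyme name.
#' @slot replicateId Replicate identifier.
#' @slot peaks A `data.frame` with numeric columns `size`, `height`, `area`.
#'
#' @seealso [trfProfile()], [filterPeaks()], [totalFluorescence()]
#' @export
setClass("TRFProfile",
  slots = c(sampleId = "character", enzyme = "character",
            replicateId = "character", peaks = "data.frame"),
  validity = function(object) {
    p <- object@peaks
    msg <- character()
    if (!all(c("size", "height", "area") %in% names(p))) {
      msg <- c(msg, "peaks must have columns size, height, area")
    } else {
      if (nrow(p) && any(p$height <= 0)) msg <- c(msg, "peak heights must be > 0")
      if (nrow(p) && any(p$size <= 0)) msg <- c(msg, "peak sizes must be > 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Peak profiles mapped onto a shared set of size bins
#'
#' Result of moving-average alignment of several peak profiles: a common
#' ordered set of fragment-size bins, and per profile the summed height and
#' area plus the height-weighted mean size within each bin (`NA` size and
#' zero height where a profile has no peak in a bin).
#'
#' @slot enzyme Restriction enzyme name.
#' @slot binCenters Ordered bin centers (mean pooled size per bin).
#' @slot size,height,area Numeric matrices, bins x profiles.
#' @slot sampleIds,replicateIds Per-profile identifiers.
#'
#' @seealso [alignPeaks()], [consensusProfile()]
#' @export
setClass("BinnedProfileSet",
  slots = c(enzyme = "character", binCenters = "numeric",
            size = "matrix", height = "matrix", area = "matrix",
            sampleIds = "character", replicateIds = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@binCenters)
    k <- length(object@sampleIds)
    for (s in c("size", "height", "area")) {
      m <- slot(object, s)
      if (!identical(dim(m), c(n, k))) {
        msg <- c(msg, sprintf("%s matrix must be bins x profiles", s))
      }
    }
    if (is.unsorted(object@binCenters)) msg <- c(msg, "binCenters must be sorted")
    if (length(object@replicateIds) != k) {
      msg <- c(msg, "replicateIds must match sampleIds in length")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Consensus T-RFLP profile of a replicate pair
#'
#' The per-sample, per-enzyme consensus fingerprint: only fragments present
#' in both replicates are kept, with size, height and area averaged and
#' heights converted to relative abundances.
#'
#' @slot sampleId Sample identifier.
#' @slot enzyme Restriction enzyme name.
#' @slot bins A `data.frame` with columns `bin_size`, `height`, `area`,
#'   `rel_abundance`, sorted by `bin_size`. Zero rows mark an empty
#'   consensus (no fragment shared by both replicates).
#'
#' @seealso [consensusProfile()], [runPipeline()]
#' @export
setClass("ConsensusProfile",
  slots = c(sampleId = "character", enzyme = "character", bins = "data.frame"),
  validity = function(object) {
    b <- object@bins
    msg <- character()
    need <- c("bin_size", "height", "area", "rel_abundance")
    if (!all(need %in% names(b))) {
      msg <- c(msg, "bins must have columns bin_size, height, area, rel_abundance")
    } else if (nrow(b)) {
      if (abs(sum(b$rel_abundance) - 1) > 1e-9) {
        msg <- c(msg, "relative abundances must sum to 1 (tol 1e-9)")
      }
      if (is.unsorted(b$bin_size)) msg <- c(msg, "bins must be sorted by size")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Time series of consensus fingerprints on a shared bin map
#'
#' Chronologically ordered consensus profiles of one enzyme, re-aligned to
#' a common set of fragment-size bins with relative abundances per date
#' (columns sum to 1; a fragment absent from a profile has abundance 0).
#'
#' @slot enzyme Restriction enzyme name.
#' @slot dates Strictly increasing sampling dates.
#' @slot binSizes Shared fragment-size bin centers.
#' @slot abundance Numeric matrix, bins x dates, of relative abundances.
#'
#' @seealso [buildProfileSeries()], [distanceToBaseline()],
#'   [correlateParameters()]
#' @export
setClass("ProfileSeries",
  slots = c(enzyme = "character", dates = "Date", binSizes = "numeric",
            abundance = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dates) > 1L && any(diff(object@dates) <= 0)) {
      msg <- c(msg, "dates must be strictly increasing")
    }
    if (!identical(dim(object@abundance),
                   c(length(object@binSizes), length(object@dates)))) {
      msg <- c(msg, "abundance must be bins x dates")
    } else if (ncol(object@abundance) &&
               any(abs(colSums(object@abundance) - 1) > 1e-6)) {
      msg <- c(msg, "each profile's abundances must sum to 1")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Partition of sequences into OTUs at a similarity threshold
#'
#' Complete-linkage clustering of aligned sequences at a fractional
#' similarity threshold (e.g. 0.987 for the species level). OTU numbers
#' are assigned in order of each cluster's lexicographically smallest
#' member identifier.
#'
#' @slot threshold Similarity fraction in (0, 1].
#' @slot membership Named integer vector mapping sequence id to OTU number.
#'
#' @seealso [assignOTUs()], [otuAbundances()]
#' @export
setClass("OTUPartition",
  slots = c(threshold = "numeric", membership = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@threshold <= 0 || object@threshold > 1) {
      msg <- c(msg, "threshold must be in (0, 1]")
    }
    m <- object@membership
    if (is.null(names(m)) || anyDuplicated(names(m))) {
      msg <- c(msg, "membership must be named by unique sequence ids")
    }
    if (length(m) && !setequal(unique(m), seq_len(max(m)))) {
      msg <- c(msg, "OTU numbers must be 1..k with no gaps")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Three-channel labeled image set for FISH quantification
#'
#' Intensity rasters of one confocal field of view for the three probes
#' used to quantify Archaea in activated sludge: EUB (Bacteria), ARC915
#' (Archaea) and MX825 (Methanosaetaceae). All channels share dimensions.
#'
#' @slot imageId Image identifier.
#' @slot channels Named list of numeric matrices `EUB`, `ARC915`, `MX825`
#'   with non-negative intensities.
#'
#' @seealso [labelImageSet()], [quantifyImage()]
#' @export
setClass("LabelImageSet",
  slots = c(imageId = "character", channels = "list"),
  validity = function(object) {
    msg <- character()
    ch <- object@channels
    need <- c("EUB", "ARC915", "MX825")
    if (!all(need %in% names(ch))) {
      msg <- c(msg, "channels must be named EUB, ARC915, MX825")
    } else {
      dims <- lapply(ch[need], dim)
      if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
        msg <- c(msg, "all channels must have identical dimensions")
      }
      if (any(vapply(ch[need], function(m) any(m < 0), TRUE))) {
        msg <- c(msg, "intensities must be non-negative")
      }
    }
    if (length(msg)) msg else TRUE
  }
)
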
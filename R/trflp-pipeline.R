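# Raw-peak-to-consensus T-RFLP processing: detection filtering, replicate
# quality control, iterative fluorescence normalization, moving-average peak
# alignment and replicate consensus.

#' Construct a replicate peak profile
#'
#' @param sampleId,enzyme,replicateId Identifiers.
#' @param peaks `data.frame` with numeric columns `size`, `height`, `area`.
#' @return A [TRFProfile-class].
#' @export
trfProfile <- function(sampleId, enzyme, replicateId, peaks) {
  peaks <- as.data.frame(peaks)[, c("size", "height", "area")]
  rownames(peaks) <- NULL
  new("TRFProfile", sampleId = as.character(sampleId),
      enzyme = as.character(enzyme), replicateId = as.character(replicateId),
      peaks = peaks)
}

#' Filter peaks to the analyzable window
#'
#' Retains peaks from fragments of 50-1020 bases with a height strictly
#' above 50 fluorescence units; smaller fragments fall outside the sizing
#' range and lower peaks are indistinguishable from baseline noise. The
#' profile's total fluorescence changes accordingly.
#'
#' @param profile A [TRFProfile-class].
#' @param sizeRange Retained fragment-size window in bases (inclusive).
#' @param minHeight Detection threshold in FU; peaks with height
#'   `<= minHeight` are removed (strict).
#' @return The filtered [TRFProfile-class].
#' @examples
#' p <- trfProfile("S1", "AluI", "1",
#'   data.frame(size = c(40, 100, 200), height = c(500, 50, 60),
#'              area = c(500, 50, 60)))
#' peaks(filterPeaks(p))  # only the size-200 peak survives
#' @export
filterPeaks <- function(profile, sizeRange = c(50, 1020), minHeight = 50) {
  stopifnot(is(profile, "TRFProfile"))
  p <- profile@peaks
  keep <- p$size >= sizeRange[1L] & p$size <= sizeRange[2L] &
    p$height > minHeight
  profile@peaks <- p[keep, , drop = FALSE]
  rownames(profile@peaks) <- NULL
  profile
}

#' Select the replicate pair used for the consensus profile
#'
#' A sample x enzyme combination is analyzed only if at least two of its
#' replicate profiles have a total fluorescence above `minTF` (500 FU by
#' default); otherwise too little DNA was loaded and the sample is
#' rejected. Among eligible inputs the two profiles with the highest total
#' fluorescence are chosen; ties are broken by lower replicate id.
#'
#' @param replicates List of [TRFProfile-class] (1-3 replicates of one
#'   sample x enzyme).
#' @param minTF Total-fluorescence gate in FU (strictly above).
#' @return List with elements `selected` (list of two profiles, or `NULL`),
#'   `rejected` (logical) and `reason` (character).
#' @export
selectReplicates <- function(replicates, minTF = 500) {
  tf <- vapply(replicates, totalFluorescence, 0)
  eligible <- tf > minTF
  if (sum(eligible) < 2L) {
    return(list(selected = NULL, rejected = TRUE,
                reason = sprintf(
                  "only %d of %d replicates above %g FU total fluorescence",
                  sum(eligible), length(replicates), minTF)))
  }
  repIds <- vapply(replicates, function(p) p@replicateId, "")
  ord <- order(-tf, repIds)
  list(selected = replicates[ord[1:2]], rejected = FALSE, reason = "")
}

# Core iterative normalization on a list of peak data.frames
# (columns height, area, ...). Profiles are repeatedly scaled down to the
# smallest total fluorescence and peaks whose scaled height drops to or
# below `floor` are deleted, until a fixed point is reached. The removed
# fraction is the original height of deleted peaks over the original total
# fluorescence. Profiles losing all peaks are flagged empty and withdrawn
# from further iterations.
.dunbarNormalize <- function(peakList, floor = 50) {
  origTF <- vapply(peakList, function(p) sum(p$height), 0)
  removedH <- numeric(length(peakList))
  peakList <- lapply(peakList, function(p) {
    p$.orig_height <- p$height
    p
  })
  empty <- vapply(peakList, nrow, 0L) == 0L
  repeat {
    active <- which(!empty)
    if (length(active) == 0L) break
    tf <- vapply(peakList[active], function(p) sum(p$height), 0)
    m <- min(tf)
    deleted <- FALSE
    for (j in seq_along(active)) {
      i <- active[j]
      p <- peakList[[i]]
      sc <- m / tf[j]
      p$height <- p$height * sc
      p$area <- p$area * sc
      drop <- p$height <= floor
      if (any(drop)) {
        deleted <- TRUE
        removedH[i] <- removedH[i] + sum(p$.orig_height[drop])
        p <- p[!drop, , drop = FALSE]
      }
      peakList[[i]] <- p
      if (nrow(p) == 0L) empty[i] <- TRUE
    }
    if (!deleted) break
  }
  peakList <- lapply(peakList, function(p) {
    p$.orig_height <- NULL
    rownames(p) <- NULL
    p
  })
  list(peaks = peakList,
       removedFraction = ifelse(origTF > 0, removedH / origTF, 0),
       empty = empty)
}

#' Normalize peak profiles to a common DNA load
#'
#' Iterative profile normalization: (1) find the smallest total
#' fluorescence among the profiles; (2) scale every peak height and area of
#' each profile by (smallest TF / own TF); (3) delete peaks whose scaled
#' height falls to or below the detection floor; (4) recompute total
#' fluorescences; repeat until no peak is deleted. This equalizes the
#' effective amount of DNA behind each profile so that profiles become
#' comparable. The fraction of each profile's original total fluorescence
#' removed by deletions is reported.
#'
#' The comparison in step (3) uses `<= floor` because a scaled peak at
#' exactly the detection limit is indistinguishable from noise.
#'
#' @param profiles List of [TRFProfile-class].
#' @param floor Deletion floor in FU (default 50, the detection threshold).
#' @return List with elements `profiles` (normalized [TRFProfile-class]
#'   list), `removedFraction` (per profile, fraction of original total
#'   fluorescence removed) and `empty` (logical; profiles that lost all
#'   peaks and must be excluded downstream).
#' @examples
#' a <- trfProfile("S1", "AluI", "1",
#'                 data.frame(size = 100, height = 1000, area = 1000))
#' b <- trfProfile("S1", "AluI", "2",
#'                 data.frame(size = c(100, 300), height = c(1910, 90),
#'                            area = c(1910, 90)))
#' nm <- normalizeProfiles(list(a, b))
#' nm$removedFraction  # 0 and 0.045
#' @export
normalizeProfiles <- function(profiles, floor = 50) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, TRUE, "TRFProfile")))
  res <- .dunbarNormalize(lapply(profiles, function(p) p@peaks), floor = floor)
  out <- profiles
  for (i in seq_along(out)) out[[i]]@peaks <- res$peaks[[i]]
  list(profiles = out, removedFraction = res$removedFraction,
       empty = res$empty)
}

# Moving-average clustering of pooled peak sizes into bins: sizes are
# sorted ascending and a new bin starts whenever the next size exceeds the
# running mean of the current bin's members by more than `gap`; the running
# mean is updated as members join.
.movingAverageBins <- function(sizes, gap) {
  n <- length(sizes)
  bin <- integer(n)
  if (n == 0L) return(bin)
  ord <- order(sizes)
  b <- 1L
  runMean <- sizes[ord[1L]]
  count <- 1L
  bin[ord[1L]] <- 1L
  for (k in seq_len(n - 1L) + 1L) {
    s <- sizes[ord[k]]
    if (s - runMean > gap) {
      b <- b + 1L
      runMean <- s
      count <- 1L
    } else {
      count <- count + 1L
      runMean <- runMean + (s - runMean) / count
    }
    bin[ord[k]] <- b
  }
  bin
}

#' Align peak profiles on shared fragment-size bins
#'
#' Fragment sizes are size-called floats, so the same fragment is reported
#' with slightly different sizes across profiles. All peaks are pooled and
#' clustered by a moving-average procedure: sorted ascending, a new bin
#' opens when the gap from the running bin mean exceeds `gap` bases. Each
#' profile's peaks are then mapped to the shared bins; two peaks of one
#' profile falling in the same bin are summed (heights and areas) with the
#' height-weighted mean size.
#'
#' @param profiles List of [TRFProfile-class], or list of peak
#'   `data.frame`s (columns `size`, `height`, `area`).
#' @param gap Bin-opening gap in bases (default 1.0).
#' @param enzyme Enzyme label for the result (taken from the first
#'   `TRFProfile` if not given).
#' @return A [BinnedProfileSet-class].
#' @examples
#' a <- trfProfile("S1", "AluI", "1",
#'                 data.frame(size = 183.1, height = 600, area = 600))
#' b <- trfProfile("S1", "AluI", "2",
#'                 data.frame(size = 183.4, height = 550, area = 550))
#' alignPeaks(list(a, b))  # one shared bin near 183.25
#' @export
alignPeaks <- function(profiles, gap = 1.0, enzyme = NULL) {
  if (gap <= 0) stop("gap must be > 0", call. = FALSE)
  isS4prof <- vapply(profiles, is, TRUE, "TRFProfile")
  if (all(isS4prof)) {
    peakList <- lapply(profiles, function(p) p@peaks)
    sampleIds <- vapply(profiles, function(p) p@sampleId, "")
    replicateIds <- vapply(profiles, function(p) p@replicateId, "")
    if (is.null(enzyme)) enzyme <- profiles[[1L]]@enzyme
  } else {
    peakList <- lapply(profiles, as.data.frame)
    sampleIds <- names(profiles)
    if (is.null(sampleIds)) sampleIds <- sprintf("P%d", seq_along(profiles))
    replicateIds <- rep("", length(profiles))
    if (is.null(enzyme)) enzyme <- ""
  }
  k <- length(peakList)
  pooled <- do.call(rbind, lapply(seq_len(k), function(i) {
    p <- peakList[[i]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(size = p$size, height = p$height, area = p$area, profile = i)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    emptyM <- matrix(numeric(), 0L, k)
    return(new("BinnedProfileSet", enzyme = enzyme, binCenters = numeric(),
               size = emptyM, height = emptyM, area = emptyM,
               sampleIds = sampleIds, replicateIds = replicateIds))
  }
  pooled$bin <- .movingAverageBins(pooled$size, gap)
  nb <- max(pooled$bin)
  centers <- vapply(seq_len(nb),
                    function(b) mean(pooled$size[pooled$bin == b]), 0)
  sizeM <- matrix(NA_real_, nb, k)
  heightM <- matrix(0, nb, k)
  areaM <- matrix(0, nb, k)
  for (i in seq_len(k)) {
    sub <- pooled[pooled$profile == i, , drop = FALSE]
    for (b in unique(sub$bin)) {
      rows <- sub[sub$bin == b, , drop = FALSE]
      heightM[b, i] <- sum(rows$height)
      areaM[b, i] <- sum(rows$area)
      sizeM[b, i] <- sum(rows$size * rows$height) / sum(rows$height)
    }
  }
  new("BinnedProfileSet", enzyme = enzyme, binCenters = centers,
      size = sizeM, height = heightM, area = areaM,
      sampleIds = sampleIds, replicateIds = replicateIds)
}

#' Combine an aligned replicate pair into a consensus profile
#'
#' Keeps only the fragments present in both replicates; for each shared
#' bin the size, height and area are arithmetic means of the two
#' replicates' values, and the relative abundance of a fragment is its mean
#' height divided by the consensus total fluorescence.
#'
#' @param binned A [BinnedProfileSet-class] holding exactly two profiles.
#' @return A [ConsensusProfile-class]; zero bins if the replicates share no
#'   fragment (empty-consensus flag for quality control).
#' @export
consensusProfile <- function(binned) {
  stopifnot(is(binned, "BinnedProfileSet"))
  if (length(binned@sampleIds) != 2L) {
    stop("consensusProfile() expects an aligned replicate pair", call. = FALSE)
  }
  shared <- binned@height[, 1L] > 0 & binned@height[, 2L] > 0
  if (!any(shared)) {
    bins <- data.frame(bin_size = numeric(), height = numeric(),
                       area = numeric(), rel_abundance = numeric())
  } else {
    h <- rowMeans(binned@height[shared, , drop = FALSE])
    bins <- data.frame(
      bin_size = rowMeans(binned@size[shared, , drop = FALSE]),
      height = h,
      area = rowMeans(binned@area[shared, , drop = FALSE]),
      rel_abundance = h / sum(h))
    bins <- bins[order(bins$bin_size), , drop = FALSE]
    rownames(bins) <- NULL
  }
  new("ConsensusProfile", sampleId = binned@sampleIds[1L],
      enzyme = binned@enzyme, bins = bins)
}

#' Run the raw-peak-to-consensus fingerprint pipeline
#'
#' Orchestrates, per sample x enzyme: detection filtering
#' ([filterPeaks()]), replicate quality control ([selectReplicates()]),
#' normalization of the chosen replicate pair ([normalizeProfiles()]),
#' moving-average alignment ([alignPeaks()]) and consensus
#' ([consensusProfile()]). Consensus profiles with a total fluorescence
#' below `minConsensusFrac` times the median consensus total fluorescence
#' of their enzyme are excluded to avoid excessive normalization against
#' low-DNA profiles. A quality-control report accompanies the results.
#' The pipeline is deterministic and invariant to the row order of the
#' input table.
#'
#' @param peakTable A `data.frame` with columns `sample_id`, `enzyme`,
#'   `replicate`, `size_bases`, `height_fu`, `area`, or the path of such a
#'   CSV file (see [readPeakTable()]).
#' @param gap Alignment gap in bases.
#' @param floor Normalization deletion floor in FU.
#' @param minTF Replicate total-fluorescence gate in FU.
#' @param sizeRange,minHeight Detection filter, see [filterPeaks()].
#' @param minConsensusFrac Consensus profiles below this fraction of the
#'   per-enzyme median consensus total fluorescence are excluded.
#' @return List with `consensus` (list of retained
#'   [ConsensusProfile-class], named `sample/enzyme`) and `qc` (list with
#'   `nSamples`, `rejected`, `removedFraction`, `emptyConsensus`,
#'   `excludedLowTF`).
#' @examples
#' ref <- makeReferenceTaxa(2, seed = 1)
#' sc <- communityScenario(ref, c(0.7, 0.3), drift = 5, seed = 2)
#' tab <- peakTable(renderElectropherograms(sc))
#' res <- runPipeline(tab)
#' res$consensus[[1]]
#' @export
runPipeline <- function(peakTable, gap = 1.0, floor = 50, minTF = 500,
                        sizeRange = c(50, 1020), minHeight = 50,
                        minConsensusFrac = 0.25) {
  if (is.character(peakTable)) peakTable <- readPeakTable(peakTable)
  peakTable <- .validatePeakTable(peakTable)
  consensus <- list()
  rejected <- data.frame(sample_id = character(), enzyme = character(),
                         reason = character())
  removed <- data.frame(sample_id = character(), enzyme = character(),
                        replicate = character(), removed_fraction = numeric())
  emptyCons <- character()
  if (nrow(peakTable)) {
    keys <- unique(peakTable[, c("sample_id", "enzyme")])
    keys <- keys[order(keys$sample_id, keys$enzyme), , drop = FALSE]
    for (r in seq_len(nrow(keys))) {
      sid <- keys$sample_id[r]; enz <- keys$enzyme[r]
      sub <- peakTable[peakTable$sample_id == sid & peakTable$enzyme == enz, ,
                       drop = FALSE]
      reps <- sort(unique(sub$replicate))
      profs <- lapply(reps, function(rep) {
        pk <- sub[sub$replicate == rep, , drop = FALSE]
        filterPeaks(trfProfile(sid, enz, rep,
                               data.frame(size = pk$size_bases,
                                          height = pk$height_fu,
                                          area = pk$area)),
                    sizeRange = sizeRange, minHeight = minHeight)
      })
      sel <- selectReplicates(profs, minTF = minTF)
      if (sel$rejected) {
        rejected <- rbind(rejected,
                          data.frame(sample_id = sid, enzyme = enz,
                                     reason = sel$reason))
        next
      }
      nm <- normalizeProfiles(sel$selected, floor = floor)
      removed <- rbind(removed, data.frame(
        sample_id = sid, enzyme = enz,
        replicate = vapply(sel$selected, function(p) p@replicateId, ""),
        removed_fraction = nm$removedFraction))
      if (any(nm$empty)) {
        rejected <- rbind(rejected, data.frame(
          sample_id = sid, enzyme = enz,
          reason = "a replicate lost all peaks during normalization"))
        next
      }
      cons <- consensusProfile(alignPeaks(nm$profiles, gap = gap))
      key <- paste(sid, enz, sep = "/")
      if (nrow(cons@bins) == 0L) {
        emptyCons <- c(emptyCons, key)
        next
      }
      consensus[[key]] <- cons
    }
  }
  # exclude low-total-fluorescence consensus profiles per enzyme
  excluded <- character()
  if (length(consensus)) {
    enzOf <- vapply(consensus, function(x) x@enzyme, "")
    tf <- vapply(consensus, totalFluorescence, 0)
    keep <- rep(TRUE, length(consensus))
    for (enz in unique(enzOf)) {
      idx <- which(enzOf == enz)
      med <- median(tf[idx])
      low <- tf[idx] < minConsensusFrac * med
      keep[idx[low]] <- FALSE
    }
    excluded <- names(consensus)[!keep]
    consensus <- consensus[keep]
  }
  list(consensus = consensus,
       qc = list(nSamples = length(unique(peakTable$sample_id)),
                 rejected = rejected, removedFraction = removed,
                 emptyConsensus = emptyCons, excludedLowTF = excluded))
}
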
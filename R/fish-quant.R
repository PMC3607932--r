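# FISH area quantification from three-channel labeled masks: EUB
# (Bacteria), ARC915 (Archaea) and MX825 (Methanosaetaceae).

#' Construct a three-channel labeled image set
#'
#' @param imageId Image identifier.
#' @param eub,arc915,mx825 Intensity matrices of identical dimensions with
#'   non-negative values (8-bit intensities by convention).
#' @return A [LabelImageSet-class].
#' @export
labelImageSet <- function(imageId, eub, arc915, mx825) {
  new("LabelImageSet", imageId = as.character(imageId),
      channels = list(EUB = eub, ARC915 = arc915, MX825 = mx825))
}

#' Binarize an intensity channel
#'
#' A pixel is signal-positive iff its intensity is strictly above the
#' threshold; the default of 100 (on the 8-bit scale) removes background
#' noise.
#'
#' @param channel Intensity matrix.
#' @param threshold Intensity threshold (>= 0).
#' @return Logical mask of the same dimensions.
#' @examples
#' sum(binarize(matrix(c(0, 100, 101, 255), 2), 100))  # 2
#' @export
binarize <- function(channel, threshold = 100) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  channel > threshold
}

#' Quantify relative Archaea area in one image
#'
#' Each channel is binarized; pixels positive for EUB and for either
#' archaeal probe (double positives) are ambiguous and removed from all
#' masks. Because ARC915 does not cover all Methanosaetaceae cells, the
#' archaeal area is counted as ARC915-positive pixels plus MX825-positive
#' pixels not covered by ARC915 (so no pixel is counted twice); the
#' bacterial area is the remaining EUB-positive pixels. The relative
#' abundance of Archaea is the archaeal area over the combined archaeal
#' and bacterial area, in percent. Images whose combined area is below
#' `minArea` pixels (1000 by default) show dispersed cells rather than
#' flocs and are excluded (`rel_archaea = NA`, `excluded = TRUE`).
#'
#' @param images A [LabelImageSet-class].
#' @param threshold Intensity threshold passed to [binarize()].
#' @param minArea Minimum combined area in pixels for inclusion.
#' @return One-row `data.frame` with `image_id`, `area_bacteria`,
#'   `area_archaea`, `total_area`, `rel_archaea` (percent or `NA`) and
#'   `excluded`.
#' @examples
#' img <- simulateLabelImages(30, nSignal = 2000)
#' quantifyImage(img)
#' @export
quantifyImage <- function(images, threshold = 100, minArea = 1000) {
  stopifnot(is(images, "LabelImageSet"))
  validObject(images)
  E <- binarize(images@channels$EUB, threshold)
  A <- binarize(images@channels$ARC915, threshold)
  M <- binarize(images@channels$MX825, threshold)
  D <- E & (A | M)                      # ambiguous double positives
  areaArchaea <- sum(A & !D) + sum(M & !A & !D)
  areaBacteria <- sum(E & !D)
  totalArea <- areaBacteria + areaArchaea
  excluded <- totalArea < minArea
  data.frame(image_id = images@imageId,
             area_bacteria = areaBacteria,
             area_archaea = areaArchaea,
             total_area = totalArea,
             rel_archaea = if (excluded) NA_real_ else
               100 * areaArchaea / totalArea,
             excluded = excluded)
}

#' Summarize per-image Archaea percentages for a sample
#'
#' Arithmetic mean and sample standard deviation of the per-image relative
#' Archaea percentages over the non-excluded images of a sample (the
#' mean-of-images aggregation used for reporting; set `pooled = TRUE` for
#' the pooled-area ratio instead). The number of excluded images is always
#' reported alongside.
#'
#' @param quantifications `data.frame` of rows from [quantifyImage()]
#'   (or a list of such rows, which is row-bound).
#' @param pooled Aggregate as total archaeal area over total combined area
#'   instead of the mean of per-image percentages.
#' @return One-row `data.frame` with `mean_percent`, `sd_percent` (`NA`
#'   under `pooled`), `n_included`, `n_excluded`.
#' @export
summarizeFish <- function(quantifications, pooled = FALSE) {
  if (is.list(quantifications) && !is.data.frame(quantifications)) {
    quantifications <- do.call(rbind, quantifications)
  }
  inc <- quantifications[!quantifications$excluded, , drop = FALSE]
  if (nrow(inc) == 0L) {
    stop("all images were excluded; nothing to summarize", call. = FALSE)
  }
  if (pooled) {
    data.frame(mean_percent = 100 * sum(inc$area_archaea) /
                 sum(inc$total_area),
               sd_percent = NA_real_,
               n_included = nrow(inc),
               n_excluded = sum(quantifications$excluded))
  } else {
    data.frame(mean_percent = mean(inc$rel_archaea),
               sd_percent = if (nrow(inc) > 1L) sd(inc$rel_archaea) else 0,
               n_included = nrow(inc),
               n_excluded = sum(quantifications$excluded))
  }
}

#' Simulate a labeled image set with a planted Archaea fraction
#'
#' Builds a deterministic three-channel image in which signal pixels are
#' disjoint blocks of bacterial (EUB) and archaeal pixels; the archaeal
#' block is split between ARC915-only, ARC915-and-MX825 and MX825-only
#' pixels so that the single-counting rule is exercised. With `relArchaea`
#' percent planted and no noise, [quantifyImage()] recovers the fraction
#' exactly.
#'
#' @param relArchaea Planted relative Archaea area, percent.
#' @param dim Image dimensions (rows, columns).
#' @param nSignal Total number of signal pixels.
#' @param mxOnlyFrac,mxOverlapFrac Fractions of the archaeal pixels that
#'   are MX825-only and MX825-and-ARC915, respectively.
#' @param imageId Image identifier.
#' @param intensity Intensity given to signal pixels (above the default
#'   threshold of 100).
#' @return A [LabelImageSet-class].
#' @export
simulateLabelImages <- function(relArchaea, dim = c(64, 64),
                                nSignal = 2000, mxOnlyFrac = 0.2,
                                mxOverlapFrac = 0.2, imageId = "img1",
                                intensity = 200) {
  if (relArchaea < 0 || relArchaea > 100) {
    stop("relArchaea must be a percentage in [0, 100]", call. = FALSE)
  }
  npx <- prod(dim)
  nSignal <- min(nSignal, npx)
  nArch <- round(relArchaea / 100 * nSignal)
  nBact <- nSignal - nArch
  nMxOnly <- round(mxOnlyFrac * nArch)
  nMxBoth <- round(mxOverlapFrac * nArch)
  nArcOnly <- nArch - nMxOnly - nMxBoth
  eub <- arc <- mx <- matrix(0, dim[1L], dim[2L])
  idx <- seq_len(nSignal)
  bact <- idx[seq_len(nBact)]
  arch <- setdiff(idx, bact)
  eub[bact] <- intensity
  arcPix <- arch[seq_len(nArcOnly + nMxBoth)]
  arc[arcPix] <- intensity
  mxPix <- arch[nArcOnly + seq_len(nMxBoth + nMxOnly)]
  mx[mxPix] <- intensity
  labelImageSet(imageId, eub, arc, mx)
}
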
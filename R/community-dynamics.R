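# Community dynamics: Bray-Curtis distance to the baseline sample,
# dual-enzyme fragment identification against a digest database and
# Pearson correlations between fragment abundances and plant parameters.

#' Bray-Curtis distance between two abundance vectors
#'
#' \deqn{BC(p, q) = 100 \cdot \sum_i |p_i - q_i| / \sum_i (p_i + q_i)}
#' on vectors sharing a bin map: 0\% for identical profiles, 100\% for
#' profiles with disjoint support.
#'
#' @param p,q Non-negative abundance vectors of equal length.
#' @return Distance in percent.
#' @examples
#' brayCurtis(c(0.8, 0.2), c(0.6, 0.4))  # 20
#' @export
brayCurtis <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must share a bin map (equal length)", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  tot <- sum(p + q)
  if (tot == 0) stop("Bray-Curtis is undefined for two all-zero vectors",
                     call. = FALSE)
  100 * sum(abs(p - q)) / tot
}

#' Build a fingerprint time series on a shared bin map
#'
#' Aligns the consensus profiles of one enzyme across sampling dates
#' (moving-average binning, as within samples) and, by default, applies the
#' same iterative normalization across the whole series before computing
#' relative abundances, so all profiles reflect a common effective DNA
#' load. Fragments absent from a profile get abundance 0.
#'
#' @param consensus List of [ConsensusProfile-class], all of one enzyme.
#' @param dates Sampling dates (`Date` or coercible), one per profile.
#' @param gap Alignment gap in bases.
#' @param floor Normalization deletion floor in FU.
#' @param normalize Apply series-level normalization (default `TRUE`).
#' @return A [ProfileSeries-class]; the per-profile fraction of
#'   fluorescence removed by the series-level normalization is attached as
#'   attribute `removedFraction`.
#' @export
buildProfileSeries <- function(consensus, dates, gap = 1.0, floor = 50,
                               normalize = TRUE) {
  stopifnot(length(consensus) >= 1L,
            all(vapply(consensus, is, TRUE, "ConsensusProfile")))
  if (length(dates) != length(consensus)) {
    stop("one date per consensus profile required", call. = FALSE)
  }
  enzymes <- unique(vapply(consensus, function(x) x@enzyme, ""))
  if (length(enzymes) != 1L) {
    stop("all consensus profiles must come from one enzyme", call. = FALSE)
  }
  dates <- as.Date(dates)
  ord <- order(dates)
  dates <- dates[ord]
  consensus <- consensus[ord]
  peakList <- lapply(consensus, function(cp) {
    data.frame(size = cp@bins$bin_size, height = cp@bins$height,
               area = cp@bins$area)
  })
  removedFraction <- rep(0, length(peakList))
  if (normalize) {
    nm <- .dunbarNormalize(peakList, floor = floor)
    if (any(nm$empty)) {
      stop("a profile lost all fragments during series normalization",
           call. = FALSE)
    }
    peakList <- nm$peaks
    removedFraction <- nm$removedFraction
  }
  names(peakList) <- as.character(dates)
  bp <- alignPeaks(peakList, gap = gap, enzyme = enzymes)
  tf <- colSums(bp@height)
  if (any(tf == 0)) stop("a profile has no fragments", call. = FALSE)
  ab <- sweep(bp@height, 2L, tf, "/")
  out <- new("ProfileSeries", enzyme = enzymes, dates = dates,
             binSizes = bp@binCenters, abundance = ab)
  attr(out, "removedFraction") <- setNames(removedFraction,
                                           as.character(dates))
  out
}

#' Community stability: distance of every profile to the first sample
#'
#' Bray-Curtis distance of each profile in the series against the
#' chronologically first profile; the first entry is 0 by construction.
#' Peaks in this series mark deviations from the baseline community
#' composition.
#'
#' @param series A [ProfileSeries-class] with at least 2 dates.
#' @return `data.frame` with columns `date` and `distance` (percent).
#' @export
distanceToBaseline <- function(series) {
  stopifnot(is(series, "ProfileSeries"))
  if (length(series@dates) < 2L) {
    stop("series must contain at least two profiles", call. = FALSE)
  }
  base <- series@abundance[, 1L]
  dist <- apply(series@abundance, 2L, brayCurtis, q = base)
  data.frame(date = series@dates, distance = as.numeric(dist))
}

#' Identify observed dual-enzyme TRF combinations against a digest database
#'
#' A database sequence is a candidate identity for an observed
#' (AluI, RsaI) fragment combination if, for both enzymes, the predicted
#' minus observed length lies inside the drift window, or the prediction is
#' undigested/out-of-range where the observation is flagged out of range.
#' The default window of 3-7 bases brackets the systematic 4-6 base excess
#' of predicted over observed fragment sizes with one base of size-calling
#' jitter on either side. Widening the window never removes a candidate.
#'
#' @param observed `data.frame` with numeric columns `alui` and `rsai`
#'   holding observed fragment sizes in bases; `NA` marks an
#'   out-of-range observation slot.
#' @param digestDb Digest table as returned by [digestDatabase()]
#'   (columns `seq_id`, `enzyme`, `status`, `length_bases`).
#' @param labels Optional named vector mapping `seq_id` to a taxon label;
#'   defaults to the `seq_id` itself (or a `label` column of `digestDb`).
#' @param driftWindow Length-2 numeric: allowed predicted - observed range.
#' @param enzymes Names of the two enzymes (in `observed` column order).
#' @return List with `candidates` (one `data.frame` of `seq_id`, `label`
#'   per observed combination; possibly zero rows) and `table` (summary
#'   with one row per combination and the distinct candidate labels
#'   collapsed with "; ").
#' @export
identifyCombinations <- function(observed, digestDb, labels = NULL,
                                 driftWindow = c(3, 7),
                                 enzymes = c("AluI", "RsaI")) {
  if (!all(c("alui", "rsai") %in% names(observed))) {
    stop("observed must have columns 'alui' and 'rsai'", call. = FALSE)
  }
  wide <- list()
  for (e in enzymes) {
    sub <- digestDb[digestDb$enzyme == e, , drop = FALSE]
    wide[[e]] <- sub[match(unique(digestDb$seq_id), sub$seq_id), ,
                     drop = FALSE]
  }
  ids <- unique(digestDb$seq_id)
  if (is.null(labels)) {
    labels <- if ("label" %in% names(digestDb)) {
      setNames(digestDb$label[match(ids, digestDb$seq_id)], ids)
    } else {
      setNames(ids, ids)
    }
  }
  matchOne <- function(obs, status, len) {
    if (is.na(obs)) {
      status %in% c("ND", "OUT_OF_RANGE")
    } else {
      !is.na(status) & status == "ok" & !is.na(len) &
        (len - obs) >= driftWindow[1L] & (len - obs) <= driftWindow[2L]
    }
  }
  candidates <- vector("list", nrow(observed))
  collapsed <- character(nrow(observed))
  for (r in seq_len(nrow(observed))) {
    okA <- matchOne(observed$alui[r], wide[[enzymes[1L]]]$status,
                    wide[[enzymes[1L]]]$length_bases)
    okR <- matchOne(observed$rsai[r], wide[[enzymes[2L]]]$status,
                    wide[[enzymes[2L]]]$length_bases)
    hit <- ids[okA & okR]
    candidates[[r]] <- data.frame(seq_id = hit,
                                  label = unname(labels[hit]),
                                  row.names = NULL)
    collapsed[r] <- paste(unique(labels[hit]), collapse = "; ")
  }
  table <- data.frame(alui = observed$alui, rsai = observed$rsai,
                      candidates = collapsed)
  list(candidates = candidates, table = table)
}

.starLabel <- function(p, levels = c(0.05, 0.01, 0.001)) {
  if (is.na(p)) return(NA_character_)
  if (p < levels[3L]) "***" else if (p < levels[2L]) "**"
  else if (p < levels[1L]) "*" else ""
}

#' Correlate fragment abundances with process parameters
#'
#' Pearson product-moment correlation between the relative abundance of
#' each fragment in a fingerprint series and each (numeric) parameter
#' column, over the dates present in both; a fragment absent from an
#' existing profile contributes abundance 0 (set `zeroFill = FALSE` to
#' treat absences as missing instead). Significance comes from the t-test
#' \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} with `n - 2` degrees of freedom
#' (two-sided); stars mark p < 0.05 (*), < 0.01 (**) and < 0.001 (***).
#' No multiple-testing correction is applied.
#'
#' @param series A [ProfileSeries-class], or an abundance matrix with
#'   fragment sizes as rownames and dates (`as.character(Date)`) as
#'   colnames.
#' @param parameters `data.frame` with a `date` column plus numeric
#'   parameter columns.
#' @param zeroFill Treat a fragment absent from a profile as abundance 0
#'   (default) rather than missing.
#' @param starLevels Significance levels for *, **, ***.
#' @return `data.frame` with columns `trf`, `parameter`, `n_obs` (profiles
#'   in which the fragment appears), `n_pairs` (paired observations used),
#'   `r`, `t`, `p`, `stars`, `note` (`"zero_variance"` or
#'   `"too_few_pairs"` where r is undefined).
#' @export
correlateParameters <- function(series, parameters, zeroFill = TRUE,
                                starLevels = c(0.05, 0.01, 0.001)) {
  if (is(series, "ProfileSeries")) {
    ab <- abundanceMatrix(series)
  } else {
    ab <- as.matrix(series)
  }
  if (!"date" %in% names(parameters)) {
    stop("parameters must have a 'date' column", call. = FALSE)
  }
  pdates <- as.character(as.Date(parameters$date))
  shared <- intersect(colnames(ab), pdates)
  if (length(shared) < 3L) {
    stop("need at least 3 dates shared by series and parameters",
         call. = FALSE)
  }
  ab <- ab[, shared, drop = FALSE]
  pcols <- setdiff(names(parameters), "date")
  pcols <- pcols[vapply(parameters[pcols], is.numeric, TRUE)]
  rows <- list()
  for (i in seq_len(nrow(ab))) {
    a <- ab[i, ]
    nObs <- sum(a > 0)
    if (!zeroFill) a[a == 0] <- NA_real_
    for (pc in pcols) {
      v <- parameters[[pc]][match(shared, pdates)]
      ok <- complete.cases(a, v)
      nPairs <- sum(ok)
      r <- t <- p <- NA_real_
      note <- ""
      if (nPairs < 3L) {
        note <- "too_few_pairs"
      } else if (sd(a[ok]) == 0 || sd(v[ok]) == 0) {
        note <- "zero_variance"
      } else {
        r <- cor(a[ok], v[ok])
        if (abs(r) >= 1) {
          t <- sign(r) * Inf
          p <- 0
        } else {
          t <- r * sqrt((nPairs - 2) / (1 - r^2))
          p <- 2 * pt(-abs(t), df = nPairs - 2)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trf = rownames(ab)[i], parameter = pc, n_obs = nObs,
        n_pairs = nPairs, r = r, t = t, p = p,
        stars = .starLabel(p, starLevels), note = note)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
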
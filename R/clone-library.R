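# Clone-library diversity statistics: pairwise distances on aligned
# sequences, OTU assignment at nested similarity thresholds, Chao1
# richness, accumulation curves and Pareto-Lorenz evenness.

#' Pairwise distances between aligned sequences
#'
#' Uncorrected p-distance with pairwise gap deletion: for each sequence
#' pair, the proportion of differing positions over the alignment columns
#' in which both sequences carry a non-gap, determinate base. The
#' uncorrected distance is used because the OTU similarity thresholds
#' (98.7\% species, 95\% genus, 90\% family/class, 80\% phylum) are
#' sequence-identity conventions; an evolutionary-model distance can be
#' selected via `model` (passed to [ape::dist.dna()]).
#'
#' @param sequences Aligned sequences: a `DNAStringSet` or named character
#'   vector, all of the same length.
#' @param model Distance model, default `"raw"` (p-distance).
#' @return A `dist` object with sequence ids as labels.
#' @examples
#' d <- pairwiseDistances(c(a = "AAAA", b = "AAAT"))
#' as.numeric(d)  # 0.25
#' @export
pairwiseDistances <- function(sequences, model = "raw") {
  seqs <- .asSequenceCharacter(sequences)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (length(seqs) < 1L || any(!nzchar(seqs))) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned to a common length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(m) <- names(seqs)
  d <- ape::dist.dna(ape::as.DNAbin(m), model = model,
                     pairwise.deletion = TRUE)
  if (anyNA(d) || any(is.nan(d))) {
    stop("a sequence pair shares no comparable (non-gap) column",
         call. = FALSE)
  }
  d
}

#' Assign sequences to OTUs at a similarity threshold
#'
#' Complete-linkage (furthest-neighbor) agglomerative clustering of the
#' distance matrix: clusters merge while the largest within-cluster
#' pairwise distance stays at or below `1 - threshold`, so every OTU
#' satisfies the similarity threshold between all member pairs. OTU numbers
#' follow the lexicographic order of each cluster's smallest member id.
#'
#' @param d A `dist` object (see [pairwiseDistances()]).
#' @param threshold Similarity fraction in (0, 1], e.g. 0.987 for the
#'   species level.
#' @return An [OTUPartition-class].
#' @examples
#' d <- pairwiseDistances(c(a = "AAAAA", b = "AAAAT", c = "TTTTT"))
#' otuAbundances(assignOTUs(d, 0.9))
#' @export
assignOTUs <- function(d, threshold) {
  if (!inherits(d, "dist")) stop("d must be a 'dist' object", call. = FALSE)
  .assertScalarNumber(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  labs <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (is.null(labs)) labs <- sprintf("seq%d", seq_len(n))
  cutoff <- 1 - threshold
  if (n == 1L) {
    membership <- setNames(1L, labs)
  } else {
    cl <- cutree(hclust(d, method = "complete"), h = cutoff)
    # renumber OTUs by lexicographic order of their smallest member id
    firstMember <- vapply(split(labs, cl), min, "")
    newId <- setNames(seq_along(firstMember), names(firstMember)[order(firstMember)])
    membership <- setNames(as.integer(newId[as.character(cl)]), labs)
  }
  new("OTUPartition", threshold = threshold, membership = membership)
}

#' Chao1 richness estimate
#'
#' Classic (non-bias-corrected) Chao1 lower bound on species richness:
#' \deqn{S_{chao1} = S_{obs} + f_1^2 / (2 f_2)}
#' where \eqn{f_1} and \eqn{f_2} are the numbers of OTUs observed exactly
#' once and twice. When no doubletons exist the form
#' \eqn{S_{obs} + f_1 (f_1 - 1) / 2} is used. The library coverage is
#' \eqn{100 \cdot S_{obs} / S_{chao1}}: the percentage of the estimated
#' richness that the observed library captured.
#'
#' @param abundances Positive integer per-OTU clone counts.
#' @return One-row `data.frame` with `s_obs`, `f1`, `f2`, `chao1`,
#'   `coverage`.
#' @examples
#' chao1(c(1, 1, 2))$chao1  # 3 + 2^2 / (2 * 1) = 5
#' @export
chao1 <- function(abundances) {
  if (length(abundances) == 0L) stop("abundances must be nonempty", call. = FALSE)
  if (any(abundances <= 0) || any(abundances != round(abundances))) {
    stop("abundances must be positive integers", call. = FALSE)
  }
  sObs <- length(abundances)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  est <- if (f2 > 0) sObs + f1^2 / (2 * f2) else sObs + f1 * (f1 - 1) / 2
  data.frame(s_obs = sObs, f1 = f1, f2 = f2, chao1 = est,
             coverage = 100 * sObs / est)
}

#' OTU accumulation curve
#'
#' Expected number of distinct OTUs among the first k clones, as a function
#' of k, either averaged over random orderings of the clone list (the
#' default, with a required seed) or computed exactly from the
#' hypergeometric rarefaction formula
#' \eqn{E[S_k] = S - \sum_i \binom{n - n_i}{k} / \binom{n}{k}}.
#'
#' @param cloneLabels Vector of per-clone OTU labels, in library order.
#' @param nPermutations Number of random orderings (>= 1; default 1000).
#' @param seed Integer seed for the permutations.
#' @param exact Use the closed-form expectation instead of permutations.
#' @return `data.frame` with columns `n_clones` (1..n) and `otus`
#'   (expected distinct OTU count).
#' @examples
#' accumulationCurve(c("A", "A", "B"), exact = TRUE)$otus[2]  # 5/3
#' @export
accumulationCurve <- function(cloneLabels, nPermutations = 1000L, seed = 1L,
                              exact = FALSE) {
  n <- length(cloneLabels)
  if (n == 0L) stop("cloneLabels must be nonempty", call. = FALSE)
  if (exact) {
    counts <- as.integer(table(cloneLabels))
    S <- length(counts)
    otus <- vapply(seq_len(n), function(k) {
      S - sum(exp(lchoose(n - counts, k) - lchoose(n, k)))
    }, 0)
    return(data.frame(n_clones = seq_len(n), otus = otus))
  }
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 1L) stop("nPermutations must be >= 1", call. = FALSE)
  withSeed(seed, {
    acc <- numeric(n)
    for (p in seq_len(nPermutations)) {
      perm <- sample(cloneLabels)
      acc <- acc + cumsum(!duplicated(perm))
    }
    data.frame(n_clones = seq_len(n), otus = acc / nPermutations)
  })
}

#' Pareto-Lorenz evenness curve and functional organization index
#'
#' OTUs are ranked from most to least abundant; the cumulative proportion
#' of abundance (y) is plotted against the cumulative proportion of OTUs
#' (x), giving a concave curve from (0, 0) to (1, 1). The functional
#' organization index Fo is the y-value of the curve at x = 20\%, i.e. the
#' combined relative abundance of the most abundant 20\% of the OTUs,
#' expressed in percent. A perfectly even community gives Fo = 20\%; a
#' specialized community, dominated by few OTUs, gives a high Fo. When
#' 0.2 S is not an integer the curve is linearly interpolated between
#' vertices.
#'
#' @param abundances Positive per-OTU counts.
#' @return List with `x`, `y` (curve vertices including the origin) and
#'   `fo` (percent).
#' @examples
#' paretoLorenz(rep(4, 10))$fo   # 20: perfect evenness
#' paretoLorenz(c(8, 1, 1))$fo   # 48: interpolated on the first segment
#' @export
paretoLorenz <- function(abundances) {
  if (length(abundances) == 0L || any(abundances <= 0)) {
    stop("abundances must be nonempty positive counts", call. = FALSE)
  }
  ab <- sort(abundances, decreasing = TRUE)
  S <- length(ab)
  x <- c(0, seq_len(S) / S)
  y <- c(0, cumsum(ab) / sum(ab))
  fo <- 100 * approx(x, y, xout = 0.2, ties = "ordered")$y
  list(x = x, y = y, fo = fo)
}
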
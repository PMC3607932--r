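# Shared fixtures and independent oracles for the test suite.

# Per-OTU clone counts of the reference library (25 OTUs, 82 clones),
# as shipped in inst/extdata/otu_clone_counts.csv.
libraryCloneCounts <- function() {
  tab <- read.csv(system.file("extdata", "otu_clone_counts.csv",
                              package = "TRFLPtools"))
  tab$count
}

# Independent naive complete-linkage agglomeration: merge the cluster pair
# with the smallest furthest-neighbor distance while it does not exceed the
# cutoff. Direct transcription of the definition; no dendrogram machinery.
naiveCompleteLinkage <- function(dmat, cutoff) {
  clusters <- as.list(seq_len(nrow(dmat)))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- max(dmat[clusters[[i]], clusters[[j]]])
        if (d < bestD) { bestD <- d; best <- c(i, j) }
      }
    }
    if (bestD > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# Canonical form of a partition (set of sets) for comparison.
partitionKey <- function(groups) {
  key <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
  paste(key, collapse = "|")
}

partitionKeyFromMembership <- function(membership) {
  partitionKey(split(seq_along(membership), membership))
}

# Naive scan oracle for terminal-fragment prediction: test the recognition
# string at every position at or after the label origin.
naiveTRF <- function(sequence, recognition, cutOffset, labelOrigin = 1L) {
  n <- nchar(sequence); w <- nchar(recognition)
  for (pos in labelOrigin:(n - w + 1L)) {
    if (substr(sequence, pos, pos + w - 1L) == recognition) {
      return(pos - labelOrigin + cutOffset)
    }
  }
  NA_integer_
}

randomSequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A small noiseless scenario used by several pipeline tests.
noiselessScenario <- function(weights = c(0.4, 0.25, 0.15, 0.1, 0.1),
                              drift = 5, seed = 11, nReplicates = 3) {
  ref <- makeReferenceTaxa(length(weights), seed = seed)
  communityScenario(ref, weights, drift = drift, noiseSd = 0,
                    nReplicates = nReplicates, seed = seed)
}
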
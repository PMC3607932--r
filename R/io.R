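# File formats: electropherogram peak tables (CSV dialect of
# capillary-electrophoresis software exports), FASTA, square Phylip
# distance matrices and consensus-profile tables.

.PEAK_COLS <- c("sample_id", "enzyme", "replicate", "size_bases",
                "height_fu", "area")

.validatePeakTable <- function(tab) {
  miss <- setdiff(.PEAK_COLS, names(tab))
  if (length(miss)) {
    stop(sprintf("peak table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  tab <- as.data.frame(tab)[, .PEAK_COLS]
  for (col in c("size_bases", "height_fu", "area")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("peak table row %d: non-numeric value '%s' in column %s",
                   bad[1L], tab[[col]][bad[1L]], col), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("peak table row %d: missing value in column %s",
                   which(is.na(v))[1L], col), call. = FALSE)
    }
    tab[[col]] <- v
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$enzyme <- as.character(tab$enzyme)
  tab$replicate <- as.character(tab$replicate)
  tab
}

#' Read and write electropherogram peak tables
#'
#' Peak tables use a plain CSV dialect with the header
#' `sample_id,enzyme,replicate,size_bases,height_fu,area`, one detected
#' peak per row. `peakTable()` flattens a list of [TRFProfile-class] into
#' this layout; `writePeakTable()` writes it; `readPeakTable()` reads and
#' validates it (malformed rows raise an error naming the row).
#'
#' @param profiles List of [TRFProfile-class].
#' @param path File path.
#' @param tab A peak-table `data.frame`.
#' @return `peakTable()` and `readPeakTable()` return the validated
#'   `data.frame`; `writePeakTable()` returns `path` invisibly.
#' @examples
#' ref <- makeReferenceTaxa(2, seed = 1)
#' sc <- communityScenario(ref, c(0.7, 0.3), seed = 2)
#' tab <- peakTable(renderElectropherograms(sc))
#' head(tab)
#' @export
peakTable <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    stopifnot(is(p, "TRFProfile"))
    if (nrow(p@peaks) == 0L) return(NULL)
    data.frame(sample_id = p@sampleId, enzyme = p@enzyme,
               replicate = p@replicateId, size_bases = p@peaks$size,
               height_fu = p@peaks$height, area = p@peaks$area)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), enzyme = character(),
                      replicate = character(), size_bases = numeric(),
                      height_fu = numeric(), area = numeric())
  }
  rownames(out) <- NULL
  out
}

#' @rdname peakTable
#' @export
writePeakTable <- function(tab, path) {
  if (is.list(tab) && !is.data.frame(tab)) tab <- peakTable(tab)
  write.csv(.validatePeakTable(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname peakTable
#' @export
readPeakTable <- function(path) {
  .validatePeakTable(read.csv(path, stringsAsFactors = FALSE))
}

#' Write reference sequences as FASTA
#'
#' @param reference A [ReferenceCommunity-class] (or a `DNAStringSet`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(reference, path) {
  seqs <- if (is(reference, "ReferenceCommunity")) {
    reference@sequences
  } else {
    Biostrings::DNAStringSet(reference)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read aligned sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] kept for interface
#' symmetry with [writeReferenceFasta()].
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet`.
#' @export
readAlignedFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read and write square Phylip-format distance matrices
#'
#' The square (full) Phylip layout: the first line holds the number of
#' sequences; each following line holds a label and the full row of
#' distances.
#'
#' @param d A `dist` object (or square symmetric matrix) with labels.
#' @param path File path.
#' @return `writePhylipDist()` returns `path` invisibly;
#'   `readPhylipDist()` returns a `dist` object.
#' @export
writePhylipDist <- function(d, path) {
  m <- as.matrix(d)
  labs <- rownames(m)
  if (is.null(labs)) labs <- sprintf("seq%d", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(formatC(labs[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writePhylipDist
#' @export
readPhylipDist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    labs[i] <- parts[1L]
    m[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(m) <- list(labs, labs)
  as.dist(m)
}

#' Flatten consensus profiles into a table
#'
#' One row per consensus fragment, in the layout
#' `sample_id,enzyme,bin_size,height,area,rel_abundance`.
#'
#' @param consensus List of [ConsensusProfile-class] (e.g. from
#'   [runPipeline()]).
#' @param path Optional CSV path; when given the table is also written.
#' @return The `data.frame` (invisibly when `path` is given).
#' @export
consensusTable <- function(consensus, path = NULL) {
  rows <- lapply(consensus, function(cp) {
    if (nrow(cp@bins) == 0L) return(NULL)
    data.frame(sample_id = cp@sampleId, enzyme = cp@enzyme, cp@bins)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), enzyme = character(),
                      bin_size = numeric(), height = numeric(),
                      area = numeric(), rel_abundance = numeric())
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
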
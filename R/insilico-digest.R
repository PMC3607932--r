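#' Archaea-specific amplification primers
#'
#' The degenerate primer pair used to amplify archaeal 16S rRNA genes:
#' Arch18F (`TTCCGGTTGATCCYGCC`, 5'-labeled with 6-carboxyfluorescein in the
#' fingerprinting assay) and Arch959R (`YCCGGCGTTGAMTCCAAT`). IUPAC
#' degeneracy codes are allowed.
#'
#' @return Named character vector of primer sequences.
#' @examples
#' archPrimers()["Arch18F"]
#' @export
archPrimers <- function() {
  c(Arch18F = "TTCCGGTTGATCCYGCC", Arch959R = "YCCGGCGTTGAMTCCAAT")
}

#' Restriction enzyme specification
#'
#' A restriction enzyme is described by its recognition sequence and the cut
#' offset: the number of bases from the start of the recognition site to the
#' cut position on the labeled strand. The two enzymes of the fingerprinting
#' assay, available from [trflpEnzymes()], are the blunt cutters
#' AluI (AG^CT) and RsaI (GT^AC), both with cut offset 2.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence over A/C/G/T.
#' @param cutOffset Bases from recognition-site start to the cut, in
#'   `[0, nchar(recognition)]`.
#' @return For `enzymeSpec()`, a list with class `"EnzymeSpec"`; for
#'   `trflpEnzymes()`, a named list of the built-in AluI and RsaI specs.
#' @examples
#' trflpEnzymes()$AluI
#' @export
enzymeSpec <- function(name, recognition, cutOffset) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition)) {
    stop("recognition sequence must be over A/C/G/T", call. = FALSE)
  }
  cutOffset <- as.integer(cutOffset)
  if (cutOffset < 0L || cutOffset > nchar(recognition)) {
    stop("cutOffset must lie within the recognition sequence", call. = FALSE)
  }
  structure(list(name = name, recognition = recognition,
                 cutOffset = cutOffset),
            class = "EnzymeSpec")
}

#' @rdname enzymeSpec
#' @export
trflpEnzymes <- function() {
  list(AluI = enzymeSpec("AluI", "AGCT", 2L),
       RsaI = enzymeSpec("RsaI", "GTAC", 2L))
}

#' @export
print.EnzymeSpec <- function(x, ...) {
  cat(sprintf("EnzymeSpec %s: %s^%s\n", x$name,
              substr(x$recognition, 1, x$cutOffset),
              substr(x$recognition, x$cutOffset + 1L, nchar(x$recognition))))
  invisible(x)
}

#' Locate a (degenerate) primer in a sequence
#'
#' Finds the leftmost position at which every primer character's IUPAC set
#' contains the corresponding sequence character. An `N` in the sequence
#' matches nothing, so primer sites spanning undetermined bases are not
#' reported.
#'
#' @param sequence A nucleotide string (or `DNAString`) over A/C/G/T/N.
#' @param primer Primer sequence, IUPAC degeneracy codes allowed.
#' @return 1-based start position of the first match, or `NA_integer_` if
#'   the primer does not occur.
#' @examples
#' matchPrimer("AATTCCGGTTGATCCTGCCAA", archPrimers()["Arch18F"])  # 3
#' matchPrimer("TTCCGGTTGATCCAGCC", archPrimers()["Arch18F"])      # NA
#' @export
matchPrimer <- function(sequence, primer) {
  subject <- Biostrings::DNAString(.asSequenceCharacter(sequence)[1L])
  hits <- Biostrings::matchPattern(as.character(primer), subject,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  if (length(hits) == 0L) NA_integer_ else as.integer(BiocGenerics::start(hits)[1L])
}

.firstSiteAt <- function(sequence, recognition, from = 1L) {
  # leftmost exact occurrence of `recognition` starting at or after `from`
  subject <- Biostrings::DNAString(sequence)
  hits <- Biostrings::matchPattern(recognition, subject)
  st <- BiocGenerics::start(hits)
  st <- st[st >= from]
  if (length(st) == 0L) NA_integer_ else as.integer(st[1L])
}

.trfStatus <- function(len, sizeRange) {
  if (is.na(len)) {
    list(status = "ND", length = NA_real_)
  } else if (len < sizeRange[1L] || len > sizeRange[2L]) {
    list(status = "OUT_OF_RANGE", length = as.numeric(len))
  } else {
    list(status = "ok", length = as.numeric(len))
  }
}

#' Predict the labeled terminal restriction fragment length
#'
#' Simulates the restriction digest of a 5'-labeled amplicon: the terminal
#' restriction fragment (TRF) length is the number of labeled-strand bases
#' retained 5' of the first cut, counting from the label origin (the first
#' base of the labeled forward primer). With the recognition site starting
#' at position `s` (1-based) and cut offset `c`, the length is
#' `s - labelOrigin + c`. A sequence without a recognition site downstream
#' of the label yields status `"ND"` (not digested); a fragment outside the
#' sizing window (50-1020 bases by default, the range resolvable against the
#' size standard) yields `"OUT_OF_RANGE"` with the raw length retained.
#'
#' @param sequence Nucleotide string (or `DNAString`).
#' @param enzyme An `EnzymeSpec` (see [trflpEnzymes()]).
#' @param labelOrigin 1-based position of the labeled 5' base.
#' @param sizeRange Observable fragment-size window in bases.
#' @return A list with elements `status` (`"ok"`, `"ND"` or
#'   `"OUT_OF_RANGE"`) and `length` (bases; `NA` for `"ND"`).
#' @examples
#' s <- paste0("TTCCGGTTGATCCCGCC", "AAAA", "AGCT", "GGGG")
#' predictTRF(s, trflpEnzymes()$AluI)$length  # 23
#' @export
predictTRF <- function(sequence, enzyme, labelOrigin = 1L,
                       sizeRange = c(50, 1020)) {
  sequence <- .asSequenceCharacter(sequence)[1L]
  labelOrigin <- as.integer(labelOrigin)
  if (labelOrigin < 1L || labelOrigin > nchar(sequence)) {
    stop("labelOrigin must lie within the sequence", call. = FALSE)
  }
  s <- .firstSiteAt(sequence, enzyme$recognition, from = labelOrigin)
  len <- if (is.na(s)) NA_integer_ else s - labelOrigin + enzyme$cutOffset
  .trfStatus(len, sizeRange)
}

#' Predict a TRF for a clone that starts downstream of the primer
#'
#' Clone-library sequences often begin 50-100 bases downstream of the
#' forward primer, so their TRF cannot be read off directly. The clone is
#' anchored in a reference sequence that contains the primer site, assuming
#' no insertions or deletions between the primer and the anchoring region;
#' the predicted TRF is then the reference offset of the clone's first base
#' plus the position of the first cut within the clone. If the reference
#' carries a recognition site between the label origin and the clone's
#' start, the true terminal fragment ends upstream of the clone and the TRF
#' cannot be predicted (`"ND"`).
#'
#' @param clone Clone sequence (nucleotide string or `DNAString`).
#' @param reference Reference sequence containing the forward-primer site.
#' @param enzyme An `EnzymeSpec`.
#' @param primer Forward primer used to locate the label origin in the
#'   reference.
#' @param minAnchor Number of exact-matching leading clone bases required to
#'   anchor the clone in the reference.
#' @param maxOffset Largest allowed clone start offset from the label
#'   origin (no-indel assumption holds up to here).
#' @param sizeRange Observable fragment-size window in bases.
#' @return As [predictTRF()].
#' @export
predictTRFOffset <- function(clone, reference, enzyme,
                             primer = archPrimers()[["Arch18F"]],
                             minAnchor = 20L, maxOffset = 100L,
                             sizeRange = c(50, 1020)) {
  clone <- .asSequenceCharacter(clone)[1L]
  reference <- .asSequenceCharacter(reference)[1L]
  origin <- matchPrimer(reference, primer)
  if (is.na(origin)) {
    stop("reference sequence does not contain the primer site", call. = FALSE)
  }
  anchorLen <- min(as.integer(minAnchor), nchar(clone))
  anchor <- substr(clone, 1L, anchorLen)
  if (grepl("N", anchor, fixed = TRUE)) {
    stop("clone's leading bases contain N; cannot anchor unambiguously",
         call. = FALSE)
  }
  hits <- Biostrings::matchPattern(anchor, Biostrings::DNAString(reference))
  st <- BiocGenerics::start(hits)
  st <- st[st >= origin & st <= origin + as.integer(maxOffset)]
  if (length(st) == 0L) {
    stop("clone's leading bases were not found in the reference", call. = FALSE)
  }
  if (length(st) > 1L) {
    stop("clone's leading bases map ambiguously in the reference", call. = FALSE)
  }
  offset <- st[1L] - origin            # 0 when the clone starts at the label
  if (offset > 0L) {
    upstream <- .firstSiteAt(reference, enzyme$recognition, from = origin)
    if (!is.na(upstream) && upstream < st[1L]) {
      # the terminal fragment ends before the clone begins
      return(list(status = "ND", length = NA_real_))
    }
  }
  s <- .firstSiteAt(clone, enzyme$recognition)
  len <- if (is.na(s)) NA_integer_ else offset + (s - 1L) + enzyme$cutOffset
  .trfStatus(len, sizeRange)
}

#' Digest a sequence collection in silico
#'
#' Predicts the labeled TRF of every sequence for every enzyme. The label
#' origin of each sequence is located with the forward primer unless
#' supplied explicitly via `labelOrigins`; sequences in which the primer
#' cannot be found (and with no declared origin) are skipped with a warning
#' and counted in the `n_skipped` attribute.
#'
#' @param sequences A named character vector or `DNAStringSet`.
#' @param enzymes List of `EnzymeSpec`s (default AluI and RsaI).
#' @param primer Forward primer locating the label origin.
#' @param labelOrigins Optional named integer vector of 1-based label
#'   origins, overriding primer search per sequence.
#' @param sizeRange Observable fragment-size window in bases.
#' @return A `data.frame` with columns `seq_id`, `enzyme`, `status`,
#'   `length_bases`, one row per sequence x enzyme, and attribute
#'   `n_skipped`.
#' @examples
#' ref <- makeReferenceTaxa(3, seed = 1)
#' digestDatabase(ref@sequences)
#' @export
digestDatabase <- function(sequences, enzymes = trflpEnzymes(),
                           primer = archPrimers()[["Arch18F"]],
                           labelOrigins = NULL, sizeRange = c(50, 1020)) {
  seqs <- .asSequenceCharacter(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  rows <- vector("list", length(seqs))
  skipped <- 0L
  for (i in seq_along(seqs)) {
    origin <- if (!is.null(labelOrigins) && ids[i] %in% names(labelOrigins)) {
      as.integer(labelOrigins[[ids[i]]])
    } else {
      matchPrimer(seqs[i], primer)
    }
    if (is.na(origin)) {
      warning(sprintf("sequence '%s' lacks the primer site; skipped", ids[i]),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    recs <- lapply(enzymes, function(e) {
      predictTRF(seqs[i], e, labelOrigin = origin, sizeRange = sizeRange)
    })
    rows[[i]] <- data.frame(
      seq_id = ids[i],
      enzyme = vapply(enzymes, `[[`, "", "name"),
      status = vapply(recs, `[[`, "", "status"),
      length_bases = vapply(recs, `[[`, 0, "length"),
      row.names = NULL)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), enzyme = character(),
                      status = character(), length_bases = numeric())
  }
  attr(out, "n_skipped") <- skipped
  out
}
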
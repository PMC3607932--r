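# Synthetic community generator: reference taxa with planted restriction
# sites, clone-library draws, replicate electropherogram rendering and
# parameter time series with planted linear effects. The defaults define the
# simulated study conditions; ground truth is always recorded so that every
# pipeline stage can be validated end to end.

# Concrete (non-degenerate) realization of the labeled forward primer used
# in generated sequences; contains no AluI or RsaI site.
.primerRealization <- function() "TTCCGGTTGATCCCGCC"

.SITES <- c("AGCT", "GTAC")

# Sample one random base such that the 4-base window ending at position i
# does not create a restriction site; positions are filled left to right.
.fillFreeBases <- function(chars, fixed) {
  bases <- c("A", "C", "G", "T")
  n <- length(chars)
  for (i in which(!fixed)) {
    repeat {
      chars[i] <- sample(bases, 1L)
      if (i < 4L) break
      win <- paste(chars[(i - 3L):i], collapse = "")
      if (!(win %in% .SITES)) break
    }
  }
  chars
}

#' Generate reference taxa with planted terminal restriction fragments
#'
#' Builds `nTaxa` synthetic archaeal 16S-like reference sequences. Each
#' sequence starts with the labeled forward primer, contains exactly one
#' AluI site and exactly one RsaI site at controlled, pairwise-distinct
#' positions at least 60 bases from the labeled end, and is otherwise
#' random. The planted site positions determine each taxon's true TRF
#' lengths, which are recomputed with [predictTRF()] and stored, so the
#' reference set is self-consistent by construction. Output is
#' deterministic for a fixed seed.
#'
#' @param nTaxa Number of taxa (>= 1).
#' @param seed Integer seed.
#' @return A [ReferenceCommunity-class] whose taxa table carries
#'   `trf_AluI` and `trf_RsaI` ground-truth lengths; all (AluI, RsaI)
#'   length pairs are distinct across taxa.
#' @examples
#' ref <- makeReferenceTaxa(3, seed = 1)
#' referenceTaxa(ref)
#' @export
makeReferenceTaxa <- function(nTaxa, seed) {
  nTaxa <- as.integer(nTaxa)
  if (nTaxa < 1L) stop("nTaxa must be >= 1", call. = FALSE)
  aluGrid <- seq(70L, 700L, by = 9L)   # AluI TRF lengths
  rsaGrid <- seq(74L, 704L, by = 9L)   # RsaI TRF lengths; |La - Lr| >= 4
  if (nTaxa > length(aluGrid)) {
    stop(sprintf("at most %d taxa supported", length(aluGrid)), call. = FALSE)
  }
  primer <- .primerRealization()
  enz <- trflpEnzymes()
  withSeed(seed, {
    la <- sample(aluGrid, nTaxa)
    lr <- sample(rsaGrid, nTaxa)
    seqs <- character(nTaxa)
    for (i in seq_len(nTaxa)) {
      total <- max(la[i], lr[i]) + 2L + 80L
      total <- max(total, 200L)
      chars <- character(total)
      fixed <- logical(total)
      chars[1:nchar(primer)] <- strsplit(primer, "")[[1L]]
      fixed[1:nchar(primer)] <- TRUE
      # site starting at position L - 1 gives TRF length L (cut offset 2)
      for (k in 1:2) {
        L <- c(la[i], lr[i])[k]
        pos <- (L - 1L):(L + 2L)
        chars[pos] <- strsplit(.SITES[k], "")[[1L]]
        fixed[pos] <- TRUE
      }
      chars <- .fillFreeBases(chars, fixed)
      seqs[i] <- paste(chars, collapse = "")
      for (site in .SITES) {
        hits <- gregexpr(site, seqs[i], fixed = TRUE)[[1L]]
        stopifnot(sum(hits > 0L) == 1L)
      }
    }
    ids <- sprintf("tax%02d", seq_len(nTaxa))
    sset <- Biostrings::DNAStringSet(setNames(seqs, ids))
    # recompute ground truth through the digest path (self-consistency)
    trfA <- vapply(seqs, function(s) predictTRF(s, enz$AluI)$length, 0,
                   USE.NAMES = FALSE)
    trfR <- vapply(seqs, function(s) predictTRF(s, enz$RsaI)$length, 0,
                   USE.NAMES = FALSE)
    stopifnot(identical(as.integer(trfA), la), identical(as.integer(trfR), lr))
    taxa <- data.frame(taxon_id = ids,
                       name = sprintf("Synthetic archaeon %d", seq_len(nTaxa)),
                       trf_AluI = trfA, trf_RsaI = trfR)
    new("ReferenceCommunity", sequences = sset, taxa = taxa)
  })
}

#' Construct a community fingerprinting scenario
#'
#' @param reference A [ReferenceCommunity-class].
#' @param weights Per-taxon proportions (non-negative, summing to 1).
#' @param drift Bases subtracted from true TRF lengths when rendering
#'   observed peaks; emulates the systematic size-calling bias by which
#'   predicted fragments run 4-6 bases longer than observed ones
#'   (default 5).
#' @param noiseSd Relative standard deviation of multiplicative peak-height
#'   noise (default 0, noiseless).
#' @param nReplicates Replicate profiles per enzyme (default 3, as in a
#'   triplicate PCR design).
#' @param seed Integer seed.
#' @return A [CommunityScenario-class].
#' @examples
#' ref <- makeReferenceTaxa(3, seed = 1)
#' sc <- communityScenario(ref, c(0.5, 0.3, 0.2), seed = 7)
#' @export
communityScenario <- function(reference, weights, drift = 5, noiseSd = 0,
                              nReplicates = 3L, seed = 1L) {
  new("CommunityScenario", reference = reference, weights = as.numeric(weights),
      drift = as.numeric(drift), noiseSd = as.numeric(noiseSd),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Draw a clone library from a scenario
#'
#' Multinomial sampling of `nClones` clones from the scenario's ground-truth
#' abundance weights, reproducible under the scenario seed. Emulates
#' constructing a 16S rRNA gene clone library from a community sample.
#'
#' @param scenario A [CommunityScenario-class].
#' @param nClones Number of clones to draw (>= 1).
#' @return Character vector of taxon ids of length `nClones` (with repeats).
#' @examples
#' ref <- makeReferenceTaxa(2, seed = 1)
#' sc <- communityScenario(ref, c(0.8, 0.2), seed = 3)
#' table(sampleCloneLibrary(sc, 82))
#' @export
sampleCloneLibrary <- function(scenario, nClones) {
  stopifnot(is(scenario, "CommunityScenario"))
  validObject(scenario)
  nClones <- as.integer(nClones)
  if (nClones < 1L) stop("nClones must be >= 1", call. = FALSE)
  ids <- scenario@reference@taxa$taxon_id
  withSeed(scenario@seed, {
    counts <- as.integer(rmultinom(1L, nClones, prob = scenario@weights))
    sample(rep(ids, counts))
  })
}

#' Render replicate electropherogram peak profiles
#'
#' Simulates the peak tables produced by fragment-analysis software. For
#' each replicate, a total-signal factor H is drawn uniformly from
#' `hRange` fluorescence units (shared across enzymes), so that the
#' replicate quality-control threshold of 500 FU is exercised on both sides
#' under low-signal settings. A taxon with weight w contributes, per
#' enzyme, one peak at size `trueTRF - drift` with height
#' `w * H * (1 + eps)`, `eps ~ Normal(0, noiseSd)`, clipped at zero; peak
#' area equals peak height. Optionally a `Poisson(2)` number of spurious
#' sub-threshold noise peaks (heights 10-49 FU, sizes 50-1020 bases) is
#' added per profile; the 50-FU detection filter must remove them.
#'
#' @param scenario A [CommunityScenario-class].
#' @param sampleId Sample identifier attached to every profile.
#' @param enzymes List of `EnzymeSpec`s (default AluI and RsaI).
#' @param hRange Range of the per-replicate total-signal factor, FU.
#' @param spurious Add spurious sub-threshold peaks? (default `TRUE`)
#' @return List of [TRFProfile-class], one per replicate x enzyme.
#' @examples
#' ref <- makeReferenceTaxa(2, seed = 1)
#' sc <- communityScenario(ref, c(0.8, 0.2), drift = 5, seed = 2)
#' renderElectropherograms(sc)[[1]]
#' @export
renderElectropherograms <- function(scenario, sampleId = "S1",
                                    enzymes = trflpEnzymes(),
                                    hRange = c(800, 3000), spurious = TRUE) {
  stopifnot(is(scenario, "CommunityScenario"))
  validObject(scenario)
  taxa <- scenario@reference@taxa
  w <- scenario@weights
  withSeed(scenario@seed, {
    out <- list()
    for (r in seq_len(scenario@nReplicates)) {
      H <- runif(1L, hRange[1L], hRange[2L])
      for (e in enzymes) {
        trfCol <- paste0("trf_", e$name)
        if (!trfCol %in% names(taxa)) {
          stop(sprintf("reference taxa carry no '%s' ground truth", trfCol),
               call. = FALSE)
        }
        eps <- rnorm(length(w), 0, scenario@noiseSd)
        height <- pmax(w * H * (1 + eps), 0)
        size <- taxa[[trfCol]] - scenario@drift
        keep <- height > 0
        pk <- data.frame(size = size[keep], height = height[keep],
                         area = height[keep])
        if (spurious) {
          k <- rpois(1L, 2)
          if (k > 0L) {
            pk <- rbind(pk, data.frame(size = runif(k, 50, 1020),
                                       height = runif(k, 10, 49),
                                       area = runif(k, 10, 49)))
          }
        }
        pk <- pk[order(pk$size), , drop = FALSE]
        rownames(pk) <- NULL
        out[[length(out) + 1L]] <- trfProfile(sampleId, e$name,
                                              as.character(r), pk)
      }
    }
    out
  })
}

# Parameter ranges the simulated treatment-plant series is drawn from.
# Temperature, sludge retention time (SRT), food-to-microorganism ratio
# (F/M), influent COD and NO23-N follow the plant's reported operating
# ranges (e.g. water temperature 10-20 degrees C); sludge and effluent
# properties (SSVI, shear sensitivity, EPS protein/carbohydrate, effluent
# NSS) use plausible plant-scale ranges.
.parameterRanges <- function() {
  list(temperature = c(10, 20),     # degrees C
       srt         = c(2, 4),       # days
       fm          = c(0.006, 0.010), # kg BOD / kg MLSS / day
       cod         = c(818, 1298),  # mg/L
       no23n       = c(40, 56),     # mg/L
       ssvi        = c(65, 95),     # mL/g
       shear       = c(1, 3),       # relative shear sensitivity
       eps_protein = c(20, 60),     # mg/g VSS
       eps_carb    = c(5, 25),      # mg/g VSS
       nss         = c(6, 40))      # mg/L effluent non-settleable solids
}

#' Generate a process-parameter time series with planted taxon effects
#'
#' Draws a weekly series of treatment-plant process and sludge parameters
#' uniformly from realistic operating ranges, and couples selected taxa to
#' named parameters: a planted effect makes the taxon's (raw) abundance a
#' linear function of the z-scored parameter plus Gaussian noise, with the
#' ground-truth slope recorded. Taxa without a planted effect keep constant
#' baseline abundance. Per-sample relative weights (raw abundances
#' normalized to sum 1) are returned alongside.
#'
#' @param nSamples Number of sampling dates (>= 3).
#' @param plantedEffects Named list mapping `taxon_id` to
#'   `list(parameter = <name>, slope = <number>)`. Unknown parameter names
#'   are an error.
#' @param seed Integer seed.
#' @param taxa Taxon ids in the community (default: the planted ones).
#' @param noiseSd Standard deviation of the additive abundance noise on the
#'   baseline-1 scale (default 0.25; 0 gives exactly linear coupling).
#' @param startDate First sampling date.
#' @return List with elements `parameters` (data.frame of `date` plus one
#'   column per parameter), `abundance` (taxa x samples matrix of raw
#'   abundances, the correlation ground truth), `weights` (column-normalized
#'   abundances) and `effects` (data.frame of planted `taxon_id`,
#'   `parameter`, `slope`).
#' @examples
#' ps <- generateParameterSeries(12,
#'   list(tax01 = list(parameter = "temperature", slope = 0.4)), seed = 1)
#' head(ps$parameters)
#' @export
generateParameterSeries <- function(nSamples, plantedEffects = list(),
                                    seed = 1L, taxa = names(plantedEffects),
                                    noiseSd = 0.25,
                                    startDate = as.Date("2003-05-16")) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 3L) stop("nSamples must be >= 3", call. = FALSE)
  ranges <- .parameterRanges()
  for (eff in plantedEffects) {
    if (!eff$parameter %in% names(ranges)) {
      stop(sprintf("unknown parameter '%s'; known: %s", eff$parameter,
                   paste(names(ranges), collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(taxa) || !length(taxa)) {
    stop("at least one taxon id is required", call. = FALSE)
  }
  taxa <- as.character(taxa)
  withSeed(seed, {
    params <- data.frame(date = startDate + 7 * (seq_len(nSamples) - 1L))
    for (p in names(ranges)) {
      params[[p]] <- runif(nSamples, ranges[[p]][1L], ranges[[p]][2L])
    }
    ab <- matrix(1, nrow = length(taxa), ncol = nSamples,
                 dimnames = list(taxa, as.character(params$date)))
    for (tx in names(plantedEffects)) {
      eff <- plantedEffects[[tx]]
      v <- params[[eff$parameter]]
      z <- (v - mean(v)) / sd(v)
      ab[tx, ] <- 1 + eff$slope * z + rnorm(nSamples, 0, noiseSd)
    }
    ab <- pmax(ab, 0)
    wts <- sweep(ab, 2L, colSums(ab), "/")
    effects <- if (length(plantedEffects)) {
      data.frame(taxon_id = names(plantedEffects),
                 parameter = vapply(plantedEffects, `[[`, "", "parameter"),
                 slope = vapply(plantedEffects, function(e) e$slope, 0),
                 row.names = NULL)
    } else {
      data.frame(taxon_id = character(), parameter = character(),
                 slope = numeric())
    }
    list(parameters = params, abundance = ab, weights = wts, effects = effects)
  })
}
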
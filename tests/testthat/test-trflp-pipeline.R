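test_that("detection filter enforces the size window and strict height threshold", {
  p <- trfProfile("S1", "AluI", "1", data.frame(
    size = c(40, 100, 100, 200, 1040),
    height = c(500, 50, 51, 60, 500),
    area = c(500, 50, 51, 60, 500)))
  f <- filterPeaks(p)
  expect_equal(peaks(f)$size, c(100, 200))    # 40 and 1040 out of window
  expect_equal(peaks(f)$height, c(51, 60))    # height exactly 50 removed
  expect_equal(totalFluorescence(f), 111)
})

test_that("replicate selection keeps the two strongest profiles above the gate", {
  mk <- function(tf, id) trfProfile("S", "AluI", id,
    data.frame(size = 100, height = tf, area = tf))
  sel <- selectReplicates(list(mk(600, "1"), mk(550, "2"), mk(400, "3")))
  expect_false(sel$rejected)
  expect_equal(vapply(sel$selected, totalFluorescence, 0), c(600, 550))

  rej <- selectReplicates(list(mk(600, "1"), mk(450, "2"), mk(400, "3")))
  expect_true(rej$rejected)

  tie <- selectReplicates(list(mk(600, "2"), mk(600, "1"), mk(100, "3")))
  expect_false(tie$rejected)
  expect_identical(vapply(tie$selected, function(p) p@replicateId, ""),
                   c("1", "2"))
})

test_that("iterative normalization reproduces the hand-traced example", {
  a <- trfProfile("S", "AluI", "1",
                  data.frame(size = 100, height = 1000, area = 1000))
  b <- trfProfile("S", "AluI", "2",
                  data.frame(size = c(100, 300), height = c(1910, 90),
                             area = c(1910, 90)))
  nm <- normalizeProfiles(list(a, b), floor = 50)
  # B scaled by 0.5 -> {955, 45}; 45 <= 50 deleted; A rescaled to 955
  expect_equal(peaks(nm$profiles[[1]])$height, 955)
  expect_equal(peaks(nm$profiles[[2]])$height, 955)
  expect_equal(nm$removedFraction, c(0, 90 / 2000))
  expect_false(any(nm$empty))
})

test_that("normalization has a fixed point and conserves its invariants", {
  mk <- function(hs, id) trfProfile("S", "AluI", id,
    data.frame(size = seq_along(hs) * 100, height = hs, area = hs))
  # equal loads, all peaks comfortably above the floor: unchanged
  eq <- normalizeProfiles(list(mk(c(400, 600), "1"), mk(c(500, 500), "2")))
  expect_equal(peaks(eq$profiles[[1]])$height, c(400, 600))
  expect_equal(eq$removedFraction, c(0, 0))
  # a single profile is its own minimum
  single <- normalizeProfiles(list(mk(c(400, 600), "1")))
  expect_equal(peaks(single$profiles[[1]])$height, c(400, 600))

  set.seed(31)
  for (i in 1:10) {
    profs <- lapply(1:3, function(j) {
      k <- sample(2:6, 1)
      mk(runif(k, 60, 800), as.character(j))
    })
    before <- lapply(profs, function(p) peaks(p)$height)
    nm <- normalizeProfiles(profs)
    for (j in 1:3) {
      after <- peaks(nm$profiles[[j]])$height
      expect_true(all(after <= max(before[[j]]) + 1e-9))
      expect_true(nm$removedFraction[j] >= 0 && nm$removedFraction[j] < 1)
    }
    tfs <- vapply(nm$profiles[!nm$empty], totalFluorescence, 0)
    expect_lt(diff(range(tfs)), 1e-9)  # all profiles end at the common minimum
    # re-running is a no-op (fixed point)
    again <- normalizeProfiles(nm$profiles[!nm$empty])
    expect_equal(lapply(again$profiles, function(p) peaks(p)$height),
                 lapply(nm$profiles[!nm$empty], function(p) peaks(p)$height))
  }
})

test_that("moving-average alignment merges within the gap and tracks the running mean", {
  a <- trfProfile("S", "AluI", "1",
                  data.frame(size = 183.1, height = 600, area = 600))
  b <- trfProfile("S", "AluI", "2",
                  data.frame(size = 183.4, height = 550, area = 550))
  bp <- alignPeaks(list(a, b), gap = 1.0)
  expect_length(bp@binCenters, 1)

  c1 <- trfProfile("S", "AluI", "1",
                   data.frame(size = 183.0, height = 600, area = 600))
  c2 <- trfProfile("S", "AluI", "2",
                   data.frame(size = 185.0, height = 550, area = 550))
  expect_length(alignPeaks(list(c1, c2), gap = 1.0)@binCenters, 2)

  # running-mean rule: 100.0 and 100.6 merge (mean 100.3); 101.4 is 1.1 away
  tr <- trfProfile("S", "AluI", "1", data.frame(
    size = c(100.0, 100.6, 101.4), height = c(100, 100, 100),
    area = c(100, 100, 100)))
  bp3 <- alignPeaks(list(tr), gap = 1.0)
  expect_equal(bp3@binCenters, c(100.3, 101.4))
  # two same-profile peaks in one bin are summed
  expect_equal(bp3@height[, 1], c(200, 100))
})

test_that("consensus keeps shared fragments and averages their properties", {
  mk <- function(hs, id) trfProfile("S", "AluI", id, data.frame(
    size = c(100, 200)[seq_along(hs)], height = hs, area = hs))
  bp <- alignPeaks(list(mk(c(80, 20), "1"), mk(c(60, 40), "2")))
  cons <- consensusProfile(bp)
  expect_equal(profileBins(cons)$height, c(70, 30))
  expect_equal(profileBins(cons)$rel_abundance, c(0.7, 0.3))
  expect_equal(sum(profileBins(cons)$rel_abundance), 1)

  # a fragment present in only one replicate is dropped
  one <- trfProfile("S", "AluI", "1", data.frame(
    size = c(100, 300), height = c(80, 70), area = c(80, 70)))
  two <- trfProfile("S", "AluI", "2", data.frame(
    size = 100, height = 60, area = 60))
  cons2 <- consensusProfile(alignPeaks(list(one, two)))
  expect_equal(profileBins(cons2)$bin_size, 100)

  # disjoint replicates give an empty consensus
  thr <- trfProfile("S", "AluI", "2", data.frame(
    size = 500, height = 60, area = 60))
  expect_identical(nrow(profileBins(consensusProfile(alignPeaks(list(one, thr))))), 0L)
})

test_that("the noiseless full loop recovers ground-truth abundances and drifted sizes", {
  sc <- noiselessScenario(weights = c(0.4, 0.25, 0.15, 0.1, 0.1), drift = 5)
  tab <- peakTable(renderElectropherograms(sc))
  res <- runPipeline(tab)
  taxa <- referenceTaxa(sc@reference)
  for (enz in c("AluI", "RsaI")) {
    cons <- res$consensus[[paste0("S1/", enz)]]
    bins <- profileBins(cons)
    trueSizes <- taxa[[paste0("trf_", enz)]] - sc@drift
    expect_equal(sort(bins$bin_size), sort(trueSizes))
    got <- bins$rel_abundance[match(trueSizes, bins$bin_size)]
    expect_equal(got, sc@weights, tolerance = 1e-12)
    expect_lt(max(abs(got - sc@weights)), 1e-9)
  }
})

test_that("the pipeline applies replicate QC and reports rejections", {
  sc <- noiselessScenario(weights = c(0.6, 0.4), drift = 0, seed = 3)
  tab <- peakTable(renderElectropherograms(sc))
  # push one replicate of each enzyme below the 500 FU gate
  weak <- tab$replicate == "3"
  tab$height_fu[weak] <- tab$height_fu[weak] * 0.1
  tab$area[weak] <- tab$area[weak] * 0.1
  res <- runPipeline(tab)
  expect_identical(nrow(res$qc$rejected), 0L)  # two good replicates remain
  expect_length(res$consensus, 2)

  # with two weak replicates the sample x enzyme is rejected
  weak2 <- tab$replicate %in% c("2", "3")
  tab$height_fu[weak2] <- 1
  res2 <- runPipeline(tab)
  expect_identical(sort(res2$qc$rejected$enzyme), c("AluI", "RsaI"))
  expect_length(res2$consensus, 0)

  empty <- runPipeline(peakTable(list()))
  expect_length(empty$consensus, 0)
  expect_identical(empty$qc$nSamples, 0L)
})

test_that("the pipeline is invariant to input row order and common rescaling", {
  sc <- noiselessScenario(weights = c(0.5, 0.3, 0.2), drift = 4, seed = 17)
  tab <- peakTable(renderElectropherograms(sc))
  res <- runPipeline(tab)
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  res2 <- runPipeline(shuffled)
  expect_equal(consensusTable(res$consensus), consensusTable(res2$consensus))

  scaled <- tab
  scaled$height_fu <- scaled$height_fu * 2
  scaled$area <- scaled$area * 2
  res3 <- runPipeline(scaled)
  for (key in names(res$consensus)) {
    expect_equal(profileBins(res3$consensus[[key]])$rel_abundance,
                 profileBins(res$consensus[[key]])$rel_abundance,
                 tolerance = 1e-12)
  }
})

test_that("peak tables round-trip through CSV and malformed rows are reported", {
  sc <- noiselessScenario(weights = c(0.7, 0.3), seed = 23)
  tab <- peakTable(renderElectropherograms(sc))
  path <- withr::local_tempfile(fileext = ".csv")
  writePeakTable(tab, path)
  back <- readPeakTable(path)
  expect_equal(back, tab, tolerance = 1e-12)

  bad <- readLines(path)
  bad[3] <- sub("^([^,]*,[^,]*,[^,]*,)[^,]*", "\\1oops", bad[3])
  badPath <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, badPath)
  expect_error(readPeakTable(badPath), "row 2")
})
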
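makeConsensus <- function(sizes, heights, sampleId = "S", enzyme = "AluI") {
  new("ConsensusProfile", sampleId = sampleId, enzyme = enzyme,
      bins = data.frame(bin_size = sizes, height = heights, area = heights,
                        rel_abundance = heights / sum(heights)))
}

test_that("Bray-Curtis distance matches its definition and bounds", {
  expect_equal(brayCurtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 100)
  expect_equal(brayCurtis(c(0.8, 0.2), c(0.6, 0.4)), 20)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "undefined")
  expect_error(brayCurtis(c(1, 0), c(1, 0, 0)), "equal length")

  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(6); q <- runif(6); s <- runif(6)
    expect_equal(brayCurtis(p, q),
                 100 * as.numeric(vegan::vegdist(rbind(p, q), "bray")))
    # symmetry, bounds, empirical triangle inequality
    expect_equal(brayCurtis(p, q), brayCurtis(q, p))
    expect_true(brayCurtis(p, q) >= 0 && brayCurtis(p, q) <= 100)
    pn <- p / sum(p); qn <- q / sum(q); sn <- s / sum(s)
    expect_lte(brayCurtis(pn, qn),
               brayCurtis(pn, sn) + brayCurtis(sn, qn) + 1e-9)
  }
})

test_that("profile series align consensus profiles onto a shared bin map", {
  cons <- list(makeConsensus(c(100, 200), c(600, 400)),
               makeConsensus(c(100.3, 200.2), c(500, 500)),
               makeConsensus(c(100.1, 300), c(700, 300)))
  dates <- as.Date(c("2003-05-16", "2003-06-16", "2003-07-16"))
  ser <- buildProfileSeries(cons, dates, normalize = FALSE)
  expect_length(ser@binSizes, 3)  # 100-ish, 200-ish, 300
  ab <- abundanceMatrix(ser)
  expect_equal(unname(colSums(ab)), rep(1, 3))
  expect_equal(unname(ab[, 1]), c(0.6, 0.4, 0))
  expect_equal(unname(ab[, 3]), c(0.7, 0, 0.3))
})

test_that("distance to baseline is zero for a constant series and spikes on deviation", {
  constant <- list(makeConsensus(c(100, 200), c(600, 400)),
                   makeConsensus(c(100, 200), c(600, 400)),
                   makeConsensus(c(100, 200), c(600, 400)))
  dates <- as.Date("2003-05-16") + c(0, 30, 60)
  d0 <- distanceToBaseline(buildProfileSeries(constant, dates,
                                              normalize = FALSE))
  expect_equal(d0$distance, c(0, 0, 0))

  # one-sample deviation and return
  spike <- list(makeConsensus(c(100, 200), c(600, 400)),
                makeConsensus(c(100, 200), c(100, 900)),
                makeConsensus(c(100, 200), c(600, 400)))
  ds <- distanceToBaseline(buildProfileSeries(spike, dates,
                                              normalize = FALSE))
  expect_equal(ds$distance[c(1, 3)], c(0, 0))
  expect_equal(ds$distance[2], brayCurtis(c(0.6, 0.4), c(0.1, 0.9)))

  # hand-computed values for known compositions
  ser <- buildProfileSeries(list(makeConsensus(c(100, 200), c(800, 200)),
                                 makeConsensus(c(100, 200), c(600, 400))),
                            dates[1:2], normalize = FALSE)
  expect_equal(distanceToBaseline(ser)$distance[2], 20)
})

test_that("dual-enzyme combinations are identified within the drift window", {
  db <- data.frame(
    seq_id = rep(c("sq1", "sq2", "sq3"), each = 2),
    enzyme = rep(c("AluI", "RsaI"), 3),
    status = c("ok", "ok", "ok", "ok", "ND", "OUT_OF_RANGE"),
    length_bases = c(180, 80, 188, 80, NA, 1500),
    label = rep(c("Methanosaeta", "Methanosarcina", "Unclassified"), each = 2))
  obs <- data.frame(alui = c(176, 176, NA), rsai = c(74, 74, NA))
  obs$alui[2] <- 176; obs$rsai[2] <- 74

  res <- identifyCombinations(obs[1, , drop = FALSE], db)
  # sq1: drifts 4 and 6, both inside [3, 7] -> candidate
  # sq2: AluI drift 12 -> excluded
  expect_identical(res$candidates[[1]]$seq_id, "sq1")
  expect_identical(res$table$candidates, "Methanosaeta")

  # out-of-range observation slots match ND/OUT_OF_RANGE predictions
  res2 <- identifyCombinations(data.frame(alui = NA, rsai = NA), db)
  expect_identical(res2$candidates[[1]]$seq_id, "sq3")

  # empty database leaves every combination unidentified
  emptyDb <- db[0, ]
  res3 <- identifyCombinations(obs, emptyDb)
  expect_true(all(vapply(res3$candidates, nrow, 0L) == 0L))

  # widening the window never removes a candidate
  narrow <- identifyCombinations(obs, db, driftWindow = c(4, 6))
  wide <- identifyCombinations(obs, db, driftWindow = c(2, 9))
  for (r in seq_len(nrow(obs))) {
    expect_true(all(narrow$candidates[[r]]$seq_id %in%
                      wide$candidates[[r]]$seq_id))
  }
})

test_that("fragment identification recovers planted taxa from a synthetic digest database", {
  ref <- makeReferenceTaxa(6, seed = 19)
  taxa <- referenceTaxa(ref)
  db <- digestDatabase(ref@sequences)
  drift <- 5
  obs <- data.frame(alui = taxa$trf_AluI[2] - drift,
                    rsai = taxa$trf_RsaI[2] - drift)
  labels <- setNames(taxa$name, taxa$taxon_id)
  res <- identifyCombinations(obs, db, labels = labels)
  expect_identical(res$candidates[[1]]$seq_id, taxa$taxon_id[2])
  expect_identical(res$candidates[[1]]$label, taxa$name[2])
})

test_that("correlation reproduces the closed-form Pearson statistics", {
  ab <- matrix(c(1, 2, 3, 4, 5) / 15, nrow = 1)
  dates <- as.Date("2003-05-16") + 7 * (0:4)
  rownames(ab) <- "184"; colnames(ab) <- as.character(dates)
  params <- data.frame(date = dates, temperature = c(12, 15, 11, 18, 16))
  res <- correlateParameters(ab, params)
  x <- ab[1, ]; y <- params$temperature
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, rHand, tolerance = 1e-12)
  ct <- cor.test(x, y)  # independent route for t and p
  expect_equal(res$t, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_identical(res$n_pairs, 5L)

  # exact linearity
  params2 <- data.frame(date = dates, temperature = c(1, 2, 3, 4, 5))
  res2 <- correlateParameters(ab, params2)
  expect_equal(res2$r, 1)
  expect_equal(res2$p, 0)

  # zero variance is flagged, not propagated as a number
  abc <- ab; abc[1, ] <- 0.2
  res3 <- correlateParameters(abc, params)
  expect_identical(res3$note, "zero_variance")
  expect_true(is.na(res3$r))
})

test_that("significance stars follow the conventional levels", {
  ab <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) / 55, nrow = 1)
  dates <- as.Date("2003-05-16") + 7 * (0:9)
  rownames(ab) <- "74"; colnames(ab) <- as.character(dates)
  params <- data.frame(date = dates,
                       temperature = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) +
                         c(0.1, -0.2, 0.15, 0, -0.1, 0.2, -0.15, 0.1, 0, -0.1))
  res <- correlateParameters(ab, params)
  expect_identical(res$stars, "***")
  expect_lt(res$p, 0.001)
})

test_that("the null correlation rejects at close to the nominal 5% level", {
  rejections <- 0L
  for (s in 1:100) {
    ps <- generateParameterSeries(30,
      list(tax01 = list(parameter = "temperature", slope = 0)),
      seed = s, noiseSd = 0.25)
    ct <- cor.test(ps$abundance["tax01", ], ps$parameters$temperature)
    if (ct$p.value < 0.05) rejections <- rejections + 1L
  }
  # Binomial(100, 0.05): central 99.9% region
  expect_gte(rejections, 0L)
  expect_lte(rejections, 13L)
})

test_that("a planted effect propagates through the full fingerprint series to the correlation table", {
  ref <- makeReferenceTaxa(3, seed = 29)
  taxa <- referenceTaxa(ref)
  ps <- generateParameterSeries(12,
    list(tax01 = list(parameter = "temperature", slope = 0.45)),
    seed = 29, taxa = taxa$taxon_id, noiseSd = 0)
  dates <- ps$parameters$date
  drift <- 4
  cons <- lapply(seq_along(dates), function(i) {
    makeConsensus(taxa$trf_AluI - drift, 1000 * ps$weights[, i],
                  sampleId = as.character(dates[i]))
  })
  ser <- buildProfileSeries(cons, dates, normalize = FALSE)
  res <- correlateParameters(ser, ps$parameters)
  res <- res[res$parameter == "temperature", ]
  trfOfTax1 <- format(taxa$trf_AluI[1] - drift, trim = TRUE)
  hit <- res[res$trf == trfOfTax1, ]
  expect_gt(hit$r, 0)
  expect_lt(hit$p, 0.05)
  expect_identical(hit$n_obs, 12L)
})
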
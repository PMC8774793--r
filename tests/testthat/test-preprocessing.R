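# Preprocessing: binning, reflectance correction, absorption, indices,
# light filter, grouped IQR filter, minute averaging.

test_that("spectra bin to even nanometres by averaging", {
  b <- binSpectrum(c(400.1, 400.3), c(10, 20))
  expect_equal(b$wavelength, 400L)
  expect_equal(b$signal, 15)

  b1 <- binSpectrum(500.0, 7)
  expect_equal(b1$signal, 7)

  # 0.46-nm grid with constant signal: every bin is the constant
  wl <- seq(400, 402, by = 0.46)
  b2 <- binSpectrum(wl, rep(7, length(wl)))
  expect_equal(b2$wavelength, c(400L, 402L))
  expect_equal(b2$signal, c(7, 7))

  # brute-force assignment oracle: nearest even, ties to the lower even
  set.seed(31)
  wlr <- runif(200, 400, 800)
  sg <- runif(200, 0, 4000)
  b3 <- binSpectrum(wlr, sg)
  oracleBin <- vapply(wlr, function(w) {
    cand <- seq(398L, 802L, by = 2L)
    d <- abs(cand - w)
    cand[which(d == min(d))[1L]]
  }, integer(1))
  oracle <- vapply(split(sg, oracleBin), mean, numeric(1))
  expect_equal(b3$signal, unname(oracle))
  expect_error(binSpectrum(numeric(0), numeric(0)), "empty")
})

test_that("reflectance correction divides by the nearest-PPFR reference", {
  ref <- toySpectrum()
  lut <- grayLookupTable(c(200, 1000), list(ref, toySpectrum(2)))
  expect_equal(nearestLookupEntry(lut, 900), 2L)   # nearest key 1000
  expect_equal(nearestLookupEntry(lut, 600), 1L)   # tie -> lower key

  r <- correctReflectance(ref, lut, 250)
  expect_equal(r$signal, rep(1, nrow(ref)))        # self-division
  half <- ref; half$signal <- 0.5 * ref$signal
  r2 <- correctReflectance(half, lut, 250)
  expect_equal(r2$signal, rep(0.5, nrow(ref)))

  # zero reference signal is masked, not infinite
  ref0 <- ref; ref0$signal[3] <- 0
  lut0 <- grayLookupTable(500, list(ref0))
  r3 <- correctReflectance(ref, lut0, 500)
  expect_true(is.na(r3$signal[3]))
  expect_false(any(is.infinite(r3$signal)))

  # field mode scales linearly over the grid
  lutF <- scaledLookupTable(ref, referencePPFR = 1000)
  expect_equal(lutF@ppfr, seq(200, 1500, by = 100))
  e <- lutF@spectra[[nearestLookupEntry(lutF, 410)]]
  expect_equal(e$signal, ref$signal * 0.4)
})

test_that("absorption is the banded-sum ratio", {
  ref <- flatSpectrum(1)
  zero <- ref; zero$signal[] <- 0
  expect_equal(computeAbsorption(zero, ref), 0)

  # constant spectra: bin-count ratio, the constant cancels
  cst <- flatSpectrum(3)
  nb <- function(lo, hi) sum(cst$wavelength >= lo & cst$wavelength <= hi)
  expect_equal(computeAbsorption(cst, cst),
               (nb(420, 500) + nb(640, 690)) / nb(400, 800))

  set.seed(5)
  pl <- toySpectrum(); pl$signal <- runif(nrow(pl), 0, 100)
  rf <- toySpectrum(); rf$signal <- runif(nrow(rf), 1, 100)
  oracle <- (sum(pl$signal[pl$wavelength >= 420 & pl$wavelength <= 500]) +
             sum(pl$signal[pl$wavelength >= 640 & pl$wavelength <= 690])) /
    sum(rf$signal)
  expect_equal(computeAbsorption(pl, rf), oracle, tolerance = 1e-12)
  expect_error(computeAbsorption(pl, zero), "denominator")
})

test_that("normalized-difference indices follow their band definitions", {
  s <- flatSpectrum(1)
  set <- function(sp, wl, v) { sp$signal[sp$wavelength == wl] <- v; sp }
  expect_equal(computeIndex(set(set(s, 530, 0.4), 570, 0.4), "PRI"), 0)
  expect_equal(computeIndex(set(set(s, 750, 0.5), 706, 0.1), "NDVI"),
               0.4 / 0.6, tolerance = 1e-12)
  expect_equal(computeIndex(set(set(s, 416, 0.04), 436, 0.06), "NPQI"),
               -0.2, tolerance = 1e-12)
  expect_true(is.na(computeIndex(set(set(s, 530, 0), 570, 0), "PRI")))

  # a flat reference cancels in the normalized difference: raw ("p")
  # and corrected index agree exactly
  pl <- toySpectrum()
  lut <- grayLookupTable(500, list(flatSpectrum(250)))
  corrected <- correctReflectance(pl, lut, 500)
  for (w in c("PRI", "NPQI", "NDVI")) {
    expect_equal(computeIndex(pl, w, raw = TRUE),
                 computeIndex(corrected, w), tolerance = 1e-12)
  }
})

test_that("light-adapted selection is strictly greater-than", {
  rec <- data.frame(timestamp = Sys.time() + 1:3, genotype = "A",
                    fqfm = 0.5, ppfr = c(100, 100.5, 80))
  out <- filterLightAdapted(rec)
  expect_equal(out$ppfr, 100.5)
  expect_equal(attr(out, "removed"), 2L)

  recN <- data.frame(ppfr = c(50, 99, 100, 101, 150, 200, 100.0001,
                              40, 60, 300), fqfm = 0.5)
  expect_equal(nrow(filterLightAdapted(recN)), 5L)  # 5 at or below 100
  expect_error(filterLightAdapted(data.frame(fqfm = 0.5)), "environment")
})

test_that("IQR fences match the brute-force quartile oracle", {
  f <- iqrFilter(c(1, 2, 3, 4, 100))
  expect_equal(f$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(f$fences$lower, 2 - 2.5 * 2)
  expect_equal(f$fences$upper, 4 + 2.5 * 2)

  # constant series: nothing removed
  expect_true(all(iqrFilter(rep(5, 10))$keep))

  # random series against the hand-written type-7 oracle
  set.seed(77)
  x <- c(rnorm(50), 8, -9)
  f2 <- iqrFilter(x)
  q1 <- oracleQuartile(x, 0.25); q3 <- oracleQuartile(x, 0.75)
  expect_equal(f2$fences$lower, q1 - 2.5 * (q3 - q1))
  expect_equal(f2$fences$upper, q3 + 2.5 * (q3 - q1))
  expect_equal(f2$keep, x >= q1 - 2.5 * (q3 - q1) & x <= q3 + 2.5 * (q3 - q1))

  # grouping respected: two groups clean in isolation, outlying jointly
  g1 <- c(1, 1.1, 0.9, 1.05, 0.95)
  g2 <- g1 + 100
  f3 <- iqrFilter(c(g1, g2), groups = rep(c("a", "b"), each = 5))
  expect_true(all(f3$keep))

  # groups smaller than 4 pass through
  f4 <- iqrFilter(c(1, 100, 2, 2.1, 1.9, 2.05, 50),
                  groups = c("s", "s", rep("big", 5)))
  expect_true(all(f4$keep[1:2]))
  expect_false(f4$fences$applied[f4$fences$group == "s"])
})

test_that("minute averaging groups by minute, replicate, treatment, genotype", {
  ts <- as.POSIXct("2017-06-01 11:05:10", tz = "UTC")
  rec <- data.frame(
    timestamp = c(ts, ts + 20, ts + 90),
    experiment_id = "E1", condition = "glasshouse_in", genotype = "A",
    treatment = "control", replicate_id = "R1",
    fqfm = c(0.4, 0.6, 0.9), pri = c(0, 0.2, 0.5), ppfr = 500,
    humidity = 60, temperature = 21)
  out <- averagePerMinute(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$fqfm, c(0.5, 0.9))
  expect_equal(out$pri, c(0.1, 0.5))
  expect_equal(out$n, c(2L, 1L))

  # single record unchanged
  one <- averagePerMinute(rec[3, ])
  expect_equal(one$fqfm, 0.9)

  # group-by mean oracle on a larger synthetic table
  cfg <- smallConfig(seed = 14)
  sim <- simulateExperiment(cfg)
  al <- alignEnvironment(sim$records, sim$weather)
  dup <- rbind(al, al)  # force group sizes of 2
  out2 <- averagePerMinute(dup)
  key <- paste(floor(as.numeric(al$timestamp) / 60), al$genotype,
               al$treatment, al$replicate_id)
  oracle <- tapply(al$fqfm, key, mean)
  key2 <- paste(floor(as.numeric(out2$timestamp) / 60), out2$genotype,
                out2$treatment, out2$replicate_id)
  expect_equal(out2$fqfm, as.vector(oracle[key2]), tolerance = 1e-12)
  expect_true(all(out2$n == 2L))
})

test_that("the preprocessing chain reports counts per step", {
  cfg <- smallConfig(seed = 15)
  sim <- simulateExperiment(cfg)
  al <- alignEnvironment(sim$records, sim$weather)
  pre <- preprocessRecords(al)
  rep <- attr(pre, "report")
  expect_true(any(grepl("light_adapted", rep)))
  expect_true(any(grepl("minute_averaged", rep)))
  expect_true(all(pre$ppfr > 100))
})
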
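# Energy cascade: ETR, seasonal ET, epsilon_e/t/c, energy accounting and
# genotype-adjusted means.

test_that("ETR is the four-factor product", {
  expect_equal(etr(0.5, 1000, energyConstants(epsilonI = 0.9)), 225)
  expect_equal(etr(0, 1000), 0)
  expect_equal(etr(0.4, 500, energyConstants(epsilonI = 1.0)), 100)
  expect_error(etr(1.2, 100), "fqfm")
  expect_error(etr(0.5, -1), "ppfr")
})

test_that("slope extrapolation is linear and clipped", {
  expect_equal(extrapolateFqFm(0, 0.7, c(0, 500, 2000)), rep(0.7, 3))
  expect_equal(extrapolateFqFm(-2e-4, 0.75, 1000), 0.55)
  expect_equal(extrapolateFqFm(-1e-2, 0.75, 2000), 0)  # clipped, not < 0
  expect_equal(extrapolateFqFm(1e-2, 0.75, 2000), 1)   # clipped above
})

test_that("the low-light intercept uses the strict threshold", {
  rec <- data.frame(fqfm = c(0.8, 0.7, 0.3), ppfr = c(50, 104.9, 105))
  expect_equal(lowLightIntercept(rec), 0.75)
  expect_true(is.na(lowLightIntercept(data.frame(fqfm = 0.5, ppfr = 200))))
})

test_that("seasonal ET sums 3600-second hours inside the window only", {
  sowing <- as.Date("2017-05-01"); harvest <- as.Date("2017-09-01")
  tIn <- as.POSIXct("2017-07-01 12:00:00", tz = "UTC")
  tOut <- as.POSIXct("2017-05-05 12:00:00", tz = "UTC")  # before DAS 21
  expect_equal(seasonalET(225, tIn, sowing, harvest), 810000)
  expect_equal(seasonalET(c(225, 500), c(tIn, tOut), sowing, harvest),
               810000)
  expect_error(seasonalET(225, tOut, sowing, sowing + 30), "window")

  # brute-force loop oracle over a toy 10-day hourly series
  ts <- seq(as.POSIXct("2017-06-10 00:00:00", tz = "UTC"),
            by = 3600, length.out = 240)
  set.seed(6)
  e <- runif(240, 0, 300)
  oracle <- 0
  for (i in seq_along(ts)) {
    d <- as.Date(ts[i], tz = "UTC")
    if (d >= sowing + 21 && d <= harvest - 21) oracle <- oracle + e[i] * 3600
  }
  expect_equal(seasonalET(e, ts, sowing, harvest), oracle)
})

test_that("epsilon_e is the PPFR-weighted mean and ignores epsilon_i", {
  expect_equal(epsilonE(rep(0.63, 5), c(0, 10, 500, 1500, 900)), 0.63)
  expect_equal(epsilonE(c(0.6, 0.4), c(500, 1500)), 0.45)
  expect_error(epsilonE(0.5, 0), "PPFR")

  # epsilon_i cancels: epsilon_e recomputed from ETR at any epsilon_i
  set.seed(7)
  fq <- runif(24, 0.3, 0.8); pp <- runif(24, 0, 1800)
  for (ei in c(0.5, 0.9, 1)) {
    kc <- energyConstants(epsilonI = ei)
    viaETR <- sum(etr(fq, pp, kc)) / (kc$psiiFraction * kc$epsilonI * sum(pp))
    expect_equal(viaETR, epsilonE(fq, pp), tolerance = 1e-12)
  }
})

test_that("biomass scales to total energy via root and stover fractions", {
  expect_equal(biomassToTotalEnergy(0.91, "maize", "shoot"), 18e6)
  expect_equal(biomassToTotalEnergy(0.52, "maize", "grain"), 18e6)
  expect_equal(biomassToTotalEnergy(0.83, "soybean", "shoot"), 18e6)
  expect_error(biomassToTotalEnergy(0.5, "maize", "grain",
                                    energyConstants(rootFractionMaize = 0.7)),
               "sum")
})

test_that("epsilon_t inverts the energy budget; epsilon_c is the product", {
  # cumulative PPFR energy of 2e9 J corresponds to 2e9/0.219 umol
  expect_equal(epsilonT(4.5e7, 0.5, 2e9 / 0.219,
                        energyConstants(epsilonI = 0.9)), 0.05)
  expect_equal(epsilonT(0, 0.5, 1e9), 0)
  expect_error(epsilonT(1e7, 0, 1e9), "> 0")

  expect_equal(round(epsilonC(0.527, 0.093), 3), 0.049)  # maize N22
  expect_equal(round(epsilonC(0.622, 0.049), 3), 0.030)  # soybean Ascasubi
  expect_equal(epsilonC(0, 0.5), 0)
  expect_equal(epsilonC(0.5, 0), 0)
  expect_error(epsilonC(1.2, 0.5), "\\[0, 1\\]")
})

test_that("noiseless generator round-trips through epsilonT to 6 digits", {
  cfg <- noiselessConfig(seed = 40, nGenotypes = 2)
  sim <- simulateExperiment(cfg)
  kc <- energyConstants()
  hp <- PhotoCascade:::.hourlyPPFR(sim$weather)
  win <- PhotoCascade:::.inSeasonWindow(hp$timestamp, cfg$sowing,
                                        cfg$harvest, kc)
  cumPPFR <- sum(hp$ppfr[win]) * 3600
  for (j in 1:2) {
    m <- mean(sim$biomass$mass[sim$biomass$genotype ==
                                 sim$truth$genotypes[j]])
    eT <- epsilonT(biomassToTotalEnergy(m, cfg$crop, cfg$measuredPart, kc),
                   sim$truth$epsilonE[j], cumPPFR, kc)
    expect_equal(eT, cfg$epsilonT[j], tolerance = 1e-7)
  }
})

test_that("genotype-adjusted efficiencies remove experiment offsets", {
  df <- expand.grid(genotype = c("A", "B", "C"), rep = 1:3,
                    experiment_id = "E1", stringsAsFactors = FALSE)
  df$eps <- c(A = 0.04, B = 0.06, C = 0.05)[df$genotype]
  out <- genotypeAdjustedEfficiencies(df, "eps")
  expect_equal(out$mean, c(0.04, 0.06, 0.05), tolerance = 1e-12)

  # constant offset in a second experiment leaves differences unchanged
  df2 <- df; df2$experiment_id <- "E2"; df2$eps <- df2$eps + 0.01
  out2 <- genotypeAdjustedEfficiencies(rbind(df, df2), "eps")
  expect_equal(diff(out2$mean), diff(out$mean), tolerance = 1e-12)

  # unbalanced design against a brute-force two-way LS oracle
  set.seed(8)
  dfu <- data.frame(
    genotype = c("A", "A", "B", "B", "B", "C", "A", "B", "C", "C"),
    experiment_id = c(rep("E1", 6), rep("E2", 4)),
    eps = runif(10, 0.02, 0.08))
  outU <- genotypeAdjustedEfficiencies(dfu, "eps")
  X <- model.matrix(~ genotype + experiment_id, dfu)
  bet <- solve(crossprod(X), crossprod(X, dfu$eps))
  oracle <- c(bet["(Intercept)", ] + 0.5 * bet["experiment_idE2", ],
              bet["(Intercept)", ] + bet["genotypeB", ] +
                0.5 * bet["experiment_idE2", ],
              bet["(Intercept)", ] + bet["genotypeC", ] +
                0.5 * bet["experiment_idE2", ])
  expect_equal(outU$mean, unname(oracle), tolerance = 1e-8)

  # genotype confined to one of several experiments is flagged
  dff <- rbind(dfu, data.frame(genotype = "D", experiment_id = "E2",
                               eps = 0.03))
  outF <- genotypeAdjustedEfficiencies(dff, "eps")
  expect_true(outF$flagged[outF$genotype == "D"])
  expect_false(any(outF$flagged[outF$genotype %in% c("A", "B")]))
})

test_that("predicted and extrapolated paths agree for a shared linear response", {
  cfg <- noiselessConfig(seed = 41, nGenotypes = 2)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  kc <- energyConstants()
  hp <- PhotoCascade:::.hourlyPPFR(sim$weather)
  win <- PhotoCascade:::.inSeasonWindow(hp$timestamp, cfg$sowing,
                                        cfg$harvest, kc)
  pp <- hp$ppfr[win]
  eff <- efficiencyFromFit(fit, sim$weather, cfg$sowing, cfg$harvest,
                           method = "predicted")
  sl <- responseSlopes(fit)
  for (j in 1:2) {
    # same intercept/slope fed to the extrapolation formula: identical
    fq <- extrapolateFqFm(sl$slope[j], sim$truth$a[j], pp)
    expect_equal(eff$epsilon_e[j], epsilonE(fq, pp), tolerance = 1e-9)
  }
})

test_that("proportionality: epsilon_e minus intercept scales with the slope", {
  set.seed(9)
  pp <- runif(200, 0, 1500)
  i0 <- 0.7
  slopes <- -c(0.5, 1, 1.5, 2) * 1e-4  # shallow: no clipping engaged
  ee <- vapply(slopes, function(b) epsilonE(extrapolateFqFm(b, i0, pp), pp),
               numeric(1))
  ratio <- (ee - i0) / slopes
  expect_equal(ratio, rep(ratio[1], 4), tolerance = 1e-10)
  # and the shared factor is sum(P^2)/sum(P)
  expect_equal(ratio[1], sum(pp^2) / sum(pp), tolerance = 1e-10)
})

test_that("the cascade ordering holds: epsilon_c never exceeds epsilon_e", {
  cfg <- smallConfig(seed = 42, nGenotypes = 3)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  eff <- efficiencyFromFit(fit, sim$weather, cfg$sowing, cfg$harvest,
                           biomass = sim$biomass, method = "predicted")
  expect_equal(eff$epsilon_c, eff$epsilon_e * eff$epsilon_t,
               tolerance = 1e-12)
  expect_true(all(eff$epsilon_t < 1))
  expect_true(all(eff$epsilon_c <= eff$epsilon_e))
  expect_true(all(eff$epsilon_e >= 0 & eff$epsilon_e <= 1))
})
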
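# G x E fixed-effects models: design construction, OLS, slope and
# adjusted-mean extraction, biomass correlation.

test_that("the design carries the stated interaction columns", {
  cfg <- smallConfig(seed = 20, nGenotypes = 2, nReplicates = 1)
  sim <- preprocessedExperiment(cfg)
  d <- buildDesign(sim$pre, "maize")
  expect_equal(sum(startsWith(colnames(d$X), "P:G:")), 2L)   # one GP per genotype
  expect_equal(sum(startsWith(colnames(d$X), "PI:G:")), 2L)  # one GPI per genotype
  expect_true(all(c("H", "P", "I", "N", "PI") %in% colnames(d$X)))

  cfg2 <- smallConfig(seed = 20, nGenotypes = 2, nReplicates = 2)
  sim2 <- preprocessedExperiment(cfg2)
  d2 <- buildDesign(sim2$pre, "soybean")
  expect_equal(sum(startsWith(colnames(d2$X), "P:GR:")), 4L)  # genotypes x replicates
  expect_equal(sum(startsWith(colnames(d2$X), "GR:")), 4L)

  # covariate entirely missing is named in the error
  broken <- sim$pre; broken$pndvi <- NA_real_
  expect_error(buildDesign(broken, "maize"), "pndvi")
})

test_that("noiseless data are interpolated exactly; constant response is flat", {
  cfg <- noiselessConfig(seed = 21, priNoiseSD = 0.01, priCoefMean = 0.15,
                         priCoefSD = 0.03, interceptSD = 0.02)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  expect_equal(fit@r.squared, 1, tolerance = 1e-9)
  expect_lt(fit@sigma, 1e-10)

  flat <- sim$pre; flat$fqfm <- 0.6
  fitF <- fitGxE(flat, "maize")
  co <- coef(fitF)
  expect_equal(unname(co["(Intercept)"]), 0.6, tolerance = 1e-10)
  expect_true(all(abs(co[-1][!is.na(co[-1])]) < 1e-10))
})

test_that("OLS coefficients equal the normal-equations oracle", {
  cfg <- smallConfig(seed = 22, nGenotypes = 3)
  sim <- preprocessedExperiment(cfg)
  d <- buildDesign(sim$pre, "maize")
  fit <- fitGxE(sim$pre, "maize")
  kept <- !is.na(coef(fit))
  Xk <- d$X[, kept, drop = FALSE]
  oracle <- solve(crossprod(Xk), crossprod(Xk, d$y))
  expect_equal(unname(coef(fit)[kept]), unname(drop(oracle)),
               tolerance = 1e-8)
  expect_error(fitGxE(sim$pre[0, ], "maize"), "missing|observations")
})

test_that("slopes match a finite-difference oracle on an independent lm fit", {
  cfg <- smallConfig(seed = 23, nGenotypes = 3)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  sl <- responseSlopes(fit)

  df <- sim$pre  # single experiment: no experiment term in the lm formula
  df$repf <- interaction(df$experiment_id, df$treatment, df$replicate_id)
  lmFit <- lm(fqfm ~ genotype + repf + humidity + ppfr +
                pri + pndvi + ppfr:pri + genotype:ppfr + genotype:pri +
                genotype:ppfr:pri, data = df)
  ref <- df[1, ]
  ref$humidity <- mean(df$humidity); ref$pri <- mean(df$pri)
  ref$pndvi <- mean(df$pndvi)
  for (i in seq_len(nrow(sl))) {
    nd <- ref[rep(1, 2), ]
    nd$genotype <- sl$genotype[i]
    nd$ppfr <- mean(df$ppfr) + c(0, 1)
    pr <- suppressWarnings(predict(lmFit, newdata = nd))
    expect_equal(sl$slope[i], unname(diff(pr)), tolerance = 1e-8)
  }
  expect_error(responseSlopes(fit, genotypes = "nope"), "absent")
})

test_that("slopes agree with emmeans::emtrends", {
  cfg <- smallConfig(seed = 29, nGenotypes = 3)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  sl <- responseSlopes(fit)

  df <- sim$pre  # single experiment: no experiment term in the lm formula
  df$repf <- interaction(df$experiment_id, df$treatment, df$replicate_id)
  lmFit <- lm(fqfm ~ genotype + repf + humidity + ppfr +
                pri + pndvi + ppfr:pri + genotype:ppfr + genotype:pri +
                genotype:ppfr:pri, data = df)
  em <- as.data.frame(emmeans::emtrends(lmFit, "genotype", var = "ppfr"))
  em <- em[match(sl$genotype, em$genotype), ]
  expect_equal(sl$slope, em$ppfr.trend, tolerance = 1e-8)
  expect_equal(sl$se, em$SE, tolerance = 1e-6)
})

test_that("noiseless slopes and the soybean plot-level variant recover truth", {
  cfg <- noiselessConfig(seed = 24, nGenotypes = 3, interceptSD = 0.02)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  sl <- responseSlopes(fit)
  expect_equal(sl$slope, sim$truth$b, tolerance = 1e-10)

  fitS <- fitGxE(sim$pre, "soybean")
  slS <- responseSlopes(fitS)
  expect_equal(nrow(slS), cfg$nGenotypes * cfg$nReplicates)
  g <- match(slS$genotype, sim$truth$genotypes)
  expect_equal(slS$slope, sim$truth$b[g], tolerance = 1e-8)
})

test_that("slopes ignore affine rescaling of additive covariates", {
  cfg <- smallConfig(seed = 25, nGenotypes = 3)
  sim <- preprocessedExperiment(cfg)
  sl1 <- responseSlopes(fitGxE(sim$pre, "maize"))
  scaled <- sim$pre
  scaled$humidity <- 3.7 * scaled$humidity - 12
  scaled$pndvi <- -2 * scaled$pndvi + 0.3
  sl2 <- responseSlopes(fitGxE(scaled, "maize"))
  expect_equal(sl1$slope, sl2$slope, tolerance = 1e-9)
})

test_that("adjusted means reduce to raw means when balanced; shift equivariant", {
  cfg <- noiselessConfig(seed = 26, nGenotypes = 3, interceptSD = 0.02,
                         slopeMean = 0, slopeSD = 0)
  sim <- preprocessedExperiment(cfg)
  fit <- fitGxE(sim$pre, "maize")
  am <- adjustedMeans(fit)
  raw <- tapply(sim$pre$fqfm, sim$pre$genotype, mean)
  # flat response in all covariates: adjusted = raw genotype means
  expect_equal(am$mean, as.vector(raw[am$genotype]), tolerance = 1e-9)

  shifted <- sim$pre; shifted$fqfm <- shifted$fqfm + 0.1
  am2 <- adjustedMeans(fitGxE(shifted, "maize"))
  expect_equal(am2$mean - am$mean, rep(0.1, 3), tolerance = 1e-9)
})

test_that("adjusted means match a brute-force reference-grid oracle", {
  # unbalanced two-experiment data: pool two simulated experiments with
  # different replicate counts
  cfgA <- smallConfig(seed = 27, nGenotypes = 3, nReplicates = 2,
                      experimentId = "EA")
  cfgB <- smallConfig(seed = 28, nGenotypes = 3, nReplicates = 1,
                      experimentId = "EB",
                      measurementDays = as.Date("2017-05-01") +
                        unique(round(seq(30, 70, length.out = 8))))
  simA <- preprocessedExperiment(cfgA)
  simB <- preprocessedExperiment(cfgB)
  pre <- rbind(simA$pre, simB$pre)
  fit <- fitGxE(pre, "maize")
  am <- adjustedMeans(fit)

  df <- pre
  df$repf <- interaction(df$experiment_id, df$treatment, df$replicate_id,
                         drop = TRUE)
  lmFit <- lm(fqfm ~ experiment_id + genotype + repf + humidity + ppfr +
                pri + pndvi + ppfr:pri + genotype:ppfr + genotype:pri +
                genotype:ppfr:pri, data = df)
  cells <- unique(df[, c("experiment_id", "treatment", "replicate_id",
                         "repf")])
  for (i in seq_len(nrow(am))) {
    nd <- cells
    nd$genotype <- am$genotype[i]
    nd$humidity <- mean(df$humidity); nd$ppfr <- mean(df$ppfr)
    nd$pri <- mean(df$pri); nd$pndvi <- mean(df$pndvi)
    pr <- suppressWarnings(predict(lmFit, newdata = nd))
    # equal weight per experiment, then per observed cell within it
    wExp <- 1 / length(unique(cells$experiment_id))
    w <- wExp / table(cells$experiment_id)[cells$experiment_id]
    expect_equal(am$mean[i], sum(as.numeric(w) * pr), tolerance = 1e-8)
  }
})

test_that("Pearson correlation with biomass follows the textbook formula", {
  est <- data.frame(genotype = letters[1:5], slope = c(1, 2, 3, 4, 5))
  bio <- data.frame(genotype = letters[1:5], mass = 2 * (1:5) + 1)
  expect_equal(correlateWithBiomass(est, bio)$r, 1)
  bio2 <- bio; bio2$mass <- -bio$mass
  expect_equal(correlateWithBiomass(est, bio2)$r, -1)

  est3 <- data.frame(genotype = letters[1:5],
                     slope = c(-2.1, -1.3, -3.7, -0.8, -2.9))
  bio3 <- data.frame(genotype = letters[1:5],
                     mass = c(0.91, 1.4, 0.52, 1.7, 0.77))
  x <- est3$slope; y <- bio3$mass
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlateWithBiomass(est3, bio3)$r, oracle,
               tolerance = 1e-12)

  expect_error(correlateWithBiomass(est[1:2, ], bio), ">= 3")
  flat <- est; flat$slope <- 1
  expect_true(is.na(correlateWithBiomass(flat, bio)$r))
})
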
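# Synthetic-season generator: environment, measurement campaigns and
# biomass with known ground truth for every downstream stage.
#
# The generative mean structure of Fq'/Fm' deliberately matches the
# analysis model's mean structure (linear in PPFR and PRI), so parameter
# recovery is a well-posed round trip; a `curvature` switch adds a mild
# saturating response as a misspecification stressor.

#' Configuration for a synthetic growing season
#'
#' Bundles every tunable of the generator: the season window, genotype and
#' replicate structure, the sparse measurement campaign (a subset of days,
#' hourly scan runs), the diurnal environment model, the genotype parameter
#' distributions for the Fq'/Fm' response, PRI seasonal drift, noise
#' standard deviations, and the true transduction efficiency used to
#' generate biomass.
#'
#' Defaults emulate a container/glasshouse soybean campaign: a 120-day
#' season, 8 genotypes in 2 replicates scanned hourly (09:00-16:00) on 30
#' days, a half-sinusoid diurnal PPFR peaking at 1600 umol m-2 s-1 scaled
#' by a day-level beta-distributed cloud multiplier, Fq'/Fm' near 0.78 at
#' low light declining ~1.8e-4 per unit PPFR, and a constant true
#' epsilon_t of 0.045.
#'
#' @param seed Integer RNG seed; all generator stages derive their streams
#'   from it (environment: `seed`, measurements: `seed + 1`,
#'   biomass: `seed + 2`).
#' @param sowing,harvest Season window (`Date`).
#' @param nGenotypes,nReplicates Genotype and replicate counts
#'   (`nGenotypes * nReplicates` must be at most 60: one scan minute each
#'   within a run hour).
#' @param measurementDays Dates with measurement runs (subset of the
#'   season); default 30 days evenly spaced between 25 and 95 days after
#'   sowing.
#' @param runHours Hours of day (0-23) at which scan runs start.
#' @param daylength,peakPPFR Daylight hours and clear-sky midday PPFR
#'   (umol photons m-2 s-1).
#' @param cloudMin,cloudMax,cloudShape1,cloudShape2 Day-level cloud
#'   multiplier `cloudMin + (cloudMax - cloudMin) * Beta(shape1, shape2)`.
#' @param tempMin,tempMax,humidityMin,humidityMax Diurnal temperature
#'   (degC) and relative humidity (%) ranges; temperature co-varies and
#'   humidity anti-varies with light.
#' @param interceptMean,interceptSD Genotype intercept a_g of Fq'/Fm' at
#'   zero light.
#' @param slopeMean,slopeSD Genotype slope b_g of Fq'/Fm' per unit PPFR
#'   (negative: decline with light).
#' @param priCoefMean,priCoefSD Genotype coefficient c_g of Fq'/Fm' on PRI.
#' @param pri0,priPerDAS,priPerPPFR,priNoiseSD PRI seasonal drift (linear
#'   in days after sowing) plus light-linked term and measurement noise.
#' @param priDaySD SD of the day-level random PRI component (canopy
#'   structure variation tracked by the spectra but not predictable from
#'   weather or calendar; it feeds Fq'/Fm' through `c_g`).
#' @param fqfmNoiseSD,indexNoiseSD Additive noise SDs for Fq'/Fm' and the
#'   other spectral indices.
#' @param epsilonT True transduction efficiency; scalar or one value per
#'   genotype.
#' @param epsilonI Light-interception efficiency used in the forward
#'   biomass model.
#' @param curvature Saturating-response switch: the mean response uses
#'   `P / (1 + curvature * P)` instead of `P`; 0 keeps the linear
#'   (well-specified) default.
#' @param biomassNoiseSD Multiplicative (mean-one lognormal) replicate
#'   noise on generated biomass.
#' @param crop,condition,experimentId,treatment,measuredPart Labels carried
#'   into the emitted record tables.
#' @return A validated `SynthConfig` list.
#' @export
synthConfig <- function(seed = 1L,
                        sowing = as.Date("2017-05-01"),
                        harvest = sowing + 119,
                        nGenotypes = 8L,
                        nReplicates = 2L,
                        measurementDays = NULL,
                        runHours = 9:16,
                        daylength = 14,
                        peakPPFR = 1600,
                        cloudMin = 0.25, cloudMax = 1,
                        cloudShape1 = 3, cloudShape2 = 1,
                        tempMin = 12, tempMax = 28,
                        humidityMin = 45, humidityMax = 95,
                        interceptMean = 0.78, interceptSD = 0.02,
                        slopeMean = -1.8e-4, slopeSD = 4e-5,
                        priCoefMean = 0.15, priCoefSD = 0.05,
                        pri0 = 0.02, priPerDAS = -8e-4,
                        priPerPPFR = -2e-5, priNoiseSD = 0.01,
                        priDaySD = 0.03,
                        fqfmNoiseSD = 0.03, indexNoiseSD = 0.01,
                        epsilonT = 0.045,
                        epsilonI = 0.9,
                        curvature = 0,
                        biomassNoiseSD = 0.05,
                        crop = "soybean",
                        condition = "glasshouse_in",
                        experimentId = "E1",
                        treatment = "control",
                        measuredPart = "shoot") {
  sowing <- as.Date(sowing); harvest <- as.Date(harvest)
  if (harvest <= sowing) stop("harvest must be after sowing", call. = FALSE)
  if (is.null(measurementDays)) {
    lastDas <- min(95, as.integer(harvest - sowing) - 5L)
    measurementDays <- sowing + unique(round(seq(25, lastDas, length.out = 30)))
  }
  measurementDays <- as.Date(measurementDays)
  if (any(measurementDays < sowing | measurementDays > harvest)) {
    stop("measurementDays must lie within the season", call. = FALSE)
  }
  for (nm in c("interceptSD", "slopeSD", "priCoefSD", "priNoiseSD",
               "priDaySD", "fqfmNoiseSD", "indexNoiseSD",
               "biomassNoiseSD")) {
    v <- get(nm)
    stopifnotScalarNumeric(v, nm)
    if (v < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (nGenotypes * nReplicates > 60) {
    stop("nGenotypes * nReplicates must be <= 60 (one scan minute each)",
         call. = FALSE)
  }
  if (!length(epsilonT) %in% c(1L, nGenotypes) || any(epsilonT < 0)) {
    stop("epsilonT must be a non-negative scalar or one value per genotype",
         call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed), sowing = sowing, harvest = harvest,
    nGenotypes = as.integer(nGenotypes),
    nReplicates = as.integer(nReplicates),
    measurementDays = measurementDays, runHours = as.integer(runHours),
    daylength = daylength, peakPPFR = peakPPFR,
    cloudMin = cloudMin, cloudMax = cloudMax,
    cloudShape1 = cloudShape1, cloudShape2 = cloudShape2,
    tempMin = tempMin, tempMax = tempMax,
    humidityMin = humidityMin, humidityMax = humidityMax,
    interceptMean = interceptMean, interceptSD = interceptSD,
    slopeMean = slopeMean, slopeSD = slopeSD,
    priCoefMean = priCoefMean, priCoefSD = priCoefSD,
    pri0 = pri0, priPerDAS = priPerDAS, priPerPPFR = priPerPPFR,
    priNoiseSD = priNoiseSD, priDaySD = priDaySD,
    fqfmNoiseSD = fqfmNoiseSD,
    indexNoiseSD = indexNoiseSD,
    epsilonT = rep_len(epsilonT, nGenotypes), epsilonI = epsilonI,
    curvature = curvature, biomassNoiseSD = biomassNoiseSD,
    crop = crop, condition = condition, experimentId = experimentId,
    treatment = treatment, measuredPart = measuredPart)
  class(cfg) <- "SynthConfig"
  cfg
}

# Saturating-response transform of PPFR used in the generative mean.
.pEff <- function(ppfr, curvature) {
  if (curvature == 0) ppfr else ppfr / (1 + curvature * ppfr)
}

#' Simulate minute-resolution weather for a whole season
#'
#' Deterministic given the config seed: PPFR follows a half-sinusoid
#' daylight shape scaled by a day-level cloud multiplier (zero at night),
#' temperature co-varies with light (lagged), humidity anti-varies.
#'
#' @param config A [synthConfig()] object.
#' @return A weather-record `data.frame` (one row per minute of the
#'   season) in the `weather` schema.
#' @export
simulateEnvironment <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  days <- seq(config$sowing, config$harvest, by = "day")
  nd <- length(days)
  drawn <- withSeed(config$seed, {
    list(cloud = config$cloudMin + (config$cloudMax - config$cloudMin) *
           rbeta(nd, config$cloudShape1, config$cloudShape2),
         humidityOffset = rnorm(nd, 0, 3))
  })
  cloud <- drawn$cloud
  minutes <- 0:1439
  hod <- minutes / 60
  sunrise <- 12 - config$daylength / 2
  frac <- (hod - sunrise) / config$daylength
  shape <- ifelse(frac > 0 & frac < 1, sinpi(frac), 0)
  fracLag <- (hod - sunrise - 1.5) / config$daylength
  shapeLag <- ifelse(fracLag > 0 & fracLag < 1, sinpi(fracLag), 0)
  # humidity follows its own diurnal phase (45 min behind the light) with
  # day-level offsets, so it is correlated with but never an exact
  # function of PPFR
  fracH <- (hod - sunrise - 0.75) / config$daylength
  shapeH <- ifelse(fracH > 0 & fracH < 1, sinpi(fracH), 0)
  dayIdx <- rep(seq_len(nd), each = length(minutes))
  cl <- cloud[dayIdx]
  sh <- rep(shape, nd)
  shL <- rep(shapeLag, nd)
  dayStart <- as.numeric(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"))
  ts <- as.POSIXct(dayStart[dayIdx] + rep(minutes, nd) * 60,
                   origin = "1970-01-01", tz = "UTC")
  ppfr <- config$peakPPFR * cl * sh
  temperature <- config$tempMin +
    (config$tempMax - config$tempMin) * (0.25 + 0.75 * cl * shL)
  humidity <- pmin(100, pmax(0, config$humidityMax -
    (config$humidityMax - config$humidityMin) *
      (0.2 + 0.8 * cl * rep(shapeH, nd)) +
    drawn$humidityOffset[dayIdx]))
  data.frame(timestamp = ts, condition = config$condition, ppfr = ppfr,
             temperature = temperature, humidity = humidity,
             stringsAsFactors = FALSE)
}

# Hourly PPFR means over the season (timestamp = hour start, date, hour).
.hourlyPPFR <- function(weather) {
  hrNum <- floor(as.numeric(weather$timestamp) / 3600)
  sums <- rowsum(cbind(ppfr = weather$ppfr, n = 1), hrNum)
  hrs <- as.numeric(rownames(sums))
  agg <- data.frame(timestamp = as.POSIXct(hrs * 3600,
                                           origin = "1970-01-01", tz = "UTC"),
                    ppfr = sums[, "ppfr"] / sums[, "n"])
  agg <- agg[order(agg$timestamp), , drop = FALSE]
  agg$date <- as.Date(agg$timestamp, tz = "UTC")
  agg$hour <- as.integer(hrs[order(hrs)] %% 24)
  rownames(agg) <- NULL
  agg
}

# Noiseless per-genotype epsilon_e over the germination->senescence window:
# the PPFR-weighted seasonal mean of the clipped true response.
.trueEpsilonE <- function(a, b, cc, config, weather, dayEffect = NULL,
                          constants = energyConstants()) {
  hp <- .hourlyPPFR(weather)
  win <- hp$date >= config$sowing + constants$germinationOffset &
    hp$date <= config$harvest - constants$senescenceOffset
  hp <- hp[win, , drop = FALSE]
  das <- as.numeric(hp$date - config$sowing)
  if (is.null(dayEffect)) dayEffect <- rep(0, max(das) + 1L)
  priTrue <- config$pri0 + config$priPerDAS * das +
    config$priPerPPFR * hp$ppfr + dayEffect[das + 1L]
  pe <- .pEff(hp$ppfr, config$curvature)
  denom <- sum(hp$ppfr)
  vapply(seq_along(a), function(g) {
    fq <- clip01(a[g] + b[g] * pe + cc[g] * priTrue)
    sum(fq * hp$ppfr) / denom
  }, numeric(1))
}

#' Simulate a sparse measurement campaign with known truth
#'
#' Generates fluorescence/spectral records on the configured measurement
#' days and run hours only. Each genotype x replicate is scanned in its
#' own minute within the run hour. Fq'/Fm' follows the genotype response
#' `a_g + b_g * PPFR + c_g * PRI` plus noise, clipped to \[0, 1\]; PRI
#' drifts linearly over the season with a light-linked term. Only
#' light-adapted records (PPFR > 100 umol m-2 s-1) are emitted.
#'
#' @param config A [synthConfig()] object.
#' @param weather Minute-resolution weather covering the measurement days
#'   (from [simulateEnvironment()]).
#' @return A list with `records` (lift schema, environment not attached)
#'   and `truth` (class `SynthTruth`): per-genotype `a`, `b`, `c`, true
#'   `epsilonT`, noiseless seasonal `epsilonE`, the clipped fraction and
#'   the noise SDs.
#' @export
simulateMeasurements <- function(config, weather) {
  stopifnot(inherits(config, "SynthConfig"))
  nG <- config$nGenotypes; nR <- config$nReplicates
  genotypes <- sprintf("G%02d", seq_len(nG))
  replicates <- sprintf("R%d", seq_len(nR))
  res <- withSeed(config$seed + 1L, {
    a <- rnorm(nG, config$interceptMean, config$interceptSD)
    b <- rnorm(nG, config$slopeMean, config$slopeSD)
    cc <- rnorm(nG, config$priCoefMean, config$priCoefSD)
    nSeasonDays <- as.integer(config$harvest - config$sowing) + 1L
    dayEff <- rnorm(nSeasonDays, 0, config$priDaySD)

    scan <- expand.grid(replicate = seq_len(nR), genotype = seq_len(nG),
                        KEEP.OUT.ATTRS = FALSE)
    scan$slot <- seq_len(nrow(scan)) - 1L
    grid <- expand.grid(slot = scan$slot, hour = config$runHours,
                        day = config$measurementDays,
                        KEEP.OUT.ATTRS = FALSE)
    grid$genotype <- scan$genotype[grid$slot + 1L]
    grid$replicate <- scan$replicate[grid$slot + 1L]
    ts <- as.POSIXct(paste(grid$day, "00:00:00"), tz = "UTC") +
      grid$hour * 3600 + grid$slot * 60

    wKey <- paste0(floor(as.numeric(weather$timestamp) / 60), "|",
                   weather$condition)
    idx <- match(paste0(floor(as.numeric(ts) / 60), "|", config$condition),
                 wKey)
    if (anyNA(idx)) {
      stop("weather does not cover all measurement minutes", call. = FALSE)
    }
    ppfr <- weather$ppfr[idx]
    das <- as.numeric(grid$day - config$sowing)
    n <- length(ppfr)
    pri <- config$pri0 + config$priPerDAS * das + config$priPerPPFR * ppfr +
      dayEff[das + 1L] + rnorm(n, 0, config$priNoiseSD)
    pndvi <- pmin(1, pmax(-1, 0.5 + 0.002 * das - 1e-5 * ppfr +
                            rnorm(n, 0, config$indexNoiseSD)))
    npqi <- pmin(1, pmax(-1, -0.05 + rnorm(n, 0, config$indexNoiseSD)))
    ndvi <- pmin(1, pmax(-1, 0.7 + 0.001 * das +
                           rnorm(n, 0, config$indexNoiseSD)))
    absorption <- clip01(0.8 + rnorm(n, 0, config$indexNoiseSD))
    irradiance680 <- pmax(0, 0.4 * ppfr + rnorm(n, 0, 5))
    g <- grid$genotype
    fqRaw <- a[g] + b[g] * .pEff(ppfr, config$curvature) + cc[g] * pri +
      rnorm(n, 0, config$fqfmNoiseSD)
    fq <- clip01(fqRaw)
    clippedFraction <- mean(fqRaw != fq)

    records <- data.frame(
      timestamp = ts,
      experiment_id = config$experimentId,
      condition = config$condition,
      genotype = genotypes[g],
      treatment = config$treatment,
      replicate_id = replicates[grid$replicate],
      fqfm = fq, pri = pri, pndvi = pndvi, npqi = npqi, ndvi = ndvi,
      absorption = absorption, irradiance_680 = irradiance680,
      stringsAsFactors = FALSE)
    lightAdapted <- ppfr > 100
    records <- records[lightAdapted, , drop = FALSE]
    rownames(records) <- NULL
    list(records = records, a = a, b = b, cc = cc, dayEffect = dayEff,
         clippedFraction = clippedFraction)
  })
  truth <- list(
    genotypes = genotypes, a = res$a, b = res$b, c = res$cc,
    priDayEffect = res$dayEffect,
    epsilonT = config$epsilonT,
    epsilonE = .trueEpsilonE(res$a, res$b, res$cc, config, weather,
                             dayEffect = res$dayEffect),
    clippedFraction = res$clippedFraction,
    fqfmNoiseSD = config$fqfmNoiseSD, priNoiseSD = config$priNoiseSD)
  class(truth) <- "SynthTruth"
  list(records = res$records, truth = truth)
}

#' Generate biomass from the configured truth by the forward energy model
#'
#' Applies the efficiency cascade forwards: cumulative in-window PPFR
#' (umol m-2, hourly means x 3600 s) is converted to energy at 0.219 J
#' umol-1, multiplied by epsilon_i, the genotype's noiseless seasonal
#' epsilon_e and its true epsilon_t, converted to dry mass at 18 MJ kg-1,
#' and reduced to the measured plant part via the root (and, for
#' field-maize grain, stover) fraction. The efficiency module's
#' [epsilonT()] inverts this construction exactly on noiseless input.
#'
#' @param truth A `SynthTruth` object from [simulateMeasurements()].
#' @param config The matching [synthConfig()].
#' @param weather Minute-resolution season weather.
#' @param constants An [energyConstants()] set.
#' @return A biomass-record `data.frame` (one row per genotype x
#'   replicate) in the `biomass` schema.
#' @export
generateBiomass <- function(truth, config, weather,
                            constants = energyConstants()) {
  stopifnot(inherits(truth, "SynthTruth"), inherits(config, "SynthConfig"))
  hp <- .hourlyPPFR(weather)
  win <- hp$date >= config$sowing + constants$germinationOffset &
    hp$date <= config$harvest - constants$senescenceOffset
  cumPPFR <- sum(hp$ppfr[win]) * 3600
  nG <- config$nGenotypes
  energy <- cumPPFR * constants$joulesPerUmol * config$epsilonI *
    truth$epsilonE * truth$epsilonT
  totalMass <- energy / constants$biomassEnergy
  root <- if (config$crop == "maize") constants$rootFractionMaize else
    constants$rootFractionSoybean
  frac <- if (config$crop == "maize" && config$measuredPart == "grain") {
    1 - root - constants$stoverFractionMaizeField
  } else {
    1 - root
  }
  measured <- totalMass * frac
  out <- expand.grid(replicate = seq_len(config$nReplicates),
                     genotype = seq_len(nG), KEEP.OUT.ATTRS = FALSE)
  noise <- withSeed(config$seed + 2L, {
    sdl <- config$biomassNoiseSD
    if (sdl > 0) exp(rnorm(nrow(out), 0, sdl) - sdl^2 / 2) else
      rep(1, nrow(out))
  })
  data.frame(
    experiment_id = config$experimentId,
    genotype = truth$genotypes[out$genotype],
    treatment = config$treatment,
    replicate_id = sprintf("R%d", out$replicate),
    crop = config$crop,
    measured_part = config$measuredPart,
    mass = measured[out$genotype] * noise,
    sowing_date = config$sowing,
    harvest_date = config$harvest,
    stringsAsFactors = FALSE)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper chaining [simulateEnvironment()],
#' [simulateMeasurements()] and [generateBiomass()].
#'
#' @param config A [synthConfig()] object.
#' @param constants An [energyConstants()] set used by the forward
#'   biomass model.
#' @return A list with `weather`, `records`, `biomass`, `truth`, `config`.
#' @export
simulateExperiment <- function(config, constants = energyConstants()) {
  weather <- simulateEnvironment(config)
  sim <- simulateMeasurements(config, weather)
  biomass <- generateBiomass(sim$truth, config, weather, constants)
  list(weather = weather, records = sim$records, biomass = biomass,
       truth = sim$truth, config = config)
}

#' Write the generator's ground truth as a plain-text sidecar
#'
#' One key/value or genotype-row entry per line (tab-separated), so test
#' harnesses outside R can read the hidden parameters.
#'
#' @param truth A `SynthTruth` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(inherits(truth, "SynthTruth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("clippedFraction\t%.6g", truth$clippedFraction), con)
  writeLines(sprintf("fqfmNoiseSD\t%.6g", truth$fqfmNoiseSD), con)
  writeLines("genotype\ta\tb\tc\tepsilonT\tepsilonE", con)
  writeLines(sprintf("%s\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                     truth$genotypes, truth$a, truth$b, truth$c,
                     truth$epsilonT, truth$epsilonE), con)
  invisible(path)
}
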
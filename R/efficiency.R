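# Energy-conversion cascade: ETR, seasonal electron transport, epsilon_e
# (intercepted light -> photochemical energy), epsilon_t (photochemical
# energy -> biomass energy) and epsilon_c = epsilon_e * epsilon_t.
#
# Unit convention: cumulative PPFR is carried in umol photons m-2 and
# converted to joules (0.219 J umol-1) only inside epsilonT(), so the
# conversion factor can never be applied twice.

#' Energy-accounting constants
#'
#' The fixed conventions of the cascade: the fraction of PPFR reaching
#' photosystem II (0.5), the assumed light-interception efficiency
#' (epsilon_i = 0.9), the photon energy conversion (0.219 J umol-1), the
#' energy content of dry biomass (18 MJ kg-1), root fractions of total
#' biomass (maize 9%, soybean 17%), the field-maize stover fraction
#' (39%), the growing-season window (germination 21 days after sowing to
#' senescence 21 days before harvest) and the low-light threshold for the
#' common intercept (PPFR < 105 umol m-2 s-1).
#'
#' @param psiiFraction,epsilonI,joulesPerUmol,biomassEnergy,rootFractionMaize,rootFractionSoybean,stoverFractionMaizeField,germinationOffset,senescenceOffset,lowLightThreshold
#'   Overrides for individual constants.
#' @return A validated list of class `EnergyConstants`.
#' @export
energyConstants <- function(psiiFraction = 0.5,
                            epsilonI = 0.9,
                            joulesPerUmol = 0.219,
                            biomassEnergy = 18e6,
                            rootFractionMaize = 0.09,
                            rootFractionSoybean = 0.17,
                            stoverFractionMaizeField = 0.39,
                            germinationOffset = 21,
                            senescenceOffset = 21,
                            lowLightThreshold = 105) {
  k <- list(psiiFraction = psiiFraction, epsilonI = epsilonI,
            joulesPerUmol = joulesPerUmol, biomassEnergy = biomassEnergy,
            rootFractionMaize = rootFractionMaize,
            rootFractionSoybean = rootFractionSoybean,
            stoverFractionMaizeField = stoverFractionMaizeField,
            germinationOffset = germinationOffset,
            senescenceOffset = senescenceOffset,
            lowLightThreshold = lowLightThreshold)
  fr <- c("psiiFraction", "epsilonI", "rootFractionMaize",
          "rootFractionSoybean", "stoverFractionMaizeField")
  for (nm in fr) {
    if (k[[nm]] < 0 || k[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (germinationOffset < 0 || senescenceOffset < 0) {
    stop("window offsets must be >= 0", call. = FALSE)
  }
  class(k) <- "EnergyConstants"
  k
}

#' @export
print.EnergyConstants <- function(x, ...) {
  cat("EnergyConstants:\n")
  for (nm in names(x)) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Electron transport rate through photosystem II
#'
#' `ETR = Fq'/Fm' x PPFR x 0.5 x epsilon_i` in umol electrons m-2 s-1:
#' half the photon flux is apportioned to PSII and epsilon_i of the
#' incident flux is intercepted.
#'
#' @param fqfm Operating efficiency of PSII (fraction in \[0, 1\]).
#' @param ppfr Photosynthetic photon fluence rate (umol m-2 s-1, >= 0).
#' @param constants An [energyConstants()] set.
#' @return ETR (vectorized over `fqfm`/`ppfr`).
#' @export
etr <- function(fqfm, ppfr, constants = energyConstants()) {
  if (any(fqfm < 0 | fqfm > 1, na.rm = TRUE)) {
    stop("fqfm must lie in [0, 1]", call. = FALSE)
  }
  if (any(ppfr < 0, na.rm = TRUE)) stop("ppfr must be >= 0", call. = FALSE)
  fqfm * ppfr * constants$psiiFraction * constants$epsilonI
}

#' Extrapolate hourly Fq'/Fm' from a response slope
#'
#' The simple seasonal extrapolation: `fqfm = intercept + slope x PPFR`,
#' clipped to \[0, 1\]. The intercept is the crop's common low-light
#' Fq'/Fm' (see [lowLightIntercept()]).
#'
#' @param slope Genotype response slope ((umol m-2 s-1)^-1).
#' @param intercept Common low-light intercept (fraction).
#' @param ppfr Hourly PPFR series.
#' @return Hourly Fq'/Fm' series in \[0, 1\].
#' @export
extrapolateFqFm <- function(slope, intercept, ppfr) {
  clip01(intercept + slope * ppfr)
}

#' Common low-light Fq'/Fm' intercept
#'
#' The mean Fq'/Fm' of all records measured below the low-light threshold
#' (PPFR < 105 umol m-2 s-1, strict) over the season -- the crop-level
#' intercept of the slope extrapolation.
#'
#' @param records Lift records with environment attached.
#' @param constants An [energyConstants()] set.
#' @return Mean low-light Fq'/Fm' (`NA` if no record qualifies).
#' @export
lowLightIntercept <- function(records, constants = energyConstants()) {
  sel <- records$ppfr < constants$lowLightThreshold
  if (!any(sel, na.rm = TRUE)) return(NA_real_)
  mean(records$fqfm[which(sel)], na.rm = TRUE)
}

# Germination -> senescence window membership for a timestamp series.
.inSeasonWindow <- function(timestamps, sowing, harvest,
                            constants = energyConstants()) {
  d <- as.Date(timestamps, tz = "UTC")
  d >= as.Date(sowing) + constants$germinationOffset &
    d <= as.Date(harvest) - constants$senescenceOffset
}

#' Cumulative seasonal electron transport
#'
#' `Seasonal ET = sum(ETR x 3600 s)` over the hours between germination
#' (21 days after sowing) and senescence (21 days before harvest), in
#' umol electrons m-2.
#'
#' @param etrHourly Hourly ETR series (umol m-2 s-1).
#' @param timestamps Matching hourly timestamps.
#' @param sowing,harvest Season dates.
#' @param constants An [energyConstants()] set.
#' @return Seasonal ET (scalar).
#' @export
seasonalET <- function(etrHourly, timestamps, sowing, harvest,
                       constants = energyConstants()) {
  win <- .inSeasonWindow(timestamps, sowing, harvest, constants)
  if (!any(win)) {
    stop("empty germination-senescence window", call. = FALSE)
  }
  sum(etrHourly[win] * 3600, na.rm = TRUE)
}

#' Conversion efficiency of intercepted light to photochemical energy
#'
#' The PPFR-weighted seasonal mean of Fq'/Fm' over the
#' germination-senescence window:
#' `epsilon_e = sum(fqfm x PPFR) / sum(PPFR)`. The interception
#' efficiency epsilon_i cancels from numerator and denominator, so
#' epsilon_e does not depend on it.
#'
#' @param fqfmHourly Hourly (predicted) Fq'/Fm' series.
#' @param ppfrHourly Matching hourly PPFR series.
#' @param timestamps Optional hourly timestamps; with `sowing`/`harvest`
#'   the window restriction is applied, otherwise all hours enter.
#' @param sowing,harvest Season dates (optional, see `timestamps`).
#' @param constants An [energyConstants()] set.
#' @return epsilon_e (fraction).
#' @export
epsilonE <- function(fqfmHourly, ppfrHourly, timestamps = NULL,
                     sowing = NULL, harvest = NULL,
                     constants = energyConstants()) {
  if (!is.null(timestamps) && !is.null(sowing)) {
    win <- .inSeasonWindow(timestamps, sowing, harvest, constants)
    fqfmHourly <- fqfmHourly[win]
    ppfrHourly <- ppfrHourly[win]
  }
  ok <- !is.na(fqfmHourly) & !is.na(ppfrHourly)
  denom <- sum(ppfrHourly[ok])
  if (denom <= 0) stop("zero cumulative PPFR", call. = FALSE)
  sum(fqfmHourly[ok] * ppfrHourly[ok]) / denom
}

#' Total biomass energy from a measured plant part
#'
#' Scales the measured dry mass up to total biomass via the root-fraction
#' convention (and the stover fraction for field-maize grain), then
#' converts to energy at 18 MJ kg-1.
#'
#' @param mass Measured dry mass (kg m-2).
#' @param crop `"maize"` or `"soybean"`.
#' @param measuredPart `"shoot"` or `"grain"` (grain only for maize).
#' @param constants An [energyConstants()] set.
#' @return Total biomass energy (J m-2), vectorized over `mass`.
#' @export
biomassToTotalEnergy <- function(mass, crop, measuredPart = "shoot",
                                 constants = energyConstants()) {
  crop <- match.arg(crop, c("maize", "soybean"))
  measuredPart <- match.arg(measuredPart, c("shoot", "grain"))
  root <- if (crop == "maize") constants$rootFractionMaize else
    constants$rootFractionSoybean
  frac <- if (crop == "maize" && measuredPart == "grain") {
    1 - root - constants$stoverFractionMaizeField
  } else {
    1 - root
  }
  if (frac <= 0) stop("component fractions sum to >= 1", call. = FALSE)
  if (any(mass <= 0, na.rm = TRUE)) stop("mass must be > 0", call. = FALSE)
  (mass / frac) * constants$biomassEnergy
}

#' Transduction efficiency of photochemical energy into biomass
#'
#' Inverts the forward energy model:
#' `epsilon_t = total_energy / (epsilon_e x epsilon_i x cumulative_PPFR
#'  x 0.219)`, with cumulative PPFR supplied in umol photons m-2 (the
#' joule conversion happens here and only here).
#'
#' @param totalEnergy Total biomass energy (J m-2, >= 0).
#' @param epsilonE Seasonal epsilon_e (fraction, > 0).
#' @param cumulativePPFR Seasonal cumulative PPFR (umol photons m-2, > 0).
#' @param constants An [energyConstants()] set.
#' @return epsilon_t (fraction).
#' @export
epsilonT <- function(totalEnergy, epsilonE, cumulativePPFR,
                     constants = energyConstants()) {
  if (any(epsilonE <= 0) || any(cumulativePPFR <= 0)) {
    stop("epsilonE and cumulativePPFR must be > 0", call. = FALSE)
  }
  totalEnergy / (epsilonE * constants$epsilonI * cumulativePPFR *
                   constants$joulesPerUmol)
}

#' Conversion efficiency of intercepted light into biomass
#'
#' `epsilon_c = epsilon_e x epsilon_t`.
#'
#' @param epsilonE,epsilonT Component efficiencies (fractions in
#'   \[0, 1\]).
#' @return epsilon_c, vectorized.
#' @export
epsilonC <- function(epsilonE, epsilonT) {
  if (any(epsilonE < 0 | epsilonE > 1, na.rm = TRUE) ||
      any(epsilonT < 0 | epsilonT > 1, na.rm = TRUE)) {
    stop("efficiencies must lie in [0, 1]", call. = FALSE)
  }
  epsilonE * epsilonT
}

#' Genotype-adjusted efficiency means across experiments
#'
#' Two-way fixed-effects fit (genotype + experiment) on replicate-level
#' efficiency values; genotype marginal means are predictions averaged
#' with equal weight over the experiment levels, with delta-method
#' standard errors. A genotype observed in only one of several
#' experiments is flagged (its mean rests on the additivity assumption).
#'
#' @param results A `data.frame` with `genotype`, `experiment_id` and the
#'   value column.
#' @param valueCol Name of the value column (e.g. `"epsilon_t"`).
#' @return A `data.frame`: `genotype`, `mean`, `se`, `n`, `flagged`.
#' @export
genotypeAdjustedEfficiencies <- function(results, valueCol) {
  if (!valueCol %in% names(results)) {
    stop("no column '", valueCol, "' in results", call. = FALSE)
  }
  df <- data.frame(y = results[[valueCol]],
                   genotype = factor(results$genotype),
                   experiment = factor(results$experiment_id))
  df <- df[complete.cases(df), , drop = FALSE]
  nExp <- nlevels(df$experiment)
  fit <- if (nExp > 1L) lm(y ~ genotype + experiment, data = df) else
    lm(y ~ genotype, data = df)
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  V <- vcov(fit)
  Vfull <- matrix(0, length(beta), length(beta),
                  dimnames = list(names(beta), names(beta)))
  Vfull[rownames(V), colnames(V)] <- V
  genLevels <- levels(df$genotype)
  expLevels <- levels(df$experiment)
  out <- lapply(genLevels, function(g) {
    cvec <- setNames(numeric(length(beta)), names(beta))
    cvec["(Intercept)"] <- 1
    gn <- paste0("genotype", g)
    if (gn %in% names(cvec)) cvec[gn] <- 1
    for (e in expLevels[-1L]) {
      cvec[paste0("experiment", e)] <- 1 / nExp
    }
    seen <- unique(df$experiment[df$genotype == g])
    data.frame(genotype = g,
               mean = sum(cvec * beta),
               se = sqrt(max(0, drop(cvec %*% Vfull %*% cvec))),
               n = sum(df$genotype == g),
               flagged = nExp > 1L && length(seen) == 1L)
  })
  do.call(rbind, out)
}

#' Seasonal efficiencies per genotype from a fitted G x E model
#'
#' Closes the energy budget for every genotype: hourly Fq'/Fm' over the
#' season is obtained either from the model's own genotype predictions
#' (`method = "predicted"`: adjusted prediction at each hourly PPFR,
#' other covariates at their grand means) or from the slope extrapolation
#' with the crop's common low-light intercept (`method =
#' "extrapolated"`). From there: seasonal ET, epsilon_e, and -- when
#' biomass records are supplied -- epsilon_t and epsilon_c.
#'
#' @param fit A [GxEFit-class] object.
#' @param weather Minute-resolution season weather.
#' @param sowing,harvest Season dates.
#' @param biomass Optional biomass records for the same genotypes.
#' @param records Records used for the common intercept
#'   (`method = "extrapolated"` only; must include the low-light range).
#' @param method `"predicted"` or `"extrapolated"`.
#' @param constants An [energyConstants()] set.
#' @return A `data.frame`: one row per genotype with `seasonal_et`
#'   (umol electrons m-2), `cumulative_ppfr` (umol photons m-2),
#'   `epsilon_e`, and (with biomass) `epsilon_t`, `epsilon_c`, `method`.
#' @export
efficiencyFromFit <- function(fit, weather, sowing, harvest, biomass = NULL,
                              records = NULL,
                              method = c("predicted", "extrapolated"),
                              constants = energyConstants()) {
  method <- match.arg(method)
  stopifnot(is(fit, "GxEFit"))
  hp <- .hourlyPPFR(weather)
  win <- .inSeasonWindow(hp$timestamp, sowing, harvest, constants)
  hp <- hp[win, , drop = FALSE]
  cumPPFR <- sum(hp$ppfr) * 3600
  genotypes <- fit@meta$genLevels

  if (method == "extrapolated") {
    if (is.null(records)) {
      stop("records needed to estimate the common low-light intercept",
           call. = FALSE)
    }
    intercept <- lowLightIntercept(records, constants)
    if (is.na(intercept)) {
      stop("no low-light records below the intercept threshold",
           call. = FALSE)
    }
    slopes <- responseSlopes(fit)
    slopeG <- vapply(split(slopes$slope, slopes$genotype), mean, numeric(1))
    fqfmFor <- function(g) extrapolateFqFm(slopeG[[g]], intercept, hp$ppfr)
  } else {
    grid <- fit@meta$repGrid
    wExp <- 1 / length(unique(grid$experiment_id))
    cellsPerExp <- table(grid$experiment_id)
    w <- as.numeric(wExp / cellsPerExp[grid$experiment_id])
    fqfmFor <- function(g) {
      # adjusted prediction at each hourly PPFR, averaged over the
      # observed factor cells, covariates at grand means
      pred <- numeric(length(hp$ppfr))
      for (i in seq_len(nrow(grid))) {
        nd <- .gxeReferenceRow(fit, g, grid$experiment_id[i],
                               grid$treatment[i], grid$replicate_id[i])
        nd <- nd[rep(1L, length(hp$ppfr)), , drop = FALSE]
        nd$ppfr <- hp$ppfr
        X <- .gxeRows(fit, nd)
        kept <- !is.na(fit@coefficients)
        pred <- pred + w[i] * drop(X[, kept, drop = FALSE] %*%
                                     fit@coefficients[kept])
      }
      clip01(pred)
    }
  }

  rows <- lapply(genotypes, function(g) {
    fq <- fqfmFor(g)
    et <- etr(fq, hp$ppfr, constants)
    data.frame(genotype = g,
               seasonal_et = sum(et * 3600),
               cumulative_ppfr = cumPPFR,
               epsilon_e = sum(fq * hp$ppfr) / sum(hp$ppfr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$method <- method
  if (!is.null(biomass)) {
    bioG <- aggregate(list(mass = biomass$mass),
                      by = list(genotype = biomass$genotype), mean)
    crop <- biomass$crop[1L]
    part <- biomass$measured_part[1L]
    idx <- match(out$genotype, bioG$genotype)
    energy <- ifelse(is.na(idx), NA_real_,
                     biomassToTotalEnergy(bioG$mass[pmax(idx, 1L)], crop,
                                          part, constants))
    out$epsilon_t <- energy / (out$epsilon_e * constants$epsilonI *
                                 cumPPFR * constants$joulesPerUmol)
    out$epsilon_c <- out$epsilon_e * out$epsilon_t
  }
  rownames(out) <- NULL
  out
}
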
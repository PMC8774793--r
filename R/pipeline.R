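# End-to-end orchestration and paper-style reporting: run the full
# pipeline from records (or a synthetic config) to efficiency tables, and
# match predicted ETR against gas-exchange assimilation.

.writeStage <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: weather alignment, preprocessing (light-adapted
#' selection, grouped IQR filtering, minute averaging), the G x E model
#' fit, response-slope and adjusted-mean extraction, slope-biomass
#' correlation, and the seasonal efficiency budget (both the
#' model-predicted and the slope-extrapolation path when biomass is
#' available). Deterministic given the seed; with `outDir` set, every
#' stage table is written as CSV with a provenance comment header
#' (config hash + seed).
#'
#' @param lift,weather,biomass Record tables (see [readDataset()]); or
#'   pass `config` to simulate them.
#' @param config Optional [synthConfig()]; when given, the three tables
#'   are generated from it and `sowing`/`harvest` default to its season.
#' @param modelKind `"maize"` or `"soybean"` (see [fitGxE()]).
#' @param sowing,harvest Season window; defaults to the biomass records'
#'   dates.
#' @param constants An [energyConstants()] set.
#' @param outDir Optional output directory for stage CSVs.
#' @param seed Seed recorded in all outputs (the pipeline itself is
#'   deterministic; the seed governs a simulated `config`).
#' @return A list with `records` (preprocessed), `fit`, `slopes`,
#'   `means`, `correlation`, `efficiencies` (predicted path),
#'   `efficienciesExtrapolated`, `intercept`, `report`, `seed`.
#' @export
runPipeline <- function(lift = NULL, weather = NULL, biomass = NULL,
                        config = NULL,
                        modelKind = c("soybean", "maize"),
                        sowing = NULL, harvest = NULL,
                        constants = energyConstants(),
                        outDir = NULL, seed = 1) {
  modelKind <- match.arg(modelKind)
  if (!is.null(config)) {
    config$seed <- as.integer(seed)
    sim <- simulateExperiment(config, constants)
    lift <- sim$records; weather <- sim$weather; biomass <- sim$biomass
    sowing <- sowing %||% config$sowing
    harvest <- harvest %||% config$harvest
  }
  if (is.null(lift) || is.null(weather)) {
    stop("stage 'align': lift and weather records are required",
         call. = FALSE)
  }
  if (is.null(sowing) || is.null(harvest)) {
    if (is.null(biomass)) {
      stop("stage 'efficiency': biomass records (or explicit ",
           "sowing/harvest dates) are required", call. = FALSE)
    }
    sowing <- as.Date(biomass$sowing_date[1L])
    harvest <- as.Date(biomass$harvest_date[1L])
  }
  aligned <- alignEnvironment(lift, weather)
  pre <- preprocessRecords(aligned)
  fit <- fitGxE(pre, modelKind)
  slopes <- responseSlopes(fit)
  means <- adjustedMeans(fit)
  correlation <- if (!is.null(biomass) &&
                     length(unique(slopes$genotype)) >= 3L) {
    correlateWithBiomass(slopes, biomass, valueCol = "slope")
  } else NULL  # Pearson r needs >= 3 paired genotypes
  effPred <- efficiencyFromFit(fit, weather, sowing, harvest,
                               biomass = biomass, method = "predicted",
                               constants = constants)
  intercept <- lowLightIntercept(aligned, constants)
  effExtra <- if (!is.na(intercept)) {
    efficiencyFromFit(fit, weather, sowing, harvest, biomass = biomass,
                      records = aligned, method = "extrapolated",
                      constants = constants)
  } else NULL
  report <- c(sprintf("aligned: %d records (%d dropped)", nrow(aligned),
                      attr(aligned, "dropped")),
              attr(pre, "report"),
              sprintf("model: %s, R-squared %.3f", modelKind,
                      fit@r.squared))
  out <- list(records = pre, fit = fit, slopes = slopes, means = means,
              correlation = correlation, efficiencies = effPred,
              efficienciesExtrapolated = effExtra, intercept = intercept,
              report = report, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hash <- sum(utf8ToInt(paste(modelKind, format(sowing),
                                format(harvest), collapse = "")))
    prov <- sprintf("PhotoCascade pipeline; seed=%d; config_hash=%d",
                    as.integer(seed), hash)
    .writeStage(slopes, file.path(outDir, "estimates.csv"), prov)
    .writeStage(means, file.path(outDir, "adjusted_means.csv"), prov)
    .writeStage(effPred, file.path(outDir, "efficiencies.csv"), prov)
    if (!is.null(effExtra)) {
      .writeStage(effExtra, file.path(outDir,
                                      "efficiencies_extrapolated.csv"),
                  prov)
    }
    if (!is.null(correlation)) {
      .writeStage(data.frame(r = correlation$r, n = correlation$n),
                  file.path(outDir, "correlation.csv"), prov)
    }
    writeLines(c(paste0("# ", prov), report),
               file.path(outDir, "pipeline_report.txt"))
  }
  out
}

#' Match predicted ETR against gas-exchange assimilation
#'
#' Aggregates both series to half-hour x plot means (half-open bins
#' anchored at :00/:30) and reports the Pearson correlation over the
#' paired bins. With fewer than 3 overlapping pairs the correlation is
#' undefined (`NA`) but the pairs are still returned.
#'
#' @param etrRecords A `data.frame` with `timestamp`, `replicate_id` and
#'   `etr` (umol electrons m-2 s-1).
#' @param gas Gas-exchange records (see [readDataset()]); rows with
#'   `stability_flag < 0.6` are excluded.
#' @return A list: `pairs` (`data.frame` with bin, replicate, mean ETR,
#'   mean assimilation), `r`, `n`.
#' @export
matchEtrAssimilation <- function(etrRecords, gas) {
  gas <- gas[is.na(gas$stability_flag) | gas$stability_flag >= 0.6, ,
             drop = FALSE]
  if (nrow(gas) == 0L || nrow(etrRecords) == 0L) {
    return(list(pairs = data.frame(bin = character(0),
                                   replicate_id = character(0),
                                   etr = numeric(0),
                                   assimilation = numeric(0)),
                r = NA_real_, n = 0L))
  }
  binOf <- function(ts) format(floorHalfHour(ts), "%Y-%m-%d %H:%M")
  e <- aggregate(list(etr = etrRecords$etr),
                 by = list(bin = binOf(etrRecords$timestamp),
                           replicate_id = etrRecords$replicate_id),
                 FUN = mean)
  a <- aggregate(list(assimilation = gas$assimilation),
                 by = list(bin = binOf(gas$timestamp),
                           replicate_id = gas$replicate_id),
                 FUN = mean)
  pairs <- merge(e, a, by = c("bin", "replicate_id"))
  r <- if (nrow(pairs) >= 3L && sd(pairs$etr) > 0 &&
           sd(pairs$assimilation) > 0) {
    cor(pairs$etr, pairs$assimilation)
  } else NA_real_
  list(pairs = pairs, r = r, n = nrow(pairs))
}
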
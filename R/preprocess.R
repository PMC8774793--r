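# Spectral and fluorescence preprocessing: even-nm binning, gray-reference
# reflectance correction, absorption and normalized-difference indices,
# light-adapted selection, grouped IQR outlier removal, minute averaging.
#
# Fixed pipeline order: bin -> correct -> indices -> light filter ->
# IQR filter -> minute averaging.

#' Bin a raw spectrum to even nanometre wavelengths
#'
#' Each raw point is assigned to its nearest even-nm wavelength (ties
#' broken toward the lower even number) and signals are averaged per bin.
#' Bins with no raw points are absent from the output.
#'
#' @param wavelength Raw wavelengths in nm (native resolution ~0.46 nm),
#'   within \[399, 801\].
#' @param signal Digital numbers (>= 0), same length.
#' @return A `data.frame` with strictly increasing even integer
#'   `wavelength` and mean `signal` per bin.
#' @export
binSpectrum <- function(wavelength, signal) {
  if (length(wavelength) == 0L) stop("empty spectrum", call. = FALSE)
  if (length(wavelength) != length(signal)) {
    stop("wavelength and signal lengths differ", call. = FALSE)
  }
  if (any(wavelength < 399 | wavelength > 801)) {
    stop("raw wavelengths must lie within [399, 801] nm", call. = FALSE)
  }
  bin <- evenBin(wavelength)
  agg <- vapply(split(signal, bin), mean, numeric(1))
  data.frame(wavelength = as.integer(names(agg)), signal = unname(agg))
}

#' Gray-reference lookup table
#'
#' Maps PPFR levels to reference spectra used for reflectance correction.
#' Glasshouse mode stores measured reference spectra; field mode scales a
#' single reference spectrum linearly with PPFR over a 200-1500 grid
#' (spectra snapped to the nearest grid key, not interpolated).
#'
#' @slot ppfr Positive PPFR keys, sorted increasing.
#' @slot spectra List of binned spectra (`data.frame`s from
#'   [binSpectrum()]), one per key.
#' @slot mode `"measured"` or `"scaled"`.
#' @export
setClass("GrayLookupTable",
         representation(ppfr = "numeric", spectra = "list",
                        mode = "character"),
         validity = function(object) {
           if (length(object@ppfr) == 0L) return("at least one entry required")
           if (any(object@ppfr <= 0)) return("PPFR keys must be positive")
           if (length(object@ppfr) != length(object@spectra)) {
             return("one spectrum per PPFR key required")
           }
           if (is.unsorted(object@ppfr, strictly = TRUE)) {
             return("PPFR keys must be strictly increasing")
           }
           TRUE
         })

#' @describeIn GrayLookupTable Build a lookup table from measured
#'   gray-reference spectra at known PPFR levels.
#' @param ppfr PPFR levels (umol m-2 s-1) of the reference measurements.
#' @param spectra List of binned reference spectra, one per level.
#' @export
grayLookupTable <- function(ppfr, spectra) {
  o <- order(ppfr)
  new("GrayLookupTable", ppfr = as.numeric(ppfr[o]), spectra = spectra[o],
      mode = "measured")
}

#' @describeIn GrayLookupTable Build a field-mode lookup table by scaling
#'   one reference spectrum proportionally to PPFR over a grid.
#' @param reference A binned reference spectrum.
#' @param referencePPFR PPFR at which `reference` was taken.
#' @param grid PPFR grid covered by the scaled table.
#' @export
scaledLookupTable <- function(reference, referencePPFR,
                              grid = seq(200, 1500, by = 100)) {
  stopifnotScalarNumeric(referencePPFR, "referencePPFR")
  spectra <- lapply(grid, function(p) {
    data.frame(wavelength = reference$wavelength,
               signal = reference$signal * p / referencePPFR)
  })
  new("GrayLookupTable", ppfr = as.numeric(grid), spectra = spectra,
      mode = "scaled")
}

setMethod("show", "GrayLookupTable", function(object) {
  cat(sprintf("GrayLookupTable (%s): %d entries, PPFR %g-%g\n",
              object@mode, length(object@ppfr), min(object@ppfr),
              max(object@ppfr)))
})

#' Select the lookup entry nearest to a PPFR value
#'
#' Ties between two equally distant keys are broken toward the lower key.
#'
#' @param lut A [GrayLookupTable-class] object.
#' @param ppfr Query PPFR (umol m-2 s-1).
#' @return The index of the selected entry.
#' @export
nearestLookupEntry <- function(lut, ppfr) {
  d <- abs(lut@ppfr - ppfr)
  which(d == min(d))[1L]  # keys sorted increasing: first match = lower key
}

#' Correct a plant spectrum to reflectance with a gray reference
#'
#' Divides the plant signal wavelength-wise by the reference spectrum of
#' the lookup entry whose PPFR key is nearest to the measurement's PPFR.
#' Wavelengths where the reference signal is zero are masked (`NA`), never
#' infinite.
#'
#' @param plant A binned plant spectrum (`data.frame`).
#' @param lut A [GrayLookupTable-class].
#' @param ppfr PPFR at the plant measurement.
#' @return A reflectance spectrum (`data.frame`, dimensionless `signal`)
#'   over the wavelengths shared with the reference.
#' @export
correctReflectance <- function(plant, lut, ppfr) {
  ref <- lut@spectra[[nearestLookupEntry(lut, ppfr)]]
  idx <- match(plant$wavelength, ref$wavelength)
  keep <- !is.na(idx)
  refSig <- ref$signal[idx[keep]]
  refl <- plant$signal[keep] / refSig
  refl[refSig == 0] <- NA_real_
  data.frame(wavelength = plant$wavelength[keep], signal = refl)
}

#' Canopy absorption from the chlorophyll absorption bands
#'
#' `(sum signal 420-500 nm + sum signal 640-690 nm) / sum reference
#' 400-800 nm`, band limits inclusive.
#'
#' @param plant Binned plant spectrum.
#' @param reference Binned reference spectrum covering 400-800 nm.
#' @return Absorption fraction (scalar).
#' @export
computeAbsorption <- function(plant, reference) {
  inBand <- function(s, lo, hi) sum(s$signal[s$wavelength >= lo &
                                               s$wavelength <= hi])
  denom <- inBand(reference, 400, 800)
  if (denom == 0) stop("zero reference denominator", call. = FALSE)
  (inBand(plant, 420, 500) + inBand(plant, 640, 690)) / denom
}

.indexBands <- list(PRI = c(530, 570), NPQI = c(416, 436),
                    NDVI = c(750, 706))

#' Normalized-difference spectral index
#'
#' PRI = (R530 - R570)/(R530 + R570), NPQI = (R416 - R436)/(R416 + R436),
#' NDVI = (R750 - R706)/(R750 + R706). Computed on corrected reflectance
#' or, with `raw = TRUE`, on raw digital numbers (the "p"-prefixed
#' pseudo-index convention, e.g. pNDVI). Band wavelengths snap to the
#' nearest even-nm bin present in the spectrum.
#'
#' @param spectrum A binned (reflectance or raw) spectrum.
#' @param which `"PRI"`, `"NPQI"` or `"NDVI"`.
#' @param raw Flag recording that the input is uncorrected digital
#'   numbers; the arithmetic is identical, the flag names the convention.
#' @return Index value in \[-1, 1\], or `NA` if both bands are zero.
#' @export
computeIndex <- function(spectrum, which = c("PRI", "NPQI", "NDVI"),
                         raw = FALSE) {
  which <- match.arg(which)
  bands <- evenBin(.indexBands[[which]])
  idx <- match(bands, spectrum$wavelength)
  if (anyNA(idx)) {
    stop(sprintf("%s bands (%d, %d nm) absent from spectrum", which,
                 bands[1], bands[2]), call. = FALSE)
  }
  r1 <- spectrum$signal[idx[1]]
  r2 <- spectrum$signal[idx[2]]
  if (is.na(r1) || is.na(r2) || (r1 == 0 && r2 == 0)) return(NA_real_)
  (r1 - r2) / (r1 + r2)
}

#' Keep only light-adapted measurements
#'
#' Strictly greater-than comparison of attached PPFR against the
#' threshold (default 100 umol photons m-2 s-1).
#'
#' @param records Lift records with environment attached.
#' @param threshold PPFR threshold.
#' @return Filtered records; attribute `"removed"` counts dropped rows.
#' @export
filterLightAdapted <- function(records, threshold = 100) {
  if (!"ppfr" %in% names(records)) {
    stop("environment not attached: run alignEnvironment() first",
         call. = FALSE)
  }
  keep <- records$ppfr > threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Grouped interquartile-range outlier partition
#'
#' Within each group, keeps x iff `Q1 - k*IQR <= x <= Q3 + k*IQR`
#' (quartiles by linear interpolation between order statistics, the
#' "type 7" convention). Groups with fewer than 4 non-missing values pass
#' through untouched and are listed in the report. Missing values are
#' always kept.
#'
#' @param values Numeric series.
#' @param groups Optional grouping (vector or list of vectors, as in
#'   [interaction()]); `NULL` treats the series as one group.
#' @param k Fence multiplier (default 2.5).
#' @return A list: `keep` (logical, same length as `values`) and `fences`
#'   (`data.frame` with group, lower, upper, n, applied flag).
#' @export
iqrFilter <- function(values, groups = NULL, k = 2.5) {
  n <- length(values)
  if (is.null(groups)) {
    g <- factor(rep("all", n))
  } else if (is.list(groups)) {
    g <- interaction(groups, drop = TRUE, lex.order = TRUE)
  } else {
    g <- factor(groups)
  }
  keep <- rep(TRUE, n)
  fences <- lapply(levels(g), function(lv) {
    idx <- which(g == lv)
    v <- values[idx]
    obs <- !is.na(v)
    if (sum(obs) < 4L) {
      return(data.frame(group = lv, lower = NA_real_, upper = NA_real_,
                        n = sum(obs), applied = FALSE))
    }
    q <- quantile(v[obs], c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - k * (q[2] - q[1])
    hi <- q[2] + k * (q[2] - q[1])
    drop <- obs & (v < lo | v > hi)
    keep[idx[drop]] <<- FALSE
    data.frame(group = lv, lower = lo, upper = hi, n = sum(obs),
               applied = TRUE)
  })
  list(keep = keep, fences = do.call(rbind, fences))
}

#' Remove rows with outlying values in any listed variable
#'
#' Applies [iqrFilter()] per variable within the stated grouping and drops
#' rows flagged by any variable. The per-variable removal counts are
#' attached as a plain-text report.
#'
#' @param records A record `data.frame`.
#' @param vars Variable names to screen.
#' @param by Column names defining the grouping (e.g. crop and treatment
#'   for spectral variables, month for environmental ones, experiment for
#'   biomass).
#' @param k Fence multiplier.
#' @return Filtered records with attributes `"removed"` (total rows
#'   dropped) and `"report"` (character lines, removals per variable).
#' @export
filterOutliers <- function(records, vars, by = NULL, k = 2.5) {
  vars <- intersect(vars, names(records))
  groups <- if (is.null(by)) NULL else
    lapply(intersect(by, names(records)), function(cn) records[[cn]])
  keep <- rep(TRUE, nrow(records))
  report <- character(0)
  for (v in vars) {
    f <- iqrFilter(records[[v]], groups = groups, k = k)
    report <- c(report, sprintf("%s: removed %d", v, sum(!f$keep)))
    keep <- keep & f$keep
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  attr(out, "report") <- report
  out
}

#' Average records per minute, replicate, treatment and genotype
#'
#' Fq'/Fm', the spectral indices and the attached environment are replaced
#' by their group means; the group size is kept in column `n`.
#'
#' @param records Lift records with environment attached.
#' @return One record per (minute, replicate, treatment, genotype) --
#'   experiment and condition are carried along as part of the key.
#' @export
averagePerMinute <- function(records) {
  if (nrow(records) == 0L) return(records)
  keyCols <- c("experiment_id", "condition", "genotype", "treatment",
               "replicate_id")
  keyCols <- intersect(keyCols, names(records))
  minute <- floorMinute(records$timestamp)
  numCols <- intersect(c("fqfm", "pri", "pndvi", "npqi", "ndvi",
                         "absorption", "irradiance_680", "ppfr",
                         "temperature", "humidity"), names(records))
  by <- c(list(timestamp = minute),
          lapply(records[keyCols], identity))
  agg <- aggregate(records[numCols], by = by,
                   FUN = function(v) mean(v, na.rm = TRUE))
  nAgg <- aggregate(list(n = rep(1L, nrow(records))), by = by, FUN = sum)
  agg$n <- nAgg$n
  agg <- agg[order(agg$timestamp), , drop = FALSE]
  for (v in numCols) agg[[v]][is.nan(agg[[v]])] <- NA_real_
  rownames(agg) <- NULL
  agg
}

#' Standard preprocessing chain for aligned records
#'
#' Applies, in the fixed order, the light-adapted selection (PPFR > 100),
#' grouped 2.5 x IQR outlier removal (spectral variables per crop... here
#' per treatment within the table; environmental variables per month) and
#' per-minute averaging. Spectral binning/correction happens upstream when
#' raw spectra rather than precomputed indices are supplied.
#'
#' @param records Aligned lift records.
#' @param lightThreshold PPFR threshold for light adaptation.
#' @param k IQR fence multiplier.
#' @return Minute-averaged analysis records with a `"report"` attribute
#'   describing counts removed per step.
#' @export
preprocessRecords <- function(records, lightThreshold = 100, k = 2.5) {
  la <- filterLightAdapted(records, lightThreshold)
  report <- sprintf("light_adapted: removed %d", attr(la, "removed"))
  specVars <- c("pri", "pndvi", "npqi", "ndvi", "absorption",
                "irradiance_680", "fqfm")
  sp <- filterOutliers(la, specVars, by = c("condition", "treatment"), k = k)
  report <- c(report, paste0("spectral_iqr ", attr(sp, "report")))
  month <- format(sp$timestamp, "%Y-%m")
  envKeep <- rep(TRUE, nrow(sp))
  for (v in intersect(c("ppfr", "temperature", "humidity"), names(sp))) {
    f <- iqrFilter(sp[[v]], groups = month, k = k)
    report <- c(report, sprintf("env_iqr %s: removed %d", v, sum(!f$keep)))
    envKeep <- envKeep & f$keep
  }
  sp <- sp[envKeep, , drop = FALSE]
  out <- averagePerMinute(sp)
  report <- c(report, sprintf("minute_averaged: %d records", nrow(out)))
  attr(out, "report") <- report
  out
}
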
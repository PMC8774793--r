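# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Nearest even integer, ties broken toward the lower even number
# (531 -> 530, 401 -> 400).
evenBin <- function(wavelength) {
  2L * as.integer(ceiling(wavelength / 2 - 0.5))
}

# Floor POSIXct to whole minutes / hours (UTC storage, single-site study:
# timestamps are local experiment time, no timezone arithmetic).
floorMinute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

floorHour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

# Half-open half-hour bins anchored at :00/:30.
floorHalfHour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 1800) * 1800,
             origin = "1970-01-01", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotScalarNumeric <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}
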
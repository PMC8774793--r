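# Tabular data model: the four CSV schemas and the weather join.
#
# Dialect: comma-separated, period decimal, timestamps "YYYY-MM-DD HH:MM:SS"
# (an ISO-8601 "T" separator is accepted on read), dates "YYYY-MM-DD".
# Lines starting with "#" are provenance comments and are skipped.

.conditions <- c("glasshouse_in", "glasshouse_out", "field")
.crops <- c("maize", "soybean")
.parts <- c("shoot", "grain")

.schemas <- list(
  lift = list(
    mandatory = c("timestamp", "experiment_id", "condition", "genotype",
                  "treatment", "replicate_id", "fqfm"),
    optional = c("pri", "pndvi", "npqi", "ndvi", "absorption",
                 "irradiance_680", "ppfr", "temperature", "humidity"),
    timestamp = "timestamp"
  ),
  weather = list(
    mandatory = c("timestamp", "condition", "ppfr", "temperature",
                  "humidity"),
    optional = character(0),
    timestamp = "timestamp"
  ),
  biomass = list(
    mandatory = c("experiment_id", "genotype", "treatment", "replicate_id",
                  "crop", "measured_part", "mass", "sowing_date",
                  "harvest_date"),
    optional = character(0),
    timestamp = NA_character_
  ),
  gasexchange = list(
    mandatory = c("timestamp", "replicate_id", "genotype", "assimilation",
                  "stability_flag"),
    optional = character(0),
    timestamp = "timestamp"
  )
)

.parseTimestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  x <- ifelse(grepl("^\\d{4}-\\d{2}-\\d{2}$", x), paste(x, "00:00:00"), x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  retry <- which(is.na(out) & !is.na(x))
  if (length(retry)) {
    out[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d %H:%M",
                                      tz = "UTC"))
  }
  out
}

# Logical keep-vector of rows satisfying the schema's type invariants.
.validRows <- function(x, schema) {
  n <- nrow(x)
  ok <- rep(TRUE, n)
  ndOk <- function(v) is.na(v) | (v >= -1 & v <= 1)
  if (schema == "lift") {
    ok <- ok & !is.na(x$fqfm) & x$fqfm >= 0 & x$fqfm <= 1
    ok <- ok & x$condition %in% .conditions
    for (idx in intersect(c("pri", "pndvi", "npqi", "ndvi"), names(x))) {
      ok <- ok & ndOk(x[[idx]])
    }
    if ("ppfr" %in% names(x)) ok <- ok & (is.na(x$ppfr) | x$ppfr >= 0)
  } else if (schema == "weather") {
    ok <- ok & !is.na(x$ppfr) & x$ppfr >= 0
    ok <- ok & !is.na(x$humidity) & x$humidity >= 0 & x$humidity <= 100
    ok <- ok & x$condition %in% .conditions
  } else if (schema == "biomass") {
    ok <- ok & !is.na(x$mass) & x$mass > 0
    ok <- ok & x$crop %in% .crops & x$measured_part %in% .parts
    ok <- ok & !is.na(x$harvest_date) & !is.na(x$sowing_date) &
      x$harvest_date > x$sowing_date
  } else if (schema == "gasexchange") {
    ok <- ok & !is.na(x$assimilation)
  }
  ok
}

#' Read one of the four dataset schemas from CSV
#'
#' Reads and validates a `lift`, `weather`, `biomass` or `gasexchange`
#' table. Rows violating the schema's type invariants (e.g. `fqfm` outside
#' \[0, 1\], negative PPFR, humidity outside \[0, 100\], non-positive mass)
#' are dropped; the number of rejected rows is attached as attribute
#' `"rejected"` and reported with a message.
#'
#' @param path Path to a CSV file (comma-separated, period decimal,
#'   ISO-8601-style timestamps; `#` comment lines allowed).
#' @param schema One of `"lift"`, `"weather"`, `"biomass"`,
#'   `"gasexchange"`.
#' @return A `data.frame` of validated records with attribute `"rejected"`
#'   (count of dropped rows). Timestamp columns are `POSIXct` (minute or
#'   second precision as stored); date columns are `Date`.
#' @seealso [writeDataset()], [alignEnvironment()]
#' @export
readDataset <- function(path, schema = c("lift", "weather", "biomass",
                                         "gasexchange")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- .schemas[[schema]]
  x <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(sc$mandatory, names(x))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing mandatory column(s): %s",
                 schema, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.na(sc$timestamp) && nrow(x) > 0) {
    ts <- .parseTimestamp(as.character(x[[sc$timestamp]]))
    bad <- which(is.na(ts) & !is.na(x[[sc$timestamp]]))
    if (length(bad)) {
      stop(sprintf(
        "schema '%s': unparseable timestamp at data line(s): %s",
        schema, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    x[[sc$timestamp]] <- ts
  }
  if (schema == "biomass" && nrow(x) > 0) {
    x$sowing_date <- as.Date(x$sowing_date)
    x$harvest_date <- as.Date(x$harvest_date)
  }
  if (nrow(x) > 0) {
    keep <- .validRows(x, schema)
    rejected <- sum(!keep)
    x <- x[keep, , drop = FALSE]
    rownames(x) <- NULL
  } else {
    rejected <- 0L
  }
  if (rejected > 0) {
    message(sprintf("readDataset: rejected %d row(s) violating '%s' invariants",
                    rejected, schema))
  }
  attr(x, "rejected") <- rejected
  x
}

#' Write a dataset back to its CSV schema
#'
#' Inverse of [readDataset()]: formats timestamps/dates in the documented
#' dialect and writes a plain CSV. An optional provenance header is written
#' as `#`-prefixed comment lines that [readDataset()] skips.
#'
#' @param x A record `data.frame`.
#' @param path Output file path.
#' @param schema One of the four schema names (see [readDataset()]).
#' @param provenance Optional character vector written as `# `-prefixed
#'   header lines.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(x, path, schema = c("lift", "weather", "biomass",
                                             "gasexchange"),
                         provenance = NULL) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  missing <- setdiff(sc$mandatory, names(x))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing mandatory column(s): %s",
                 schema, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- x
  if (!is.na(sc$timestamp) && nrow(out) > 0) {
    out[[sc$timestamp]] <- format(out[[sc$timestamp]], "%Y-%m-%d %H:%M:%S",
                                  tz = "UTC")
  }
  for (dc in intersect(c("sowing_date", "harvest_date"), names(out))) {
    out[[dc]] <- format(as.Date(out[[dc]]), "%Y-%m-%d")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach per-minute weather to fluorescence records
#'
#' Joins each measurement record to the weather record of the same minute
#' and growing condition, attaching `ppfr`, `temperature` and `humidity`.
#' Weather must already be averaged to one record per (minute, condition);
#' duplicates raise an error. Records without a matching weather minute are
#' dropped and counted (attribute `"dropped"`); no interpolation is done.
#'
#' @param lift A lift-record `data.frame` (see [readDataset()]).
#' @param weather A weather-record `data.frame`, one row per
#'   (minute, condition).
#' @return `lift` with `ppfr`, `temperature`, `humidity` columns attached
#'   and attribute `"dropped"` (count of unmatched records). Idempotent:
#'   aligning an already aligned table re-attaches the same values.
#' @export
alignEnvironment <- function(lift, weather) {
  wKey <- paste0(floor(as.numeric(weather$timestamp) / 60), "|",
                 weather$condition)
  if (anyDuplicated(wKey)) {
    stop("weather has duplicate rows for a (minute, condition); ",
         "average per minute first", call. = FALSE)
  }
  lKey <- paste0(floor(as.numeric(lift$timestamp) / 60), "|",
                 lift$condition)
  idx <- match(lKey, wKey)
  matched <- !is.na(idx)
  out <- lift[matched, , drop = FALSE]
  out$ppfr <- weather$ppfr[idx[matched]]
  out$temperature <- weather$temperature[idx[matched]]
  out$humidity <- weather$humidity[idx[matched]]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!matched)
  out
}
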
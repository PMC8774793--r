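# Hourly seasonal prediction of Fq'/Fm': season grid construction,
# regularized iterative-PCA imputation of missing spectral covariates,
# ridge-penalized linear model with internal cross-validation for the
# penalty, full-season prediction, and day-blocked cross-validation.

.vColsAll <- c("month", "hour", "irradiance_680", "absorption",
               "reflectance_mean")
.wColsAll <- c("pri", "pndvi", "npqi", "das", "humidity", "temperature",
               "ppfr", "sqrt_ppfr")
.spectralCols <- c("pri", "pndvi", "npqi", "irradiance_680", "absorption",
                   "reflectance_mean")

#' Build the hourly season grid
#'
#' One row per genotype x hour from sowing to harvest, carrying the
#' hourly weather means (PPFR, sqrt PPFR, humidity, temperature),
#' calendar descriptors (days after sowing, hour, month), the hourly
#' means of the observed spectral covariates and of measured Fq'/Fm'
#' (replicates collapsed), and an `in_window` flag marking the fitting
#' window 100 < PPFR < 2000 umol m-2 s-1.
#'
#' @param records Preprocessed (minute-averaged, environment-attached)
#'   lift records.
#' @param weather Minute-resolution weather for the season.
#' @param sowing,harvest Season window (`Date`).
#' @return A `data.frame` season grid with attributes `vCols`/`wCols`
#'   naming the covariate blocks available in this grid.
#' @export
buildSeasonGrid <- function(records, weather, sowing, harvest) {
  sowing <- as.Date(sowing); harvest <- as.Date(harvest)
  hr <- floorHour(weather$timestamp)
  env <- aggregate(weather[, c("ppfr", "temperature", "humidity")],
                   by = list(timestamp = hr), mean)
  env$date <- as.Date(env$timestamp, tz = "UTC")
  env <- env[env$date >= sowing & env$date <= harvest, , drop = FALSE]
  env$hour <- as.integer(format(env$timestamp, "%H", tz = "UTC"))
  env$month <- as.integer(format(env$timestamp, "%m", tz = "UTC"))
  env$das <- as.numeric(env$date - sowing)
  env$sqrt_ppfr <- sqrt(env$ppfr)
  env$in_window <- env$ppfr > 100 & env$ppfr < 2000

  genotypes <- sort(unique(records$genotype))
  grid <- merge(data.frame(genotype = genotypes), env, by = NULL)
  grid <- grid[order(grid$genotype, grid$timestamp), , drop = FALSE]

  specAvail <- intersect(.spectralCols, names(records))
  obsCols <- c("fqfm", specAvail)
  obs <- aggregate(records[obsCols],
                   by = list(genotype = records$genotype,
                             timestamp = floorHour(records$timestamp)),
                   FUN = function(v) mean(v, na.rm = TRUE))
  for (v in obsCols) obs[[v]][is.nan(obs[[v]])] <- NA_real_
  key <- function(d) paste(d$genotype, format(d$timestamp, "%Y-%m-%d %H"))
  idx <- match(key(grid), key(obs))
  for (v in obsCols) grid[[v]] <- obs[[v]][idx]
  rownames(grid) <- NULL
  attr(grid, "sowing") <- sowing
  attr(grid, "harvest") <- harvest
  attr(grid, "vCols") <- intersect(.vColsAll, names(grid))
  attr(grid, "wCols") <- intersect(.wColsAll, names(grid))
  grid
}

#' Regularized iterative-PCA completion of a numeric matrix
#'
#' Missing cells are initialized with column means, then the matrix is
#' repeatedly reconstructed from its leading `ncp` principal components
#' (singular values shrunken toward zero by the mean trailing eigenvalue
#' when `regularize = TRUE`, which pulls imputed cells toward the column
#' means) and only the missing cells are re-imputed, until the imputed
#' values change by less than `tol` (relative squared change). Observed
#' cells are never modified.
#'
#' @param x Numeric matrix with `NA`s.
#' @param ncp Number of components (default 6).
#' @param scale Standardize columns to unit variance during iteration.
#' @param regularize Shrink singular values (regularized variant); turn
#'   off for plain EM-PCA completion.
#' @param tol Relative convergence tolerance on the imputed cells.
#' @param maxIter Iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @return The completed matrix, with attribute `"iterations"`.
#' @export
iterativePCAImpute <- function(x, ncp = 6, scale = TRUE, regularize = TRUE,
                               tol = 1e-6, maxIter = 1000) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "iterations") <- 0L
    return(x)
  }
  if (any(colSums(!miss) == 0L)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[colSums(!miss) == 0L], collapse = ", "),
         call. = FALSE)
  }
  ncp <- min(ncp, ncol(x) - 1L, nrow(x) - 1L)
  # init: column means of observed cells
  mu0 <- colMeans(x, na.rm = TRUE)
  xc <- x
  xc[miss] <- mu0[col(x)][miss]
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    m <- colMeans(xc)
    s <- if (scale) pmax(apply(xc, 2, sd), 1e-12) else rep(1, ncol(xc))
    z <- sweep(sweep(xc, 2, m), 2, s, "/")
    sv <- svd(z)
    d <- sv$d
    lambda <- d^2
    dShr <- if (regularize && length(d) > ncp) {
      sigma2 <- mean(lambda[(ncp + 1):length(lambda)])
      pmax((lambda[seq_len(ncp)] - sigma2) / d[seq_len(ncp)], 0)
    } else {
      d[seq_len(ncp)]
    }
    fit <- sv$u[, seq_len(ncp), drop = FALSE] %*%
      (dShr * t(sv$v[, seq_len(ncp), drop = FALSE]))
    new <- sweep(sweep(fit, 2, s, "*"), 2, m, "+")
    prev <- xc[miss]
    xc[miss] <- new[miss]
    delta <- sum((xc[miss] - prev)^2) / max(sum(prev^2), .Machine$double.eps)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("iterativePCAImpute did not converge in ", maxIter,
            " iterations")
  }
  attr(xc, "iterations") <- it
  xc
}

#' Impute missing spectral covariates on the season grid
#'
#' For every genotype separately, completes the numeric covariate block
#' (hour, DAS, humidity, temperature, PPFR, sqrt PPFR, and the spectral
#' variables) over the in-window hours with [iterativePCAImpute()] on the
#' first `nComponents` principal components. Observed cells are
#' untouched; only spectral cells can be missing (the environment block
#' is always observed).
#'
#' @param grid A season grid from [buildSeasonGrid()].
#' @param nComponents Number of principal components (default 6).
#' @param ... Passed to [iterativePCAImpute()].
#' @return The grid with spectral gaps filled and a logical
#'   `imputed` column flagging rows whose spectral block was imputed.
#' @export
imputeSpectral <- function(grid, nComponents = 6, ...) {
  specCols <- intersect(.spectralCols, names(grid))
  numCols <- unique(c("hour", "das", "humidity", "temperature", "ppfr",
                      "sqrt_ppfr", specCols))
  grid$imputed <- FALSE
  for (g in unique(grid$genotype)) {
    rows <- which(grid$genotype == g & grid$in_window)
    if (!length(rows)) next
    block <- as.matrix(grid[rows, numCols])
    if (!anyNA(block)) next
    done <- iterativePCAImpute(block, ncp = nComponents, ...)
    wasMissing <- is.na(block)
    for (j in seq_along(numCols)) {
      grid[rows, numCols[j]] <- done[, j]
    }
    grid$imputed[rows] <- rowSums(wasMissing[, specCols, drop = FALSE]) > 0
  }
  grid
}

#' Ridge-penalized hourly Fq'/Fm' model
#'
#' Penalized least-squares fit of the hourly model: intercept
#' (unpenalized) plus equally L2-penalized one-hot blocks for experiment
#' and genotype, the seasonal/optical covariate block (month, hour,
#' irradiance, absorption, reflectance), the environmental block (PRI,
#' pNDVI, NPQI, DAS, humidity, temperature, PPFR, sqrt PPFR) and the
#' genotype x environmental interactions -- the ridge analogue of treating
#' those blocks as random effects with one shared variance. All columns
#' are standardized to mean 0, SD 1 before fitting.
#'
#' @slot mu Unpenalized intercept (training mean of the response).
#' @slot beta Named penalized coefficients on the standardized scale.
#' @slot lambda Selected ridge penalty.
#' @slot center,scale Per-column standardization parameters.
#' @slot lambdaGrid,cvError The internal-CV curve.
#' @slot meta Genotype/experiment levels and covariate block names.
#' @export
setClass("RidgeFit",
         representation(mu = "numeric", beta = "numeric", lambda = "numeric",
                        center = "numeric", scale = "numeric",
                        lambdaGrid = "numeric", cvError = "numeric",
                        meta = "list"),
         validity = function(object) {
           if (object@lambda <= 0) return("lambda must be > 0")
           if (length(object@beta) != length(object@center)) {
             return("beta/center length mismatch")
           }
           TRUE
         })

setMethod("show", "RidgeFit", function(object) {
  cat(sprintf("RidgeFit: %d standardized columns, lambda = %.4g\n",
              length(object@beta), object@lambda))
  cat(sprintf("  genotypes: %s\n",
              paste(object@meta$genLevels, collapse = ", ")))
})

#' @describeIn RidgeFit Penalized coefficients (standardized scale).
#' @param object A `RidgeFit`.
#' @export
setMethod("coef", "RidgeFit", function(object) {
  c("(Intercept)" = object@mu, object@beta)
})

# Numeric design for the ridge model from season-grid rows.
.ridgeDesign <- function(rows, meta) {
  n <- nrow(rows)
  oneHot <- function(values, levels, prefix) {
    m <- matrix(vapply(levels, function(lv) as.numeric(values == lv),
                       numeric(n)), nrow = n)
    colnames(m) <- paste0(prefix, ":", levels)
    m
  }
  blocks <- list()
  if (length(meta$expLevels) > 1L && "experiment_id" %in% names(rows)) {
    blocks$E <- oneHot(rows$experiment_id, meta$expLevels, "E")
  }
  blocks$G <- oneHot(rows$genotype, meta$genLevels, "G")
  blocks$v <- as.matrix(rows[meta$vCols])
  blocks$w <- as.matrix(rows[meta$wCols])
  G <- blocks$G
  gw <- lapply(meta$wCols, function(wv) {
    m <- G * rows[[wv]]
    colnames(m) <- paste0(colnames(G), ":", wv)
    m
  })
  do.call(cbind, c(blocks, gw))
}

# Closed-form ridge path via one SVD: beta(lambda) in standardized space.
.ridgeSolve <- function(z, yc, lambda) {
  sv <- svd(z)
  uty <- drop(crossprod(sv$u, yc))
  vapply(lambda, function(l) {
    drop(sv$v %*% (sv$d * uty / (sv$d^2 + l)))
  }, numeric(ncol(z)))
}

#' Fit the ridge model with internal cross-validation for the penalty
#'
#' Standardizes the design (columns to mean 0, SD 1; constant columns are
#' zeroed), selects the penalty minimizing the k-fold record-level CV
#' mean-squared error over the grid, and refits on all records. The
#' intercept is the training response mean and is not penalized.
#'
#' @param grid Season-grid rows with observed `fqfm` (training records);
#'   rows outside the PPFR fitting window are dropped.
#' @param lambdaGrid Ridge penalties to search (default 100 log-spaced
#'   values, 1e-5 to 1e5).
#' @param nFolds Internal CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A [RidgeFit-class] object.
#' @export
fitRidge <- function(grid, lambdaGrid = NULL, nFolds = 10, seed = 1) {
  lambdaGrid <- lambdaGrid %||% 10^seq(-5, 5, length.out = 100)
  if (!length(lambdaGrid)) stop("empty lambda grid", call. = FALSE)
  lambdaGrid <- sort(lambdaGrid)
  rows <- grid[grid$in_window & !is.na(grid$fqfm), , drop = FALSE]
  if (length(unique(as.Date(rows$timestamp, tz = "UTC"))) < 2L) {
    stop("need measurements on >= 2 days", call. = FALSE)
  }
  meta <- list(
    expLevels = sort(unique(rows$experiment_id %||% character(0))),
    genLevels = sort(unique(rows$genotype)),
    vCols = intersect(attr(grid, "vCols") %||% .vColsAll, names(grid)),
    wCols = intersect(attr(grid, "wCols") %||% .wColsAll, names(grid)))
  X <- .ridgeDesign(rows, meta)
  y <- rows$fqfm
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1  # constant columns standardize to all-zero
  z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)

  folds <- withSeed(seed, sample(rep_len(seq_len(nFolds), n)))
  cvErr <- matrix(NA_real_, length(lambdaGrid), nFolds)
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    if (sum(tr) < 2L || sum(!tr) < 1L) next
    mTr <- mean(y[tr])
    betas <- .ridgeSolve(z[tr, , drop = FALSE], y[tr] - mTr, lambdaGrid)
    pred <- z[!tr, , drop = FALSE] %*% betas + mTr
    cvErr[, f] <- colMeans((pred - y[!tr])^2)
  }
  cvMean <- rowMeans(cvErr, na.rm = TRUE)
  lambda <- lambdaGrid[which.min(cvMean)]
  beta <- drop(.ridgeSolve(z, yc, lambda))
  names(beta) <- colnames(X)
  new("RidgeFit", mu = mean(y), beta = beta, lambda = lambda,
      center = setNames(ctr, colnames(X)), scale = setNames(scl, colnames(X)),
      lambdaGrid = lambdaGrid, cvError = cvMean, meta = meta)
}

#' Predict Fq'/Fm' for every in-window hour of the season
#'
#' Applies the ridge fit to the (completed) season grid using the fit's
#' stored standardization. Predictions are clipped to \[0, 1\] and
#' produced only for rows inside the PPFR fitting window; out-of-window
#' hours carry `NA`.
#'
#' @param fit A [RidgeFit-class] object.
#' @param grid A completed season grid ([imputeSpectral()] first when
#'   spectral covariates have gaps).
#' @return The grid with a `fqfm_pred` column.
#' @export
predictSeason <- function(fit, grid) {
  stopifnot(is(fit, "RidgeFit"))
  unknown <- setdiff(unique(grid$genotype), fit@meta$genLevels)
  if (length(unknown)) {
    stop("unknown genotype level(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grid$fqfm_pred <- NA_real_
  rows <- which(grid$in_window)
  if (!length(rows)) return(grid)
  sub <- grid[rows, , drop = FALSE]
  if (anyNA(sub[c(fit@meta$vCols, fit@meta$wCols)])) {
    stop("covariate gaps on in-window rows: impute first", call. = FALSE)
  }
  X <- .ridgeDesign(sub, fit@meta)
  X <- X[, names(fit@beta), drop = FALSE]
  z <- sweep(sweep(X, 2, fit@center), 2, fit@scale, "/")
  grid$fqfm_pred[rows] <- clip01(drop(z %*% fit@beta) + fit@mu)
  grid
}

#' Day-blocked cross-validation of the seasonal prediction
#'
#' Splits the measuring days at random into a 2/3 training and 1/3
#' validation set (floor rule on the training count), fits the ridge
#' model on training days only (standardization, penalty selection and
#' imputation statistics never see validation Fq'/Fm'), and reports the
#' Pearson correlation between predicted and measured Fq'/Fm' on the
#' held-out days. Run twice: once with the validation days' spectral
#' covariates observed (an independent spectral sensor) and once with
#' them removed and imputed.
#'
#' @param records Preprocessed lift records.
#' @param weather Minute-resolution season weather.
#' @param sowing,harvest Season window.
#' @param seed Seed for the day split and fold assignment.
#' @param trainDays,validationDays Optional explicit day sets (`Date`),
#'   overriding the random split.
#' @param lambdaGrid,nFolds,nComponents Passed to [fitRidge()] /
#'   [imputeSpectral()].
#' @return A list: `rObserved`, `rImputed`, `lambdaObserved`,
#'   `lambdaImputed`, `n` (validation pairs), `trainDays`,
#'   `validationDays`, `seed`.
#' @export
crossvalidateByDay <- function(records, weather, sowing, harvest, seed = 1,
                               trainDays = NULL, validationDays = NULL,
                               lambdaGrid = NULL, nFolds = 10,
                               nComponents = 6) {
  days <- sort(unique(as.Date(records$timestamp, tz = "UTC")))
  if (length(days) < 3L) {
    stop("need >= 3 measuring days, got ", length(days), call. = FALSE)
  }
  if (is.null(trainDays)) {
    nTrain <- floor(2 / 3 * length(days))
    trainDays <- withSeed(seed, sort(sample(days, nTrain)))
  }
  trainDays <- as.Date(trainDays)
  validationDays <- as.Date(validationDays %||% setdiff(days, trainDays),
                            origin = "1970-01-01")

  recDay <- as.Date(records$timestamp, tz = "UTC")
  trainRec <- records[recDay %in% trainDays, , drop = FALSE]
  gridAll <- buildSeasonGrid(records, weather, sowing, harvest)
  gridDay <- as.Date(gridAll$timestamp, tz = "UTC")
  # training view: validation-day fqfm withheld
  gridTrain <- gridAll
  gridTrain$fqfm[!(gridDay %in% trainDays)] <- NA_real_

  specCols <- intersect(.spectralCols, names(gridAll))
  evalRun <- function(grid) {
    gridFit <- imputeSpectral(grid, nComponents = nComponents)
    fit <- fitRidge(gridFit, lambdaGrid = lambdaGrid, nFolds = nFolds,
                    seed = seed)
    pred <- predictSeason(fit, gridFit)
    val <- gridDay %in% validationDays & !is.na(pred$fqfm_pred)
    measured <- gridAll$fqfm  # replicate-averaged hourly measurements
    ok <- val & !is.na(measured)
    r <- if (sum(ok) >= 3L && sd(pred$fqfm_pred[ok]) > 0 &&
             sd(measured[ok]) > 0) {
      cor(pred$fqfm_pred[ok], measured[ok])
    } else NA_real_
    list(r = r, lambda = fit@lambda, n = sum(ok))
  }

  runObserved <- evalRun(gridTrain)
  gridBlind <- gridTrain
  for (v in specCols) {
    gridBlind[[v]][!(gridDay %in% trainDays)] <- NA_real_
  }
  runImputed <- evalRun(gridBlind)

  list(rObserved = runObserved$r, rImputed = runImputed$r,
       lambdaObserved = runObserved$lambda,
       lambdaImputed = runImputed$lambda,
       n = runObserved$n, trainDays = trainDays,
       validationDays = validationDays, seed = seed)
}
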
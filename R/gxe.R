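# Fixed-effects genotype x environment models for Fq'/Fm'.
#
# Two mean structures are supported. The maize-style model carries
# genotype x covariate interactions at genotype level:
#   y = mu + E + G + R(E,T) + H + P + I + N + P:I + G:P + G:I + G:P:I + e
# The soybean-style model carries them at plot (replicate) level:
#   y = mu + E + G + R(E,T) + H + P + I + N + P:I
#       + G:R + G:P:R + G:I:R + G:P:I:R + e
# with H humidity, P PPFR, I PRI, N pNDVI, R the replicate factor nested
# within experiment x treatment. Covariates are centered at their grand
# means before interaction construction (collinearity control; slopes are
# algebraically unaffected). Estimation is ordinary least squares;
# aliased columns are dropped deterministically left-to-right in the
# stated term order (R's QR pivoting rule).

.gxeCovariates <- c(H = "humidity", P = "ppfr", I = "pri", N = "pndvi")

# Build the full (pre-aliasing) design matrix for `data` under `meta`.
# One-hot blocks for every observed factor level, term order as stated.
.gxeDesign <- function(data, meta) {
  n <- nrow(data)
  repKey <- paste(data$experiment_id, data$treatment, data$replicate_id,
                  sep = "/")
  oneHot <- function(values, levels, prefix) {
    m <- vapply(levels, function(lv) as.numeric(values == lv), numeric(n))
    m <- matrix(m, nrow = n)
    colnames(m) <- paste0(prefix, ":", levels)
    m
  }
  E <- oneHot(data$experiment_id, meta$expLevels, "E")
  G <- oneHot(data$genotype, meta$genLevels, "G")
  R <- oneHot(repKey, meta$repLevels, "R")
  Hc <- data$humidity - meta$centers[["H"]]
  Pc <- data$ppfr - meta$centers[["P"]]
  Ic <- data$pri - meta$centers[["I"]]
  Nc <- data$pndvi - meta$centers[["N"]]
  cov <- cbind(H = Hc, P = Pc, I = Ic, N = Nc, PI = Pc * Ic)
  blocks <- list("(Intercept)" = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")),
                 E = E, G = G, R = R, cov = cov)
  scaleBlock <- function(m, s, prefix) {
    out <- m * s
    colnames(out) <- paste0(prefix, ":", colnames(m))
    out
  }
  if (meta$modelKind == "maize") {
    blocks$GP <- scaleBlock(G, Pc, "P")
    blocks$GI <- scaleBlock(G, Ic, "I")
    blocks$GPI <- scaleBlock(G, Pc * Ic, "PI")
  } else {
    GR <- matrix(0, n, length(meta$genRepLevels))
    colnames(GR) <- meta$genRepLevels
    pairKey <- paste(data$genotype, repKey, sep = "|")
    for (j in seq_along(meta$genRepLevels)) {
      GR[, j] <- as.numeric(pairKey == meta$genRepLevels[j])
    }
    colnames(GR) <- paste0("GR:", meta$genRepLevels)
    blocks$GR <- GR
    blocks$GPR <- scaleBlock(GR, Pc, "P")
    blocks$GIR <- scaleBlock(GR, Ic, "I")
    blocks$GPIR <- scaleBlock(GR, Pc * Ic, "PI")
  }
  do.call(cbind, blocks)
}

#' Build the design matrix and response for a G x E model
#'
#' Emits the full one-hot design in the stated term order (intercept,
#' experiment, genotype, nested replicate, humidity, PPFR, PRI, pNDVI,
#' PPFR x PRI, then the genotype- or plot-level interaction blocks).
#' Aliased columns are not dropped here; [fitGxE()] drops them
#' deterministically during the QR factorization.
#'
#' @param records Minute-averaged, environment-attached lift records with
#'   non-missing `humidity`, `ppfr`, `pri`, `pndvi`.
#' @param modelKind `"maize"` (genotype-level interactions) or
#'   `"soybean"` (plot-level interactions).
#' @return A list: `X` (design matrix), `y` (Fq'/Fm' response), `meta`
#'   (factor levels, covariate centers, observed genotype x replicate
#'   pairs).
#' @export
buildDesign <- function(records, modelKind = c("maize", "soybean")) {
  modelKind <- match.arg(modelKind)
  for (cv in .gxeCovariates) {
    if (!cv %in% names(records) || all(is.na(records[[cv]]))) {
      stop("covariate entirely missing: ", cv, call. = FALSE)
    }
  }
  need <- c("fqfm", .gxeCovariates)
  cc <- complete.cases(records[, need])
  records <- records[cc, , drop = FALSE]
  if (nrow(records) == 0L) stop("no complete observations", call. = FALSE)
  repKey <- paste(records$experiment_id, records$treatment,
                  records$replicate_id, sep = "/")
  meta <- list(
    modelKind = modelKind,
    expLevels = sort(unique(records$experiment_id)),
    genLevels = sort(unique(records$genotype)),
    repLevels = sort(unique(repKey)),
    repGrid = unique(records[, c("experiment_id", "treatment",
                                 "replicate_id")]),
    centers = vapply(.gxeCovariates, function(cv) mean(records[[cv]]),
                     numeric(1)))
  names(meta$centers) <- names(.gxeCovariates)
  if (modelKind == "soybean") {
    meta$genRepLevels <- sort(unique(paste(records$genotype, repKey,
                                           sep = "|")))
  }
  list(X = .gxeDesign(records, meta), y = records$fqfm, meta = meta)
}

#' Fitted fixed-effects G x E model
#'
#' Ordinary-least-squares fit of the maize- or soybean-style model.
#' Coefficients of aliased (dropped) columns are `NA` and act as zeros in
#' predictions; `vcov` covers the retained columns only.
#'
#' @slot modelKind `"maize"` or `"soybean"`.
#' @slot coefficients Named coefficient vector over all built columns
#'   (`NA` = aliased, dropped).
#' @slot vcov Covariance matrix of the retained coefficients.
#' @slot sigma Residual standard deviation.
#' @slot df Residual degrees of freedom.
#' @slot r.squared Coefficient of determination.
#' @slot n Number of observations used.
#' @slot meta Design metadata (factor levels, covariate centers).
#' @export
setClass("GxEFit",
         representation(modelKind = "character", coefficients = "numeric",
                        vcov = "matrix", sigma = "numeric", df = "numeric",
                        r.squared = "numeric", n = "integer", meta = "list"),
         validity = function(object) {
           kept <- names(object@coefficients)[!is.na(object@coefficients)]
           if (!identical(rownames(object@vcov), kept)) {
             return("vcov rows must match retained coefficients")
           }
           ev <- eigen(object@vcov, symmetric = TRUE, only.values = TRUE)
           tol <- -1e-8 * max(abs(ev$values), 1)
           if (any(ev$values < tol)) {
             return("vcov must be positive semi-definite")
           }
           TRUE
         })

setMethod("show", "GxEFit", function(object) {
  cat(sprintf(
    "GxEFit (%s style): n = %d, %d/%d coefficients retained\n",
    object@modelKind, object@n, sum(!is.na(object@coefficients)),
    length(object@coefficients)))
  cat(sprintf("  residual SD = %.4g, R-squared = %.3f\n",
              object@sigma, object@r.squared))
  cat(sprintf("  genotypes: %s\n",
              paste(object@meta$genLevels, collapse = ", ")))
})

#' @describeIn GxEFit Named coefficient vector (`NA` for aliased columns).
#' @param object A `GxEFit`.
#' @export
setMethod("coef", "GxEFit", function(object) object@coefficients)

#' @describeIn GxEFit Covariance matrix of the retained coefficients.
#' @export
setMethod("vcov", "GxEFit", function(object) object@vcov)

#' Fit the G x E model by ordinary least squares
#'
#' Builds the design via [buildDesign()] and solves the least-squares
#' problem. Rank deficiency is resolved deterministically: columns are
#' processed left-to-right in the stated term order and a column aliased
#' with earlier ones is dropped (coefficient `NA`, treated as zero).
#'
#' @param records Minute-averaged lift records with environment attached.
#' @param modelKind `"maize"` or `"soybean"` (see [buildDesign()]).
#' @return A [GxEFit-class] object.
#' @export
fitGxE <- function(records, modelKind = c("maize", "soybean")) {
  d <- buildDesign(records, modelKind)
  n <- length(d$y)
  fit <- lm.fit(d$X, d$y)
  r <- fit$rank
  if (n <= r) stop("need more observations than retained columns",
                   call. = FALSE)
  piv <- fit$qr$pivot[seq_len(r)]
  Rm <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  XtXinv <- chol2inv(Rm)  # order: pivoted columns piv
  ord <- order(piv)       # back to original column order
  XtXinv <- XtXinv[ord, ord, drop = FALSE]
  keptNames <- colnames(d$X)[sort(piv)]
  dimnames(XtXinv) <- list(keptNames, keptNames)
  rss <- sum(fit$residuals^2)
  tss <- sum((d$y - mean(d$y))^2)
  sigma2 <- rss / (n - r)
  new("GxEFit",
      modelKind = d$meta$modelKind,
      coefficients = setNames(fit$coefficients, colnames(d$X)),
      vcov = sigma2 * XtXinv,
      sigma = sqrt(sigma2),
      df = n - r,
      r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
      n = as.integer(n),
      meta = d$meta)
}

# Value and SE of an estimable linear combination given as a full-design
# row vector; aliased entries act as zeros (valid because the reduced
# solution with zeroed aliased coefficients is a least-squares solution).
.gxeCombination <- function(fit, cvec) {
  beta <- fit@coefficients
  kept <- !is.na(beta)
  ck <- cvec[kept]
  value <- sum(ck * beta[kept])
  se <- sqrt(max(0, drop(ck %*% fit@vcov %*% ck)))
  c(value = value, se = se)
}

# Design rows for prediction-style newdata under the fit's metadata.
.gxeRows <- function(fit, newdata) {
  .gxeDesign(newdata, fit@meta)
}

# A covariate-reference newdata row: first observed factor combination,
# covariates at their grand means.
.gxeReferenceRow <- function(fit, genotype,
                             experiment = NULL, treatment = NULL,
                             replicate = NULL, ppfr = NULL, pri = NULL) {
  g <- fit@meta$repGrid[1L, ]
  data.frame(
    experiment_id = experiment %||% g$experiment_id,
    treatment = treatment %||% g$treatment,
    replicate_id = replicate %||% g$replicate_id,
    genotype = genotype,
    humidity = fit@meta$centers[["H"]],
    ppfr = ppfr %||% fit@meta$centers[["P"]],
    pri = pri %||% fit@meta$centers[["I"]],
    pndvi = fit@meta$centers[["N"]],
    stringsAsFactors = FALSE)
}

#' Genotype-specific Fq'/Fm' response slopes to PPFR
#'
#' The slope of expected Fq'/Fm' per unit PPFR for each genotype (maize
#' style) or each genotype x plot (soybean style), evaluated with the
#' other covariates held at their grand means (so the three-way
#' PPFR x PRI x genotype term is evaluated at the PRI grand mean).
#' Computed model-free as a prediction difference over a unit PPFR step;
#' standard errors by the delta method on the coefficient covariance.
#'
#' @param fit A [GxEFit-class] object.
#' @param genotypes Genotypes to extract (default: all in the fit).
#' @return A `data.frame` with `genotype` (and `replicate_id`,
#'   `experiment_id`, `treatment` for soybean style), `slope`
#'   ((umol photons m-2 s-1)^-1) and `se`.
#' @export
responseSlopes <- function(fit, genotypes = NULL) {
  stopifnot(is(fit, "GxEFit"))
  genotypes <- genotypes %||% fit@meta$genLevels
  bad <- setdiff(genotypes, fit@meta$genLevels)
  if (length(bad)) {
    stop("genotype absent from fit: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p0 <- fit@meta$centers[["P"]]
  slopeFor <- function(g, experiment = NULL, treatment = NULL,
                       replicate = NULL) {
    nd <- rbind(.gxeReferenceRow(fit, g, experiment, treatment, replicate,
                                 ppfr = p0),
                .gxeReferenceRow(fit, g, experiment, treatment, replicate,
                                 ppfr = p0 + 1))
    X <- .gxeRows(fit, nd)
    .gxeCombination(fit, X[2L, ] - X[1L, ])
  }
  if (fit@modelKind == "maize") {
    est <- t(vapply(genotypes, slopeFor, numeric(2)))
    data.frame(genotype = genotypes, slope = est[, "value"],
               se = est[, "se"], row.names = NULL)
  } else {
    pairs <- do.call(rbind, strsplit(fit@meta$genRepLevels,
                                     split = "|", fixed = TRUE))
    keys <- do.call(rbind, strsplit(pairs[, 2L], split = "/", fixed = TRUE))
    tab <- data.frame(genotype = pairs[, 1L], experiment_id = keys[, 1L],
                      treatment = keys[, 2L], replicate_id = keys[, 3L],
                      stringsAsFactors = FALSE)
    tab <- tab[tab$genotype %in% genotypes, , drop = FALSE]
    est <- t(mapply(function(g, e, tr, r) slopeFor(g, e, tr, r),
                    tab$genotype, tab$experiment_id, tab$treatment,
                    tab$replicate_id))
    tab$slope <- est[, 1L]
    tab$se <- est[, 2L]
    rownames(tab) <- NULL
    tab
  }
}

#' Adjusted (marginal) Fq'/Fm' means per genotype
#'
#' Model prediction for each genotype with covariates fixed at their
#' grand means, averaged over the observed factor levels with equal
#' weight per experiment and, within an experiment, equal weight per
#' observed treatment x replicate cell. Standard errors by the delta
#' method.
#'
#' @param fit A [GxEFit-class] object.
#' @param genotypes Genotypes to extract (default: all).
#' @return A `data.frame` with `genotype`, `mean`, `se`.
#' @export
adjustedMeans <- function(fit, genotypes = NULL) {
  stopifnot(is(fit, "GxEFit"))
  genotypes <- genotypes %||% fit@meta$genLevels
  bad <- setdiff(genotypes, fit@meta$genLevels)
  if (length(bad)) {
    stop("genotype absent from fit: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grid <- fit@meta$repGrid
  wExp <- 1 / length(unique(grid$experiment_id))
  cellsPerExp <- table(grid$experiment_id)
  w <- as.numeric(wExp / cellsPerExp[grid$experiment_id])
  est <- t(vapply(genotypes, function(g) {
    nd <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      .gxeReferenceRow(fit, g, grid$experiment_id[i], grid$treatment[i],
                       grid$replicate_id[i])
    }))
    X <- .gxeRows(fit, nd)
    .gxeCombination(fit, drop(w %*% X))
  }, numeric(2)))
  data.frame(genotype = genotypes, mean = est[, "value"], se = est[, "se"],
             row.names = NULL)
}

#' Pearson correlation of genotype estimates with biomass
#'
#' Averages both the estimate and the biomass over replicates to genotype
#' level, then computes the Pearson correlation over the paired
#' genotypes. Pairs with missing biomass are dropped; zero variance in
#' either vector yields `NA`.
#'
#' @param estimates A `data.frame` with `genotype` and a value column
#'   (e.g. the output of [responseSlopes()] or [adjustedMeans()]).
#' @param biomass Biomass records (see [readDataset()]).
#' @param valueCol Name of the value column in `estimates`.
#' @return A list: `r`, `n` (paired genotypes), `pairs` (`data.frame`).
#' @export
correlateWithBiomass <- function(estimates, biomass, valueCol = "slope") {
  if (!valueCol %in% names(estimates)) {
    stop("no column '", valueCol, "' in estimates", call. = FALSE)
  }
  estG <- aggregate(estimates[[valueCol]],
                    by = list(genotype = estimates$genotype),
                    FUN = mean)
  names(estG)[2L] <- "estimate"
  bioG <- aggregate(list(mass = biomass$mass),
                    by = list(genotype = biomass$genotype), FUN = mean)
  pairs <- merge(estG, bioG, by = "genotype")
  pairs <- pairs[complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 3L) {
    stop("need >= 3 paired genotypes, got ", nrow(pairs), call. = FALSE)
  }
  r <- if (sd(pairs$estimate) == 0 || sd(pairs$mass) == 0) NA_real_ else
    cor(pairs$estimate, pairs$mass)
  list(r = r, n = nrow(pairs), pairs = pairs)
}
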
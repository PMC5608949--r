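## Preprocessing chain for raw multifluid intensity matrices:
## run-day rescaling and filtering, probabilistic quotient normalization,
## log2 transform, robust multivariate outlier exclusion, and two-stage
## imputation (censored-normal MLE, then predictive mean matching).

#' Filter features with too many sparsely measured run days
#'
#' A run-day median is only trustworthy when enough values were measured
#' on that day.  A feature is removed when the number of run days with
#' fewer than three non-missing values exceeds half of the total number
#' of run days (strictly more than half).
#'
#' @param x An [mf_data] object with raw intensities.
#' @return List with the filtered `data` and the `dropped` feature ids.
#' @export
runday_filter <- function(x) {
  stopifnot(inherits(x, "mf_data"))
  days <- unique(x$runday)
  if (length(days) == 0L) stop("no run days present")
  miss_by_day <- vapply(days, function(d) {
    colSums(!is.na(x$values[x$runday == d, , drop = FALSE])) < 3L
  }, logical(ncol(x$values)))
  miss_by_day <- matrix(miss_by_day, ncol = length(days))
  bad <- rowSums(miss_by_day) > length(days) / 2
  dropped <- feature_ids(x)[bad]
  data <- if (any(bad)) mf_subset(x, features = !bad) else x
  list(data = data, dropped = dropped)
}

#' Rescale each feature by its run-day median
#'
#' Corrects day-to-day drift of the measurement platform: every value is
#' divided by the median of its feature on its run day (computed over
#' non-missing values).  After rescaling, each (feature, run day) cell
#' has median 1.
#'
#' @param x An [mf_data] object (raw scale).
#' @return List with the rescaled `data` and the `medians` matrix
#'   (features x run days) used, for later back-mapping of imputed raw
#'   values.
#' @export
runday_normalize <- function(x) {
  stopifnot(inherits(x, "mf_data"), !x$log2)
  days <- unique(x$runday)
  med <- matrix(NA_real_, ncol(x$values), length(days),
                dimnames = list(feature_ids(x), days))
  v <- x$values
  for (d in days) {
    rows <- x$runday == d
    m <- apply(v[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    med[, d] <- m
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2L, m, `/`)
  }
  list(data = mf_data(v, x$runday, x$fluid), medians = med)
}

#' Probabilistic quotient normalization of one fluid block
#'
#' Corrects per-sample dilution (e.g. urine concentration, saliva flow):
#' a reference pseudo-sample is the per-feature mean over all samples,
#' using only features of the block with no missing entries; each
#' sample's dilution factor is the median quotient of its values against
#' the reference over those complete features, and all of the sample's
#' values in the block are divided by it.
#'
#' @param x An [mf_data] object (raw scale, run-day rescaled).
#' @param fluid Fluid label selecting the feature block to normalize.
#' @return List with normalized `data`, the per-sample `dilution`
#'   factors, and the `reference` pseudo-sample (named over the
#'   complete features).
#' @export
pqn_normalize <- function(x, fluid) {
  stopifnot(inherits(x, "mf_data"), !x$log2)
  block <- which(x$fluid == fluid)
  if (length(block) == 0L) stop("no features with fluid '", fluid, "'")
  v <- x$values[, block, drop = FALSE]
  complete <- colSums(is.na(v)) == 0L
  if (!any(complete))
    stop("no fully observed feature in fluid '", fluid,
         "'; PQN needs at least one complete feature ",
         "(impute or relax the fluid selection)")
  ref <- colMeans(v[, complete, drop = FALSE])
  quot <- sweep(v[, complete, drop = FALSE], 2L, ref, `/`)
  d <- apply(quot, 1L, stats::median)
  if (any(d <= 0)) stop("non-positive dilution factor estimated")
  out <- x$values
  out[, block] <- sweep(v, 1L, d, `/`)
  list(data = mf_data(out, x$runday, x$fluid),
       dilution = stats::setNames(d, sample_ids(x)),
       reference = ref)
}

#' Log2-transform an intensity matrix
#'
#' @param x An [mf_data] object with strictly positive intensities.
#' @return The matrix on the log2 scale (missing entries preserved).
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "mf_data"))
  if (x$log2) stop("already log2-transformed")
  mf_data(log2(x$values), x$runday, x$fluid, log2 = TRUE)
}

#' Robust multivariate outlier detection
#'
#' Computes a robust Mahalanobis-type outlier score per sample: features
#' are centred by their median and scaled by their MAD, the matrix is
#' projected onto principal components retaining at least 99% of the
#' variance, and each sample's distance is aggregated over components
#' scaled by their robust spread.  Samples whose score exceeds
#' `threshold_sd` robust standard deviations above the median score are
#' flagged.  Run per fluid on features without missing values, on the
#' log scale.
#'
#' @param x_complete Numeric matrix (samples x features), fully
#'   observed, log scale, with sample ids as rownames.
#' @param threshold_sd Exclusion criterion in robust SD units
#'   (default 4).
#' @return Character vector of flagged sample ids.
#' @export
detect_outliers <- function(x_complete, threshold_sd = 4) {
  x_complete <- as.matrix(x_complete)
  if (threshold_sd <= 0) stop("threshold_sd must be positive")
  if (ncol(x_complete) < 3L)
    stop("need at least 3 fully observed features for outlier detection")
  if (anyNA(x_complete)) stop("x_complete must not contain missing values")
  med <- apply(x_complete, 2L, stats::median)
  sc <- apply(x_complete, 2L, robust_sd)
  if (any(sc == 0)) stop("zero-spread feature in outlier detection")
  z <- sweep(sweep(x_complete, 2L, med), 2L, sc, `/`)
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- min(which(cum >= 0.99), min(dim(x_complete)))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  spread <- apply(scores, 2L, robust_sd)
  spread[spread == 0] <- 1
  d <- sqrt(rowSums(sweep(scores, 2L, spread, `/`)^2))
  cut <- stats::median(d) + threshold_sd * robust_sd(d)
  rownames(x_complete)[d > cut]
}

#' Drop features with excessive missingness
#'
#' @param x An [mf_data] object.
#' @param max_frac Maximum tolerated missing fraction; features with
#'   strictly more are removed (default 0.20).
#' @return List with filtered `data` and `dropped` feature ids.
#' @export
missingness_filter <- function(x, max_frac = 0.20) {
  stopifnot(inherits(x, "mf_data"))
  frac <- colMeans(is.na(x$values))
  bad <- frac > max_frac
  list(data = if (any(bad)) mf_subset(x, features = !bad) else x,
       dropped = feature_ids(x)[bad])
}

#' Maximum-likelihood fit of a left-censored normal
#'
#' Fits N(mu, sigma^2) to `observed` values together with `n_censored`
#' values known only to lie at or below the censor point `censor`, by
#' maximizing the likelihood
#' `sum(log dnorm(x; mu, sigma)) + n_censored * log pnorm(censor; mu, sigma)`.
#'
#' @param observed Numeric vector of observed values.
#' @param n_censored Number of left-censored observations.
#' @param censor Censor point (detection limit).
#' @return List with `mu`, `sigma`, `converged`.
#' @export
fit_censored_normal <- function(observed, n_censored, censor) {
  stopifnot(length(observed) >= 2L, n_censored >= 0)
  m0 <- mean(observed); s0 <- stats::sd(observed)
  if (n_censored == 0L)
    return(list(mu = m0, sigma = s0, converged = TRUE))
  nll <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    -(sum(stats::dnorm(observed, mu, sig, log = TRUE)) +
        n_censored * stats::pnorm(censor, mu, sig, log.p = TRUE))
  }
  ## start from observed moments, inflated to account for the cut tail
  fit <- try(stats::optim(c(m0, log(s0 * 1.2)), nll, method = "Nelder-Mead",
                          control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0)
    return(list(mu = m0, sigma = s0, converged = FALSE))
  sigma <- exp(fit$par[2])
  if (!is.finite(sigma) || sigma < 1e-8)
    return(list(mu = m0, sigma = s0, converged = FALSE))
  list(mu = fit$par[1], sigma = sigma, converged = TRUE)
}

#' Impute left-censored missing values per feature and run day
#'
#' Assumes missingness arises from a detection limit: for every
#' (feature, run day) cell with strictly more than 10 non-missing
#' values, a left-censored normal is fitted by maximum likelihood with
#' the censor point at the minimum observed value of that cell, and each
#' missing value is drawn from the fitted normal truncated to the
#' censored tail.  Works on log-transformed raw (pre-normalization)
#' data.  Cells with too few observations, or where the fit fails, are
#' left missing for [impute_pmm()].
#'
#' @param x_log_raw An [mf_data] object on the log2 scale (raw,
#'   pre-normalization values).
#' @param seed Integer master seed; draws use per-(feature, run day)
#'   substreams so feature order does not change them.
#' @param min_obs Minimum non-missing count per cell for the censored
#'   fit (strictly more than this; default 10).
#' @return List with imputed `data` and a `report` data frame (one row
#'   per imputed cell: feature, runday, n_imputed, censor, mu, sigma,
#'   converged).
#' @export
impute_censored <- function(x_log_raw, seed = 1L, min_obs = 10L) {
  stopifnot(inherits(x_log_raw, "mf_data"), x_log_raw$log2)
  v <- x_log_raw$values
  days <- unique(x_log_raw$runday)
  rows_of <- lapply(days, function(d) which(x_log_raw$runday == d))
  names(rows_of) <- days
  rep_rows <- list()
  for (j in seq_len(ncol(v))) {
    if (!anyNA(v[, j])) next
    fid <- colnames(v)[j]
    for (d in days) {
      rows <- rows_of[[d]]
      obs <- v[rows, j]
      miss <- which(is.na(obs))
      if (length(miss) == 0L) next
      kept <- obs[!is.na(obs)]
      if (length(kept) <= min_obs) next
      cens <- min(kept)
      fit <- fit_censored_normal(kept, length(miss), cens)
      if (!fit$converged) {
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(feature = fid, runday = d, n_imputed = 0L,
                     censor = cens, mu = NA_real_, sigma = NA_real_,
                     converged = FALSE)
        next
      }
      draws <- with_substream(seed, paste0("cens|", fid, "|", d), {
        p0 <- stats::pnorm(cens, fit$mu, fit$sigma)
        u <- stats::runif(length(miss))
        if (p0 < 1e-300) rep(cens, length(miss))
        else pmin(stats::qnorm(u * p0, fit$mu, fit$sigma), cens)
      })
      v[rows[miss], j] <- draws
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(feature = fid, runday = d, n_imputed = length(miss),
                   censor = cens, mu = fit$mu, sigma = fit$sigma,
                   converged = TRUE)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(feature = character(0), runday = character(0),
               n_imputed = integer(0), censor = numeric(0),
               mu = numeric(0), sigma = numeric(0), converged = logical(0))
  list(data = mf_data(v, x_log_raw$runday, x_log_raw$fluid, log2 = TRUE),
       report = report)
}

#' Predictive mean matching imputation of residual missing values
#'
#' For each feature with missing entries, regresses the feature on its
#' `k` most correlated fully observed features, ranks observed values by
#' the closeness of their predicted means to the predicted mean of each
#' missing entry, and draws uniformly from the `donors` closest
#' observations.  Imputed values are therefore always observed values of
#' the same feature.  Features with fewer than 10 observed values (or
#' when no complete predictor exists) are drawn from their marginal
#' empirical distribution instead.
#'
#' @param x An [mf_data] object (log scale, partially missing).
#' @param donors Number of donor candidates (default 5).
#' @param k Number of predictor features (default 10).
#' @param seed Integer master seed (per-feature substreams).
#' @return List with fully observed `data` and a per-feature `counts`
#'   data frame (pmm draws, marginal draws).
#' @export
impute_pmm <- function(x, donors = 5L, k = 10L, seed = 1L) {
  stopifnot(inherits(x, "mf_data"))
  v <- x$values
  complete <- which(colSums(is.na(v)) == 0L)
  counts <- list()
  for (j in seq_len(ncol(v))) {
    y <- v[, j]
    miss <- which(is.na(y))
    if (length(miss) == 0L) next
    obs <- which(!is.na(y))
    fid <- colnames(v)[j]
    marginal <- length(obs) < 10L || length(complete) == 0L
    if (!marginal) {
      preds <- setdiff(complete, j)
      if (length(preds) == 0L) marginal <- TRUE
    }
    if (marginal) {
      v[miss, j] <- with_substream(seed, paste0("pmm|", fid),
        sample(y[obs], length(miss), replace = TRUE))
      counts[[fid]] <- data.frame(feature = fid, pmm = 0L,
                                  marginal = length(miss))
      next
    }
    cors <- abs(suppressWarnings(
      stats::cor(y[obs], v[obs, preds, drop = FALSE])))
    cors[is.na(cors)] <- 0
    top <- preds[order(cors, decreasing = TRUE)[seq_len(min(k, length(preds)))]]
    X <- cbind(1, v[, top, drop = FALSE])
    beta <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])$coefficients
    beta[is.na(beta)] <- 0
    pred <- drop(X %*% beta)
    v[miss, j] <- with_substream(seed, paste0("pmm|", fid), {
      vapply(miss, function(i) {
        nd <- order(abs(pred[obs] - pred[i]))[seq_len(min(donors, length(obs)))]
        y[obs][nd][sample(length(nd), 1L)]
      }, numeric(1))
    })
    counts[[fid]] <- data.frame(feature = fid, pmm = length(miss),
                                marginal = 0L)
  }
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(feature = character(0), pmm = integer(0),
               marginal = integer(0))
  rownames(counts) <- NULL
  list(data = mf_data(v, x$runday, x$fluid, log2 = x$log2),
       counts = counts)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: run-day filtering, run-day median rescaling,
#' probabilistic quotient normalization of the configured fluids, log2
#' transform, per-fluid robust multivariate outlier exclusion,
#' missingness filtering, censored-normal imputation (fitted on the
#' log2 raw, pre-normalization values and mapped back to the normalized
#' scale), and predictive mean matching for the remainder.  The output
#' matrix is fully observed, on the log2 scale.
#'
#' @param x An [mf_data] object with raw intensities.
#' @param pqn_fluids Fluids to dilution-normalize (default urine and
#'   saliva, `c("U", "S")`).
#' @param outlier_sd Outlier exclusion criterion in robust SD units.
#' @param max_missing Maximum missing fraction per feature.
#' @param seed Integer master seed for the imputation draws.
#' @return List with the processed `data` and a `report` of class
#'   `mf_preprocess_report`.
#' @export
mf_preprocess <- function(x, pqn_fluids = c("U", "S"), outlier_sd = 4,
                          max_missing = 0.20, seed = 1L) {
  stopifnot(inherits(x, "mf_data"), !x$log2)
  f1 <- runday_filter(x)
  rn <- runday_normalize(f1$data)
  cur <- rn$data
  dilution <- list()
  for (fl in intersect(pqn_fluids, unique(cur$fluid))) {
    pq <- pqn_normalize(cur, fl)
    cur <- pq$data
    dilution[[fl]] <- pq$dilution
  }
  cur <- log2_transform(cur)

  outliers <- character(0)
  skipped_fluids <- character(0)
  for (fl in unique(cur$fluid)) {
    block <- cur$values[, cur$fluid == fl, drop = FALSE]
    block <- block[, colSums(is.na(block)) == 0L, drop = FALSE]
    if (ncol(block) < 3L) {
      skipped_fluids <- c(skipped_fluids, fl)
      next
    }
    outliers <- union(outliers, detect_outliers(block, outlier_sd))
  }
  keep <- setdiff(sample_ids(cur), outliers)
  cur <- mf_subset(cur, samples = keep)

  f2 <- missingness_filter(cur, max_missing)
  cur <- f2$data

  ## censored fit on log2 raw values of the retained cells, then map the
  ## draws onto the normalized scale via the run-day medians and
  ## dilution factors applied to that cell
  raw_kept <- mf_subset(x, samples = keep,
                        features = intersect(feature_ids(x),
                                             feature_ids(cur)))
  ic <- impute_censored(log2_transform(raw_kept), seed = seed)
  imp_raw <- ic$data$values
  v <- cur$values
  was_missing <- is.na(v)
  med <- rn$medians
  for (j in seq_len(ncol(v))) {
    fid <- colnames(v)[j]
    fl <- cur$fluid[[j]]
    fill <- which(was_missing[, j] & !is.na(imp_raw[, fid]))
    if (length(fill) == 0L) next
    sm <- rownames(v)[fill]
    offset <- log2(med[fid, cur$runday[sm]])
    if (fl %in% names(dilution))
      offset <- offset + log2(dilution[[fl]][sm])
    v[fill, j] <- imp_raw[sm, fid] - offset
  }
  cur <- mf_data(v, cur$runday, cur$fluid, log2 = TRUE)
  n_cens <- colSums(was_missing & !is.na(v))

  pm <- impute_pmm(cur, seed = seed)
  cur <- pm$data

  report <- structure(list(
    features_dropped_runday = f1$dropped,
    features_dropped_missingness = f2$dropped,
    samples_dropped_outlier = outliers,
    outlier_skipped_fluids = skipped_fluids,
    dilution_factors = dilution,
    censored_fits = ic$report,
    censored_draws = n_cens[n_cens > 0],
    pmm_counts = pm$counts), class = "mf_preprocess_report")
  list(data = cur, report = report)
}

#' @export
print.mf_preprocess_report <- function(x, ...) {
  cat("<mf_preprocess_report>\n")
  cat("  features dropped (run-day rule):   ",
      length(x$features_dropped_runday), "\n")
  cat("  features dropped (missingness):    ",
      length(x$features_dropped_missingness), "\n")
  cat("  samples excluded as outliers:      ",
      length(x$samples_dropped_outlier), "\n")
  cat("  fluids dilution-normalized (PQN):  ",
      paste(names(x$dilution_factors), collapse = ", "), "\n")
  cat("  censored-normal draws:             ", sum(x$censored_draws), "\n")
  cat("  predictive-mean-matching draws:    ",
      sum(x$pmm_counts$pmm) + sum(x$pmm_counts$marginal), "\n")
  invisible(x)
}
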
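## Build an intensity matrix from a per-day observation plan: counts[d, j]
## non-missing values for feature j on day d (5 samples per day).
planned_matrix <- function(counts, per_day = 5L) {
  n_days <- nrow(counts)
  n <- n_days * per_day
  v <- matrix(NA_real_, n, ncol(counts),
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%d", seq_len(ncol(counts)))))
  runday <- rep(sprintf("d%d", seq_len(n_days)), each = per_day)
  set.seed(99)
  for (d in seq_len(n_days))
    for (j in seq_len(ncol(counts))) {
      rows <- which(runday == sprintf("d%d", d))[seq_len(counts[d, j])]
      v[rows, j] <- 2^rnorm(length(rows), 10)
    }
  mf_data(v, runday, rep("P", ncol(counts)))
}

test_that("run-day filter drops features sparse on more than half the days", {
  ## f1: >=3 on every day; f2: 2,2,2,5 -> 3 of 4 days fail (> half) ->
  ## dropped; f3: 2,2,3,3 -> 2 of 4 fail, not more than half -> retained
  x <- planned_matrix(cbind(f1 = c(3, 4, 5, 5), f2 = c(2, 2, 2, 5),
                            f3 = c(2, 2, 3, 3)))
  out <- runday_filter(x)
  expect_identical(out$dropped, "f2")
  expect_setequal(colnames(out$data$values), c("f1", "f3"))
})

test_that("run-day rescaling divides by the per-day feature median", {
  v <- matrix(c(2, 4, 6, 5, 5, 5), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  x <- mf_data(v, runday = rep("d1", 3), fluid = c("P", "P"))
  out <- runday_normalize(x)
  expect_equal(unname(out$data$values[, "f1"]), c(0.5, 1, 1.5))
  expect_equal(unname(out$data$values[, "f2"]), c(1, 1, 1))
  expect_equal(unname(out$medians[, "d1"]), c(4, 5))
})

test_that("run-day rescaling leaves every (feature, day) with median 1", {
  x <- planned_matrix(cbind(f1 = c(5, 5, 5, 5), f2 = c(3, 4, 5, 3)))
  out <- runday_normalize(x)$data
  for (d in unique(out$runday)) {
    meds <- apply(out$values[out$runday == d, , drop = FALSE], 2,
                  median, na.rm = TRUE)
    expect_equal(unname(meds), rep(1, 2))
  }
})

test_that("PQN estimates the planted per-sample dilution exactly in the noise-free case", {
  set.seed(1)
  r <- 2^rnorm(6, 10)                       # true profile
  dil <- c(s1 = 1, s2 = 2, s3 = 0.25)
  v <- outer(dil, r)
  colnames(v) <- paste0("f", 1:6)
  x <- mf_data(v, runday = rep("d1", 3), fluid = rep("U", 6))
  out <- pqn_normalize(x, "U")
  ## dilution factors are recovered up to the common scale mean(dil)
  expect_equal(unname(out$dilution / out$dilution["s1"]),
               unname(dil / dil["s1"]), tolerance = 1e-12)
  ## a sample equal to the reference gets d = 1 and is unchanged
  v2 <- rbind(v, sM = colMeans(v))
  x2 <- mf_data(v2, runday = rep("d1", 4), fluid = rep("U", 6))
  out2 <- pqn_normalize(x2, "U")
  expect_equal(unname(out2$dilution["sM"]), 1, tolerance = 1e-12)
  expect_equal(out2$data$values["sM", ], x2$values["sM", ],
               tolerance = 1e-12)
})

test_that("PQN self-quotient against its reference is exactly 1", {
  syn <- generate_synthetic(synth_config(
    n_samples = 60, n_features = c(U = 40), n_subpathways = c(U = 8),
    n_rundays = 1, censor_quantile = 0.1, censored_frac = 0.4,
    unknown_frac = 0, seed = 3))
  out <- pqn_normalize(syn$data, "U")
  complete <- names(out$reference)
  quot <- sweep(out$data$values[, complete], 2, out$reference, `/`)
  expect_equal(unname(apply(quot, 1, median)), rep(1, 60),
               tolerance = 1e-12)
})

test_that("PQN demands at least one complete feature", {
  v <- matrix(c(1, NA, NA, 1), 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  x <- mf_data(v, runday = c("d1", "d1"), fluid = c("U", "U"))
  expect_error(pqn_normalize(x, "U"), "complete feature")
})

test_that("log2 transform is exact and invertible", {
  v <- matrix(c(8, 1, 2, 1024), 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  x <- mf_data(v, runday = c("d1", "d1"), fluid = c("P", "P"))
  lg <- log2_transform(x)
  expect_equal(unname(lg$values[, "f1"]), c(3, 0))
  expect_true(lg$log2)
  expect_equal(2^lg$values, v, tolerance = 1e-12)
  expect_error(log2_transform(lg), "already")
  expect_error(mf_data(matrix(c(-1, 2), 1,
                              dimnames = list("s1", c("f1", "f2"))),
                       "d1", c("P", "P")), "non-positive")
})

test_that("a planted extreme sample is flagged and duplicates of inliers are not", {
  flagged <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(300 * 10), 300)
    x[7, ] <- 10                      # 10 SD on every axis
    rownames(x) <- sprintf("s%03d", 1:300)
    out <- detect_outliers(x, threshold_sd = 4)
    "s007" %in% out
  }, logical(1))
  expect_true(all(flagged))

  set.seed(1)
  x <- matrix(rnorm(200 * 8), 200)
  x[2, ] <- x[1, ]                    # duplicate of an inlier
  rownames(x) <- sprintf("s%03d", 1:200)
  expect_false("s002" %in% detect_outliers(x))
})

test_that("flag rate on a homogeneous Gaussian cloud is small", {
  rates <- vapply(1:10, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(300 * 10), 300)
    rownames(x) <- sprintf("s%03d", 1:300)
    length(detect_outliers(x, 4)) / 300
  }, numeric(1))
  expect_lt(mean(rates), 0.02)
})

test_that("outlier detection validates its inputs", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("s%d", 1:10)))
  expect_error(detect_outliers(x), "at least 3")
  x3 <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("s%d", 1:10)))
  expect_error(detect_outliers(x3, threshold_sd = 0), "positive")
})

test_that("missingness filter applies a strict 20% rule", {
  n <- 100
  v <- matrix(2^rnorm(n * 3, 10), n,
              dimnames = list(sprintf("s%03d", 1:n), c("f20", "f21", "f0")))
  v[1:20, "f20"] <- NA              # exactly 20% -> retained
  v[1:21, "f21"] <- NA              # 21% -> dropped
  x <- mf_data(v, rep("d1", n), rep("P", 3))
  out <- missingness_filter(x, 0.20)
  expect_identical(out$dropped, "f21")
  expect_setequal(colnames(out$data$values), c("f20", "f0"))
})

test_that("censored-normal MLE agrees with an independent fitting routine", {
  set.seed(21)
  x <- rnorm(400, mean = 5, sd = 2)
  cens <- quantile(x, 0.3)
  obs <- x[x >= cens]
  fit <- fit_censored_normal(obs, sum(x < cens), min(obs))
  ## independent oracle: fitdistrplus on the censored-data representation
  cdat <- data.frame(
    left = c(obs, rep(NA, sum(x < cens))),
    right = c(obs, rep(min(obs), sum(x < cens))))
  oracle <- fitdistrplus::fitdistcens(cdat, "norm")
  expect_equal(fit$mu, unname(oracle$estimate["mean"]), tolerance = 1e-3)
  expect_equal(fit$sigma, unname(oracle$estimate["sd"]), tolerance = 1e-3)
  ## no censoring: plain moments
  nofit <- fit_censored_normal(c(1, 2, 3), 0, 0)
  expect_equal(nofit$mu, 2)
})

test_that("censored imputation respects the censor bound and observed values", {
  syn <- generate_synthetic(synth_config(
    n_samples = 120, n_features = c(P = 10), n_subpathways = c(P = 2),
    n_rundays = 2, censor_quantile = 0.15, censored_frac = 1,
    unknown_frac = 0, seed = 8))
  xlog <- log2_transform(syn$data)
  out <- impute_censored(xlog, seed = 5)
  expect_false(anyNA(out$data$values))
  obs_mask <- !is.na(xlog$values)
  expect_identical(out$data$values[obs_mask], xlog$values[obs_mask])
  for (d in unique(xlog$runday)) {
    rows <- xlog$runday == d
    for (j in seq_len(ncol(xlog$values))) {
      imp <- is.na(xlog$values[rows, j])
      if (!any(imp)) next
      expect_true(all(out$data$values[rows, j][imp] <=
                        min(xlog$values[rows, j], na.rm = TRUE)))
    }
  }
  ## determinism and identity
  out2 <- impute_censored(xlog, seed = 5)
  expect_identical(out$data$values, out2$data$values)
  clean <- impute_censored(
    log2_transform(generate_synthetic(synth_config(
      n_samples = 30, n_features = c(P = 4), n_subpathways = c(P = 2),
      censor_quantile = 0, censored_frac = 0, unknown_frac = 0,
      seed = 2))$data), seed = 1)
  expect_identical(sum(clean$report$n_imputed), 0L)
})

test_that("censored imputation skips cells with too few observations", {
  v <- matrix(2^rnorm(5 * 2, 10), 5,
              dimnames = list(sprintf("s%d", 1:5), c("f1", "f2")))
  v[1, "f1"] <- NA
  x <- log2_transform(mf_data(v, rep("d1", 5), c("P", "P")))
  out <- impute_censored(x, seed = 1)
  expect_true(is.na(out$data$values[1, "f1"]))   # left for PMM
})

test_that("PMM imputes observed donor values deterministically", {
  set.seed(4)
  n <- 300
  base <- matrix(rnorm(n * 6), n)
  y <- base[, 1] + rnorm(n, sd = 0.3)
  v <- cbind(base, y)
  colnames(v) <- c(paste0("c", 1:6), "y")
  rownames(v) <- sprintf("s%03d", seq_len(n))
  miss <- sample(n, 40)
  v[miss, "y"] <- NA
  x <- mf_data(v + 20, rep("d1", n), rep("P", 7))   # keep positive
  out <- impute_pmm(x, seed = 9)
  expect_false(anyNA(out$data$values))
  imputed <- out$data$values[miss, "y"]
  observed <- x$values[-miss, "y"]
  expect_true(all(imputed %in% observed))
  out2 <- impute_pmm(x, seed = 9)
  expect_identical(out$data$values, out2$data$values)
  obs_mask <- !is.na(x$values)
  expect_identical(out$data$values[obs_mask], x$values[obs_mask])
})

test_that("PMM beats mean imputation on a correlated feature", {
  set.seed(11)
  n <- 1000
  xx <- rnorm(n)
  y <- xx + rnorm(n, sd = 0.1)
  extra <- matrix(rnorm(n * 9), n)
  v <- cbind(x = xx, y = y, extra) + 20
  colnames(v) <- c("x", "y", paste0("e", 1:9))
  rownames(v) <- sprintf("s%04d", seq_len(n))
  miss <- sample(n, 100)
  truth <- v[miss, "y"]
  v[miss, "y"] <- NA
  xm <- mf_data(v, rep("d1", n), rep("P", 11))
  out <- impute_pmm(xm, seed = 2)
  rmse_pmm <- sqrt(mean((out$data$values[miss, "y"] - truth)^2))
  rmse_mean <- sqrt(mean((mean(v[, "y"], na.rm = TRUE) - truth)^2))
  expect_lt(rmse_pmm, rmse_mean)
})

test_that("the full pipeline returns a fully observed log2 matrix and preserves observed values", {
  syn <- generate_synthetic(make_paper_shaped_config(
    n_samples = 250, scale = 0.08, n_rundays = 5, seed = 13))
  pp <- mf_preprocess(syn$data, seed = 13)
  expect_false(anyNA(pp$data$values))
  expect_true(pp$data$log2)
  expect_s3_class(pp$report, "mf_preprocess_report")

  ## recompute the deterministic (non-imputation) chain and check that
  ## observed cells are identical
  rn <- runday_normalize(runday_filter(syn$data)$data)
  cur <- rn$data
  for (fl in c("U", "S")) cur <- pqn_normalize(cur, fl)$data
  cur <- log2_transform(cur)
  keep_s <- rownames(pp$data$values)
  keep_f <- colnames(pp$data$values)
  ref <- cur$values[keep_s, keep_f]
  mask <- !is.na(ref)
  expect_equal(pp$data$values[mask], ref[mask], tolerance = 1e-12)

  ## dilution factors recorded for both configured fluids
  expect_setequal(names(pp$report$dilution_factors), c("U", "S"))
  expect_true(all(unlist(pp$report$dilution_factors) > 0))
})
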
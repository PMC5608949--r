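## Gaussian graphical model inference with shrinkage partial correlations
## and dual (Pearson + partial) Bonferroni edge selection.

#' Partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and rescales the off-diagonal entries
#' of the precision matrix: `pcor(i,j) = -Omega_ij / sqrt(Omega_ii *
#' Omega_jj)`.
#'
#' @param R Symmetric positive-definite correlation matrix.
#' @return Matrix of partial correlations (unit diagonal).
#' @export
cor_to_pcor <- function(R) {
  Om <- solve(R)
  d <- 1 / sqrt(diag(Om))
  pc <- -Om * tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(R)
  pc
}

## Analytic shrinkage intensity toward the identity for a correlation
## matrix (Schaefer-Strimmer form of the Ledoit-Wolf estimator):
## lambda* = sum_{i<j} Var-hat(r_ij) / sum_{i<j} r_ij^2, clipped to [0,1].
shrinkage_intensity <- function(z) {
  n <- nrow(z); p <- ncol(z)
  xs <- scale(z)
  num <- 0; den <- 0
  for (j in seq_len(p - 1L)) {
    w <- xs[, (j + 1L):p, drop = FALSE] * xs[, j]
    wbar <- colMeans(w)
    r <- wbar * n / (n - 1)
    vr <- n / (n - 1)^3 * colSums(sweep(w, 2L, wbar)^2)
    num <- num + sum(vr)
    den <- den + sum(r^2)
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

#' Shrinkage partial correlation estimator
#'
#' Computes the sample correlation matrix of all columns (variables plus
#' appended covariates), shrinks it toward the identity with an
#' analytically estimated intensity (Ledoit-Wolf/Schaefer-Strimmer),
#' inverts, and converts to partial correlations.  Covariates are
#' conditioned on by inclusion and their rows/columns dropped from the
#' result, so the returned matrix describes the variables given all
#' other variables and the covariates.
#'
#' @param x Numeric matrix (n x (p + c)); covariate columns appended
#'   last.  `p + c` may exceed `n`.
#' @param n_covariates Number of trailing covariate columns.
#' @param lambda Optional fixed shrinkage intensity in `[0, 1]`;
#'   `NULL` (default) estimates it from the data.
#' @return List with `pcor` (p x p), `lambda`, and `n`.
#' @export
shrinkage_pcor <- function(x, n_covariates = 0L, lambda = NULL) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0 | !is.finite(sds)] %||%
                 which(sds == 0), collapse = ", "))
  z <- scale(x)
  R <- stats::cor(z)
  lam <- if (is.null(lambda)) shrinkage_intensity(z) else lambda
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  if (lam == 1)
    warning("shrinkage intensity is 1 (pure identity target); ",
            "all partial correlations are zero")
  Rs <- (1 - lam) * R
  diag(Rs) <- 1
  pc <- cor_to_pcor(Rs)
  p <- ncol(x) - n_covariates
  pc <- pc[seq_len(p), seq_len(p), drop = FALSE]
  list(pcor = pc, lambda = lam, n = nrow(x))
}

## Log-likelihood of the null density f0(r) ~ (1 - r^2)^((kappa-3)/2)
## for a vector of partial correlations; kappa acts as an effective
## degree of freedom.
kappa_loglik <- function(kappa, r2) {
  sum((kappa - 3) / 2 * log1p(-r2)) -
    length(r2) * lbeta(0.5, (kappa - 1) / 2)
}

fit_kappa <- function(r, lower = 3.001, upper = 1e7) {
  r2 <- pmin(r^2, 1 - 1e-15)
  opt <- stats::optimize(function(lk) kappa_loglik(exp(lk), r2),
                         interval = log(c(lower, upper)), maximum = TRUE)
  exp(opt$maximum)
}

## Two-sided tail probability of |R| > |r| under the fitted null
## (r^2 ~ Beta(1/2, (kappa-1)/2)).
kappa_pvalue <- function(r, kappa) {
  stats::pbeta(pmin(r^2, 1), 0.5, (kappa - 1) / 2, lower.tail = FALSE)
}

pearson_t_pvalue <- function(r, df) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::pt(-t, df)
}

#' Edge p-values for Pearson and partial correlations
#'
#' The Pearson side uses the exact t-test with `n - 2 - c` degrees of
#' freedom (`c` covariates, correlations computed on
#' covariate-residualized data).  The partial side, by default, fits the
#' null density `f0(r) ~ (1 - r^2)^((kappa - 3) / 2)` by maximum
#' likelihood over the effective degree of freedom `kappa` on the
#' observed off-diagonal partial correlations — appropriate after
#' shrinkage, where the nominal degrees of freedom no longer apply — and
#' computes two-sided tail probabilities under it.  The classical
#' partial-correlation t-test with `n - 2 - (p + c - 2)` degrees of
#' freedom is exact when the sample size comfortably exceeds the
#' variable count, so `method = "auto"` uses it whenever
#' `n - p - c >= 30` and reserves the fitted null for the
#' high-dimensional shrinkage regime where those degrees of freedom do
#' not exist (or when there are too few variable pairs, fewer than 25,
#' to fit a density at all).
#'
#' @param pearson_r,partial_r Symmetric correlation matrices (p x p).
#' @param n Number of samples (>= 10).
#' @param n_covariates Number of conditioned covariates.
#' @param method `"auto"` (default), `"kappa"`, or `"exact"`.
#' @return List with `pearson_p`, `partial_p` (symmetric matrices,
#'   unit diagonal set to `NA`), and `kappa` (NA for the exact route).
#' @export
edge_pvalues <- function(pearson_r, partial_r, n, n_covariates = 0L,
                         method = c("auto", "kappa", "exact")) {
  method <- match.arg(method)
  if (n < 10) stop("need at least 10 samples")
  p <- ncol(partial_r)
  off <- upper.tri(partial_r)
  n_pairs <- sum(off)
  if (method == "auto") {
    df_exact <- n - p - n_covariates
    method <- if (df_exact >= 30L || n_pairs < 25L) "exact" else "kappa"
  }

  pearson_p <- matrix(NA_real_, p, p, dimnames = dimnames(pearson_r))
  pearson_p[off] <- pearson_t_pvalue(pearson_r[off], n - 2 - n_covariates)

  partial_p <- matrix(NA_real_, p, p, dimnames = dimnames(partial_r))
  kap <- NA_real_
  if (method == "kappa") {
    kap <- fit_kappa(partial_r[off])
    if (kap <= 3 + 1e-2) {
      warning("fitted null degree of freedom kappa <= 3; ",
              "falling back to a Fisher-z approximation")
      se <- 1 / sqrt(max(kap, 4) - 3)
      partial_p[off] <- 2 * stats::pnorm(-abs(atanh(
        pmin(pmax(partial_r[off], -1 + 1e-15), 1 - 1e-15))) / se)
    } else {
      partial_p[off] <- kappa_pvalue(partial_r[off], kap)
    }
  } else {
    df <- n - 2 - (p - 2) - n_covariates
    if (df < 1) stop("not enough samples for the exact partial test")
    partial_p[off] <- pearson_t_pvalue(partial_r[off], df)
  }
  pearson_p[lower.tri(pearson_p)] <- t(pearson_p)[lower.tri(pearson_p)]
  partial_p[lower.tri(partial_p)] <- t(partial_p)[lower.tri(partial_p)]
  list(pearson_p = pearson_p, partial_p = partial_p, kappa = kap)
}

## Residualize each column of x on [1, covariates].
residualize <- function(x, covariates = NULL) {
  if (is.null(covariates) || ncol(as.matrix(covariates)) == 0L) return(x)
  X <- cbind(1, as.matrix(covariates))
  qr_x <- qr(X)
  qr.resid(qr_x, as.matrix(x))
}

#' Infer a Gaussian graphical model network
#'
#' Draws an edge between two variables when both their Pearson
#' correlation (on covariate-residualized data) and their shrinkage
#' partial correlation (conditioning on all other variables and the
#' covariates) are significant at `alpha` after Bonferroni correction
#' for the `p * (p - 1) / 2` variable pairs — covariates never count as
#' variables and never appear as nodes.
#'
#' @param data Numeric matrix (n x p), fully observed, with node
#'   identities as column names.
#' @param covariates Optional numeric matrix/data frame (n x c) of
#'   covariates (e.g. age, gender, BMI) to condition on.
#' @param alpha Significance level before Bonferroni correction
#'   (default 0.05).
#' @param lambda Optional fixed shrinkage intensity (`NULL`: estimated).
#' @param method P-value method for the partial side (see
#'   [edge_pvalues()]).
#' @param level Network level tag for the result.
#' @param node_attrs Optional per-node attribute data frame.
#' @return An [mf_network] whose edges carry `pearson_r`, `partial_r`,
#'   `pearson_p`, `partial_p`; the shrinkage intensity, fitted kappa,
#'   sample size and test count are attached as attributes
#'   (`lambda`, `kappa`, `n_samples`, `n_tests`).
#' @export
build_ggm <- function(data, covariates = NULL, alpha = 0.05,
                      lambda = NULL, method = "auto",
                      level = "metabolite", node_attrs = NULL) {
  data <- as.matrix(data)
  p <- ncol(data)
  if (p < 2L) stop("need at least 2 variables")
  if (anyNA(data)) stop("data must be fully observed (run preprocessing)")
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(p))
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_cov <- if (is.null(cov_m)) 0L else ncol(cov_m)

  sp <- shrinkage_pcor(cbind(data, cov_m), n_covariates = n_cov,
                       lambda = lambda)
  res <- residualize(data, cov_m)
  pearson_r <- stats::cor(res)
  pv <- edge_pvalues(pearson_r, sp$pcor, n = nrow(data),
                     n_covariates = n_cov, method = method)
  n_tests <- p * (p - 1) / 2
  thr <- alpha / n_tests
  off <- which(upper.tri(pearson_r), arr.ind = TRUE)
  sig <- pv$pearson_p[off] < thr & pv$partial_p[off] < thr
  sig[is.na(sig)] <- FALSE
  edges <- data.frame(
    from = colnames(data)[off[sig, 1L]],
    to = colnames(data)[off[sig, 2L]],
    pearson_r = pearson_r[off][sig],
    partial_r = sp$pcor[off][sig],
    pearson_p = pv$pearson_p[off][sig],
    partial_p = pv$partial_p[off][sig],
    stringsAsFactors = FALSE)
  net <- mf_network(level, nodes = colnames(data), edges = edges,
                    node_attrs = node_attrs)
  attr(net, "lambda") <- sp$lambda
  attr(net, "kappa") <- pv$kappa
  attr(net, "n_samples") <- nrow(data)
  attr(net, "n_tests") <- n_tests
  attr(net, "alpha") <- alpha
  net
}

#' Metabolite-level network from a processed intensity matrix
#'
#' Renames columns to `"FLUID::feature"` node identities and calls
#' [build_ggm()].  Metabolites of unknown structure take part in the
#' estimation by default (they are genuine variables of the system even
#' without pathway labels); set `include_unknowns = FALSE` to restrict
#' to annotated metabolites.
#'
#' @param x Processed [mf_data] (fully observed, log2 scale).
#' @param annotations Annotation table (see [read_annotations()]); may
#'   be `NULL` when `include_unknowns = TRUE`.
#' @param covariates,alpha,lambda,method Passed to [build_ggm()].
#' @param include_unknowns Keep unannotated metabolites (default TRUE).
#' @return An [mf_network] at the metabolite level.
#' @export
build_metabolite_network <- function(x, annotations = NULL,
                                     covariates = NULL, alpha = 0.05,
                                     lambda = NULL, method = "auto",
                                     include_unknowns = TRUE) {
  stopifnot(inherits(x, "mf_data"))
  v <- x$values
  colnames(v) <- node_id(x$fluid, colnames(v))
  attrs <- NULL
  if (!is.null(annotations)) {
    ann <- annotations[match(feature_ids(x), annotations$feature_id), ]
    if (!include_unknowns) {
      keep <- !is.na(ann$known) & ann$known
      v <- v[, keep, drop = FALSE]
      ann <- ann[keep, , drop = FALSE]
    }
    attrs <- data.frame(node = node_id(ann$fluid, ann$feature_id),
                        sub_pathway = ann$sub_pathway,
                        super_pathway = ann$super_pathway,
                        stringsAsFactors = FALSE)
  }
  build_ggm(v, covariates = covariates, alpha = alpha, lambda = lambda,
            method = method, level = "metabolite", node_attrs = attrs)
}
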
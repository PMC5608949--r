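## Synthetic multifluid metabolomics generator with known ground truth.
## Emulates the data properties the pipeline is built for: run-day batch
## offsets, per-sample dilution in urine/saliva, log-normal intensities
## with left-censoring at a detection limit, latent-factor correlation
## within (and optionally across) fluid-resolved sub-pathways, and
## planted phenotype effects of tunable sparsity.

#' Synthetic data configuration
#'
#' The latent model works on the log2 scale: each member of a
#' (fluid, sub-pathway) block is
#' `z = a * f + beta * P + sqrt(1 - a^2 - beta^2) * e` with a shared
#' pathway factor `f ~ N(0,1)`, standardized phenotype `P`, per-feature
#' planted effect `beta` (0 unless the feature belongs to a planted
#' module), and iid noise `e`.  Cross-fluid pathway pairs share a
#' common factor component.  Raw intensities are
#' `2^(z + mu_j) * runday_offset * dilution`, and a configurable
#' fraction of features is left-censored at its own intensity quantile
#' (a per-feature detection limit).
#'
#' @param n_samples Number of samples.
#' @param n_features Named integer vector: features per fluid.
#' @param n_subpathways Named integer vector: sub-pathways per fluid.
#' @param loading Within-pathway factor loading `a` in `[0, 1)`.
#' @param cross_fluid_pairs Optional data frame with columns `sub1`,
#'   `sub2` (sub-pathway node identities) and `loading`: the two
#'   pathway factors share a common component with that loading.
#' @param n_rundays Number of run days (samples split evenly).
#' @param runday_log2_sd SD of the per-run-day log2 offset.
#' @param dilution_log2_sd Named numeric vector: SD of the per-sample
#'   log2 dilution factor per fluid (0 disables dilution).
#' @param censor_quantile Detection-limit quantile `q` in `[0, 1)` for
#'   censored features.
#' @param censored_frac Fraction of features subject to censoring (the
#'   rest are fully observed, as is typical for abundant metabolites).
#' @param phenotype `list(name =, type = "binary"|"gaussian")`.
#' @param planted_modules List of `list(features =, beta =)`: feature
#'   ids (bare, not node identities) with per-member effect sizes in SD
#'   units on the log2 scale (`beta` recycled over the features).
#' @param unknown_frac Fraction of features left without pathway
#'   annotation ("unknowns").
#' @param baseline_log2_mean,baseline_log2_sd Distribution of the
#'   per-feature baseline abundance `mu_j` (log2 ion counts).
#' @param seed Master seed; the same configuration and seed reproduce
#'   the dataset exactly.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 200L,
                         n_features = c(P = 30L, U = 30L, S = 20L),
                         n_subpathways = c(P = 6L, U = 6L, S = 4L),
                         loading = 0.6,
                         cross_fluid_pairs = NULL,
                         n_rundays = 4L,
                         runday_log2_sd = 0.5,
                         dilution_log2_sd = c(P = 0, U = 1.25, S = 1),
                         censor_quantile = 0.1,
                         censored_frac = 0.5,
                         phenotype = list(name = "phenotype",
                                          type = "gaussian"),
                         planted_modules = list(),
                         unknown_frac = 0.2,
                         baseline_log2_mean = 10,
                         baseline_log2_sd = 2,
                         seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features = n_features, n_subpathways = n_subpathways,
              loading = loading, cross_fluid_pairs = cross_fluid_pairs,
              n_rundays = as.integer(n_rundays),
              runday_log2_sd = runday_log2_sd,
              dilution_log2_sd = dilution_log2_sd,
              censor_quantile = censor_quantile,
              censored_frac = censored_frac,
              phenotype = phenotype,
              planted_modules = planted_modules,
              unknown_frac = unknown_frac,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_samples > 0, all(cfg$n_features > 0),
            all(cfg$n_subpathways > 0), cfg$n_rundays > 0)
  if (!identical(sort(names(cfg$n_features)),
                 sort(names(cfg$n_subpathways))))
    stop("n_features and n_subpathways must name the same fluids")
  if (cfg$loading < 0 || cfg$loading >= 1)
    stop("loading must lie in [0, 1)")
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 1)
    stop("censor_quantile must lie in [0, 1)")
  if (!cfg$phenotype$type %in% c("binary", "gaussian"))
    stop("phenotype type must be 'binary' or 'gaussian'")
  max_beta <- 0
  for (pm in cfg$planted_modules)
    max_beta <- max(max_beta, abs(pm$beta))
  if (cfg$loading^2 + max_beta^2 >= 1)
    stop("variance budget exceeded: loading^2 + max(beta)^2 must be < 1")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  samples:", x$n_samples, " run days:", x$n_rundays, "\n")
  cat("  features:",
      paste(sprintf("%s=%d", names(x$n_features), x$n_features),
            collapse = ", "), "\n")
  cat("  sub-pathways:",
      paste(sprintf("%s=%d", names(x$n_subpathways), x$n_subpathways),
            collapse = ", "), "\n")
  cat("  loading:", x$loading,
      " censoring: q =", x$censor_quantile,
      "on", sprintf("%.0f%%", 100 * x$censored_frac), "of features\n")
  cat("  phenotype:", x$phenotype$name, sprintf("(%s)", x$phenotype$type),
      " planted modules:", length(x$planted_modules), "\n")
  invisible(x)
}

#' Configuration shaped like a multifluid population study
#'
#' Three fluids (plasma `P`, urine `U`, saliva `S`) with feature counts
#' proportional to a typical untargeted multifluid panel (scaled down
#' by default for speed), sub-pathway blocks mapping many-to-one onto
#' super-pathways, urine/saliva dilution, run-day batches and
#' left-censoring.  All parameters can be overridden via `...`.
#'
#' @param n_samples Sample count (default 906).
#' @param scale Feature-count scale factor relative to the full panel
#'   of roughly 335/473/189 plasma/urine/saliva metabolites (default
#'   1/5).
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
make_paper_shaped_config <- function(n_samples = 906L, scale = 0.2, ...) {
  nf <- pmax(c(P = round(335 * scale), U = round(473 * scale),
               S = round(189 * scale)), 4L)
  ns <- pmax(round(c(P = 54, U = 53, S = 45) * scale), 2L)
  defaults <- list(
    n_samples = n_samples, n_features = nf, n_subpathways = ns,
    loading = 0.6,
    cross_fluid_pairs = data.frame(
      sub1 = c("P::SP01", "P::SP02", "P::SP03"),
      sub2 = c("U::SP01", "U::SP02", "U::SP03"),
      loading = 0.7, stringsAsFactors = FALSE),
    n_rundays = 10L, runday_log2_sd = 0.5,
    dilution_log2_sd = c(P = 0, U = 1.25, S = 1),
    censor_quantile = 0.1, censored_frac = 0.5,
    unknown_frac = 0.39, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

#' Generate a synthetic multifluid dataset
#'
#' @param config A `synth_config`.
#' @param seed Optional override of `config$seed`.
#' @return Object of class `mf_synth`: a list with `data` (raw
#'   [mf_data] with missing entries), `annotations`, `phenotypes`, and
#'   `truth` (latent factors, dilution and run-day offsets, censor
#'   points, per-feature planted effects, planted modules, the
#'   configuration).
#' @export
generate_synthetic <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(seed %||% config$seed)
  n <- config$n_samples
  fluids <- names(config$n_features)

  sample_id <- sprintf("sample%04d", seq_len(n))
  runday <- rep(sprintf("day%02d", seq_len(config$n_rundays)),
                length.out = n)
  runday <- sort(runday)

  ## feature layout: per fluid, features dealt round-robin into
  ## sub-pathway blocks named from a shared pool so the same pathway
  ## can exist in several fluids
  feats <- list()
  for (fl in fluids) {
    nf <- config$n_features[[fl]]
    ns <- config$n_subpathways[[fl]]
    sub <- sprintf("SP%02d", rep_len(seq_len(ns), nf))
    feats[[fl]] <- data.frame(
      feature_id = sprintf("%s_met%03d", tolower(fl), seq_len(nf)),
      fluid = fl, sub_pathway = sort(sub), stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, feats)
  ## super-pathway count follows the panel size (8 for a full-size study,
  ## fewer for scaled-down panels) so the sub -> super map stays
  ## many-to-one
  nsuper <- min(8L, max(2L, ceiling(max(config$n_subpathways) / 2)))
  sub_index <- as.integer(sub("SP", "", feats$sub_pathway))
  feats$super_pathway <- sprintf("Super%d", (sub_index - 1L) %% nsuper + 1L)
  p <- nrow(feats)

  ## phenotype and standard covariates
  P <- switch(config$phenotype$type,
              binary = stats::rbinom(n, 1L, 0.5),
              gaussian = stats::rnorm(n))
  age <- stats::rnorm(n, 50, 13)
  gender <- stats::rbinom(n, 1L, 0.5)
  bmi <- stats::rnorm(n, 27, 4.5)
  Pstd <- (P - mean(P)) / stats::sd(P)

  ## latent pathway factors, with shared components for cross-fluid pairs
  path_key <- unique(node_id(feats$fluid, feats$sub_pathway))
  fac <- matrix(stats::rnorm(n * length(path_key)), n,
                dimnames = list(sample_id, path_key))
  cfp <- config$cross_fluid_pairs
  if (!is.null(cfp)) {
    for (i in seq_len(nrow(cfp))) {
      s1 <- cfp$sub1[i]; s2 <- cfp$sub2[i]; w <- cfp$loading[i]
      if (!s1 %in% path_key || !s2 %in% path_key)
        stop("cross-fluid pair refers to unknown sub-pathway: ",
             s1, " / ", s2)
      g <- stats::rnorm(n)
      fac[, s1] <- w * g + sqrt(1 - w^2) * fac[, s1]
      fac[, s2] <- w * g + sqrt(1 - w^2) * fac[, s2]
    }
  }

  ## planted phenotype effects
  beta <- stats::setNames(numeric(p), feats$feature_id)
  for (pm in config$planted_modules) {
    missing_f <- setdiff(pm$features, feats$feature_id)
    if (length(missing_f) > 0)
      stop("planted module refers to unknown feature(s): ",
           paste(missing_f, collapse = ", "))
    beta[pm$features] <- rep_len(pm$beta, length(pm$features))
  }

  a <- config$loading
  fkey <- node_id(feats$fluid, feats$sub_pathway)
  noise_sd <- sqrt(1 - a^2 - beta^2)
  z <- fac[, fkey, drop = FALSE] * a +
    outer(Pstd, beta) +
    matrix(stats::rnorm(n * p), n) * rep(noise_sd, each = n)

  mu <- stats::rnorm(p, config$baseline_log2_mean, config$baseline_log2_sd)
  day_offset <- stats::setNames(
    2^stats::rnorm(config$n_rundays, 0, config$runday_log2_sd),
    sprintf("day%02d", seq_len(config$n_rundays)))
  dil <- sapply(fluids, function(fl)
    2^stats::rnorm(n, 0, config$dilution_log2_sd[[fl]] %||% 0))
  dimnames(dil) <- list(sample_id, fluids)

  raw <- 2^sweep(z, 2L, mu, `+`) * day_offset[runday] *
    dil[, feats$fluid, drop = FALSE]
  dimnames(raw) <- list(sample_id, feats$feature_id)

  ## left-censoring: a fraction of features has a detection limit at its
  ## own raw-intensity quantile
  censored <- sort(sample(p, round(config$censored_frac * p)))
  censor_point <- stats::setNames(rep(NA_real_, p), feats$feature_id)
  if (config$censor_quantile > 0 && length(censored) > 0) {
    for (j in censored) {
      cp <- stats::quantile(raw[, j], config$censor_quantile, names = FALSE)
      censor_point[j] <- cp
      raw[raw[, j] < cp, j] <- NA
    }
  }

  ## unknowns: hide the pathway labels of a random feature subset
  ann <- feats
  n_unknown <- round(config$unknown_frac * p)
  if (n_unknown > 0) {
    hide <- sort(sample(p, n_unknown))
    ann$sub_pathway[hide] <- NA
    ann$super_pathway[hide] <- NA
  }
  ann <- as_annotations(ann)

  phen <- data.frame(sample_id = sample_id, age = age, gender = gender,
                     BMI = bmi, stringsAsFactors = FALSE)
  phen[[config$phenotype$name]] <- P

  truth <- list(factors = fac, dilution = dil,
                runday_offsets = day_offset, censor_points = censor_point,
                beta = beta, mu = mu,
                planted_modules = config$planted_modules,
                config = config)
  structure(list(data = mf_data(raw, runday, feats$fluid),
                 annotations = ann, phenotypes = phen, truth = truth),
            class = "mf_synth")
}

#' @export
print.mf_synth <- function(x, ...) {
  cat("<mf_synth> synthetic multifluid dataset\n")
  print(x$data)
  cat("  planted modules:", length(x$truth$planted_modules), "\n")
  invisible(x)
}

#' Write the four artifacts of a synthetic dataset
#'
#' Writes intensity TSV + metadata TSV, annotation TSV, phenotype TSV,
#' and the ground truth as JSON into a directory.
#'
#' @param synth An `mf_synth`.
#' @param dir Output directory (created if needed).
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_tsv(synth$data, file.path(dir, "intensities.tsv"),
                      file.path(dir, "metadata.tsv"))
  utils::write.table(
    synth$annotations[c("feature_id", "fluid", "sub_pathway",
                        "super_pathway")],
    file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  utils::write.table(synth$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- synth$truth
  truth$config <- unclass(truth$config)
  truth$factors <- NULL            # large; regenerable from config+seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}
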
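## Phenotype-driven greedy module identification: regression scoring of
## module representatives, seed-wise greedy growth, consolidation of
## overlapping optima, and node-level Bonferroni significance.

#' Module representative (average z-score)
#'
#' A candidate module is represented by the average of the scaled
#' intensities (average z-score) of its member metabolites.  At the
#' metabolite level the members are the module's nodes themselves; at
#' the sub-/super-pathway level they are the set union of all
#' metabolites annotated to the module's pathway nodes.  The mean
#' z-score is used (rather than an eigenmetabolite) because modules mix
#' heterogeneous pathways.
#'
#' @param x Processed [mf_data] (fully observed).
#' @param nodes Character vector of module node identities.
#' @param level `"metabolite"`, `"sub_pathway"` or `"super_pathway"`.
#' @param annotations Annotation table (required for pathway levels).
#' @return Named numeric vector over samples.
#' @export
module_representative <- function(x, nodes,
                                  level = c("metabolite", "sub_pathway",
                                            "super_pathway"),
                                  annotations = NULL) {
  level <- match.arg(level)
  idx <- member_features(x, nodes, level, annotations)
  z <- zscore(x$values[, idx, drop = FALSE], what = "member metabolite")
  stats::setNames(rowMeans(z), sample_ids(x))
}

## Resolve module nodes to member feature column indices (set union).
member_features <- function(x, nodes, level, annotations) {
  if (length(nodes) == 0L) stop("empty module (no nodes)")
  ids <- node_id(x$fluid, feature_ids(x))
  if (level == "metabolite") {
    idx <- match(nodes, ids)
    if (anyNA(idx))
      stop("node(s) not present in the data: ",
           paste(nodes[is.na(idx)], collapse = ", "))
    return(sort(idx))
  }
  if (is.null(annotations))
    stop("annotations are required at the ", level, " level")
  ann <- annotations[match(feature_ids(x), annotations$feature_id), ]
  key <- if (level == "sub_pathway")
    node_id(ann$fluid, ann$sub_pathway) else
    node_id(ann$fluid, ann$super_pathway)
  idx <- which(key %in% nodes)
  if (length(idx) == 0L)
    stop("no member metabolites found for nodes: ",
         paste(nodes, collapse = ", "))
  sort(idx)
}

## OLS of y on [1, P, covariates]; returns the two-sided p-value of the
## P coefficient on the log scale for underflow-safe scoring.
ols_phenotype_test <- function(y, design_qr, df, xtxinv11) {
  beta <- qr.coef(design_qr, y)
  res <- qr.resid(design_qr, y)
  sigma2 <- sum(res^2) / df
  if (sigma2 <= 0) return(list(logp = -Inf, t = Inf))
  t <- beta[2L] / sqrt(sigma2 * xtxinv11)
  list(logp = log(2) + stats::pt(-abs(t), df, log.p = TRUE), t = t)
}

#' Score a module representative against a phenotype
#'
#' Ordinary least squares of the representative on an intercept, the
#' phenotype and the covariates; the module score is the negative
#' log10 p-value of the phenotype coefficient (two-sided t-test),
#' capped at `cap` to absorb numerical underflow.  A single-node module
#' uses the same formula with its own z-score as representative, which
#' realizes the univariate analysis.
#'
#' @param r_m Numeric representative vector (non-constant).
#' @param phenotype Numeric phenotype vector (binary traits 0/1 coded).
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param cap Score cap (default 300).
#' @return List with `score` and `p_value`.
#' @export
score_module <- function(r_m, phenotype, covariates = NULL, cap = 300) {
  n <- length(r_m)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::sd(r_m) == 0) stop("constant module representative")
  if (length(unique(phenotype)) < 2L) stop("constant phenotype")
  X <- cbind(`(Intercept)` = 1, phenotype = phenotype)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  xtxinv <- chol2inv(qr.R(qx))
  fit <- ols_phenotype_test(r_m, qx, n - ncol(X), xtxinv[2L, 2L])
  list(score = min(-fit$logp / log(10), cap),
       p_value = exp(fit$logp))
}

#' Build a memoized module scorer
#'
#' Joins the processed data with the phenotype table, z-scores all
#' metabolites once, fixes the regression design (intercept, phenotype,
#' covariates), and returns a function `scorer(nodes)` evaluating the
#' module score of any node set at the chosen level.  When the
#' phenotype itself appears in the covariate list it is removed (e.g.
#' the scoring model for gender does not contain gender as a
#' covariate).  Scores are cached by node set, so repeated evaluation
#' during the greedy search and across seeds is cheap.
#'
#' @param x Processed [mf_data].
#' @param phenotype_table Data frame with `sample_id`, the phenotype
#'   column and covariate columns.
#' @param phenotype Name of the phenotype column.
#' @param covariates Covariate column names (default
#'   `c("age", "gender", "BMI")`).
#' @param level Network level the node identities refer to.
#' @param annotations Annotation table (pathway levels).
#' @param cap Score cap (default 300).
#' @return Function of class `module_scorer`: `scorer(nodes)` returns
#'   `list(score, p_value)`.
#' @export
make_module_scorer <- function(x, phenotype_table, phenotype,
                               covariates = c("age", "gender", "BMI"),
                               level = "metabolite", annotations = NULL,
                               cap = 300) {
  stopifnot(inherits(x, "mf_data"))
  if (!phenotype %in% names(phenotype_table))
    stop("phenotype column '", phenotype, "' missing")
  common <- intersect(sample_ids(x), phenotype_table$sample_id)
  if (length(common) < 10L)
    stop("fewer than 10 samples shared between data and phenotypes")
  x <- mf_subset(x, samples = common)
  ph <- phenotype_table[match(common, phenotype_table$sample_id), ]
  P <- ph[[phenotype]]
  if (length(unique(P)) < 2L) stop("phenotype has fewer than 2 levels")
  covariates <- setdiff(covariates, phenotype)
  miss <- setdiff(covariates, names(ph))
  if (length(miss) > 0)
    stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
  covm <- if (length(covariates))
    as.matrix(ph[covariates]) else NULL

  X <- cbind(`(Intercept)` = 1, phenotype = P)
  if (!is.null(covm)) X <- cbind(X, covm)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  xtxinv11 <- chol2inv(qr.R(qx))[2L, 2L]
  df <- nrow(X) - ncol(X)
  z <- zscore(x$values, what = "metabolite")
  cache <- new.env(parent = emptyenv())

  scorer <- function(nodes) {
    key <- paste(sort(nodes), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    idx <- member_features(x, nodes, level, annotations)
    r_m <- rowMeans(z[, idx, drop = FALSE])
    out <- if (stats::sd(r_m) == 0) {
      list(score = 0, p_value = 1)
    } else {
      fit <- ols_phenotype_test(r_m, qx, df, xtxinv11)
      list(score = min(-fit$logp / log(10), cap),
           p_value = exp(fit$logp))
    }
    out$members <- colnames(z)[idx]
    cache[[key]] <- out
    out
  }
  class(scorer) <- c("module_scorer", "function")
  attr(scorer, "phenotype") <- phenotype
  attr(scorer, "covariates") <- covariates
  attr(scorer, "level") <- level
  attr(scorer, "n_samples") <- nrow(X)
  scorer
}

adjacency_list <- function(network) {
  adj <- lapply(stats::setNames(vector("list", length(network$nodes)),
                                network$nodes), function(.) character(0))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

#' Greedy search for an optimal module from one seed node
#'
#' Starts from the seed and repeatedly evaluates every network neighbor
#' of the current module, extending it by the neighbor giving the
#' highest extended-module score.  The neighbor is only added if the
#' extended score strictly exceeds both the current module score and
#' the maximum single-node score over all components of the extended
#' module; the search stops otherwise.  Equal-scoring candidates are
#' broken toward the lexicographically smallest node id, making the
#' search deterministic.
#'
#' @param network An [mf_network].
#' @param seed Seed node identity (must be a network node).
#' @param scorer Function mapping a node-set to `list(score, p_value)`
#'   (see [make_module_scorer()]).
#' @return List of class `mf_module` with `nodes`, `members`, `score`,
#'   `p_value`, `seeds`, `status = "optimal"`.
#' @export
greedy_search <- function(network, seed, scorer) {
  if (!seed %in% network$nodes)
    stop("seed node '", seed, "' not in network")
  adj <- adjacency_list(network)
  single <- function(u) scorer(u)$score
  M <- seed
  cur <- scorer(M)
  max_single <- single(seed)
  repeat {
    nb <- sort(setdiff(unique(unlist(adj[M], use.names = FALSE)), M))
    if (length(nb) == 0L) break
    cand <- vapply(nb, function(v) scorer(c(M, v))$score, numeric(1))
    best <- which.max(cand)            # first max = smallest node id
    v <- nb[best]
    new_max_single <- max(max_single, single(v))
    if (cand[best] > cur$score && cand[best] > new_max_single) {
      M <- c(M, v)
      cur <- scorer(M)
      max_single <- new_max_single
    } else break
  }
  structure(list(nodes = sort(M), members = cur$members %||% sort(M),
                 score = cur$score, p_value = cur$p_value,
                 seeds = seed, status = "optimal"),
            class = "mf_module")
}

#' @export
print.mf_module <- function(x, ...) {
  cat(sprintf("<mf_module %s> %d node(s), score %.2f (p = %.3g)\n",
              x$status, length(x$nodes), x$score, x$p_value))
  cat("  ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Consolidate overlapping optimal modules into maximal modules
#'
#' Builds the overlap graph over the per-seed optimal modules (two
#' modules are adjacent when they share at least one node); each
#' connected component's node union forms one maximal module, which is
#' rescored.  Maximal modules are pairwise disjoint by construction.
#'
#' @param modules List of `mf_module` objects (one per seed).
#' @param scorer Scoring function (see [make_module_scorer()]).
#' @return List of `mf_module` objects with `status = "maximal"`.
#' @export
consolidate <- function(modules, scorer) {
  if (length(modules) == 0L) return(list())
  comp <- seq_along(modules)
  node_sets <- lapply(modules, `[[`, "nodes")
  for (i in seq_along(modules)) {
    overlapping <- which(vapply(seq_along(modules), function(j)
      comp[j] != comp[i] && length(intersect(node_sets[[i]],
                                             node_sets[[j]])) > 0,
      logical(1)))
    for (j in overlapping) comp[comp == comp[j]] <- comp[i]
  }
  lapply(unique(comp), function(ci) {
    members <- which(comp == ci)
    nodes <- sort(unique(unlist(node_sets[members])))
    sc <- scorer(nodes)
    structure(list(nodes = nodes, members = sc$members %||% nodes,
                   score = sc$score, p_value = sc$p_value,
                   seeds = sort(unique(unlist(
                     lapply(modules[members], `[[`, "seeds")))),
                   status = "maximal"),
              class = "mf_module")
  })
}

#' Node-level Bonferroni significance filter
#'
#' Keeps a maximal module when its p-value is below `alpha` divided by
#' the number of network nodes and its score strictly exceeds the
#' maximum single-node score over its components (so a module never
#' merely rides on one strong member; single-node modules can never
#' pass the strict dominance rule and are not reported).
#'
#' @param modules List of maximal `mf_module` objects.
#' @param n_nodes Number of nodes of the underlying network.
#' @param alpha Significance level (default 0.05).
#' @param scorer Scoring function, used for single-node scores.
#' @param level,phenotype Metadata recorded in the report.
#' @return Object of class `module_report`.
#' @export
filter_significant <- function(modules, n_nodes, alpha = 0.05, scorer,
                               level = NA_character_,
                               phenotype = NA_character_) {
  if (n_nodes == 0L) stop("n_nodes must be positive")
  thr <- alpha / n_nodes
  kept <- Filter(function(m) {
    best_single <- max(vapply(m$nodes, function(u) scorer(u)$score,
                              numeric(1)))
    m$p_value < thr && m$score > best_single
  }, modules)
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "score"),
                     decreasing = TRUE)]
  structure(list(modules = kept, level = level, phenotype = phenotype,
                 n_nodes = n_nodes, alpha = alpha,
                 bonferroni_threshold = thr),
            class = "module_report")
}

#' Identify phenotype-associated modules on one level of the map
#'
#' Runs the full procedure: every node of the chosen level's network is
#' used as a seed for the greedy search, the per-seed optimal modules
#' are consolidated into maximal modules, and the maximal modules are
#' filtered by the node-level Bonferroni rule and the single-component
#' dominance rule.  When the phenotype appears in the covariate list it
#' is dropped from the covariates automatically.
#'
#' @param map An `mf_map` (see [build_hierarchical_map()]) or an
#'   [mf_network].
#' @param x Processed [mf_data] the map was built on.
#' @param phenotype_table Data frame with `sample_id`, phenotype and
#'   covariates.
#' @param phenotype Phenotype column name.
#' @param level Map level to search (ignored when `map` is already a
#'   network).
#' @param covariates Covariate columns (default age, gender, BMI).
#' @param alpha Significance level (default 0.05).
#' @param annotations Annotation table; taken from the map if absent.
#' @return Object of class `module_report`; modules are ordered by
#'   decreasing score.
#' @export
run_module_identification <- function(map, x, phenotype_table, phenotype,
                                      level = c("metabolite",
                                                "sub_pathway",
                                                "super_pathway"),
                                      covariates = c("age", "gender",
                                                     "BMI"),
                                      alpha = 0.05, annotations = NULL) {
  level <- match.arg(level)
  network <- if (inherits(map, "mf_map")) map[[level]] else map
  stopifnot(inherits(network, "mf_network"))
  if (is.null(annotations) && inherits(map, "mf_map"))
    annotations <- map$annotations
  scorer <- make_module_scorer(x, phenotype_table, phenotype,
                               covariates = covariates, level = level,
                               annotations = annotations)
  optima <- lapply(network$nodes, function(s)
    greedy_search(network, s, scorer))
  maximal <- consolidate(optima, scorer)
  report <- filter_significant(maximal, n_nodes = length(network$nodes),
                               alpha = alpha, scorer = scorer,
                               level = level, phenotype = phenotype)
  report$n_seeds <- length(network$nodes)
  report
}

#' @export
print.module_report <- function(x, ...) {
  cat(sprintf(
    "<module_report> %s level, phenotype '%s'\n", x$level, x$phenotype))
  cat(sprintf("  %d node(s), Bonferroni threshold p < %.3g\n",
              x$n_nodes, x$bonferroni_threshold))
  cat(sprintf("  %d significant module(s)\n", length(x$modules)))
  for (m in x$modules)
    cat(sprintf("  - score %6.2f  p %.3g  [%s]\n", m$score, m$p_value,
                paste(m$nodes, collapse = ", ")))
  invisible(x)
}

#' Tabulate a module report
#'
#' @param report A `module_report`.
#' @return Data frame with one row per reported module.
#' @export
module_report_table <- function(report) {
  mods <- report$modules
  data.frame(
    module = if (length(mods)) seq_along(mods) else integer(0),
    n_nodes = vapply(mods, function(m) length(m$nodes), integer(1)),
    nodes = vapply(mods, function(m) paste(m$nodes, collapse = ";"), ""),
    score = vapply(mods, `[[`, numeric(1), "score"),
    p_value = vapply(mods, `[[`, numeric(1), "p_value"),
    seeds = vapply(mods, function(m) paste(m$seeds, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
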
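## Shared fixtures and independent oracles used across the test files.

## Tiny deterministic intensity container.
tiny_mf_data <- function() {
  v <- matrix(c(2, 4, 6, 10, NA, 30), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  mf_data(v, runday = c("d1", "d1", "d1"), fluid = c("P", "U"))
}

## Markov chain X -> Y -> Z with regression coefficients 0.6.
chain_data <- function(n = 500, seed = 1) {
  set.seed(seed)
  X <- rnorm(n)
  Y <- 0.6 * X + rnorm(n)
  Z <- 0.6 * Y + rnorm(n)
  cbind(X = X, Y = Y, Z = Z)
}

## Single-factor block: m members with loading a on a shared factor.
factor_block <- function(n, m, a, seed = 1, prefix = "m") {
  set.seed(seed)
  f <- rnorm(n)
  x <- vapply(seq_len(m), function(i) a * f + sqrt(1 - a^2) * rnorm(n),
              numeric(n))
  colnames(x) <- paste0(prefix, seq_len(m))
  x
}

## Study conditions for the sparse planted-module experiments: one fluid
## of 28 metabolites in 7 four-member sub-pathways; the planted module is
## one whole pathway with per-member effect beta (SD units, log2 scale);
## clean measurement (no censoring, single run day) so the experiment
## isolates network inference + module search.
planted_module_config <- function(seed, n_samples = 1500, beta = 0.075,
                                  loading = 0.45) {
  synth_config(
    n_samples = n_samples,
    n_features = c(P = 28), n_subpathways = c(P = 7),
    loading = loading, n_rundays = 1, runday_log2_sd = 0,
    dilution_log2_sd = c(P = 0),
    censor_quantile = 0, censored_frac = 0, unknown_frac = 0,
    phenotype = list(name = "igf1", type = "gaussian"),
    planted_modules = list(list(features = sprintf("p_met%03d", 1:4),
                                beta = beta)),
    seed = seed)
}

planted_nodes <- sprintf("P::p_met%03d", 1:4)

## Generate + run the full module identification under the planted-module
## conditions; optionally permute the phenotype first.
run_planted_search <- function(seed, permute = FALSE, ...) {
  syn <- generate_synthetic(planted_module_config(seed, ...))
  x <- log2_transform(syn$data)
  ph <- syn$phenotypes
  if (permute) {
    set.seed(seed + 5000L)
    ph$igf1 <- sample(ph$igf1)
  }
  covs <- as.matrix(ph[match(rownames(x$values), ph$sample_id),
                       c("age", "gender", "BMI")])
  net <- suppressWarnings(
    build_metabolite_network(x, syn$annotations, covariates = covs))
  report <- run_module_identification(net, x, ph, phenotype = "igf1",
                                      level = "metabolite",
                                      annotations = syn$annotations)
  list(syn = syn, x = x, ph = ph, net = net, report = report)
}

## --- independent oracle for the greedy search -------------------------

## Random undirected graph as an adjacency list over letter node ids.
random_graph <- function(n_nodes, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n_nodes)]
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  adj <- lapply(setNames(vector("list", n_nodes), ids),
                function(.) character(0))
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  list(ids = ids, edges = edges, adj = adj)
}

graph_to_network <- function(g) {
  edges <- if (nrow(g$edges) > 0)
    data.frame(from = g$edges[, 1], to = g$edges[, 2],
               pearson_r = 0.5, partial_r = 0.3,
               pearson_p = 1e-6, partial_p = 1e-6,
               stringsAsFactors = FALSE)
  else NULL
  mf_network("metabolite", nodes = g$ids, edges = edges)
}

is_connected_subset <- function(nodes, adj) {
  if (length(nodes) == 1L) return(TRUE)
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier) > 0) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier])), nodes), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(nodes)
}

## Enumerate every connected node subset of a small graph (brute force).
connected_subsets <- function(g) {
  n <- length(g$ids)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    nodes <- g$ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (is_connected_subset(nodes, g$adj))
      out[[length(out) + 1L]] <- sort(nodes)
  }
  out
}

## Deterministic stub scorer: every connected subset gets a frozen
## p-value drawn once; score = -log10(p).  Shared by the greedy search
## and the exhaustive oracle so both see identical scores.
stub_scorer <- function(subsets, seed = 1) {
  set.seed(seed)
  keys <- vapply(subsets, paste, "", collapse = "|")
  p <- setNames(runif(length(keys)), keys)
  scorer <- function(nodes) {
    key <- paste(sort(nodes), collapse = "|")
    stopifnot(key %in% names(p))
    list(score = -log10(p[[key]]), p_value = p[[key]])
  }
  class(scorer) <- c("module_scorer", "function")
  scorer
}

## Fixed score table variant used for hand-crafted examples.
table_scorer <- function(score_table) {
  scorer <- function(nodes) {
    key <- paste(sort(nodes), collapse = "|")
    s <- score_table[[key]]
    stopifnot(!is.null(s))
    list(score = s, p_value = 10^(-s))
  }
  class(scorer) <- c("module_scorer", "function")
  scorer
}
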
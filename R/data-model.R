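#' Intensity matrix container
#'
#' Bundles a samples x features matrix of metabolite intensities with the
#' per-sample run-day labels and per-feature fluid labels that every
#' downstream stage needs.  Raw intensities are strictly positive ion
#' counts; missing measurements are `NA`.  After [log2_transform()] the
#' `log2` flag is set and values may be negative.
#'
#' @param values Numeric matrix (samples x features) with unique row names
#'   (sample ids) and column names (feature ids).
#' @param runday Character vector of run-day labels, one per sample.
#' @param fluid Character vector of fluid labels, one per feature.
#' @param log2 Logical; `TRUE` once the matrix is on the log2 scale.
#' @return An object of class `mf_data`.
#' @export
mf_data <- function(values, runday, fluid, log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  runday <- as.character(runday)
  fluid <- as.character(fluid)
  if (length(runday) != nrow(values))
    stop("need one run-day label per sample")
  if (length(fluid) != ncol(values))
    stop("need one fluid label per feature")
  if (anyNA(runday)) stop("missing run-day label")
  if (anyNA(fluid)) stop("missing fluid label")
  if (!log2) {
    bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-positive intensity at sample '", rownames(values)[bad[1, 1]],
           "', feature '", colnames(values)[bad[1, 2]], "'")
  }
  structure(list(values = values,
                 runday = stats::setNames(runday, rownames(values)),
                 fluid = stats::setNames(fluid, colnames(values)),
                 log2 = log2),
            class = "mf_data")
}

#' @export
print.mf_data <- function(x, ...) {
  v <- x$values
  cat("<mf_data> ", nrow(v), " samples x ", ncol(v), " features",
      if (x$log2) " (log2 scale)", "\n", sep = "")
  cat("  fluids:   ", paste(sprintf("%s (%d)", names(table(x$fluid)),
                                    table(x$fluid)), collapse = ", "), "\n")
  cat("  run days: ", length(unique(x$runday)), "\n")
  cat("  missing:  ", sum(is.na(v)),
      sprintf(" (%.1f%%)", 100 * mean(is.na(v))), "\n")
  invisible(x)
}

#' @export
dim.mf_data <- function(x) dim(x$values)

## Subset samples/features keeping labels aligned.
mf_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  mf_data(v, x$runday[rownames(v)], x$fluid[colnames(v)], log2 = x$log2)
}

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

#' Correlation network at one level of the hierarchical map
#'
#' An undirected network whose nodes are `"FLUID::name"` identities at the
#' metabolite, sub-pathway or super-pathway level.  Metabolite- and
#' sub-pathway-level edges carry four statistics (Pearson r and p, partial
#' r and p); super-pathway edges, produced by collapsing, carry only a
#' member-edge count.
#'
#' @param level One of `"metabolite"`, `"sub_pathway"`, `"super_pathway"`.
#' @param nodes Character vector of node identities.
#' @param edges Data frame with columns `from`, `to` and, for
#'   statistical levels, `pearson_r`, `partial_r`, `pearson_p`,
#'   `partial_p`; for the collapsed level, `n_member_edges`.
#' @param node_attrs Optional data frame of per-node attributes keyed by
#'   a `node` column (e.g. fluid, pathway membership).
#' @return An object of class `mf_network`.
#' @export
mf_network <- function(level = c("metabolite", "sub_pathway", "super_pathway"),
                       nodes, edges = NULL, node_attrs = NULL) {
  level <- match.arg(level)
  nodes <- sort(unique(as.character(nodes)))
  stat_cols <- c("pearson_r", "partial_r", "pearson_p", "partial_p")
  if (is.null(edges) || nrow(edges) == 0L) {
    cols <- if (level == "super_pathway") c("from", "to", "n_member_edges")
            else c("from", "to", stat_cols)
    edges <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)),
        rep(list(numeric(0)), length(cols) - 2L)), cols))
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges need 'from' and 'to' columns")
    if (level != "super_pathway" && !all(stat_cols %in% names(edges)))
      stop("edges at the ", level,
           " level must carry pearson_r, partial_r, pearson_p, partial_p")
    ## canonical unordered representation: from < to, rows sorted
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (any(edges$from == edges$to)) stop("self-loop in edge list")
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edge in edge list")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    miss <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(miss) > 0)
      stop("edge endpoint(s) not in node set: ", paste(miss, collapse = ", "))
  }
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs, stringsAsFactors = FALSE)
    stopifnot("node" %in% names(node_attrs))
    node_attrs <- node_attrs[match(nodes, node_attrs$node), , drop = FALSE]
    rownames(node_attrs) <- NULL
  }
  structure(list(level = level, nodes = nodes, edges = edges,
                 node_attrs = node_attrs),
            class = "mf_network")
}

#' @export
print.mf_network <- function(x, ...) {
  cat("<mf_network> level: ", x$level, "\n", sep = "")
  cat("  ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  fl <- split_node_id(x$nodes)$fluid
  cat("  fluids: ", paste(sprintf("%s (%d)", names(table(fl)), table(fl)),
                          collapse = ", "), "\n", sep = "")
  if (nrow(x$edges) > 0 && x$level != "super_pathway") {
    intra <- fluid_of(x$edges$from) == fluid_of(x$edges$to)
    cat("  intrafluid edges: ", sum(intra), ", interfluid: ", sum(!intra),
        "\n", sep = "")
  }
  invisible(x)
}

fluid_of <- function(id) split_node_id(id)$fluid

#' @export
summary.mf_network <- function(object, ...) {
  e <- object$edges
  out <- list(level = object$level, n_nodes = length(object$nodes),
              n_edges = nrow(e))
  if (nrow(e) > 0) {
    intra <- fluid_of(e$from) == fluid_of(e$to)
    out$n_intrafluid <- sum(intra)
    out$n_interfluid <- sum(!intra)
  }
  structure(out, class = "summary.mf_network")
}

#' @export
print.summary.mf_network <- function(x, ...) {
  cat(sprintf("%s network: %d nodes, %d edges", x$level, x$n_nodes, x$n_edges))
  if (!is.null(x$n_intrafluid))
    cat(sprintf(" (%d intrafluid, %d interfluid)", x$n_intrafluid,
                x$n_interfluid))
  cat("\n")
  invisible(x)
}
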
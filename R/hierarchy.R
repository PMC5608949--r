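## Eigenmetabolite aggregation of sub-pathways and construction of the
## three-level hierarchical map (metabolite GGM, sub-pathway GGM,
## collapsed super-pathway network).

#' Eigenmetabolite of a pathway
#'
#' Z-scores the member metabolites and takes the first principal
#' component score vector as the pathway representative.  The explained
#' variance is the leading eigenvalue of the member correlation matrix
#' divided by its trace (the member count).  The sign is fixed so that
#' the eigenmetabolite correlates non-negatively with the mean of the
#' z-scored members, which makes the representative deterministic.
#'
#' @param x_members Numeric matrix (n samples x m members), fully
#'   observed, m >= 1.
#' @return List of class `eigenmetabolite` with `scores` (length n,
#'   zero mean), `explained_variance` in (0, 1], `loadings` (length m),
#'   and `n_members`.
#' @export
eigenmetabolite <- function(x_members) {
  x_members <- as.matrix(x_members)
  m <- ncol(x_members)
  if (m < 1L) stop("pathway needs at least one member")
  if (anyNA(x_members)) stop("members must be fully observed")
  z <- zscore(x_members, what = "pathway member")
  if (m == 1L) {
    return(structure(list(scores = drop(z), explained_variance = 1,
                          loadings = stats::setNames(1, colnames(z)),
                          n_members = 1L),
                     class = "eigenmetabolite"))
  }
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  ev <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  s <- sum(scores * rowMeans(z))
  if (s < 0 || (s == 0 && loadings[1L] < 0)) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = scores, explained_variance = ev,
                 loadings = loadings, n_members = m),
            class = "eigenmetabolite")
}

#' @export
print.eigenmetabolite <- function(x, ...) {
  cat(sprintf(
    "<eigenmetabolite> %d member(s), explained variance %.3f\n",
    x$n_members, x$explained_variance))
  invisible(x)
}

## Group the known metabolites of a processed matrix by
## (fluid, sub-pathway); returns a named list of column-index vectors
## keyed by the "FLUID::sub_pathway" node identity.
subpathway_groups <- function(x, annotations) {
  ann <- annotations[match(feature_ids(x), annotations$feature_id), ]
  known <- which(!is.na(ann$known) & ann$known)
  if (length(known) == 0L) stop("no annotated (known) metabolites")
  key <- node_id(ann$fluid[known], ann$sub_pathway[known])
  split(known, key)
}

#' Sub-pathway network from eigenmetabolites
#'
#' Computes one eigenmetabolite per (fluid, sub-pathway) over the known
#' metabolites, then infers a GGM on the eigenmetabolite matrix exactly
#' as at the metabolite level.  Unknown metabolites cannot be assigned
#' to a pathway and are excluded.
#'
#' @param x Processed [mf_data] (fully observed, log2 scale).
#' @param annotations Annotation table (see [read_annotations()]).
#' @param covariates,alpha,lambda,method Passed to [build_ggm()].
#' @return List with the sub-pathway `network` ([mf_network]), the
#'   `eigen` list of [eigenmetabolite] objects keyed by node identity,
#'   and the explained-variance table `ev_table` (node, n_members,
#'   explained_variance).
#' @export
build_subpathway_network <- function(x, annotations, covariates = NULL,
                                     alpha = 0.05, lambda = NULL,
                                     method = "auto") {
  stopifnot(inherits(x, "mf_data"))
  groups <- subpathway_groups(x, annotations)
  if (length(groups) < 2L) stop("need at least 2 sub-pathway nodes")
  eig <- lapply(groups, function(idx)
    eigenmetabolite(x$values[, idx, drop = FALSE]))
  em <- vapply(eig, `[[`, numeric(nrow(x$values)), "scores")
  colnames(em) <- names(groups)
  rownames(em) <- sample_ids(x)
  sub2super <- subpathway_hierarchy(annotations)
  attrs <- data.frame(node = names(groups),
                      super_pathway = sub2super[names(groups)],
                      stringsAsFactors = FALSE)
  net <- build_ggm(em, covariates = covariates, alpha = alpha,
                   lambda = lambda, method = method,
                   level = "sub_pathway", node_attrs = attrs)
  ev <- data.frame(node = names(groups),
                   n_members = vapply(eig, `[[`, integer(1), "n_members"),
                   explained_variance =
                     vapply(eig, `[[`, numeric(1), "explained_variance"),
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(network = net, eigen = eig, ev_table = ev)
}

#' Fluid-resolved sub-pathway to super-pathway mapping
#'
#' @param annotations Annotation table.
#' @return Named character vector mapping `"FLUID::sub_pathway"` node
#'   identities to `"FLUID::super_pathway"` identities.
#' @export
subpathway_hierarchy <- function(annotations) {
  known <- annotations[!is.na(annotations$known) & annotations$known, ]
  map <- unique(data.frame(sub = node_id(known$fluid, known$sub_pathway),
                           super = node_id(known$fluid, known$super_pathway),
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$sub))
    stop("sub-pathway mapped to more than one super-pathway")
  stats::setNames(map$super, map$sub)
}

#' Collapse a sub-pathway network to the super-pathway level
#'
#' Super-pathway nodes are (fluid, super-pathway) pairs; two distinct
#' super-pathway nodes are linked whenever at least one sub-pathway edge
#' connects their member sub-pathways.  Edges collapsing onto a single
#' super-pathway node (intra-super-pathway correlations) are dropped as
#' self-loops.  Collapsed edges carry the number of member sub-pathway
#' edges (`n_member_edges`) but no correlation statistics.
#'
#' @param subnet Sub-pathway [mf_network].
#' @param hierarchy Named map from sub-pathway to super-pathway node
#'   identities (see [subpathway_hierarchy()]), covering every subnet
#'   node.
#' @return An [mf_network] at the super-pathway level.
#' @export
collapse_to_superpathway <- function(subnet, hierarchy) {
  stopifnot(inherits(subnet, "mf_network"), subnet$level == "sub_pathway")
  unmapped <- setdiff(subnet$nodes, names(hierarchy))
  if (length(unmapped) > 0)
    stop("sub-pathway node(s) missing from the hierarchy: ",
         paste(unmapped, collapse = ", "))
  nodes <- sort(unique(unname(hierarchy[subnet$nodes])))
  e <- subnet$edges
  edges <- NULL
  if (nrow(e) > 0) {
    a <- unname(hierarchy[e$from])
    b <- unname(hierarchy[e$to])
    keep <- a != b
    if (any(keep)) {
      lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
      agg <- stats::aggregate(list(n_member_edges = rep(1L, sum(keep))),
                              by = list(from = lo, to = hi), FUN = sum)
      edges <- agg
    }
  }
  mf_network("super_pathway", nodes = nodes, edges = edges)
}

#' Build the full three-level hierarchical map
#'
#' Infers the metabolite-level GGM, the sub-pathway eigenmetabolite GGM,
#' and the collapsed super-pathway network from one processed matrix,
#' all with the same covariate conditioning and significance rule.
#'
#' @param x Processed [mf_data] (fully observed, log2 scale).
#' @param annotations Annotation table.
#' @param covariates,alpha,lambda,method Passed to [build_ggm()].
#' @param include_unknowns Keep unannotated metabolites at the
#'   metabolite level (default TRUE; pathway levels always exclude
#'   them).
#' @return Object of class `mf_map`: a list with elements `metabolite`,
#'   `sub_pathway`, `super_pathway` ([mf_network]s), `eigen`,
#'   `ev_table`, and `annotations`.
#' @export
build_hierarchical_map <- function(x, annotations, covariates = NULL,
                                   alpha = 0.05, lambda = NULL,
                                   method = "auto",
                                   include_unknowns = TRUE) {
  met <- build_metabolite_network(x, annotations, covariates = covariates,
                                  alpha = alpha, lambda = lambda,
                                  method = method,
                                  include_unknowns = include_unknowns)
  sub <- build_subpathway_network(x, annotations, covariates = covariates,
                                  alpha = alpha, lambda = lambda,
                                  method = method)
  super <- collapse_to_superpathway(sub$network,
                                    subpathway_hierarchy(annotations))
  structure(list(metabolite = met,
                 sub_pathway = sub$network,
                 super_pathway = super,
                 eigen = sub$eigen,
                 ev_table = sub$ev_table,
                 annotations = annotations),
            class = "mf_map")
}

#' @export
print.mf_map <- function(x, ...) {
  cat("<mf_map> hierarchical multifluid correlation map\n")
  for (lv in c("metabolite", "sub_pathway", "super_pathway"))
    cat(sprintf("  %-13s %4d nodes, %4d edges\n", lv,
                length(x[[lv]]$nodes), nrow(x[[lv]]$edges)))
  cat(sprintf("  median sub-pathway explained variance: %.2f\n",
              stats::median(x$ev_table$explained_variance)))
  invisible(x)
}

#' Write the explained-variance table of a map
#'
#' @param map An `mf_map` or the result of [build_subpathway_network()].
#' @param path Output TSV path.
#' @export
write_ev_table <- function(map, path) {
  utils::write.table(map$ev_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
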
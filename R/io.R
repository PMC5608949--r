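#' Read an intensity matrix with sample/feature metadata
#'
#' The matrix file is a TSV whose header row holds feature ids and whose
#' first column holds sample ids; empty fields or `NA` encode missing
#' measurements.  The metadata file is a TSV with columns `id`, `type`
#' and `label`, where rows of type `"sample"` give the run-day label of
#' each sample and rows of type `"feature"` give the fluid label of each
#' feature.
#'
#' @param path Path to the intensity TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param log2 Set to `TRUE` when reading back an already
#'   log2-transformed (e.g. fully preprocessed) matrix, where negative
#'   values are legitimate.
#' @return An [mf_data] object.
#' @export
read_intensity_tsv <- function(path, metadata_path, log2 = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (ncol(tab) < 2L) stop("intensity file needs sample ids plus features")
  sample_id <- tab[[1L]]
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  feat <- colnames(tab)[-1L]
  if (anyDuplicated(feat))
    stop("duplicate feature ids in ", path)
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(sample_id, feat))
  meta <- utils::read.delim(metadata_path, colClasses = "character")
  need <- c("id", "type", "label")
  if (!all(need %in% names(meta)))
    stop("metadata file needs columns id, type, label")
  smeta <- meta[meta$type == "sample", ]
  fmeta <- meta[meta$type == "feature", ]
  runday <- smeta$label[match(sample_id, smeta$id)]
  if (anyNA(runday))
    stop("sample(s) without run-day label: ",
         paste(sample_id[is.na(runday)], collapse = ", "))
  fluid <- fmeta$label[match(feat, fmeta$id)]
  if (anyNA(fluid))
    stop("feature(s) without fluid label: ",
         paste(feat[is.na(fluid)], collapse = ", "))
  mf_data(vals, runday, fluid, log2 = log2)
}

#' Write an intensity matrix and its metadata
#'
#' Inverse of [read_intensity_tsv()]; `read_intensity_tsv()` on the two
#' written files reproduces the object.
#'
#' @param x An [mf_data] object.
#' @param path,metadata_path Output file paths.
#' @export
write_intensity_tsv <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "mf_data"))
  tab <- data.frame(sample_id = sample_ids(x), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  meta <- rbind(
    data.frame(id = sample_ids(x), type = "sample",
               label = unname(x$runday)),
    data.frame(id = feature_ids(x), type = "feature",
               label = unname(x$fluid)))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metabolite annotation table
#'
#' Expects TSV columns `feature_id`, `fluid`, `sub_pathway`,
#' `super_pathway`.  Metabolites of unknown chemical structure leave both
#' pathway fields empty and are flagged `known = FALSE`; they take part
#' in metabolite-level network estimation but are excluded from pathway
#' aggregation.  Each sub-pathway must map to exactly one super-pathway.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `feature_id`, `fluid`, `known`,
#'   `sub_pathway`, `super_pathway`, `node_id`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("NA", ""))
  need <- c("feature_id", "fluid", "sub_pathway", "super_pathway")
  if (!all(need %in% names(tab)))
    stop("annotation file needs columns ", paste(need, collapse = ", "))
  as_annotations(tab[need])
}

#' Validate and complete an annotation table
#'
#' @param tab Data frame with columns `feature_id`, `fluid`,
#'   `sub_pathway`, `super_pathway` (`NA` pathway fields mean unknown).
#' @return The validated table with `known` and `node_id` columns added.
#' @export
as_annotations <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$feature_id))
    stop("duplicate feature_id in annotations")
  if (anyNA(tab$fluid)) stop("feature without fluid label")
  half <- xor(is.na(tab$sub_pathway), is.na(tab$super_pathway))
  if (any(half))
    stop("feature(s) with only one of sub-/super-pathway set: ",
         paste(tab$feature_id[half], collapse = ", "))
  tab$known <- !is.na(tab$sub_pathway)
  map <- unique(tab[tab$known, c("fluid", "sub_pathway", "super_pathway")])
  dup <- duplicated(map[c("fluid", "sub_pathway")])
  if (any(dup))
    stop("sub-pathway mapped to more than one super-pathway: ",
         paste(unique(map$sub_pathway[dup]), collapse = ", "))
  tab$node_id <- node_id(tab$fluid, tab$feature_id)
  tab
}

#' Read a phenotype/covariate table
#'
#' TSV with a `sample_id` column plus one column per phenotype or
#' covariate (numeric, or 0/1 coded for binary traits such as gender).
#'
#' @param path Path to the TSV.
#' @return Data frame keyed by `sample_id`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype file needs sample_id")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in phenotypes")
  tab
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

num_attr <- function(v) sprintf("%.17g", v)

#' Write a correlation network to GraphML or edge-list TSV
#'
#' GraphML output carries the network level as a graph attribute, fluid
#' and name (plus any extra node attributes) per node, and the four edge
#' statistics (`pearson_r`, `partial_r`, `pearson_p`, `partial_p`) — or
#' the member-edge count for collapsed super-pathway networks — per edge.
#' Nodes and edges are emitted in lexicographic order so output is
#' byte-stable.  The edge-list TSV holds one row per edge with the same
#' statistics columns and a `# level=` header comment.
#'
#' @param net An [mf_network].
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(net, "mf_network"))
  format <- match.arg(format)
  if (format == "tsv") return(write_network_tsv(net, path))

  stat_cols <- setdiff(names(net$edges), c("from", "to"))
  extra <- if (!is.null(net$node_attrs))
    setdiff(names(net$node_attrs), "node") else character(0)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="level" for="graph" attr.name="level" attr.type="string"/>')
  w('  <key id="fluid" for="node" attr.name="fluid" attr.type="string"/>')
  w('  <key id="name" for="node" attr.name="name" attr.type="string"/>')
  for (a in extra)
    w('  <key id="', a, '" for="node" attr.name="', a,
      '" attr.type="string"/>')
  for (s in stat_cols)
    w('  <key id="', s, '" for="edge" attr.name="', s,
      '" attr.type="double"/>')
  w('  <graph id="G" edgedefault="undirected">')
  w('    <data key="level">', net$level, '</data>')
  parts <- split_node_id(net$nodes)
  for (i in seq_along(net$nodes)) {
    line <- paste0('    <node id="', xml_escape(net$nodes[i]), '">',
                   '<data key="fluid">', xml_escape(parts$fluid[i]),
                   '</data>',
                   '<data key="name">', xml_escape(parts$name[i]), '</data>')
    for (a in extra) {
      v <- net$node_attrs[[a]][i]
      if (!is.na(v))
        line <- paste0(line, '<data key="', a, '">',
                       xml_escape(as.character(v)), '</data>')
    }
    w(line, '</node>')
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    line <- paste0('    <edge source="', xml_escape(e$from[i]),
                   '" target="', xml_escape(e$to[i]), '">')
    for (s in stat_cols)
      line <- paste0(line, '<data key="', s, '">', num_attr(e[[s]][i]),
                     '</data>')
    w(line, '</edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

write_network_tsv <- function(net, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# mfmap edge list; level=", net$level), con)
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"tsv"`.  The TSV form stores only the
#'   edge list, so isolated nodes are not recovered from it.
#' @return An [mf_network].
#' @export
read_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    level <- sub("^.*level=", "", first)
    edges <- utils::read.delim(path, comment.char = "#")
    return(mf_network(level, nodes = unique(c(edges$from, edges$to)),
                      edges = edges))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  graph <- xml2::xml_find_first(doc, ".//graph")
  level <- xml2::xml_text(
    xml2::xml_find_first(graph, "./data[@key='level']"))
  node_nodes <- xml2::xml_find_all(graph, "./node")
  ids <- xml2::xml_attr(node_nodes, "id")
  extra_keys <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//key[@for='node']"), "id")
  extra_keys <- setdiff(extra_keys, c("fluid", "name"))
  node_attrs <- data.frame(node = ids, stringsAsFactors = FALSE)
  for (a in extra_keys) {
    node_attrs[[a]] <- vapply(node_nodes, function(nd) {
      d <- xml2::xml_find_first(nd, paste0("./data[@key='", a, "']"))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, "")
  }
  edge_nodes <- xml2::xml_find_all(graph, "./edge")
  stat_keys <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//key[@for='edge']"), "id")
  edges <- NULL
  if (length(edge_nodes) > 0) {
    edges <- data.frame(from = xml2::xml_attr(edge_nodes, "source"),
                        to = xml2::xml_attr(edge_nodes, "target"),
                        stringsAsFactors = FALSE)
    for (s in stat_keys)
      edges[[s]] <- as.numeric(vapply(edge_nodes, function(nd)
        xml2::xml_text(
          xml2::xml_find_first(nd, paste0("./data[@key='", s, "']"))), ""))
  }
  mf_network(level, nodes = ids, edges = edges,
             node_attrs = if (length(extra_keys)) node_attrs else NULL)
}

#' Write a module report to JSON (and optionally TSV)
#'
#' The JSON object records the network level, phenotype, node count,
#' node-level Bonferroni threshold and, per reported module, its member
#' nodes, member metabolites, score, p-value and seed provenance.
#'
#' @param report A `module_report` (see [run_module_identification()]).
#' @param path Output JSON path.
#' @param tsv_path Optional path for a human-readable TSV (one row per
#'   module).
#' @export
write_module_report <- function(report, path, tsv_path = NULL) {
  stopifnot(inherits(report, "module_report"))
  obj <- list(level = report$level,
              phenotype = report$phenotype,
              n_nodes = report$n_nodes,
              bonferroni_threshold = report$bonferroni_threshold,
              modules = lapply(report$modules, function(m)
                list(nodes = m$nodes, members = m$members,
                     score = m$score, p_value = m$p_value,
                     seeds = m$seeds, status = m$status)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsv_path)) {
    tab <- module_report_table(report)
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
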
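#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose a fluid-resolved node identity
#'
#' Nodes at every level of the hierarchical map are identified by a
#' `"<FLUID>::<name>"` string, so that the same metabolite or pathway
#' name measured in two fluids yields two distinct nodes (e.g.
#' `"P::betaine"` and `"U::betaine"`).
#'
#' @param fluid Fluid label (e.g. `"P"`, `"U"`, `"S"`).
#' @param name Metabolite or pathway name.
#' @return Character vector of node identity strings.
#' @export
#' @examples
#' node_id("P", "betaine")
node_id <- function(fluid, name) {
  stopifnot(length(fluid) == length(name) || length(fluid) == 1L ||
              length(name) == 1L)
  paste0(fluid, "::", name)
}

#' Split node identities back into fluid and name
#'
#' @param id Character vector of `"FLUID::name"` strings.
#' @return Data frame with columns `fluid` and `name`.
#' @export
split_node_id <- function(id) {
  m <- regmatches(id, regexpr("::", id, fixed = TRUE), invert = TRUE)
  bad <- lengths(m) != 2L
  if (any(bad))
    stop("malformed node id(s): ", paste(id[bad], collapse = ", "))
  data.frame(fluid = vapply(m, `[`, "", 1L),
             name  = vapply(m, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

## Column-wise z-score; zero-variance columns raise an error naming them.
zscore <- function(x, what = "column") {
  x <- as.matrix(x)
  s <- apply(x, 2L, stats::sd)
  if (any(!is.finite(s)) || any(s == 0)) {
    bad <- colnames(x)[!is.finite(s) | s == 0] %||% which(!is.finite(s) | s == 0)
    stop("zero-variance ", what, ": ", paste(bad, collapse = ", "))
  }
  scale(x, center = TRUE, scale = s)[, , drop = FALSE]
}

## Stable 31-bit string hash (polynomial rolling hash). Used to derive
## reproducible RNG substreams keyed by (feature, run day) so that the
## draws for one cell do not depend on processing order.
stable_hash <- function(key) {
  p <- 2147483629
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% p
  as.integer(h)
}

## Evaluate `expr` under a substream seed derived from (master, key),
## restoring the caller's RNG state afterwards.
with_substream <- function(master, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  seed <- (as.integer(master) %% 2147483L) * 1000L +
    stable_hash(key) %% 1000L
  set.seed(seed)
  force(expr)
}

## Robust scale estimate falling back gracefully for constant vectors.
robust_sd <- function(x) {
  m <- stats::mad(x)
  if (m == 0) stats::sd(x) else m
}
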
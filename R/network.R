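#' Symptom network
#'
#' A weighted signed network over questionnaire items: node metadata plus a
#' symmetric zero-diagonal matrix of edge weights (partial correlations).
#'
#' @param weights p x p numeric matrix, symmetric with zero diagonal and all
#'   `|weight| < 1`.
#' @param items `item_metadata` for the p nodes, in matrix order.
#' @param tol asymmetry tolerance; the matrix is symmetrized by averaging if
#'   the maximum asymmetry is below `tol`, otherwise an error is thrown.
#' @return An object of class `symptom_network` with elements `items` and
#'   `weights` (dimnames set to item ids).
#' @export
symptom_network <- function(weights, items, tol = 1e-8) {
  items <- validate_item_metadata(items)
  weights <- as.matrix(weights)
  p <- nrow(items)
  if (!all(dim(weights) == c(p, p)))
    stop("weights must be ", p, "x", p, call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop("weights matrix asymmetric (max |w - t(w)| = ",
         format(asym), " > ", format(tol), ")", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(abs(weights) >= 1))
    stop("all |weights| must be < 1 (partial correlations)", call. = FALSE)
  dimnames(weights) <- list(items$item_id, items$item_id)
  structure(list(items = items, weights = weights), class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  p <- nrow(x$items)
  cat("<symptom_network> ", p, " nodes, ", edge_count(x), " / ",
      p * (p - 1) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Count network edges
#'
#' Number of unordered node pairs whose absolute weight exceeds `tol`
#' (default 0: an exact nonzero test on the stored values). Monotone
#' non-increasing in `tol`.
#'
#' @param net a `symptom_network`.
#' @param tol nonnegative threshold.
#' @return Integer edge count.
#' @export
edge_count <- function(net, tol = 0) {
  stopifnot(inherits(net, "symptom_network"), tol >= 0)
  w <- net$weights
  sum(abs(w[upper.tri(w)]) > tol)
}

#' Read a weights matrix from CSV
#'
#' Accepts either a full symmetric p x p grid or a lower-triangular grid
#' (entries above the diagonal empty), each with a header row and a header
#' column of item ids. Lower-triangular input is mirrored; the diagonal is
#' forced to zero.
#'
#' @param path CSV file path.
#' @param items `item_metadata`; the file's item ids must all be known and
#'   the matrix is returned in metadata order.
#' @param tol asymmetry tolerance for full matrices.
#' @return A validated [symptom_network()].
#' @export
read_weights_matrix <- function(path, items, tol = 1e-8) {
  items <- validate_item_metadata(items)
  raw <- utils::read.csv(path, header = TRUE, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(raw)
  ids <- rownames(m)
  unknown <- setdiff(c(ids, colnames(m)), items$item_id)
  if (length(unknown))
    stop("unknown item_id(s) in weights file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("weights file must be a square grid with matching row/column ids",
         call. = FALSE)
  storage.mode(m) <- "double"
  up <- m[upper.tri(m)]
  if (all(is.na(up))) {          # lower-triangular grid: mirror
    m[upper.tri(m)] <- 0
    m[is.na(m)] <- 0
    m <- m + t(m)
  } else if (anyNA(m)) {
    stop("weights file mixes filled and empty cells off-pattern", call. = FALSE)
  }
  diag(m) <- 0
  # reorder to metadata order (file may be a subset ordering of known items)
  if (!identical(ids, items$item_id)) {
    items <- items[match(ids, items$item_id), , drop = FALSE]
    items <- validate_item_metadata(as.data.frame(items))
  }
  symptom_network(m, items, tol = tol)
}

#' Write a weights matrix to CSV
#'
#' Full symmetric grid with header row/column of item ids. A
#' read -> write -> read round trip reproduces the stored weights exactly.
#'
#' @param net a `symptom_network`.
#' @param path output CSV path.
#' @export
write_weights_matrix <- function(net, path) {
  stopifnot(inherits(net, "symptom_network"))
  df <- as.data.frame(net$weights)
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' The packaged loneliness-depression-anxiety network
#'
#' Edge weights (partial correlations, printed to two decimals) of the 19-item
#' network over the Three-Item Loneliness Scale, PHQ-9 and GAD-7, estimated by
#' an unregularized stepwise-BIC Gaussian graphical model in a nationally
#' representative population sample (N = 1041) surveyed during the early
#' COVID-19 lockdown. Of the 171 possible edges, 52 (30.41%) are nonzero.
#' Because the stored values are rounded to two decimals, quantities derived
#' from this matrix carry rounding error of that order.
#'
#' @return A [symptom_network()] with 19 nodes.
#' @examples
#' net <- lad_network()
#' edge_count(net)  # 52
#' @export
lad_network <- function() {
  read_weights_matrix(
    system.file("extdata", "lad_edge_weights.csv", package = "symptomnet",
                mustWork = TRUE),
    default_items())
}

#' Convert a symptom network to an igraph object
#'
#' Nodes carry a `construct` attribute, edges a signed `weight`.
#'
#' @param net a `symptom_network`.
#' @param tol edges with `|weight| <= tol` are dropped.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net, tol = 0) {
  stopifnot(inherits(net, "symptom_network"))
  w <- net$weights
  w[abs(w) <= tol] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$construct <- net$items$construct[match(igraph::V(g)$name,
                                                      net$items$item_id)]
  g
}

#' Export a symptom network to GraphML
#'
#' @param net a `symptom_network`.
#' @param path output path.
#' @param ... passed to [as_igraph()].
#' @export
write_graphml <- function(net, path, ...) {
  g <- as_igraph(net, ...)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
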
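#' Bridge expected influence (1-step)
#'
#' For each node, the signed sum of its edge weights to nodes of *other*
#' construct clusters. Together with the within-cluster sum it decomposes the
#' ordinary one-step expected influence:
#' `bridge_ei_raw + within-cluster EI = EI`. High-bridge nodes are the
#' candidate pathways through which disorder clusters activate one another.
#'
#' @param net a `symptom_network`.
#' @param clusters named character vector mapping every node to a cluster;
#'   defaults to the item metadata's construct labels.
#' @return A data frame of class `bridge_table`: node, cluster,
#'   `bridge_ei_raw`, `bridge_ei_z` (sample-SD z-scores) and rank
#'   (1 = highest raw bridge EI).
#' @export
bridge_expected_influence <- function(net, clusters = NULL) {
  stopifnot(inherits(net, "symptom_network"))
  ids <- net$items$item_id
  if (is.null(clusters)) {
    clusters <- stats::setNames(net$items$construct, ids)
  }
  miss <- setdiff(ids, names(clusters))
  if (length(miss))
    stop("nodes without cluster assignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cl <- clusters[ids]
  if (anyNA(cl))
    stop("nodes without cluster assignment", call. = FALSE)
  w <- net$weights
  other <- outer(cl, cl, FUN = "!=")
  bei <- rowSums(w * other)
  bei_z <- if (stats::sd(bei) > 0) standardize(bei) else bei * 0
  structure(data.frame(
    node = ids,
    cluster = unname(cl),
    bridge_ei_raw = unname(bei),
    bridge_ei_z = unname(bei_z),
    rank = rank(-bei, ties.method = "min"),
    row.names = NULL), class = c("bridge_table", "data.frame"))
}
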
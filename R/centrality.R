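#' One-step expected influence
#'
#' Signed sum of each node's incident edge weights. Unlike strength, negative
#' edges subtract, which is the recommended index when a network contains
#' negative partial correlations. Linear in the weights: scaling all weights
#' by `c` scales every EI by `c`.
#'
#' @param net a `symptom_network`.
#' @return Named numeric vector of raw expected influence per node.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  rowSums(net$weights)
}

#' All-pairs shortest-path distances
#'
#' Edge lengths are `1 / |weight|` (the standard convention for
#' partial-correlation networks: stronger associations are shorter), absent
#' edges have no length; distances are Dijkstra shortest paths and
#' unreachable pairs are `Inf`.
#'
#' @param net a `symptom_network`.
#' @return p x p symmetric nonnegative matrix with zero diagonal.
#' @export
node_distances <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  L <- 1 / abs(net$weights)
  diag(L) <- Inf                      # no self loops
  p <- nrow(L)
  D <- matrix(Inf, p, p, dimnames = dimnames(net$weights))
  for (s in seq_len(p)) D[s, ] <- dijkstra(L, s)$dist
  D
}

# O(p^2) Dijkstra from source s on length matrix L (Inf = no edge).
# Returns distances, predecessor lists (with tie tolerance) and path counts,
# which is what Brandes' betweenness accumulation needs.
dijkstra <- function(L, s, tie_tol = 1e-9) {
  p <- nrow(L)
  dist <- rep(Inf, p); dist[s] <- 0
  sigma <- rep(0, p); sigma[s] <- 1
  preds <- vector("list", p)
  done <- rep(FALSE, p)
  order_settled <- integer(0)
  repeat {
    u <- NA_integer_
    du <- Inf
    for (v in seq_len(p)) if (!done[v] && dist[v] < du) { u <- v; du <- dist[v] }
    if (is.na(u)) break
    done[u] <- TRUE
    order_settled <- c(order_settled, u)
    nb <- which(is.finite(L[u, ]))
    for (v in nb) {
      if (done[v]) next
      alt <- du + L[u, v]
      if (alt < dist[v] - tie_tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= tie_tol) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_settled)
}

#' Betweenness centrality
#'
#' For every unordered node pair (s, t) distinct from i, the fraction of
#' shortest s--t paths (lengths `1 / |weight|`) passing through i, with
#' fractional credit for tied geodesics (Brandes accumulation; ties detected
#' with a float tolerance of 1e-9). Invariant under global sign flips of the
#' weights.
#'
#' @param net a `symptom_network`.
#' @return Named numeric vector.
#' @export
betweenness <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  L <- 1 / abs(net$weights)
  diag(L) <- Inf
  p <- nrow(L)
  bc <- rep(0, p)
  for (s in seq_len(p)) {
    dj <- dijkstra(L, s)
    delta <- rep(0, p)
    for (v in rev(dj$order)) {
      for (u in dj$preds[[v]]) {
        delta[u] <- delta[u] + dj$sigma[u] / dj$sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2                        # undirected: each pair counted twice
  names(bc) <- rownames(net$weights)
  bc
}

#' Closeness centrality
#'
#' `(|C| - 1) / sum of shortest-path distances` within the node's connected
#' component C. On a disconnected network closeness is computed per component
#' and the result carries attribute `components`; isolated nodes get 0.
#'
#' @param net a `symptom_network`.
#' @return Named numeric vector (attribute `components` gives the component
#'   membership when the network is disconnected).
#' @export
closeness <- function(net) {
  D <- node_distances(net)
  p <- nrow(D)
  comp <- integer(p)
  cid <- 0
  for (v in seq_len(p)) {
    if (comp[v] == 0) {
      cid <- cid + 1
      comp[is.finite(D[v, ]) | seq_len(p) == v] <- cid
    }
  }
  cl <- vapply(seq_len(p), function(i) {
    members <- which(comp == comp[i])
    if (length(members) == 1L) return(0)
    (length(members) - 1) / sum(D[i, setdiff(members, i)])
  }, 0)
  names(cl) <- rownames(D)
  if (cid > 1) attr(cl, "components") <- comp
  cl
}

#' Standardize a centrality vector
#'
#' z-scores with the sample (n-1 denominator) standard deviation, the
#' convention under which the packaged network reproduces its published
#' standardized expected-influence values.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return z-scored vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize: zero standard deviation", call. = FALSE)
  (values - mean(values)) / s
}

#' Centrality table
#'
#' Raw and standardized betweenness, closeness and expected influence per
#' node, plus per-index ranks (1 = highest).
#'
#' @param net a `symptom_network`.
#' @return A data frame, one row per node.
#' @export
centrality_table <- function(net) {
  b <- betweenness(net)
  cl <- closeness(net)
  ei <- expected_influence(net)
  data.frame(
    node = net$items$item_id,
    construct = net$items$construct,
    betweenness_raw = unname(b),
    closeness_raw = unname(cl),
    ei_raw = unname(ei),
    betweenness_z = unname(standardize(b)),
    closeness_z = unname(standardize(cl)),
    ei_z = unname(standardize(ei)),
    betweenness_rank = rank(-b, ties.method = "min"),
    closeness_rank = rank(-cl, ties.method = "min"),
    ei_rank = rank(-ei, ties.method = "min"),
    row.names = NULL)
}
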
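#' Enumerate k-cliques of a symptom network
#'
#' All node subsets of size k in which every pair is connected by a nonzero
#' edge (sign is ignored).
#'
#' @param net a `symptom_network`.
#' @param k clique size, `3 <= k <= p`.
#' @return List of character vectors (sorted item ids), in a stable order.
#' @export
enumerate_cliques <- function(net, k) {
  stopifnot(inherits(net, "symptom_network"))
  p <- nrow(net$weights)
  if (k < 3 || k > p) stop("k must be in [3, p]", call. = FALSE)
  g <- as_igraph(net)
  cl <- igraph::cliques(g, min = k, max = k)
  out <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  out[order(vapply(out, paste, "", collapse = "|"))]
}

#' Intensity of a clique
#'
#' Geometric mean of the absolute weights of the clique's `k(k-1)/2` edges.
#' Absolute values are used so that cliques containing negative edges can
#' still percolate; a zero edge inside the clique is an error (the set is
#' not a clique).
#'
#' @param net a `symptom_network`.
#' @param clique character vector of item ids or integer node indices.
#' @return Scalar intensity.
#' @export
clique_intensity <- function(net, clique) {
  stopifnot(inherits(net, "symptom_network"))
  idx <- if (is.character(clique))
    match(clique, net$items$item_id) else as.integer(clique)
  if (anyNA(idx)) stop("unknown item in clique", call. = FALSE)
  pairs <- utils::combn(idx, 2)
  w <- net$weights[t(pairs)]
  if (any(w == 0))
    stop("clique contains a zero-weight pair; not fully connected",
         call. = FALSE)
  exp(mean(log(abs(w))))
}

#' Weighted clique percolation
#'
#' Retains the k-cliques whose intensity is at least `I`, links cliques that
#' share `k - 1` nodes, and reports the node-unions of the resulting clique
#' chains as communities. A node may belong to several communities; nodes in
#' no retained clique are unassigned.
#'
#' @param net a `symptom_network`.
#' @param k clique size.
#' @param I nonnegative intensity threshold.
#' @return An object of class `clique_solution` with `k`, `I`, `communities`
#'   (list of sorted id vectors, largest first), `unassigned` (sorted ids)
#'   and `clique_list` (data frame of retained cliques with intensities).
#' @export
percolate <- function(net, k, I) {
  stopifnot(I >= 0)
  cl <- enumerate_cliques(net, k)
  ints <- vapply(cl, function(x) clique_intensity(net, x), 0)
  keep <- ints >= I
  cl <- cl[keep]; ints <- ints[keep]
  communities <- list()
  if (length(cl)) {
    nc <- length(cl)
    # union-find over cliques adjacent by (k-1)-node overlap
    parent <- seq_len(nc)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nc > 1) {
      for (a in seq_len(nc - 1)) {
        for (b in (a + 1):nc) {
          if (length(intersect(cl[[a]], cl[[b]])) == k - 1) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[rb] <- ra
          }
        }
      }
    }
    roots <- vapply(seq_len(nc), find, 0L)
    communities <- lapply(split(seq_len(nc), roots), function(members) {
      sort(unique(unlist(cl[members])))
    })
    ord <- order(-lengths(communities),
                 vapply(communities, paste, "", collapse = "|"))
    communities <- unname(communities[ord])
  }
  assigned <- unique(unlist(communities))
  structure(list(
    k = k, I = I,
    communities = communities,
    unassigned = sort(setdiff(net$items$item_id, assigned)),
    clique_list = data.frame(
      clique = vapply(cl, paste, "", collapse = ","),
      intensity = ints)), class = "clique_solution")
}

#' @export
print.clique_solution <- function(x, ...) {
  cat("<clique_solution> k = ", x$k, ", I = ", x$I, ": ",
      length(x$communities), " communities, ", length(x$unassigned),
      " unassigned\n", sep = "")
  for (i in seq_along(x$communities))
    cat("  [", i, "] ", paste(x$communities[[i]], collapse = " "), "\n",
        sep = "")
  if (length(x$unassigned))
    cat("  unassigned: ", paste(x$unassigned, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Permutation-based (k, I) parameter search for clique percolation
#'
#' Evaluates every (k, I) candidate on a grid: the community count and size
#' distribution on the observed network, and the same statistics on
#' `n_permutations` null networks in which the nonzero weights are shuffled
#' over the fixed edge skeleton (weight organization is tested, not
#' topology). Candidates are ranked by how far the observed community count
#' departs above the permutation null (z-score of the count, then raw count,
#' then larger I). The full diagnostic grid is returned so a solution can
#' also be chosen manually.
#'
#' @param net a `symptom_network`.
#' @param k_range integer vector of clique sizes (default 3:6).
#' @param I_range numeric upper/lower bounds of the intensity grid (default
#'   0.40 down to 0.01).
#' @param step grid step for I.
#' @param n_permutations permutation count per k.
#' @param seed root seed for the permutations.
#' @return A list with `grid` (diagnostics per candidate, ranked), `best`
#'   (top row) and `solution` (the [percolate()] result at the top
#'   candidate).
#' @export
cpm_parameter_search <- function(net, k_range = 3:6, I_range = c(0.40, 0.01),
                                 step = 0.005, n_permutations = 100,
                                 seed = 1L) {
  stopifnot(inherits(net, "symptom_network"), length(k_range) >= 1)
  Is <- seq(max(I_range), min(I_range), by = -abs(step))
  if (!length(Is)) stop("empty I grid", call. = FALSE)
  w <- net$weights
  nz <- which(upper.tri(w) & w != 0)
  rows <- list()
  for (k in k_range) {
    cl <- tryCatch(enumerate_cliques(net, k), error = function(e) list())
    if (!length(cl)) {
      rows[[length(rows) + 1]] <- data.frame(
        k = k, I = Is, n_communities = 0L, mean_size = NA_real_,
        null_mean = 0, null_sd = 0, z = 0)
      next
    }
    pairs <- lapply(cl, function(x) {
      idx <- match(x, net$items$item_id)
      pr <- utils::combn(idx, 2)
      (pr[2, ] - 1) * nrow(w) + pr[1, ]   # linear indices, upper triangle
    })
    nc <- length(cl)
    adj_pairs <- list()
    if (nc > 1) {
      for (a in seq_len(nc - 1)) for (b in (a + 1):nc)
        if (length(intersect(cl[[a]], cl[[b]])) == k - 1)
          adj_pairs[[length(adj_pairs) + 1]] <- c(a, b)
    }
    count_communities <- function(weight_vec_abs) {
      ints <- vapply(pairs, function(pp)
        exp(mean(log(weight_vec_abs[pp]))), 0)
      vapply(Is, function(I) {
        keep <- which(ints >= I)
        if (!length(keep)) return(c(0, NA))
        parent <- seq_along(keep)
        pos <- match(seq_len(nc), keep)
        find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
        for (ab in adj_pairs) {
          a <- pos[ab[1]]; b <- pos[ab[2]]
          if (!is.na(a) && !is.na(b)) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[rb] <- ra
          }
        }
        roots <- vapply(seq_along(keep), find, 0L)
        comms <- split(keep, roots)
        sizes <- vapply(comms, function(m)
          length(unique(unlist(cl[m]))), 0L)
        c(length(comms), mean(sizes))
      }, c(0, 0))
    }
    wa <- abs(w)
    obs <- count_communities(wa)
    perm_counts <- with_seed(child_seed(seed, paste0("cpm-perm-k", k)), {
      vapply(seq_len(n_permutations), function(r) {
        wp <- wa
        wp[nz] <- sample(wa[nz])
        wp[lower.tri(wp)] <- t(wp)[lower.tri(wp)]
        count_communities(wp)[1, ]
      }, numeric(length(Is)))
    })
    nm <- rowMeans(perm_counts)
    nsd <- apply(perm_counts, 1, stats::sd)
    rows[[length(rows) + 1]] <- data.frame(
      k = k, I = Is, n_communities = as.integer(obs[1, ]),
      mean_size = obs[2, ], null_mean = nm, null_sd = nsd,
      z = (obs[1, ] - nm) / (nsd + 1e-12))
  }
  grid <- do.call(rbind, rows)
  grid <- grid[order(-grid$z, -grid$n_communities, -grid$I, grid$k), ]
  rownames(grid) <- NULL
  best <- grid[1, ]
  list(grid = grid, best = best,
       solution = percolate(net, best$k, best$I))
}

#' Serialize a clique solution to JSON
#'
#' @param sol a `clique_solution`.
#' @param path output path.
#' @export
write_clique_solution <- function(sol, path) {
  jsonlite::write_json(list(
    k = sol$k, I = sol$I,
    communities = sol$communities,
    unassigned = sol$unassigned,
    cliques = sol$clique_list), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
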
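# Centralities on the unweighted skeleton of the heterogeneous network.
# Distances are hop counts ("shortest topological distance"); edge weights
# play no role here (they serve edge existence and the intersection ratio).

bfs_distances_sigma <- function(adj, source, keys) {
  # single-source BFS returning hop distances and shortest-path counts,
  # plus predecessor lists (for Brandes' accumulation)
  n <- length(keys)
  dist <- setNames(rep(Inf, n), keys)
  sigma <- setNames(rep(0, n), keys)
  preds <- setNames(vector("list", n), keys)
  order_visited <- character(0)
  dist[source] <- 0
  sigma[source] <- 1
  queue <- source
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order_visited <- c(order_visited, v)
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_visited)
}

#' Degree centrality
#'
#' Number of distinct neighbors (any category) divided by `|V| - 1`;
#' weights are ignored.
#' @param net a `hetero_network` (or any object with `nodes$key`/`edges`).
#' @param v node key, or `NULL` for all nodes.
#' @return named numeric vector (or scalar when `v` given).
#' @export
degree_centrality <- function(net, v = NULL) {
  keys <- net$nodes$key
  n <- length(keys)
  if (n < 2) stop("degree centrality needs at least 2 nodes", call. = FALSE)
  deg <- setNames(rep(0L, n), keys)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  out <- deg / (n - 1)
  if (is.null(v)) out else pick_node(out, v)
}

#' Closeness centrality (Wasserman-Faust corrected)
#'
#' On a connected network this is `(|V|-1) / sum of hop distances`. On
#' disconnected networks the Wasserman-Faust correction is applied:
#' `(reachable/(|V|-1)) * (reachable / sum of distances to reachable nodes)`,
#' which reduces to the plain formula when everything is reachable. Isolated
#' nodes score 0.
#' @inheritParams degree_centrality
#' @return named numeric vector (or scalar when `v` given).
#' @export
closeness_centrality <- function(net, v = NULL) {
  keys <- net$nodes$key
  n <- length(keys)
  if (n < 2) stop("closeness centrality needs at least 2 nodes", call. = FALSE)
  adj <- adjacency_list(net)
  cc <- setNames(numeric(n), keys)
  for (s in keys) {
    d <- bfs_distances_sigma(adj, s, keys)$dist
    reach <- d[names(d) != s & is.finite(d)]
    if (!length(reach)) {
      cc[s] <- 0
    } else {
      r <- length(reach)
      cc[s] <- (r / (n - 1)) * (r / sum(reach))
    }
  }
  if (is.null(v)) cc else pick_node(cc, v)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths over unordered node pairs (excluding the node
#' itself) that pass through the node, normalized by
#' `(|V|-1)(|V|-2)/2`. Computed with Brandes' accumulation over BFS trees.
#' @inheritParams degree_centrality
#' @return named numeric vector (or scalar when `v` given).
#' @export
betweenness_centrality <- function(net, v = NULL) {
  keys <- net$nodes$key
  n <- length(keys)
  if (n < 3) stop("betweenness centrality needs at least 3 nodes", call. = FALSE)
  adj <- adjacency_list(net)
  bc <- setNames(numeric(n), keys)
  for (s in keys) {
    b <- bfs_distances_sigma(adj, s, keys)
    delta <- setNames(numeric(n), keys)
    for (w in rev(b$order)) {
      for (p in b$preds[[w]]) {
        delta[p] <- delta[p] + (b$sigma[p] / b$sigma[w]) * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair accumulated from both endpoints
  bc <- bc / ((n - 1) * (n - 2) / 2)
  if (is.null(v)) bc else pick_node(bc, v)
}

pick_node <- function(values, v) {
  if (!v %in% names(values)) stop("unknown node: ", v, call. = FALSE)
  unname(values[v])
}
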
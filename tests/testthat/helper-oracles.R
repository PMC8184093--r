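# Independent oracles and fixture builders shared across the suite.

# --- graph fixtures ---------------------------------------------------------

# wrap a symmetric 0/1 adjacency matrix as the network structure the
# centrality functions consume
net_from_adjacency <- function(A, categories = NULL) {
  n <- nrow(A)
  keys <- sprintf("gene:n%02d", seq_len(n))
  if (!is.null(categories)) keys <- paste(categories, sprintf("n%02d", seq_len(n)), sep = ":")
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(from = keys[idx[, 1]], to = keys[idx[, 2]],
                      weight = A[idx], stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(key = keys, entity_id = keys,
                       name = keys,
                       category = sub(":.*$", "", keys),
                       freq = 1L, stringsAsFactors = FALSE),
    edges = edges
  ), class = "hetero_network")
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# --- centrality oracles (independent of the package's BFS/Brandes code) ----

oracle_distances <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::distances(g)
}

# shortest-path counts via matrix powers: every walk of minimal length is a
# shortest path, so sigma(s,t) = (A^d(s,t))[s,t]
oracle_sigma <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  maxd <- max(D[is.finite(D)])
  pows <- vector("list", max(maxd, 1))
  pows[[1]] <- A
  if (maxd >= 2) for (k in 2:maxd) pows[[k]] <- pows[[k - 1]] %*% A
  sigma <- matrix(0, n, n)
  for (s in 1:n) for (t in 1:n) {
    d <- D[s, t]
    if (s == t) sigma[s, t] <- 1
    else if (is.finite(d)) sigma[s, t] <- pows[[d]][s, t]
  }
  list(D = D, sigma = sigma)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  os <- oracle_sigma(A)
  D <- os$D; sigma <- os$sigma
  bc <- numeric(n)
  for (v in 1:n) {
    total <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        total <- total + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    bc[v] <- total
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  vapply(1:n, function(v) {
    d <- D[v, -v]
    reach <- d[is.finite(d)]
    if (!length(reach)) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, 0)
}

oracle_degree <- function(A) rowSums(A > 0) / (nrow(A) - 1)

# --- modularity brute force -------------------------------------------------

# best 2-partition by exhaustive enumeration (n <= ~12)
brute_force_best_bipartition <- function(net) {
  nodes <- net$nodes$name
  n <- length(nodes)
  best_q <- -Inf
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {  # fix node 1 in group 0 to halve the space
    side <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    labels <- stats::setNames(side, nodes)
    q <- network_modularity(net, labels)
    if (q > best_q) {
      best_q <- q
      best <- labels
    }
  }
  list(labels = best, modularity = best_q)
}

# --- misc -------------------------------------------------------------------

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# two 4-cliques joined by a single weak edge, expressed as document sets
two_clique_docs <- function() {
  a <- paste0("a", 1:4)
  b <- paste0("b", 1:4)
  c(replicate(3, a, simplify = FALSE),
    replicate(3, b, simplify = FALSE),
    list(c("a1", "b1")))
}

medline_fixture_lines <- function() {
  c("PMID- 101",
    "TI  - Spike protein binding and host cell entry",
    "AB  - The spike protein mediates entry. Spike protein binding assays",
    "      were performed across host cells.",
    "JT  - Journal of Virology",
    "DP  - 2020 Jun",
    "AD  - Dept of X, University of Oxford, Oxford, UK",
    "MH  - COVID-19",
    "",
    "PMID- 102",
    "TI  - Immune response genes in infection",
    "AB  - Genes, genes, GENE expression and the spike protein.",
    "JT  - Nature",
    "DP  - 2020 Jul 15",
    "AD  - 23Strands, Pyrmont, NSW, Australia",
    "",
    "TI  - block without a pmid",
    "AB  - should be skipped",
    "",
    "PMID- 103",
    "TI  - Yearly dated record",
    "AB  - spike protein once more",
    "JT  - Journal of Virology",
    "DP  - 2021",
    "")
}
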
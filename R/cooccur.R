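#' Build an entity co-occurrence network from per-document entity sets
#'
#' Node frequency `F(i)` is the number of documents containing entity `i`;
#' edge co-frequency `CF(i,j)` is the number of documents containing both.
#' An edge exists iff the two entities co-occur in at least one document.
#'
#' @param doc_entity_sets list of character vectors, one per document
#'   (duplicates within a document are collapsed).
#' @return A `cooc_network`: list with `nodes` (data.frame name, freq),
#'   `edges` (data.frame from, to, cf, weight), `normalized` flag and
#'   optional `community` labels.
#' @export
build_network <- function(doc_entity_sets) {
  sets <- lapply(doc_entity_sets, function(s) sort(unique(as.character(s))))
  freq_tab <- table(unlist(sets, use.names = FALSE))
  if (!length(freq_tab)) {
    return(structure(
      list(nodes = data.frame(name = character(), freq = integer()),
           edges = data.frame(from = character(), to = character(),
                              cf = integer(), weight = numeric()),
           normalized = FALSE, community = NULL),
      class = "cooc_network"))
  }
  nodes <- data.frame(name = names(freq_tab), freq = as.integer(freq_tab),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  pair_keys <- unlist(lapply(sets, function(s) {
    if (length(s) < 2) return(character(0))
    p <- combn(s, 2)
    paste(p[1, ], p[2, ], sep = "\t")
  }), use.names = FALSE)
  if (length(pair_keys)) {
    cf_tab <- table(pair_keys)
    parts <- strsplit(names(cf_tab), "\t", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      cf = as.integer(cf_tab),
      weight = NA_real_,
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        cf = integer(), weight = numeric())
  }
  structure(list(nodes = nodes, edges = edges, normalized = FALSE,
                 community = NULL),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("<cooc_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (x$normalized) ", Jaccard-normalized", "\n", sep = "")
  invisible(x)
}

#' Normalize co-occurrence weights by the Jaccard coefficient
#'
#' Each edge weight becomes `CF(i,j) / (F(i) + F(j) - CF(i,j))`, the overlap
#' of the two entities' document sets; raw co-frequencies are retained in
#' the `cf` column.
#'
#' @param net a `cooc_network` built by [build_network()].
#' @return The network with `weight` filled and `normalized = TRUE`.
#' @export
jaccard_normalize <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (!nrow(net$edges)) {
    net$normalized <- TRUE
    return(net)
  }
  f <- setNames(net$nodes$freq, net$nodes$name)
  denom <- f[net$edges$from] + f[net$edges$to] - net$edges$cf
  stopifnot("corrupted network: nonpositive Jaccard denominator" = all(denom > 0))
  net$edges$weight <- unname(net$edges$cf / denom)
  net$normalized <- TRUE
  net
}

#' Node strength: sum of normalized weights over incident edges
#'
#' @param net a Jaccard-normalized `cooc_network`.
#' @param node entity name; must exist in the network.
#' @return numeric strength (0 for an isolated node).
#' @export
node_strength <- function(net, node) {
  stopifnot(inherits(net, "cooc_network"), net$normalized)
  if (!node %in% net$nodes$name) stop("unknown node: ", node, call. = FALSE)
  inc <- net$edges$from == node | net$edges$to == node
  sum(net$edges$weight[inc])
}

as_igraph <- function(net) {
  if (!nrow(net$nodes)) return(igraph::make_empty_graph(directed = FALSE))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes
  )
  igraph::E(g)$cf <- net$edges$cf
  igraph::E(g)$weight <- if (net$normalized) net$edges$weight else as.numeric(net$edges$cf)
  if (!is.null(net$community)) {
    g <- igraph::set_vertex_attr(g, "community",
                                 value = unname(net$community[igraph::V(g)$name]))
  }
  g
}

#' Detect communities by greedy modularity optimization
#'
#' Louvain-style local moving on the edge weights (Jaccard weights when the
#' network is normalized, raw co-frequencies otherwise), seeded for
#' determinism. Labels are contiguous integers from 0. Communities smaller
#' than `min_size` are merged into the neighboring community with the
#' largest connecting weight.
#'
#' @param net a nonempty `cooc_network`.
#' @param resolution resolution parameter (default 1.0).
#' @param seed integer RNG seed.
#' @param min_size minimum community size (default 1 = no merging).
#' @return named integer vector, node name -> community label.
#' @export
detect_communities <- function(net, resolution = 1.0, seed = 1L, min_size = 1L) {
  stopifnot(inherits(net, "cooc_network"), nrow(net$nodes) > 0)
  g <- as_igraph(net)
  memb <- with_local_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(cl)
  })
  labels <- setNames(as.integer(memb), igraph::V(g)$name)
  if (min_size > 1) labels <- merge_small_communities(net, labels, min_size)
  # relabel to contiguous ints from 0, in order of first appearance
  labels <- setNames(match(labels, unique(labels)) - 1L, names(labels))
  labels
}

merge_small_communities <- function(net, labels, min_size) {
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1) break
    lab <- small[which.min(sizes[small])]
    members <- names(labels)[labels == lab]
    w <- if (net$normalized) net$edges$weight else as.numeric(net$edges$cf)
    link <- numeric(0)
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$from[k]; b <- net$edges$to[k]
      la <- labels[[a]]; lb <- labels[[b]]
      if (la == lab && lb != lab) link[as.character(lb)] <- (link[as.character(lb)] %|0|% 0) + w[k]
      if (lb == lab && la != lab) link[as.character(la)] <- (link[as.character(la)] %|0|% 0) + w[k]
    }
    target <- if (length(link)) as.integer(names(link)[which.max(link)]) else {
      others <- unique(labels[labels != lab])
      others[1]
    }
    labels[members] <- target
  }
  labels
}

`%|0|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Modularity of a labeling of a co-occurrence network
#'
#' Convenience wrapper used by tests and reports; weights follow the same
#' convention as [detect_communities()].
#' @param net a `cooc_network`.
#' @param labels named membership vector (any integer coding).
#' @return numeric modularity.
#' @export
network_modularity <- function(net, labels) {
  g <- as_igraph(net)
  memb <- labels[igraph::V(g)$name]
  igraph::modularity(g, match(memb, unique(memb)),
                     weights = igraph::E(g)$weight)
}

#' Export a co-occurrence network to disk
#'
#' Lossless for node names, frequencies, community labels, raw
#' co-frequencies and normalized weights.
#'
#' @param net a `cooc_network`.
#' @param path output path. For `"pajek"` a companion `.clu` file with
#'   community labels is written next to the `.net` file when communities
#'   are present.
#' @param format one of `"graphml"`, `"pajek"`, `"edge-csv"`.
#' @param community optional named labels to attach before export.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "pajek", "edge-csv"),
                         community = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  format <- match.arg(format)
  if (!is.null(community)) net$community <- community
  if (format == "edge-csv") {
    write.csv(net$edges, path, row.names = FALSE)
    return(invisible(path))
  }
  g <- as_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    igraph::write_graph(g, path, format = "pajek")
    if (!is.null(net$community)) {
      clu <- sub("\\.net$", "", path)
      clu <- paste0(clu, ".clu")
      writeLines(c(paste("*Vertices", nrow(net$nodes)),
                   as.character(unname(net$community[net$nodes$name]))), clu)
    }
  }
  invisible(path)
}

#' Read back a GraphML export as a `cooc_network`
#'
#' Inverse of [export_graph()] for the GraphML format; used for round-trip
#' verification.
#' @param path GraphML file written by [export_graph()].
#' @return a `cooc_network`.
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(g)$name,
                      freq = as.integer(igraph::V(g)$freq),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    from = pmin(el[, 1], el[, 2]),
    to = pmax(el[, 1], el[, 2]),
    cf = as.integer(igraph::E(g)$cf),
    weight = as.numeric(igraph::E(g)$weight),
    stringsAsFactors = FALSE
  )
  ord <- order(edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  community <- NULL
  if ("community" %in% igraph::vertex_attr_names(g)) {
    community <- setNames(as.integer(igraph::V(g)$community), igraph::V(g)$name)
  }
  normalized <- !all(is.na(edges$weight)) &&
    !isTRUE(all.equal(edges$weight, as.numeric(edges$cf)))
  structure(list(nodes = nodes, edges = edges,
                 normalized = normalized || nrow(edges) == 0,
                 community = community),
            class = "cooc_network")
}
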
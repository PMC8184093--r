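entity_key <- function(category, entity_id) paste(category, entity_id, sep = ":")

#' Build the heterogeneous disease-chemical-gene-variant network
#'
#' Nodes are resolved bio-entities of the four categories; edge weight is
#' the number of documents in which the two entities co-occur. Entities that
#' never co-occur with anything remain as isolated nodes; intra- and
#' inter-category edges are both kept.
#'
#' @param doc_entities named list pmid -> data.frame(entity_id, name,
#'   category), as from [resolve_mentions()].
#' @return A `hetero_network`: list with `nodes` (data.frame key, entity_id,
#'   name, category, freq) and `edges` (data.frame from, to, weight; keys).
#' @export
build_hetero_network <- function(doc_entities) {
  all_nodes <- unique(do.call(rbind, lapply(doc_entities, function(d) {
    data.frame(key = entity_key(d$category, d$entity_id),
               entity_id = d$entity_id, name = d$name, category = d$category,
               stringsAsFactors = FALSE)
  })))
  keys_per_doc <- lapply(doc_entities, function(d)
    sort(unique(entity_key(d$category, d$entity_id))))
  freq_tab <- table(unlist(keys_per_doc, use.names = FALSE))
  all_nodes$freq <- as.integer(freq_tab[all_nodes$key])
  all_nodes <- all_nodes[order(all_nodes$key), , drop = FALSE]
  rownames(all_nodes) <- NULL
  pair_keys <- unlist(lapply(keys_per_doc, function(s) {
    if (length(s) < 2) return(character(0))
    p <- combn(s, 2)
    paste(p[1, ], p[2, ], sep = "\n")
  }), use.names = FALSE)
  if (length(pair_keys)) {
    tab <- table(pair_keys)
    parts <- strsplit(names(tab), "\n", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      weight = as.integer(tab),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(), weight = integer())
  }
  structure(list(nodes = all_nodes, edges = edges), class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("<hetero_network> ", nrow(x$nodes), " nodes (",
      paste(names(table(x$nodes$category)), table(x$nodes$category),
            sep = "=", collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Category-pair edge tallies
#'
#' 4x4 symmetric table counting edges once per unordered node pair; the sum
#' over the upper triangle plus the diagonal equals the total edge count.
#'
#' @param net a `hetero_network`.
#' @return 4x4 integer matrix (disease, chemical, gene, variant).
#' @export
edge_tallies <- function(net) {
  cats <- c("disease", "chemical", "gene", "variant")
  catmap <- setNames(net$nodes$category, net$nodes$key)
  m <- matrix(0L, 4, 4, dimnames = list(cats, cats))
  if (nrow(net$edges)) {
    a <- catmap[net$edges$from]
    b <- catmap[net$edges$to]
    for (k in seq_along(a)) {
      i <- a[k]; j <- b[k]
      m[i, j] <- m[i, j] + 1L
      if (i != j) m[j, i] <- m[j, i] + 1L
    }
  }
  m
}

adjacency_list <- function(net) {
  keys <- net$nodes$key
  adj <- setNames(vector("list", length(keys)), keys)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$from[k]; b <- net$edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Export the heterogeneous network as GraphML
#'
#' Node attributes: entity_id, name, category, freq; edge attribute: weight.
#' @param net a `hetero_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_hetero_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = net$nodes$key,
                                       entity_id = net$nodes$entity_id,
                                       display = net$nodes$name,
                                       category = net$nodes$category,
                                       freq = net$nodes$freq))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
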
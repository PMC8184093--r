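#' Prepare a time-sliced document-term stream
#'
#' Builds the document-term matrix over the vocabulary, term-frequency
#' weighted and L2-normalized per document, and assigns each document to a
#' time slice from its publication date. Slices are indexed 0..S-1 over the
#' contiguous calendar range observed (empty slices are allowed).
#'
#' @param x a `corpus`.
#' @param terms result of [extract_terms()] on the same corpus.
#' @param granularity `"month"` or `"year"`.
#' @param cutoff optional `c(year, month)` (or just a year for yearly
#'   granularity); later documents are excluded before streaming.
#' @return A `sep_stream`: list with unit-row matrix `x`, raw count matrix
#'   `counts`, integer `slice`, `pmid`, `slice_labels`, `vocab`, and counts
#'   of documents `dropped` (no vocabulary terms) and `undated`/`cut`.
#' @export
prepare_stream <- function(x, terms, granularity = c("month", "year"),
                           cutoff = NULL) {
  stopifnot(inherits(x, "corpus"))
  granularity <- match.arg(granularity)
  tab <- records_table(x)
  vocab <- terms$vocabulary$terms
  if (!length(vocab)) stop("empty vocabulary", call. = FALSE)

  dated <- if (granularity == "month") {
    !is.na(tab$pub_year) & !is.na(tab$pub_month)
  } else !is.na(tab$pub_year)
  cut <- rep(FALSE, nrow(tab))
  if (!is.null(cutoff)) {
    if (granularity == "month") {
      stopifnot(length(cutoff) == 2)
      cut <- dated & (tab$pub_year * 12 + tab$pub_month) > (cutoff[1] * 12 + cutoff[2])
    } else {
      cut <- dated & tab$pub_year > cutoff[1]
    }
  }
  usable <- dated & !cut
  if (!any(usable)) stop("no records with usable dates", call. = FALSE)

  key <- if (granularity == "month") {
    tab$pub_year * 12L + tab$pub_month
  } else tab$pub_year
  counts <- matrix(0, nrow = sum(usable), ncol = length(vocab),
                   dimnames = list(tab$pmid[usable], vocab))
  for (pm in rownames(counts)) {
    cnt <- terms$doc_terms[[pm]]
    cnt <- cnt[names(cnt) %in% vocab]
    if (length(cnt)) counts[pm, names(cnt)] <- cnt
  }
  nonempty <- rowSums(counts) > 0
  dropped <- sum(!nonempty)
  if (dropped) {
    message(dropped, " document(s) with no vocabulary terms dropped from stream")
  }
  counts <- counts[nonempty, , drop = FALSE]
  if (!nrow(counts)) stop("no documents left after dropping empty term sets",
                          call. = FALSE)
  key <- key[usable][nonempty]
  base <- min(key)
  slice <- as.integer(key - base)
  slice_labels <- if (granularity == "month") {
    k <- base:max(key)
    sprintf("%d-%02d", (k - 1L) %/% 12L, (k - 1L) %% 12L + 1L)
  } else as.character(base:max(key))
  structure(
    list(x = l2_normalize_rows(counts), counts = counts, slice = slice,
         pmid = rownames(counts), slice_labels = slice_labels,
         vocab = vocab, granularity = granularity,
         dropped = dropped, excluded = sum(!usable)),
    class = "sep_stream"
  )
}

#' @export
print.sep_stream <- function(x, ...) {
  cat("<sep_stream> ", nrow(x$x), " documents, ", length(x$slice_labels),
      " ", x$granularity, " slices, ", length(x$vocab), " terms\n", sep = "")
  invisible(x)
}

topic_label <- function(stream, member_idx) {
  totals <- colSums(stream$counts[member_idx, , drop = FALSE])
  mx <- max(totals)
  # ties on the top-frequency term broken lexicographically
  sort(names(totals)[totals == mx])[1]
}

make_topic <- function(stream, member_idx, id, birth_slice) {
  centroid <- colMeans(stream$x[member_idx, , drop = FALSE])
  radius <- max(euclidean_to(stream$x[member_idx, , drop = FALSE], centroid))
  list(id = id, label = topic_label(stream, member_idx),
       birth_slice = birth_slice, centroid = centroid,
       radius = radius, members = member_idx)
}

#' Initialize the first topic from slice 0
#'
#' All slice-0 documents form one topic; the centroid is their mean vector,
#' the radius the largest centroid-to-document Euclidean distance, and the
#' label the top-frequency term among members.
#'
#' @param stream a `sep_stream`.
#' @return a topic (list with id, label, birth_slice, centroid, radius,
#'   members).
#' @export
init_topic <- function(stream) {
  idx <- which(stream$slice == 0L)
  if (!length(idx)) {
    stop("slice 0 is empty; re-slice the stream to start at a populated slice",
         call. = FALSE)
  }
  make_topic(stream, idx, id = 1L, birth_slice = 0L)
}

#' Drift test for one document against a topic
#'
#' A document at Euclidean distance `E` from the topic centroid drifts when
#' `(E - r) / r > sigma`, `r` being the topic radius. A zero-radius topic
#' (singleton or identical members) treats any departure beyond `eps` as
#' drift.
#'
#' @param doc numeric document vector (same term space as the topic).
#' @param topic a topic as returned by [init_topic()] etc.
#' @param sigma drift threshold, > 0 (default 0.1).
#' @param eps zero-radius tolerance (default 1e-9).
#' @return `"assigned"` or `"drifted"`.
#' @export
drift_test <- function(doc, topic, sigma = 0.1, eps = 1e-9) {
  stopifnot(sigma > 0)
  e <- sqrt(sum((doc - topic$centroid)^2))
  drifted <- if (topic$radius <= eps) e > eps else (e - topic$radius) / topic$radius > sigma
  if (drifted) "drifted" else "assigned"
}

#' Update a topic with newly assigned members
#'
#' Recomputes centroid (mean of the full membership), radius (max distance)
#' and label (top-frequency term over the full membership).
#'
#' @param topic a topic.
#' @param new_member_idx row indices of the newly assigned documents.
#' @param stream the `sep_stream` the indices refer to.
#' @return the updated topic.
#' @export
update_topic <- function(topic, new_member_idx, stream) {
  members <- c(topic$members, new_member_idx)
  out <- make_topic(stream, members, id = topic$id,
                    birth_slice = topic$birth_slice)
  out
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[i + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ulab <- unique(labels)
  if (length(ulab) < 2) return(-1)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(ulab[ulab != labels[i]],
                    function(l) mean(d[i, labels == l]), 0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

seeded_kmeans <- function(x, k, restarts = 10) {
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers + 0  # plain matrix
    km <- suppressWarnings(
      tryCatch(kmeans(x, centers = centers, iter.max = 50),
               error = function(e) NULL)
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) best <- list(cluster = rep(1L, nrow(x)))
  best
}

#' Cluster drifted documents into descendant topics
#'
#' K-means over the drifted document vectors; K is chosen by the best mean
#' silhouette over K = 2..min(k_max, n-1), falling back to a single topic
#' when fewer than 3 documents drifted or no K reaches the
#' `min_silhouette` structure criterion (k-means will split even a
#' homogeneous cloud of term vectors with a weakly positive silhouette, so
#' a strictly positive bar is required to avoid over-fragmentation). Each
#' new topic receives a lineage edge from every parent topic whose rejected
#' documents feed it.
#'
#' @param stream a `sep_stream`.
#' @param drifted_idx row indices of drifted documents.
#' @param parent_ids topic id each drifted document was tested against.
#' @param slice_index birth slice for the new topics.
#' @param next_id first free topic id.
#' @param k_max largest K considered (default 10).
#' @param seed RNG seed for k-means++ restarts.
#' @param min_silhouette smallest mean silhouette accepted as evidence of
#'   cluster structure (default 0.1).
#' @return list(`topics`, `edges` data.frame from,to).
#' @export
spawn_topics <- function(stream, drifted_idx, parent_ids, slice_index,
                         next_id, k_max = 10, seed = 1L,
                         min_silhouette = 0.1) {
  stopifnot(length(drifted_idx) >= 1, length(parent_ids) == length(drifted_idx))
  n <- length(drifted_idx)
  xd <- stream$x[drifted_idx, , drop = FALSE]
  labels <- rep(1L, n)
  if (n >= 3) {
    d <- dist(xd)
    ks <- 2:min(k_max, n - 1)
    best_k <- 1L
    best_sil <- min_silhouette
    with_local_seed(seed, {
      for (k in ks) {
        km <- seeded_kmeans(xd, k)
        sil <- mean_silhouette(d, km$cluster)
        if (sil > best_sil + 1e-12) {
          best_sil <- sil
          best_k <- k
          labels <- as.integer(km$cluster)
        }
      }
    })
    if (best_k == 1L) labels <- rep(1L, n)
  }
  topics <- list()
  edges <- data.frame(from = integer(), to = integer())
  for (l in sort(unique(labels))) {
    sel <- labels == l
    tid <- next_id
    next_id <- next_id + 1L
    topics[[length(topics) + 1L]] <-
      make_topic(stream, drifted_idx[sel], id = tid, birth_slice = slice_index)
    for (p in sort(unique(parent_ids[sel]))) {
      edges <- rbind(edges, data.frame(from = p, to = tid))
    }
  }
  list(topics = topics, edges = edges)
}

#' Run the full topic-evolution stream
#'
#' Slice 0 forms the initial topic. Documents of each later slice are
#' classified in a batch against the slice-start topic state: the candidate
#' topic is the cosine-nearest centroid (for slice 1 only the initial topic
#' exists), and the document drifts when its Euclidean distance to that
#' centroid exceeds the topic radius by more than `sigma` relatively
#' (see [drift_test()]). Assigned documents update their topics at slice
#' end; drifted documents are clustered into descendant topics with lineage
#' edges from their candidate parents.
#'
#' @param stream a `sep_stream` with at least 2 populated slices.
#' @param sigma drift threshold (default 0.1).
#' @param k_max largest descendant count considered per slice (default 10).
#' @param seed RNG seed.
#' @param eps zero-radius tolerance passed to the drift rule.
#' @param min_silhouette structure criterion passed to [spawn_topics()].
#' @return A `sep_graph`: list with `topics`, `edges` (data.frame from, to),
#'   `assignment` (named topic id per pmid), `sigma`, `stream` metadata.
#' @export
run_sep <- function(stream, sigma = 0.1, k_max = 10, seed = 1L, eps = 1e-9,
                    min_silhouette = 0.1) {
  stopifnot(inherits(stream, "sep_stream"), sigma > 0)
  slices <- sort(unique(stream$slice))
  if (length(slices) < 2) stop("stream needs at least 2 populated slices", call. = FALSE)
  topics <- list(init_topic(stream))
  edges <- data.frame(from = integer(), to = integer())
  for (s in slices[-1]) {
    idx <- which(stream$slice == s)
    if (!length(idx)) next
    centroids <- do.call(rbind, lapply(topics, `[[`, "centroid"))
    cnorm <- sqrt(rowSums(centroids^2))
    cnorm[cnorm == 0] <- 1
    # cosine similarity doc x topic (docs are unit rows)
    sim <- stream$x[idx, , drop = FALSE] %*% t(centroids / cnorm)
    candidate <- apply(sim, 1, which.max)  # ties -> earliest topic
    status <- character(length(idx))
    for (k in seq_along(idx)) {
      status[k] <- drift_test(stream$x[idx[k], ], topics[[candidate[k]]],
                              sigma = sigma, eps = eps)
    }
    assigned <- status == "assigned"
    for (t in unique(candidate[assigned])) {
      sel <- assigned & candidate == t
      topics[[t]] <- update_topic(topics[[t]], idx[sel], stream)
    }
    if (any(!assigned)) {
      parent_ids <- vapply(topics, `[[`, 0L, "id")[candidate[!assigned]]
      sp <- spawn_topics(stream, idx[!assigned], parent_ids,
                         slice_index = s,
                         next_id = length(topics) + 1L,
                         k_max = k_max, seed = seed + s,
                         min_silhouette = min_silhouette)
      topics <- c(topics, sp$topics)
      edges <- rbind(edges, sp$edges)
    }
  }
  assignment <- integer(nrow(stream$x))
  for (t in topics) assignment[t$members] <- t$id
  names(assignment) <- stream$pmid
  structure(
    list(topics = topics, edges = edges, assignment = assignment,
         sigma = sigma, n_docs = nrow(stream$x),
         slice_labels = stream$slice_labels),
    class = "sep_graph"
  )
}

#' @export
print.sep_graph <- function(x, ...) {
  cat("<sep_graph> ", length(x$topics), " topics, ", nrow(x$edges),
      " lineage edges over ", x$n_docs, " documents\n", sep = "")
  invisible(x)
}

#' Summary statistics of a topic lineage graph
#'
#' @param graph a `sep_graph`.
#' @param list_n how many largest/smallest topics to list (default 4).
#' @return list with `n_topics`, `max_members`, `min_members`, `sd_members`
#'   (population standard deviation), and `topics`: a data.frame
#'   (id, label, birth_slice, birth_label, members, display) sorted by size
#'   descending; `largest`/`smallest` hold the formatted extremes.
#' @export
sep_statistics <- function(graph, list_n = 4) {
  stopifnot(inherits(graph, "sep_graph"), length(graph$topics) > 0)
  sizes <- vapply(graph$topics, function(t) length(t$members), 0L)
  df <- data.frame(
    id = vapply(graph$topics, `[[`, 0L, "id"),
    label = vapply(graph$topics, `[[`, "", "label"),
    birth_slice = vapply(graph$topics, `[[`, 0L, "birth_slice"),
    members = sizes,
    stringsAsFactors = FALSE
  )
  df$birth_label <- graph$slice_labels[df$birth_slice + 1L]
  df$display <- sprintf("%s [%s] — %d", df$label, df$birth_label, df$members)
  df <- df[order(-df$members, df$label), , drop = FALSE]
  rownames(df) <- NULL
  list(
    n_topics = nrow(df),
    max_members = max(sizes),
    min_members = min(sizes),
    sd_members = population_sd(sizes),
    topics = df,
    largest = head(df$display, list_n),
    smallest = head(df$display[order(df$members, df$label)], list_n)
  )
}

#' Export a topic lineage graph
#'
#' GraphML with node attributes (label, birth_slice, member_count) plus a
#' CSV membership table (pmid, topic id).
#' @param graph a `sep_graph`.
#' @param graphml_path,membership_csv_path output paths (either may be NULL
#'   to skip).
#' @return invisibly, the paths written.
#' @export
export_sep <- function(graph, graphml_path = NULL, membership_csv_path = NULL) {
  stopifnot(inherits(graph, "sep_graph"))
  written <- character(0)
  if (!is.null(graphml_path)) {
    ids <- vapply(graph$topics, `[[`, 0L, "id")
    vertices <- data.frame(
      name = as.character(ids),
      label = vapply(graph$topics, `[[`, "", "label"),
      birth_slice = vapply(graph$topics, `[[`, 0L, "birth_slice"),
      member_count = vapply(graph$topics, function(t) length(t$members), 0L)
    )
    edges <- graph$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$from), to = as.character(edges$to)),
      directed = TRUE, vertices = vertices
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(membership_csv_path)) {
    write.csv(
      data.frame(pmid = names(graph$assignment), topic = unname(graph$assignment)),
      membership_csv_path, row.names = FALSE
    )
    written <- c(written, membership_csv_path)
  }
  invisible(written)
}

#' Undirected projection of a topic lineage graph
#'
#' Feeds community detection over topic lineages: nodes are topics, edges
#' the lineage links with unit co-frequency.
#' @param graph a `sep_graph`.
#' @return a `cooc_network` over topic ids (as character).
#' @export
sep_projection <- function(graph) {
  ids <- as.character(vapply(graph$topics, `[[`, 0L, "id"))
  sizes <- vapply(graph$topics, function(t) length(t$members), 0L)
  nodes <- data.frame(name = ids, freq = sizes, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(graph$edges)) {
    edges <- data.frame(
      from = pmin(as.character(graph$edges$from), as.character(graph$edges$to)),
      to = pmax(as.character(graph$edges$from), as.character(graph$edges$to)),
      cf = 1L, weight = 1.0, stringsAsFactors = FALSE
    )
    edges <- unique(edges)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        cf = integer(), weight = numeric())
  }
  structure(list(nodes = nodes, edges = edges, normalized = TRUE,
                 community = NULL),
            class = "cooc_network")
}
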
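#' Entropy-based weights for combining centralities
#'
#' Given the three min-max-normalized centrality value sets, computes an
#' entropy per set and turns low-entropy (more discriminating) sets into
#' higher weights: `w = (1 - H) / (m - sum(H))` over the `m` usable sets.
#'
#' In the default `"standard"` mode each normalized set is first converted
#' to proportions `p_i = n_i / sum(n)` before the entropy
#' `H = -(1/ln|V|) sum p ln p` (with `0 ln 0 := 0`), which keeps `H` in
#' `[0,1]` and the weights nonnegative. The `"literal"` mode evaluates the
#' entropy on the normalized values directly, as the formula is printed in
#' the method it follows; it can yield `H > 1` and negative weights.
#'
#' A centrality constant across all nodes has an undefined min-max
#' normalization: it receives weight 0 and the remaining weights
#' renormalize (with a message).
#'
#' @param ndc,ncc,nbc min-max-normalized centrality vectors (may contain
#'   `NA` for a degenerate, constant set).
#' @param mode `"standard"` (proportions before entropy) or `"literal"`.
#' @return named numeric vector `c(dc=, cc=, bc=)` summing to 1.
#' @export
entropy_weights <- function(ndc, ncc, nbc, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  sets <- list(dc = ndc, cc = ncc, bc = nbc)
  nn <- length(ndc)
  stopifnot(length(ncc) == nn, length(nbc) == nn, nn >= 2)
  usable <- vapply(sets, function(s) !anyNA(s) && sum(s) > 0, TRUE)
  if (!any(usable)) stop("all centrality sets are degenerate", call. = FALSE)
  if (!all(usable)) {
    message("constant centrality set(s) [", paste(names(sets)[!usable], collapse = ", "),
            "] received weight 0; remaining weights renormalized")
  }
  H <- vapply(sets[usable], function(s) {
    vals <- if (mode == "standard") s / sum(s) else s
    vals <- vals[vals > 0]
    -sum(vals * log(vals)) / log(nn)
  }, 0)
  w <- setNames(rep(0, 3), names(sets))
  w[names(H)] <- (1 - H) / (sum(usable) - sum(H))
  w
}

#' Combine normalized centralities into a single score
#'
#' `combined(v) = w_dc * nDC(v) + w_cc * nCC(v) + w_bc * nBC(v)`; with
#' weights summing to 1 and inputs in `[0,1]` the result is in `[0,1]`.
#' Degenerate (NA) normalized sets contribute 0 (their weight is 0).
#'
#' @inheritParams entropy_weights
#' @param weights named vector from [entropy_weights()].
#' @return numeric vector of combined scores.
#' @export
combine_centralities <- function(ndc, ncc, nbc, weights) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  weights[["dc"]] * zero_na(ndc) + weights[["cc"]] * zero_na(ncc) +
    weights[["bc"]] * zero_na(nbc)
}

#' Intersection ratio: disease specificity of a node
#'
#' Fraction of the node's disease edge weight that points at the target
#' disease: `IR(v) = w(v, target) / sum_j w(v, disease_j)`. A node with no
#' disease edges gets `IR = 0` and is flagged.
#'
#' @param net a `hetero_network`.
#' @param v node key.
#' @param target_disease key of the target disease node (must be a disease
#'   node present in the network).
#' @return numeric in `[0,1]`, with attribute `no_disease_edges = TRUE` when
#'   the zero fallback applied.
#' @export
intersection_ratio <- function(net, v, target_disease) {
  cats <- setNames(net$nodes$category, net$nodes$key)
  if (!target_disease %in% net$nodes$key || cats[target_disease] != "disease") {
    stop("target disease node not in network: ", target_disease, call. = FALSE)
  }
  if (!v %in% net$nodes$key) stop("unknown node: ", v, call. = FALSE)
  inc <- net$edges$from == v | net$edges$to == v
  other <- ifelse(net$edges$from[inc] == v, net$edges$to[inc], net$edges$from[inc])
  w <- net$edges$weight[inc]
  is_dis <- cats[other] == "disease"
  denom <- sum(w[is_dis])
  if (denom == 0) {
    return(structure(0, no_disease_edges = TRUE))
  }
  sum(w[is_dis & other == target_disease]) / denom
}

#' Per-gene profiles: centralities, combined score, intersection ratio
#'
#' Computes the three centralities over the whole heterogeneous network,
#' min-max normalizes each over all nodes, derives entropy weights and the
#' combined score, then attaches the intersection ratio toward the target
#' disease for every gene node.
#'
#' @param net a `hetero_network` with at least 3 nodes.
#' @param target_disease key of the target disease node (default: the node
#'   whose display name is "COVID-19", if present).
#' @param entropy_mode passed to [entropy_weights()].
#' @return data.frame (one row per gene): key, symbol, dc, cc, bc, ndc, ncc,
#'   nbc, combined, ir; attribute `"weights"` carries the entropy weights.
#' @export
gene_profiles <- function(net, target_disease = NULL,
                          entropy_mode = c("standard", "literal")) {
  entropy_mode <- match.arg(entropy_mode)
  if (is.null(target_disease)) {
    cand <- net$nodes$key[net$nodes$category == "disease" &
                            net$nodes$name == "COVID-19"]
    if (!length(cand)) stop("no COVID-19 disease node; pass target_disease",
                            call. = FALSE)
    target_disease <- cand[1]
  }
  dc <- degree_centrality(net)
  cc <- closeness_centrality(net)
  bc <- betweenness_centrality(net)
  ndc <- minmax_normalize(dc)
  ncc <- minmax_normalize(cc)
  nbc <- minmax_normalize(bc)
  w <- entropy_weights(ndc, ncc, nbc, mode = entropy_mode)
  combined <- combine_centralities(ndc, ncc, nbc, w)
  genes <- net$nodes[net$nodes$category == "gene", , drop = FALSE]
  ir <- vapply(genes$key, function(k)
    as.numeric(intersection_ratio(net, k, target_disease)), 0)
  out <- data.frame(
    key = genes$key, symbol = genes$name,
    dc = unname(dc[genes$key]), cc = unname(cc[genes$key]),
    bc = unname(bc[genes$key]),
    ndc = unname(ndc[match(genes$key, net$nodes$key)]),
    ncc = unname(ncc[match(genes$key, net$nodes$key)]),
    nbc = unname(nbc[match(genes$key, net$nodes$key)]),
    combined = unname(combined[match(genes$key, net$nodes$key)]),
    ir = unname(ir),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "weights") <- w
  attr(out, "target_disease") <- target_disease
  out
}

#' Quadrant map of genes and the emerging-gene list
#'
#' Both indicators are min-max normalized over the genes; the plane is split
#' at the thresholds into quadrants (I: both high; II: combined high only;
#' III: both low; IV: intersection ratio high only). The "highlighted" set
#' is the `top_k` genes by combined score; the emerging list is the
#' quadrant-I genes minus the highlighted set, ranked by normalized
#' intersection ratio then combined score.
#'
#' @param profiles data.frame from [gene_profiles()] (needs >= 2 genes).
#' @param ir_threshold,cc_threshold thresholds in (0,1) on the normalized
#'   axes (default 0.5 each).
#' @param top_k size of the highlighted set (default 4).
#' @return list with `profiles` (plus ir_norm, combined_norm, quadrant,
#'   highlighted, emerging columns), `highlighted` (character symbols) and
#'   `emerging` (data.frame, ranked).
#' @export
emerging_map <- function(profiles, ir_threshold = 0.5, cc_threshold = 0.5,
                         top_k = 4) {
  stopifnot(ir_threshold > 0, ir_threshold < 1,
            cc_threshold > 0, cc_threshold < 1)
  if (nrow(profiles) < 2) stop("need at least 2 genes to normalize", call. = FALSE)
  p <- profiles
  p$ir_norm <- minmax_normalize(p$ir)
  p$combined_norm <- minmax_normalize(p$combined)
  if (anyNA(p$ir_norm)) p$ir_norm <- rep(0, nrow(p))
  if (anyNA(p$combined_norm)) p$combined_norm <- rep(0, nrow(p))
  hi_ir <- p$ir_norm > ir_threshold
  hi_cc <- p$combined_norm > cc_threshold
  p$quadrant <- ifelse(hi_ir & hi_cc, "I",
                       ifelse(!hi_ir & hi_cc, "II",
                              ifelse(!hi_ir & !hi_cc, "III", "IV")))
  ord <- order(-p$combined, p$symbol)
  p$highlighted <- seq_len(nrow(p)) %in% ord[seq_len(min(top_k, nrow(p)))]
  p$emerging <- p$quadrant == "I" & !p$highlighted
  em <- p[p$emerging, , drop = FALSE]
  em <- em[order(-em$ir_norm, -em$combined_norm, em$symbol), , drop = FALSE]
  rownames(em) <- NULL
  list(profiles = p,
       highlighted = p$symbol[p$highlighted][order(-p$combined[p$highlighted])],
       emerging = em)
}

#' Monthly frequency trend of top entities in a category
#'
#' Raw frequency counts mentions by default (`level = "mention"`); set
#' `level = "document"` for document frequency. The top `top_k` entities of
#' the category are selected by total frequency; their monthly series run
#' over the corpus date range, undated records excluded.
#'
#' @param mention_table resolved mentions (from [resolve_mentions()]).
#' @param x the dated `corpus` the mentions came from.
#' @param category one of disease/chemical/gene/variant.
#' @param top_k entities to keep (default 10; fewer if the category is
#'   smaller).
#' @param level `"mention"` or `"document"`.
#' @return list with `totals` (data.frame entity_id, name, frequency, ranked)
#'   and `series` (data.frame entity_id, name, year, month, count).
#' @export
entity_frequency_trend <- function(mention_table, x, category, top_k = 10,
                                   level = c("mention", "document")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "corpus"))
  mt <- mention_table[mention_table$category == category, , drop = FALSE]
  if (level == "document") mt <- unique(mt[, c("pmid", "entity_id", "name")])
  if (!nrow(mt)) {
    return(list(totals = data.frame(entity_id = character(), name = character(),
                                    frequency = integer()),
                series = data.frame(entity_id = character(), name = character(),
                                    year = integer(), month = integer(),
                                    count = integer())))
  }
  tot <- aggregate(list(frequency = mt$pmid), by = list(entity_id = mt$entity_id),
                   FUN = length)
  tot$name <- mt$name[match(tot$entity_id, mt$entity_id)]
  tot <- tot[order(-tot$frequency, tot$name), c("entity_id", "name", "frequency")]
  tot <- head(tot, top_k)
  rownames(tot) <- NULL

  tab <- records_table(x)
  dated <- tab[!is.na(tab$pub_year) & !is.na(tab$pub_month), , drop = FALSE]
  mt <- mt[mt$entity_id %in% tot$entity_id & mt$pmid %in% dated$pmid, , drop = FALSE]
  mt$year <- dated$pub_year[match(mt$pmid, dated$pmid)]
  mt$month <- dated$pub_month[match(mt$pmid, dated$pmid)]
  if (nrow(mt)) {
    series <- aggregate(list(count = mt$pmid),
                        by = list(entity_id = mt$entity_id, year = mt$year,
                                  month = mt$month),
                        FUN = length)
    series$name <- tot$name[match(series$entity_id, tot$entity_id)]
    series <- series[order(series$entity_id, series$year, series$month),
                     c("entity_id", "name", "year", "month", "count")]
    rownames(series) <- NULL
  } else {
    series <- data.frame(entity_id = character(), name = character(),
                         year = integer(), month = integer(), count = integer())
  }
  list(totals = tot, series = series)
}
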
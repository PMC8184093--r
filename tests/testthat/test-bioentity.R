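pubtator_fixture <- function() {
  c("123|t|ACE2 and COVID-19",
    "123|a|A study of ACE2 in COVID-19 with remdesivir and rs2285666.",
    "123\t0\t4\tACE2\tGene\t59272",
    "123\t9\t17\tCOVID-19\tDisease\tMESH:D000086382",
    "123\t40\t50\tremdesivir\tChemical\tMESH:C000606551",
    "123\t55\t64\trs2285666\tSNP\trs2285666",
    "123\t70\t80\tHomo sapiens\tSpecies\t9606",
    "",
    "124|t|Mutation mapping",
    "124|a|A protein mutation in TMPRSS2 and a mouse gene.",
    "124\t22\t29\tTMPRSS2\tGene\t7113",
    "124\t2\t18\tc.439+4G>A\tDNAMutation\tc.439+4G>A",
    "124\t30\t35\tAce2\tGene\t70008",
    "malformed line without tabs",
    "124\t40\t47\tCOVID-19\tDisease\tMESH:D000086382")
}

test_that("PubTator parsing maps types and skips junk", {
  expect_warning(m <- read_pubtator(pubtator_fixture()), "malformed")
  expect_identical(attr(m, "n_malformed"), 1L)
  expect_identical(attr(m, "n_dropped_type"), 1L)  # the Species line
  expect_identical(nrow(m), 8L)
  g <- m[m$text == "ACE2", ]
  expect_identical(g$category, "gene")
  expect_identical(g$raw_id, "59272")
  expect_identical(m$category[m$type_raw == "DNAMutation"], "variant")
})

test_that("mention resolution applies the dictionary cleaning rules", {
  m <- suppressWarnings(read_pubtator(pubtator_fixture()))
  res <- resolve_mentions(m)
  r <- res$report
  expect_identical(r$category, c("disease", "chemical", "gene", "variant"))
  # the mouse gene is excluded, both human genes kept
  expect_identical(r[r$category == "gene", ]$raw, 3L)
  expect_identical(r[r$category == "gene", ]$cleaned, 2L)
  expect_identical(r[r$category == "gene", ]$unique, 2L)
  # DNA mutation maps onto rs2285666 and merges with the explicit SNP mention
  expect_identical(r[r$category == "variant", ]$unique, 1L)
  expect_identical(unique(
    res$mention_table$entity_id[res$mention_table$category == "variant"]),
    "rs2285666")
  # all-mappable categories keep their raw counts
  expect_identical(r[r$category == "disease", ]$cleaned,
                   r[r$category == "disease", ]$raw)
  # per-document unique entity sets
  expect_identical(sort(res$doc_entities[["123"]]$category),
                   c("chemical", "disease", "gene", "variant"))
})

test_that("heterogeneous network counts co-document weights and keeps isolates", {
  doc_entities <- list(
    d1 = data.frame(entity_id = c("59272", "D000086382"),
                    name = c("ACE2", "COVID-19"),
                    category = c("gene", "disease")),
    d2 = data.frame(entity_id = c("59272", "D000086382"),
                    name = c("ACE2", "COVID-19"),
                    category = c("gene", "disease")),
    d3 = data.frame(entity_id = c("59272", "D000086382"),
                    name = c("ACE2", "COVID-19"),
                    category = c("gene", "disease")),
    d4 = data.frame(entity_id = "rs999", name = "rs999", category = "variant")
  )
  net <- build_hetero_network(doc_entities)
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(net$edges$weight, 3L)
  expect_true("variant:rs999" %in% net$nodes$key)  # isolated node retained

  tal <- edge_tallies(net)
  expect_identical(tal["disease", "gene"], 1L)
  expect_identical(tal["gene", "disease"], 1L)
  # conservation: upper triangle plus diagonal equals the edge count
  expect_identical(sum(tal[upper.tri(tal, diag = TRUE)]), nrow(net$edges))
})

test_that("centralities reproduce closed-form anchors", {
  # path a-b-c
  path3 <- net_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(degree_centrality(path3)), c(0.5, 1, 0.5))
  expect_equal(unname(closeness_centrality(path3)), c(2 / 3, 1, 2 / 3))
  # star with 5 nodes: center betweenness 1, leaves 0
  A_star <- matrix(0, 5, 5); A_star[1, 2:5] <- 1; A_star <- A_star + t(A_star)
  star <- net_from_adjacency(A_star)
  expect_equal(unname(betweenness_centrality(star)), c(1, 0, 0, 0, 0))
  expect_equal(unname(closeness_centrality(star))[1], 1)
  # 4-cycle: betweenness 1/6 everywhere
  A_c4 <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(unname(betweenness_centrality(net_from_adjacency(A_c4))),
               rep(1 / 6, 4), tolerance = 1e-12)
  # complete graph: degree centrality 1 for all
  A_k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(degree_centrality(net_from_adjacency(A_k4))), rep(1, 4))
  # two disjoint edges: Wasserman-Faust closeness = 1/3 each
  A_2e <- matrix(0, 4, 4); A_2e[1, 2] <- A_2e[3, 4] <- 1; A_2e <- A_2e + t(A_2e)
  expect_equal(unname(closeness_centrality(net_from_adjacency(A_2e))),
               rep(1 / 3, 4), tolerance = 1e-12)
  # isolated node scores zero; tiny networks refuse centralities
  A_iso <- matrix(0, 3, 3); A_iso[1, 2] <- A_iso[2, 1] <- 1
  expect_identical(unname(degree_centrality(net_from_adjacency(A_iso), "gene:n03")), 0)
  expect_error(degree_centrality(net_from_adjacency(matrix(0, 1, 1))), "at least 2")
  expect_error(betweenness_centrality(net_from_adjacency(matrix(0, 2, 2))), "at least 3")
})

test_that("centralities match independent oracles on random graphs", {
  withr::local_seed(2024)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    A <- random_adjacency(n, runif(1, 1.2 / n, 0.4))
    net <- net_from_adjacency(A)
    expect_equal(unname(degree_centrality(net)), oracle_degree(A),
                 tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(net)), oracle_closeness(A),
                 tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(A),
                 tolerance = 1e-9)
    # second, library-based cross-check on the same graph
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(unname(betweenness_centrality(net)),
                 igraph::betweenness(g, normalized = TRUE), tolerance = 1e-9)
  }
})

test_that("entropy weights behave across regular and degenerate inputs", {
  # identical centrality value sets: exact symmetry
  v <- c(0, 0.25, 0.5, 1)
  expect_equal(unname(entropy_weights(v, v, v)), rep(1 / 3, 3),
               tolerance = 1e-12)
  # dispersed set vs concentrated set: concentration earns more weight
  dispersed <- c(1, 0.9, 0.95, 0.85) / 1  # near-uniform proportions
  concentrated <- c(1, 0, 0, 0)
  w <- entropy_weights(minmax_dc <- bibliomine:::minmax_normalize(dispersed),
                       bibliomine:::minmax_normalize(c(0.3, 0.6, 0.9, 0.2)),
                       bibliomine:::minmax_normalize(concentrated))
  expect_gt(w[["bc"]], w[["dc"]])
  # constant set: weight 0 and renormalization
  expect_message(
    w0 <- entropy_weights(c(NA, NA, NA, NA), v, v),
    "weight 0")
  expect_identical(unname(w0[["dc"]]), 0)
  expect_equal(sum(w0), 1, tolerance = 1e-12)
  # weights always sum to 1 on random inputs
  withr::local_seed(5)
  for (rep in 1:20) {
    sets <- replicate(3, bibliomine:::minmax_normalize(runif(6)),
                      simplify = FALSE)
    w <- entropy_weights(sets[[1]], sets[[2]], sets[[3]])
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # permutation invariance in the node order
    p <- sample(6)
    wp <- entropy_weights(sets[[1]][p], sets[[2]][p], sets[[3]][p])
    expect_equal(w, wp, tolerance = 1e-12)
  }
})

test_that("literal entropy mode evaluates the printed formula", {
  v <- c(0, 0.5, 1)
  H_lit <- -(0.5 * log(0.5) + 1 * log(1)) / log(3)
  w <- entropy_weights(v, v, v, mode = "literal")
  expect_equal(unname(w), rep((1 - H_lit) / (3 - 3 * H_lit), 3),
               tolerance = 1e-12)
})

test_that("combined centrality is a monotone weighted sum", {
  w <- c(dc = 0.5, cc = 0.3, bc = 0.2)
  expect_equal(combine_centralities(1, 0, 0.5, w), 0.6, tolerance = 1e-12)
  expect_equal(combine_centralities(1, 1, 1, w), 1)
  expect_equal(combine_centralities(0, 0, 0, w), 0)
  # raising any single normalized centrality never lowers the score
  withr::local_seed(8)
  for (rep in 1:20) {
    n0 <- runif(3)
    base <- combine_centralities(n0[1], n0[2], n0[3], w)
    bump <- pmin(n0 + c(0.2, 0, 0), 1)
    expect_gte(combine_centralities(bump[1], bump[2], bump[3], w), base)
  }
})

test_that("intersection ratio follows the disease-edge share", {
  doc <- function(...) {
    ids <- c(...)
    data.frame(entity_id = ids,
               name = ids,
               category = ifelse(grepl("^D", ids), "disease", "gene"))
  }
  docs <- c(replicate(3, doc("G1", "Dtarget"), simplify = FALSE),
            list(doc("G1", "Dother")),
            list(doc("G2", "Dtarget")),
            list(doc("G3", "G1")))
  net <- build_hetero_network(setNames(docs, paste0("d", seq_along(docs))))
  # w(target)=3, w(other)=1 -> 0.75
  expect_equal(intersection_ratio(net, "gene:G1", "disease:Dtarget"), 0.75)
  # only linked to the target -> 1
  expect_identical(intersection_ratio(net, "gene:G2", "disease:Dtarget"), 1)
  # no disease edges -> 0 with a flag
  ir3 <- intersection_ratio(net, "gene:G3", "disease:Dtarget")
  expect_identical(as.numeric(ir3), 0)
  expect_true(attr(ir3, "no_disease_edges"))
  expect_error(intersection_ratio(net, "gene:G1", "disease:Dmissing"),
               "target disease")
  # scale invariance under uniform multiplication of disease edge weights
  net2 <- net
  sel <- net2$nodes$category[match(net2$edges$to, net2$nodes$key)] == "disease" |
    net2$nodes$category[match(net2$edges$from, net2$nodes$key)] == "disease"
  net2$edges$weight[sel] <- net2$edges$weight[sel] * 7L
  expect_equal(intersection_ratio(net2, "gene:G1", "disease:Dtarget"), 0.75)
})

test_that("the quadrant map separates highlighted and emerging genes", {
  profiles <- data.frame(
    key = paste0("gene:", 1:6),
    symbol = c("HUB", "F1", "F2", "F3", "EMERGING", "WEAK"),
    combined = c(1.0, 0.9, 0.85, 0.8, 0.7, 0.05),
    ir = c(0.5, 0.4, 0.45, 0.3, 1.0, 0.2)
  )
  em <- emerging_map(profiles, ir_threshold = 0.5, cc_threshold = 0.5,
                     top_k = 4)
  expect_identical(em$highlighted, c("HUB", "F1", "F2", "F3"))
  expect_identical(em$emerging$symbol, "EMERGING")
  p <- em$profiles
  expect_identical(p$quadrant[p$symbol == "EMERGING"], "I")
  expect_identical(p$quadrant[p$symbol == "WEAK"], "III")
  expect_identical(p$quadrant[p$symbol == "HUB"], "II")
  expect_error(emerging_map(profiles[1, ]), "at least 2")
})

test_that("entity frequency trends count mentions by default", {
  m <- suppressWarnings(read_pubtator(pubtator_fixture()))
  res <- resolve_mentions(m)
  recs <- list(
    bibliomine:::publication_record("123", pub_year = 2020L, pub_month = 3L),
    bibliomine:::publication_record("124", pub_year = 2020L, pub_month = 4L)
  )
  corp <- corpus(recs)
  tr <- entity_frequency_trend(res$mention_table, corp, "disease", top_k = 10)
  expect_identical(tr$totals$frequency, 2L)  # two COVID-19 mentions
  expect_identical(tr$series$count, c(1L, 1L))
  trd <- entity_frequency_trend(res$mention_table, corp, "disease",
                                level = "document")
  expect_identical(trd$totals$frequency, 2L)  # two documents here too
  # fewer entities than top_k: all returned
  trg <- entity_frequency_trend(res$mention_table, corp, "gene", top_k = 10)
  expect_identical(nrow(trg$totals), 2L)
})
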
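# A tiny hand-buildable stream: documents as explicit term vectors.
stream_from_matrix <- function(counts, slice, vocab = colnames(counts)) {
  rownames(counts) <- sprintf("d%02d", seq_len(nrow(counts)))
  structure(
    list(x = bibliomine:::l2_normalize_rows(counts), counts = counts,
         slice = as.integer(slice), pmid = rownames(counts),
         slice_labels = as.character(seq(0, max(slice))),
         vocab = vocab, granularity = "month", dropped = 0L, excluded = 0L),
    class = "sep_stream"
  )
}

test_that("stream preparation slices by date and drops empty documents", {
  mk <- function(pmid, m, text) bibliomine:::publication_record(
    pmid = pmid, title = text, pub_year = 2020L, pub_month = m)
  corp <- corpus(list(mk("1", 1L, "alpha beta"), mk("2", 1L, "alpha"),
                      mk("3", 2L, "beta gamma"), mk("4", 2L, "zzz qqq")))
  tm <- extract_terms(corp, min_df = 1, ngram_max = 1)
  tm$vocabulary$terms <- c("alpha", "beta", "gamma")
  expect_message(st <- prepare_stream(corp, tm, "month"), "dropped")
  expect_identical(nrow(st$x), 3L)
  expect_identical(st$slice, c(0L, 0L, 1L))
  expect_equal(unname(rowSums(st$x^2)), rep(1, 3), tolerance = 1e-12)

  # yearly granularity on a 2020-2021 fixture gives two slices
  corp2 <- corpus(list(mk("1", 1L, "alpha"),
                       bibliomine:::publication_record("2", title = "beta",
                                                       pub_year = 2021L)))
  st2 <- prepare_stream(corp2, tm, "year")
  expect_identical(sort(unique(st2$slice)), c(0L, 1L))
})

test_that("initial topic has centroid, radius and label per definition", {
  # two identical documents: radius 0
  counts <- rbind(c(2, 0), c(2, 0))
  colnames(counts) <- c("sar", "cov")
  st <- stream_from_matrix(counts, c(0, 0))
  t0 <- init_topic(st)
  expect_identical(t0$radius, 0)
  expect_equal(t0$centroid, c(sar = 1, cov = 0))
  expect_identical(t0$label, "sar")

  # two orthogonal unit vectors: centroid norm 1/sqrt(2), radius 1/sqrt(2)
  counts2 <- rbind(c(1, 0), c(0, 1))
  colnames(counts2) <- c("sar", "cov")
  st2 <- stream_from_matrix(counts2, c(0, 0))
  t2 <- init_topic(st2)
  expect_equal(sqrt(sum(t2$centroid^2)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(t2$radius, 1 / sqrt(2), tolerance = 1e-12)

  st3 <- stream_from_matrix(counts2, c(1, 1))
  expect_error(init_topic(st3), "slice 0")
})

test_that("drift rule follows the relative-distance threshold", {
  topic <- list(centroid = c(1, 0), radius = 1)
  # E = 1.2, r = 1: ratio 0.2 > 0.1 -> drifted
  expect_identical(drift_test(c(1, 1.2), topic, sigma = 0.1), "drifted")
  # E = 1.05: ratio 0.05 -> assigned
  expect_identical(drift_test(c(1, 1.05), topic, sigma = 0.1), "assigned")
  # doc at the centroid: assigned for any sigma
  expect_identical(drift_test(c(1, 0), topic, sigma = 1e-6), "assigned")
  # zero radius: any measurable departure drifts
  degenerate <- list(centroid = c(1, 0), radius = 0)
  expect_identical(drift_test(c(1, 1e-6), degenerate), "drifted")
  expect_identical(drift_test(c(1, 0), degenerate), "assigned")
})

test_that("topic update recomputes centroid, radius and label over members", {
  counts <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(3, 3, 0))
  colnames(counts) <- c("ta", "tb", "tc")
  st <- stream_from_matrix(counts, c(0, 0, 1, 1))
  t0 <- init_topic(st)  # members 1,2

  # duplicate of an existing member direction leaves the centroid unchanged
  t_dup <- update_topic(t0, integer(0), st)
  expect_equal(t_dup$centroid, t0$centroid, tolerance = 1e-12)

  t1 <- update_topic(t0, c(3L, 4L), st)
  x <- st$x
  expect_equal(t1$centroid, colMeans(x[1:4, ]), tolerance = 1e-12)
  expect_equal(t1$radius,
               max(sqrt(rowSums((x[1:4, ] - rep(colMeans(x[1:4, ]),
                                                each = 4))^2))),
               tolerance = 1e-12)
  # member at distance beyond the old radius extends the radius
  expect_gte(t1$radius, t0$radius)
  # label from full-membership raw counts: ta has 6, tb 6 -> lexicographic tie
  expect_identical(t1$label, "ta")
})

test_that("spawning splits orthogonal blocks and keeps singletons whole", {
  # two orthogonal vocabulary blocks -> exactly 2 descendant topics
  counts <- rbind(matrix(rep(c(2, 1, 0, 0), 4), 4, byrow = TRUE),
                  matrix(rep(c(0, 0, 1, 2), 4), 4, byrow = TRUE))
  counts <- counts + 0
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  st <- stream_from_matrix(counts, rep(1, 8))
  sp <- spawn_topics(st, 1:8, rep(1L, 8), slice_index = 1L, next_id = 2L,
                     seed = 1)
  expect_length(sp$topics, 2)
  members <- lapply(sp$topics, `[[`, "members")
  expect_true(setequal(members[[1]], 1:4) || setequal(members[[1]], 5:8))
  expect_identical(sp$edges$from, c(1L, 1L))

  # single drifted document: singleton topic with radius 0
  sp1 <- spawn_topics(st, 3L, 1L, slice_index = 1L, next_id = 2L, seed = 1)
  expect_length(sp1$topics, 1)
  expect_identical(sp1$topics[[1]]$radius, 0)
})

test_that("a constant-vocabulary stream yields one topic and no edges", {
  plan <- topic_plan(births = 0L, parents = NA_integer_, n_slices = 5L,
                     docs_per_slice = 30L, noise = 0, seed = 5)
  gen <- generate_topic_stream(plan)
  tm <- extract_terms(gen$corpus, min_df = 2, ngram_max = 1)
  st <- prepare_stream(gen$corpus, tm, "month")
  sg <- run_sep(st, sigma = 0.1, seed = 5)
  expect_length(sg$topics, 1)
  expect_identical(nrow(sg$edges), 0L)
})

test_that("a two-phase stream spawns a descendant linked to the root", {
  plan <- topic_plan(births = c(0L, 3L), parents = c(NA, 1L), n_slices = 6L,
                     docs_per_slice = 20L, noise = 0, seed = 7)
  gen <- generate_topic_stream(plan)
  tm <- extract_terms(gen$corpus, min_df = 2, ngram_max = 1)
  st <- prepare_stream(gen$corpus, tm, "month")
  sg <- run_sep(st, sigma = 0.1, seed = 7)
  births <- vapply(sg$topics, `[[`, 0L, "birth_slice")
  expect_true(any(births == 3L))
  expect_true(all(sg$edges$from == 1L | sg$edges$to > sg$edges$from))
  expect_true(1L %in% sg$edges$from)
})

test_that("every streamed document lands in exactly one topic", {
  plan <- topic_plan(seed = 3, docs_per_slice = 30L)
  gen <- generate_topic_stream(plan)
  tm <- extract_terms(gen$corpus, min_df = 3, ngram_max = 1)
  st <- prepare_stream(gen$corpus, tm, "month")
  sg <- run_sep(st, sigma = 0.1, seed = 3)
  memberships <- unlist(lapply(sg$topics, `[[`, "members"))
  expect_identical(sort(memberships), seq_len(nrow(st$x)))
  expect_true(all(sg$assignment > 0))
  # lineage edges only point from earlier-or-equal birth to later topics
  births <- setNames(vapply(sg$topics, `[[`, 0L, "birth_slice"),
                     vapply(sg$topics, `[[`, 0L, "id"))
  if (nrow(sg$edges)) {
    expect_true(all(births[as.character(sg$edges$from)] <=
                      births[as.character(sg$edges$to)]))
  }
  # every topic born after slice 0 has a predecessor
  late <- names(births)[births > 0]
  expect_true(all(late %in% as.character(sg$edges$to)))
})

test_that("cosine and Euclidean candidate rankings agree on unit geometry", {
  withr::local_seed(11)
  for (rep in 1:10) {
    x <- matrix(rexp(8 * 30), 8, 30)
    x <- bibliomine:::l2_normalize_rows(x)
    centroids <- bibliomine:::l2_normalize_rows(matrix(rexp(4 * 30), 4, 30))
    for (i in 1:8) {
      cosr <- order(-drop(centroids %*% x[i, ]))
      eucr <- order(sqrt(rowSums((centroids - rep(x[i, ], each = 4))^2)))
      expect_identical(cosr, eucr)
    }
  }
})

test_that("raising sigma never increases the final topic count", {
  plan <- topic_plan(seed = 9)
  gen <- generate_topic_stream(plan)
  tm <- extract_terms(gen$corpus, min_df = 3, ngram_max = 1)
  st <- prepare_stream(gen$corpus, tm, "month")
  counts <- vapply(c(0.05, 0.1, 0.3, 0.8),
                   function(s) length(run_sep(st, sigma = s, seed = 9)$topics),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("identical stream, seed and parameters give identical graphs", {
  plan <- topic_plan(seed = 4, docs_per_slice = 25L)
  gen <- generate_topic_stream(plan)
  tm <- extract_terms(gen$corpus, min_df = 3, ngram_max = 1)
  st <- prepare_stream(gen$corpus, tm, "month")
  expect_identical(run_sep(st, sigma = 0.1, seed = 12),
                   run_sep(st, sigma = 0.1, seed = 12))
})

test_that("summary statistics use population standard deviation", {
  counts <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(1, 1))
  colnames(counts) <- c("u", "v")
  st <- stream_from_matrix(counts, c(0, 0, 0, 1, 1))
  sg <- run_sep(st, sigma = 10, seed = 1)  # huge sigma: everything assigned
  stats <- sep_statistics(sg)
  expect_identical(stats$n_topics, 1L)
  expect_identical(stats$max_members, 5L)

  fake <- structure(list(
    topics = list(list(id = 1L, label = "x", birth_slice = 0L,
                       members = 1:3),
                  list(id = 2L, label = "y", birth_slice = 1L,
                       members = 1:5)),
    edges = data.frame(from = 1L, to = 2L),
    assignment = integer(0), n_docs = 8L, slice_labels = c("a", "b")),
    class = "sep_graph")
  s <- sep_statistics(fake)
  expect_identical(s$max_members, 5L)
  expect_identical(s$min_members, 3L)
  expect_equal(s$sd_members, 1)  # population sd of (3,5)
  expect_match(s$largest[1], "^y \\[b\\] — 5$")
})

test_that("SEP export writes GraphML and a membership table", {
  plan <- topic_plan(births = c(0L, 2L), parents = c(NA, 1L), n_slices = 4L,
                     docs_per_slice = 15L, noise = 0, seed = 2)
  gen <- generate_topic_stream(plan)
  tm <- extract_terms(gen$corpus, min_df = 2, ngram_max = 1)
  st <- prepare_stream(gen$corpus, tm, "month")
  sg <- run_sep(st, seed = 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_sep(sg, gml, csv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(sg$topics))
  memb <- utils::read.csv(csv, colClasses = c(pmid = "character"))
  expect_identical(nrow(memb), sg$n_docs)
  expect_identical(sort(unique(memb$topic)),
                   sort(vapply(sg$topics, `[[`, 0L, "id")))
})
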
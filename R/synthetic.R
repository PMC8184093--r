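# Synthetic corpus generators. They define the study conditions for every
# pipeline stage: a sliced document stream with a planted topic birth/split
# schedule, affiliation lists with planted collaboration communities, and
# PubTator-style entity annotations with a planted hub gene and a planted
# target-disease-specific gene. All are pure functions of (parameters, seed).

#' Plan a planted topic birth/split schedule
#'
#' @param births integer vector: birth slice of each topic (first must be 0).
#' @param parents integer vector: index of each topic's parent (NA for
#'   slice-0 roots).
#' @param n_slices number of monthly slices.
#' @param docs_per_slice documents each living topic emits per slice.
#' @param noise probability in `[0, 1)` that a token is drawn from the global
#'   vocabulary instead of the topic's own block.
#' @param block_size terms per topic vocabulary block (blocks are disjoint).
#' @param tokens_per_doc tokens sampled per document.
#' @param seed RNG seed.
#' @return a `topic_plan` list.
#' @export
topic_plan <- function(births = c(0L, 2L, 2L, 4L),
                       parents = c(NA, 1L, 1L, 2L),
                       n_slices = 6L, docs_per_slice = 75L, noise = 0.1,
                       block_size = 40L, tokens_per_doc = 30L, seed = 1L) {
  stopifnot(length(births) == length(parents),
            births[1] == 0L, noise >= 0, noise < 1,
            all(is.na(parents) | births[parents] <= births),
            all(births < n_slices))
  structure(list(births = as.integer(births), parents = as.integer(parents),
                 n_slices = as.integer(n_slices),
                 docs_per_slice = as.integer(docs_per_slice),
                 noise = noise, block_size = as.integer(block_size),
                 tokens_per_doc = as.integer(tokens_per_doc),
                 seed = as.integer(seed)),
            class = "topic_plan")
}

#' Generate a dated document stream following a planted topic schedule
#'
#' Each topic owns a disjoint vocabulary block; from its birth slice on it
#' emits `docs_per_slice` documents per monthly slice, each document
#' sampling tokens from its block with probability `1 - noise` and from the
#' global vocabulary otherwise. Dates start at 2020-01.
#'
#' @param plan a [topic_plan()].
#' @return list with `corpus` (dated records) and `truth`: list with
#'   `doc_topic` (named integer, pmid -> planted topic), `lineage`
#'   (data.frame from, to over planted topic ids) and `blocks`.
#' @export
generate_topic_stream <- function(plan) {
  stopifnot(inherits(plan, "topic_plan"))
  with_local_seed(plan$seed, {
    k <- length(plan$births)
    blocks <- lapply(seq_len(k), function(t)
      sprintf("block%dterm%03d", t, seq_len(plan$block_size)))
    global <- unlist(blocks)
    records <- list()
    doc_topic <- integer(0)
    pm <- 0L
    for (s in seq_len(plan$n_slices) - 1L) {
      for (t in seq_len(k)) {
        if (plan$births[t] > s) next
        for (d in seq_len(plan$docs_per_slice)) {
          pm <- pm + 1L
          from_block <- runif(plan$tokens_per_doc) >= plan$noise
          toks <- ifelse(from_block,
                         sample(blocks[[t]], plan$tokens_per_doc, replace = TRUE),
                         sample(global, plan$tokens_per_doc, replace = TRUE))
          # title reuses the document's own leading terms so that topic
          # labels resolve to block vocabulary, not to boilerplate words
          records[[pm]] <- publication_record(
            pmid = sprintf("S%05d", pm),
            title = paste(toks[1:3], collapse = " "),
            abstract = paste(toks[-(1:3)], collapse = " "),
            journal = "Synthetic Journal",
            pub_year = 2020L + s %/% 12L,
            pub_month = s %% 12L + 1L
          )
          doc_topic <- c(doc_topic, t)
        }
      }
    }
    names(doc_topic) <- vapply(records, `[[`, "", "pmid")
    lineage <- data.frame(from = plan$parents[!is.na(plan$parents)],
                          to = which(!is.na(plan$parents)))
    list(corpus = corpus(records, provenance = "synthetic topic stream"),
         truth = list(doc_topic = doc_topic, lineage = lineage,
                      blocks = blocks))
  })
}

#' Generate a collaboration corpus with planted institution communities
#'
#' Institutions are split into `k_communities`. Each document picks a home
#' community and includes each of its institutions with probability
#' `sqrt(p_in)` (so a within-community pair co-occurs with probability
#' `p_in`) and each outside institution with probability
#' `p_out / sqrt(p_in)` (cross pairs co-occur with probability ~`p_out`).
#'
#' @param n_institutions,k_communities sizes (communities round-robin).
#' @param p_in,p_out planted within/between co-occurrence probabilities,
#'   `p_in > p_out`.
#' @param n_docs number of documents.
#' @param seed RNG seed.
#' @return list with `corpus` (records carrying affiliation strings),
#'   `truth` (named integer: institution -> community), and `gazetteer`
#'   (the country gazetteer matching the generated strings).
#' @export
generate_collaboration <- function(n_institutions = 30L, k_communities = 3L,
                                   p_in = 0.9, p_out = 0.05, n_docs = 200L,
                                   seed = 1L) {
  stopifnot(p_in > p_out, p_in <= 1, p_out >= 0)
  countries <- c("United States", "China", "United Kingdom", "Australia",
                 "Germany", "Canada")
  insts <- sprintf("University of Site%02d", seq_len(n_institutions))
  community <- rep(seq_len(k_communities), length.out = n_institutions)
  names(community) <- insts
  a <- sqrt(p_in)
  b <- if (a > 0) min(1, p_out / a) else 0
  with_local_seed(seed, {
    records <- list()
    for (i in seq_len(n_docs)) {
      home <- sample.int(k_communities, 1)
      take <- ifelse(community == home, runif(n_institutions) < a,
                     runif(n_institutions) < b)
      chosen <- insts[take]
      if (!length(chosen)) chosen <- sample(insts[community == home], 1)
      ads <- sprintf("Department of Genetics, %s, City%02d, %s",
                     chosen, match(chosen, insts),
                     countries[(match(chosen, insts) - 1) %% length(countries) + 1])
      records[[i]] <- publication_record(
        pmid = sprintf("C%05d", i),
        title = "synthetic collaboration document",
        journal = "Synthetic Journal",
        pub_year = 2020L, pub_month = (i - 1L) %% 12L + 1L,
        affiliations = ads
      )
    }
    list(corpus = corpus(records, provenance = "synthetic collaboration"),
         truth = community,
         gazetteer = setNames(countries, countries))
  })
}

#' Generate a bio-entity corpus with a planted hub and a planted
#' disease-specific gene
#'
#' Documents mention entities drawn from the bundled synthetic dictionaries.
#' The corpus plants a three-tier gene structure mirroring the shape such
#' literature takes: one hub gene cutting across all study themes (broadest
#' co-occurrence, highest expected combined centrality), a small
#' "frequently highlighted" tier (IL6, TMPRSS2, TNF) at half the hub's
#' breadth, and one emerging disease-specific gene that is mentioned with no
#' disease but the target (intersection ratio exactly 1) yet stays central
#' as the exclusive bridge to its private genetic variants. Each gene of
#' interest owns two private variants reachable only through it. A non-human
#' gene and a Species annotation are planted to exercise the cleaning rules.
#'
#' @param n_docs number of documents (default 300).
#' @param seed RNG seed.
#' @param p_target probability a document mentions the target disease.
#' @param p_hub probability a document mentions the hub gene.
#' @param p_specific probability a target-only document mentions the
#'   specific gene.
#' @param hub_symbol,specific_symbol gene symbols (must differ; must exist
#'   in the bundled gene dictionary).
#' @param target_name display name of the target disease in the bundled MeSH
#'   dictionary (default "COVID-19").
#' @return list with `pubtator` (character lines in PubTator raw format),
#'   `corpus` (dated records with matching titles/abstracts) and `truth`
#'   (hub/specific/target keys and per-document entity list).
#' @export
generate_bioentity_corpus <- function(n_docs = 300L, seed = 1L,
                                      p_target = 0.7, p_hub = 0.5,
                                      p_specific = 0.45,
                                      hub_symbol = "ACE2",
                                      specific_symbol = "ISG15",
                                      target_name = "COVID-19") {
  stopifnot(hub_symbol != specific_symbol)
  mesh <- load_dictionary("mesh")
  genes <- load_dictionary("genes")
  snps <- load_dictionary("snps")
  human <- genes[genes$tax_id == "9606", ]
  target <- mesh[mesh$name == target_name & mesh$category == "disease", ]
  stopifnot(nrow(target) == 1)
  distractors <- mesh[mesh$category == "disease" & mesh$name != target_name, ]
  chems <- mesh[mesh$category == "chemical", ]
  hub <- human[human$symbol == hub_symbol, ]
  spec <- human[human$symbol == specific_symbol, ]
  stopifnot(nrow(hub) == 1, nrow(spec) == 1)
  frequent <- c("IL6", "TMPRSS2", "TNF")
  frequent <- setdiff(frequent, c(hub_symbol, specific_symbol))
  freq_genes <- human[human$symbol %in% frequent, ]
  others <- human[!human$symbol %in% c(hub_symbol, specific_symbol, frequent), ]
  others <- head(others, 18)
  variants <- head(snps$rsid[!duplicated(snps$rsid)], 10)
  # private variants: two per gene of interest (hub, frequently-highlighted,
  # specific) — each variant reachable only through its owning gene
  var_owner <- rep(c(hub_symbol, frequent, specific_symbol),
                   each = 2)[seq_along(variants)]
  nonhuman <- genes[genes$tax_id != "9606", ][1, ]

  with_local_seed(seed, {
    docs <- data.frame(pmid = sprintf("B%05d", seq_len(n_docs)),
                       title = "Synthetic bio-entity literature record",
                       abstract = "", stringsAsFactors = FALSE)
    mention_rows <- list()
    doc_truth <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      ents <- list()  # rows: text, type_raw, raw_id
      add <- function(text, type, id) {
        ents[[length(ents) + 1L]] <<- c(text, type, id)
      }
      has_spec <- runif(1) < p_specific && runif(1) < p_target
      if (has_spec) {
        # specific-gene study: the target is the only disease it is ever
        # mentioned with, and it is the sole bridge to a couple of private
        # variants — central enough for quadrant I, but not a hub
        add(spec$symbol, "Gene", spec$gene_id)
        if (runif(1) < 0.3) {
          # variant-mapping study of the specific gene
          own <- variants[var_owner == specific_symbol]
          rs <- own[sample.int(length(own), 1)]
          add(rs, "SNP", rs)
        } else {
          add(target$name, "Disease", target$mesh_id)
          g <- sample.int(nrow(others), 1)
          if (runif(1) < 0.6) add(others$symbol[g], "Gene", others$gene_id[g])
          g2 <- sample.int(nrow(others), 1)
          if (runif(1) < 0.3 && g2 != g) add(others$symbol[g2], "Gene",
                                             others$gene_id[g2])
          if (runif(1) < 0.5) {
            j <- sample.int(nrow(chems), 1)
            add(chems$name[j], "Chemical", chems$mesh_id[j])
          }
          if (runif(1) < 0.2) add(hub$symbol, "Gene", hub$gene_id)
        }
      } else if (runif(1) < 0.12) {
        # variant-mapping study of the hub or a frequently-highlighted gene
        gsym <- sample(c(hub_symbol, freq_genes$symbol), 1)
        grow <- human[human$symbol == gsym, ]
        add(grow$symbol, "Gene", grow$gene_id)
        own <- variants[var_owner == gsym]
        rs <- own[sample.int(length(own), 1)]
        add(rs, "SNP", rs)
      } else {
        # thematic study: one or two focal genes, one or two diseases,
        # occasionally a chemical; the hub and the frequently-highlighted
        # genes cut across themes
        if (runif(1) < p_target) add(target$name, "Disease", target$mesh_id)
        j <- sample.int(nrow(distractors), 1)
        if (runif(1) < 0.6) add(distractors$name[j], "Disease",
                                distractors$mesh_id[j])
        j2 <- sample.int(nrow(distractors), 1)
        if (runif(1) < 0.2) add(distractors$name[j2], "Disease",
                                distractors$mesh_id[j2])
        g <- sample.int(nrow(others), 1)
        if (runif(1) < 0.8) add(others$symbol[g], "Gene", others$gene_id[g])
        g2 <- sample.int(nrow(others), 1)
        if (runif(1) < 0.25 && g2 != g) add(others$symbol[g2], "Gene",
                                            others$gene_id[g2])
        j3 <- sample.int(nrow(chems), 1)
        if (runif(1) < 0.4) add(chems$name[j3], "Chemical", chems$mesh_id[j3])
        for (f in seq_len(nrow(freq_genes))) {
          if (runif(1) < 0.25) add(freq_genes$symbol[f], "Gene",
                                  freq_genes$gene_id[f])
        }
        if (runif(1) < p_hub) add(hub$symbol, "Gene", hub$gene_id)
      }
      if (runif(1) < 0.05) add(nonhuman$symbol, "Gene", nonhuman$gene_id)
      if (runif(1) < 0.05) add("Homo sapiens", "Species", "9606")
      if (!length(ents)) add(target$name, "Disease", target$mesh_id)

      texts <- vapply(ents, `[`, "", 1)
      abstract <- paste(texts, collapse = " ; ")
      docs$abstract[i] <- abstract
      offset <- nchar(docs$title[i]) + 1L  # abstract starts after title + space
      pos <- offset
      for (k in seq_along(ents)) {
        start <- pos
        end <- start + nchar(texts[k])
        mention_rows[[length(mention_rows) + 1L]] <- data.frame(
          pmid = docs$pmid[i], start = start, end = end, text = texts[k],
          type_raw = ents[[k]][2], raw_id = ents[[k]][3],
          stringsAsFactors = FALSE
        )
        pos <- end + 3L  # " ; "
      }
      doc_truth[[i]] <- ents
    }
    mentions <- do.call(rbind, mention_rows)
    pt_path <- tempfile(fileext = ".pubtator")
    write_pubtator(docs, mentions, pt_path)
    pubtator <- readLines(pt_path)
    unlink(pt_path)
    records <- lapply(seq_len(n_docs), function(i) {
      publication_record(
        pmid = docs$pmid[i], title = docs$title[i], abstract = docs$abstract[i],
        journal = "Synthetic Journal",
        pub_year = 2020L + (i - 1L) %/% 240L,
        pub_month = ((i - 1L) %/% 20L) %% 12L + 1L
      )
    })
    list(
      pubtator = pubtator,
      corpus = corpus(records, provenance = "synthetic bio-entity corpus"),
      truth = list(
        hub = entity_key("gene", hub$gene_id),
        specific = entity_key("gene", spec$gene_id),
        target = entity_key("disease", target$mesh_id),
        hub_symbol = hub_symbol, specific_symbol = specific_symbol,
        doc_entities = doc_truth
      )
    )
  })
}
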
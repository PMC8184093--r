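#' Assemble a validated pipeline configuration
#'
#' @param input_medline path to a MEDLINE flat file (required).
#' @param input_pubtator path to a PubTator annotation file (optional; the
#'   bio-entity stages are skipped without it).
#' @param outdir output directory for the report bundle.
#' @param granularity slice granularity for the topic stream.
#' @param sigma topic drift threshold (> 0).
#' @param k_max largest descendant-topic count per slice.
#' @param min_df,ngram_max term-extraction parameters.
#' @param resolution community-detection resolution.
#' @param seed integer seed threaded through every stochastic stage.
#' @param cutoff optional `c(year, month)` date cutoff.
#' @param target_disease key of the intersection-ratio target disease
#'   (default: the COVID-19 node).
#' @param ir_threshold,cc_threshold,top_k emerging-map parameters.
#' @param entropy_mode `"standard"` or `"literal"`.
#' @param alias_table,country_gazetteer affiliation-cleaning inputs.
#' @param normalize_terms Jaccard-normalize the co-term network (default
#'   FALSE: raw co-frequencies, while the co-institution network is always
#'   normalized).
#' @return a validated `run_config` list.
#' @export
run_config <- function(input_medline, input_pubtator = NULL, outdir,
                       granularity = "month", sigma = 0.1, k_max = 10,
                       min_df = 5, ngram_max = 3, resolution = 1.0,
                       seed = 1L, cutoff = NULL, target_disease = NULL,
                       ir_threshold = 0.5, cc_threshold = 0.5, top_k = 4,
                       entropy_mode = "standard",
                       alias_table = character(),
                       country_gazetteer = character(),
                       normalize_terms = FALSE) {
  stopifnot(sigma > 0, k_max >= 1, min_df >= 1, ngram_max %in% 1:3,
            resolution > 0, ir_threshold > 0, ir_threshold < 1,
            cc_threshold > 0, cc_threshold < 1, top_k >= 1,
            entropy_mode %in% c("standard", "literal"),
            granularity %in% c("month", "year"))
  if (!file.exists(input_medline)) {
    stop("config error: input_medline does not exist: ", input_medline,
         call. = FALSE)
  }
  if (!is.null(input_pubtator) && !file.exists(input_pubtator)) {
    stop("config error: input_pubtator does not exist: ", input_pubtator,
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full literature-profiling pipeline
#'
#' Parses the inputs, then emits the full report bundle under the configured
#' output directory: monthly trend, top-N country/institution/journal tables,
#' co-term and co-institution GraphML with communities, topic-evolution
#' GraphML + statistics + membership, and (when annotations are provided)
#' the cleaning report, category-pair edge tallies, per-category top-10
#' entity tables, the gene-profile table and the emerging-gene list. A
#' `manifest.json` records the configuration, seed, package version and an
#' md5 checksum per output. Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return invisibly, a named character vector of the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  written <- character(0)

  corp <- stage("parse", parse_medline(config$input_medline))

  trend <- stage("trend", monthly_trend(corp, cutoff = config$cutoff))
  write.csv(trend$series, out("monthly_trend.csv"), row.names = FALSE)
  written["monthly_trend"] <- out("monthly_trend.csv")

  aff <- stage("affiliations",
               corpus_affiliations(corp, config$alias_table,
                                   config$country_gazetteer))
  tabr <- records_table(corp)
  tops <- list(
    top_countries = top_n(aff$countries, 20),
    top_institutions = top_n(aff$institutions, 20),
    top_journals = top_n(as.list(tabr$journal[nzchar(tabr$journal)]), 20)
  )
  for (nm in names(tops)) {
    write.csv(tops[[nm]], out(paste0(nm, ".csv")), row.names = FALSE)
    written[nm] <- out(paste0(nm, ".csv"))
  }

  terms <- stage("terms", extract_terms(corp, min_df = config$min_df,
                                        ngram_max = config$ngram_max))
  term_sets <- lapply(terms$doc_terms, names)
  coterm <- stage("coterm", {
    net <- build_network(term_sets)
    if (config$normalize_terms) net <- jaccard_normalize(net)
    net
  })
  if (nrow(coterm$nodes)) {
    coterm$community <- detect_communities(coterm, config$resolution, config$seed)
  }
  export_graph(coterm, out("coterm.graphml"), "graphml")
  written["coterm"] <- out("coterm.graphml")

  coinst <- stage("coauthor", jaccard_normalize(build_network(aff$institutions)))
  if (nrow(coinst$nodes)) {
    coinst$community <- detect_communities(coinst, config$resolution, config$seed)
  }
  export_graph(coinst, out("coinstitution.graphml"), "graphml")
  written["coinstitution"] <- out("coinstitution.graphml")

  sepres <- stage("sep", {
    stream <- prepare_stream(corp, terms, granularity = config$granularity,
                             cutoff = config$cutoff)
    run_sep(stream, sigma = config$sigma, k_max = config$k_max,
            seed = config$seed)
  })
  export_sep(sepres, out("sep.graphml"), out("sep_membership.csv"))
  stats <- sep_statistics(sepres)
  write.csv(stats$topics, out("sep_statistics.csv"), row.names = FALSE)
  written["sep"] <- out("sep.graphml")
  written["sep_membership"] <- out("sep_membership.csv")
  written["sep_statistics"] <- out("sep_statistics.csv")

  if (!is.null(config$input_pubtator)) {
    res <- stage("bioentity", {
      mentions <- read_pubtator(config$input_pubtator)
      resolve_mentions(mentions)
    })
    write.csv(res$report, out("cleaning_report.csv"), row.names = FALSE)
    written["cleaning_report"] <- out("cleaning_report.csv")

    net <- stage("bioentity_network", build_hetero_network(res$doc_entities))
    export_hetero_graphml(net, out("bioentity.graphml"))
    written["bioentity_graph"] <- out("bioentity.graphml")
    tal <- edge_tallies(net)
    write.csv(data.frame(category = rownames(tal), tal), out("edge_tallies.csv"),
              row.names = FALSE)
    written["edge_tallies"] <- out("edge_tallies.csv")

    top_tabs <- lapply(c("disease", "chemical", "gene", "variant"), function(ct) {
      tr <- entity_frequency_trend(res$mention_table, corp, ct, top_k = 10)
      if (nrow(tr$totals)) cbind(category = ct, tr$totals) else NULL
    })
    write.csv(do.call(rbind, top_tabs), out("top_entities.csv"), row.names = FALSE)
    written["top_entities"] <- out("top_entities.csv")

    prof <- stage("rank_genes", {
      p <- gene_profiles(net, target_disease = config$target_disease,
                         entropy_mode = config$entropy_mode)
      emerging_map(p, config$ir_threshold, config$cc_threshold, config$top_k)
    })
    write.csv(prof$profiles, out("gene_profiles.csv"), row.names = FALSE)
    write.csv(prof$emerging, out("emerging_genes.csv"), row.names = FALSE)
    written["gene_profiles"] <- out("gene_profiles.csv")
    written["emerging_genes"] <- out("emerging_genes.csv")
  }

  manifest <- list(
    package = "bibliomine",
    version = as.character(packageVersion("bibliomine")),
    seed = config$seed,
    parameters = config[!(names(config) %in%
                            c("alias_table", "country_gazetteer"))],
    outputs = lapply(written, function(f)
      list(file = basename(f), md5 = unname(md5sum(f))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  written["manifest"] <- out("manifest.json")
  invisible(written)
}
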
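#!/usr/bin/env Rscript
# Descriptive profiling of the collaboration corpus: monthly publication
# trend, top-N rankings, and the Jaccard-normalized co-institution network
# with detected communities, checked against the planted community labels.
# Run analysis/01_simulate_corpora.R first.

library(bibliomine)

seed <- 1L
dir.create("results/profile", showWarnings = FALSE, recursive = TRUE)

corp <- parse_medline("results/data/collaboration.medline")
truth <- unlist(jsonlite::read_json("results/data/collaboration_truth.json"))

trend <- monthly_trend(corp)
write.csv(trend$series, "results/profile/monthly_trend.csv", row.names = FALSE)
message("monthly trend: ", sum(trend$series$count), " dated records (",
        trend$excluded, " excluded), ", nrow(trend$series), " months")

gaz <- c("United States", "China", "United Kingdom", "Australia",
         "Germany", "Canada")
aff <- corpus_affiliations(corp, country_gazetteer = setNames(gaz, gaz))
write.csv(top_n(aff$countries, 20), "results/profile/top_countries.csv",
          row.names = FALSE)
write.csv(top_n(aff$institutions, 20), "results/profile/top_institutions.csv",
          row.names = FALSE)

net <- jaccard_normalize(build_network(aff$institutions))
labels <- detect_communities(net, resolution = 1.0, seed = seed)
net$community <- labels
export_graph(net, "results/profile/coinstitution.graphml", "graphml")

ari <- mclust::adjustedRandIndex(truth[names(labels)], labels)
message(nrow(net$nodes), " institutions, ", nrow(net$edges), " edges, ",
        length(unique(labels)), " communities; ARI vs planted labels = ",
        round(ari, 3))

strongest <- names(sort(vapply(net$nodes$name, node_strength, 0, net = net),
                        decreasing = TRUE))[1:5]
message("strongest collaborators (sum of Jaccard weights): ",
        paste(strongest, collapse = ", "))
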
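#!/usr/bin/env Rscript
# Generate the three synthetic study corpora with planted ground truth:
# a topic stream with a 4-topic birth/split schedule, a collaboration corpus
# with 3 planted institution communities, and a bio-entity corpus with a
# planted hub gene and a planted disease-specific emerging gene.
# Inputs for the downstream steps land under results/data/.

library(bibliomine)

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

plan <- topic_plan(seed = seed)  # 4 topics over 6 monthly slices, noise 0.1
stream <- generate_topic_stream(plan)
write_medline(stream$corpus, "results/data/topic_stream.medline")
jsonlite::write_json(
  list(doc_topic = as.list(stream$truth$doc_topic),
       lineage = stream$truth$lineage),
  "results/data/topic_stream_truth.json", auto_unbox = TRUE)
message("topic stream: ", length(stream$corpus), " records, ",
        length(plan$births), " planted topics")

collab <- generate_collaboration(p_in = 0.9, p_out = 0.05, seed = seed)
write_medline(collab$corpus, "results/data/collaboration.medline")
jsonlite::write_json(as.list(collab$truth),
                     "results/data/collaboration_truth.json", auto_unbox = TRUE)
message("collaboration corpus: ", length(collab$corpus), " records, ",
        length(unique(collab$truth)), " planted communities")

bio <- generate_bioentity_corpus(n_docs = 300L, seed = seed)
write_medline(bio$corpus, "results/data/bioentity.medline")
writeLines(bio$pubtator, "results/data/bioentity.pubtator")
jsonlite::write_json(bio$truth[c("hub", "specific", "target",
                                 "hub_symbol", "specific_symbol")],
                     "results/data/bioentity_truth.json", auto_unbox = TRUE)
message("bio-entity corpus: ", length(bio$corpus), " records; hub = ",
        bio$truth$hub_symbol, ", specific = ", bio$truth$specific_symbol)
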
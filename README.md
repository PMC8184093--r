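# bibliomine

Intelligent-bibliometrics tooling for profiling a biomedical research field
from its literature. Given publication records (MEDLINE flat files) and
bio-entity annotations (PubTator raw format), the package answers four
questions about a field such as COVID-19 genetic research:

1. **Who are the key players?** Affiliation cleaning, country/institution/
   journal rankings, and a co-authorship network normalized by the Jaccard
   coefficient `J(i,j) = CF(i,j) / (F(i) + F(j) − CF(i,j))`, with
   Louvain-style community detection.
2. **What are the main topics?** A co-term network over cleaned title +
   abstract n-grams.
3. **How do research foci drift?** A streaming topic-evolution tracker:
   documents arrive in time slices, each is matched to the cosine-nearest
   topic centroid and *drifts* when `(E − r)/r > σ` (Euclidean distance E,
   topic radius r, threshold σ = 0.1); drifted documents are clustered into
   descendant topics, yielding a directed topic lineage graph.
4. **Which genes are established vs emerging?** A heterogeneous
   disease–chemical–gene–variant co-occurrence network; degree, closeness
   and betweenness centralities combined with entropy-derived weights
   `w = (1 − H)/(3 − ΣH)`; disease specificity as the intersection ratio
   `IR(v) = w(v, target)/Σ_d w(v, d)`; and a quadrant map of genes whose
   high-IR, high-centrality corner (minus the top-k "frequently
   highlighted" genes) is the emerging-gene list.

It is organized as an analysis workflow: every computation lives in the
package (`R/`), and the numbered scripts under `analysis/` are thin drivers
that generate synthetic study corpora with planted ground truth, run each
stage, and write tables and graphs under `results/`. Everything works
offline: synthetic generators and small bundled dictionary fixtures stand
in for live database access.

## Worked example

```r
library(bibliomine)

# a synthetic literature corpus with a planted hub gene (ACE2) and a
# planted emerging, target-disease-specific gene (ISG15)
gen <- generate_bioentity_corpus(n_docs = 300, seed = 1)
res <- resolve_mentions(read_pubtator(gen$pubtator))
net <- build_hetero_network(res$doc_entities)
net
#> <hetero_network> 67 nodes (chemical=15, disease=20, gene=23, variant=9), 644 edges

prof <- gene_profiles(net, target_disease = gen$truth$target)
round(attr(prof, "weights"), 3)
#>    dc    cc    bc
#> 0.160 0.074 0.767

em <- emerging_map(prof, ir_threshold = 0.5, cc_threshold = 0.5, top_k = 4)
em$highlighted
#> [1] "ACE2"    "TNF"     "IL6"     "TMPRSS2"
em$emerging$symbol
#> [1] "ISG15"
intersection_ratio(net, gen$truth$specific, gen$truth$target)
#> [1] 1
```

The entropy weights say betweenness is the most concentrated (hence most
discriminating) centrality on this network, so it dominates the combined
score. The four broadest genes are flagged as frequently highlighted; the
planted specific gene has intersection ratio exactly 1 (its only disease
co-mention is the target) and lands in the emerging list.

Topic evolution on a planted 4-topic birth/split stream:

```r
gen <- generate_topic_stream(topic_plan(seed = 1))  # 1,200 docs, 6 slices
terms <- extract_terms(gen$corpus, min_df = 3, ngram_max = 1)
graph <- run_sep(prepare_stream(gen$corpus, terms, "month"),
                 sigma = 0.1, seed = 1)
graph
#> <sep_graph> 4 topics, 5 lineage edges over 1200 documents
sep_statistics(graph)$largest
#> [1] "block1term030 [2020-01] — 450" "block2term018 [2020-03] — 300"
#> [3] "block3term036 [2020-03] — 300" "block4term025 [2020-05] — 150"
```

All four planted topics are recovered at their planted birth slices with
their lineage edges (document-to-topic adjusted Rand index 1.0 on this
seed).

## The analysis workflow

```sh
Rscript analysis/01_simulate_corpora.R     # synthetic corpora + ground truth
Rscript analysis/02_profile_corpus.R       # trend, rankings, co-institution communities
Rscript analysis/03_topic_evolution.R      # topic lineage graph + statistics
Rscript analysis/04_gene_prioritization.R  # bio-entity network, emerging genes
Rscript analysis/05_full_pipeline.R        # one-stop seeded run with manifest
```

Outputs (CSV tables, GraphML graphs, a checksummed `manifest.json`) land
under `results/`.

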
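---
title: "Profiling a biomedical research field from its literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a biomedical research field from its literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bibliomine)
```

bibliomine profiles a fast-moving biomedical research field — the motivating
case is COVID-19 genetic research — from its publication record alone. It
answers four kinds of questions: who the key players are (institutions,
countries), what the field's main topics are, how research foci drift over
time, and which genes the literature treats as established versus emerging
for a target disease. Three method families carry this: co-occurrence
network analysis, a streaming topic-evolution tracker, and a heterogeneous
bio-entity network with an entropy-weighted gene ranking. This vignette
explains each model, its assumptions and tunable parameters, the synthetic
study corpora the package tests itself on, and the design decisions taken
where the methods leave choices open.

## Corpus ingestion and cleaning

Records enter as MEDLINE flat files (`parse_medline()`), the export format
of PubMed. Only the fields the analyses need are read: PMID, title,
abstract, journal, publication date, affiliations, MeSH terms. Publication
dates are parsed permissively — "2020 Jun", "2020 June" and "2020 06" all
give month 6 — while season or quarter dates leave the month absent, and a
record with a month is required to have a year. Records without a PMID are
skipped and counted; duplicate PMIDs keep the first occurrence, so
ingestion is order-stable.

Terms come from titles and abstracts (`extract_terms()`): lowercase word
n-grams up to length 3, after removal of a compact English stopword list
and suffix-rule plural folding (`-ies` to `-y`; `-ses`/`-xes`/`-zes`/
`-ches`/`-shes` drop `-es`; other trailing `-s` dropped except after
`-ss`/`-us`/`-is`). Terms below a document-frequency floor `min_df`
(default 5) are discarded. These rules are a deliberately simple, fully
reproducible stand-in for the heavier disambiguation real bibliometric
platforms apply; the suffix rules occasionally overfold an irregular noun,
which costs display polish but no correctness, since folding is applied
consistently on both sides of every comparison.

Affiliations are cleaned by a two-step rule (`clean_affiliations()`): an
alias table maps known institution variants to canonical names; otherwise
the first comma-separated segment containing an institutional keyword
(University, College, Hospital, Institute, Academy, Center/Centre) is
taken. The country is the last gazetteer match in the string, which is
where addresses put it. Strings resolving to neither are reported in a
cleaning log rather than silently dropped. No public specification exists
for the affiliation disambiguation behind published institution rankings,
so this rule set is a documented stand-in, not a reconstruction.

## Co-occurrence networks

For any per-document entity sets (terms, institutions), `build_network()`
sets node frequency `F(i)` to the number of documents containing entity
*i* and edge co-frequency `CF(i,j)` to the number containing both; an edge
exists iff `CF >= 1`. Co-authorship-style networks are normalized by the
Jaccard coefficient

$$ J(i,j) = \frac{CF(i,j)}{F(i) + F(j) - CF(i,j)}, $$

the overlap of the two entities' document sets: symmetric, in (0, 1], and
equal to 1 exactly when the two entities occur in the same documents. This
removes the scale advantage of prolific institutions. Co-term networks
keep raw co-frequencies by default (`normalize_terms = FALSE` in the
pipeline), mirroring the convention that term maps are weighted by counts
while collaboration maps are normalized; a node's collaborative strength
is the sum of its incident Jaccard weights (`node_strength()`).

Communities are found by Louvain-style greedy modularity optimization
(`detect_communities()`, via igraph) on the edge weights, with a
resolution parameter (default 1.0) and an explicit seed; labels are
contiguous integers from 0. An optional minimum-community-size floor
merges undersized communities into their best-connected neighbor (default
disabled). The exact clustering variant used by interactive mapping tools
is not recoverable from their published defaults, so community *counts* on
real corpora are treated as qualitative; the package instead verifies
recovery against planted partitions and against brute-force modularity
maximization on small fixtures. Graphs export losslessly to GraphML,
Pajek (.net plus a .clu membership file) and CSV edge lists; layout and
rendering are left to external viewers.

## Topic evolution over a document stream

The tracker treats each document as a term vector and the corpus as a
stream of time slices (monthly or yearly). Vectors are term-frequency
weighted and L2-normalized (`prepare_stream()`); documents containing no
vocabulary term are dropped with a logged count. A topic *T* carries a
centroid *c* (the mean vector of its members), a radius *r* (the largest
Euclidean distance from the centroid to a member), and a label (the
top-frequency term among members, ties broken lexicographically).

The stream is processed batch-per-slice:

1. All documents of slice 0 form the initial topic.
2. Each document of a later slice is matched to its candidate topic — the
   centroid with the highest cosine similarity; slice 1 can only see the
   initial topic.
3. The document **drifts** when its Euclidean distance *E* to that
   centroid satisfies `(E - r) / r > sigma` (default `sigma = 0.1`);
   otherwise it is assigned to the candidate.
4. At slice end, assigned documents update their topics (centroid, radius
   and label recomputed over the full membership), and the slice's drifted
   documents are clustered by k-means into descendant topics, each linked
   by a directed lineage edge from every parent whose rejected documents
   feed it.

Two readings in the method's original description required a decision.
First, the slice indices of the worked steps are off by one against each
other; the only consistent reading — slice-1 documents tested against the
slice-0 topic, updates applied once per slice — is implemented. Second,
candidate matching uses cosine similarity while the drift test is
Euclidean. With L2-normalized document vectors these are rank-equivalent
against any fixed centroid direction (E² = 2 − 2·cos for unit vectors),
because cosine ignores centroid length; the test suite asserts this
equivalence. The threshold semantics remain Euclidean, as printed.

Numerical choices:

* **Zero radius.** A topic of identical members has `r = 0` and the drift
  ratio is undefined; any departure beyond `eps = 1e-9` counts as drift.
* **Choosing K.** The number of descendant topics per slice is selected by
  the best mean silhouette over K = 2..min(`k_max`, n−1), with k-means++
  seeding, 10 restarts and a fixed seed. K-means will split even a
  homogeneous cloud of term vectors with a *weakly positive* silhouette
  (around 0.05 on multinomial unit vectors), while genuinely separate
  vocabulary blocks score several-fold higher, so a split is accepted only
  when the best silhouette reaches `min_silhouette` (default 0.1); below
  it, or with fewer than 3 drifted documents, the drifted set forms a
  single descendant. A nonpositive bar, by contrast, fragments every
  drift set and cascades: tiny descendants have tiny radii and reject all
  later same-topic documents.
* **Determinism.** Identical stream, seed and parameters give identical
  lineage graphs; per-slice k-means seeds are derived from the run seed.

Raising `sigma` only ever removes drift events, so the final topic count
is non-increasing in `sigma` on a fixed stream — a property the suite
checks. Summary statistics (`sep_statistics()`) report topic count,
extreme member counts and the *population* standard deviation of member
counts, plus `label [birth slice] — count` listings.

## Heterogeneous bio-entity network and gene prioritization

Entity mentions arrive in PubTator raw format (`read_pubtator()`):
diseases, chemicals, genes, and genetic variants (Mutation/SNP/DNAMutation/
ProteinMutation all map to the variant category; other types are dropped
with a count). Cleaning (`resolve_mentions()`) keeps diseases and
chemicals only when their identifier maps to a MeSH dictionary entry,
genes only when present in the Homo sapiens gene list, and DNA/protein
mutations only when they map to an rsID, merging them with explicit SNP
mentions under that rsID. The package ships small synthetic dictionary
fixtures (35 MeSH descriptors, 32 genes, 20 rsIDs) carrying real entity
names so outputs read naturally; full MeSH/NCBI/dbSNP files can be
supplied instead. The cleaning report (raw / cleaned / unique per
category) mirrors the stepwise shape such studies publish.

`build_hetero_network()` links two resolved entities with weight equal to
their co-document count, keeping intra- and inter-category edges and
isolated nodes. Category-pair edge tallies count each unordered edge once
(the diagonal therefore counts within-category pairs once, a documented
choice where conventions differ), and their sum over the upper triangle
plus diagonal equals the edge count.

Three centralities are computed on the **unweighted skeleton** (weights
serve edge existence and the intersection ratio; distances are hop
counts):

* degree centrality `DC(v)` — distinct neighbors over `|V| − 1`;
* closeness centrality `CC(v)` — on connected graphs `(|V|−1)/Σd`; on
  disconnected graphs the Wasserman–Faust correction
  `(reach/(|V|−1)) · (reach/Σd_reach)`, which reduces to the plain formula
  when everything is reachable and gives isolated nodes 0;
* betweenness centrality `BC(v)` — the fraction of shortest paths over
  unordered pairs passing through *v*, normalized by `(|V|−1)(|V|−2)/2`,
  computed by Brandes' accumulation and verified against exhaustive
  path-counting oracles.

The three are min-max normalized over all nodes and combined with
entropy weights: less dispersed (more discriminating) centralities earn
larger weights via `w = (1 − H)/(3 − ΣH)`. The printed form of this
classical construction applies the entropy to the min-max values directly,
which can push `H` above 1 and make weights negative; the default
`"standard"` mode therefore converts each normalized set to proportions
before the entropy (keeping `H` in [0, 1] and the weights a convex
combination), while a `"literal"` mode evaluates the formula exactly as
printed. A centrality constant across all nodes has no min-max
normalization; it receives weight 0 and the remaining weights renormalize,
with a message.

Disease specificity is the intersection ratio
`IR(v) = w(v, target) / Σ_d w(v, d)` over disease neighbors — 1 when the
target disease is the only disease the entity is ever co-mentioned with,
0 (flagged) when it has no disease edges. `emerging_map()` min-max
normalizes IR (x-axis) and the combined centrality (y-axis) over genes and
splits the plane at configurable thresholds (default 0.5/0.5). The
"frequently highlighted" set is the top `top_k` genes by combined
centrality (default 4, the size such studies typically name); the
emerging list is the quadrant-I genes (both axes high) minus the
highlighted set, ranked by normalized IR then combined score. Raw entity
frequency (`entity_frequency_trend()`) counts mentions by default — the
most plausible reading of "raw frequency" — with a document-frequency
switch.

## Synthetic study corpora

Every stage is testable offline against generators whose plants define the
expected outcome (`generate_topic_stream()`, `generate_collaboration()`,
`generate_bioentity_corpus()`); all are pure functions of their parameters
and seed.

* **Topic stream.** Each planted topic owns a disjoint 40-term vocabulary
  block and emits 75 documents of 30 tokens per monthly slice from its
  birth slice on; a token comes from the topic's block with probability
  0.9 and from the global vocabulary otherwise (noise 0.1). The default
  schedule plants 4 topics over 6 slices — a root at slice 0, two children
  born at slice 2, a grandchild at slice 4 (~1,200 documents) — sizes
  chosen so drift, spawning and lineage recovery are all exercised while a
  10-seed recovery experiment runs in seconds per seed.
* **Collaboration corpus.** 30 institutions in 3 planted communities, 200
  documents; a document from a community includes each member with
  probability `sqrt(p_in)` and outsiders with `p_out / sqrt(p_in)`, so
  within-community pairs co-occur with probability `p_in = 0.9` and cross
  pairs with about `p_out = 0.05`. Affiliation strings carry real-looking
  department/institution/city/country segments so the full cleaning path
  is exercised.
* **Bio-entity corpus.** 300 documents drawing entities from the bundled
  dictionaries, with a three-tier gene plant that mirrors the shape of
  disease-gene literature: one hub gene in half the thematic documents
  (broadest co-occurrence — the top combined centrality), three
  "frequently highlighted" genes at half the hub's presence, and one
  emerging gene that is (a) never mentioned with any disease but the
  target, forcing IR = 1, and (b) the exclusive bridge to its two private
  variants, keeping its centrality high but below the highlighted tier.
  Each gene of interest owns private variants reachable only through it —
  the pattern of variant-mapping studies. A non-human gene and a Species
  annotation exercise the cleaning rules.

What the generators deliberately do **not** emulate: realistic vocabulary
burstiness and topical overlap (blocks are disjoint; real topics share
terms), citation structure, affiliation noise (typos, multi-country
institutions), entity-recognition errors (mentions are planted with exact
identifiers), and publishing-lag truncation. Passing tests therefore show
the algorithms recover structure that is genuinely present under the
stated noise — not that the method's thresholds are tuned for any real
corpus.

## Problem sizes and budgets

The shipped analyses and tests run at deliberately small scale: ~1,200
stream documents, 200 collaboration documents, 300 bio-entity documents,
random oracle graphs of 6–30 nodes. These sizes make the 10-seed recovery
experiments and the exhaustive oracles (all-pairs shortest-path counting;
brute-force modularity over all bipartitions of 8 nodes) fast enough to
re-run on every change, while leaving every code path — drift, spawning,
merging, disconnected closeness, degenerate entropy sets — exercised.

## Known limitations

* The term-cleaning rules are intentionally simple; on real corpora a
  curated thesaurus would change vocabularies and hence topic labels.
* Headline counts published for any particular real corpus (total
  records, topic counts, entity counts) depend on live database queries,
  neural entity extraction and full dictionary versions, none of which
  this package reproduces; its claims are the structural and formula-level
  properties its tests compute.
* The emerging-gene map inherits the instability of betweenness
  centrality on dense networks; entropy weighting typically concentrates
  weight on betweenness precisely because it is the most dispersed
  centrality, so small co-occurrence changes can reorder mid-table genes.
  The quadrant thresholds (0.5/0.5 on normalized axes) and the highlighted
  set size are configurable for this reason.
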
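#' Load the bundled synthetic dictionary fixtures
#'
#' Small tab-separated dictionaries shipped with the package stand in for
#' the full MeSH descriptor file, the NCBI Homo sapiens gene list and a
#' dbSNP rsID list. They carry real entity names (ACE2, TMPRSS2, rs2285666,
#' ...) so outputs read naturally, but they are fixtures, not the full
#' resources.
#'
#' @param which one of `"mesh"`, `"genes"`, `"snps"`.
#' @param path optional path to a user-supplied TSV with the same columns.
#' @return data.frame. Columns: mesh (`mesh_id`, `name`, `category`);
#'   genes (`gene_id`, `symbol`, `tax_id`); snps (`rsid`, `alias`).
#' @export
load_dictionary <- function(which = c("mesh", "genes", "snps"), path = NULL) {
  which <- match.arg(which)
  file <- path %||% system.file("extdata",
                                paste0(which, "_dictionary_synthetic.tsv"),
                                package = "bibliomine", mustWork = TRUE)
  read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
}

#' Resolve raw mentions to cleaned bio-entities
#'
#' Applies the dictionary cleaning rules: diseases and chemicals are kept
#' only when their identifier maps to a MeSH entry of the same category;
#' genes only when present in the Homo sapiens gene dictionary; DNA/protein
#' mutation mentions only when they map to an rsID (via the alias column),
#' after which they merge with explicit SNP mentions under that rsID.
#' Everything unresolved is counted, never fatal.
#'
#' @param mentions data.frame from [read_pubtator()].
#' @param mesh_dict,gene_dict,snp_dict dictionaries as from
#'   [load_dictionary()].
#' @return list with
#'   * `mention_table`: resolved mentions (pmid, entity_id, name, category);
#'   * `doc_entities`: named list pmid -> data.frame(entity_id, name,
#'     category) of unique entities per document;
#'   * `report`: data.frame (category, raw, cleaned, unique) in the shape of
#'     a stepwise cleaning table.
#' @export
resolve_mentions <- function(mentions, mesh_dict = load_dictionary("mesh"),
                             gene_dict = load_dictionary("genes"),
                             snp_dict = load_dictionary("snps")) {
  norm_id <- sub("^(MESH|mesh):", "", mentions$raw_id)
  entity_id <- rep(NA_character_, nrow(mentions))
  name <- rep(NA_character_, nrow(mentions))

  for (cat in c("disease", "chemical")) {
    dict <- mesh_dict[mesh_dict$category == cat, , drop = FALSE]
    sel <- mentions$category == cat
    hit <- match(norm_id, dict$mesh_id)
    use <- sel & !is.na(hit)
    entity_id[use] <- dict$mesh_id[hit[use]]
    name[use] <- dict$name[hit[use]]
  }

  human <- gene_dict[gene_dict$tax_id == "9606", , drop = FALSE]
  sel <- mentions$category == "gene"
  hit <- match(mentions$raw_id, human$gene_id)
  use <- sel & !is.na(hit)
  entity_id[use] <- human$gene_id[hit[use]]
  name[use] <- human$symbol[hit[use]]

  sel <- mentions$category == "variant"
  rs_direct <- sel & mentions$raw_id %in% snp_dict$rsid
  entity_id[rs_direct] <- mentions$raw_id[rs_direct]
  alias <- snp_dict[nzchar(snp_dict$alias) & snp_dict$alias != "-", , drop = FALSE]
  hit_id <- match(mentions$raw_id, alias$alias)
  hit_tx <- match(mentions$text, alias$alias)
  hit <- ifelse(is.na(hit_id), hit_tx, hit_id)
  use <- sel & !rs_direct & !is.na(hit)
  entity_id[use] <- alias$rsid[hit[use]]
  name[sel & !is.na(entity_id)] <- entity_id[sel & !is.na(entity_id)]

  resolved <- !is.na(entity_id)
  mention_table <- data.frame(
    pmid = mentions$pmid[resolved],
    entity_id = entity_id[resolved],
    name = name[resolved],
    category = mentions$category[resolved],
    stringsAsFactors = FALSE
  )

  doc_entities <- lapply(split(mention_table, mention_table$pmid), function(d) {
    u <- unique(d[, c("entity_id", "name", "category")])
    rownames(u) <- NULL
    u
  })

  cats <- c("disease", "chemical", "gene", "variant")
  report <- data.frame(
    category = cats,
    raw = vapply(cats, function(ct) sum(mentions$category == ct), 0L),
    cleaned = vapply(cats, function(ct) sum(mention_table$category == ct), 0L),
    unique = vapply(cats, function(ct)
      length(unique(mention_table$entity_id[mention_table$category == ct])), 0L),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(mention_table = mention_table, doc_entities = doc_entities,
       report = report)
}
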
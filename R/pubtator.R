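PUBTATOR_TYPE_MAP <- c(
  Disease = "disease", Chemical = "chemical", Gene = "gene",
  Mutation = "variant", SNP = "variant",
  DNAMutation = "variant", ProteinMutation = "variant"
)

#' Parse PubTator raw annotation format
#'
#' The format alternates `PMID|t|title` / `PMID|a|abstract` lines with
#' tab-delimited annotation lines `pmid<TAB>start<TAB>end<TAB>text<TAB>type
#' <TAB>identifier`. Types are mapped onto the four bio-entity categories
#' (Disease, Chemical, Gene; Mutation/SNP/DNAMutation/ProteinMutation all
#' map to variant); other types are dropped and counted.
#'
#' @param input path to a PubTator file, or a character vector of its lines.
#' @return data.frame of mentions: `pmid`, `start`, `end`, `text`,
#'   `type_raw`, `category`, `raw_id`. Attributes `n_dropped_type` (out of
#'   scope types) and `n_malformed` (skipped lines).
#' @export
read_pubtator <- function(input) {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input, warn = FALSE) else input
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  is_text <- grepl("^[^\t|]+\\|[ta]\\|", lines)
  ann <- lines[!is_text]
  rows <- strsplit(ann, "\t", fixed = TRUE)
  ok <- lengths(rows) >= 6
  n_malformed <- sum(!ok)
  if (n_malformed) {
    warning(n_malformed, " malformed PubTator annotation line(s) skipped",
            call. = FALSE)
  }
  rows <- rows[ok]
  if (!length(rows)) {
    out <- data.frame(pmid = character(), start = integer(), end = integer(),
                      text = character(), type_raw = character(),
                      category = character(), raw_id = character())
    attr(out, "n_dropped_type") <- 0L
    attr(out, "n_malformed") <- n_malformed
    return(out)
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    pmid = m[, 1],
    start = suppressWarnings(as.integer(m[, 2])),
    end = suppressWarnings(as.integer(m[, 3])),
    text = m[, 4],
    type_raw = m[, 5],
    category = unname(PUBTATOR_TYPE_MAP[m[, 5]]),
    raw_id = m[, 6],
    stringsAsFactors = FALSE
  )
  n_dropped <- sum(is.na(out$category))
  out <- out[!is.na(out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_type") <- n_dropped
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Write mentions (plus document text) in PubTator raw format
#'
#' Inverse of [read_pubtator()] for fixture generation and round trips.
#'
#' @param docs data.frame with `pmid`, `title`, `abstract`.
#' @param mentions data.frame as returned by [read_pubtator()] (`type_raw`
#'   is written as the annotation type).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(docs, mentions, path) {
  out <- character(0)
  for (i in seq_len(nrow(docs))) {
    pm <- docs$pmid[i]
    out <- c(out,
             paste0(pm, "|t|", docs$title[i]),
             paste0(pm, "|a|", docs$abstract[i]))
    sel <- mentions[mentions$pmid == pm, , drop = FALSE]
    if (nrow(sel)) {
      out <- c(out, paste(sel$pmid, sel$start, sel$end, sel$text,
                          sel$type_raw, sel$raw_id, sep = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
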
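#' Parse a MEDLINE flat file into a corpus
#'
#' Reads the tagged flat-file export format used by PubMed (fields `PMID`,
#' `TI`, `AB`, `JT`, `AD`, `DP`, `MH`; continuation lines indented). Records
#' are separated by blank lines and kept in file order.
#'
#' The `DP` (date of publication) field is parsed into `pub_year` and, when a
#' month is present, `pub_month`. Month names ("Jun", "June") and numerals
#' ("06") are accepted; season or quarter dates leave the month absent.
#'
#' Blocks without a `PMID` are skipped with a warning and counted; duplicate
#' PMIDs keep the first occurrence.
#'
#' @param input path to a MEDLINE file, or a character vector of its lines.
#' @param provenance free-text note stored on the corpus.
#' @return A `corpus` object: a list with `records` (list of publication
#'   records) and `provenance`. Attributes `n_skipped` and `n_duplicates`
#'   carry the counts of dropped blocks.
#' @export
parse_medline <- function(input, provenance = "medline") {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input, warn = FALSE) else input
  blocks <- split_blocks(lines)
  records <- list()
  pmids_seen <- character()
  n_skipped <- 0L
  n_dup <- 0L
  for (block in blocks) {
    fields <- parse_medline_block(block)
    pmid <- fields[["PMID"]][1]
    if (is.null(pmid) || is.na(pmid) || !nzchar(pmid)) {
      warning("MEDLINE block without PMID skipped", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    if (pmid %in% pmids_seen) {
      warning("duplicate PMID ", pmid, ": keeping first occurrence", call. = FALSE)
      n_dup <- n_dup + 1L
      next
    }
    pmids_seen <- c(pmids_seen, pmid)
    dp <- parse_dp(fields[["DP"]][1])
    records[[length(records) + 1L]] <- publication_record(
      pmid = pmid,
      title = fields[["TI"]][1] %|NA|% "",
      abstract = fields[["AB"]][1] %|NA|% "",
      journal = fields[["JT"]][1] %|NA|% "",
      pub_year = dp$year,
      pub_month = dp$month,
      affiliations = fields[["AD"]] %||% character(),
      mesh_terms = fields[["MH"]] %||% character()
    )
  }
  structure(
    list(records = records, provenance = provenance),
    n_skipped = n_skipped, n_duplicates = n_dup,
    class = "corpus"
  )
}

`%|NA|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

split_blocks <- function(lines) {
  lines <- sub("\r$", "", lines)
  is_blank <- !nzchar(trimws(lines))
  grp <- cumsum(is_blank)
  blocks <- split(lines[!is_blank], grp[!is_blank])
  Filter(length, unname(blocks))
}

parse_medline_block <- function(block) {
  tag_re <- "^([A-Z][A-Z0-9]{0,3})\\s*- "
  tags <- character(0)
  vals <- character(0)
  for (line in block) {
    if (grepl(tag_re, line)) {
      tags <- c(tags, sub(paste0(tag_re, ".*$"), "\\1", line))
      vals <- c(vals, sub(tag_re, "", line))
    } else if (length(vals) && grepl("^\\s+", line)) {
      vals[length(vals)] <- paste(vals[length(vals)], trimws(line))
    }
  }
  split(vals, factor(tags, levels = unique(tags)))
}

MONTH_NAMES <- c(jan = 1, feb = 2, mar = 3, apr = 4, may = 5, jun = 6,
                 jul = 7, aug = 8, sep = 9, oct = 10, nov = 11, dec = 12)

parse_dp <- function(dp) {
  if (is.null(dp) || is.na(dp) || !nzchar(trimws(dp))) {
    return(list(year = NA_integer_, month = NA_integer_))
  }
  toks <- strsplit(trimws(dp), "[ -]+")[[1]]
  year <- suppressWarnings(as.integer(toks[grepl("^[0-9]{4}$", toks)][1]))
  month <- NA_integer_
  for (tok in toks[-1]) {
    low <- tolower(substr(tok, 1, 3))
    if (low %in% names(MONTH_NAMES)) {
      month <- as.integer(MONTH_NAMES[[low]])
      break
    }
    if (grepl("^[0-9]{1,2}$", tok) && as.integer(tok) >= 1 && as.integer(tok) <= 12) {
      month <- as.integer(tok)
      break
    }
  }
  if (is.na(year)) month <- NA_integer_
  list(year = year, month = month)
}

publication_record <- function(pmid, title = "", abstract = "", journal = "",
                               pub_year = NA_integer_, pub_month = NA_integer_,
                               affiliations = character(), mesh_terms = character()) {
  stopifnot(nzchar(pmid))
  if (!is.na(pub_month) && is.na(pub_year)) {
    stop("pub_month present requires pub_year", call. = FALSE)
  }
  structure(
    list(pmid = pmid, title = title, abstract = abstract, journal = journal,
         pub_year = as.integer(pub_year), pub_month = as.integer(pub_month),
         affiliations = affiliations, mesh_terms = mesh_terms),
    class = "publication_record"
  )
}

#' Build a corpus from a list of publication records
#' @param records list of records created by the parser or a generator.
#' @param provenance free-text source note.
#' @return A `corpus` object.
#' @export
corpus <- function(records, provenance = "") {
  pmids <- vapply(records, `[[`, "", "pmid")
  if (anyDuplicated(pmids)) stop("duplicate pmids in corpus", call. = FALSE)
  structure(list(records = records, provenance = provenance), class = "corpus")
}

#' @export
length.corpus <- function(x) length(x$records)

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus> ", length(x$records), " records",
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"), "\n", sep = "")
  invisible(x)
}

#' Tabulate the scalar fields of a corpus
#' @param x a `corpus`.
#' @return data.frame with one row per record (pmid, title, abstract, journal,
#'   pub_year, pub_month).
#' @export
records_table <- function(x) {
  stopifnot(inherits(x, "corpus"))
  data.frame(
    pmid = vapply(x$records, `[[`, "", "pmid"),
    title = vapply(x$records, `[[`, "", "title"),
    abstract = vapply(x$records, `[[`, "", "abstract"),
    journal = vapply(x$records, `[[`, "", "journal"),
    pub_year = vapply(x$records, `[[`, NA_integer_, "pub_year"),
    pub_month = vapply(x$records, `[[`, NA_integer_, "pub_month"),
    stringsAsFactors = FALSE
  )
}

#' Write a corpus back to MEDLINE flat-file format
#'
#' Covers the fields the parser reads (PMID/TI/AB/JT/DP/AD/MH); used for
#' fixtures and round-trip checks.
#' @param x a `corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  out <- character(0)
  for (rec in x$records) {
    out <- c(out, paste0("PMID- ", rec$pmid))
    if (nzchar(rec$title)) out <- c(out, paste0("TI  - ", rec$title))
    if (nzchar(rec$abstract)) out <- c(out, paste0("AB  - ", rec$abstract))
    if (nzchar(rec$journal)) out <- c(out, paste0("JT  - ", rec$journal))
    if (!is.na(rec$pub_year)) {
      dp <- as.character(rec$pub_year)
      if (!is.na(rec$pub_month)) {
        dp <- paste(dp, c("Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul",
                          "Aug", "Sep", "Oct", "Nov", "Dec")[rec$pub_month])
      }
      out <- c(out, paste0("DP  - ", dp))
    }
    for (ad in rec$affiliations) out <- c(out, paste0("AD  - ", ad))
    for (mh in rec$mesh_terms) out <- c(out, paste0("MH  - ", mh))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
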
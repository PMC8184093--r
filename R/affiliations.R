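INSTITUTION_KEYWORDS <- c("University", "College", "Hospital", "Institute",
                          "Academy", "Center", "Centre")

#' Clean raw affiliation strings into (institution, country) pairs
#'
#' Each affiliation string yields at most one pair. The institution is the
#' alias-table hit when one applies, otherwise the first comma-separated
#' segment containing an institutional keyword (University, College,
#' Hospital, Institute, Academy, Center/Centre). The country is the last
#' gazetteer match in the string. Unmatched parts are `NA` and reported in
#' the cleaning log attached as attribute `"log"`.
#'
#' @param affiliations character vector of raw affiliation strings (or a
#'   single publication record, whose `affiliations` field is used).
#' @param alias_table named character vector mapping raw institution variants
#'   to canonical names (may be empty).
#' @param country_gazetteer named character vector mapping surface forms to
#'   canonical country names (e.g. `c("UK" = "United Kingdom")`); an unnamed
#'   vector is treated as mapping each country to itself.
#' @return data.frame with columns `affiliation`, `institution`, `country`;
#'   attribute `"log"` holds lines describing unresolved strings.
#' @export
clean_affiliations <- function(affiliations, alias_table = character(),
                               country_gazetteer = character()) {
  if (inherits(affiliations, "publication_record")) {
    affiliations <- affiliations$affiliations
  }
  if (length(country_gazetteer) && is.null(names(country_gazetteer))) {
    names(country_gazetteer) <- country_gazetteer
  }
  inst <- rep(NA_character_, length(affiliations))
  ctry <- rep(NA_character_, length(affiliations))
  log <- character(0)
  kw_re <- paste0("\\b(", paste(INSTITUTION_KEYWORDS, collapse = "|"), ")\\b")
  for (i in seq_along(affiliations)) {
    s <- affiliations[i]
    hit <- NA_character_
    for (raw in names(alias_table)) {
      if (grepl(raw, s, fixed = TRUE)) {
        hit <- unname(alias_table[raw])
        break
      }
    }
    if (is.na(hit)) {
      segs <- trimws(strsplit(s, ",")[[1]])
      kw <- segs[grepl(kw_re, segs)]
      if (length(kw)) hit <- kw[1]
    }
    inst[i] <- hit
    last_pos <- -1L
    for (surface in names(country_gazetteer)) {
      m <- gregexpr(paste0("\\b", surface, "\\b"), s)[[1]]
      pos <- m[length(m)]
      if (pos > last_pos) {
        last_pos <- pos
        ctry[i] <- unname(country_gazetteer[surface])
      }
    }
    if (is.na(inst[i]) || is.na(ctry[i])) {
      log <- c(log, sprintf("unresolved %s: %s",
                            paste(c("institution", "country")[c(is.na(inst[i]), is.na(ctry[i]))],
                                  collapse = "+"), s))
    }
  }
  structure(
    data.frame(affiliation = affiliations, institution = inst, country = ctry,
               stringsAsFactors = FALSE),
    log = log
  )
}

#' Per-document institution and country sets for a whole corpus
#'
#' @inheritParams clean_affiliations
#' @param x a `corpus`.
#' @return list with `institutions` and `countries`: named lists
#'   (pmid -> unique character vector), plus a combined cleaning `log`
#'   attribute on the result.
#' @export
corpus_affiliations <- function(x, alias_table = character(),
                                country_gazetteer = character()) {
  stopifnot(inherits(x, "corpus"))
  insts <- list()
  ctrys <- list()
  logs <- character(0)
  for (rec in x$records) {
    cl <- clean_affiliations(rec$affiliations, alias_table, country_gazetteer)
    insts[[rec$pmid]] <- unique(cl$institution[!is.na(cl$institution)])
    ctrys[[rec$pmid]] <- unique(cl$country[!is.na(cl$country)])
    logs <- c(logs, attr(cl, "log"))
  }
  structure(list(institutions = insts, countries = ctrys), log = logs)
}
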
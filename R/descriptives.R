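#' Monthly publication trend
#'
#' Bins records by (year, month). Records missing the month, or dated after
#' the cutoff, are excluded and counted separately; the returned series
#' covers the contiguous calendar range observed among included records.
#'
#' @param x a `corpus`.
#' @param cutoff `c(year, month)`; records dated strictly after it are
#'   excluded. `NULL` disables the cutoff.
#' @return list with `series` (data.frame year, month, count — zero-filled
#'   over the observed range) and `excluded` (integer count).
#' @export
monthly_trend <- function(x, cutoff = NULL) {
  stopifnot(inherits(x, "corpus"))
  tab <- records_table(x)
  dated <- !is.na(tab$pub_year) & !is.na(tab$pub_month)
  keep <- dated
  if (!is.null(cutoff)) {
    stopifnot(length(cutoff) == 2, cutoff[2] >= 1, cutoff[2] <= 12)
    lim <- cutoff[1] * 12 + cutoff[2]
    keep <- dated & (tab$pub_year * 12 + tab$pub_month) <= lim
  }
  excluded <- sum(!keep)
  if (!any(keep)) {
    return(list(series = data.frame(year = integer(), month = integer(),
                                    count = integer()),
                excluded = excluded))
  }
  idx <- tab$pub_year[keep] * 12 + tab$pub_month[keep]
  rng <- seq(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  series <- data.frame(
    year = (rng - 1L) %/% 12L,
    month = (rng - 1L) %% 12L + 1L,
    count = counts
  )
  list(series = series, excluded = excluded)
}

#' Top-N entities by frequency
#'
#' Descending by count; ties broken lexicographically by entity name.
#'
#' @param freq named numeric vector (entity -> count) or a list of character
#'   vectors whose elements are tallied.
#' @param n number of entries to return.
#' @return data.frame with columns `entity`, `count`, at most `n` rows.
#' @export
top_n <- function(freq, n) {
  stopifnot(n >= 1)
  if (is.list(freq)) {
    tab <- table(unlist(freq, use.names = FALSE))
    freq <- setNames(as.numeric(tab), names(tab))
  }
  if (!length(freq)) {
    return(data.frame(entity = character(), count = numeric()))
  }
  ord <- order(-freq, names(freq))
  out <- data.frame(entity = names(freq)[ord], count = unname(freq[ord]),
                    stringsAsFactors = FALSE)
  head(out, n)
}
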
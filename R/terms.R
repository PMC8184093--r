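# A compact English stopword list; enough for title/abstract term cleaning.
STOPWORDS <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "did", "do", "does", "doing", "down", "during", "each", "few", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "may", "me", "might", "more", "most", "must", "my", "no", "nor",
  "not", "of", "off", "on", "once", "only", "or", "other", "our", "ours",
  "out", "over", "own", "same", "she", "should", "so", "some", "such",
  "than", "that", "the", "their", "theirs", "them", "then", "there",
  "these", "they", "this", "those", "through", "to", "too", "under",
  "until", "up", "upon", "using", "very", "was", "we", "were", "what",
  "when", "where", "which", "while", "who", "whom", "why", "will", "with",
  "within", "without", "would", "you", "your", "yours"
)

#' Fold simple English plurals to singular
#'
#' Suffix rules only: `-ies` to `-y`, `-ses/-xes/-zes/-ches/-shes` drop
#' `-es`, other trailing `-s` dropped unless the word ends in `-ss`, `-us`
#' or `-is`.
#' @param tokens character vector of lowercase tokens.
#' @return character vector of folded tokens.
#' @export
singularize <- function(tokens) {
  out <- tokens
  i <- grepl("ies$", out) & nchar(out) > 4
  out[i] <- sub("ies$", "y", out[i])
  j <- !i & grepl("(ses|xes|zes|ches|shes)$", out)
  out[j] <- sub("es$", "", out[j])
  k <- !i & !j & grepl("s$", out) & !grepl("(ss|us|is)$", out) & nchar(out) > 3
  out[k] <- sub("s$", "", out[k])
  out
}

tokenize_text <- function(text, stopwords = STOPWORDS) {
  toks <- strsplit(tolower(text), "[^a-z0-9']+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[0-9']+$", toks)]
  toks <- toks[nchar(toks) > 1]
  toks <- singularize(toks)
  toks[!(toks %in% stopwords)]
}

ngrams_of <- function(tokens, ngram_max) {
  if (!length(tokens)) return(character(0))
  out <- tokens
  if (ngram_max >= 2) {
    for (n in 2:ngram_max) {
      if (length(tokens) < n) break
      idx <- seq_len(length(tokens) - n + 1)
      grams <- vapply(idx, function(i) paste(tokens[i:(i + n - 1)], collapse = " "), "")
      out <- c(out, grams)
    }
  }
  out
}

#' Extract a cleaned term vocabulary from titles and abstracts
#'
#' Terms are lowercase word n-grams (up to `ngram_max`) over the
#' concatenated title and abstract, after stopword removal and plural
#' folding; terms seen in fewer than `min_df` documents are dropped.
#'
#' @param x a `corpus`.
#' @param min_df minimum document frequency a term must reach (default 5).
#' @param ngram_max longest n-gram to form, 1 to 3 (default 3).
#' @param stopwords stopword list; defaults to a compact English list.
#' @return A list with
#'   * `vocabulary`: list(`terms` sorted character vector, `doc_frequency`
#'     named integer vector, `min_df`);
#'   * `doc_terms`: named list, pmid -> named integer vector of within-document
#'     term counts (surviving terms only).
#' @export
extract_terms <- function(x, min_df = 5, ngram_max = 3, stopwords = STOPWORDS) {
  stopifnot(inherits(x, "corpus"), min_df >= 1, ngram_max %in% 1:3)
  per_doc <- lapply(x$records, function(rec) {
    toks <- tokenize_text(paste(rec$title, rec$abstract), stopwords)
    grams <- ngrams_of(toks, ngram_max)
    if (!length(grams)) return(integer(0))
    tab <- table(grams)
    setNames(as.integer(tab), names(tab))
  })
  names(per_doc) <- vapply(x$records, `[[`, "", "pmid")
  df <- table(unlist(lapply(per_doc, names), use.names = FALSE))
  keep <- sort(names(df)[df >= min_df])
  doc_frequency <- setNames(as.integer(df[keep]), keep)
  doc_terms <- lapply(per_doc, function(cnt) cnt[names(cnt) %in% keep])
  list(
    vocabulary = list(terms = keep, doc_frequency = doc_frequency, min_df = min_df),
    doc_terms = doc_terms
  )
}
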
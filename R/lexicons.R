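#' Load the feature lexicons
#'
#' Reads the five lexicons the custom features are built from: word classes
#' (Infection, Possession, Concern, Humour, Symptomatic), the positive and
#' negative word dictionaries, laughter tokens (slang plus laughing
#' emojis/emoticons) and negative (ill/sad/angry) emojis and emoticons.
#' Word entries are lower-cased and passed through the same lemmatiser used
#' by [tokenize()], so dictionary matching is consistent by construction.
#'
#' The packaged defaults live under `inst/extdata/lexicons/` as editable
#' JSON files; pass a directory with files of the same names to use your
#' own curated lists.
#'
#' @param dir directory containing `word_classes.json`,
#'   `positive_words.json`, `negative_words.json`, `laughter_tokens.json`
#'   and `negative_emoticons.json`. Defaults to the packaged lexicons.
#' @return an object of class `symptweet_lexicons`: a list with elements
#'   `word_classes` (named list of character vectors), `positive_words`,
#'   `negative_words`, `laughter_tokens`, `negative_emoticons`.
#' @examples
#' lex <- load_lexicons()
#' names(lex$word_classes)
#' @export
load_lexicons <- function(dir = system.file("extdata", "lexicons",
                                            package = "symptweet")) {
  read1 <- function(name) {
    path <- file.path(dir, paste0(name, ".json"))
    if (!file.exists(path)) stop("lexicon file not found: ", path)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  wc <- lapply(read1("word_classes"), lemmatise_entries)
  lex <- list(
    word_classes       = wc,
    positive_words     = lemmatise_entries(read1("positive_words")),
    negative_words     = lemmatise_entries(read1("negative_words")),
    laughter_tokens    = read1("laughter_tokens"),
    negative_emoticons = read1("negative_emoticons")
  )
  overlap <- intersect(lex$laughter_tokens, lex$negative_emoticons)
  if (length(overlap) > 0)
    stop("laughter and negative emoji/emoticon lists must be disjoint; ",
         "both contain: ", paste(overlap, collapse = ", "))
  if (any(vapply(lex, length, 1L) == 0))
    stop("all lexicons must be non-empty")
  class(lex) <- "symptweet_lexicons"
  lex
}

# lemmatise every word of every (possibly multi-word) entry so that lexicon
# entries live in the same lemma space as the token stream
lemmatise_entries <- function(entries) {
  vapply(tolower(entries), function(e) {
    paste(lemmatise(strsplit(e, " +")[[1]]), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# package-level cache of the default lexicons
the <- new.env(parent = emptyenv())

default_lexicons <- function() {
  if (is.null(the$lexicons)) the$lexicons <- load_lexicons()
  the$lexicons
}
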
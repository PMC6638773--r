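# Compound feature vectors: n-gram weights plus four custom feature
# blocks (word-class counts, positive/negative word counts, laughter
# indicator, negative emoji/emoticon indicator), and their two view
# projections used by co-training.

doc_ngrams <- function(tokens, n_range) {
  w <- word_tokens(tokens)
  out <- character(0)
  for (n in seq(n_range[1], n_range[2])) {
    if (length(w) < n) next
    if (n == 1) {
      out <- c(out, w)
    } else {
      idx <- seq_len(length(w) - n + 1)
      gram <- w[idx]
      for (k in seq_len(n - 1)) gram <- paste(gram, w[idx + k])
      out <- c(out, gram)
    }
  }
  out
}

#' Build an n-gram vocabulary from training texts
#'
#' Collects all word-level n-grams in the requested size range whose
#' document frequency is at least `min_doc_freq`, in deterministic
#' (sorted) order. Emojis, emoticons and the `<URL>` token do not enter
#' n-grams; their information is carried by the custom feature blocks.
#' Build the vocabulary from the training partition only, never from test
#' or unlabelled data you will evaluate on.
#'
#' @param token_lists list of token vectors (from [tokenize()]), or a
#'   character vector of raw texts (tokenised internally).
#' @param n_range integer pair `c(min_n, max_n)`.
#' @param min_doc_freq minimum number of documents a term must occur in.
#' @return object of class `symptweet_vocabulary` with elements `terms`,
#'   `n_range`, `min_doc_freq`.
#' @export
build_vocabulary <- function(token_lists, n_range = c(1, 2),
                             min_doc_freq = 2) {
  stopifnot(length(n_range) == 2, n_range[1] >= 1,
            n_range[2] >= n_range[1], min_doc_freq >= 1)
  if (is.character(token_lists)) token_lists <- lapply(token_lists, tokenize)
  if (length(token_lists) == 0) {
    warning("empty corpus: vocabulary has no terms")
    terms <- character(0)
  } else {
    per_doc <- lapply(token_lists, function(t) unique(doc_ngrams(t, n_range)))
    df <- table(unlist(per_doc, use.names = FALSE))
    terms <- sort(names(df)[df >= min_doc_freq])
  }
  structure(list(terms = terms, n_range = as.integer(n_range),
                 min_doc_freq = as.integer(min_doc_freq)),
            class = "symptweet_vocabulary")
}

#' @export
print.symptweet_vocabulary <- function(x, ...) {
  cat("n-gram vocabulary:", length(x$terms), "terms (n in",
      x$n_range[1], "..", x$n_range[2], ", min doc freq",
      x$min_doc_freq, ")\n")
  invisible(x)
}

count_in_set <- function(tokens, entries) {
  single <- entries[!grepl(" ", entries)]
  multi <- entries[grepl(" ", entries)]
  cnt <- sum(tokens %in% single)
  if (length(multi) > 0 && length(tokens) >= 2) {
    bi <- paste(tokens[-length(tokens)], tokens[-1])
    for (m in multi) {
      mlen <- length(strsplit(m, " ")[[1]])
      if (mlen == 2) cnt <- cnt + sum(bi == m)
      else {
        joined <- paste(tokens, collapse = " ")
        cnt <- cnt + length(gregexpr(m, joined, fixed = TRUE)[[1]]) *
          (regexpr(m, joined, fixed = TRUE) > 0)
      }
    }
  }
  cnt
}

#' Word-class counts
#'
#' For each curated word class (Infection, Possession, Concern, Humour,
#' Symptomatic), the number of token occurrences belonging to that class.
#'
#' @param tokens lemmatised token vector (from [tokenize()]).
#' @param lexicons a [load_lexicons()] object.
#' @return named integer vector, one entry per class.
#' @export
word_class_counts <- function(tokens, lexicons = default_lexicons()) {
  vapply(lexicons$word_classes,
         function(ws) as.integer(count_in_set(tokens, ws)), integer(1))
}

#' Positive and negative word counts
#'
#' Counts of tokens appearing in the positive and negative word
#' dictionaries; words in neither dictionary are not counted.
#'
#' @inheritParams word_class_counts
#' @return integer vector `c(pos_count = , neg_count = )`.
#' @export
posneg_counts <- function(tokens, lexicons = default_lexicons()) {
  c(pos_count = sum(tokens %in% lexicons$positive_words),
    neg_count = sum(tokens %in% lexicons$negative_words))
}

token_in_lexset <- function(tokens, set) {
  any(tokens %in% set) || any(tolower(tokens) %in% set)
}

#' Laughter indicator
#'
#' Binary feature: 1 if the text contains any laughter emoji/emoticon or
#' any laughter slang token (lol, lmao, rofl, ha(ha)...), matched
#' case-insensitively on token boundaries. Laughter suggests banter rather
#' than a genuine symptom report.
#'
#' @param text raw text (used when `tokens` is `NULL`).
#' @param tokens optional pre-computed token vector.
#' @inheritParams word_class_counts
#' @return 0 or 1.
#' @export
denotes_laughter <- function(text, tokens = NULL,
                             lexicons = default_lexicons()) {
  if (is.null(tokens)) tokens <- tokenize(text)
  slang <- token_in_lexset(tokens, lexicons$laughter_tokens)
  # lengthened laughs ("hahahaha") collapse to the same indicator
  ha <- any(grepl("^(ha)+h?$", tokens) & nchar(tokens) >= 4)
  as.integer(slang || ha)
}

#' Negative emoji/emoticon indicator
#'
#' Binary feature: 1 if the text contains any member of the negative
#' emoji/emoticon list (sad, angry or ill faces such as the medical-mask
#' emoji, or emoticons like ":'(" ). These mark the negative tone typical
#' of someone reporting symptoms.
#'
#' @inheritParams denotes_laughter
#' @return 0 or 1.
#' @export
negative_emoji <- function(text, lexicons = default_lexicons(),
                           tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize(text)
  as.integer(token_in_lexset(tokens, lexicons$negative_emoticons))
}

custom_feature_names <- function(lexicons) {
  c(paste0("wc:", names(lexicons$word_classes)),
    "pos_count", "neg_count", "denotes_laughter", "negative_emoji")
}

#' Build the compound feature matrix for a corpus
#'
#' Each post is represented by the union of its n-gram weights (raw term
#' frequency by default, optionally binary presence) and the four custom
#' feature blocks. Column names are prefixed `ng:` (n-grams) and `wc:`
#' (word classes); the block membership of every column is returned so
#' that view projections and ablation can slice the matrix by block.
#'
#' @param texts character vector of cleaned texts, or a list of token
#'   vectors.
#' @param vocabulary a [build_vocabulary()] object.
#' @param lexicons a [load_lexicons()] object.
#' @param weighting `"count"` (term frequency) or `"binary"`.
#' @param ids optional row names (post ids).
#' @return list of class `symptweet_features`: `X` (numeric matrix),
#'   `blocks` (character vector over columns, one of `"ngram"`,
#'   `"word_class"`, `"posneg"`, `"laughter"`, `"negemoji"`),
#'   `vocabulary`, `weighting`.
#' @export
featurize_corpus <- function(texts, vocabulary,
                             lexicons = default_lexicons(),
                             weighting = c("count", "binary"),
                             ids = NULL) {
  weighting <- match.arg(weighting)
  token_lists <- if (is.character(texts)) lapply(texts, tokenize) else texts
  n <- length(token_lists)
  terms <- vocabulary$terms
  p_ng <- length(terms)
  cn <- c(if (p_ng > 0) paste0("ng:", terms), custom_feature_names(lexicons))
  X <- matrix(0, nrow = n, ncol = length(cn),
              dimnames = list(ids, cn))
  nwc <- length(lexicons$word_classes)
  for (i in seq_len(n)) {
    toks <- token_lists[[i]]
    if (p_ng > 0) {
      grams <- doc_ngrams(toks, vocabulary$n_range)
      j <- match(grams, terms)
      j <- j[!is.na(j)]
      if (length(j) > 0) {
        tab <- tabulate(j, nbins = p_ng)
        if (weighting == "binary") tab <- as.integer(tab > 0)
        X[i, seq_len(p_ng)] <- tab
      }
    }
    X[i, p_ng + seq_len(nwc)] <- word_class_counts(toks, lexicons)
    X[i, p_ng + nwc + 1:2] <- posneg_counts(toks, lexicons)
    X[i, p_ng + nwc + 3] <- denotes_laughter(NULL, tokens = toks,
                                             lexicons = lexicons)
    X[i, p_ng + nwc + 4] <- negative_emoji(NULL, tokens = toks,
                                           lexicons = lexicons)
  }
  blocks <- c(rep("ngram", p_ng), rep("word_class", nwc),
              rep("posneg", 2), "laughter", "negemoji")
  structure(list(X = X, blocks = blocks, vocabulary = vocabulary,
                 weighting = weighting),
            class = "symptweet_features")
}

#' Build a single compound feature vector
#'
#' Convenience wrapper around [featurize_corpus()] for one post.
#'
#' @param text a single cleaned text.
#' @inheritParams featurize_corpus
#' @return named numeric vector.
#' @export
build_vector <- function(text, vocabulary, lexicons = default_lexicons(),
                         weighting = "count") {
  f <- featurize_corpus(text, vocabulary, lexicons, weighting)
  f$X[1, ]
}

#' Project the compound features onto the two co-training views
#'
#' View 1 is the taxonomical view (n-grams, word classes, laughter,
#' negative emoji); view 2 is the sentimental view (n-grams,
#' positive/negative word counts, laughter, negative emoji). View 1
#' excludes the pos/neg counts; view 2 excludes the word-class counts;
#' their union covers every feature.
#'
#' @param blocks block labels over columns (from [featurize_corpus()]),
#'   or a `symptweet_features` object.
#' @return list with integer index vectors `X1` and `X2`.
#' @export
build_views <- function(blocks) {
  if (inherits(blocks, "symptweet_features")) blocks <- blocks$blocks
  list(
    X1 = which(blocks %in% c("ngram", "word_class", "laughter", "negemoji")),
    X2 = which(blocks %in% c("ngram", "posneg", "laughter", "negemoji"))
  )
}
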
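# Evaluation: confusion matrices, precision/recall/accuracy, F-beta,
# Fleiss' kappa, feature ablation, word informativeness and keyword
# retrieval assessment. "relevant" is always the positive class.

#' Confusion matrix
#'
#' @param pred,truth character/factor label vectors of equal length;
#'   `"relevant"` is the positive class.
#' @param positive name of the positive class.
#' @return object of class `confusion_matrix`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(pred, truth, positive = "relevant") {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  structure(list(
    tp = sum(pred == positive & truth == positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive),
    tn = sum(pred != positive & truth != positive)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("Predicted True", "Predicted False"),
                              c("Actual True", "Actual False")))
  print(m)
  invisible(x)
}

#' Precision, recall and accuracy from a confusion matrix
#'
#' Precision is the probability that an instance predicted relevant is
#' relevant; recall the probability that a relevant instance is
#' identified. When a denominator is zero the corresponding value is
#' returned as `NA` with a warning rather than silently coerced to 0.
#'
#' @param cm a [confusion()] object (or a list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @return list with `precision`, `recall`, `accuracy`.
#' @export
prf_accuracy <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  precision <- if (cm$tp + cm$fp == 0) {
    warning("precision undefined: no positive predictions"); NA_real_
  } else cm$tp / (cm$tp + cm$fp)
  recall <- if (cm$tp + cm$fn == 0) {
    warning("recall undefined: no positive instances"); NA_real_
  } else cm$tp / (cm$tp + cm$fn)
  list(precision = precision, recall = recall,
       accuracy = if (total == 0) NA_real_ else (cm$tp + cm$tn) / total)
}

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`. `beta = 2` weighs recall
#' twice as heavily as precision — the preferred metric when losing true
#' positives (relevant posts) is costlier than admitting noise.
#'
#' @param precision,recall values in `[0, 1]` (vectorised).
#' @param beta positive weight on recall.
#' @return numeric score(s); `P = R = 0` yields 0 with a warning.
#' @export
f_beta <- function(precision, recall, beta = 2) {
  stopifnot(beta > 0, all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  denom <- beta^2 * precision + recall
  out <- ifelse(denom == 0, 0,
                (1 + beta^2) * precision * recall / denom)
  if (any(denom == 0))
    warning("F-beta undefined at precision = recall = 0; returning 0")
  out
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement for a fixed number of raters assigning
#' items to categories: `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar` is
#' the mean over items of the pairwise rater agreement and `Pe` the
#' expected chance agreement from the observed category marginals. 1 is
#' complete agreement, 0 chance-level agreement.
#'
#' @param ratings integer matrix, one row per item, one column per
#'   category; `ratings[i, j]` counts the raters who assigned item `i`
#'   to category `j`. All row sums must be equal (same rater count per
#'   item).
#' @return kappa, or `NA` with a warning in the degenerate case where
#'   every rating falls in a single category (`Pe = 1`).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2 || ncol(ratings) < 2)
    stop("need at least 2 items and 2 categories")
  n_raters <- unique(rowSums(ratings))
  if (length(n_raters) != 1)
    stop("every item must be rated by the same number of raters")
  n <- n_raters
  if (n < 2) stop("need at least 2 raters")
  N <- nrow(ratings)
  p_j <- colSums(ratings) / (N * n)
  P_i <- (rowSums(ratings^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e == 0) {
    warning("all ratings in a single category: kappa undefined")
    return(NA_real_)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Feature-block ablation
#'
#' Fits the learner with all feature blocks, then once more with each
#' block removed, and reports the drop in F1 attributable to each block
#' (positive delta = the block helps). F1 (not F2) is used so the
#' ablation reflects general classification quality rather than the
#' recall-weighted surveillance objective.
#'
#' @param X_train,y_train,X_test,y_test train/test split of a featurised
#'   corpus.
#' @param blocks block labels over columns (from [featurize_corpus()]).
#' @param spec a [learner_spec()].
#' @param beta F-measure weight (default 1).
#' @return data.frame with rows `none` (baseline) and one per block:
#'   `f1` (score with that block removed; baseline score for `none`) and
#'   `delta_f1` (baseline minus ablated).
#' @export
ablation <- function(X_train, y_train, X_test, y_test, blocks, spec,
                     beta = 1) {
  stopifnot(length(blocks) == ncol(X_train))
  score <- function(keep) {
    if (!any(keep)) stop("cannot remove every feature block")
    model <- fit(spec, X_train[, keep, drop = FALSE], y_train)
    pred <- predict_with_confidence(
      model, X_test[, keep, drop = FALSE])$label
    pr <- suppressWarnings(prf_accuracy(confusion(pred, y_test)))
    if (is.na(pr$precision) || is.na(pr$recall)) return(0)
    suppressWarnings(f_beta(pr$precision, pr$recall, beta))
  }
  base <- score(rep(TRUE, length(blocks)))
  blks <- unique(blocks)
  out <- data.frame(block = c("none", blks),
                    f1 = NA_real_, delta_f1 = NA_real_,
                    stringsAsFactors = FALSE)
  out$f1[1] <- base; out$delta_f1[1] <- 0
  for (k in seq_along(blks)) {
    s <- score(blocks != blks[k])
    out$f1[k + 1] <- s
    out$delta_f1[k + 1] <- base - s
  }
  out
}

#' Word informativeness
#'
#' For every unigram, the ratio of the largest to the smallest smoothed
#' class-conditional probability of the word appearing in a post,
#' `I = max_c P(w | c) / min_c P(w | c)`: words occurring
#' overwhelmingly in one class are the most informative. Per-class
#' occurrence counts are smoothed by adding 0.5 before forming the
#' ratio, so single-class words yield a finite ratio. Also reported are
#' the normalised class priors (each class-conditional probability
#' divided by their sum).
#'
#' @param texts character vector of cleaned texts (or token lists).
#' @param labels `"relevant"`/`"irrelevant"` labels.
#' @param min_count drop words occurring in fewer than this many posts.
#' @param smoothing additive smoothing constant (default 0.5).
#' @return data.frame sorted by decreasing `I`: `word`, `n_relevant`,
#'   `n_irrelevant`, `I`, `prior_relevant`, `prior_irrelevant`.
#' @export
informativeness <- function(texts, labels, min_count = 1,
                            smoothing = 0.5) {
  labels <- as.character(as_label_factor(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  token_lists <- if (is.character(texts)) lapply(texts, tokenize) else texts
  stopifnot(length(token_lists) == length(labels))
  words_per_doc <- lapply(token_lists,
                          function(t) unique(word_tokens(t)))
  rel <- labels == "relevant"
  n_rel <- sum(rel); n_irr <- sum(!rel)
  tab_rel <- table(unlist(words_per_doc[rel], use.names = FALSE))
  tab_irr <- table(unlist(words_per_doc[!rel], use.names = FALSE))
  words <- union(names(tab_rel), names(tab_irr))
  k_rel <- as.numeric(tab_rel[words]); k_rel[is.na(k_rel)] <- 0
  k_irr <- as.numeric(tab_irr[words]); k_irr[is.na(k_irr)] <- 0
  keep <- (k_rel + k_irr) >= min_count
  words <- words[keep]; k_rel <- k_rel[keep]; k_irr <- k_irr[keep]
  p_rel <- (k_rel + smoothing) / (n_rel + 2 * smoothing)
  p_irr <- (k_irr + smoothing) / (n_irr + 2 * smoothing)
  I <- pmax(p_rel, p_irr) / pmin(p_rel, p_irr)
  out <- data.frame(word = words, n_relevant = k_rel,
                    n_irrelevant = k_irr, I = I,
                    prior_relevant = p_rel / (p_rel + p_irr),
                    prior_irrelevant = p_irr / (p_rel + p_irr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$I, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keyword retrieval assessment
#'
#' Scores each collection keyword as an information-retrieval query
#' against a labelled corpus. A post matches a (possibly multi-word)
#' keyword when it contains every term of the keyword, case-insensitive,
#' in any order — the semantics of a streaming-API track phrase, where
#' spaces act as logical ANDs. Precision is the relevant fraction of the
#' matched set; recall the matched fraction of all relevant posts.
#'
#' @param keywords character vector of keywords/phrases.
#' @param texts corpus texts.
#' @param labels `"relevant"`/`"irrelevant"` labels.
#' @return data.frame: `keyword`, `precision` (0 when nothing matches),
#'   `recall`, `n_matched`.
#' @export
keyword_ir <- function(keywords, texts, labels) {
  if (length(texts) == 0) stop("corpus is empty")
  labels <- as.character(as_label_factor(labels))
  lower <- tolower(texts)
  n_rel <- sum(labels == "relevant")
  rows <- lapply(keywords, function(kw) {
    terms <- strsplit(tolower(kw), "[[:space:]]+")[[1]]
    matched <- rep(TRUE, length(lower))
    for (term in terms) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                    "\\b")
      matched <- matched & grepl(pat, lower, perl = TRUE)
    }
    n_m <- sum(matched)
    n_mr <- sum(matched & labels == "relevant")
    data.frame(keyword = kw,
               precision = if (n_m == 0) 0 else n_mr / n_m,
               recall = if (n_rel == 0) 0 else n_mr / n_rel,
               n_matched = n_m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
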
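# Shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# tokenised semisup benchmark (8,500 posts), shared by the conservation
# and semi-supervised-benefit tests
benchmark_tokens <- function() {
  memo("bench", {
    fx <- packaged_fixture("semisup_benchmark")
    list(fx = fx,
         tok = lapply(replace_urls(fx$tweets$text), tokenize))
  })
}

# one featurised seed-split of the benchmark: 350 train / 150 holdout
# labelled posts, 8,000 unlabelled
benchmark_split <- function(seed) {
  memo(paste0("split", seed), {
    b <- benchmark_tokens()
    fx <- b$fx
    lidx <- fx$labelled_idx
    h <- withr::with_seed(seed, sample(lidx, 150))
    tr <- setdiff(lidx, h)
    vocab <- build_vocabulary(b$tok[tr], n_range = c(1, 1),
                              min_doc_freq = 2)
    feats <- featurize_corpus(b$tok, vocab, ids = fx$tweets$id)
    list(X = feats$X, blocks = feats$blocks, tr = tr, h = h,
         u = fx$unlabelled_idx, y = fx$annotations$label)
  })
}

holdout_f2_of <- function(model, X, idx, y) {
  pred <- predict_with_confidence(model, X[idx, , drop = FALSE])$label
  pr <- suppressWarnings(prf_accuracy(confusion(pred, y[idx])))
  if (is.na(pr$precision) || is.na(pr$recall)) return(0)
  suppressWarnings(f_beta(pr$precision, pr$recall, 2))
}

# small featurised labelled corpus for unit tests
small_featurized <- function() {
  memo("small", {
    fx <- packaged_fixture("small_labelled")
    ann <- fx$annotations
    keep <- ann$is_base
    texts <- replace_urls(fx$tweets$text[keep])
    tok <- lapply(texts, tokenize)
    vocab <- build_vocabulary(tok, n_range = c(1, 1), min_doc_freq = 2)
    feats <- featurize_corpus(tok, vocab, ids = fx$tweets$id[keep])
    list(X = feats$X, blocks = feats$blocks, y = ann$label[keep],
         texts = texts, tok = tok, vocab = vocab)
  })
}
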
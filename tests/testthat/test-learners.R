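families <- c("naive_bayes", "decision_tree", "logistic_regression",
              "svm", "mlp")

toy_separable <- function(n = 80, gap = 6) {
  X <- cbind(x1 = c(rnorm(n / 2, -gap), rnorm(n / 2, gap)),
             x2 = rnorm(n))
  list(X = X, y = rep(c("irrelevant", "relevant"), each = n / 2))
}

test_that("all five families satisfy the fit/predict/confidence contract", {
  set.seed(10)
  d <- toy_separable()
  fast_hp <- list(naive_bayes = list(), decision_tree = list(),
                  logistic_regression = list(C = 1), svm = list(C = 10),
                  mlp = list(hidden = c(16, 16), epochs = 40))
  for (fam in families) {
    spec <- learner_spec(fam, fast_hp[[fam]], seed = 7)
    m <- fit(spec, d$X, d$y)
    pr <- predict_with_confidence(m, d$X)
    expect_true(all(pr$label %in% c("relevant", "irrelevant")), info = fam)
    expect_true(all(pr$confidence >= 0.5 & pr$confidence <= 1), info = fam)
    # determinism under a fixed seed
    m2 <- fit(spec, d$X, d$y)
    expect_identical(pr, predict_with_confidence(m2, d$X), info = fam)
    # dimension mismatch is an error
    expect_error(predict_with_confidence(m, d$X[, 1, drop = FALSE]),
                 "mismatch", info = fam)
  }
})

test_that("separable toy data is fit perfectly by MLP, LR and SVM", {
  set.seed(11)
  d <- toy_separable()
  for (fam in c("mlp", "logistic_regression", "svm")) {
    hp <- switch(fam, logistic_regression = list(C = 1),
                 svm = list(C = 10),
                 mlp = list(hidden = c(16, 16), epochs = 60))
    m <- fit(learner_spec(fam, hp, seed = 3), d$X, d$y)
    pr <- predict_with_confidence(m, d$X)
    expect_equal(mean(pr$label == d$y), 1, info = fam)
    # deep-in-class points get high confidence
    # class-centre points are classified confidently (Platt-scaled SVM
    # probabilities saturate below 1 on small samples, and an RBF
    # kernel cannot extrapolate beyond the training support, so the
    # probes sit at the cluster centres)
    deep <- predict_with_confidence(
      m, cbind(x1 = c(-6, 6), x2 = c(0, 0)))
    expect_true(all(deep$confidence > 0.7), info = fam)
    expect_equal(deep$label, c("irrelevant", "relevant"), info = fam)
  }
})

test_that("degenerate training inputs are rejected", {
  d <- toy_separable(20)
  spec <- learner_spec("logistic_regression", list(C = 1))
  expect_error(fit(spec, d$X, rep("relevant", 20)), "both classes")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(fit(spec, Xna, d$y), "NA")
  expect_error(fit(spec, d$X, rep(c("relevant", "maybe"), 10)),
               "relevant")
  expect_error(learner_spec("boosted_stump"), "unknown")
  expect_error(learner_spec("mlp", list(nonsense = 1)), "invalid")
})

test_that("test error on generated data stays near the Bayes optimum", {
  sp <- corpus_spec(n_tweets = 1200, dup_rate = 0, rt_rate = 0,
                    bot_rate = 0, signal_weight = 0.25, seed = 88)
  corp <- generate_corpus(sp)
  ann <- corp$annotations
  texts <- replace_urls(corp$tweets$text)
  tok <- lapply(texts, tokenize)
  h <- withr::with_seed(5, sample(1200, 400))
  tr <- setdiff(1:1200, h)
  vocab <- build_vocabulary(tok[tr], c(1, 1), 2)
  X <- featurize_corpus(tok, vocab)$X
  bo <- bayes_optimal_labels(texts[h], sp)
  acc_bayes <- mean(bo$label == ann$label[h])
  m <- fit(learner_spec("logistic_regression", list(C = 1), seed = 2),
           X[tr, ], ann$label[tr])
  acc_lr <- mean(predict_with_confidence(m, X[h, ])$label == ann$label[h])
  # a learner cannot beat the closed-form optimum by more than noise
  expect_lte(acc_lr, acc_bayes + 0.03)
  # and a competent learner should land within a few points of it
  expect_gt(acc_lr, acc_bayes - 0.1)
})

test_that("confidence is roughly calibrated on generated data", {
  sp <- corpus_spec(n_tweets = 1500, dup_rate = 0, rt_rate = 0,
                    bot_rate = 0, signal_weight = 0.25, seed = 54)
  corp <- generate_corpus(sp)
  ann <- corp$annotations
  tok <- lapply(replace_urls(corp$tweets$text), tokenize)
  h <- withr::with_seed(6, sample(1500, 500))
  tr <- setdiff(1:1500, h)
  vocab <- build_vocabulary(tok[tr], c(1, 1), 2)
  X <- featurize_corpus(tok, vocab)$X
  m <- fit(learner_spec("logistic_regression", list(C = 1), seed = 2),
           X[tr, ], ann$label[tr])
  pr <- predict_with_confidence(m, X[h, ])
  band <- pr$confidence >= 0.7 & pr$confidence <= 0.95
  expect_gte(sum(band), 10)
  # instances the model is 70-95% sure about are right much more often
  # than chance and not perfectly
  expect_gte(mean(pr$label[band] == ann$label[h][band]), 0.6)
})

test_that("grid search returns the dominant spec deterministically", {
  set.seed(12)
  d <- toy_separable(120, gap = 2)
  grid <- list(
    learner_spec("logistic_regression", list(C = 1e-8), seed = 3),
    learner_spec("logistic_regression", list(C = 1), seed = 3)
  )
  best <- grid_search(grid, d$X, d$y, holdout_fraction = 0.3,
                      metric = "F2", seed = 9)
  expect_equal(best$hyperparams$C, 1)
  best2 <- grid_search(grid, d$X, d$y, holdout_fraction = 0.3,
                       metric = "F2", seed = 9)
  expect_equal(attr(best, "scores"), attr(best2, "scores"))
  single <- grid_search(grid[1], d$X, d$y, seed = 1)
  expect_equal(single$hyperparams$C, 1e-8)
  expect_error(grid_search(list(), d$X, d$y), "empty")
})

test_that("oversampling reaches the target and keeps the original data", {
  set.seed(13)
  n <- 400
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("r", 1:n), NULL))
  y <- ifelse(seq_len(n) <= round(0.237 * n), "relevant", "irrelevant")
  os <- oversample(X, y, 0.47, seed = 2)
  frac <- mean(os$y == "relevant")
  expect_gte(frac, 0.47)
  expect_lt(frac, 0.48)
  # original multiset preserved
  expect_identical(os$X[seq_len(n), ], X)
  expect_identical(os$y[seq_len(n)], y)
  # added rows are copies of minority rows
  expect_true(all(rownames(os$X)[-seq_len(n)] %in%
                    rownames(X)[y == "relevant"]))
  # balanced input is returned unchanged
  yb <- rep(c("relevant", "irrelevant"), each = n / 2)
  expect_identical(oversample(X, yb, 0.5, seed = 1)$y, yb)
  # determinism
  os2 <- oversample(X, y, 0.47, seed = 2)
  expect_identical(os$X, os2$X)
  expect_error(oversample(X, rep("relevant", n), 0.47), "both classes")
})

test_that("the MLP at its tuned defaults is the strongest family on the
           synthetic benchmark (mean F2 over seeds)", {
  corp <- generate_corpus(corpus_spec(n_tweets = 700, signal_weight = 0.25,
                                      seed = 4242))
  ann <- corp$annotations
  keep <- ann$is_base
  tok <- lapply(replace_urls(corp$tweets$text[keep]), tokenize)
  y <- ann$label[keep]
  res <- sapply(1:5, function(seed) {
    set.seed(seed)
    n <- length(y)
    h <- sample(n, round(0.3 * n)); tr <- setdiff(seq_len(n), h)
    vocab <- build_vocabulary(tok[tr], c(1, 1), 2)
    X <- featurize_corpus(tok, vocab)$X
    os <- oversample(X[tr, ], y[tr], 0.47, seed = seed)
    sapply(families, function(fam) {
      m <- fit(learner_spec(fam, seed = seed), os$X, os$y)
      pred <- predict_with_confidence(m, X[h, ])$label
      pr <- suppressWarnings(prf_accuracy(confusion(pred, y[h])))
      if (is.na(pr$precision) || is.na(pr$recall)) 0 else
        suppressWarnings(f_beta(pr$precision, pr$recall, 2))
    })
  })
  means <- rowMeans(res)
  expect_equal(names(which.max(means)), "mlp")
  expect_true(all(means["mlp"] >= means[setdiff(families, "mlp")]))
})
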
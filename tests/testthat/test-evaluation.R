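test_that("confusion matrices count the four cells", {
  pred <- c(rep("relevant", 6), rep("irrelevant", 4))
  cm <- confusion(pred, pred)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 6, fp = 0, fn = 0, tn = 4))
  flip <- ifelse(pred == "relevant", "irrelevant", "relevant")
  cm2 <- confusion(flip, pred)
  expect_equal(cm2$tp + cm2$tn, 0)
  expect_error(confusion("relevant", c("relevant", "relevant")),
               "same length")
})

test_that("metrics agree with brute-force counting on random vectors", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    pred <- sample(c("relevant", "irrelevant"), n, replace = TRUE)
    truth <- sample(c("relevant", "irrelevant"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
    cm <- confusion(pred, truth)
    pr <- suppressWarnings(prf_accuracy(cm))
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (k in seq_len(n)) {
      if (pred[k] == "relevant" && truth[k] == "relevant") tp <- tp + 1
      if (pred[k] == "relevant" && truth[k] == "irrelevant") fp <- fp + 1
      if (pred[k] == "irrelevant" && truth[k] == "relevant") fn <- fn + 1
      if (pred[k] == "irrelevant" && truth[k] == "irrelevant") tn <- tn + 1
    }
    expect_equal(cm$tp, tp)
    expect_equal(cm$tn, tn)
    if (tp + fp > 0) expect_equal(pr$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(pr$recall, tp / (tp + fn))
    expect_equal(pr$accuracy, (tp + tn) / n)
  }
})

test_that("undefined denominators are flagged, not zeroed", {
  cm <- confusion(rep("irrelevant", 5), rep("irrelevant", 5))
  w <- capture_warnings(pr <- prf_accuracy(cm))
  expect_true(any(grepl("precision undefined", w)))
  expect_true(any(grepl("recall undefined", w)))
  expect_true(is.na(pr$precision))
  expect_true(is.na(pr$recall))
})

test_that("f_beta follows its definition and recall-weighting property", {
  expect_equal(f_beta(1, 1, 2), 1)
  expect_equal(f_beta(0.5, 0.5, 7), 0.5)  # symmetry at P = R
  # F1 equals the harmonic mean
  p <- 0.7; r <- 0.4
  expect_equal(f_beta(p, r, 1), 2 * p * r / (p + r))
  # F2 rewards recall: swapping a high-P/low-R pair increases F2
  expect_gt(f_beta(0.6, 0.9, 2), f_beta(0.9, 0.6, 2))
  expect_warning(z <- f_beta(0, 0, 2), "undefined")
  expect_equal(z, 0)
})

test_that("Fleiss' kappa matches the formula on hand-worked tables", {
  # complete agreement on mixed categories
  full <- rbind(c(3, 0), c(0, 3), c(3, 0), c(0, 3))
  expect_equal(fleiss_kappa(full), 1)
  # engineered chance-level table: mean pairwise agreement equals the
  # marginal chance agreement
  chance <- rbind(c(2, 0), c(0, 2), c(1, 1), c(1, 1))
  expect_equal(fleiss_kappa(chance), 0)
  # 4-item, 3-rater, 3-category table, worked by hand:
  m <- rbind(c(3, 0, 0),
             c(1, 2, 0),
             c(0, 1, 2),
             c(1, 1, 1))
  # P_i = (sum_j n_ij^2 - n) / (n(n-1)): 1, 1/3, 1/3, 0
  P_bar <- mean(c(1, 1 / 3, 1 / 3, 0))
  p_j <- c(5, 4, 3) / 12
  P_e <- sum(p_j^2)
  expect_equal(fleiss_kappa(m), (P_bar - P_e) / (1 - P_e))
  # degenerate single-category table
  expect_warning(k <- fleiss_kappa(rbind(c(3, 0), c(3, 0))), "undefined")
  expect_true(is.na(k))
  expect_error(fleiss_kappa(rbind(c(3, 0), c(2, 2))), "same number")
})

test_that("kappa is invariant to category relabelling and item order", {
  set.seed(5)
  m <- t(rmultinom(12, 3, c(0.5, 0.3, 0.2)))
  expect_equal(fleiss_kappa(m), fleiss_kappa(m[, c(3, 1, 2)]))
  expect_equal(fleiss_kappa(m), fleiss_kappa(m[sample(12), ]))
})

test_that("ablation attributes the planted signal to the right block", {
  # corpus where only the negative-emoji indicator separates the classes
  lex <- load_lexicons()
  set.seed(21)
  n <- 400
  y <- rep(c("relevant", "irrelevant"), each = n / 2)
  noise <- replicate(n, paste(sample(c("the", "a", "day", "week", "thing",
                                       "stuff", "time", "word"),
                                     8, replace = TRUE), collapse = " "))
  texts <- ifelse(y == "relevant" & runif(n) < 0.9,
                  paste(noise, "\U0001F637"), noise)
  tok <- lapply(texts, tokenize)
  vocab <- build_vocabulary(tok, c(1, 1), 2)
  f <- featurize_corpus(tok, vocab, lex)
  tr <- sample(n, n / 2); te <- setdiff(seq_len(n), tr)
  ab <- ablation(f$X[tr, ], y[tr], f$X[te, ], y[te], f$blocks,
                 learner_spec("decision_tree", seed = 1))
  expect_equal(ab$delta_f1[ab$block == "none"], 0)
  biggest <- ab$block[which.max(ab$delta_f1)]
  expect_equal(biggest, "negemoji")
  # removing an uninformative block barely moves F1
  expect_lt(abs(ab$delta_f1[ab$block == "posneg"]), 0.05)
  expect_error(ablation(f$X[tr, ], y[tr], f$X[te, ], y[te],
                        rep("ngram", ncol(f$X)),
                        learner_spec("decision_tree")),
               "every feature block")
})

test_that("informativeness matches a brute-force probability ratio", {
  texts <- c("chest tight bad", "chest cough", "health report",
             "health study day", "chest hurt", "day off")
  labels <- c("relevant", "relevant", "irrelevant", "irrelevant",
              "relevant", "irrelevant")
  inf <- informativeness(texts, labels)
  # brute-force oracle with the same add-0.5 smoothing
  brute <- function(w) {
    docs <- lapply(texts, function(t) unique(tokenize(t)))
    kr <- sum(vapply(docs[labels == "relevant"],
                     function(d) w %in% d, TRUE))
    ki <- sum(vapply(docs[labels == "irrelevant"],
                     function(d) w %in% d, TRUE))
    pr <- (kr + 0.5) / (3 + 1); pi <- (ki + 0.5) / (3 + 1)
    max(pr, pi) / min(pr, pi)
  }
  for (w in inf$word) {
    expect_equal(inf$I[inf$word == w], brute(w), info = w)
  }
  # a word used only in relevant posts ranks above an even word
  expect_lt(which(inf$word == "chest"), which(inf$word == "day"))
  # priors normalise to one
  expect_equal(inf$prior_relevant + inf$prior_irrelevant,
               rep(1, nrow(inf)))
  # balanced corpus, evenly occurring word: I = 1
  even <- informativeness(c("x y", "x z"), c("relevant", "irrelevant"))
  expect_equal(even$I[even$word == "x"], 1)
})

test_that("keyword retrieval matches brute-force tallies", {
  texts <- c("my asthma is bad", "asthma awareness week",
             "cannot breathe tonight", "i cannot really breathe",
             "lovely day", "air pollution report")
  labels <- c("relevant", "irrelevant", "relevant", "relevant",
              "irrelevant", "irrelevant")
  ir <- keyword_ir(c("asthma", "cannot breathe", "pea souper"),
                   texts, labels)
  # brute force: multi-word keyword = AND over terms, any order
  expect_equal(ir$n_matched, c(2, 2, 0))
  expect_equal(ir$precision, c(1 / 2, 2 / 2, 0))
  expect_equal(ir$recall, c(1 / 3, 2 / 3, 0))
  # a keyword matching everything has recall 1 and precision = the
  # relevant fraction
  all_ir <- keyword_ir("a", c("a b", "a c", "a d"),
                       c("relevant", "irrelevant", "irrelevant"))
  expect_equal(all_ir$recall, 1)
  expect_equal(all_ir$precision, 1 / 3)
  # keyword recalls may sum above 1 (overlapping queries) - this is
  # deliberately not constrained
  overlap <- keyword_ir(c("asthma", "bad"), texts[1], "relevant")
  expect_equal(sum(overlap$recall), 2)
})
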
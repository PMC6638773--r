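# End-to-end pipeline: clean -> featurise -> (supervised | self-train |
# co-train) -> evaluate -> optional daily-signal correlation, with a
# reproducibility manifest.

derive_seed <- function(seed, stage) {
  # fixed fan-out so each stage is independently reproducible
  offsets <- c(split = 11L, learner = 23L, semisup = 37L, sample = 53L)
  (as.integer(seed) * 97L + offsets[[stage]]) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it by a
#'   fixed fan-out.
#' @param fixture name of a [packaged_fixture()] used when no input
#'   files are given.
#' @param corpus_path,labels_path optional paths to a raw JSONL corpus
#'   and a `id,label` CSV; when given they replace the fixture.
#' @param family,hyperparams base learner (see [learner_spec()]).
#' @param theta,batch_size,patience semi-supervised controls (see
#'   [iter_label_config()]).
#' @param method `"co"`, `"self"` or `"both"`.
#' @param ngram_range,min_doc_freq vocabulary controls.
#' @param holdout_fraction fraction of the labelled pool held out for
#'   evaluation.
#' @param oversample_to minority fraction targeted by training-set
#'   oversampling (`NULL` to disable).
#' @param reference_path optional `date,value` CSV of a reference
#'   health-indicator series for the signal stage.
#' @param window moving-average window for the signal stage.
#' @param out_dir optional directory for the manifest and trace files.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, fixture = "semisup_benchmark",
                       corpus_path = NULL, labels_path = NULL,
                       family = "logistic_regression",
                       hyperparams = list(C = 1), theta = 0.8,
                       batch_size = 500, patience = 2, method = "both",
                       ngram_range = c(1, 1), min_doc_freq = 2,
                       holdout_fraction = 0.3, oversample_to = 0.47,
                       reference_path = NULL, window = 7,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full relevance-filtering pipeline
#'
#' Executes cleaning, featurisation, supervised and semi-supervised
#' training, evaluation, and (when a reference series is configured) the
#' daily-signal correlation, returning a manifest that records seeds,
#' counts and every reported metric. Re-running with an identical
#' configuration reproduces the manifest exactly.
#'
#' @param cfg a [run_config()].
#' @return the manifest (list), invisibly written as JSON to
#'   `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$corpus_path, cfg$labels_path, cfg$reference_path))
    if (!is.null(p) && !file.exists(p))
      stop("pipeline input does not exist: ", p)

  manifest <- list(package_version =
                     as.character(utils::packageVersion("symptweet")),
                   seed = cfg$seed)

  # ---- corpus ----
  if (!is.null(cfg$corpus_path)) {
    raw <- load_corpus(cfg$corpus_path)
    cleaned <- clean_corpus(raw)
    tweets <- cleaned$tweets
    manifest$clean_report <- unclass(cleaned$report)
    labels <- utils::read.csv(cfg$labels_path, stringsAsFactors = FALSE)
    lab <- labels$label[match(tweets$id, labels$id)]
    keep_l <- which(!is.na(lab))
    pool_ids <- tweets$id[keep_l]; pool_y <- lab[keep_l]
    unlab_ids <- tweets$id[-keep_l]
    texts <- tweets$text
    names(texts) <- tweets$id
  } else {
    fx <- packaged_fixture(cfg$fixture)
    cleaned <- clean_corpus(fx$tweets)
    tweets <- cleaned$tweets
    manifest$clean_report <- unclass(cleaned$report)
    ann <- fx$annotations
    texts <- replace_urls(fx$tweets$text)
    names(texts) <- fx$tweets$id
    if (!is.null(fx$labelled_idx)) {
      pool_ids <- fx$tweets$id[fx$labelled_idx]
      pool_y <- ann$label[fx$labelled_idx]
      unlab_ids <- fx$tweets$id[fx$unlabelled_idx]
    } else {
      pool_ids <- ann$id[ann$is_base]
      pool_y <- ann$label[ann$is_base]
      unlab_ids <- character(0)
    }
  }
  manifest$n_labelled_pool <- length(pool_ids)
  manifest$n_unlabelled <- length(unlab_ids)

  # ---- split + featurise (vocabulary from training texts only) ----
  split_seed <- derive_seed(cfg$seed, "split")
  n_pool <- length(pool_ids)
  idx_h <- withr::with_seed(split_seed,
    sample.int(n_pool, size = round(cfg$holdout_fraction * n_pool)))
  train_ids <- pool_ids[-idx_h]; y_train <- pool_y[-idx_h]
  hold_ids <- pool_ids[idx_h];   y_hold <- pool_y[idx_h]

  tok <- lapply(texts, tokenize)
  vocab <- build_vocabulary(tok[train_ids], n_range = cfg$ngram_range,
                            min_doc_freq = cfg$min_doc_freq)
  all_ids <- c(train_ids, hold_ids, unlab_ids)
  feats <- featurize_corpus(tok[all_ids], vocab, ids = all_ids)
  X <- feats$X
  X_l <- X[train_ids, , drop = FALSE]
  X_h <- X[hold_ids, , drop = FALSE]
  X_u <- X[unlab_ids, , drop = FALSE]
  manifest$n_features <- ncol(X)

  spec <- learner_spec(cfg$family, cfg$hyperparams,
                       seed = derive_seed(cfg$seed, "learner"))
  train_X <- X_l; train_y <- y_train
  if (!is.null(cfg$oversample_to)) {
    os <- oversample(X_l, y_train, cfg$oversample_to,
                     seed = derive_seed(cfg$seed, "sample"))
    train_X <- os$X; train_y <- os$y
  }

  eval_model <- function(model) {
    pred <- predict_with_confidence(model, X_h)$label
    cm <- confusion(pred, y_hold)
    pr <- suppressWarnings(prf_accuracy(cm))
    list(precision = pr$precision, recall = pr$recall,
         accuracy = pr$accuracy,
         f1 = suppressWarnings(f_beta(pr$precision, pr$recall, 1)),
         f2 = suppressWarnings(f_beta(pr$precision, pr$recall, 2)),
         confusion = unclass(cm))
  }

  sup_model <- fit(spec, train_X, train_y)
  manifest$supervised <- eval_model(sup_model)
  best_model <- sup_model

  if (nrow(X_u) > 0 && cfg$method %in% c("self", "co", "both")) {
    cfg_it <- iter_label_config(theta = cfg$theta,
                                batch_size = cfg$batch_size,
                                patience = cfg$patience,
                                seed = derive_seed(cfg$seed, "semisup"))
    if (cfg$method %in% c("self", "both")) {
      st <- self_train(train_X, train_y, X_u, spec, cfg_it, X_h, y_hold)
      manifest$self_training <- eval_model(st$model)
      manifest$self_training$n_assimilated <-
        sum(st$trace$n_assimilated)
      if ((manifest$self_training$f2 %||% 0) >=
          (manifest$supervised$f2 %||% 0)) best_model <- st$model
    }
    if (cfg$method %in% c("co", "both")) {
      ct <- co_train(train_X, train_y, X_u, feats$blocks, spec, cfg_it,
                     X_h, y_hold)
      manifest$co_training <- eval_model(ct$model)
      manifest$co_training$n_assimilated <- sum(ct$trace$n_assimilated)
      if ((manifest$co_training$f2 %||% 0) >=
          (manifest$supervised$f2 %||% 0)) best_model <- ct$model
    }
  }

  # ---- optional signal stage ----
  if (!is.null(cfg$reference_path)) {
    ref <- utils::read.csv(cfg$reference_path,
                           stringsAsFactors = FALSE)
    ref <- data.frame(date = as.Date(ref[[1]]),
                      value = as.numeric(ref[[2]]))
    pred_all <- predict_with_confidence(best_model, X)$label
    classified <- data.frame(
      timestamp = tweets$timestamp[match(all_ids, tweets$id)],
      label = pred_all)
    classified <- classified[!is.na(classified$timestamp), ]
    sig <- daily_signal(classified, mode = "proportion")
    res <- correlate(moving_average(sig, cfg$window),
                     moving_average(ref, cfg$window))
    manifest$signal <- list(r = res$r, p = res$p, n = res$n)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}
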
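# Confidence-based iterative labelling: self-training on the full feature
# space and co-training on the taxonomical/sentimental view pair.

#' Configuration for iterative labelling
#'
#' @param theta confidence threshold in `(0, 1]`: an unlabelled instance
#'   is assimilated only when a learner's confidence in its predicted
#'   label strictly exceeds `theta`.
#' @param batch_size number of unlabelled instances offered per iteration
#'   (default 200).
#' @param patience number of consecutive iterations with hold-out F2
#'   strictly below the best seen before stopping (default 2).
#' @param max_iterations iteration cap.
#' @param seed integer seed (used when `shuffle = TRUE` and for refits).
#' @param shuffle offer unlabelled instances in seeded random order
#'   instead of stored order.
#' @return object of class `iter_label_config`.
#' @export
iter_label_config <- function(theta = 0.8, batch_size = 200, patience = 2,
                              max_iterations = Inf, seed = 1L,
                              shuffle = FALSE) {
  stopifnot(theta > 0, theta <= 1, batch_size >= 1, patience >= 1,
            max_iterations >= 1)
  structure(list(theta = theta, batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_iterations = max_iterations, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle)),
            class = "iter_label_config")
}

holdout_f2 <- function(model, X_h, y_h) {
  pred <- predict_with_confidence(model, X_h)$label
  cm <- confusion(pred, y_h)
  pr <- suppressWarnings(prf_accuracy(cm))
  p <- pr$precision; r <- pr$recall
  if (is.na(p) || is.na(r)) return(0)
  suppressWarnings(f_beta(p, r, 2))
}

check_semisup_inputs <- function(X_l, y_l, X_u, X_h, y_h) {
  if (nrow(X_l) == 0) stop("labelled set is empty")
  y_l <- as.character(as_label_factor(y_l))
  if (length(unique(y_l)) < 2)
    stop("labelled set must contain both classes")
  ids_l <- rownames(X_l); ids_u <- rownames(X_u); ids_h <- rownames(X_h)
  if (!is.null(ids_h) && (length(intersect(ids_h, ids_l)) > 0 ||
                          length(intersect(ids_h, ids_u)) > 0))
    stop("holdout set overlaps the labelled or unlabelled pool")
  y_l
}

# Shared engine for self-training (views = NULL) and co-training
# (views = list(X1 = idx, X2 = idx)). One sequential pass over U in
# stored (or seeded shuffled) order; instances below the threshold stay
# in U but are not re-offered.
iter_label_engine <- function(X_l, y_l, X_u, spec, cfg, X_h, y_h,
                              u_truth = NULL, views = NULL) {
  y_l <- check_semisup_inputs(X_l, y_l, X_u, X_h, y_h)
  y_h <- as.character(as_label_factor(y_h))
  n_u0 <- nrow(X_u)
  n_total <- nrow(X_l) + n_u0
  order_u <- seq_len(n_u0)
  if (cfg$shuffle && n_u0 > 0)
    order_u <- withr::with_seed(cfg$seed, sample.int(n_u0))

  cur_X <- X_l
  cur_y <- y_l
  co <- !is.null(views)

  fit_all <- function() {
    if (co) {
      list(m1 = fit(spec, cur_X[, views$X1, drop = FALSE], cur_y),
           m2 = fit(spec, cur_X[, views$X2, drop = FALSE], cur_y),
           mall = fit(spec, cur_X, cur_y))
    } else {
      list(mall = fit(spec, cur_X, cur_y))
    }
  }

  models <- fit_all()
  f2 <- holdout_f2(models$mall, X_h, y_h)
  trace <- data.frame(iteration = 0L, n_offered = 0L, n_assimilated = 0L,
                      n_correct = if (is.null(u_truth)) NA_integer_ else 0L,
                      n_labelled = nrow(cur_X), n_unlabelled = n_u0,
                      holdout_f2 = f2)
  best_f2 <- f2
  best_model <- models$mall
  deteriorating <- 0L
  assimilated <- rep(FALSE, n_u0)
  pos <- 1L
  iter <- 0L

  while (pos <= n_u0 && iter < cfg$max_iterations) {
    iter <- iter + 1L
    take <- order_u[pos:min(pos + cfg$batch_size - 1L, n_u0)]
    pos <- pos + length(take)
    Xb <- X_u[take, , drop = FALSE]

    if (co) {
      pr1 <- predict_with_confidence(models$m1,
                                     Xb[, views$X1, drop = FALSE])
      pr2 <- predict_with_confidence(models$m2,
                                     Xb[, views$X2, drop = FALSE])
      use1 <- pr1$confidence >= pr2$confidence
      # exact confidence tie with disagreeing labels: leave in U
      tie_disagree <- pr1$confidence == pr2$confidence &
        pr1$label != pr2$label
      lab <- ifelse(use1, pr1$label, pr2$label)
      conf <- pmax(pr1$confidence, pr2$confidence)
      assim <- conf > cfg$theta & !tie_disagree
    } else {
      pr <- predict_with_confidence(models$mall, Xb)
      lab <- pr$label
      conf <- pr$confidence
      assim <- conf > cfg$theta
    }

    n_correct <- if (is.null(u_truth)) NA_integer_ else
      sum(lab[assim] == u_truth[take[assim]])

    if (any(assim)) {
      assimilated[take[assim]] <- TRUE
      cur_X <- rbind(cur_X, Xb[assim, , drop = FALSE])
      cur_y <- c(cur_y, lab[assim])
      models <- fit_all()
    }
    f2 <- holdout_f2(models$mall, X_h, y_h)
    trace <- rbind(trace, data.frame(
      iteration = iter, n_offered = length(take),
      n_assimilated = sum(assim), n_correct = n_correct,
      n_labelled = nrow(cur_X),
      n_unlabelled = n_total - nrow(cur_X),
      holdout_f2 = f2))

    if (f2 > best_f2) {
      best_f2 <- f2
      best_model <- models$mall
      deteriorating <- 0L
    } else if (f2 < best_f2) {
      deteriorating <- deteriorating + 1L
      if (deteriorating >= cfg$patience) break
    } else {
      deteriorating <- 0L
    }
  }

  rownames(trace) <- NULL
  list(model = best_model, final_model = models$mall, trace = trace,
       labelled_X = cur_X, labelled_y = cur_y)
}

#' Self-training (confidence-based iterative labelling)
#'
#' Starting from a labelled seed set, repeatedly offers a batch of
#' unlabelled instances to the current classifier and assimilates into
#' the training set those it labels with confidence above `cfg$theta`,
#' refitting after each batch. Stops when the unlabelled pool has been
#' offered in full, the iteration cap is hit, or hold-out F2 has stayed
#' strictly below its best for `cfg$patience` consecutive iterations. The
#' returned model is the snapshot with the best hold-out F2.
#'
#' @param X_l,y_l labelled seed set (both classes present).
#' @param X_u unlabelled pool (same feature columns as `X_l`).
#' @param spec base [learner_spec()].
#' @param cfg an [iter_label_config()].
#' @param X_h,y_h labelled hold-out set, disjoint (by row names) from
#'   `X_l` and `X_u`, used for the stopping rule and model selection.
#' @param u_truth optional hidden truth for `X_u` rows (character vector
#'   aligned with `X_u`); only used to score assimilation correctness in
#'   the trace, never shown to the learner.
#' @return list with `model` (best-F2 snapshot), `final_model`, `trace`
#'   (per-iteration data.frame: `n_offered`, `n_assimilated`,
#'   `n_correct`, `n_labelled`, `n_unlabelled`, `holdout_f2`) and the
#'   grown labelled set (`labelled_X`, `labelled_y`).
#' @export
self_train <- function(X_l, y_l, X_u, spec, cfg, X_h, y_h,
                       u_truth = NULL) {
  iter_label_engine(X_l, y_l, X_u, spec, cfg, X_h, y_h, u_truth,
                    views = NULL)
}

#' Two-view co-training
#'
#' Maintains one learner per feature view (taxonomical `X1`: n-grams,
#' word classes, emoji indicators; sentimental `X2`: n-grams, pos/neg
#' word counts, emoji indicators). A batch instance is assimilated when
#' at least one view-learner exceeds the confidence threshold, taking the
#' more confident learner's label; on an exact confidence tie with
#' disagreeing labels the instance stays unlabelled. Both view-learners
#' are refit on the grown labelled set each iteration, and an
#' all-features learner is refit alongside them: that all-features model
#' is the one applied in practice, and the best hold-out-F2 snapshot of
#' it is returned.
#'
#' @inheritParams self_train
#' @param blocks feature-block labels over the columns of `X_l`/`X_u`
#'   (from [featurize_corpus()]), used to build the two views.
#' @return as [self_train()].
#' @export
co_train <- function(X_l, y_l, X_u, blocks, spec, cfg, X_h, y_h,
                     u_truth = NULL) {
  views <- build_views(blocks)
  if (length(views$X1) == 0 || length(views$X2) == 0)
    stop("view projection failed: a view has no features")
  iter_label_engine(X_l, y_l, X_u, spec, cfg, X_h, y_h, u_truth,
                    views = views)
}

#' Assimilation-quality diagnostic
#'
#' Runs the iterative labelling process against a pseudo-unlabelled set
#' whose true labels are withheld from the learner and used only for
#' scoring, and reports the fraction of assimilated instances per step
#' whose assigned pseudo-label matches the hidden truth.
#'
#' @inheritParams co_train
#' @param X_u,u_truth the pseudo-unlabelled instances and their hidden
#'   labels.
#' @param method `"self"` or `"co"`.
#' @return data.frame: one row per step with `n_assimilated`,
#'   `n_correct` and `prop_correct` (`NaN` where nothing was
#'   assimilated).
#' @export
assimilation_quality <- function(X_l, y_l, X_u, u_truth, spec, cfg,
                                 X_h, y_h, blocks = NULL,
                                 method = c("self", "co")) {
  method <- match.arg(method)
  res <- if (method == "self") {
    self_train(X_l, y_l, X_u, spec, cfg, X_h, y_h, u_truth = u_truth)
  } else {
    co_train(X_l, y_l, X_u, blocks, spec, cfg, X_h, y_h,
             u_truth = u_truth)
  }
  tr <- res$trace[res$trace$iteration > 0, , drop = FALSE]
  tr$prop_correct <- ifelse(tr$n_assimilated > 0,
                            tr$n_correct / tr$n_assimilated, NaN)
  tr[, c("iteration", "n_offered", "n_assimilated", "n_correct",
         "prop_correct")]
}

#' Paired comparison of two score vectors
#'
#' Two-sided paired t-test on per-resample performance scores (e.g. F2
#' over repeated splits).
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 2),
#'   paired by resample.
#' @return list with `t_statistic`, `p_value`, `mean_difference`, and
#'   `degenerate` (`TRUE` when the differences have zero variance; then
#'   `t_statistic` is 0 for identical vectors and `p_value` is 1, or both
#'   are `NA` for a constant non-zero difference).
#' @export
compare_models_paired <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t_statistic = 0, p_value = 1, mean_difference = 0,
                  degenerate = TRUE))
    warning("score differences have zero variance; t-test undefined")
    return(list(t_statistic = NA_real_, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = unname(tt$estimate), degenerate = FALSE)
}
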
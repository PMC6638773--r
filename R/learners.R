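# Uniform base-learner contract over five classifier families, plus an
# oracle stub used in diagnostics and tests. Labels are always the factor
# levels c("irrelevant", "relevant"), with "relevant" the positive class.

LABEL_LEVELS <- c("irrelevant", "relevant")

learner_defaults <- list(
  naive_bayes         = list(laplace = 0),
  decision_tree       = list(cp = 0.01, minsplit = 20),
  logistic_regression = list(C = 1e-5),
  svm                 = list(C = 0.01, gamma = NULL),
  mlp                 = list(hidden = c(128, 128), learning_rate = 1e-3,
                             alpha = 1e-4, batch_size = 200, epochs = 100),
  oracle              = list(labels = NULL, confidence = 0.99,
                             invert = FALSE)
)

#' Specify a base learner
#'
#' A learner specification names one of five classifier families and its
#' hyper-parameters. The defaults are the tuned settings used for the
#' relevance-classification task: logistic regression with L2 penalty and
#' `C = 1e-5`; RBF-kernel SVM with `C = 0.01`; an MLP with two hidden
#' layers of 128 units, learning rate 0.001, L2 penalty `alpha = 1e-4`,
#' batch size 200, 100 epochs, Adam. (`C` follows the usual
#' inverse-regularisation convention, so these defaults are strongly
#' regularised; pass e.g. `hyperparams = list(C = 1)` for a lightly
#' regularised fit.) The `"oracle"` family is a label-lookup stub (keyed
#' on row names) used to probe the semi-supervised machinery with a
#' perfect or deliberately wrong teacher.
#'
#' @param family one of `"naive_bayes"`, `"decision_tree"`,
#'   `"logistic_regression"`, `"svm"`, `"mlp"`, `"oracle"`.
#' @param hyperparams named list overriding the family defaults.
#' @param seed integer seed fixing every random choice made during
#'   fitting.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(family, hyperparams = list(), seed = 1L) {
  if (!family %in% names(learner_defaults))
    stop("unknown learner family: ", family)
  unknown <- setdiff(names(hyperparams), names(learner_defaults[[family]]))
  if (length(unknown) > 0)
    stop("invalid hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  hp <- modifyList(learner_defaults[[family]], hyperparams)
  structure(list(family = family, hyperparams = hp,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

as_label_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (!all(y %in% LABEL_LEVELS))
    stop("labels must be 'relevant' or 'irrelevant'")
  factor(y, levels = LABEL_LEVELS)
}

#' Train a base learner
#'
#' Fits the classifier named by `spec` on a numeric feature matrix. All
#' families share this contract; fitting is deterministic given
#' `spec$seed`.
#'
#' @param spec a [learner_spec()].
#' @param X numeric matrix, one row per instance (row names are instance
#'   ids; required by the `"oracle"` family).
#' @param y labels, `"relevant"`/`"irrelevant"`; both classes must be
#'   present.
#' @return object of class `symptweet_model`.
#' @export
fit <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("feature matrix contains NA/NaN/Inf values")
  if (spec$family != "oracle") {
    y <- as_label_factor(y)
    if (nrow(X) != length(y) || nrow(X) == 0)
      stop("X and y must be non-empty and of matching length")
    if (nlevels(droplevels(y)) < 2)
      stop("training data must contain both classes")
  }
  hp <- spec$hyperparams
  feature_names <- colnames(X)
  Xs <- X
  colnames(Xs) <- paste0("f", seq_len(ncol(Xs)))
  fitted <- withr::with_seed(spec$seed, switch(
    spec$family,
    naive_bayes = {
      nb <- e1071::naiveBayes(x = as.data.frame(Xs), y = y,
                              laplace = hp$laplace)
      # floor the per-class Gaussian sd so constant columns cannot
      # produce degenerate (0/Inf) densities at prediction time
      nb$tables <- lapply(nb$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-3)
        tb
      })
      nb
    },
    decision_tree = {
      df <- as.data.frame(Xs)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit))
    },
    logistic_regression = {
      Xg <- if (ncol(Xs) < 2) cbind(Xs, `f0` = 0) else Xs
      glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                     lambda = 1 / (hp$C * nrow(Xg)), standardize = FALSE)
    },
    svm = e1071::svm(
      Xs, y, kernel = "radial", cost = hp$C,
      gamma = hp$gamma %||% (1 / ncol(Xs)),
      probability = TRUE, scale = FALSE),
    mlp = mlp_fit(Xs, as.integer(y) - 1L, hidden = hp$hidden,
                  learning_rate = hp$learning_rate, alpha = hp$alpha,
                  batch_size = hp$batch_size, epochs = hp$epochs),
    oracle = {
      if (is.null(hp$labels)) stop("oracle learner needs hyperparams$labels")
      hp$labels
    }
  ))
  structure(list(spec = spec, fitted = fitted,
                 feature_names = feature_names, n_features = ncol(X)),
            class = "symptweet_model")
}

#' @export
print.symptweet_model <- function(x, ...) {
  cat("symptweet model (", x$spec$family, "), ", x$n_features,
      " features\n", sep = "")
  invisible(x)
}

# probability of the "relevant" class for every row of X
prob_relevant <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature dimension mismatch: model has ", model$n_features,
         ", data has ", ncol(X))
  Xs <- X
  colnames(Xs) <- paste0("f", seq_len(ncol(Xs)))
  fam <- model$spec$family
  hp <- model$spec$hyperparams
  p <- switch(
    fam,
    naive_bayes = {
      pr <- predict(model$fitted, as.data.frame(Xs), type = "raw",
                    threshold = 1e-3)
      pr[, "relevant"]
    },
    decision_tree = predict(model$fitted, as.data.frame(Xs))[, "relevant"],
    logistic_regression = {
      Xg <- if (ncol(Xs) < 2) cbind(Xs, `f0` = 0) else Xs
      as.numeric(predict(model$fitted, newx = Xg, type = "response"))
    },
    svm = {
      pr <- predict(model$fitted, Xs, probability = TRUE)
      attr(pr, "probabilities")[, "relevant"]
    },
    mlp = mlp_prob(model$fitted, Xs),
    oracle = {
      if (is.null(rownames(X)))
        stop("oracle learner needs row names on X")
      lab <- model$fitted[rownames(X)]
      if (any(is.na(lab))) stop("oracle has no label for some instances")
      if (isTRUE(hp$invert))
        lab <- ifelse(lab == "relevant", "irrelevant", "relevant")
      ifelse(lab == "relevant", hp$confidence, 1 - hp$confidence)
    }
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Predict labels with confidence
#'
#' The confidence is the model's estimated probability of the class it
#' predicts, hence always in `[0.5, 1]` for a two-class problem.
#'
#' @param model a fitted [fit()] model.
#' @param X numeric feature matrix.
#' @return data.frame with columns `label` (character) and `confidence`.
#' @export
predict_with_confidence <- function(model, X) {
  p <- prob_relevant(model, X)
  data.frame(
    label = ifelse(p >= 0.5, "relevant", "irrelevant"),
    confidence = pmax(p, 1 - p),
    stringsAsFactors = FALSE
  )
}

#' Grid search over learner specifications
#'
#' Evaluates each candidate specification on a seeded hold-out split of
#' the training data and returns the one maximising the requested
#' F-measure; ties are broken in favour of the earlier entry in the grid.
#'
#' @param grid list of [learner_spec()] objects.
#' @param X,y training data.
#' @param holdout_fraction fraction of the training partition held out
#'   for scoring (default 0.1).
#' @param metric `"F2"` or `"F1"`.
#' @param seed seed for the hold-out split.
#' @return the winning `learner_spec`, with attributes `score` and
#'   `scores` (all candidate scores).
#' @export
grid_search <- function(grid, X, y, holdout_fraction = 0.1,
                        metric = c("F2", "F1"), seed = 1L) {
  metric <- match.arg(metric)
  if (length(grid) == 0) stop("empty specification grid")
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  beta <- if (metric == "F2") 2 else 1
  y <- as_label_factor(y)
  n <- nrow(X)
  idx_h <- withr::with_seed(seed,
    sample.int(n, size = max(1, round(holdout_fraction * n))))
  Xt <- X[-idx_h, , drop = FALSE]; yt <- y[-idx_h]
  Xh <- X[idx_h, , drop = FALSE];  yh <- y[idx_h]
  scores <- vapply(grid, function(sp) {
    model <- fit(sp, Xt, yt)
    pred <- predict_with_confidence(model, Xh)$label
    cm <- confusion(pred, as.character(yh))
    pr <- prf_accuracy(cm)
    if (is.na(pr$precision) || is.na(pr$recall)) return(0)
    f_beta(pr$precision, pr$recall, beta)
  }, numeric(1))
  best <- which.max(scores)  # which.max takes the first maximum
  out <- grid[[best]]
  attr(out, "score") <- scores[best]
  attr(out, "scores") <- scores
  out
}

#' Random oversampling of the minority class
#'
#' Duplicates randomly chosen minority-class instances (with replacement)
#' until the minority fraction reaches the target. Apply to training data
#' only; evaluation data must stay unbalanced.
#'
#' @param X,y training data.
#' @param target_minority_fraction target fraction in `(0, 0.5]`
#'   (default 0.47, the balance used for the relevance task).
#' @param seed integer seed.
#' @return list with the augmented `X` and `y`; the original instances
#'   are always a sub-multiset of the output.
#' @export
oversample <- function(X, y, target_minority_fraction = 0.47, seed = 1L) {
  stopifnot(target_minority_fraction > 0, target_minority_fraction <= 0.5)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n <- length(y); n_min <- min(tab)
  t <- target_minority_fraction
  if (n_min / n >= t) return(list(X = X, y = as.character(y)))
  m <- ceiling((t * n - n_min) / (1 - t))
  extra <- withr::with_seed(seed,
    sample(which(y == minority), size = m, replace = TRUE))
  list(X = rbind(X, X[extra, , drop = FALSE]),
       y = as.character(c(as.character(y), as.character(y[extra]))))
}
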
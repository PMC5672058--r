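# LDA feature construction, cross-validated regular classification,
# cross-classification transfer tests, and binomial chance-level
# thresholding.

#' Build LDA feature vectors from epochs
#'
#' One vector per trial: the per-trial band amplitude (inner mean over band
#' bins) at each of the 20 sensorimotor feature electrodes, for the alpha
#' band (20 features) or alpha followed by beta (40 features).  Electrode
#' order is fixed by [feature_electrodes()].  Electrodes invalid in more
#' than `max_missing` of the trials are dropped from the feature set (for
#' both bands) and reported via the `"dropped"` attribute; remaining trials
#' with a masked retained electrode are omitted.
#'
#' @param epochs An `epoch_collection` (128 Hz, 2-s windows).
#' @param bands `"alpha"` or `c("alpha", "beta")`.
#' @param electrodes Feature electrode set (ordered).
#' @param max_missing Maximal tolerated fraction of trials missing per
#'   electrode before the electrode is dropped.
#' @return A `feature_set`: list with `x` (trials x features matrix),
#'   `label` (condition per trial), `origin`, `trial`, `electrodes`,
#'   `bands`.
#' @export
build_features <- function(epochs, bands = "alpha",
                           electrodes = feature_electrodes(),
                           max_missing = 0.2) {
  stopifnot(all(bands %in% names(analysis_bands())))
  stopifnot(all(electrodes %in% epochs$labels))
  amp_list <- lapply(analysis_bands()[bands], function(b)
    band_amplitudes(epochs, b)[, electrodes, drop = FALSE])
  miss_frac <- colMeans(is.na(amp_list[[1]]))
  drop <- names(miss_frac)[miss_frac > max_missing]
  keep_el <- setdiff(electrodes, drop)
  if (!length(keep_el)) stop("all feature electrodes dropped", call. = FALSE)
  x <- do.call(cbind, lapply(seq_along(bands), function(i) {
    m <- amp_list[[i]][, keep_el, drop = FALSE]
    colnames(m) <- paste0(keep_el, ".", bands[i])
    m
  }))
  keep_tr <- stats::complete.cases(x)
  out <- list(x = x[keep_tr, , drop = FALSE],
              label = epochs$condition[keep_tr],
              origin = epochs$origin[keep_tr],
              trial = epochs$trial[keep_tr],
              electrodes = keep_el, bands = bands)
  attr(out, "dropped") <- drop
  class(out) <- "feature_set"
  out
}

#' Select a binary condition-vs-rest problem from a feature set
#'
#' @param features A `feature_set`.
#' @param condition Positive-class condition.
#' @param rest_origin Block origin of the rest trials (defaults to the
#'   condition's own block type, the "individual baseline" convention).
#' @return A `feature_set` restricted to the two classes, with labels
#'   `condition` and `"REST"`.
#' @export
binary_problem <- function(features, condition,
                           rest_origin = substr(condition, 1, 2)) {
  sel <- features$label == condition |
    (features$label == "REST" & features$origin == rest_origin)
  out <- features
  out$x <- features$x[sel, , drop = FALSE]
  out$label <- features$label[sel]
  out$origin <- features$origin[sel]
  out$trial <- features$trial[sel]
  out
}

#' Train a two-class linear discriminant
#'
#' Closed-form LDA with pooled within-class covariance and empirical class
#' priors.  The weight vector is `solve(S_pooled, mean1 - mean0)`; the
#' decision threshold incorporates the prior log-odds.  When the pooled
#' covariance is numerically singular, diagonal loading (shrinkage toward
#' the average variance) is applied with an escalating coefficient and
#' recorded in the model.
#'
#' @param x Trials x features numeric matrix.
#' @param y Class labels (exactly two distinct values).  The *second* level
#'   in sorted order is treated as the positive class unless `positive` is
#'   given; with condition-vs-REST labels the condition is positive.
#' @param positive Label of the positive class.
#' @param shrinkage Initial shrinkage coefficient (0 = plain LDA).
#' @return An `lda_model`: means, pooled covariance, weights `w`, bias
#'   `b` (classify positive when `x %*% w + b > 0`; ties go to the negative
#'   class, i.e. REST), priors, shrinkage used.
#' @export
lda_train <- function(x, y, positive = NULL, shrinkage = 0) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("REST" %in% classes) setdiff(classes, "REST") else classes[2]
  }
  negative <- setdiff(classes, positive)
  n1 <- sum(y == positive); n0 <- sum(y == negative)
  if (min(n0, n1) < 2) stop("need at least 2 trials per class", call. = FALSE)
  x1 <- x[y == positive, , drop = FALSE]
  x0 <- x[y == negative, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  S <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x0, 2, m0))) /
    (n0 + n1 - 2)
  lam <- shrinkage
  repeat {
    Sr <- S
    if (lam > 0) {
      Sr <- (1 - lam) * S + lam * mean(diag(S)) * diag(ncol(S))
    }
    w <- tryCatch(solve(Sr, m1 - m0), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    lam <- if (lam == 0) 1e-6 else lam * 10
    if (lam > 1) stop("covariance irreparably singular", call. = FALSE)
  }
  b <- -sum(w * (m1 + m0)) / 2 + log(n1 / n0)
  structure(list(classes = c(negative = negative, positive = positive),
                 mean0 = m0, mean1 = m1, cov = S, w = w, b = b,
                 priors = c(n0, n1) / (n0 + n1), shrinkage = lam),
            class = "lda_model")
}

#' Predict with a trained discriminant
#'
#' @param model An `lda_model`.
#' @param x Trials x features matrix (same feature order as training).
#' @return Character vector of predicted labels.  A tie on the discriminant
#'   score predicts the negative class (REST).
#' @export
lda_predict <- function(model, x) {
  score <- as.vector(as.matrix(x) %*% model$w) + model$b
  ifelse(score > 0, model$classes[["positive"]], model$classes[["negative"]])
}

#' Binomial chance-level threshold for a binary classifier
#'
#' The smallest number of correct predictions k whose cumulative binomial
#' probability reaches `1 - alpha` under random guessing, returned as a
#' proportion k/n.  With about 90 trials per classification this gives the
#' conventional ~59% chance level.
#'
#' @param n_trials Number of classified trials (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param p0 Null success probability.
#' @return Threshold proportion in (0, 1].
#' @export
chance_threshold <- function(n_trials, alpha = 0.05, p0 = 0.5) {
  stopifnot(n_trials >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  k <- stats::qbinom(1 - alpha, n_trials, p0)
  k / n_trials
}

new_report <- function(confusion, fold_acc, positive, negative, kind,
                       alpha = 0.05) {
  n <- sum(confusion)
  acc <- sum(diag(confusion)) / n
  thr <- chance_threshold(n, alpha)
  structure(list(accuracy = 100 * acc, confusion = confusion,
                 fold_accuracies = 100 * fold_acc, n_trials = n,
                 chance_threshold = 100 * thr,
                 above_chance = acc > thr, positive = positive,
                 negative = negative, kind = kind),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s: %s vs %s\n", x$kind, x$positive,
              x$negative))
  cat(sprintf("  accuracy %.1f%% (n = %d, chance level %.1f%%, %s)\n",
              x$accuracy, x$n_trials, x$chance_threshold,
              if (x$above_chance) "above chance" else "not above chance"))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation of the discriminant
#'
#' Folds are stratified by class, shuffled once from `seed`, and the fold
#' confusion matrices are aggregated into one report (rows = actual,
#' columns = predicted, positive class first).  `k = n` requests
#' leave-one-out.
#'
#' @param x Trials x features matrix.
#' @param y Labels (two classes).
#' @param k Number of folds.
#' @param seed RNG seed for the fold shuffle.
#' @param positive Positive-class label (see [lda_train()]).
#' @return A `classification_report`.
#' @export
crossvalidate <- function(x, y, k = 5, seed = 1, positive = NULL) {
  x <- as.matrix(x); y <- as.character(y)
  n <- nrow(x)
  stopifnot(length(y) == n)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("REST" %in% classes) setdiff(classes, "REST") else classes[2]
  }
  negative <- setdiff(classes, positive)
  fold <- integer(n)
  if (k >= n) {                              # leave-one-out
    k <- n
    fold <- seq_len(n)
  } else {
    if (min(table(y)) < k) stop("each class needs at least k trials", call. = FALSE)
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
    for (cl in classes) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  conf <- matrix(0, 2, 2, dimnames = list(actual = c(positive, negative),
                                          predicted = c(positive, negative)))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- lda_train(x[!test, , drop = FALSE], y[!test], positive = positive)
    pred <- lda_predict(model, x[test, , drop = FALSE])
    fold_acc[f] <- mean(pred == y[test])
    for (cl_a in c(positive, negative)) for (cl_p in c(positive, negative)) {
      conf[cl_a, cl_p] <- conf[cl_a, cl_p] + sum(y[test] == cl_a & pred == cl_p)
    }
  }
  new_report(conf, fold_acc, positive, negative, kind = "regular (cross-validated)")
}

#' Cross-classification transfer test
#'
#' Trains the discriminant once on all training trials (condition A vs its
#' own rest baseline) and evaluates it once on all test trials (condition B
#' vs the *test* condition's rest baseline).  Train and test trial sets
#' must be disjoint and share an identical feature space.
#'
#' @param train A `feature_set` with two classes (condition vs REST).
#' @param test A `feature_set` with two classes (other condition vs REST).
#' @return A `classification_report`; rows of the confusion matrix are the
#'   actual test classes, the positive prediction retains the training
#'   condition's name.
#' @export
cross_classify <- function(train, test) {
  stopifnot(inherits(train, "feature_set"), inherits(test, "feature_set"))
  if (!identical(colnames(train$x), colnames(test$x))) {
    stop("train/test feature spaces differ (electrode dropped in one only)",
         call. = FALSE)
  }
  if (length(common <- intersect(train$trial, test$trial)) &&
      any(train$label[match(common, train$trial)] != "REST" |
            test$label[match(common, test$trial)] != "REST")) {
    stop("train and test trial sets must be disjoint", call. = FALSE)
  }
  pos_tr <- setdiff(unique(train$label), "REST")
  pos_te <- setdiff(unique(test$label), "REST")
  stopifnot(length(pos_tr) == 1, length(pos_te) == 1)
  model <- lda_train(train$x, train$label, positive = pos_tr)
  pred <- lda_predict(model, test$x)
  actual <- test$label
  conf <- matrix(0, 2, 2, dimnames = list(actual = c(pos_te, "REST"),
                                          predicted = c(pos_tr, "REST")))
  conf[1, 1] <- sum(actual == pos_te & pred == pos_tr)
  conf[1, 2] <- sum(actual == pos_te & pred == "REST")
  conf[2, 1] <- sum(actual == "REST" & pred == pos_tr)
  conf[2, 2] <- sum(actual == "REST" & pred == "REST")
  rep <- new_report(conf, fold_acc = sum(diag(conf)) / sum(conf),
                    positive = paste0(pos_tr, "/", pos_te),
                    negative = "REST", kind = "cross-classification")
  rep
}
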
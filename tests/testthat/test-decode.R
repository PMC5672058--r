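make_gaussian_problem <- function(n_per_class = 30, p = 4, delta = 0,
                                  seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = delta), ncol = p))
  y <- rep(c("REST", "MT_LOW"), each = n_per_class)
  list(x = x, y = y)
}

test_that("feature vectors have 20 (alpha) or 40 (alpha+beta) entries", {
  cfg <- tiny_config(n_trials = 4, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 19)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  fa <- build_features(ep, "alpha")
  expect_equal(ncol(fa$x), 20)
  expect_identical(fa$electrodes, feature_electrodes())
  fab <- build_features(ep, c("alpha", "beta"))
  expect_equal(ncol(fab$x), 40)
  expect_identical(colnames(fab$x)[1:20], paste0(feature_electrodes(), ".alpha"))
  expect_identical(colnames(fab$x)[21:40], paste0(feature_electrodes(), ".beta"))
})

test_that("a constant-spectrum trial yields constant features", {
  # an impulse train has a flat magnitude spectrum
  n_ch <- 64; n <- 256
  lay <- standard_layout()
  data <- array(0, c(n_ch, n, 4))
  data[, 1, ] <- 256                      # unit-amplitude flat spectrum
  ep <- mucross:::new_epoch_collection(
    data = data, rate = 128, labels = lay$names,
    condition = c("MT_LOW", "MT_LOW", "REST", "REST"),
    block = rep(1L, 4), origin = rep("MT", 4), trial = 1:4,
    valid = matrix(TRUE, n_ch, 4))
  f <- build_features(ep, "alpha")
  expect_true(all(abs(f$x - 2) < 1e-9))   # amplitude 2/N * N = 2 per bin
})

test_that("electrodes missing in too many trials are dropped consistently", {
  cfg <- tiny_config(n_trials = 5, eog_rate = 0)
  sim <- simulate_subject(cfg, seed = 20)
  rec <- preprocess_recording(sim$recording, calibration = NULL)
  ep <- extract_epochs(rec)
  ep$valid[match("C3", ep$labels), ] <- FALSE
  f <- build_features(ep, "alpha")
  expect_equal(ncol(f$x), 19)
  expect_identical(attr(f, "dropped"), "C3")
})

test_that("LDA separates distant clouds and is at chance for null data", {
  sep <- make_gaussian_problem(delta = 8, seed = 2)
  model <- lda_train(sep$x, sep$y)
  expect_equal(mean(lda_predict(model, sep$x) == sep$y), 1)
  null <- make_gaussian_problem(n_per_class = 100, delta = 0, seed = 3)
  hold <- make_gaussian_problem(n_per_class = 100, delta = 0, seed = 4)
  m0 <- lda_train(null$x, null$y)
  acc <- mean(lda_predict(m0, hold$x) == hold$y)
  expect_gt(acc, 0.38); expect_lt(acc, 0.62)
})

test_that("LDA weights equal the closed form on a hand-computed system", {
  # two features; pooled covariance [[2, 1], [1, 2]], mean diff (1, 3):
  # solve(S, d) = (1/3) * [2*1 - 1*3, 2*3 - 1*1] = (-1/3, 5/3)
  S <- matrix(c(2, 1, 1, 2), 2)
  d <- c(1, 3)
  manual <- c(-1 / 3, 5 / 3)
  expect_equal(solve(S, d), manual, tolerance = 1e-10)
  # build a dataset whose pooled covariance and mean difference are exact
  base <- matrix(c(1, 1, -1, -1, 1, -1, 1, -1), 4)   # zero-mean, cov 4/3*I
  A <- chol(S)
  cloud <- base %*% A * sqrt(3) / 2                  # empirical cov = S
  x <- rbind(sweep(cloud, 2, c(0, 0), "+"), sweep(cloud, 2, d, "+"))
  y <- rep(c("REST", "MT_LOW"), each = 4)
  model <- lda_train(x, y)
  expect_equal(unname(model$cov), S, tolerance = 1e-10)
  expect_equal(unname(model$w), manual, tolerance = 1e-10)
})

test_that("predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  pr <- make_gaussian_problem(n_per_class = 40, p = 5, delta = 0.8, seed = 5)
  model <- lda_train(pr$x, pr$y)
  fit <- MASS::lda(pr$x, grouping = pr$y)
  test <- make_gaussian_problem(n_per_class = 40, p = 5, delta = 0.8, seed = 6)
  expect_identical(lda_predict(model, test$x),
                   as.character(predict(fit, test$x)$class))
})

test_that("stratified cross-validation is deterministic and sane", {
  sep <- make_gaussian_problem(n_per_class = 20, delta = 6, seed = 7)
  rep1 <- crossvalidate(sep$x, sep$y, k = 5, seed = 11)
  rep2 <- crossvalidate(sep$x, sep$y, k = 5, seed = 11)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_equal(rep1$accuracy, 100)
  expect_equal(sum(rep1$confusion), rep1$n_trials)
  # shuffled labels: within binomial noise of 50%
  set.seed(8)
  shuf <- make_gaussian_problem(n_per_class = 50, delta = 3, seed = 8)
  yperm <- sample(shuf$y)
  racc <- crossvalidate(shuf$x, yperm, k = 5, seed = 9)$accuracy
  expect_gt(racc, 35); expect_lt(racc, 65)
  small <- c(1:3, 51:53)                 # 3 per class, fewer than k folds
  expect_error(crossvalidate(shuf$x[small, ], shuf$y[small], k = 5),
               "at least")
})

test_that("leave-one-out on a 6-trial toy set matches manual enumeration", {
  x <- matrix(c(0.1, 0.3, -0.2, 1.9, 2.2, 2.0,
                0.0, 0.2, 0.1, 1.0, 1.2, 0.8), ncol = 2)
  y <- rep(c("REST", "MT_LOW"), each = 3)
  rep_loo <- crossvalidate(x, y, k = 6)
  preds <- character(6)
  for (i in 1:6) {
    m <- lda_train(x[-i, , drop = FALSE], y[-i])
    preds[i] <- lda_predict(m, x[i, , drop = FALSE])
  }
  expect_equal(rep_loo$accuracy, 100 * mean(preds == y))
  conf <- table(factor(y, c("MT_LOW", "REST")),
                factor(preds, c("MT_LOW", "REST")))
  expect_equal(unclass(rep_loo$confusion), unclass(conf), ignore_attr = TRUE)
})

test_that("cross-classification trains once and refuses mismatched spaces", {
  tr <- make_gaussian_problem(n_per_class = 30, delta = 2, seed = 10)
  te <- make_gaussian_problem(n_per_class = 30, delta = 2, seed = 11)
  fs <- function(pr, trial0) {
    structure(list(x = `colnames<-`(pr$x, c("C3.alpha", "C4.alpha",
                                            "CP3.alpha", "CP4.alpha")),
                   label = pr$y, origin = "MT",
                   trial = trial0 + seq_along(pr$y),
                   electrodes = c("C3", "C4", "CP3", "CP4"), bands = "alpha"),
              class = "feature_set")
  }
  rep_cc <- cross_classify(fs(tr, 0), fs(te, 1000))
  rep_cv <- crossvalidate(te$x, te$y, k = 5, seed = 1)
  expect_lt(abs(rep_cc$accuracy - rep_cv$accuracy), 15)  # consistency, noisy
  bad <- fs(te, 1000)
  colnames(bad$x)[1] <- "Cz.alpha"
  expect_error(cross_classify(fs(tr, 0), bad), "feature spaces differ")
})

test_that("the binomial chance threshold matches its defining examples", {
  expect_equal(chance_threshold(90), 53 / 90)       # the ~58.9% convention
  expect_equal(round(100 * chance_threshold(90), 1), 58.9)
  expect_equal(chance_threshold(1), 1)
  # n = 100 against a direct pmf-summation oracle
  n <- 100
  cdf <- cumsum(choose(n, 0:n) * 0.5^n)
  k <- which(cdf >= 0.95)[1] - 1
  expect_equal(chance_threshold(100), k / n)
  expect_error(chance_threshold(10, alpha = 1.2), "alpha")
})

test_that("LDA predictions agree with the least-squares formulation", {
  # two-class LDA direction is proportional to the least-squares weights
  for (seed in 1:5) {
    pr <- make_gaussian_problem(n_per_class = 25, p = 3, delta = 1, seed = seed)
    model <- lda_train(pr$x, pr$y)
    z <- ifelse(pr$y == model$classes[["positive"]], 1, -1)
    beta <- stats::coef(stats::lm(z ~ pr$x))[-1]
    expect_gt(abs(cor(as.vector(model$w), as.vector(beta))), 1 - 1e-8)
  }
})
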
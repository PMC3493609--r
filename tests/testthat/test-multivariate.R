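random_instance <- function(seed, n = 30, p = 8) {
  withr::with_seed(seed, {
    X <- matrix(exp(rnorm(n * p, 0, 0.5)), n, p,
                dimnames = list(NULL, paste0("m", seq_len(p))))
    list(X = X, y = sample(rep(0:1, length.out = n)))
  })
}

test_that("preprocessing centers, scales and inverts on training data", {
  d <- random_instance(1)
  pre <- fit_preprocessor(d$X)
  Z <- predict(pre, d$X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
  back <- inverse_preprocess(pre, Z)
  expect_lt(max(abs(back - d$X) / d$X), 1e-10)
  const <- d$X; const[, 2] <- 4
  expect_error(fit_preprocessor(const), "zero-variance.*m2")
  expect_error(fit_preprocessor(d$X - 10), "positive")
})

test_that("one-component PLS-DA reduces to least squares on a single feature", {
  d <- random_instance(2, p = 1)
  model <- fit_pls_da(d$X, d$y, n_components = 1)
  z <- scale(log(d$X))
  ls <- lm(y ~ z, data = data.frame(y = d$y, z = z))
  expect_equal(unname(model$fitted), unname(fitted(ls)), tolerance = 1e-10)
})

test_that("the first PLS weight vector is proportional to X'y", {
  d <- random_instance(3)
  model <- fit_pls_da(d$X, d$y, n_components = 2)
  Z <- predict(model$preproc, d$X)
  yc <- d$y - mean(d$y)
  w_ref <- crossprod(Z, yc)
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(unname(drop(model$weights[, 1])), unname(drop(w_ref)),
               tolerance = 1e-12)
})

test_that("NIPALS score vectors are mutually orthogonal", {
  for (s in 1:5) {
    d <- random_instance(10 + s, n = 25, p = 10)
    model <- fit_pls_da(d$X, d$y, n_components = 4)
    G <- crossprod(model$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
})

test_that("strong planted effects are perfectly separated in training", {
  d <- make_planted(4, n_informative = 2, n_noise = 5, shift_sd = 6)
  model <- fit_pls_da(d$X, d$y, n_components = 2)
  expect_equal(model$auroc_train, 1.0)
  expect_error(fit_pls_da(d$X, d$y, n_components = 40), "rank")
})

test_that("OPLS-DA equals one-more-component PLS-DA in prediction", {
  d <- random_instance(5, n = 28, p = 9)
  opls0 <- fit_opls_da(d$X, d$y, n_orthogonal = 0)
  pls1 <- fit_pls_da(d$X, d$y, n_components = 1)
  expect_equal(predict(opls0, d$X), predict(pls1, d$X), tolerance = 1e-10)
  for (k in 1:3) {
    opls <- fit_opls_da(d$X, d$y, n_orthogonal = k)
    pls <- fit_pls_da(d$X, d$y, n_components = k + 1)
    expect_lt(max(abs(predict(opls, d$X) - predict(pls, d$X))), 1e-8)
    # orthogonal scores carry no label information
    yc <- d$y - mean(d$y)
    for (a in seq_len(k)) {
      expect_lt(abs(sum(opls$ortho_scores[, a] * yc)), 1e-10)
    }
  }
  expect_error(fit_opls_da(d$X, d$y, n_orthogonal = 30), "rank")
})

test_that("independent NIPALS implementation agrees with ours", {
  d <- random_instance(6, n = 26, p = 7)
  ours <- fit_pls_da(d$X, d$y, n_components = 2)
  ref <- mixOmics::pls(log(d$X), d$y, ncomp = 2, scale = TRUE, mode = "regression")
  for (a in 1:2) {
    expect_gt(abs(cor(ours$scores[, a], ref$variates$X[, a])), 1 - 1e-9)
  }
})

test_that("Q2 is 1 for perfectly predictable labels and matches a LOO oracle", {
  y <- rep(c(0, 1), each = 8)
  X <- matrix(exp(y + 1), ncol = 1, dimnames = list(NULL, "m"))
  # the single feature is a deterministic function of the label
  expect_equal(q_squared(X, y, n_folds = 4, seed = 2,
                         fit_fun = function(X, y) fit_pls_da(X, y, 1)),
               1, tolerance = 1e-10)
  # smallest stratified folds on a 6-subject toy set (one subject per class
  # per fold, the blocked assignment) vs a hand-rolled lm PRESS oracle
  withr::with_seed(9, {
    x <- exp(rnorm(6)); yy <- c(0, 1, 0, 1, 0, 1)
    Xm <- matrix(x, ncol = 1, dimnames = list(NULL, "m"))
    fold <- c(1, 1, 2, 2, 3, 3)
    press <- 0; tss <- 0
    for (k in 1:3) {
      test <- fold == k
      fit <- lm(y ~ lx, data = data.frame(y = yy[!test], lx = log(x[!test])))
      pred <- predict(fit, newdata = data.frame(lx = log(x[test])))
      press <- press + sum((yy[test] - pred)^2)
      tss <- tss + sum((yy[test] - mean(yy[!test]))^2)
    }
    got <- q_squared(Xm, yy, n_folds = 3, fold_scheme = "blocked",
                     fit_fun = function(X, y) fit_pls_da(X, y, 1))
    expect_equal(got, unname(1 - press / tss), tolerance = 1e-10)
  })
})

test_that("cross-validated Q2 does not exceed fit R2 on random instances", {
  exceed <- 0
  for (s in 1:20) {
    d <- make_planted(100 + s, n_informative = 1, n_noise = 6,
                      shift_sd = 2, n0 = 10, n1 = 20)
    model <- fit_pls_da(d$X, d$y, n_components = 2)
    q2 <- q_squared(d$X, d$y, n_folds = 5, seed = s)
    if (q2 > model$r2y) exceed <- exceed + 1
  }
  expect_lte(exceed, 1)
})

test_that("AUROC equals exhaustive pair counting and is rank-invariant", {
  expect_equal(auroc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  withr::with_seed(12, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      sc <- sample(1:5, n, replace = TRUE)  # ties likely
      lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      pairs <- outer(sc[lb == 1], sc[lb == 0],
                     function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(auroc(sc, lb), mean(pairs))
      expect_equal(auroc(exp(sc), lb), auroc(sc, lb))
    }
  })
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  withr::with_seed(13, {
    sc <- rnorm(40); lb <- sample(0:1, 40, replace = TRUE)
    ref <- suppressMessages(as.numeric(pROC::auc(lb, sc, direction = "<")))
    expect_equal(auroc(sc, lb), ref, tolerance = 1e-12)
  })
})

test_that("external validation partitions the cohort into stratified thirds", {
  co <- generate_cohort(default_study_spec(), seed = 3)
  X <- conc_matrix(co)
  ev <- external_validation(X, co$group, seed = 21)
  expect_setequal(ev$per_repeat$n_test, c(18L, 18L, 19L))
  expect_equal(sum(ev$per_repeat$n_test), nrow(X))
  # every subject is in exactly one test set
  expect_equal(sort(unique(ev$assignment)), 1:3)
  expect_equal(length(ev$assignment), nrow(X))
  ev2 <- external_validation(X, co$group, seed = 21)
  expect_identical(ev$assignment, ev2$assignment)
  # the planted group effect is detected out of sample
  expect_gt(mean(ev$per_repeat$auroc_test), 0.9)
  expect_equal(ev$summary$mean[3], mean(ev$per_repeat$auroc_test))
})

test_that("model accessors expose tidy loadings and fit summaries", {
  d <- make_planted(7, n_informative = 2, n_noise = 4)
  model <- fit_opls_da(d$X, d$y, n_orthogonal = 1)
  td <- tidy(model)
  expect_equal(sort(td$term), sort(colnames(d$X)))
  expect_false(is.unsorted(td$loading))
  gl <- glance(model)
  expect_equal(gl$kind, "OPLS-DA")
  expect_true(gl$r2y >= 0 && gl$r2y <= 1)
  expect_s3_class(autoplot(model), "ggplot")
  expect_s3_class(plot_loadings(model), "ggplot")
})
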
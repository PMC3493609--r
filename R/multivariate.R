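#' Fit a log / center / unit-variance preprocessor
#'
#' Concentrations are natural-log transformed, then each feature is
#' centered and scaled to unit variance. Parameters are estimated from the
#' supplied (training) rows only, so the same object can transform held-out
#' data without leakage.
#'
#' @param X Strictly positive subjects-by-features matrix.
#' @param transform `"log"` (default) or `"none"` for data already on a
#'   modeling scale.
#' @return A `lipid_preproc` object.
#' @export
fit_preprocessor <- function(X, transform = c("log", "none")) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  if (transform == "log") {
    if (any(X <= 0, na.rm = TRUE)) abort("log preprocessing requires positive values")
    X <- log(X)
  }
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  zero <- which(scale == 0 | !is.finite(scale))
  if (length(zero) > 0) {
    abort(paste0("zero-variance feature(s): ",
                 paste(colnames(X)[zero] %||% zero, collapse = ", ")))
  }
  structure(list(transform = transform, center = center, scale = scale,
                 features = colnames(X)),
            class = "lipid_preproc")
}

#' @export
predict.lipid_preproc <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features %||% TRUE, drop = FALSE]
  if (object$transform == "log") X <- log(X)
  sweep(sweep(X, 2, object$center), 2, object$scale, "/")
}

#' Invert a preprocessor transform
#' @param object A `lipid_preproc`.
#' @param Z Preprocessed matrix.
#' @export
inverse_preprocess <- function(object, Z) {
  X <- sweep(sweep(as.matrix(Z), 2, object$scale, "*"), 2, object$center, "+")
  if (object$transform == "log") X <- exp(X)
  X
}

# NIPALS PLS1 on centered X and centered y. With a single response the
# weight step is closed-form, so each component costs a few matrix
# products. Returns weights W, loadings P, scores T, y-loadings c and the
# regression vector in the centered space.
pls1_nipals <- function(Xc, yc, ncomp) {
  p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(Xc), ncomp); cvec <- numeric(ncomp)
  E <- Xc; f <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) abort("n_components exceeds the informative rank of X")
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) abort("degenerate score vector; reduce n_components")
    pv <- crossprod(E, t) / tt
    cc <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - cc * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; cvec[a] <- cc
  }
  # b = W (P'W)^-1 c maps centered X to centered predictions
  b <- W %*% solve(crossprod(P, W), cvec)
  list(W = W, P = P, scores = Tm, c = cvec, coef = b)
}

encode_labels <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) abort("discriminant models require exactly two classes")
  list(levels = levels(f), y01 = as.numeric(f) - 1)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Binary partial least squares discriminant analysis: the class label is
#' coded 0/1 and centered, features are log/center/scale preprocessed
#' (fitted on the supplied rows), and latent components are extracted by
#' NIPALS with iterative deflation. Deterministic given `X` and `y`.
#'
#' @param X Subjects-by-features matrix of positive concentrations.
#' @param y Two-level class labels (first factor level is coded 0).
#' @param n_components Number of latent components.
#' @param transform Preprocessor transform (see [fit_preprocessor()]).
#' @return A `lipid_pls` model object.
#' @export
fit_pls_da <- function(X, y, n_components = 2, transform = "log") {
  X <- as.matrix(X)
  lab <- encode_labels(y)
  if (n_components > qr(scale(X, scale = FALSE))$rank) {
    abort("n_components exceeds the rank of X")
  }
  pre <- fit_preprocessor(X, transform = transform)
  Z <- predict(pre, X)
  yc <- lab$y01 - mean(lab$y01)
  fit <- pls1_nipals(Z, yc, n_components)
  fitted <- drop(Z %*% fit$coef)
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  scores_hat <- fitted + mean(lab$y01)
  structure(list(kind = "PLS-DA", preproc = pre, weights = fit$W,
                 loadings = fit$P, scores = fit$scores, y_loadings = fit$c,
                 coef = fit$coef, y_mean = mean(lab$y01),
                 levels = lab$levels, features = colnames(X),
                 n_predictive = n_components, n_orthogonal = 0L,
                 r2y = r2y, fitted = scores_hat, y01 = lab$y01,
                 auroc_train = auroc(scores_hat, lab$y01)),
            class = c("lipid_pls", "lipid_model"))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal PLS-DA removes, one component at a time, systematic variation
#' in `X` that is uncorrelated with the class label, then fits a single
#' predictive latent variable on the filtered matrix. Predictions equal
#' those of a PLS-DA model with `n_orthogonal + 1` components; the payoff
#' is interpretability, with all class-predictive variation collapsed onto
#' one component whose scores and loadings feed the standard score and
#' loading displays.
#'
#' @inheritParams fit_pls_da
#' @param n_orthogonal Number of orthogonal (label-uncorrelated) components
#'   to remove (default 1; 0 reduces to one-component PLS-DA).
#' @return A `lipid_opls` model object.
#' @export
fit_opls_da <- function(X, y, n_orthogonal = 1, transform = "log") {
  X <- as.matrix(X)
  lab <- encode_labels(y)
  rk <- qr(scale(X, scale = FALSE))$rank
  if (n_orthogonal > rk - 1) abort("n_orthogonal exceeds rank(X) - 1")
  pre <- fit_preprocessor(X, transform = transform)
  Z <- predict(pre, X)
  yc <- lab$y01 - mean(lab$y01)
  p <- ncol(Z)
  w <- crossprod(Z, yc); w <- w / sqrt(sum(w^2))
  Wo <- matrix(0, p, n_orthogonal); Po <- matrix(0, p, n_orthogonal)
  To <- matrix(0, nrow(Z), n_orthogonal)
  E <- Z
  for (a in seq_len(n_orthogonal)) {
    t <- E %*% w
    pv <- crossprod(E, t) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) abort("no orthogonal variation left to remove")
    wo <- wo / nwo
    to <- E %*% wo
    po <- crossprod(E, to) / sum(to^2)
    E <- E - tcrossprod(to, po)
    Wo[, a] <- wo; Po[, a] <- po; To[, a] <- to
  }
  t_pred <- E %*% w
  tt <- sum(t_pred^2)
  p_pred <- crossprod(E, t_pred) / tt
  c_pred <- sum(yc * t_pred) / tt
  fitted <- drop(t_pred * c_pred)
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  scores_hat <- fitted + mean(lab$y01)
  # orient so the second class (coded 1) loads positive
  structure(list(kind = "OPLS-DA", preproc = pre, weights = w,
                 loadings = p_pred, scores = t_pred, y_loadings = c_pred,
                 ortho_weights = Wo, ortho_loadings = Po, ortho_scores = To,
                 y_mean = mean(lab$y01), levels = lab$levels,
                 features = colnames(X), n_predictive = 1L,
                 n_orthogonal = as.integer(n_orthogonal),
                 r2y = r2y, fitted = scores_hat, y01 = lab$y01,
                 auroc_train = auroc(scores_hat, lab$y01)),
            class = c("lipid_opls", "lipid_model"))
}

#' Predict class scores from a fitted discriminant model
#'
#' @param object A `lipid_pls` or `lipid_opls` model.
#' @param newdata Subjects-by-features matrix on the raw concentration
#'   scale.
#' @param type `"score"` for the continuous 0/1-scale prediction,
#'   `"class"` for labels thresholded at the midpoint of the training class
#'   score means.
#' @param ... Unused.
#' @export
predict.lipid_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  Z <- predict(object$preproc, as.matrix(newdata)[, object$features, drop = FALSE])
  if (inherits(object, "lipid_opls")) {
    if (object$n_orthogonal > 0) {
      for (a in seq_len(object$n_orthogonal)) {
        to <- Z %*% object$ortho_weights[, a]
        Z <- Z - tcrossprod(to, object$ortho_loadings[, a])
      }
    }
    score <- drop(Z %*% object$weights) * object$y_loadings + object$y_mean
  } else {
    score <- drop(Z %*% object$coef) + object$y_mean
  }
  if (type == "score") return(score)
  thr <- midpoint_threshold(object)
  object$levels[(score > thr) + 1L]
}

# class decision boundary: midpoint of the training class score means
midpoint_threshold <- function(object) {
  (mean(object$fitted[object$y01 == 0]) +
     mean(object$fitted[object$y01 == 1])) / 2
}

#' Area under the ROC curve by pair counting
#'
#' Equals the Mann-Whitney concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie), computed from midranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Two-level labels; the second level (or 1) is "positive".
#' @export
auroc <- function(scores, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2) abort("AUROC needs both classes present")
  pos <- as.numeric(f) == 2
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

make_folds <- function(y01, n_folds, scheme = c("stratified", "blocked"), seed = NULL) {
  scheme <- match.arg(scheme)
  n <- length(y01)
  fold <- integer(n)
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    if (length(idx) < n_folds && length(idx) < 2) {
      abort("a class has too few subjects to stratify across folds")
    }
    if (scheme == "stratified") {
      idx <- sample(idx)
    }
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  if (any(vapply(split(y01, fold), function(v) length(unique(v)), integer(1)) < 2)) {
    abort("a cross-validation fold lost one class entirely")
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS/TSS, with squared prediction errors accumulated over
#' held-out folds. Preprocessing is refitted inside each training fold and
#' the total sum of squares is taken about each training fold's mean label,
#' so no information leaks from test to train.
#'
#' @param X Positive subjects-by-features matrix.
#' @param y Two-level labels.
#' @param n_folds Number of folds (default 7).
#' @param fit_fun Model-fitting function `(X, y) -> lipid_model`; default
#'   two-component PLS-DA.
#' @param fold_scheme `"stratified"` (random, seed-controlled) or
#'   `"blocked"` (deterministic interleaved assignment within class, the
#'   venetian-blind convention).
#' @param seed Seed for stratified fold assignment.
#' @return Q2 (at most 1; negative when CV predictions are worse than
#'   predicting the training mean).
#' @export
q_squared <- function(X, y, n_folds = 7, fit_fun = NULL,
                      fold_scheme = c("stratified", "blocked"), seed = 1L) {
  fold_scheme <- match.arg(fold_scheme)
  X <- as.matrix(X)
  lab <- encode_labels(y)
  if (n_folds < 2 || n_folds > nrow(X)) abort("n_folds must be in [2, n]")
  if (is.null(fit_fun)) {
    fit_fun <- function(X, y) fit_pls_da(X, y, n_components = min(2, ncol(X)))
  }
  if (fold_scheme == "stratified") {
    fold <- withr::with_seed(as.integer(seed),
                             make_folds(lab$y01, n_folds, "stratified"))
  } else {
    fold <- make_folds(lab$y01, n_folds, "blocked")
  }
  press <- 0; tss <- 0
  for (k in sort(unique(fold))) {
    test <- fold == k
    model <- fit_fun(X[!test, , drop = FALSE], lab$y01[!test])
    pred <- predict(model, X[test, , drop = FALSE])
    press <- press + sum((lab$y01[test] - pred)^2)
    tss <- tss + sum((lab$y01[test] - mean(lab$y01[!test]))^2)
  }
  1 - press / tss
}

#' Repeated stratified 2/3-1/3 external validation
#'
#' Subjects are partitioned, stratified by class, into `repeats` test sets
#' that together cover the cohort exactly once; each repeat trains on the
#' complementary two thirds and evaluates on the held-out third. Reports
#' per-repeat training Q2 (cross-validated within the training set), test
#' Q2 and test AUROC, plus their means and standard deviations.
#'
#' @param X Positive subjects-by-features matrix.
#' @param y Two-level labels.
#' @param repeats Number of train/test splits (default 3, giving 2/3-1/3).
#' @param fit_fun Model-fitting function; default OPLS-DA with one
#'   orthogonal component.
#' @param n_folds Folds for the training-set Q2.
#' @param seed Split seed.
#' @return A `lipid_validation` list with `per_repeat` (tibble) and
#'   `summary` (mean/sd tibble).
#' @export
external_validation <- function(X, y, repeats = 3, fit_fun = NULL,
                                n_folds = 7, seed = 1L) {
  X <- as.matrix(X)
  lab <- encode_labels(y)
  if (is.null(fit_fun)) {
    fit_fun <- function(X, y) fit_opls_da(X, y, n_orthogonal = 1)
  }
  part <- withr::with_seed(as.integer(seed),
                           make_folds(lab$y01, repeats, "stratified"))
  rows <- purrr::map(sort(unique(part)), function(k) {
    test <- part == k
    Xtr <- X[!test, , drop = FALSE]; ytr <- lab$y01[!test]
    model <- fit_fun(Xtr, ytr)
    pred <- predict(model, X[test, , drop = FALSE])
    q2_train <- q_squared(Xtr, ytr, n_folds = min(n_folds, nrow(Xtr)),
                          fit_fun = fit_fun, seed = seed + k)
    tibble(
      repeat_id = k, n_test = sum(test),
      q2_train = q2_train,
      q2_test = 1 - sum((lab$y01[test] - pred)^2) /
        sum((lab$y01[test] - mean(ytr))^2),
      auroc_test = auroc(pred, lab$y01[test])
    )
  })
  per_repeat <- bind_rows(rows)
  summary <- tibble(
    statistic = c("q2_train", "q2_test", "auroc_test"),
    mean = c(mean(per_repeat$q2_train), mean(per_repeat$q2_test),
             mean(per_repeat$auroc_test)),
    sd = c(sd(per_repeat$q2_train), sd(per_repeat$q2_test),
           sd(per_repeat$auroc_test))
  )
  structure(list(per_repeat = per_repeat, summary = summary,
                 assignment = part),
            class = "lipid_validation")
}

#' @method tidy lipid_model
#' @export
tidy.lipid_model <- function(x, ...) {
  if (inherits(x, "lipid_opls")) {
    out <- tibble(term = x$features,
                  loading = drop(x$loadings),
                  weight = drop(x$weights))
  } else {
    out <- tibble(term = x$features,
                  loading = x$loadings[, 1],
                  weight = x$weights[, 1])
  }
  arrange(out, .data$loading)
}

#' @method glance lipid_model
#' @export
glance.lipid_model <- function(x, ...) {
  tibble(kind = x$kind, n_predictive = x$n_predictive,
         n_orthogonal = x$n_orthogonal, r2y = x$r2y,
         auroc_train = x$auroc_train)
}

#' @export
print.lipid_model <- function(x, ...) {
  cat(sprintf("%s model: %d predictive + %d orthogonal component(s), %d feature(s)\n",
              x$kind, x$n_predictive, x$n_orthogonal, length(x$features)))
  cat(sprintf("  R2Y = %.3f, training AUROC = %.3f\n", x$r2y, x$auroc_train))
  invisible(x)
}
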
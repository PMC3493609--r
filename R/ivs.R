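#' Configure iterative variable selection
#'
#' IVS is a stochastic wrapper around the discriminant model: the feature
#' set is randomly partitioned into subsets, each subset is optimized by
#' greedy backward deletion followed by forward re-addition against a
#' cross-validated objective, the optimized subsets are unioned, and the
#' partition/optimize cycle repeats until the objective stops improving.
#'
#' @param n_subsets Number of random subsets per outer iteration; default
#'   `ceiling(p / 20)` chosen at run time so each subset is small enough
#'   for exhaustive single-move search.
#' @param objective `"q2"` (cross-validated, default) or `"r2"` (fit).
#' @param max_outer_iterations Cap on partition/optimize cycles.
#' @param convergence_tolerance Minimum objective gain for accepting a
#'   move or another outer iteration.
#' @param n_runs Independent restarts for [ivs_ensemble()] (default 100).
#' @param n_folds,fold_scheme Cross-validation settings for the objective.
#' @param n_components Components of the inner PLS-DA model (capped at the
#'   subset size).
#' @param seed Base seed from which run seeds are derived.
#' @export
ivs_config <- function(n_subsets = NULL, objective = c("q2", "r2"),
                       max_outer_iterations = 10,
                       convergence_tolerance = 1e-4,
                       n_runs = 100, n_folds = 7,
                       fold_scheme = "stratified",
                       n_components = 2, seed = 1L) {
  objective <- match.arg(objective)
  if (!is.null(n_subsets) && n_subsets < 1) abort("n_subsets must be >= 1")
  if (convergence_tolerance <= 0) abort("convergence_tolerance must be > 0")
  if (n_runs < 1) abort("n_runs must be >= 1")
  structure(list(n_subsets = n_subsets, objective = objective,
                 max_outer_iterations = max_outer_iterations,
                 convergence_tolerance = convergence_tolerance,
                 n_runs = n_runs, n_folds = n_folds,
                 fold_scheme = fold_scheme,
                 n_components = n_components, seed = as.integer(seed)),
            class = "ivs_config")
}

# Q2 with a fold assignment fixed for the whole run, so greedy move
# comparisons see a noise-free objective. X arrives already preprocessed
# upstream of the log transform decision (raw positive concentrations).
ivs_objective_factory <- function(X, y01, config, fold) {
  cache <- new.env(parent = emptyenv())
  function(vars) {
    key <- paste(sort(vars), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    Xs <- X[, vars, drop = FALSE]
    ncomp <- min(config$n_components, length(vars))
    val <- if (config$objective == "r2") {
      fit_pls_da(Xs, y01, n_components = ncomp)$r2y
    } else {
      press <- 0; tss <- 0
      for (k in seq_len(max(fold))) {
        test <- fold == k
        model <- tryCatch(
          fit_pls_da(Xs[!test, , drop = FALSE], y01[!test], n_components = ncomp),
          error = function(e) abort(paste0("objective unevaluable in fold ", k,
                                           ": ", conditionMessage(e))))
        pred <- predict(model, Xs[test, , drop = FALSE])
        press <- press + sum((y01[test] - pred)^2)
        tss <- tss + sum((y01[test] - mean(y01[!test]))^2)
      }
      1 - press / tss
    }
    cache[[key]] <- val
    val
  }
}

# greedy backward deletion to convergence, then forward re-addition, cycled
# until neither pass finds a move improving the objective by > tol; ties on
# gain break to the lexicographically first variable
greedy_optimize <- function(obj, vars, tol) {
  active <- sort(vars)
  excluded <- character()
  current <- obj(active)
  repeat {
    improved <- FALSE
    repeat {  # backward pass
      if (length(active) <= 1) break
      gains <- vapply(active, function(v) obj(setdiff(active, v)) - current,
                      numeric(1))
      best <- which(gains > tol)
      if (length(best) == 0) break
      top <- active[gains >= max(gains[best]) - 1e-15 & gains > tol]
      pick <- sort(top)[1]
      excluded <- c(excluded, pick)
      active <- setdiff(active, pick)
      current <- obj(active)
      improved <- TRUE
    }
    repeat {  # forward pass
      if (length(excluded) == 0) break
      gains <- vapply(excluded, function(v) obj(sort(c(active, v))) - current,
                      numeric(1))
      best <- which(gains > tol)
      if (length(best) == 0) break
      top <- excluded[gains >= max(gains[best]) - 1e-15 & gains > tol]
      pick <- sort(top)[1]
      active <- sort(c(active, pick))
      excluded <- setdiff(excluded, pick)
      current <- obj(active)
      improved <- TRUE
    }
    if (!improved) break
  }
  list(active = active, objective = current)
}

#' One IVS optimization run
#'
#' @param X Positive subjects-by-features matrix with column names.
#' @param y Two-level labels.
#' @param config An [ivs_config()].
#' @param run_seed Seed controlling this run's partitions and folds;
#'   identical seeds reproduce the run exactly.
#' @return An `ivs_result`: `selected_variables`, `objective_trajectory`
#'   (outer-iteration objective values, non-decreasing), `final_q2`,
#'   `run_seed`.
#' @export
ivs_run <- function(X, y, config = ivs_config(), run_seed = config$seed) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) abort("IVS needs at least two candidate features")
  lab <- encode_labels(y)
  withr::local_seed(as.integer(run_seed))
  fold <- make_folds(lab$y01, config$n_folds, "stratified")
  obj <- ivs_objective_factory(X, lab$y01, config, fold)
  tol <- config$convergence_tolerance
  n_subsets <- config$n_subsets %||% ceiling(ncol(X) / 20)
  selected <- colnames(X)
  current <- obj(selected)
  trajectory <- current
  for (iter in seq_len(config$max_outer_iterations)) {
    parts <- split(sample(selected),
                   rep_len(seq_len(min(n_subsets, length(selected))),
                           length(selected)))
    opt <- purrr::map(parts, ~ greedy_optimize(obj, .x, tol))
    union_vars <- sort(unique(unlist(purrr::map(opt, "active"))))
    refined <- greedy_optimize(obj, union_vars, tol)
    if (refined$objective - current <= tol) break
    selected <- refined$active
    current <- refined$objective
    trajectory <- c(trajectory, current)
  }
  final_q2 <- if (config$objective == "q2") current else {
    q_squared(X[, selected, drop = FALSE], lab$y01,
              n_folds = config$n_folds, seed = run_seed)
  }
  structure(list(selected_variables = selected,
                 objective_trajectory = trajectory,
                 final_q2 = final_q2, run_seed = as.integer(run_seed)),
            class = "ivs_result")
}

#' Ensemble of independent IVS runs
#'
#' Runs `config$n_runs` independent [ivs_run()] restarts with seeds derived
#' from `config$seed` and returns the best run by cross-validated Q2 (ties
#' broken by smaller selection, then lower run index).
#'
#' @inheritParams ivs_run
#' @return A list with `best` (an `ivs_result`) and `all_runs`.
#' @export
ivs_ensemble <- function(X, y, config = ivs_config()) {
  # affine seed stream: run i always gets the same seed for a given base
  # seed, so enlarging n_runs extends (never reshuffles) the ensemble
  seeds <- as.integer((as.double(config$seed) * 7919 +
                         104729 * seq_len(config$n_runs)) %% 2147483646 + 1)
  runs <- purrr::map(seeds, ~ ivs_run(X, y, config, run_seed = .x))
  q2 <- vapply(runs, function(r) r$final_q2, numeric(1))
  size <- vapply(runs, function(r) length(r$selected_variables), numeric(1))
  best_idx <- order(-q2, size, seq_along(runs))[1]
  list(best = runs[[best_idx]], all_runs = runs, best_index = best_idx)
}

#' Build the final OPLS-DA model on an IVS-selected feature set
#'
#' @param X Positive subjects-by-features matrix.
#' @param y Two-level labels.
#' @param selected Nonempty character vector of selected features.
#' @param n_orthogonal Orthogonal components (default 1).
#' @return A `lipid_opls` model; loadings in [tidy()] order give the
#'   loading-plot arrangement, with class-1-elevated features positive.
#' @export
build_final_model <- function(X, y, selected, n_orthogonal = 1) {
  if (length(selected) == 0) abort("selected feature set is empty")
  X <- as.matrix(X)
  n_orthogonal <- min(n_orthogonal, length(selected) - 1)
  if (n_orthogonal < 1) {
    fit_opls_da(X[, selected, drop = FALSE], y, n_orthogonal = 0)
  } else {
    fit_opls_da(X[, selected, drop = FALSE], y, n_orthogonal = n_orthogonal)
  }
}

#' Estimate selection-induced overfitting by embedded validation
#'
#' Feature selection is deliberately kept outside the final model's
#' cross-validation, so its optimism must be quantified separately: the
#' cohort is split 2/3-1/3 (stratified), an IVS ensemble is optimized on
#' the training portion alone, and the best model's training Q2 is
#' compared with its held-out test Q2. The mean and standard deviation of
#' the percent drop across validations estimate how much the reported
#' statistics are inflated by selection.
#'
#' @param X Positive subjects-by-features matrix.
#' @param y Two-level labels.
#' @param config An [ivs_config()]; `sub_runs` overrides its `n_runs`.
#' @param n_validations Independent split/select/test cycles (default 7).
#' @param sub_runs IVS restarts per validation (default 100).
#' @param seed Split seed.
#' @return A list with `per_validation` tibble and `mean_pct_drop`,
#'   `sd_pct_drop`.
#' @export
overfitting_estimate <- function(X, y, config = ivs_config(),
                                 n_validations = 7, sub_runs = 100,
                                 seed = config$seed) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  lab <- encode_labels(y)
  sub_config <- config
  sub_config$n_runs <- sub_runs
  rows <- purrr::map(seq_len(n_validations), function(v) {
    split <- withr::with_seed(as.integer(seed) + v,
                              make_folds(lab$y01, 3, "stratified"))
    test <- split == 1  # one stratified third held out
    Xtr <- X[!test, , drop = FALSE]; ytr <- lab$y01[!test]
    sub_config$seed <- as.integer(seed) + 7919L * v
    ens <- ivs_ensemble(Xtr, ytr, sub_config)
    sel <- ens$best$selected_variables
    model <- build_final_model(Xtr, ytr, sel)
    pred <- predict(model, X[test, , drop = FALSE])
    q2_train <- ens$best$final_q2
    q2_test <- 1 - sum((lab$y01[test] - pred)^2) /
      sum((lab$y01[test] - mean(ytr))^2)
    tibble(validation = v, n_selected = length(sel),
           q2_train = q2_train, q2_test = q2_test,
           pct_drop = 100 * (q2_train - q2_test) / max(q2_train, 1e-6))
  })
  per_validation <- bind_rows(rows)
  list(per_validation = per_validation,
       mean_pct_drop = mean(per_validation$pct_drop),
       sd_pct_drop = sd(per_validation$pct_drop))
}
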
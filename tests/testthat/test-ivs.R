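test_that("a no-move configuration returns the full feature set", {
  d <- make_planted(1, n_informative = 1, n_noise = 6)
  cfg <- ivs_config(n_subsets = 1, convergence_tolerance = Inf, n_folds = 5)
  res <- ivs_run(d$X, d$y, cfg, run_seed = 3)
  expect_setequal(res$selected_variables, colnames(d$X))
  expect_length(res$objective_trajectory, 1)
})

test_that("runs are deterministic and trajectories never decrease", {
  d <- make_planted(2, n_informative = 2, n_noise = 15)
  cfg <- ivs_config(n_folds = 5)
  r1 <- ivs_run(d$X, d$y, cfg, run_seed = 42)
  r2 <- ivs_run(d$X, d$y, cfg, run_seed = 42)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$objective_trajectory) >= 0))
  r3 <- ivs_run(d$X, d$y, cfg, run_seed = 43)
  expect_true(is.numeric(r3$final_q2))
  expect_gt(length(r3$selected_variables), 0)
})

test_that("strong planted features are recovered", {
  hits <- 0
  for (s in 1:5) {
    d <- make_planted(50 + s, n_informative = 1, n_noise = 20, shift_sd = 4)
    r <- ivs_run(d$X, d$y, ivs_config(n_folds = 5), run_seed = s)
    hits <- hits + (d$informative %in% r$selected_variables)
  }
  expect_gte(hits, 4)
})

test_that("the ensemble picks the maximum-Q2 run and grows monotonically", {
  d <- make_planted(3, n_informative = 2, n_noise = 12)
  cfg1 <- ivs_config(n_runs = 1, n_folds = 5, seed = 5)
  ens1 <- ivs_ensemble(d$X, d$y, cfg1)
  single <- ivs_run(d$X, d$y, cfg1, run_seed = ens1$all_runs[[1]]$run_seed)
  expect_identical(ens1$best, single)
  cfg4 <- ivs_config(n_runs = 4, n_folds = 5, seed = 5)
  ens4 <- ivs_ensemble(d$X, d$y, cfg4)
  q2s <- vapply(ens4$all_runs, function(r) r$final_q2, numeric(1))
  expect_equal(ens4$best$final_q2, max(q2s))
  # the seed stream is prefix-stable, so more runs never lower the best Q2
  expect_identical(ens4$all_runs[[1]]$run_seed, ens1$all_runs[[1]]$run_seed)
  expect_gte(ens4$best$final_q2, ens1$best$final_q2)
})

test_that("final models are built on the selected columns with the expected orientation", {
  co <- generate_cohort(default_study_spec(), seed = 4)
  X <- conc_matrix(co)
  y <- co$group
  full <- build_final_model(X, y, colnames(X))
  direct <- fit_opls_da(X, y, n_orthogonal = 1)
  expect_equal(full$loadings, direct$loadings)
  ens <- ivs_ensemble(X, y, ivs_config(n_runs = 3, seed = 8))
  model <- build_final_model(X, y, ens$best$selected_variables)
  expect_setequal(model$features, ens$best$selected_variables)
  expect_gt(model$auroc_train, 0.9)
  # scores track the class label and class-1-elevated features load positive
  y01 <- as.numeric(y) - 1
  expect_gt(cor(model$fitted, y01), 0.5)
  td <- tidy(model)
  if ("18:1n9" %in% td$term) {
    expect_gt(td$loading[td$term == "18:1n9"], 0)
  }
  expect_error(build_final_model(X, y, character()), "empty")
})

test_that("overfitting estimates are finite, seeded and flag signal-free data", {
  d <- make_planted(6, n_informative = 2, n_noise = 8, shift_sd = 3,
                    n0 = 12, n1 = 24)
  cfg <- ivs_config(n_folds = 5)
  est <- overfitting_estimate(d$X, d$y, cfg, n_validations = 3,
                              sub_runs = 4, seed = 10)
  expect_equal(nrow(est$per_validation), 3L)
  expect_true(is.finite(est$mean_pct_drop) && is.finite(est$sd_pct_drop))
  est2 <- overfitting_estimate(d$X, d$y, cfg, n_validations = 3,
                               sub_runs = 4, seed = 10)
  expect_equal(est$per_validation, est2$per_validation)
  # pure noise: selection overfits training, held-out Q2 collapses
  withr::with_seed(77, {
    Xn <- matrix(exp(rnorm(36 * 10, 0, 0.4)), 36, 10,
                 dimnames = list(NULL, paste0("n", 1:10)))
    yn <- rep(0:1, each = 18)
  })
  null_est <- overfitting_estimate(Xn, yn, cfg, n_validations = 3,
                                   sub_runs = 4, seed = 11)
  expect_gt(null_est$mean_pct_drop, 50)
  expect_lt(mean(null_est$per_validation$q2_test), 0.2)
})
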
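test_that("geometric mean matches the product definition and guards its domain", {
  expect_equal(geometric_mean(c(5, 5, 5)), 5)
  expect_equal(geometric_mean(c(1, 100)), 10)
  withr::with_seed(2, {
    for (i in 1:20) {
      x <- runif(sample(2:12, 1), 0.01, 50)
      expect_equal(geometric_mean(x), prod(x)^(1 / length(x)),
                   tolerance = 1e-12)
      # scale equivariance
      expect_equal(geometric_mean(3.7 * x), 3.7 * geometric_mean(x),
                   tolerance = 1e-12)
    }
  })
  expect_error(geometric_mean(numeric()), "empty")
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(c(1, -2)), "positive")
})

test_that("percent change in geometric mean matches published worked examples", {
  expect_equal(round(delta_gm(290, 621)), 114)
  expect_equal(round(delta_gm(0.60, 0.96)), 60)
  expect_equal(delta_gm(42, 42), 0)
  # invariant under common rescaling of both groups
  expect_equal(delta_gm(3 * 290, 3 * 621), delta_gm(290, 621))
  expect_error(delta_gm(0, 5), "positive")
})

test_that("Mann-Whitney U and exact p match brute-force enumeration", {
  # identical samples: central U, approx p near 1
  x <- c(1, 2, 3, 4)
  res <- mann_whitney_u(x, x)
  expect_equal(res$u, 8)
  expect_gte(res$p_value, 0.99)
  # complete separation at n1 = n2 = 4: two extreme labelings out of C(8,4)
  sep <- mann_whitney_u(1:4, 5:8, mode = "exact")
  expect_equal(sep$u, 0)
  expect_equal(sep$p_value, 2 / 70)
  withr::with_seed(31, {
    for (i in 1:15) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      vals <- sample(1:6, n1 + n2, replace = TRUE)  # ties guaranteed
      a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
      got <- mann_whitney_u(a, b, mode = "exact")
      want <- oracle_mann_whitney(a, b)
      expect_equal(got$u, want$u)
      expect_equal(got$p_value, want$p_value)
      # U(x,y) + U(y,x) = n1 n2
      expect_equal(got$u + mann_whitney_u(b, a, mode = "exact")$u, n1 * n2)
    }
  })
  expect_error(mann_whitney_u(numeric(), 1:3), "nonempty")
})

test_that("approximate p-values agree with the tie-corrected normal reference", {
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- sample(1:10, 8, replace = TRUE)
      b <- sample(1:10, 12, replace = TRUE) + 2
      ours <- mann_whitney_u(a, b)$p_value
      ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      expect_equal(ours, ref)
    }
  })
})

test_that("BH step-up matches the definitional oracle and is monotone", {
  expect_false(any(bh_fdr(rep(1, 5), q = 0.1)))
  expect_true(bh_fdr(0.001, q = 0.1))
  withr::with_seed(8, {
    for (i in 1:30) {
      m <- sample(1:12, 1)
      p <- round(runif(m), 3)
      got <- bh_fdr(p, q = 0.1)
      expect_equal(got, oracle_bh(p, 0.1))
      # lowering any p never removes a rejection
      j <- sample(m, 1)
      p2 <- p; p2[j] <- p2[j] / 2
      expect_true(all(bh_fdr(p2, q = 0.1)[got]))
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cohort summaries compute class sums per subject and a joint FDR family", {
  co <- tiny_cohort(n0 = 6, n1 = 6)
  res <- summarize_cohort(co, q = 0.1)
  expect_true(all(c("16:0", "Total NEFA") %in% res$metabolite))
  # class sum row equals the summary of per-subject totals
  totals <- rowSums(conc_matrix(co))
  g0 <- co$group == "non-diabetic"
  row <- res[res$metabolite == "Total NEFA", ]
  expect_equal(row$gm_group0, geometric_mean(totals[g0]))
  expect_equal(row$min_group1, min(totals[!g0]))
  expect_equal(row$delta_gm_pct,
               delta_gm(geometric_mean(totals[g0]), geometric_mean(totals[!g0])))
  expect_equal(res$fdr_significant, bh_fdr(res$p_value, 0.1))
  # sub-class sums appear when a class has more than one member
  expect_true(any(grepl("NEFA:SFA", res$metabolite)))
})

test_that("zero-noise cohorts give exact effect sizes and constants are flagged", {
  spec <- cohort_spec(
    metabolite_specs = tibble::tibble(
      name = c("up", "flat"), chem_class = "SFA", family = "NEFA",
      carbons = 16L, double_bonds = 0L, unit = "uM",
      gm_group0 = c(10, 7), gm_group1 = c(20, 7), log_sd = 0
    ),
    n_per_group = c(5L, 5L)
  )
  co <- generate_cohort(spec, seed = 1)
  res <- summarize_cohort(co, class_sums = FALSE)
  expect_equal(res$delta_gm_pct[res$metabolite == "up"], 100)
  flat <- res[res$metabolite == "flat", ]
  expect_true(flat$constant_flag)
  expect_equal(flat$p_value, 1)
  expect_false(flat$fdr_significant)
})

test_that("report formatting rounds like the published tables", {
  co <- tiny_cohort(n0 = 6, n1 = 6)
  fm <- format_univariate(summarize_cohort(co))
  expect_true(all(fm$delta_gm_pct == round(fm$delta_gm_pct)))
  expect_match(fm$group0[1], "^\\d+\\.?\\d* \\[")
})
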
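#' Geometric mean
#'
#' The exponential of the arithmetic mean of natural logs; the central
#' location statistic for log-normally distributed concentrations.
#'
#' @param values Non-empty vector of strictly positive values. `NA`s are
#'   removed when `na.rm = TRUE`.
#' @param na.rm Drop missing values first.
#' @export
geometric_mean <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0) abort("geometric mean of an empty vector is undefined")
  if (any(is.na(values)) || any(values <= 0)) {
    abort("geometric mean requires strictly positive values")
  }
  exp(mean(log(values)))
}

#' Percent change in geometric mean between groups
#'
#' @param gm0 Reference-group geometric mean (> 0).
#' @param gm1 Comparison-group geometric mean.
#' @return `100 * (gm1 - gm0) / gm0`, in percent. Report tables round this
#'   to the nearest integer.
#' @export
delta_gm <- function(gm0, gm1) {
  if (any(gm0 <= 0)) abort("reference geometric mean must be positive")
  100 * (gm1 - gm0) / gm0
}

#' Mann-Whitney U test for two independent samples
#'
#' Computes the U statistic from rank sums with midranks for ties, and a
#' two-sided p-value either by full enumeration of the permutation null
#' (`mode = "exact"`, feasible for n1 + n2 <= 20; valid under ties) or by
#' the tie-corrected normal approximation with continuity correction
#' (`mode = "approx"`, via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples.
#' @param mode `"approx"` or `"exact"`.
#' @return A list with `u` (U for `x` relative to `y`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y, mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "approx") {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  } else {
    if (n1 + n2 > 20) {
      abort("exact mode enumerates C(n1+n2, n1) labelings; use approx for n1+n2 > 20")
    }
    u_perm <- u_null_distribution(r, n1)
    mu <- n1 * n2 / 2
    p <- mean(abs(u_perm - mu) >= abs(u - mu) - 1e-12)
  }
  list(u = u, p_value = min(p, 1))
}

# all C(n,n1) assignments of the (mid)ranks to group 1: the exact
# permutation null of the rank sum, hence of U
u_null_distribution <- function(r, n1) {
  idx <- combn(length(r), n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Benjamini-Hochberg step-up rejections
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q Acceptable false discovery rate (default 0.1).
#' @return Logical rejection vector: TRUE where the hypothesis is rejected
#'   with FDR controlled at `q`.
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Univariate group comparison of a cohort panel
#'
#' For every metabolite, and for every class sum (per-subject totals within
#' an annotation family or chemical class, computed before any averaging
#' because the geometric mean of sums differs from the sum of geometric
#' means), this computes group geometric means with ranges, the percent
#' change in geometric mean, a Mann-Whitney U test, and a joint
#' Benjamini-Hochberg FDR decision across all hypotheses tested in the
#' call.
#'
#' @param table A `cohort_tbl`; the first factor level of `group` is the
#'   reference group.
#' @param q FDR level (default 0.1).
#' @param class_sums Include per-family/per-class Σ rows (default TRUE).
#' @param mode Mann-Whitney p-value mode passed to [mann_whitney_u()].
#' @return A tibble with one row per tested variable: `metabolite`,
#'   `is_sum`, `n0`, `n1`, `gm_group0`, `gm_group1`, ranges, `delta_gm_pct`,
#'   `u_statistic`, `p_value`, `fdr_significant`, `constant_flag`.
#' @export
summarize_cohort <- function(table, q = 0.1, class_sums = TRUE,
                             mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  mets <- metabolite_names(table)
  g <- table$group
  ref <- levels(g)[1]
  vars <- purrr::map(mets, ~ list(name = .x, values = table[[.x]], is_sum = FALSE))
  if (class_sums) {
    ann <- cohort_annotation(table)
    ann <- ann[ann$name %in% mets, ]
    fam_groups <- split(ann$name, ann$family)
    cls_groups <- split(ann$name, paste(ann$family, ann$chem_class, sep = ":"))
    sums <- c(
      purrr::imap(fam_groups, ~ list(label = paste0("Total ", .y), members = .x)),
      purrr::imap(cls_groups, ~ list(label = paste0("Total ", .y), members = .x))
    )
    sums <- purrr::keep(sums, ~ length(.x$members) > 1)
    for (s in sums) {
      units <- unique(ann$unit[ann$name %in% s$members])
      if (length(units) > 1) {
        abort(paste0("class sum '", s$label, "' mixes units: ",
                     paste(units, collapse = ", ")))
      }
      vals <- rowSums(conc_matrix(table, s$members))
      vars <- c(vars, list(list(name = s$label, values = vals, is_sum = TRUE)))
    }
  }
  rows <- purrr::map(vars, function(v) {
    x0 <- v$values[g == ref]
    x1 <- v$values[g != ref]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    constant <- length(unique(c(x0, x1))) == 1
    if (constant) {
      mw <- list(u = length(x0) * length(x1) / 2, p_value = 1)
    } else {
      mw <- mann_whitney_u(x0, x1, mode = mode)
    }
    tibble(
      metabolite = v$name, is_sum = v$is_sum,
      n0 = length(x0), n1 = length(x1),
      gm_group0 = geometric_mean(x0), gm_group1 = geometric_mean(x1),
      min_group0 = min(x0), max_group0 = max(x0),
      min_group1 = min(x1), max_group1 = max(x1),
      delta_gm_pct = delta_gm(geometric_mean(x0), geometric_mean(x1)),
      u_statistic = mw$u, p_value = mw$p_value,
      constant_flag = constant
    )
  })
  out <- bind_rows(rows)
  out$fdr_significant <- bh_fdr(out$p_value, q = q)
  attr(out, "q") <- q
  class(out) <- c("lipid_univariate", class(out))
  out
}

#' Format a univariate summary like a report table
#'
#' Geometric means to 3 significant figures, ranges in brackets, percent
#' change rounded to the nearest integer.
#' @param result A [summarize_cohort()] tibble.
#' @export
format_univariate <- function(result) {
  f3 <- function(x) signif(x, 3)
  tibble(
    metabolite = result$metabolite,
    group0 = sprintf("%g [%g, %g]", f3(result$gm_group0),
                     f3(result$min_group0), f3(result$max_group0)),
    group1 = sprintf("%g [%g, %g]", f3(result$gm_group1),
                     f3(result$min_group1), f3(result$max_group1)),
    delta_gm_pct = round(result$delta_gm_pct),
    p_value = result$p_value,
    fdr_significant = result$fdr_significant
  )
}
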
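# small handmade panels and planted-signal matrices used across tests

tiny_annotation <- function() {
  annotation_table(
    tibble::tibble(
      name = c("16:0", "16:1n7", "18:0", "18:1n9"),
      chem_class = c("SFA", "MUFA", "SFA", "MUFA"),
      family = "NEFA",
      carbons = c(16L, 16L, 18L, 18L),
      double_bonds = c(0L, 1L, 0L, 1L),
      unit = "uM"
    ),
    pathway_edges = tibble::tibble(
      substrate = c("16:0", "18:0"),
      product = c("16:1n7", "18:1n9"),
      enzyme = "SCD"
    )
  )
}

tiny_cohort <- function(n0 = 5, n1 = 6, seed = 1) {
  withr::with_seed(seed, {
    n <- n0 + n1
    data <- tibble::tibble(
      subject = sprintf("P%02d", seq_len(n)),
      group = rep(c("non-diabetic", "diabetic"), c(n0, n1)),
      glucose = c(rnorm(n0, 92, 10), rnorm(n1, 210, 79)),
      `16:0` = exp(rnorm(n, log(90), 0.3)),
      `16:1n7` = exp(rnorm(n, log(3), 0.3)),
      `18:0` = exp(rnorm(n, log(40), 0.3)),
      `18:1n9` = exp(rnorm(n, log(50), 0.3))
    )
    data$group <- factor(data$group, levels = c("non-diabetic", "diabetic"))
    cohort_table(data, tiny_annotation(), clinical = "glucose")
  })
}

# two-group matrix with a known number of informative log-normal features
# (group shift of shift_sd log-sds) among pure noise features
make_planted <- function(seed, n_informative = 2, n_noise = 20,
                         shift_sd = 4, n0 = 12, n1 = 43, log_sd = 0.4) {
  withr::with_seed(seed, {
    p <- n_informative + n_noise
    X <- matrix(exp(rnorm((n0 + n1) * p, 0, log_sd)), n0 + n1, p)
    colnames(X) <- c(sprintf("signal%02d", seq_len(n_informative)),
                     sprintf("noise%02d", seq_len(n_noise)))
    rows1 <- (n0 + 1):(n0 + n1)
    for (i in seq_len(n_informative)) {
      X[rows1, i] <- X[rows1, i] * exp(shift_sd * log_sd)
    }
    list(X = X, y = rep(c("ctrl", "case"), c(n0, n1)),
         informative = colnames(X)[seq_len(n_informative)])
  })
}

# independent brute-force U statistic and exact two-sided p by direct
# enumeration with pairwise counting (not rank sums)
oracle_mann_whitney <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  labelings <- utils::combn(length(pool), n1)
  u_all <- apply(labelings, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p_value = p)
}

# literal step-up definition checked against every k
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks) > 0) reject[ord[seq_len(max(ks))]] <- TRUE
  reject
}
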
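test_that("Spearman correlations respect ranks and match the closed formula", {
  co <- tiny_cohort(n0 = 8, n1 = 8, seed = 2)
  pair <- spearman_pair(co)
  expect_equal(dim(pair$rho_group0), c(5L, 5L))
  expect_lt(max(abs(pair$rho_group0 - t(pair$rho_group0)), na.rm = TRUE), 1e-12)
  expect_equal(unname(diag(pair$rho_group0)), rep(1, 5))
  # monotone transforms leave rho unchanged
  mono <- co
  mono$`16:0` <- exp(mono$`16:0` / 50)
  pair2 <- spearman_pair(mono)
  expect_equal(pair$rho_group0, pair2$rho_group0, tolerance = 1e-12)
  # exact reversal
  withr::with_seed(4, {
    x <- rnorm(8)
    m <- cbind(a = x, b = -x, c = rnorm(8))
  })
  sm <- lipidisc:::spearman_matrix(m)
  expect_equal(sm$rho["a", "b"], -1)
  expect_equal(sm$p["a", "b"], 0)
  # closed-form 1 - 6 sum d^2 / (n (n^2-1)) for tie-free data
  d2 <- sum((rank(m[, "a"]) - rank(m[, "c"]))^2)
  expect_equal(sm$rho["a", "c"], 1 - 6 * d2 / (8 * 63), tolerance = 1e-12)
})

test_that("permutation p-values are exact for tiny groups and constants are masked", {
  withr::with_seed(5, {
    m <- cbind(a = rnorm(6), b = rnorm(6), flat = rep(2, 6))
  })
  m[, "b"] <- m[, "a"] + rnorm(6, 0, 0.1)
  sm <- lipidisc:::spearman_matrix(m, p_method = "permutation")
  expect_true(sm$p["a", "b"] < 0.05)
  expect_true(all(is.na(sm$rho["flat", ])))
  # the permutation null of a perfect monotone pair is 2/n! per tail
  m2 <- cbind(x = 1:5, y = (1:5)^3)
  sm2 <- lipidisc:::spearman_matrix(m2, p_method = "permutation")
  expect_equal(sm2$rho["x", "y"], 1)
  expect_equal(sm2$p["x", "y"], 2 / factorial(5))
  expect_error(lipidisc:::spearman_matrix(matrix(rnorm(18), 9, 2), "permutation"),
               "n <= 8")
})

test_that("correlation distances are metric-ready", {
  expect_equal(correlation_distance(matrix(c(1, -1, -1, 1), 2))[1, 2], 0)
  expect_equal(correlation_distance(matrix(c(1, 0, 0, 1), 2))[1, 2], 1)
  withr::with_seed(6, {
    r <- cor(matrix(rnorm(80), 16, 5), method = "spearman")
  })
  d <- correlation_distance(r)
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("multidimensional scaling reconstructs realizable configurations", {
  # three mutually equidistant points form an equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  emb3 <- mds_embed(d3, method = "classical")
  sides <- as.matrix(dist(emb3$coordinates))[upper.tri(matrix(0, 3, 3))]
  expect_lt(max(abs(sides - 1)), 1e-6)
  # planar-realizable distances are recovered exactly
  withr::with_seed(7, P <- matrix(rnorm(24), 12, 2))
  dP <- as.matrix(dist(P))
  rownames(dP) <- colnames(dP) <- paste0("p", 1:12)
  emb <- mds_embed(dP, method = "classical")
  expect_lt(max(abs(as.matrix(dist(emb$coordinates)) - dP)), 1e-8)
  expect_lt(emb$stress, 1e-12)
  # stress majorization never ends worse than its classical start
  withr::with_seed(8, P3 <- matrix(rnorm(30), 10, 3))
  d3d <- as.matrix(dist(P3))
  expect_lte(mds_embed(d3d, method = "stress")$stress,
             mds_embed(d3d, method = "classical")$stress + 1e-12)
  # full-dimensional embedding of a metric input is exact
  embF <- mds_embed(d3d, dims = 9, method = "classical")
  expect_lt(embF$stress, 1e-10)
  expect_error(mds_embed(d3d, dims = 10), "below the number of points")
  asym <- matrix(c(0, 1, 2, 1, 0, 1, 1, 1, 0), 3)
  expect_error(mds_embed(asym), "symmetric")
})

test_that("display alignment is a rigid motion", {
  withr::with_seed(9, P <- matrix(rnorm(16), 8, 2))
  dP <- as.matrix(dist(P))
  rownames(dP) <- colnames(dP) <- paste0("v", 1:8)
  emb <- mds_embed(dP, method = "classical", origin_node = "v3",
                   quadrant_nodes = c("v1", "v2"))
  X <- emb$coordinates
  expect_equal(unname(X["v3", ]), c(0, 0), tolerance = 1e-10)
  cen <- colMeans(X[c("v1", "v2"), ])
  expect_gt(cen[1], 0)
  expect_lt(cen[2], 0)
  expect_lt(max(abs(as.matrix(dist(X)) - dP)), 1e-10)
})

test_that("Hotelling ellipses have the nominal geometry", {
  withr::with_seed(10, iso <- matrix(rnorm(4000), 2000, 2))
  ell <- hotelling_ellipse(iso)
  ev <- eigen(ell$shape)$values
  expect_lt(ev[1] / ev[2], 1.2)  # isotropic cloud gives a near-circle
  expect_error(hotelling_ellipse(matrix(rnorm(6), 3, 2)), "more points")
  bound <- ellipse_boundary(ell, n_points = 50)
  expect_equal(nrow(bound), 50L)
  on_bound <- cbind(bound$x, bound$y)
  m <- stats::mahalanobis(on_bound, ell$center, ell$shape)
  expect_lt(max(abs(m - ell$radius2)), 1e-8)
})

test_that("connectivity networks threshold edges per group and nest by p", {
  co <- generate_cohort(default_study_spec(), seed = 5)
  pcn0 <- build_pcn(co, group = "non-diabetic")
  pcn1 <- build_pcn(co, group = "diabetic")
  expect_equal(pcn0$p_threshold, 0.05)
  expect_equal(pcn1$p_threshold, 0.01)
  expect_true(all(pcn1$edges$p < 0.01))
  loose <- build_pcn(co, group = "diabetic", p_threshold = 0.05)
  strict_keys <- paste(pcn1$edges$from, pcn1$edges$to)
  expect_true(all(strict_keys %in% paste(loose$edges$from, loose$edges$to)))
  expect_equal(unname(unlist(pcn1$nodes[pcn1$nodes$name == "glucose",
                                        c("x", "y")])), c(0, 0),
               tolerance = 1e-10)
  expect_true(all(c("clinical", "metabolite<20C", "metabolite>=20C") %in%
                    pcn1$nodes$role))
  expect_gt(length(pcn1$ellipses), 0)
  expect_s3_class(autoplot(pcn1), "ggplot")
  g <- as_igraph(pcn1)
  expect_equal(igraph::vcount(g), nrow(pcn1$nodes))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(pcn1, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("perfectly coupled variables sit at zero distance with an ever-present edge", {
  spec <- cohort_spec(
    metabolite_specs = tibble::tibble(
      name = c("A", "B"), chem_class = "SFA", family = "NEFA",
      carbons = 16L, double_bonds = 0L, unit = "uM",
      gm_group0 = c(10, 3), gm_group1 = c(12, 4), log_sd = c(0.4, 0.3)),
    pathway_couplings = tibble::tibble(
      substrate = "A", product = "P", enzyme = "E",
      gm_ratio_group0 = 2, gm_ratio_group1 = 2, ratio_log_sd = 0),
    n_per_group = c(10L, 10L))
  co <- generate_cohort(spec, seed = 3)
  pair <- spearman_pair(co, variables = c("A", "B", "P"))
  expect_equal(pair$rho_group0["A", "P"], 1)
  d <- correlation_distance(pair$rho_group0)
  expect_equal(d["A", "P"], 0)
  pcn <- build_pcn(co, group = levels(co$group)[1], p_threshold = 1e-6)
  expect_true(any(pcn$edges$from == "A" & pcn$edges$to == "P" |
                    pcn$edges$from == "P" & pcn$edges$to == "A"))
})

test_that("planted correlation blocks stay together in the embedding", {
  block_spec <- cohort_spec(
    metabolite_specs = tibble::tibble(
      name = c("a1", "b1"), chem_class = c("SFA", "PUFA"), family = "NEFA",
      carbons = 16L, double_bonds = 0L, unit = "uM",
      gm_group0 = c(10, 5), gm_group1 = c(10, 5), log_sd = 0.4),
    pathway_couplings = tibble::tibble(
      substrate = c("a1", "a1", "b1", "b1"),
      product = c("a2", "a3", "b2", "b3"), enzyme = "E",
      gm_ratio_group0 = 1, gm_ratio_group1 = 1, ratio_log_sd = 0.05),
    n_per_group = c(30L, 30L), shared_log_weight = 0)
  co <- generate_cohort(block_spec, seed = 6)
  pcn <- build_pcn(co, group = levels(co$group)[1], p_threshold = 0.05)
  xy <- as.matrix(pcn$nodes[, c("x", "y")])
  rownames(xy) <- pcn$nodes$name
  within <- mean(c(dist(xy[c("a1", "a2", "a3"), ]), dist(xy[c("b1", "b2", "b3"), ])))
  between <- mean(as.matrix(dist(xy))[c("a1", "a2", "a3"), c("b1", "b2", "b3")])
  expect_lt(within, between)
})

test_that("the heatmap matrix carries each group in its own triangle", {
  co <- tiny_cohort(n0 = 8, n1 = 8, seed = 3)
  pair <- spearman_pair(co)
  m <- correlation_heatmap_matrix(pair, p_mask = 1.1)  # keep everything
  p <- length(pair$variables)
  expect_equal(sum(!is.na(m)), p * (p - 1))
  expect_equal(m[upper.tri(m)], pair$rho_group0[upper.tri(m)])
  expect_equal(m[lower.tri(m)], pair$rho_group1[lower.tri(m)])
  expect_s3_class(plot_correlation_heatmap(pair), "ggplot")
})

test_that("pathway graphs size nodes by effect and color by FDR status", {
  co <- generate_cohort(default_study_spec(), seed = 5)
  univ <- summarize_cohort(co)
  idx <- compute_all_indices(co)
  pg <- build_pathway_graph(univ, idx, cohort_annotation(co))
  mets <- univ[!univ$is_sum, ]
  expect_equal(pg$nodes$size[match(mets$metabolite, pg$nodes$name)],
               abs(mets$delta_gm_pct))
  expect_equal(order(pg$nodes$size), order(abs(mets$delta_gm_pct[
    match(pg$nodes$name, mets$metabolite)])))
  scd_edges <- pg$edges[pg$edges$enzyme == "SCD", ]
  expect_true(all(scd_edges$status == "increased"))
  # edges without a computed ratio stay gray at zero width
  nae_edge <- pg$edges[pg$edges$product == "O-EA", ]
  expect_equal(nae_edge$status, "no-ratio")
  expect_equal(nae_edge$width, 0)
  # a fully non-significant summary turns the graph gray
  null_univ <- univ
  null_univ$fdr_significant <- FALSE
  null_idx <- idx
  null_idx$fdr_significant <- FALSE
  pg0 <- build_pathway_graph(null_univ, null_idx, cohort_annotation(co))
  expect_true(all(pg0$nodes$status == "not-significant"))
  expect_true(all(pg0$edges$status %in% c("not-significant", "no-ratio")))
  expect_s3_class(autoplot(pg), "ggplot")
})
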
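#' Per-group Spearman correlation matrices
#'
#' Computes, separately within each group, the Spearman rank correlation
#' (midranks for ties) between every pair of panel variables (metabolites
#' plus clinical covariates), with two-sided p-values from the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))`, or by
#' full permutation enumeration for small groups (`p_method =
#' "permutation"`, n <= 8).
#'
#' @param table A `cohort_tbl`.
#' @param variables Variables to correlate; defaults to all metabolites
#'   and clinical covariates.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @return A `correlation_pair` object: `variables`, `rho_group0`,
#'   `rho_group1`, `p_group0`, `p_group1`, `n_per_group`, `groups`.
#'   Variables constant within a group have their row/column masked as NA.
#' @export
spearman_pair <- function(table, variables = NULL, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  variables <- variables %||% c(metabolite_names(table), clinical_names(table))
  groups <- levels(table$group)
  per_group <- purrr::map(groups, function(gl) {
    sub <- as.data.frame(table)[table$group == gl, variables, drop = FALSE]
    if (nrow(sub) < 4) abort("need at least 4 subjects per group for correlations")
    spearman_matrix(as.matrix(sub), p_method)
  })
  structure(list(variables = variables,
                 rho_group0 = per_group[[1]]$rho, rho_group1 = per_group[[2]]$rho,
                 p_group0 = per_group[[1]]$p, p_group1 = per_group[[2]]$p,
                 n_per_group = c(sum(table$group == groups[1]),
                                 sum(table$group == groups[2])),
                 groups = groups),
            class = "correlation_pair")
}

spearman_matrix <- function(X, p_method = "t") {
  n <- nrow(X)
  constant <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) <= 1)
  rho <- suppressWarnings(cor(X, method = "spearman", use = "pairwise.complete.obs"))
  rho[constant, ] <- NA; rho[, constant] <- NA
  diag(rho)[!constant] <- 1
  if (p_method == "t") {
    r <- pmin(pmax(rho, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p[abs(r) >= 1 - 1e-15] <- 0
  } else {
    if (n > 8) abort("exact permutation p-values enumerate n! orderings; limited to n <= 8")
    perms <- permutations_of(n)
    p <- matrix(NA_real_, ncol(X), ncol(X))
    for (i in seq_len(ncol(X) - 1)) {
      for (j in (i + 1):ncol(X)) {
        if (constant[i] || constant[j]) next
        ri <- rank(X[, i]); rj <- rank(X[, j])
        obs <- abs(cor(ri, rj))
        null <- abs(apply(perms, 1, function(pp) cor(ri[pp], rj)))
        p[i, j] <- p[j, i] <- mean(null >= obs - 1e-12)
      }
    }
  }
  diag(p) <- NA
  dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlation-pattern distance
#'
#' `d(i, j) = 1 - |rho(i, j)|`: strongly correlated variables (of either
#' sign) are close, uncorrelated ones are at distance 1. Missing
#' correlations (constant variables) are assigned the maximal distance 1.
#' @param rho Symmetric correlation matrix.
#' @export
correlation_distance <- function(rho) {
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Embed a distance matrix by multidimensional scaling
#'
#' Classical (Torgerson) scaling, optionally refined by SMACOF stress
#' majorization (the default), which iteratively minimizes raw stress from
#' the classical solution. An optional rigid alignment (rotation +
#' translation, distance-preserving) places a named node at the origin and
#' the centroid of a node group in the lower-right quadrant, matching the
#' conventional display orientation.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal.
#' @param dims Embedding dimension (default 2; must be < n).
#' @param method `"stress"` (majorization, default) or `"classical"`.
#' @param origin_node Optional row name translated to the origin.
#' @param quadrant_nodes Optional row names whose centroid is rotated into
#'   the lower-right quadrant (first two dimensions).
#' @param max_iter,tol Majorization controls.
#' @return A list with `coordinates` (n x dims, rownames kept) and
#'   `stress` (normalized residual sum of squares of distances).
#' @export
mds_embed <- function(d, dims = 2, method = c("stress", "classical"),
                      origin_node = NULL, quadrant_nodes = NULL,
                      max_iter = 200, tol = 1e-8) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  if (dims >= n) abort("embedding dimension must be below the number of points")
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(d < 0)) {
    abort("d must be a symmetric nonnegative matrix with zero diagonal")
  }
  # zero trailing eigenvalues are expected for realizable metric inputs at
  # high dims; cmdscale then returns fewer axes and we pad below
  X <- suppressWarnings(cmdscale(d, k = dims))
  if (ncol(X) < dims) {  # degenerate spectra return fewer axes; pad
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  }
  if (method == "stress") {
    # SMACOF: Guttman transform iterations on raw stress
    denom <- sum(d^2)
    for (it in seq_len(max_iter)) {
      delta <- as.matrix(stats::dist(X))
      ratio <- ifelse(delta > 0, d / delta, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      Xn <- (B %*% X) / n
      delta_n <- as.matrix(stats::dist(Xn))
      if (sum((d - delta_n)^2) >= sum((d - delta)^2) - tol * denom) {
        X <- Xn
        break
      }
      X <- Xn
    }
  }
  delta <- as.matrix(stats::dist(X))
  stress <- sum((d - delta)^2) / sum(d^2)
  rownames(X) <- rownames(d)
  X <- align_coordinates(X, origin_node, quadrant_nodes)
  list(coordinates = X, stress = stress)
}

# rigid motion only: translate a node to the origin, then rotate the
# quadrant group's centroid onto the -45 degree ray (lower right)
align_coordinates <- function(X, origin_node = NULL, quadrant_nodes = NULL) {
  if (!is.null(origin_node) && origin_node %in% rownames(X)) {
    X <- sweep(X, 2, X[origin_node, ])
  }
  quadrant_nodes <- intersect(quadrant_nodes, rownames(X))
  if (length(quadrant_nodes) > 0 && ncol(X) >= 2) {
    cen <- colMeans(X[quadrant_nodes, , drop = FALSE])
    if (sqrt(sum(cen[1:2]^2)) > 1e-12) {
      # for row-vector coordinates, X %*% R(theta) rotates points by -theta;
      # sending the centroid (at angle phi) to -pi/4 needs theta = phi + pi/4
      theta <- atan2(cen[2], cen[1]) + pi / 4
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      X[, 1:2] <- X[, 1:2] %*% R
    }
  }
  X
}

#' Hotelling T-squared confidence ellipse
#'
#' Center and shape come from the sample mean and covariance; the boundary
#' is the Hotelling T-squared quantile via the F distribution,
#' `r2 = dims (k - 1) / (k - dims) * F(1 - alpha; dims, k - dims)`, times
#' the `(1 + 1/k)` prediction factor when `prediction = TRUE` (coverage of
#' a new point rather than of the mean).
#'
#' @param points k x dims coordinate matrix (k > dims + 1).
#' @param alpha Significance level (default 0.05 for a 95% ellipse).
#' @param prediction Include the new-point factor (default TRUE).
#' @return A `hotelling_ellipse` list: `center`, `shape` (covariance),
#'   `radius2`, `alpha`, `k`.
#' @export
hotelling_ellipse <- function(points, alpha = 0.05, prediction = TRUE) {
  points <- as.matrix(points)
  k <- nrow(points); dims <- ncol(points)
  if (k <= dims + 1) abort("need more points than dimensions + 1 for an ellipse")
  shape <- cov(points)
  if (!all(is.finite(shape)) || det(shape) <= 0) {
    abort("singular covariance; ellipse undefined")
  }
  radius2 <- dims * (k - 1) / (k - dims) * qf(1 - alpha, dims, k - dims)
  if (prediction) radius2 <- radius2 * (1 + 1 / k)
  structure(list(center = colMeans(points), shape = shape,
                 radius2 = radius2, alpha = alpha, k = k),
            class = "hotelling_ellipse")
}

#' Test whether points fall inside a Hotelling ellipse
#' @param ellipse A [hotelling_ellipse()].
#' @param points Matrix of points (columns match the ellipse dimensions).
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  m <- stats::mahalanobis(as.matrix(points), ellipse$center, ellipse$shape)
  m <= ellipse$radius2
}

#' Boundary polygon of a 2-D Hotelling ellipse (for plotting)
#' @param ellipse A [hotelling_ellipse()] fitted on 2-D points.
#' @param n_points Vertices along the boundary.
#' @export
ellipse_boundary <- function(ellipse, n_points = 100) {
  stopifnot(length(ellipse$center) == 2)
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(ang), sin(ang))
  ch <- chol(ellipse$shape)
  pts <- sqrt(ellipse$radius2) * circ %*% ch
  tibble(x = pts[, 1] + ellipse$center[1], y = pts[, 2] + ellipse$center[2])
}

#' Build a parameter connectivity network for one group
#'
#' Variables (metabolites and clinical covariates) become nodes positioned
#' by multidimensional scaling of `1 - |rho|` Spearman distances within the
#' chosen group; pairs correlated at `p < p_threshold` become signed edges;
#' metabolite classes with enough members get Hotelling T-squared
#' confidence ellipses in the embedding. The display is oriented with the
#' glucose node at the origin and the saturated-fatty-acid centroid in the
#' lower-right quadrant when those variables are present.
#'
#' @param table A `cohort_tbl`.
#' @param group Group label to analyze.
#' @param p_threshold Edge significance threshold; defaults to 0.05 for
#'   the first (reference) group and 0.01 for the second, the conventional
#'   display thresholds for unequal group sizes.
#' @param dims Embedding dimension (default 2).
#' @param method MDS method (see [mds_embed()]).
#' @param ellipse_alpha Ellipse significance level (default 0.05).
#' @return A `pcn` object with `nodes`, `edges`, `ellipses`, `stress`,
#'   `group`, `p_threshold`.
#' @export
build_pcn <- function(table, group = levels(table$group)[2],
                      p_threshold = NULL, dims = 2,
                      method = "stress", ellipse_alpha = 0.05) {
  groups <- levels(table$group)
  if (!group %in% groups) abort(paste0("group '", group, "' not present"))
  gi <- match(group, groups)
  if (is.null(p_threshold)) p_threshold <- if (gi == 1) 0.05 else 0.01
  pair <- spearman_pair(table)
  rho <- if (gi == 1) pair$rho_group0 else pair$rho_group1
  pm <- if (gi == 1) pair$p_group0 else pair$p_group1
  d <- correlation_distance(rho)
  ann <- cohort_annotation(table)
  sfa <- ann$name[ann$chem_class == "SFA"]
  emb <- mds_embed(d, dims = dims, method = method,
                   origin_node = if ("glucose" %in% rownames(d)) "glucose",
                   quadrant_nodes = sfa)
  vars <- pair$variables
  info <- ann[match(vars, ann$name), ]
  role <- dplyr::case_when(
    vars %in% clinical_names(table) ~ "clinical",
    !is.na(info$carbons) & info$carbons >= 20 ~ "metabolite>=20C",
    TRUE ~ "metabolite<20C"
  )
  nodes <- tibble(name = vars, role = role,
                  chem_class = ifelse(vars %in% clinical_names(table),
                                      "clinical", info$chem_class),
                  x = emb$coordinates[, 1],
                  y = if (dims >= 2) emb$coordinates[, 2] else 0)
  idx <- which(upper.tri(pm) & pm < p_threshold, arr.ind = TRUE)
  edge_rho <- rho[idx]
  edges <- tibble(from = vars[idx[, 1]], to = vars[idx[, 2]],
                  rho = edge_rho, p = pm[idx],
                  sign = ifelse(edge_rho >= 0, "positive", "negative"))
  if (nrow(edges) == 0) warn("no edges pass the significance threshold")
  classes <- split(nodes$name[!is.na(nodes$chem_class)],
                   nodes$chem_class[!is.na(nodes$chem_class)])
  ellipses <- purrr::compact(purrr::imap(classes, function(members, cls) {
    if (cls == "clinical" || length(members) < dims + 2) return(NULL)
    pts <- emb$coordinates[members, 1:min(dims, 2), drop = FALSE]
    tryCatch(hotelling_ellipse(pts, alpha = ellipse_alpha),
             error = function(e) NULL)
  }))
  structure(list(nodes = nodes, edges = edges, ellipses = ellipses,
                 stress = emb$stress, group = group,
                 p_threshold = p_threshold),
            class = "pcn")
}

#' Assemble the annotated biosynthetic pathway graph
#'
#' Nodes are metabolites sized by the magnitude of their percent change in
#' geometric mean; directed edges follow the annotated substrate-to-product
#' gradient, with width given by the magnitude of the change in the
#' product:substrate ratio and color by the FDR significance and direction
#' of the change. Edges without a computed ratio are kept gray with zero
#' width.
#'
#' @param univ A [summarize_cohort()] result.
#' @param idx An index/ratio result with columns `ratio`, `delta_gm_pct`,
#'   `fdr_significant` (e.g. from [compute_all_indices()]), or NULL.
#' @param annotation An [annotation_table()] with pathway edges.
#' @return A `pathway_graph` with `nodes` and `edges` tibbles.
#' @export
build_pathway_graph <- function(univ, idx, annotation) {
  mets <- univ[!univ$is_sum, ]
  direction <- function(delta, sig) {
    dplyr::case_when(!sig ~ "not-significant",
                     delta > 0 ~ "increased",
                     TRUE ~ "decreased")
  }
  nodes <- tibble(name = mets$metabolite,
                  size = abs(mets$delta_gm_pct),
                  status = direction(mets$delta_gm_pct, mets$fdr_significant),
                  chem_class = annotation$chem_class[match(mets$metabolite,
                                                           annotation$name)])
  ed <- pathway_edges(annotation)
  ed <- ed[ed$substrate %in% nodes$name & ed$product %in% nodes$name, ]
  ratio_key <- paste0(ed$product, "/", ed$substrate)
  hit <- if (is.null(idx)) rep(NA_integer_, nrow(ed)) else match(ratio_key, idx$ratio)
  edges <- tibble(
    substrate = ed$substrate, product = ed$product, enzyme = ed$enzyme,
    delta_ps_pct = ifelse(is.na(hit), NA_real_, idx$delta_gm_pct[hit]),
    width = ifelse(is.na(hit), 0, abs(idx$delta_gm_pct[hit])),
    status = ifelse(is.na(hit), "no-ratio",
                    direction(idx$delta_gm_pct[hit], idx$fdr_significant[hit]))
  )
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' Convert a network to an igraph object
#' @param x A `pcn` or `pathway_graph`.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "pcn")) {
    igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                  vertices = x$nodes)
  } else if (inherits(x, "pathway_graph")) {
    igraph::graph_from_data_frame(
      dplyr::rename(x$edges, from = "substrate", to = "product"),
      directed = TRUE, vertices = x$nodes)
  } else {
    abort("cannot convert this object to igraph")
  }
}

#' Export a network as GraphML
#' @param x A `pcn` or `pathway_graph`.
#' @param path Output file path.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}

#' Two-group correlation heatmap matrix
#'
#' Returns a square matrix whose upper triangle holds the first group's
#' Spearman correlations and lower triangle the second group's, with
#' non-significant cells (at `p_mask`) set to NA — the standard two-cohort
#' triangle display.
#'
#' @param pair A [spearman_pair()] result.
#' @param p_mask Significance threshold for display (default 0.05).
#' @export
correlation_heatmap_matrix <- function(pair, p_mask = 0.05) {
  v <- pair$variables
  m <- matrix(NA_real_, length(v), length(v), dimnames = list(v, v))
  up <- upper.tri(m); lo <- lower.tri(m)
  m[up] <- ifelse(pair$p_group0[up] < p_mask, pair$rho_group0[up], NA)
  m[lo] <- ifelse(pair$p_group1[lo] < p_mask, pair$rho_group1[lo], NA)
  m
}
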
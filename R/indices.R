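#' Built-in enzyme activity index definitions
#'
#' Activity of fatty-acid modifying enzymes is proxied by plasma NEFA
#' product:substrate concentration ratios. Four composite indices are
#' defined, each from two component ratios:
#' \describe{
#'   \item{SCD}{stearoyl-CoA desaturase: 16:1n7/16:0 and 18:1n9/18:0}
#'   \item{D6D}{delta-6 desaturase: 18:3n6/18:2n6 and 20:3n3/20:4n6}
#'   \item{ELOVL2}{very long chain elongase 2: 22:4n6/20:4n6 and
#'     22:5n3/20:5n3}
#'   \item{ELOVL2/D6D/SPCS}{combined elongation, desaturation and Sprecher
#'     pathway chain shortening completing VLCPUFA synthesis:
#'     22:5n6/22:4n6 and 22:6n3/22:5n3}
#' }
#' @return A list of index definitions (name, components tibble,
#'   aggregation).
#' @export
builtin_index_defs <- function() {
  def <- function(name, products, substrates) {
    structure(list(name = name,
                   components = tibble(product = products, substrate = substrates),
                   aggregation = "arithmetic-mean-of-ratios"),
              class = "activity_index_def")
  }
  list(
    def("SCD", c("16:1n7", "18:1n9"), c("16:0", "18:0")),
    def("D6D", c("18:3n6", "20:3n3"), c("18:2n6", "20:4n6")),
    def("ELOVL2", c("22:4n6", "22:5n3"), c("20:4n6", "20:5n3")),
    def("ELOVL2/D6D/SPCS", c("22:5n6", "22:6n3"), c("22:4n6", "22:5n3"))
  )
}

#' Define a custom activity index
#' @param name Index name.
#' @param products,substrates Equal-length metabolite name vectors; ratio i
#'   is `products[i] / substrates[i]`.
#' @export
activity_index_def <- function(name, products, substrates) {
  if (length(products) != length(substrates) || length(products) < 1) {
    abort("an index needs at least one product/substrate pair")
  }
  structure(list(name = name,
                 components = tibble(product = products, substrate = substrates),
                 aggregation = "arithmetic-mean-of-ratios"),
            class = "activity_index_def")
}

#' Per-subject product:substrate concentration ratio
#'
#' @param table A `cohort_tbl`.
#' @param product,substrate Metabolite names.
#' @return Numeric vector, one ratio per subject; `NA` where either
#'   concentration is masked.
#' @export
compute_ratio <- function(table, product, substrate) {
  for (m in c(product, substrate)) {
    if (!m %in% metabolite_names(table)) {
      abort(paste0("metabolite '", m, "' is not in the panel"))
    }
  }
  table[[product]] / table[[substrate]]
}

#' Compute an activity index and its group comparison
#'
#' Every component ratio is summarized individually, and the composite
#' index value per subject is the arithmetic mean of that subject's
#' component ratios (subjects missing any component are masked, never
#' imputed). Geometric means, ranges, percent change and the Mann-Whitney
#' test follow the univariate conventions; FDR decisions should be taken
#' jointly by passing the returned p-values through [bh_fdr()] together
#' with the rest of the tested family.
#'
#' @param table A `cohort_tbl`.
#' @param def An index definition from [builtin_index_defs()] or
#'   [activity_index_def()].
#' @param mode Mann-Whitney p-value mode.
#' @return A tibble: one row per component ratio plus one composite row
#'   (named after the index), with the same statistics columns as
#'   [summarize_cohort()] and a `per_subject` list-column of subject-level
#'   values.
#' @export
compute_index <- function(table, def, mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  g <- table$group
  ref <- levels(g)[1]
  comp_values <- purrr::pmap(def$components, function(product, substrate) {
    compute_ratio(table, product, substrate)
  })
  names(comp_values) <- paste0(def$components$product, "/", def$components$substrate)
  composite <- rowMeans(do.call(cbind, comp_values))
  values <- c(comp_values, setNames(list(composite), def$name))
  rows <- purrr::imap(values, function(v, nm) {
    x0 <- v[g == ref]; x1 <- v[g != ref]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    mw <- mann_whitney_u(x0, x1, mode = mode)
    tibble(
      ratio = nm, index = def$name, is_composite = nm == def$name,
      gm_group0 = geometric_mean(x0), gm_group1 = geometric_mean(x1),
      min_group0 = min(x0), max_group0 = max(x0),
      min_group1 = min(x1), max_group1 = max(x1),
      delta_gm_pct = delta_gm(geometric_mean(x0), geometric_mean(x1)),
      u_statistic = mw$u, p_value = mw$p_value,
      per_subject = list(v)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("lipid_index", class(out))
  out
}

#' Compute all built-in indices with a joint FDR decision
#' @param table A `cohort_tbl`.
#' @param q FDR level across all index hypotheses in the call.
#' @param mode Mann-Whitney p-value mode.
#' @export
compute_all_indices <- function(table, q = 0.1, mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  out <- bind_rows(purrr::map(builtin_index_defs(), compute_index,
                              table = table, mode = mode))
  out$fdr_significant <- bh_fdr(out$p_value, q = q)
  class(out) <- c("lipid_index", class(out))
  out
}
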
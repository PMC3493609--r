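#' Specify a synthetic two-group lipidomics cohort
#'
#' Concentrations are modeled log-normally: the group geometric mean sets
#' the log-scale location and `log_sd` the log-scale spread, with a shared
#' log-scale factor (weight `shared_log_weight`) inducing the positive
#' inter-metabolite correlation typical of fasting NEFA panels. Pathway
#' couplings generate a product metabolite as its substrate times a
#' log-normal ratio, so the group ratio geometric mean is planted exactly.
#' Clinical covariates are Gaussian per group and rank-coupled to a named
#' metabolite sum through a Gaussian copula to approximate a target
#' Spearman correlation.
#'
#' Sampling is moment-matched: every standard-normal draw is centered and
#' scaled within group, so generated per-metabolite sample geometric means
#' equal their specification at any group size.
#'
#' @param metabolite_specs Tibble with columns `name`, `chem_class`,
#'   `family`, `unit`, `gm_group0`, `gm_group1`, `log_sd`.
#' @param pathway_couplings Tibble with columns `substrate`, `product`,
#'   `enzyme`, `gm_ratio_group0`, `gm_ratio_group1`, `ratio_log_sd`. A
#'   product may also be declared in `metabolite_specs` (its class, family
#'   and unit then annotate it), but its values are generated from the
#'   coupling; chained couplings must be listed substrate-first.
#' @param covariate_specs Tibble with columns `name`, `mean_group0`,
#'   `sd_group0`, `mean_group1`, `sd_group1`, `rho_target`, `rho_to`
#'   (an annotation family whose per-subject sum the covariate tracks, or
#'   a metabolite name).
#' @param n_per_group Integer pair, subjects per group (default `c(12, 43)`).
#' @param shared_log_weight Fraction of log-scale variance carried by the
#'   shared factor (default 0.6).
#' @param group_labels Labels for the two groups.
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(metabolite_specs,
                        pathway_couplings = NULL,
                        covariate_specs = NULL,
                        n_per_group = c(12L, 43L),
                        shared_log_weight = 0.6,
                        group_labels = c("non-diabetic", "diabetic"),
                        seed = 1L) {
  met <- as_tibble(metabolite_specs)
  stopifnot(all(c("name", "gm_group0", "gm_group1", "log_sd") %in% names(met)))
  if (any(met$gm_group0 <= 0 | met$gm_group1 <= 0)) abort("geometric means must be positive")
  if (any(met$log_sd < 0)) abort("log_sd must be nonnegative")
  if (any(n_per_group < 3)) abort("group sizes must be at least 3")
  if (shared_log_weight < 0 || shared_log_weight >= 1) {
    abort("shared_log_weight must lie in [0, 1)")
  }
  cpl <- if (is.null(pathway_couplings)) {
    tibble(substrate = character(), product = character(), enzyme = character(),
           gm_ratio_group0 = numeric(), gm_ratio_group1 = numeric(),
           ratio_log_sd = numeric())
  } else as_tibble(pathway_couplings)
  bad <- setdiff(cpl$substrate, c(met$name, cpl$product))
  if (length(bad) > 0) {
    abort(paste0("coupling references undeclared substrate(s): ",
                 paste(bad, collapse = ", ")))
  }
  cov <- if (is.null(covariate_specs)) {
    tibble(name = character(), mean_group0 = numeric(), sd_group0 = numeric(),
           mean_group1 = numeric(), sd_group1 = numeric(),
           rho_target = numeric(), rho_to = character())
  } else as_tibble(covariate_specs)
  if (any(abs(cov$rho_target) > 0.999)) {
    abort("copula target |rho| > 0.999 is infeasible")
  }
  structure(list(metabolite_specs = met, pathway_couplings = cpl,
                 covariate_specs = cov, n_per_group = as.integer(n_per_group),
                 shared_log_weight = shared_log_weight,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "cohort_spec")
}

# center (and unless degenerate, scale) a draw so planted moments are exact
standardize_draw <- function(z) {
  z <- z - mean(z)
  s <- sqrt(sum(z^2) / (length(z) - 1))
  if (s > 0) z / s else z
}

#' Generate a synthetic cohort from a specification
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the spec's seed. Identical seeds
#'   give bitwise-identical cohorts.
#' @return A `cohort_tbl` with annotation built from the spec (including
#'   its pathway couplings as annotation edges).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(as.integer(seed))
  met <- spec$metabolite_specs
  cpl <- spec$pathway_couplings
  w <- spec$shared_log_weight
  groups <- rep(spec$group_labels, spec$n_per_group)
  blocks <- purrr::map(1:2, function(gi) {
    n <- spec$n_per_group[gi]
    gcol <- function(base) paste0(base, "_group", gi - 1)
    z_shared <- standardize_draw(rnorm(n))
    all_names <- union(met$name, cpl$product)
    conc <- matrix(NA_real_, n, length(all_names),
                   dimnames = list(NULL, all_names))
    for (i in seq_len(nrow(met))) {
      if (met$name[i] %in% cpl$product) next  # governed by its coupling
      gm <- met[[gcol("gm")]][i]
      lsd <- met$log_sd[i]
      if (lsd == 0) {
        conc[, met$name[i]] <- rep(gm, n)
      } else {
        eps <- standardize_draw(rnorm(n))
        conc[, met$name[i]] <- gm * exp(lsd * (sqrt(w) * z_shared + sqrt(1 - w) * eps))
      }
    }
    # couplings are applied in order, so chained products (substrate itself
    # a product) must be listed downstream of their substrate
    if (nrow(cpl) > 0) {
      for (j in seq_len(nrow(cpl))) {
        sub <- cpl$substrate[j]
        if (all(is.na(conc[, sub]))) {
          abort(paste0("coupling substrate '", sub, "' generated after its product"))
        }
        ratio_gm <- cpl[[gcol("gm_ratio")]][j]
        rsd <- cpl$ratio_log_sd[j]
        ratio <- if (rsd == 0) rep(ratio_gm, n) else {
          ratio_gm * exp(rsd * standardize_draw(rnorm(n)))
        }
        conc[, cpl$product[j]] <- conc[, sub] * ratio
      }
    }
    fam <- spec_annotation(spec)
    cov <- spec$covariate_specs
    covs <- matrix(NA_real_, n, nrow(cov), dimnames = list(NULL, cov$name))
    for (k in seq_len(nrow(cov))) {
      target <- cov$rho_to[k]
      members <- if (target %in% fam$family) fam$name[fam$family == target] else target
      s <- rowSums(conc[, members, drop = FALSE])
      # Gaussian copula: Pearson correlation on normal scores that yields
      # the requested Spearman correlation
      r <- 2 * sin(pi * cov$rho_target[k] / 6)
      z_s <- standardize_draw(qnorm((rank(s) - 0.375) / (n + 0.25)))
      zc <- standardize_draw(r * z_s + sqrt(1 - r^2) * standardize_draw(rnorm(n)))
      v <- cov[[gcol("mean")]][k] + cov[[gcol("sd")]][k] * zc
      # clinical chemistry values cannot be negative; winsorize the tail
      v <- pmax(v, 0.02 * abs(cov[[gcol("mean")]][k]))
      covs[, k] <- v
    }
    list(conc = conc, covs = covs)
  })
  conc <- rbind(blocks[[1]]$conc, blocks[[2]]$conc)
  covs <- rbind(blocks[[1]]$covs, blocks[[2]]$covs)
  edges <- cpl[, c("substrate", "product", "enzyme")]
  if (!is.null(spec$annotation_edges)) {
    edges <- bind_rows(edges, spec$annotation_edges)
  }
  ann <- annotation_table(spec_annotation(spec), pathway_edges = edges)
  data <- bind_cols(
    tibble(subject = sprintf("S%03d", seq_along(groups)),
           group = factor(groups, levels = spec$group_labels)),
    as_tibble(covs), as_tibble(conc)
  )
  cohort_table(data, ann, clinical = spec$covariate_specs$name)
}

# full annotation rows for spec metabolites plus any coupling products not
# declared explicitly (those inherit their substrate's class/family/unit)
spec_annotation <- function(spec) {
  met <- spec$metabolite_specs
  base <- tibble(name = met$name, chem_class = met$chem_class,
                 family = met$family, carbons = met$carbons %||% NA_integer_,
                 double_bonds = met$double_bonds %||% NA_integer_,
                 unit = met$unit)
  cpl <- spec$pathway_couplings
  extra <- cpl[!cpl$product %in% met$name, ]
  if (nrow(extra) > 0) {
    sub_ann <- base[match(extra$substrate, base$name), ]
    add <- tibble(name = extra$product,
                  chem_class = sub_ann$chem_class,
                  family = sub_ann$family,
                  carbons = NA_integer_, double_bonds = NA_integer_,
                  unit = sub_ann$unit)
    base <- bind_rows(base, add)
  }
  base
}

#' Generate synthetic quantification records with planted QC failures
#'
#' @param n Number of records.
#' @param fail_fractions Named fractions among `"sn"`, `"below_calibrant"`,
#'   `"recovery"`; each record independently fails at most one rule, with
#'   the given marginal probabilities (must sum to at most 1).
#' @param seed Integer seed.
#' @return A [quant_records()] tibble.
#' @export
generate_quant_records <- function(n, fail_fractions = c(), seed = 1L) {
  fr <- c(sn = 0, below_calibrant = 0, recovery = 0)
  fr[names(fail_fractions)] <- fail_fractions
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    abort("fail fractions must lie in [0,1] and sum to at most 1")
  }
  withr::local_seed(as.integer(seed))
  u <- runif(n)
  rule <- rep("pass", n)
  rule[u < fr[1] + fr[2] + fr[3]] <- "recovery"
  rule[u < fr[1] + fr[2]] <- "below_calibrant"
  rule[u < fr[1]] <- "sn"
  sn <- ifelse(rule == "sn", runif(n, 0.1, 1.9), runif(n, 2.5, 50))
  calibrant <- runif(n, 0.5, 2)
  raw <- ifelse(rule == "below_calibrant",
                calibrant * runif(n, 0.1, 0.9),
                calibrant * runif(n, 1.5, 20))
  recovery <- ifelse(rule == "recovery", runif(n, 0.01, 0.39), runif(n, 0.5, 1.1))
  quant_records(analyte = sprintf("analyte_%04d", seq_len(n)),
                raw_concentration = raw, signal_to_noise = sn,
                surrogate_recovery = recovery, lowest_calibrant = calibrant)
}
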
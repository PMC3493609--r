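#' Configure an end-to-end analysis run
#'
#' A single configuration drives the whole chain: simulate (or read) a
#' cohort, apply univariate statistics and activity indices, fit the
#' IVS-optimized discriminant model, and build correlation networks. Every
#' random stage derives from the one seed, so a rerun with the same
#' configuration reproduces all artifacts.
#'
#' @param cohort_path,annotation_path Input files; if NULL, a cohort is
#'   generated from `spec`.
#' @param spec A [cohort_spec()] (default [default_study_spec()]).
#' @param q FDR level for univariate and index tests.
#' @param n_orthogonal Orthogonal components of the final OPLS-DA model.
#' @param ivs An [ivs_config()]; set `run_ivs = FALSE` to skip selection.
#' @param run_ivs Run IVS feature selection (default TRUE).
#' @param network_thresholds Named numeric edge p thresholds per group
#'   (NULL uses the 0.05/0.01 convention).
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed.
#' @export
pipeline_config <- function(cohort_path = NULL, annotation_path = NULL,
                            spec = default_study_spec(),
                            q = 0.1, n_orthogonal = 1,
                            ivs = ivs_config(n_runs = 10),
                            run_ivs = TRUE,
                            network_thresholds = NULL,
                            out_dir = "lipidisc-run", seed = 1L) {
  structure(list(cohort_path = cohort_path, annotation_path = annotation_path,
                 spec = spec, q = q, n_orthogonal = n_orthogonal,
                 ivs = ivs, run_ivs = run_ivs,
                 network_thresholds = network_thresholds,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis chain and write a report bundle
#'
#' Stages: cohort acquisition, univariate summary (report-table CSV),
#' activity indices, discriminant modeling (optionally IVS-optimized),
#' external validation, per-group connectivity networks and the pathway
#' graph. Artifacts are written under `config$out_dir` together with a
#' manifest recording the seed and every threshold applied; any stage
#' failure aborts with the stage name and leaves a `failed` marker file.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(out, "failed"))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) {
      if (!file.exists(config$cohort_path)) {
        abort(paste0("input path does not exist: ", config$cohort_path))
      }
      read_cohort(config$cohort_path, config$annotation_path)
    } else {
      generate_cohort(config$spec, seed = config$seed)
    }
  })
  stage("write-cohort", write_cohort(cohort, file.path(out, "cohort.csv"),
                                     file.path(out, "annotation.csv")))
  univ <- stage("univariate", summarize_cohort(cohort, q = config$q))
  stage("write-univariate", {
    readr::write_csv(format_univariate(univ), file.path(out, "univariate.csv"))
    readr::write_csv(select(univ, -dplyr::any_of("per_subject")),
                     file.path(out, "univariate_full.csv"))
  })
  idx <- stage("indices", compute_all_indices(cohort, q = config$q))
  stage("write-indices", {
    readr::write_csv(select(idx, -"per_subject"), file.path(out, "indices.csv"))
  })
  X <- conc_matrix(cohort)
  y <- cohort$group
  selection <- NULL
  if (config$run_ivs) {
    ivs_cfg <- config$ivs
    ivs_cfg$seed <- config$seed + 101L
    ens <- stage("ivs", ivs_ensemble(X, y, ivs_cfg))
    selection <- ens$best$selected_variables
    stage("write-ivs", {
      audit <- purrr::map(ens$all_runs, function(r) {
        list(run_seed = r$run_seed, final_q2 = r$final_q2,
             selected = r$selected_variables,
             trajectory = r$objective_trajectory)
      })
      jsonlite::write_json(audit, file.path(out, "ivs_runs.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  } else {
    selection <- colnames(X)
  }
  model <- stage("model", build_final_model(X, y, selection,
                                            n_orthogonal = config$n_orthogonal))
  q2 <- stage("model-q2", q_squared(X[, selection, drop = FALSE], y,
                                    seed = config$seed + 7L))
  validation <- stage("validation",
                      external_validation(X[, selection, drop = FALSE], y,
                                          seed = config$seed + 11L))
  stage("write-model", {
    jsonlite::write_json(
      list(kind = model$kind, features = model$features,
           n_orthogonal = model$n_orthogonal, r2y = model$r2y,
           q2 = q2, auroc_train = model$auroc_train,
           weights = drop(model$weights), loadings = drop(model$loadings)),
      file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(tibble(subject = cohort$subject, group = as.character(y),
                            score = model$fitted,
                            orthogonal = model$ortho_scores[, 1]),
                     file.path(out, "scores.csv"))
    readr::write_csv(tidy(model), file.path(out, "loadings.csv"))
    readr::write_csv(validation$per_repeat, file.path(out, "validation.csv"))
  })
  groups <- levels(y)
  networks <- stage("networks", {
    purrr::map(groups, function(gl) {
      thr <- config$network_thresholds[[gl]]
      build_pcn(cohort, group = gl, p_threshold = thr)
    }) |> setNames(groups)
  })
  stage("write-networks", {
    for (gl in groups) {
      safe <- gsub("[^A-Za-z0-9]+", "_", gl)
      readr::write_csv(networks[[gl]]$nodes,
                       file.path(out, paste0("pcn_", safe, "_nodes.csv")))
      readr::write_csv(networks[[gl]]$edges,
                       file.path(out, paste0("pcn_", safe, "_edges.csv")))
      write_graphml(networks[[gl]], file.path(out, paste0("pcn_", safe, ".graphml")))
    }
  })
  pathway <- stage("pathway", {
    pg <- build_pathway_graph(univ, idx, cohort_annotation(cohort))
    readr::write_csv(pg$nodes, file.path(out, "pathway_nodes.csv"))
    readr::write_csv(pg$edges, file.path(out, "pathway_edges.csv"))
    write_graphml(pg, file.path(out, "pathway.graphml"))
    pg
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("lipidisc")),
    seed = config$seed, q = config$q,
    n_orthogonal = config$n_orthogonal,
    run_ivs = config$run_ivs,
    ivs = if (config$run_ivs) {
      c(config$ivs[c("objective", "max_outer_iterations",
                     "convergence_tolerance", "n_runs", "n_folds",
                     "n_components")])
    },
    network_thresholds = purrr::map(networks, "p_threshold"),
    n_selected = length(selection),
    selected = selection,
    # hash of the analysis parameters (output location excluded)
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, univariate = univ, indices = idx,
                 model = model, q2 = q2, validation = validation,
                 networks = networks, pathway = pathway,
                 manifest = manifest))
}
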
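#' Build a metabolite annotation table
#'
#' Annotations carry the chemical identity of each analyte in a targeted
#' panel: its chemical class (SFA, MUFA, PUFA, trans-FA, epoxide, diol,
#' ketone, alcohol, isoprostane, NAE, MAG, LAA, ...), the broader panel
#' family used for class sums (NEFA, oxylipin, NAE, LAA, MAG), acyl chain
#' length and unsaturation, the reporting unit, and the biosynthetic
#' substrate-to-product edges (with enzyme labels) that define pathway
#' graphs and activity indices.
#'
#' @param metabolites A data frame with columns `name`, `chem_class`,
#'   `family`, `carbons`, `double_bonds`, `unit`. Units must be uniform
#'   within a family so that class sums are well defined.
#' @param pathway_edges Optional data frame with columns `substrate`,
#'   `product`, `enzyme`; both endpoints must be annotated metabolites.
#' @return A tibble of metabolite annotations with the edge table attached
#'   as the `pathway_edges` attribute.
#' @export
annotation_table <- function(metabolites, pathway_edges = NULL) {
  met <- as_tibble(metabolites)
  required <- c("name", "chem_class", "family", "carbons", "double_bonds", "unit")
  missing_cols <- setdiff(required, names(met))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(met$name)) {
    abort("metabolite names must be unique within an annotation panel")
  }
  if (!all(met$unit %in% c("uM", "nM"))) {
    abort("unit must be 'uM' or 'nM'")
  }
  if (is.null(pathway_edges)) {
    pathway_edges <- tibble(substrate = character(), product = character(),
                            enzyme = character())
  }
  edges <- as_tibble(pathway_edges)
  bad <- setdiff(c(edges$substrate, edges$product), met$name)
  if (length(bad) > 0) {
    abort(paste0("pathway edge references unannotated metabolite(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  attr(met, "pathway_edges") <- edges
  class(met) <- c("lipid_annotation", class(met))
  met
}

#' @export
pathway_edges <- function(annotation) {
  attr(annotation, "pathway_edges") %||%
    tibble(substrate = character(), product = character(), enzyme = character())
}

#' Assemble a validated two-group cohort table
#'
#' A cohort table is a tibble with one row per subject: a `subject`
#' identifier, a two-level `group` factor, clinical covariate columns, and
#' one strictly positive concentration column per annotated metabolite.
#' Missing concentrations are `NA` (an explicit mask); zeros are rejected
#' because every downstream statistic works on the log scale.
#'
#' @param data Data frame with `subject`, `group`, clinical and metabolite
#'   columns.
#' @param annotation An [annotation_table()]; every metabolite column must
#'   be annotated.
#' @param clinical Character vector naming the clinical covariate columns
#'   present in `data` (may be empty).
#' @return A `cohort_tbl` tibble carrying `annotation`, `metabolites` and
#'   `clinical` attributes.
#' @export
cohort_table <- function(data, annotation, clinical = character()) {
  data <- as_tibble(data)
  if (!"group" %in% names(data)) abort("cohort table requires a 'group' column")
  if (!"subject" %in% names(data)) {
    data$subject <- paste0("S", seq_len(nrow(data)))
  }
  if (!is.factor(data$group)) {
    # order of appearance, so written cohorts round-trip with their levels
    data$group <- factor(data$group, levels = unique(as.character(data$group)))
  }
  if (nlevels(data$group) != 2) {
    abort("group must have exactly two levels")
  }
  if (anyDuplicated(clinical)) abort("clinical covariate names must be unique")
  mets <- intersect(annotation$name, names(data))
  unknown <- setdiff(names(data), c("subject", "group", clinical, annotation$name))
  if (length(unknown) > 0) {
    abort(paste0("column(s) without annotation: ", paste(unknown, collapse = ", ")))
  }
  for (m in mets) {
    v <- data[[m]]
    if (!is.numeric(v)) abort(paste0("metabolite column '", m, "' is not numeric"))
    if (any(!is.na(v) & v <= 0)) {
      abort(paste0("nonpositive concentration in metabolite '", m, "'"))
    }
  }
  out <- data[, c("subject", "group", clinical, mets)]
  attr(out, "annotation") <- annotation
  attr(out, "metabolites") <- mets
  attr(out, "clinical") <- clinical
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' @export
metabolite_names <- function(table) attr(table, "metabolites")

#' @export
clinical_names <- function(table) attr(table, "clinical")

#' @export
cohort_annotation <- function(table) attr(table, "annotation")

#' Extract the subjects-by-metabolites concentration matrix
#' @param table A `cohort_tbl`.
#' @param variables Columns to extract; defaults to all metabolites.
#' @export
conc_matrix <- function(table, variables = metabolite_names(table)) {
  m <- as.matrix(as.data.frame(table)[, variables, drop = FALSE])
  rownames(m) <- table$subject
  m
}

# tibble subsetting drops our attributes; restore them on [ so that piped
# dplyr-free row filtering keeps the cohort class usable
#' @export
`[.cohort_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("subject", "group") %in% names(out))) {
    ann <- attr(x, "annotation")
    attr(out, "annotation") <- ann
    attr(out, "metabolites") <- intersect(attr(x, "metabolites"), names(out))
    attr(out, "clinical") <- intersect(attr(x, "clinical"), names(out))
    class(out) <- unique(c("cohort_tbl", class(out)))
  }
  out
}

#' Read a cohort table and its annotation from delimited text
#'
#' @param path CSV/TSV file: one subject per row, a `group` column, clinical
#'   covariates and metabolite concentrations in columns.
#' @param annotation_path CSV with columns `name`, `chem_class`, `family`,
#'   `carbons`, `double_bonds`, `unit` and optionally `substrate`,
#'   `product`, `enzyme` (rows with both substrate and product non-missing
#'   define pathway edges).
#' @return A validated `cohort_tbl`.
#' @export
read_cohort <- function(path, annotation_path) {
  annotation <- read_annotation(annotation_path)
  data <- readr::read_delim(path, delim = guess_delim(path),
                            show_col_types = FALSE, progress = FALSE)
  for (m in intersect(annotation$name, names(data))) {
    if (!is.numeric(data[[m]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(data[[m]]))) &
                         !is.na(data[[m]]))[1]
      abort(paste0("unparseable numeric cell at row ", bad_row,
                   ", column '", m, "'"))
    }
  }
  clinical <- setdiff(names(data),
                      c("subject", "group", annotation$name))
  cohort_table(data, annotation, clinical = clinical)
}

#' @rdname read_cohort
#' @export
read_annotation <- function(annotation_path) {
  ann <- readr::read_delim(annotation_path, delim = guess_delim(annotation_path),
                           show_col_types = FALSE, progress = FALSE)
  edge_cols <- c("substrate", "product", "enzyme")
  edges <- NULL
  if (all(c("substrate", "product") %in% names(ann))) {
    is_edge <- !is.na(ann$substrate) & !is.na(ann$product)
    edges <- ann[is_edge, intersect(edge_cols, names(ann)), drop = FALSE]
    if (!"enzyme" %in% names(edges)) edges$enzyme <- NA_character_
    ann <- ann[!is_edge, setdiff(names(ann), edge_cols)]
  }
  annotation_table(ann, pathway_edges = edges)
}

#' Write a cohort table (and optionally its annotation) to CSV
#' @param table A `cohort_tbl`.
#' @param path Output CSV path for the subject table.
#' @param annotation_path Optional output CSV path for the annotation.
#' @export
write_cohort <- function(table, path, annotation_path = NULL) {
  readr::write_csv(as_tibble(as.data.frame(table)), path, progress = FALSE)
  if (!is.null(annotation_path)) {
    ann <- cohort_annotation(table)
    edges <- pathway_edges(ann)
    flat <- as_tibble(as.data.frame(ann))
    flat$substrate <- NA_character_
    flat$product <- NA_character_
    flat$enzyme <- NA_character_
    if (nrow(edges) > 0) {
      pad <- flat[rep(1, nrow(edges)), ]
      pad[] <- NA
      pad$name <- edges$substrate
      pad$substrate <- edges$substrate
      pad$product <- edges$product
      pad$enzyme <- edges$enzyme
      # edge rows reuse annotated names so round-trip keeps nodes unique
      pad <- pad[, names(flat)]
      flat <- bind_rows(flat, pad)
    }
    readr::write_csv(flat, annotation_path, progress = FALSE)
  }
  invisible(path)
}

guess_delim <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}
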
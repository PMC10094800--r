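# Cohort table and panel annotation: containers, I/O, validation.

FUNCTIONAL_CLASSES <- c(
  "hemostasis", "extracellular_matrix", "endothelium", "inflammation",
  "complement", "lipid_metabolism", "calcification",
  "steroid_hormone_transport", "assay_parameter", "clinical"
)

ASSAYS <- c(
  "proteomics", "rotem", "thrombodynamics", "aggregometry", "coag_lab",
  "clinical"
)

#' Construct a cohort table
#'
#' A cohort table couples one row per subject (identifier, serostatus inputs,
#' optional group label, clinical covariates) with a block of numeric
#' measurement columns (protein abundances and hemostasis assay parameters).
#' Missing cells are `NA`, which is distinct from 0 throughout the pipeline.
#'
#' @param data Data frame with columns `subject_id`, `anti_n_igg`, `ami_flag`,
#'   optionally `group`, then covariates and measurement parameters.
#' @param covariate_cols Names of the clinical covariate columns.
#' @param parameter_cols Names of the numeric measurement columns.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(data, covariate_cols, parameter_cols) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  dup <- unique(data$subject_id[duplicated(data$subject_id)])
  if (length(dup) > 0) {
    stop("duplicate subject ids: ", paste(dup, collapse = ", "))
  }
  missing_cols <- setdiff(c(covariate_cols, parameter_cols), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not present in data: ", paste(missing_cols, collapse = ", "))
  }
  for (p in parameter_cols) {
    if (!is.numeric(data[[p]])) {
      stop("measurement column is not numeric: ", p)
    }
  }
  if (!"group" %in% names(data)) data$group <- factor(NA, cohort_groups())
  data$group <- factor(as.character(data$group), levels = cohort_groups())
  structure(
    list(data = data, covariate_cols = covariate_cols,
         parameter_cols = parameter_cols),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " subjects, ",
      length(x$parameter_cols), " parameters, ",
      length(x$covariate_cols), " covariates\n", sep = "")
  if (!all(is.na(x$data$group))) {
    print(table(x$data$group))
  }
  invisible(x)
}

#' Derive and attach serostatus groups
#'
#' Applies [assign_serostatus_group()] to every subject. If groups were
#' already assigned they are overwritten with a warning, since assignment is
#' a pure function of the anti-N IgG index and the AMI flag.
#'
#' @param cohort A `cohort_table`.
#' @param threshold Seropositivity cutoff (default 1.4).
#' @return The cohort with its `group` column filled in.
#' @export
assign_groups <- function(cohort, threshold = 1.4) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!all(is.na(cohort$data$group))) {
    warning("overwriting existing group assignment")
  }
  cohort$data$group <- assign_serostatus_group(
    cohort$data$anti_n_igg, cohort$data$ami_flag, threshold
  )
  cohort
}

#' Read a cohort table from a delimited file
#'
#' Expects a header row and one subject per row; columns `subject_id`,
#' `anti_n_igg`, `ami_flag`, optionally `group`, then covariates and
#' measurement parameters. Which trailing columns are covariates is
#' controlled by `covariate_cols` (default: the conventional clinical set
#' present in the file). Empty cells and the configured sentinel strings
#' parse to `NA`.
#'
#' @param path File path.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @param covariate_cols Covariate column names; defaults to the intersection
#'   of `c("sex", "age", "bmi", "smoking")` with the file's columns.
#' @param na_strings Sentinel strings read as missing.
#' @return A `cohort_table`.
#' @export
read_cohort_table <- function(path, sep = ",",
                              covariate_cols = NULL,
                              na_strings = c("", "NA", "NaN")) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = NA,
                           comment.char = "")
  if (!"subject_id" %in% names(raw)) stop("missing subject_id column")
  raw$subject_id <- as.character(raw$subject_id)
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(c("sex", "age", "bmi", "smoking"), names(raw))
  }
  id_cols <- intersect(c("subject_id", "group", "anti_n_igg", "ami_flag"),
                       names(raw))
  parameter_cols <- setdiff(names(raw), c(id_cols, covariate_cols))
  for (p in parameter_cols) {
    if (!is.numeric(raw[[p]])) {
      bad <- which(!is.na(raw[[p]]))
      stop(sprintf("non-numeric cell in measurement column '%s' (row %d)",
                   p, if (length(bad)) bad[1] else NA_integer_))
    }
  }
  if ("ami_flag" %in% names(raw)) raw$ami_flag <- as.logical(raw$ami_flag)
  if ("smoking" %in% names(raw)) raw$smoking <- as.logical(raw$smoking)
  cohort_table(raw, covariate_cols, parameter_cols)
}

#' Write a cohort table to a delimited file
#'
#' Inverse of [read_cohort_table()]: missing cells are written as empty
#' strings and round-trip back to `NA`.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_cohort_table <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.table(cohort$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a panel annotation table
#'
#' Tab-separated file with columns `parameter`, `functional_class` and
#' optionally `assay`, mapping every measured parameter to one functional
#' class (hemostasis, extracellular matrix, endothelium, inflammation,
#' complement, lipid metabolism, calcification, steroid hormone transport)
#' or to the bookkeeping classes `assay_parameter` / `clinical`.
#'
#' @param path File path.
#' @return A data frame of class `panel_annotation`.
#' @export
read_panel_annotation <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0) {
    return(panel_annotation(character(), character(), character()))
  }
  if (!all(c("parameter", "functional_class") %in% names(raw))) {
    stop("panel annotation needs columns parameter, functional_class")
  }
  assay <- if ("assay" %in% names(raw)) raw$assay else
    rep("proteomics", nrow(raw))
  panel_annotation(raw$parameter, raw$functional_class, assay)
}

#' Construct a panel annotation
#'
#' @param parameter Parameter names (case-sensitive keys matching the cohort
#'   table's measurement columns verbatim).
#' @param functional_class One class per parameter.
#' @param assay Measuring assay per parameter.
#' @return Data frame of class `panel_annotation`.
#' @export
panel_annotation <- function(parameter, functional_class,
                             assay = rep("proteomics", length(parameter))) {
  bad <- setdiff(unique(functional_class), FUNCTIONAL_CLASSES)
  if (length(bad) > 0) {
    stop("unknown functional class: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(assay), ASSAYS)
  if (length(bad) > 0) stop("unknown assay: ", paste(bad, collapse = ", "))
  df <- data.frame(parameter = as.character(parameter),
                   functional_class = as.character(functional_class),
                   assay = as.character(assay),
                   stringsAsFactors = FALSE)
  conflicting <- unique(df$parameter[duplicated(df[c("parameter")])])
  if (length(conflicting) > 0) {
    chk <- unique(df)
    if (anyDuplicated(chk$parameter)) {
      stop("parameter annotated with conflicting classes: ",
           paste(unique(chk$parameter[duplicated(chk$parameter)]),
                 collapse = ", "))
    }
    df <- chk
  }
  class(df) <- c("panel_annotation", "data.frame")
  df
}

#' Write a panel annotation table
#' @param panel A `panel_annotation`.
#' @param path Output path (TSV).
#' @export
write_panel_annotation <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a cohort table against its panel annotation
#'
#' A pure reporting step: counts subjects per group, the missing-data
#' fraction per assay, parameters lacking annotation, and duplicated subject
#' identifiers. The report is free of problems exactly when the cohort
#' invariants hold.
#'
#' @param cohort A `cohort_table`.
#' @param panel A `panel_annotation`.
#' @return List of class `validation_report` with elements
#'   `n_subjects_per_group`, `missing_fraction_by_assay`,
#'   `unannotated_parameters`, `duplicate_subjects`.
#' @export
validate_cohort <- function(cohort, panel) {
  stopifnot(inherits(cohort, "cohort_table"))
  n_per_group <- table(cohort$data$group, useNA = "no")
  assay_of <- stats::setNames(panel$assay, panel$parameter)
  missing_by_assay <- vapply(ASSAYS, function(a) {
    cols <- intersect(names(assay_of)[assay_of == a], cohort$parameter_cols)
    if (length(cols) == 0) return(NA_real_)
    block <- as.matrix(cohort$data[cols])
    mean(is.na(block))
  }, numeric(1))
  structure(
    list(
      n_subjects_per_group = n_per_group,
      missing_fraction_by_assay = missing_by_assay[!is.na(missing_by_assay)],
      unannotated_parameters = setdiff(cohort$parameter_cols,
                                       panel$parameter),
      duplicate_subjects = unique(
        cohort$data$subject_id[duplicated(cohort$data$subject_id)])
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\nsubjects per group:\n")
  print(x$n_subjects_per_group)
  cat("missing fraction by assay:\n")
  print(round(x$missing_fraction_by_assay, 4))
  if (length(x$unannotated_parameters)) {
    cat("unannotated:", paste(x$unannotated_parameters, collapse = ", "), "\n")
  }
  if (length(x$duplicate_subjects)) {
    cat("duplicates:", paste(x$duplicate_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}

# Measurement block for one group as a subjects x parameters matrix.
group_measurements <- function(cohort, group, parameters = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!group %in% cohort_groups()) stop("unknown group: ", group)
  if (is.null(parameters)) parameters <- cohort$parameter_cols
  rows <- !is.na(cohort$data$group) & cohort$data$group == group
  as.matrix(cohort$data[rows, parameters, drop = FALSE])
}
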
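#' @keywords internal
"_PACKAGE"

#' Recognized brain cell types
#'
#' The four nuclei populations resolved by fluorescence-activated nuclei
#' sorting of cortical tissue: NeuN+ neurons (NEU), IRF8+ microglia (MG),
#' SOX10+ oligodendrocytes (OLIG) and the triple-negative astrocyte-enriched
#' fraction (AST).
#' @export
CELL_TYPES <- c("NEU", "MG", "OLIG", "AST")

#' Panel specificity levels
#' @export
SPECIFICITY_LEVELS <- c("high", "medium", "low")

#' Construct and validate a beta matrix
#'
#' A beta matrix stores methylation fractions (beta values) as a numeric
#' matrix with CpG identifiers as row names and sample identifiers as column
#' names. All values must lie in \[0, 1\] and no missing values are allowed:
#' upstream preprocessing is expected to have handled detection failures, and
#' this package refuses to impute.
#'
#' @param values numeric matrix of beta values (CpGs x samples).
#' @param cpg_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return the validated matrix, classed `beta_matrix`.
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("beta matrix needs CpG row names and sample column names",
         call. = FALSE)
  rownames(values) <- as.character(cpg_ids)
  colnames(values) <- as.character(sample_ids)
  validate_beta_matrix(values)
  class(values) <- c("beta_matrix", class(values))
  values
}

validate_beta_matrix <- function(values) {
  if (anyNA(values))
    stop("beta matrix contains missing values; imputation is refused - ",
         "filter or impute upstream", call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated CpG identifiers in beta matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers in beta matrix", call. = FALSE)
  invisible(values)
}

#' Validate sample metadata against a beta matrix
#'
#' Metadata must carry one row per sample with columns `sample_id`,
#' `donor_id`, `cell_type`, `age`, `sex`, `cohort`. Cell types are restricted
#' to [CELL_TYPES] and sex to F/M.
#'
#' @param meta data.frame of sample metadata.
#' @param betas optional `beta_matrix`; when given, every sample column must
#'   have exactly one metadata row.
#' @return `meta`, with `cell_type` and `sex` as factors with fixed levels.
#' @export
validate_metadata <- function(meta, betas = NULL) {
  required <- c("sample_id", "donor_id", "cell_type", "age", "sex", "cohort")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_ct <- setdiff(unique(as.character(meta$cell_type)), CELL_TYPES)
  if (length(bad_ct))
    stop("unknown cell_type label(s): ", paste(bad_ct, collapse = ", "),
         "; expected ", paste(CELL_TYPES, collapse = "/"), call. = FALSE)
  bad_sex <- setdiff(unique(as.character(meta$sex)), c("F", "M"))
  if (length(bad_sex))
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  dup <- meta$sample_id[duplicated(paste(meta$cohort, meta$sample_id))]
  if (length(dup))
    stop("duplicated sample_id within a cohort: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!is.null(betas)) {
    absent <- setdiff(colnames(betas), meta$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  meta$cell_type <- factor(as.character(meta$cell_type), levels = CELL_TYPES)
  meta$sex <- factor(as.character(meta$sex), levels = c("F", "M"))
  meta
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) after clamping beta to
#' \[epsilon, 1 - epsilon\], the variance-stabilized scale used for linear
#' modelling of methylation. Monotone in beta; the clamp keeps fully
#' (un)methylated probes finite.
#'
#' @param beta numeric vector/matrix of beta values in \[0, 1\].
#' @param epsilon clamp bound in (0, 0.5); default 1e-6.
#' @return M-values with the shape of `beta`.
#' @examples
#' beta_to_m(c(0.5, 0.8, 0.2))  # 0, 2, -2
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}
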
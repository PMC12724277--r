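# single tabular dialect: TSV (UTF-8, '.' decimal); CSV accepted on read by
# sniffing the header line
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = sniff_sep(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a beta matrix from TSV
#'
#' Expects a header with `cpg_id` as first column and one column per
#' sample; values must be decimal betas in \[0, 1\] with no missing
#' entries.
#'
#' @param path TSV (or CSV) file path.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- read_table_auto(path)
  if (names(df)[1L] != "cpg_id")
    stop("beta matrix must start with a 'cpg_id' column: ", path,
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric beta values in ", path, call. = FALSE)
  rownames(m) <- df$cpg_id
  beta_matrix(m)
}

#' Write a beta matrix to TSV
#' @param betas a [beta_matrix()].
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  write_tsv(data.frame(cpg_id = rownames(betas), betas,
                       check.names = FALSE), path)
}

#' Read sample metadata from TSV
#' @param path TSV with header `sample_id donor_id cell_type age sex cohort`.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  validate_metadata(read_table_auto(path))
}

#' Read a CpG-ID list
#'
#' Accepts plain text (one ID per line) or a TSV whose first column is
#' `cpg_id` (further columns, e.g. p-values, are ignored). Duplicates are
#' removed with a message.
#'
#' @param path input file.
#' @return character vector of unique CpG IDs.
#' @export
read_cpg_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CpG list: ", path, call. = FALSE)
  first_fields <- strsplit(lines[1L], "[\t,]")[[1L]]
  if (first_fields[1L] == "cpg_id") {
    ids <- vapply(strsplit(lines[-1L], "[\t,]"), `[`, character(1L), 1L)
    if (!length(ids)) stop("CpG list has a header but no rows: ", path,
                           call. = FALSE)
  } else {
    if (length(first_fields) > 1L)
      stop("malformed CpG list (line 1 has ", length(first_fields),
           " fields but no 'cpg_id' header): ", path, call. = FALSE)
    ids <- vapply(strsplit(lines, "[\t,]"), `[`, character(1L), 1L)
  }
  ids <- trimws(ids)
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0L)
    message("read_cpg_list: removed ", n_dup, " duplicate ID(s)")
  unique(ids)
}

#' Write panels to the exchange TSV format
#'
#' One row per (CpG, cell type, specificity) assignment with header
#' `cpg_id cell_type specificity`.
#'
#' @param panels a single `cell_type_panel` or a list of them.
#' @param path output path.
#' @export
write_panel <- function(panels, path) {
  if (inherits(panels, "cell_type_panel")) panels <- list(panels)
  rows <- do.call(rbind, lapply(panels, function(p) {
    do.call(rbind, lapply(CELL_TYPES, function(ct) {
      ids <- p$assignments[[ct]]
      if (!length(ids)) return(NULL)
      data.frame(cpg_id = ids, cell_type = ct, specificity = p$specificity)
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(cpg_id = character(), cell_type = character(),
                       specificity = character())
  write_tsv(rows, path)
}

#' Read panels from the exchange TSV format
#'
#' Validates the cell-type and specificity vocabularies and the
#' high-specificity disjointness invariant.
#'
#' @param path TSV with header `cpg_id cell_type specificity`.
#' @return named list of `cell_type_panel`s, one per specificity present.
#' @export
read_panel <- function(path) {
  df <- read_table_auto(path)
  need <- c("cpg_id", "cell_type", "specificity")
  if (!all(need %in% names(df)))
    stop("panel file must have columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  bad_ct <- which(!df$cell_type %in% CELL_TYPES)
  if (length(bad_ct))
    stop("unknown cell_type '", df$cell_type[bad_ct[1L]], "' at row ",
         bad_ct[1L], call. = FALSE)
  bad_sp <- which(!df$specificity %in% SPECIFICITY_LEVELS)
  if (length(bad_sp))
    stop("unknown specificity '", df$specificity[bad_sp[1L]], "' at row ",
         bad_sp[1L], call. = FALSE)
  out <- lapply(intersect(SPECIFICITY_LEVELS, unique(df$specificity)),
                function(sp) {
    sub <- df[df$specificity == sp, ]
    cell_type_panel(sp, split(sub$cpg_id, factor(sub$cell_type, CELL_TYPES)),
                    provenance = paste("read from", basename(path)))
  })
  names(out) <- vapply(out, function(p) p$specificity, character(1L))
  out
}

#' Read a probe annotation table
#' @param path TSV with header
#'   `cpg_id probe_design island_context gene_context`.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  validate_annotation(read_table_auto(path))
}

#' Write enrichment results to TSV
#' @param result an `enrichment_result`.
#' @param path output path.
#' @param json optional path for a JSON mirror of the same rows.
#' @export
write_enrichment <- function(result, path, json = NULL) {
  cols <- c("cell_type", "specificity", "overlap_n", "set_size",
            "input_size", "background_size", "odds_ratio", "p_value",
            "fdr", "zero_overlap")
  write_tsv(as.data.frame(result)[, cols], path)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(result)[, cols], json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Packaged synthetic default backgrounds
#'
#' Paths to the two background universes shipped for testing and examples:
#' synthetic CpG-ID lists standing in for the EPIC- and 450K-style
#' backgrounds (the nested 450K universe is a subset of the EPIC one). Real
#' analyses should use the background from the user's own EWAS workflow;
#' array-manifest backgrounds are user-supplied and never bundled.
#'
#' @param array `"epic"` or `"450k"`.
#' @return file path usable with [read_cpg_list()].
#' @export
default_background <- function(array = c("epic", "450k")) {
  array <- match.arg(array)
  fname <- paste0("background_", array, "_synthetic.txt")
  path <- system.file("extdata", fname, package = "cellenrich")
  if (!nzchar(path)) stop("packaged background not found", call. = FALSE)
  path
}

#' Write a run manifest
#'
#' Records the command, resolved parameters, input-file MD5 digests, seed,
#' package version and timestamp, so a deterministic run can be reproduced
#' bit-identically.
#'
#' @param path output JSON path.
#' @param command subcommand name.
#' @param params named list of resolved parameters.
#' @param inputs character vector of input file paths (digested).
#' @param seed integer seed or NULL.
#' @export
write_run_manifest <- function(path, command, params = list(),
                               inputs = character(), seed = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command, parameters = params,
                   input_md5 = digests, seed = seed,
                   tool_version = as.character(utils::packageVersion("cellenrich")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
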
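#' Build the 2x2 contingency table for an ORA
#'
#' Counts a = input DMPs in the panel set, b = input DMPs outside it,
#' c = non-input background CpGs in the set, d = the remaining background.
#' The panel set is intersected with the background before counting, so CpGs
#' the study never measured cannot inflate the set margin.
#'
#' @param input_cpgs character vector of query CpG IDs (e.g. EWAS DMPs).
#' @param background character vector of all tested CpG IDs.
#' @param panel_set character vector of panel CpG IDs.
#' @param drop_missing if TRUE, input CpGs absent from the background are
#'   dropped with a warning instead of raising an error.
#' @return named integer vector `c(a, b, c, d)` with attribute `n_dropped`.
#' @export
build_contingency <- function(input_cpgs, background, panel_set,
                              drop_missing = FALSE) {
  input_cpgs <- unique(as.character(input_cpgs))
  background <- unique(as.character(background))
  if (!length(input_cpgs)) stop("empty input CpG list", call. = FALSE)
  if (!length(background)) stop("empty background", call. = FALSE)
  outside <- setdiff(input_cpgs, background)
  if (length(outside)) {
    if (!drop_missing)
      stop(length(outside), " input CpG(s) absent from background, e.g. ",
           paste(utils::head(outside, 5L), collapse = ", "),
           "; use drop_missing to discard them", call. = FALSE)
    warning("dropping ", length(outside),
            " input CpG(s) absent from background", call. = FALSE)
    input_cpgs <- setdiff(input_cpgs, outside)
    if (!length(input_cpgs))
      stop("no input CpGs remain after dropping those absent from background",
           call. = FALSE)
  }
  set_bg <- intersect(unique(as.character(panel_set)), background)
  a <- length(intersect(input_cpgs, set_bg))
  b <- length(input_cpgs) - a
  cc <- length(set_bg) - a
  d <- length(background) - length(input_cpgs) - cc
  structure(c(a = a, b = b, c = cc, d = d),
            n_dropped = length(outside))
}

#' Odds ratio with conditional Haldane-Anscombe correction
#'
#' For an all-positive table the plain cross-product ratio (a*d)/(b*c); when
#' any cell is zero, 0.5 is added to every cell first (Haldane-Anscombe).
#' When the overlap a is zero the *reported* odds ratio is 0 with
#' `zero_overlap` set - the display convention for sets with no input hits -
#' while the corrected value is kept in `corrected_or` for diagnostics.
#'
#' @param tab named integer vector `c(a, b, c, d)` as from
#'   [build_contingency()].
#' @return list with `odds_ratio` (reported), `corrected_or` (always the
#'   (conditionally corrected) cross-product ratio) and `zero_overlap`.
#' @export
odds_ratio_ha <- function(tab) {
  stopifnot(length(tab) == 4L, all(tab >= 0))
  a <- tab[[1L]]; b <- tab[[2L]]; cc <- tab[[3L]]; d <- tab[[4L]]
  if (all(c(a, b, cc, d) > 0)) {
    or <- (a * d) / (b * cc)
  } else {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  }
  zero <- a == 0L
  list(odds_ratio = if (zero) 0 else or,
       corrected_or = or,
       zero_overlap = zero)
}

#' Exact enrichment p-value
#'
#' One-sided (enrichment direction) hypergeometric tail probability
#' P(X >= a) with the table margins fixed - the exact test behind the ORA.
#' A two-sided Fisher p is available via `alternative = "two.sided"`.
#'
#' @param tab named integer vector `c(a, b, c, d)`.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return p-value in (0, 1].
#' @export
enrichment_p <- function(tab, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- tab[[1L]]; b <- tab[[2L]]; cc <- tab[[3L]]; d <- tab[[4L]]
  if (alternative == "two.sided") {
    m <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
    return(stats::fisher.test(m, alternative = "two.sided")$p.value)
  }
  # white balls = set CpGs (a + c), drawn = input size (a + b)
  stats::phyper(a - 1L, a + cc, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone), preserving input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a DMP list against a panel
#'
#' For each of the four cell types at the requested specificity level:
#' contingency table, Haldane-Anscombe odds ratio, exact one-sided
#' hypergeometric p, then BH-FDR across the four cell types (the family is
#' the specificity level). Inputs are treated as sets; ordering is
#' irrelevant.
#'
#' @param input_cpgs character vector of query CpG IDs.
#' @param background character vector of the tested CpG universe.
#' @param panel a `cell_type_panel` or a named list of CpG-ID vectors.
#' @param specificity optional check that `panel$specificity` matches.
#' @param alternative passed to [enrichment_p()].
#' @param drop_missing passed to [build_contingency()].
#' @return data.frame classed `enrichment_result` with one row per cell
#'   type: counts, odds ratio, p-value, FDR, zero-overlap flag.
#' @export
run_ora <- function(input_cpgs, background, panel, specificity = NULL,
                    alternative = "greater", drop_missing = FALSE) {
  if (inherits(panel, "cell_type_panel")) {
    if (!is.null(specificity) && !identical(panel$specificity, specificity))
      stop("panel specificity is '", panel$specificity,
           "', requested '", specificity, "'", call. = FALSE)
    specificity <- panel$specificity
    sets <- panel$assignments
  } else {
    sets <- panel
    if (is.null(specificity)) specificity <- NA_character_
  }
  stopifnot(all(CELL_TYPES %in% names(sets)))
  input_cpgs <- unique(as.character(input_cpgs))
  background <- unique(as.character(background))
  rows <- lapply(CELL_TYPES, function(ct) {
    tab <- build_contingency(input_cpgs, background, sets[[ct]],
                             drop_missing = drop_missing)
    or <- odds_ratio_ha(tab)
    data.frame(cell_type = ct, specificity = specificity,
               overlap_n = tab[["a"]],
               set_size = tab[["a"]] + tab[["c"]],
               input_size = tab[["a"]] + tab[["b"]],
               background_size = sum(tab),
               odds_ratio = or$odds_ratio,
               corrected_or = or$corrected_or,
               p_value = enrichment_p(tab, alternative),
               zero_overlap = or$zero_overlap,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[, c("cell_type", "specificity", "overlap_n", "set_size",
                 "input_size", "background_size", "odds_ratio",
                 "corrected_or", "p_value", "fdr", "zero_overlap")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, fdr_threshold = 0.05, ...) {
  cat("Cell-type over-representation analysis",
      if (!all(is.na(x$specificity)))
        paste0("(", x$specificity[1L], " specificity)"), "\n")
  cat(sprintf("  input %d CpGs against background of %d\n",
              x$input_size[1L], x$background_size[1L]))
  y <- data.frame(cell_type = x$cell_type, overlap = x$overlap_n,
                  set_size = x$set_size,
                  OR = signif(x$odds_ratio, 3L),
                  p = signif(x$p_value, 3L),
                  FDR = signif(x$fdr, 3L),
                  sig = ifelse(x$fdr < fdr_threshold, "*", ""))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Overlap decomposition across cell-type sets
#'
#' Medium- and low-specificity panels annotate CpGs to several cell types;
#' this tabulates, for the input CpGs hitting at least one set, how many
#' fall in each cell-type combination (shared vs unique membership).
#'
#' @inheritParams run_ora
#' @return data.frame with columns `combination` (e.g. `"MG+AST"`) and `n`.
#' @export
overlap_decomposition <- function(input_cpgs, panel) {
  sets <- if (inherits(panel, "cell_type_panel")) panel$assignments else panel
  input_cpgs <- unique(as.character(input_cpgs))
  member <- vapply(CELL_TYPES, function(ct) input_cpgs %in% sets[[ct]],
                   logical(length(input_cpgs)))
  if (length(input_cpgs) == 1L) member <- matrix(member, nrow = 1L)
  hit <- rowSums(member) > 0L
  if (!any(hit))
    return(data.frame(combination = character(), n = integer()))
  combos <- apply(member[hit, , drop = FALSE], 1L, function(z)
    paste(CELL_TYPES[z], collapse = "+"))
  tab <- table(combos)
  data.frame(combination = names(tab), n = as.integer(tab),
             row.names = NULL)
}
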
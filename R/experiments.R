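# median/IQR summaries of odds_ratio, p_value, fdr over iterations,
# grouped by the given columns (NA group values kept as "none")
summarize_groups <- function(df, by, extra = NULL) {
  keys <- lapply(df[by], function(x) {
    x <- as.character(x); x[is.na(x)] <- "none"; x
  })
  key <- do.call(paste, c(keys, sep = "\r"))
  groups <- split(df, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- g[1L, by, drop = FALSE]
    stats_row <- data.frame(
      median_or = stats::median(g$odds_ratio),
      iqr_or = stats::IQR(g$odds_ratio),
      median_p = stats::median(g$p_value),
      median_fdr = stats::median(g$fdr))
    if (!is.null(extra))
      stats_row <- cbind(stats_row, as.data.frame(as.list(extra(g))))
    cbind(row, stats_row)
  }))
  rownames(out) <- NULL
  out
}

# ORA that tolerates an empty DMP list: an empty input is a valid
# no-enrichment outcome (OR 0, p 1) rather than an error
ora_safe <- function(input_cpgs, background, sets) {
  if (!length(input_cpgs)) {
    out <- data.frame(cell_type = CELL_TYPES, specificity = NA_character_,
                      overlap_n = 0L,
                      set_size = vapply(sets[CELL_TYPES], function(s)
                        length(intersect(s, background)), integer(1L)),
                      input_size = 0L,
                      background_size = length(unique(background)),
                      odds_ratio = 0, corrected_or = NA_real_,
                      p_value = 1, fdr = 1, zero_overlap = TRUE,
                      row.names = NULL)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  run_ora(input_cpgs, background, sets)
}

#' Composition-shift confounding experiment
#'
#' The first validation scenario: disease and control pseudo-bulk samples
#' differ only in cell composition (equal Dirichlet weights for controls, a
#' relative neuron reduction for cases). Per iteration, DMPs are called
#' uncorrected and corrected with increasingly noisy composition estimates,
#' and each DMP list is tested for enrichment against the simulated
#' cell-type sets. Without correction, composition shift alone produces
#' spurious cell-type enrichment; accurate correction removes it, and noisy
#' correction gradually restores it.
#'
#' @param config a [simulation_config()]; `config$seed` seeds the whole
#'   experiment.
#' @return list classed `composition_shift_result`: `per_iteration` (one
#'   row per iteration x analysis x noise level x cell type) and `summary`
#'   (medians and IQRs over iterations, plus mean RMSE per noise level).
#' @export
run_composition_shift_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rows <- list()
  for (it in seq_len(config$n_iterations)) {
    ds <- simulate_pseudobulk(config)
    bg <- ds$specs$cpg_id
    unc <- call_dmps(ds$bulk, ds$group, weights = NULL,
                     fdr_threshold = config$fdr_threshold)
    res_u <- ora_safe(unc$dmps, bg, ds$sets)
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = it, analysis = "uncorrected", noise_sd = NA_real_,
      mean_rmse = NA_real_, n_dmps = length(unc$dmps),
      cell_type = res_u$cell_type, odds_ratio = res_u$odds_ratio,
      p_value = res_u$p_value, fdr = res_u$fdr)
    for (sd in config$noise_sds) {
      pw <- perturb_weights(ds$weights, sd, mode = config$noise_mode)
      cor <- call_dmps(ds$bulk, ds$group, weights = pw$weights,
                       fdr_threshold = config$fdr_threshold)
      res_c <- ora_safe(cor$dmps, bg, ds$sets)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, analysis = "corrected", noise_sd = sd,
        mean_rmse = pw$mean_rmse, n_dmps = length(cor$dmps),
        cell_type = res_c$cell_type, odds_ratio = res_c$odds_ratio,
        p_value = res_c$p_value, fdr = res_c$fdr)
    }
  }
  per_iter <- do.call(rbind, rows)
  summary <- summarize_groups(per_iter,
                              c("analysis", "noise_sd", "cell_type"),
                              extra = function(g)
                                c(mean_rmse = mean(g$mean_rmse)))
  structure(list(per_iteration = per_iter, summary = summary,
                 config = config),
            class = "composition_shift_result")
}

#' @export
print.composition_shift_result <- function(x, ...) {
  cat("Composition-shift experiment:",
      x$config$n_iterations, "iterations,",
      x$config$n_cpgs, "CpGs,",
      2L * x$config$n_per_group, "samples\n")
  print(x$summary, row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Input-size sweep experiment
#'
#' The second validation scenario: both groups share equal Dirichlet
#' weights (no composition confounding) and a varying number of DMPs is
#' injected per the 50/20/0.1/0.1/29.8% allocation over the neuron,
#' microglia, oligodendrocyte and astrocyte sets and background. DMPs are
#' called with composition correction using the true weights, and each
#' called list is tested by ORA against the simulated sets. One base
#' dataset is generated per iteration and re-injected at each DMP count.
#'
#' @param config a [simulation_config()]; the grid is `config$dmp_counts`.
#' @return list classed `input_size_result` with `per_iteration` and
#'   `summary` (median OR/p/FDR and IQR per DMP count and cell type).
#' @export
run_input_size_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rows <- list()
  for (it in seq_len(config$n_iterations)) {
    base <- simulate_pseudobulk(config,
                                alpha_control = config$alpha_control,
                                alpha_disease = config$alpha_control)
    bg <- base$specs$cpg_id
    for (n_dmps in config$dmp_counts) {
      ds <- inject_dmps(base, n_dmps, config$dmp_allocation,
                        config$effect_delta)
      called <- call_dmps(ds$bulk, ds$group, weights = ds$weights,
                          fdr_threshold = config$fdr_threshold)
      res <- ora_safe(called$dmps, bg, ds$sets)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, n_dmps = n_dmps, n_called = length(called$dmps),
        cell_type = res$cell_type, odds_ratio = res$odds_ratio,
        p_value = res$p_value, fdr = res$fdr)
    }
  }
  per_iter <- do.call(rbind, rows)
  summary <- summarize_groups(per_iter, c("n_dmps", "cell_type"))
  summary <- summary[order(summary$n_dmps,
                           match(summary$cell_type, CELL_TYPES)), ]
  rownames(summary) <- NULL
  structure(list(per_iteration = per_iter, summary = summary,
                 config = config),
            class = "input_size_result")
}

#' @export
print.input_size_result <- function(x, ...) {
  cat("Input-size experiment:", x$config$n_iterations, "iterations, grid",
      paste(range(x$config$dmp_counts), collapse = "-"), "DMPs\n")
  print(x$summary, row.names = FALSE, digits = 3L)
  invisible(x)
}
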
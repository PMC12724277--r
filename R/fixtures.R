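#' Plant a ground-truth CpG layout for synthetic purified cohorts
#'
#' Defines, per CpG, the generating means and SD that should trigger (or
#' avoid) each panel classification rule:
#' \itemize{
#'   \item `high-<ct>`: intermediate mean (0.2-0.8) in the target cell type,
#'     extreme means (<= 0.05 or >= 0.95) in the others - clear of the
#'     0.1/0.9 thresholds by at least 0.05 so recovery tests are not
#'     knife-edge.
#'   \item `medium-<ct1>+<ct2>`: intermediate (0.3-0.7) in two cell types,
#'     extreme in the rest (multi-annotation).
#'   \item `low-<ct>`: intermediate in all four cell types (so neither high
#'     nor medium applies) with the target mean separated by 0.25, reachable
#'     only through the mixed-model contrast route.
#'   \item `background`: one common intermediate mean for all four cell
#'     types with jitter below 0.02 (no extreme type, no separation).
#'   \item `all-hypo` / `all-hyper`: means below 0.05 / above 0.95 in all
#'     four cell types; must appear in no panel.
#' }
#'
#' @param n_high_per_type,n_medium,n_low_per_type,n_background,n_extreme
#'   CpG counts per category (`n_extreme` is split between all-hypo and
#'   all-hyper).
#' @param sd within-cell-type beta SD (default 0.03).
#' @param seed optional integer seed.
#' @return data.frame with `cpg_id`, `category`, `target` (comma-separated
#'   intended cell types, `""` for none), `mu_<ct>` columns and `sd`.
#' @export
plant_truth <- function(n_high_per_type = 25L, n_medium = 40L,
                        n_low_per_type = 10L, n_background = 200L,
                        n_extreme = 40L, sd = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  extreme_mu <- function(n) {
    hyper <- stats::runif(n) < 0.5
    ifelse(hyper, stats::runif(n, 0.95, 0.99), stats::runif(n, 0.01, 0.05))
  }
  add <- function(category, target, mu) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, target = target,
      mu_NEU = mu[, 1L], mu_MG = mu[, 2L],
      mu_OLIG = mu[, 3L], mu_AST = mu[, 4L])
  }
  for (k in seq_along(CELL_TYPES)) {
    n <- n_high_per_type
    mu <- matrix(extreme_mu(4L * n), n, 4L)
    mu[, k] <- stats::runif(n, 0.2, 0.8)
    add(paste0("high-", CELL_TYPES[k]), CELL_TYPES[k], mu)
  }
  if (n_medium > 0L) {
    pair_idx <- utils::combn(4L, 2L)
    for (i in seq_len(n_medium)) {
      pick <- pair_idx[, sample.int(ncol(pair_idx), 1L)]
      mu <- matrix(extreme_mu(4L), 1L, 4L)
      mu[, pick] <- stats::runif(2L, 0.3, 0.7)
      add(paste0("medium-", paste(CELL_TYPES[pick], collapse = "+")),
          paste(CELL_TYPES[pick], collapse = ","), mu)
    }
  }
  for (k in seq_along(CELL_TYPES)) {
    n <- n_low_per_type
    if (n == 0L) next
    mu <- matrix(stats::runif(4L * n, 0.35, 0.45), n, 4L)
    mu[, k] <- mu[, k] + 0.25
    add(paste0("low-", CELL_TYPES[k]), CELL_TYPES[k], mu)
  }
  if (n_background > 0L) {
    centre <- stats::runif(n_background, 0.15, 0.85)
    mu <- centre + matrix(stats::runif(4L * n_background, -0.02, 0.02),
                          n_background, 4L)
    mu <- pmin(pmax(mu, 0.12), 0.88)
    add("background", "", mu)
  }
  n_hypo <- n_extreme %/% 2L
  n_hyper <- n_extreme - n_hypo
  if (n_hypo > 0L)
    add("all-hypo", "", matrix(stats::runif(4L * n_hypo, 0.02, 0.05),
                               n_hypo, 4L))
  if (n_hyper > 0L)
    add("all-hyper", "", matrix(stats::runif(4L * n_hyper, 0.95, 0.98),
                                n_hyper, 4L))
  out <- do.call(rbind, rows)
  out <- cbind(cpg_id = sprintf("cg%06d", seq_len(nrow(out))), out)
  out$sd <- sd
  rownames(out) <- NULL
  out
}

#' Synthesize two purified-cell cohorts from a planted truth
#'
#' Emulates the sorted-nuclei study design: per cohort, each donor
#' contributes one sample of each of the four cell types; ages are normal
#' (mean 82, SD 9), sexes balanced. Betas are truncated-normal draws around
#' the planted cell-type mean plus a per-(donor, CpG) random intercept.
#'
#' @param truth a [plant_truth()] table.
#' @param n_donors donors per cohort (>= 4).
#' @param donor_sd SD of the donor random effect on the beta scale.
#' @param seed optional integer seed.
#' @param cohorts names of the two cohorts.
#' @return named list of two cohorts, each `list(betas =` a [beta_matrix()]
#'   `, meta =` metadata data.frame`)`.
#' @export
synth_purified_cohorts <- function(truth, n_donors = 20L, donor_sd = 0.02,
                                   seed = NULL, cohorts = c("A", "B")) {
  stopifnot(n_donors >= 4L, length(cohorts) == 2L)
  if (!is.null(seed)) set.seed(seed)
  n_cpgs <- nrow(truth)
  mu <- as.matrix(truth[, paste0("mu_", CELL_TYPES)])
  out <- lapply(cohorts, function(coh) {
    donor_ids <- sprintf("%s_d%02d", coh, seq_len(n_donors))
    meta <- expand.grid(cell_type = CELL_TYPES, donor_id = donor_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$sample_id <- paste(meta$donor_id, meta$cell_type, sep = "_")
    ages <- stats::rnorm(n_donors, 82, 9)
    sexes <- rep_len(c("F", "M"), n_donors)
    meta$age <- ages[match(meta$donor_id, donor_ids)]
    meta$sex <- sexes[match(meta$donor_id, donor_ids)]
    meta$cohort <- coh
    donor_eff <- matrix(stats::rnorm(n_cpgs * n_donors, 0, donor_sd),
                        n_cpgs, n_donors, dimnames = list(NULL, donor_ids))
    betas <- matrix(NA_real_, n_cpgs, nrow(meta),
                    dimnames = list(truth$cpg_id, meta$sample_id))
    for (s in seq_len(nrow(meta))) {
      ct_col <- match(meta$cell_type[s], CELL_TYPES)
      m <- mu[, ct_col] + donor_eff[, meta$donor_id[s]]
      m <- pmin(pmax(m, 0.001), 0.999)
      betas[, s] <- rtruncnorm01(m, truth$sd)
    }
    list(betas = beta_matrix(betas),
         meta = meta[, c("sample_id", "donor_id", "cell_type", "age",
                         "sex", "cohort")])
  })
  names(out) <- cohorts
  out
}

#' Synthesize a probe annotation table
#'
#' Draws probe design, island context and gene context labels independently
#' from configurable marginal frequencies, mimicking the covariates used for
#' matched permutation nulls.
#'
#' @param cpg_ids CpG identifiers to annotate.
#' @param freqs named list of named frequency vectors per factor (each sums
#'   to 1).
#' @param seed optional integer seed.
#' @return data.frame with columns `cpg_id`, `probe_design`,
#'   `island_context`, `gene_context`.
#' @export
synth_probe_annotation <- function(cpg_ids,
                                   freqs = list(
                                     probe_design = c(I = 0.2, II = 0.8),
                                     island_context = c(Island = 0.3,
                                                        Shore = 0.25,
                                                        Shelf = 0.15,
                                                        OpenSea = 0.3),
                                     gene_context = c(TSS = 0.3, Body = 0.4,
                                                      Intergenic = 0.3)),
                                   seed = NULL) {
  cpg_ids <- as.character(cpg_ids)
  if (!length(cpg_ids)) stop("empty CpG ID list", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(cpg_ids)
  draw <- function(f) sample(names(f), n, replace = TRUE, prob = f)
  ann <- data.frame(cpg_id = cpg_ids,
                    probe_design = draw(freqs$probe_design),
                    island_context = draw(freqs$island_context),
                    gene_context = draw(freqs$gene_context))
  validate_annotation(ann)
}
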
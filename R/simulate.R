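#' Simulation configuration
#'
#' Bundles every tunable of the pseudo-bulk simulation framework with the
#' study defaults: 200,000 CpGs per sample, 250 samples per group, set
#' fractions mirroring the relative sizes of the high-specificity panels
#' (about 6% of CpGs in total), equal Dirichlet mixing weights for controls
#' and (1,2,2,2) for the disease group (a relative neuron reduction), a
#' weight-noise grid spanning 0 to 1.5, 10 iterations, an injected-DMP grid
#' of powers of two from 2 to 1024 with the 50/20/0.1/0.1/29.8% allocation,
#' and BH-FDR 0.05 for DMP calling.
#'
#' @param n_cpgs CpGs per simulated sample.
#' @param n_per_group samples per group (control and disease).
#' @param set_fractions named fractions of CpGs assigned to each cell-type
#'   set; must sum to < 1, the rest is background.
#' @param alpha_control,alpha_disease Dirichlet parameters for the mixing
#'   weights of each group.
#' @param noise_sds grid of Gaussian noise SDs applied to the weights used
#'   for correction.
#' @param noise_mode `"scaled"` (noise proportional to the weight,
#'   the default calibration) or `"additive"`.
#' @param n_iterations simulation repetitions.
#' @param dmp_counts injected-DMP grid for the input-size experiment.
#' @param dmp_allocation fractions of injected DMPs per cell-type set and
#'   background; must sum to 1.
#' @param effect_delta bulk beta shift applied to designated DMPs in the
#'   disease group.
#' @param fdr_threshold BH-adjusted cutoff for DMP calling.
#' @param seed integer seed.
#' @return classed list `simulation_config`.
#' @export
simulation_config <- function(n_cpgs = 200000L,
                              n_per_group = 250L,
                              set_fractions = c(NEU = 0.025, MG = 0.025,
                                                OLIG = 0.006, AST = 0.006),
                              alpha_control = c(1, 1, 1, 1),
                              alpha_disease = c(1, 2, 2, 2),
                              noise_sds = c(0, 0.3, 0.6, 0.9, 1.2, 1.5),
                              noise_mode = c("scaled", "additive"),
                              n_iterations = 10L,
                              dmp_counts = 2L^(1:10),
                              dmp_allocation = c(NEU = 0.5, MG = 0.2,
                                                 OLIG = 0.001, AST = 0.001,
                                                 background = 0.298),
                              effect_delta = 0.2,
                              fdr_threshold = 0.05,
                              seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(all(set_fractions >= 0), sum(set_fractions) < 1,
            all(CELL_TYPES %in% names(set_fractions)),
            length(alpha_control) == 4L, all(alpha_control > 0),
            length(alpha_disease) == 4L, all(alpha_disease > 0),
            all(noise_sds >= 0), n_iterations >= 1L,
            abs(sum(dmp_allocation) - 1) < 1e-9,
            all(c(CELL_TYPES, "background") %in% names(dmp_allocation)),
            effect_delta >= 0, fdr_threshold > 0, fdr_threshold < 1)
  structure(list(n_cpgs = as.integer(n_cpgs),
                 n_per_group = as.integer(n_per_group),
                 set_fractions = set_fractions[CELL_TYPES],
                 alpha_control = alpha_control,
                 alpha_disease = alpha_disease,
                 noise_sds = noise_sds, noise_mode = noise_mode,
                 n_iterations = as.integer(n_iterations),
                 dmp_counts = as.integer(dmp_counts),
                 dmp_allocation = dmp_allocation[c(CELL_TYPES, "background")],
                 effect_delta = effect_delta,
                 fdr_threshold = fdr_threshold,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Truncated-normal draws on \[0, 1\]
#'
#' Inverse-CDF sampling of normal(mu, sd) truncated to the unit interval,
#' vectorized over `mu` and `sd`; sd = 0 returns mu exactly.
#'
#' @param mu,sd mean and SD vectors (recycled against each other).
#' @return draws, length `max(length(mu), length(sd))`.
#' @export
rtruncnorm01 <- function(mu, sd) {
  n <- max(length(mu), length(sd))
  mu <- rep_len(mu, n); sd <- rep_len(sd, n)
  out <- mu
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(0, mu[pos], sd[pos])
    phi <- stats::pnorm(1, mu[pos], sd[pos])
    u <- stats::runif(sum(pos), plo, phi)
    out[pos] <- stats::qnorm(u, mu[pos], sd[pos])
  }
  pmin(pmax(out, 0), 1)
}

#' Heteroskedastic effective SD
#'
#' SD* = SD x (1 - |0.5 - mu| / 0.5): the per-CpG noise shrinks linearly as
#' the mean approaches 0 or 1, mimicking the mean-variance relationship of
#' beta values.
#'
#' @param sd base SD; `mu` mean beta.
#' @param mu mean beta value.
#' @return effective SD, elementwise.
#' @export
sd_star <- function(sd, mu) sd * (1 - abs(0.5 - mu) / 0.5)

#' Draw per-CpG simulation specifications
#'
#' Assigns `round(fraction x n_cpgs)` CpGs to each cell-type set and the
#' rest to background, then draws per-cell-type means: a set CpG gets an
#' intermediate mean (uniform 0.15-0.85) in its target cell type and an
#' extreme mean in every other (uniform on 0.01-0.09 or 0.91-0.99, side by
#' fair coin per cell type); background CpGs are intermediate in all four.
#' Base SDs are uniform on (0, 0.1); the effective SD* follows [sd_star()].
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return data.frame with `cpg_id`, `category`, `mu_<ct>` columns and `sd`.
#' @export
simulate_cpg_specs <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_cpgs
  counts <- round(config$set_fractions * n)
  n_bg <- n - sum(counts)
  if (n_bg < 0) stop("set fractions exceed the CpG budget", call. = FALSE)
  category <- rep(c(paste0(CELL_TYPES, "-set"), "background"),
                  times = c(counts, n_bg))
  mu <- matrix(stats::runif(n * 4L, 0.15, 0.85), n, 4L,
               dimnames = list(NULL, CELL_TYPES))
  for (k in seq_along(CELL_TYPES)) {
    rows <- which(category == paste0(CELL_TYPES[k], "-set"))
    if (!length(rows)) next
    for (j in seq_along(CELL_TYPES)) {
      if (j == k) next
      hyper <- stats::runif(length(rows)) < 0.5
      lo <- stats::runif(length(rows), 0.01, 0.09)
      hi <- stats::runif(length(rows), 0.91, 0.99)
      mu[rows, j] <- ifelse(hyper, hi, lo)
    }
  }
  out <- data.frame(cpg_id = sprintf("cpg%07d", seq_len(n)),
                    category = category, sd = stats::runif(n, 0, 0.1))
  for (ct in CELL_TYPES) out[[paste0("mu_", ct)]] <- mu[, ct]
  out
}

spec_sets <- function(specs) {
  out <- lapply(CELL_TYPES, function(ct)
    specs$cpg_id[specs$category == paste0(ct, "-set")])
  names(out) <- CELL_TYPES
  out
}

#' Sample purified cell-type profiles from CpG specifications
#'
#' One truncated-normal draw per (CpG, sample, cell type), with mean
#' `mu_<ct>` and SD [sd_star()]`(sd, mu_<ct>)`.
#'
#' @param specs output of [simulate_cpg_specs()].
#' @param n_samples samples to draw.
#' @param seed optional integer seed.
#' @return named list of four matrices (CpGs x samples), one per cell type.
#' @export
sample_cell_profiles <- function(specs, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(specs)
  out <- lapply(CELL_TYPES, function(ct) {
    mu <- specs[[paste0("mu_", ct)]]
    ss <- sd_star(specs$sd, mu)
    m <- matrix(rtruncnorm01(rep(mu, n_samples), rep(ss, n_samples)),
                n, n_samples)
    rownames(m) <- specs$cpg_id
    m
  })
  names(out) <- CELL_TYPES
  out
}

#' Dirichlet mixing weights
#'
#' Rows are Dirichlet(alpha) draws (normalized gamma variates); each row of
#' cell-type proportions sums to one.
#'
#' @param n_samples number of rows.
#' @param alpha positive 4-vector of Dirichlet parameters.
#' @param seed optional integer seed.
#' @return matrix n_samples x 4, columns named by cell type.
#' @export
draw_weights <- function(n_samples, alpha, seed = NULL) {
  stopifnot(length(alpha) == 4L, all(alpha > 0))
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(n_samples * 4L, shape = rep(alpha, each = n_samples)),
              n_samples, 4L, dimnames = list(NULL, CELL_TYPES))
  g / rowSums(g)
}

#' Mix cell profiles into pseudo-bulk
#'
#' bulk(s, cpg) = sum over cell types of w_c(s) x beta_c(s, cpg): a convex
#' combination, so bulk values stay within the per-entry range of the cell
#' profiles.
#'
#' @param cell_profiles named list of four CpG x sample matrices.
#' @param weights sample x cell-type weight matrix (rows sum to 1).
#' @return pseudo-bulk matrix, CpGs x samples.
#' @export
mix_pseudobulk <- function(cell_profiles, weights) {
  stopifnot(all(CELL_TYPES %in% names(cell_profiles)),
            ncol(weights) == 4L)
  dims <- dim(cell_profiles[[1L]])
  if (nrow(weights) != dims[2L])
    stop("weight rows must match profile samples", call. = FALSE)
  bulk <- matrix(0, dims[1L], dims[2L])
  for (k in seq_along(CELL_TYPES)) {
    p <- cell_profiles[[CELL_TYPES[k]]]
    if (!identical(dim(p), dims))
      stop("cell profiles have mismatched dimensions", call. = FALSE)
    bulk <- bulk + sweep(p, 2L, weights[, k], "*")
  }
  rownames(bulk) <- rownames(cell_profiles[[1L]])
  colnames(bulk) <- colnames(cell_profiles[[1L]])
  bulk
}

#' Perturb mixing weights with Gaussian noise
#'
#' Emulates imperfect cell-composition estimates: each weight entry is
#' perturbed by Gaussian noise, floored at zero, and rows are renormalized
#' to the simplex (an all-zero row becomes uniform 0.25s). In the default
#' `"scaled"` mode the noise is proportional to the weight,
#' w' = w(1 + e) with e ~ N(0, sd); `"additive"` adds e directly. The
#' scaled mode is the calibration under which noise SD 0.6 yields a mean
#' RMSE of about 0.12 against the true proportions.
#'
#' @param weights true weight matrix (rows on the simplex).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed optional integer seed.
#' @param mode `"scaled"` or `"additive"`.
#' @return list: `weights` (perturbed), `rmse` (per sample), `mean_rmse`.
#' @export
perturb_weights <- function(weights, noise_sd, seed = NULL,
                            mode = c("scaled", "additive")) {
  mode <- match.arg(mode)
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  e <- matrix(stats::rnorm(length(weights), 0, noise_sd),
              nrow(weights), ncol(weights))
  p <- if (mode == "scaled") weights * (1 + e) else weights + e
  p[p < 0] <- 0
  rs <- rowSums(p)
  zero <- rs == 0
  if (any(zero)) { p[zero, ] <- 0.25; rs[zero] <- 1 }
  p <- p / rs
  colnames(p) <- colnames(weights)
  rmse <- sqrt(rowMeans((weights - p)^2))
  list(weights = p, rmse = rmse, mean_rmse = mean(rmse))
}

#' Per-CpG differential methylation calling on pseudo-bulk
#'
#' Ordinary least squares of bulk beta on the disease indicator, optionally
#' adjusted for cell composition by including three of the four mixing
#' weights as covariates (the fourth is collinear on the simplex). The
#' group-coefficient p-values are BH-adjusted; DMPs are CpGs below
#' `fdr_threshold`. All CpGs share one design matrix, so the fit is a
#' single vectorized least-squares solve equivalent to per-CpG `lm()`.
#'
#' @param bulk pseudo-bulk matrix, CpGs x samples.
#' @param group per-sample labels, `"control"` / `"disease"`.
#' @param weights optional sample x 4 composition matrix used for
#'   correction.
#' @param fdr_threshold BH cutoff for the DMP call.
#' @return list: `dmps` (character CpG IDs) and `table` (per-CpG estimate,
#'   p_value, fdr).
#' @export
call_dmps <- function(bulk, group, weights = NULL, fdr_threshold = 0.05) {
  group <- as.character(group)
  stopifnot(all(group %in% c("control", "disease")),
            length(group) == ncol(bulk))
  if (min(table(factor(group, c("control", "disease")))) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  g <- as.numeric(group == "disease")
  X <- cbind(intercept = 1, group = g)
  if (!is.null(weights)) {
    stopifnot(nrow(weights) == ncol(bulk), ncol(weights) == 4L)
    X <- cbind(X, weights[, 1:3, drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank-deficient", call. = FALSE)
  Y <- t(bulk)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv_gg <- chol2inv(qr.R(qrX))[2L, 2L]
  se <- sqrt(sigma2 * xtx_inv_gg)
  est <- coefs["group", ]
  p <- 2 * stats::pt(-abs(est / se), df)
  # numerically constant CpG: no information, not significance
  flat <- se < 1e-10
  p[flat] <- ifelse(abs(est[flat]) < 1e-8, 1, 0)
  fdr <- bh_fdr(p)
  tab <- data.frame(cpg_id = rownames(bulk), estimate = est,
                    p_value = p, fdr = fdr, row.names = NULL)
  list(dmps = tab$cpg_id[tab$fdr < fdr_threshold], table = tab)
}

largest_remainder <- function(n, fracs) {
  exact <- n * fracs
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

#' Generate a pseudo-bulk dataset
#'
#' Draws CpG specifications once, then per-group mixing weights and one set
#' of purified profiles per sample, and mixes them into bulk betas. The
#' methylation-generating distributions are identical in both groups; only
#' the Dirichlet parameters differ, so any group difference is purely
#' compositional.
#'
#' @param config a [simulation_config()].
#' @param alpha_control,alpha_disease override the config Dirichlet
#'   parameters (e.g. equal alphas in both groups for the input-size
#'   experiment).
#' @param seed optional integer seed.
#' @return list classed `pseudo_bulk_dataset`: `bulk`, `group`, `weights`,
#'   `specs`, `sets`, `designated_dmps` (empty until [inject_dmps()]).
#' @export
simulate_pseudobulk <- function(config,
                                alpha_control = config$alpha_control,
                                alpha_disease = config$alpha_disease,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- simulate_cpg_specs(config)
  n <- config$n_per_group
  group <- rep(c("control", "disease"), each = n)
  weights <- rbind(draw_weights(n, alpha_control),
                   draw_weights(n, alpha_disease))
  n_tot <- 2L * n
  bulk <- matrix(0, config$n_cpgs, n_tot)
  # one cell type at a time to bound memory at one profile matrix
  for (k in seq_along(CELL_TYPES)) {
    ct <- CELL_TYPES[k]
    mu <- specs[[paste0("mu_", ct)]]
    ss <- sd_star(specs$sd, mu)
    prof <- matrix(rtruncnorm01(rep(mu, n_tot), rep(ss, n_tot)),
                   config$n_cpgs, n_tot)
    bulk <- bulk + sweep(prof, 2L, weights[, k], "*")
  }
  rownames(bulk) <- specs$cpg_id
  colnames(bulk) <- sprintf("s%04d", seq_len(n_tot))
  structure(list(bulk = bulk, group = group, weights = weights,
                 specs = specs, sets = spec_sets(specs),
                 designated_dmps = character()),
            class = "pseudo_bulk_dataset")
}

#' Inject designated DMPs into a pseudo-bulk dataset
#'
#' Distributes `n_dmps` over the cell-type sets and background by the
#' allocation fractions (largest-remainder rounding so counts conserve
#' exactly), draws the designated CpGs without replacement within each
#' category, and shifts their disease-group bulk values by `effect_delta`
#' (clamped to \[0, 1\]). The designated list is recorded as ground truth.
#'
#' @param dataset a `pseudo_bulk_dataset`.
#' @param n_dmps total DMPs to inject.
#' @param allocation named fractions over the four sets and `background`.
#' @param effect_delta bulk beta shift in the disease group.
#' @param seed optional integer seed.
#' @return the dataset with shifted bulk and `designated_dmps` filled in.
#' @export
inject_dmps <- function(dataset, n_dmps,
                        allocation = c(NEU = 0.5, MG = 0.2, OLIG = 0.001,
                                       AST = 0.001, background = 0.298),
                        effect_delta = 0.2, seed = NULL) {
  stopifnot(inherits(dataset, "pseudo_bulk_dataset"), n_dmps >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- largest_remainder(n_dmps, allocation[c(CELL_TYPES, "background")])
  pools <- c(dataset$sets,
             list(background = dataset$specs$cpg_id[
               dataset$specs$category == "background"]))
  designated <- character()
  for (nm in names(counts)) {
    if (counts[[nm]] == 0L) next
    pool <- pools[[nm]]
    if (length(pool) < counts[[nm]])
      stop("category ", nm, " has only ", length(pool),
           " CpGs but needs ", counts[[nm]], call. = FALSE)
    designated <- c(designated, sample(pool, counts[[nm]]))
  }
  if (length(designated)) {
    dis <- dataset$group == "disease"
    dataset$bulk[designated, dis] <-
      pmin(pmax(dataset$bulk[designated, dis] + effect_delta, 0), 1)
  }
  dataset$designated_dmps <- designated
  dataset
}
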
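#' Construct a cell-type panel object
#'
#' A panel maps each of the four cell types to a set of CpG identifiers at
#' one specificity level. High-specificity assignments must be exclusive
#' (pairwise disjoint across cell types).
#'
#' @param specificity one of `"high"`, `"medium"`, `"low"`.
#' @param assignments named list (one entry per cell type) of character
#'   vectors of CpG IDs.
#' @param provenance free-form character record (e.g. cohort intersection).
#' @return a `cell_type_panel`.
#' @export
cell_type_panel <- function(specificity, assignments, provenance = character()) {
  specificity <- match.arg(specificity, SPECIFICITY_LEVELS)
  assignments <- lapply(CELL_TYPES, function(ct) {
    ids <- assignments[[ct]]
    if (is.null(ids)) character() else unique(as.character(ids))
  })
  names(assignments) <- CELL_TYPES
  if (specificity == "high") {
    for (i in seq_len(3)) for (j in seq(i + 1, 4)) {
      shared <- intersect(assignments[[i]], assignments[[j]])
      if (length(shared))
        stop("high-specificity sets must be disjoint; ",
             CELL_TYPES[i], "/", CELL_TYPES[j], " share ",
             length(shared), " CpG(s)", call. = FALSE)
    }
  }
  structure(list(specificity = specificity, assignments = assignments,
                 provenance = provenance),
            class = "cell_type_panel")
}

#' @export
print.cell_type_panel <- function(x, ...) {
  cat("Cell-type CpG panel (", x$specificity, " specificity)\n", sep = "")
  for (ct in CELL_TYPES)
    cat(sprintf("  %-5s %d CpGs\n", ct, length(x$assignments[[ct]])))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Per-cell-type median methylation profile
#'
#' For each CpG, the median beta over the samples of each cell type within
#' one cohort. Medians are the classification statistic for the
#' high/medium-specificity criteria.
#'
#' @param betas `beta_matrix` (CpGs x samples).
#' @param meta sample metadata (see [validate_metadata()]).
#' @return numeric matrix, CpGs x the four cell types.
#' @export
compute_median_profile <- function(betas, meta) {
  validate_beta_matrix(betas)
  meta <- validate_metadata(meta, betas)
  meta <- meta[match(colnames(betas), meta$sample_id), ]
  counts <- table(meta$cell_type)
  if (any(counts < 2))
    stop("need >= 2 samples per cell type; short: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  prof <- vapply(CELL_TYPES, function(ct) {
    cols <- which(meta$cell_type == ct)
    apply(betas[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(betas)))
  matrix(prof, nrow(betas), length(CELL_TYPES),
         dimnames = list(rownames(betas), CELL_TYPES))
}

# strict open interval (0.1, 0.9); medians at exactly 0.1/0.9 are neither
# intermediate nor counted against the extremity condition
is_intermediate <- function(x, lo = 0.1, hi = 0.9) x > lo & x < hi

classify_high_one <- function(profile, min_gap = 0.1) {
  inter <- is_intermediate(profile)
  n_inter <- rowSums(inter)
  out <- lapply(seq_along(CELL_TYPES), function(k) {
    others <- profile[, -k, drop = FALSE]
    gap_ok <- rowSums(abs(profile[, k] - others) >= min_gap) == 3L
    rownames(profile)[inter[, k] & n_inter == 1L & gap_ok]
  })
  names(out) <- CELL_TYPES
  out
}

#' High-specificity classification
#'
#' A CpG is high-specific to a cell type when, in each cohort independently,
#' its median beta is strictly intermediate (0.1 < beta < 0.9) in that cell
#' type only, and differs from every other cell type's median by at least
#' `min_gap`. CpGs hypo- or hypermethylated across all four cell types can
#' never qualify (no intermediate type).
#'
#' @param profile_a,profile_b median profiles of the two cohorts
#'   ([compute_median_profile()]), covering the same CpG universe.
#' @param min_gap minimum absolute median difference to every other cell
#'   type; default 0.1.
#' @return `cell_type_panel` of specificity `"high"`.
#' @export
classify_high <- function(profile_a, profile_b, min_gap = 0.1) {
  check_shared_universe(profile_a, profile_b)
  a <- classify_high_one(profile_a, min_gap)
  b <- classify_high_one(profile_b, min_gap)
  intersect_cohorts(cell_type_panel("high", a, "cohort A"),
                    cell_type_panel("high", b, "cohort B"))
}

classify_medium_one <- function(profile, require_gap = FALSE, min_gap = 0.1) {
  inter <- is_intermediate(profile)
  n_inter <- rowSums(inter)
  eligible <- n_inter >= 1L & n_inter <= 3L
  out <- lapply(seq_along(CELL_TYPES), function(k) {
    keep <- inter[, k] & eligible
    if (require_gap) {
      others <- profile[, -k, drop = FALSE]
      keep <- keep & rowSums(abs(profile[, k] - others) >= min_gap) == 3L
    }
    rownames(profile)[keep]
  })
  names(out) <- CELL_TYPES
  out
}

#' Medium-specificity classification
#'
#' A CpG is annotated to every cell type in which its median is intermediate,
#' in both cohorts, provided at least one cell type is non-intermediate
#' (between one and three intermediate cell types). Multi-annotation is
#' allowed; per cell type the result is a superset of the high panel.
#'
#' @inheritParams classify_high
#' @param require_gap also demand the `min_gap` median separation (off by
#'   default: the medium criterion only requires an extreme cell type).
#' @return `cell_type_panel` of specificity `"medium"`.
#' @export
classify_medium <- function(profile_a, profile_b, require_gap = FALSE,
                            min_gap = 0.1) {
  check_shared_universe(profile_a, profile_b)
  a <- classify_medium_one(profile_a, require_gap, min_gap)
  b <- classify_medium_one(profile_b, require_gap, min_gap)
  intersect_cohorts(cell_type_panel("medium", a, "cohort A"),
                    cell_type_panel("medium", b, "cohort B"))
}

check_shared_universe <- function(profile_a, profile_b) {
  if (!identical(sort(rownames(profile_a)), sort(rownames(profile_b))))
    stop("cohort profiles must cover the same CpG universe; intersect ",
         "cohorts before classification", call. = FALSE)
}

#' Intersect two cohort panels
#'
#' Per cell type, the set intersection of the two cohorts' assignments; only
#' CpGs meeting the criteria in both cohorts are retained downstream.
#'
#' @param panel_a,panel_b `cell_type_panel`s of the same specificity.
#' @return a `cell_type_panel`.
#' @export
intersect_cohorts <- function(panel_a, panel_b) {
  if (!identical(panel_a$specificity, panel_b$specificity))
    stop("cannot intersect panels of different specificity (",
         panel_a$specificity, " vs ", panel_b$specificity, ")", call. = FALSE)
  out <- lapply(CELL_TYPES, function(ct)
    intersect(panel_a$assignments[[ct]], panel_b$assignments[[ct]]))
  names(out) <- CELL_TYPES
  if (all(lengths(out) == 0L) &&
      any(lengths(panel_a$assignments) > 0L | lengths(panel_b$assignments) > 0L))
    warning("cohort intersection is empty for every cell type", call. = FALSE)
  cell_type_panel(panel_a$specificity, out,
                  c(panel_a$provenance, panel_b$provenance,
                    "intersection of cohorts"))
}

contrast_pairs <- function() {
  idx <- utils::combn(CELL_TYPES, 2L)
  paste(idx[1L, ], idx[2L, ], sep = "-")
}

#' Pairwise cell-type contrasts from linear mixed models
#'
#' Fits, per CpG, a linear mixed model of M-values on cell type, age and sex
#' with a random intercept per donor (REML, via nlme), and reports the six
#' pairwise cell-type contrasts with raw and Bonferroni-adjusted p-values
#' (default family size 6, the per-CpG pairwise family). Degenerate designs
#' where the random effect is not estimable fall back to ordinary least
#' squares with donor as a fixed covariate, flagged in the `engine` column;
#' CpGs where both engines fail are recorded in the `failed` attribute and
#' excluded from low-specificity candidacy.
#'
#' @param mvalues numeric matrix of M-values, CpGs x samples.
#' @param meta sample metadata for the columns of `mvalues`.
#' @param bonferroni_factor multiplier for p_bonf; default 6.
#' @param tolerance mixed-model convergence tolerance.
#' @return data.frame with columns `cpg_id`, `contrast`, `estimate`, `p_raw`,
#'   `p_bonf`, `engine`; attribute `failed` holds CpGs without results.
#' @export
pairwise_mixed_contrasts <- function(mvalues, meta, bonferroni_factor = 6,
                                     tolerance = 1e-8) {
  meta <- validate_metadata(meta)
  meta <- meta[match(colnames(mvalues), meta$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("samples without metadata in M-value matrix", call. = FALSE)
  pairs <- utils::combn(CELL_TYPES, 2L)
  pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  # contrast rows on (cell_typeMG, cell_typeOLIG, cell_typeAST): level_i - level_j
  dummy_of <- function(ct) match(ct, CELL_TYPES) - 1L  # 0 => reference NEU
  L <- matrix(0, nrow = 6L, ncol = 3L,
              dimnames = list(pair_names, CELL_TYPES[-1L]))
  for (r in seq_len(6L)) {
    i <- dummy_of(pairs[1L, r]); j <- dummy_of(pairs[2L, r])
    if (i > 0L) L[r, i] <- 1
    if (j > 0L) L[r, j] <- -1
  }
  covars <- c(if (length(unique(meta$age)) > 1L) "age",
              if (nlevels(droplevels(meta$sex)) > 1L) "sex")
  fml <- stats::reformulate(c("cell_type", covars), response = "M")
  ctrl <- nlme::lmeControl(tolerance = tolerance, returnObject = FALSE)
  res <- vector("list", nrow(mvalues))
  failed <- character()
  for (i in seq_len(nrow(mvalues))) {
    d <- data.frame(M = mvalues[i, ], cell_type = meta$cell_type,
                    age = meta$age, sex = meta$sex,
                    donor = factor(meta$donor_id))
    fit <- tryCatch(
      nlme::lme(fml, random = ~ 1 | donor, data = d, method = "REML",
                control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit)) {
      b <- nlme::fixef(fit)
      V <- stats::vcov(fit)
      df <- fit$fixDF$X[["cell_typeMG"]]
      engine <- "lme"
    } else {
      fit2 <- tryCatch(
        stats::lm(stats::update(fml, . ~ . + donor), data = d),
        error = function(e) NULL)
      if (is.null(fit2) || any(is.na(stats::coef(fit2)[paste0("cell_type", CELL_TYPES[-1L])]))) {
        failed <- c(failed, rownames(mvalues)[i])
        next
      }
      b <- stats::coef(fit2)
      V <- stats::vcov(fit2)
      df <- fit2$df.residual
      engine <- "lm_fixed"
    }
    cols <- paste0("cell_type", CELL_TYPES[-1L])
    est <- drop(L %*% b[cols])
    se <- sqrt(diag(L %*% V[cols, cols] %*% t(L)))
    p_raw <- 2 * stats::pt(-abs(est / se), df)
    res[[i]] <- data.frame(cpg_id = rownames(mvalues)[i],
                           contrast = pair_names, estimate = est,
                           p_raw = p_raw,
                           p_bonf = pmin(1, bonferroni_factor * p_raw),
                           engine = engine, row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cpg_id = character(), contrast = character(),
                      estimate = numeric(), p_raw = numeric(),
                      p_bonf = numeric(), engine = character())
  attr(out, "failed") <- failed
  out
}

#' Low-specificity classification
#'
#' A CpG is annotated to cell type c when its median is intermediate in both
#' cohorts and all three pairwise contrasts involving c are Bonferroni-
#' significant (p_bonf < `alpha`) in both cohorts - or when the CpG already
#' belongs to the high or medium panel for c, which is carried over
#' regardless of the statistical criterion.
#'
#' @param profile_a,profile_b cohort median profiles.
#' @param contrasts_a,contrasts_b outputs of [pairwise_mixed_contrasts()]
#'   for each cohort.
#' @param high,medium the corresponding cohort-intersected panels.
#' @param alpha Bonferroni-adjusted significance threshold; default 0.05.
#' @return `cell_type_panel` of specificity `"low"`.
#' @export
classify_low <- function(profile_a, profile_b, contrasts_a, contrasts_b,
                         high, medium, alpha = 0.05) {
  check_shared_universe(profile_a, profile_b)
  sig_by_ct <- function(contrasts) {
    # per (cpg, cell type): TRUE iff all 3 contrasts involving ct significant
    ok <- contrasts$p_bonf < alpha
    lapply(CELL_TYPES, function(ct) {
      involved <- grepl(paste0("(^", ct, "-|-", ct, "$)"), contrasts$contrast)
      n_sig <- tapply(ok[involved], contrasts$cpg_id[involved], sum)
      names(n_sig)[!is.na(n_sig) & n_sig == 3L]
    })
  }
  sa <- sig_by_ct(contrasts_a)
  sb <- sig_by_ct(contrasts_b)
  inter_a <- is_intermediate(profile_a)
  inter_b <- is_intermediate(profile_b)
  out <- lapply(seq_along(CELL_TYPES), function(k) {
    both_inter <- rownames(profile_a)[inter_a[, k] &
                                      inter_b[rownames(profile_a), k]]
    stat_route <- intersect(both_inter, intersect(sa[[k]], sb[[k]]))
    union(stat_route,
          union(high$assignments[[CELL_TYPES[k]]],
                medium$assignments[[CELL_TYPES[k]]]))
  })
  names(out) <- CELL_TYPES
  cell_type_panel("low", out, "intersection of cohorts")
}

#' Build all three specificity panels from two purified-cell cohorts
#'
#' Runs the full panel-construction workflow: restrict to the CpGs shared by
#' both cohorts, compute per-cohort median profiles, classify high and
#' medium specificity, fit mixed-model contrasts on the low-specificity
#' candidates (CpGs intermediate in at least one cell type in both cohorts
#' and not already covered by the medium panel) and assemble the nested
#' high/medium/low panels.
#'
#' @param betas_a,betas_b `beta_matrix` per cohort.
#' @param meta_a,meta_b matching sample metadata.
#' @param alpha Bonferroni threshold for the low-specificity contrasts.
#' @param bonferroni_factor per-CpG contrast family size (default 6).
#' @param medium_gap require the 0.1 median gap at medium specificity too.
#' @param epsilon M-value clamp bound.
#' @return named list of three `cell_type_panel`s (`high`, `medium`, `low`).
#' @export
build_panels <- function(betas_a, meta_a, betas_b, meta_b, alpha = 0.05,
                         bonferroni_factor = 6, medium_gap = FALSE,
                         epsilon = 1e-6) {
  shared <- intersect(rownames(betas_a), rownames(betas_b))
  if (!length(shared)) stop("cohorts share no CpGs", call. = FALSE)
  betas_a <- betas_a[shared, , drop = FALSE]
  betas_b <- betas_b[shared, , drop = FALSE]
  prof_a <- compute_median_profile(betas_a, meta_a)
  prof_b <- compute_median_profile(betas_b, meta_b)
  high <- classify_high(prof_a, prof_b)
  medium <- classify_medium(prof_a, prof_b, require_gap = medium_gap)
  inter_both <- is_intermediate(prof_a) & is_intermediate(prof_b)
  in_medium <- matrix(FALSE, length(shared), 4L,
                      dimnames = list(shared, CELL_TYPES))
  for (ct in CELL_TYPES)
    in_medium[medium$assignments[[ct]], ct] <- TRUE
  candidates <- shared[rowSums(inter_both & !in_medium) > 0L]
  if (length(candidates)) {
    ca <- pairwise_mixed_contrasts(beta_to_m(betas_a[candidates, , drop = FALSE],
                                             epsilon),
                                   meta_a, bonferroni_factor)
    cb <- pairwise_mixed_contrasts(beta_to_m(betas_b[candidates, , drop = FALSE],
                                             epsilon),
                                   meta_b, bonferroni_factor)
  } else {
    ca <- cb <- pairwise_mixed_contrasts(
      matrix(numeric(), 0L, ncol(betas_a),
             dimnames = list(NULL, colnames(betas_a))), meta_a)
  }
  low <- classify_low(prof_a, prof_b, ca, cb, high, medium, alpha)
  list(high = high, medium = medium, low = low)
}
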
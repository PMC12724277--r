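test_that("median profiles follow the usual median conventions", {
  meta <- make_meta(3L)
  betas <- matrix(0.9, nrow = 2L, ncol = nrow(meta),
                  dimnames = list(c("c1", "c2"), meta$sample_id))
  neu_cols <- meta$cell_type == "NEU"
  betas["c1", neu_cols] <- c(0.4, 0.5, 0.6)
  betas["c2", which(neu_cols)[1:2]] <- c(0.4, 0.6)
  prof <- compute_median_profile(beta_matrix(betas), meta)
  expect_equal(prof["c1", "NEU"], 0.5)   # odd count
  expect_equal(prof["c2", "NEU"], 0.6)   # median of (0.4, 0.6, 0.9)
  expect_equal(prof["c1", "MG"], 0.9)    # constant column is its own median
  # even-count midpoint on a two-sample cell type
  meta2 <- make_meta(2L)
  b2 <- matrix(0.2, 1L, nrow(meta2),
               dimnames = list("c1", meta2$sample_id))
  b2[1, meta2$cell_type == "OLIG"] <- c(0.4, 0.6)
  expect_equal(compute_median_profile(beta_matrix(b2), meta2)["c1", "OLIG"],
               0.5)
})

test_that("median profiles require complete, labelled samples", {
  meta <- make_meta(2L)
  betas <- matrix(0.5, 2L, nrow(meta),
                  dimnames = list(c("c1", "c2"), meta$sample_id))
  bad_meta <- meta
  bad_meta$cell_type[1] <- "NEURON"
  expect_error(compute_median_profile(beta_matrix(betas), bad_meta),
               "unknown cell_type")
  nas <- betas; nas[1, 1] <- NA
  expect_error(beta_matrix(nas), "missing values")
  # fewer than two samples in a cell type
  keep <- meta$cell_type != "AST" | meta$donor_id == meta$donor_id[1]
  expect_error(
    compute_median_profile(beta_matrix(betas[, meta$sample_id[keep]]),
                           meta[keep, ]),
    ">= 2 samples")
})

test_that("high-specificity classification follows the stated thresholds", {
  p <- profile_of(c(0.50, 0.05, 0.95, 0.02),   # exclusive NEU
                  c(0.50, 0.45, 0.05, 0.05),   # two intermediate types
                  c(0.15, 0.08, 0.92, 0.95),   # gap 0.07 < 0.1
                  c(0.03, 0.04, 0.02, 0.05),   # all hypo
                  c(0.95, 0.97, 0.92, 0.99))   # all hyper
  panel <- classify_high(p, p)
  expect_equal(panel$assignments$NEU, "p01")
  expect_equal(unlist(panel$assignments[-1], use.names = FALSE), character())
  expect_false("p02" %in% unlist(panel$assignments))
  expect_false("p03" %in% unlist(panel$assignments))
  expect_false("p04" %in% unlist(panel$assignments))
  expect_false("p05" %in% unlist(panel$assignments))
})

test_that("a CpG must satisfy the high criteria in both cohorts", {
  pa <- profile_of(c(0.50, 0.05, 0.95, 0.02))
  pb <- profile_of(c(0.50, 0.45, 0.95, 0.02))  # MG intermediate in cohort B
  expect_warning(panel <- classify_high(pa, pb), "empty")
  expect_length(panel$assignments$NEU, 0L)
  expect_equal(classify_high(pa, pa)$assignments$NEU, "p01")
})

test_that("medians exactly at 0.1 or 0.9 are excluded from intermediate", {
  # borderline fixture: target at exactly 0.9 is not intermediate
  p_border <- profile_of(c(0.90, 0.05, 0.95, 0.02))
  expect_length(unlist(classify_high(p_border, p_border)$assignments), 0L)
  # an off-target median at exactly 0.1 counts as non-intermediate
  p_edge <- profile_of(c(0.50, 0.10, 0.95, 0.02))
  expect_equal(classify_high(p_edge, p_edge)$assignments$NEU, "p01")
})

test_that("medium specificity annotates all intermediate types given an extreme one", {
  p <- profile_of(c(0.5, 0.5, 0.5, 0.05),   # three intermediate, one extreme
                  c(0.5, 0.5, 0.5, 0.5),    # no extreme type
                  c(0.5, 0.05, 0.95, 0.02)) # exclusive NEU
  panel <- classify_medium(p, p)
  expect_setequal(panel$assignments$NEU, c("p01", "p03"))
  expect_equal(panel$assignments$MG, "p01")
  expect_equal(panel$assignments$OLIG, "p01")
  expect_length(panel$assignments$AST, 0L)
  # high subset of medium per cell type
  high <- classify_high(p, p)
  for (ct in CELL_TYPES)
    expect_true(all(high$assignments[[ct]] %in% panel$assignments[[ct]]))
})

test_that("the optional medium gap criterion tightens the panel", {
  p <- profile_of(c(0.50, 0.45, 0.05, 0.05))
  loose <- classify_medium(p, p)
  tight <- classify_medium(p, p, require_gap = TRUE)
  expect_setequal(loose$assignments$NEU, "p01")
  expect_length(tight$assignments$NEU, 0L)  # |0.50 - 0.45| < 0.1
})

test_that("M-value transform is the clamped logit2", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_equal(beta_to_m(0.3), -beta_to_m(0.7))
  expect_equal(beta_to_m(0, epsilon = 1e-6), log2(1e-6 / (1 - 1e-6)))
  b <- seq(0, 1, 0.05)
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("pairwise contrasts recover a planted cell-type shift", {
  set.seed(71)
  meta <- make_meta(20L)
  m <- matrix(rnorm(2L * nrow(meta)), 2L,
              dimnames = list(c("c1", "c2"), meta$sample_id))
  m[2L, meta$cell_type == "NEU"] <- m[2L, meta$cell_type == "NEU"] + 4
  res <- pairwise_mixed_contrasts(m, meta)
  expect_equal(nrow(res), 12L)  # 6 contrasts x 2 CpGs
  neu_rows <- res$cpg_id == "c2" & grepl("NEU", res$contrast)
  expect_true(all(res$p_bonf[neu_rows] < 0.05))
  # Bonferroni bound
  expect_true(all(res$p_bonf >= res$p_raw))
  expect_true(all(res$p_bonf <= 1))
  expect_equal(res$p_bonf, pmin(1, 6 * res$p_raw))
})

test_that("null contrasts keep roughly nominal error rates", {
  set.seed(72)
  meta <- make_meta(20L)
  m <- matrix(rnorm(300L * nrow(meta)), 300L,
              dimnames = list(sprintf("c%03d", 1:300), meta$sample_id))
  res <- pairwise_mixed_contrasts(m, meta)
  frac <- mean(res$p_raw < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("degenerate designs fall back to a fixed-effects engine", {
  set.seed(73)
  meta <- make_meta(2L)  # 2 donors: random intercept barely identifiable
  m <- matrix(rnorm(nrow(meta)), 1L, dimnames = list("c1", meta$sample_id))
  res <- pairwise_mixed_contrasts(m, meta)
  expect_true(all(res$engine %in% c("lme", "lm_fixed")))
  expect_equal(nrow(res), 6L)
})

test_that("low specificity unions the statistical route with earlier levels", {
  p <- profile_of(c(0.65, 0.40, 0.40, 0.40),  # all intermediate: low candidate
                  c(0.50, 0.05, 0.95, 0.02),  # high NEU, carried regardless
                  c(0.45, 0.47, 0.44, 0.46))  # no separation
  high <- classify_high(p, p)
  medium <- classify_medium(p, p)
  sig_all <- function() {
    rows <- expand.grid(cpg_id = rownames(p), contrast = contrast_pairs_for_test(),
                        stringsAsFactors = FALSE)
    rows$estimate <- 1
    rows$p_raw <- ifelse(rows$cpg_id == "p01" &
                           grepl("NEU", rows$contrast), 1e-6, 0.5)
    rows$p_bonf <- pmin(1, 6 * rows$p_raw)
    rows$engine <- "lme"
    rows
  }
  contrasts <- sig_all()
  low <- classify_low(p, p, contrasts, contrasts, high, medium)
  expect_true("p01" %in% low$assignments$NEU)   # via contrasts
  expect_true("p02" %in% low$assignments$NEU)   # carried from high
  expect_false("p03" %in% low$assignments$NEU)  # not significant
  # one failed contrast blocks the statistical route
  weak <- contrasts
  weak$p_raw[weak$cpg_id == "p01" & weak$contrast == "NEU-MG"] <- 0.2
  weak$p_bonf <- pmin(1, 6 * weak$p_raw)
  low2 <- classify_low(p, p, weak, weak, high, medium)
  expect_false("p01" %in% low2$assignments$NEU)
  expect_true("p02" %in% low2$assignments$NEU)
})

test_that("cohort intersection is per cell type and idempotent", {
  pa <- cell_type_panel("high", list(NEU = c("c1", "c2")))
  pb <- cell_type_panel("high", list(NEU = c("c2", "c3")))
  expect_equal(intersect_cohorts(pa, pb)$assignments$NEU, "c2")
  expect_equal(intersect_cohorts(pa, pa)$assignments$NEU, c("c1", "c2"))
  pl <- cell_type_panel("low", list(NEU = "c1"))
  expect_error(intersect_cohorts(pa, pl), "different specificity")
  pd <- cell_type_panel("high", list(NEU = "c9"))
  expect_warning(intersect_cohorts(pa, pd), "empty")
})

test_that("high-specificity disjointness is enforced at construction", {
  expect_error(cell_type_panel("high", list(NEU = "c1", MG = "c1")),
               "disjoint")
  expect_silent(cell_type_panel("medium", list(NEU = "c1", MG = "c1")))
})

test_that("panels built from synthetic cohorts nest and are deterministic", {
  panels <- fixture_panels
  for (ct in CELL_TYPES) {
    expect_true(all(panels$high$assignments[[ct]] %in%
                      panels$medium$assignments[[ct]]))
    expect_true(all(panels$medium$assignments[[ct]] %in%
                      panels$low$assignments[[ct]]))
  }
  # high disjointness across cell types
  all_high <- unlist(panels$high$assignments)
  expect_equal(anyDuplicated(all_high), 0L)
  # determinism: rebuilding from identical inputs gives identical panels
  again <- build_panels(fixture_cohorts$A$betas, fixture_cohorts$A$meta,
                        fixture_cohorts$B$betas, fixture_cohorts$B$meta)
  expect_identical(lapply(again, `[[`, "assignments"),
                   lapply(panels, `[[`, "assignments"))
})

test_that("all-hypo and all-hyper CpGs appear in no panel at any level", {
  excluded <- fixture_truth$cpg_id[fixture_truth$category %in%
                                     c("all-hypo", "all-hyper")]
  for (panel in fixture_panels)
    expect_length(intersect(excluded, unlist(panel$assignments)), 0L)
})
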
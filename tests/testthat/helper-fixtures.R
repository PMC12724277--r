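# shared synthetic fixtures, built once per test session

# balanced purified-cohort metadata: one sample per donor x cell type
make_meta <- function(n_donors, cohort = "A") {
  donors <- sprintf("%s_d%02d", cohort, seq_len(n_donors))
  meta <- expand.grid(cell_type = CELL_TYPES, donor_id = donors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$donor_id, meta$cell_type, sep = "_")
  meta$age <- rep(seq(65, 95, length.out = n_donors),
                  each = 4L)
  meta$sex <- rep(rep_len(c("F", "M"), n_donors), each = 4L)
  meta$cohort <- cohort
  meta[, c("sample_id", "donor_id", "cell_type", "age", "sex", "cohort")]
}

# a median profile matrix from per-cell-type medians
profile_of <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- CELL_TYPES
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  m
}

# small planted-truth cohorts reused across test files
fixture_truth <- plant_truth(n_high_per_type = 10L, n_medium = 12L,
                             n_low_per_type = 4L, n_background = 40L,
                             n_extreme = 12L, sd = 0.03, seed = 421L)
fixture_cohorts <- synth_purified_cohorts(fixture_truth, n_donors = 8L,
                                          donor_sd = 0.02, seed = 422L)
fixture_panels <- build_panels(fixture_cohorts$A$betas, fixture_cohorts$A$meta,
                               fixture_cohorts$B$betas, fixture_cohorts$B$meta)

contrast_pairs_for_test <- function() {
  idx <- utils::combn(CELL_TYPES, 2L)
  paste(idx[1L, ], idx[2L, ], sep = "-")
}

# independent brute-force hypergeometric tail oracle: P(X >= a) by direct
# enumeration of the mass function from binomial coefficients
hyper_tail_oracle <- function(a, b, cc, d) {
  N <- a + b + cc + d
  K <- a + cc   # set CpGs
  n <- a + b    # input draws
  xs <- a:min(K, n)
  if (a > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
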
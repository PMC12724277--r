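small_config <- function(...) {
  simulation_config(n_cpgs = 2000L, n_per_group = 20L, n_iterations = 2L,
                    noise_sds = c(0, 0.6), dmp_counts = c(4L, 16L),
                    seed = 101L, ...)
}

test_that("configuration validation catches inconsistent settings", {
  expect_error(simulation_config(set_fractions = c(NEU = 0.5, MG = 0.4,
                                                   OLIG = 0.2, AST = 0.1)))
  expect_error(simulation_config(alpha_control = c(1, 1, 1)))
  expect_error(simulation_config(dmp_allocation = c(NEU = 0.9, MG = 0.2,
                                                    OLIG = 0, AST = 0,
                                                    background = 0.2)))
})

test_that("CpG specs respect category counts and mean ranges", {
  cfg <- simulation_config(n_cpgs = 10000L,
                           set_fractions = c(NEU = 0.02, MG = 0.025,
                                             OLIG = 0.006, AST = 0.006),
                           seed = 1L)
  specs <- simulate_cpg_specs(cfg, seed = 5L)
  expect_equal(sum(specs$category == "NEU-set"), 200L)
  expect_equal(nrow(specs), 10000L)
  neu <- specs[specs$category == "NEU-set", ]
  expect_true(all(neu$mu_NEU > 0.15 & neu$mu_NEU < 0.85))
  for (ct in c("MG", "OLIG", "AST")) {
    mu <- neu[[paste0("mu_", ct)]]
    expect_true(all(mu <= 0.09 | mu >= 0.91))
  }
  bg <- specs[specs$category == "background", ]
  for (ct in CELL_TYPES)
    expect_true(all(bg[[paste0("mu_", ct)]] >= 0.15 &
                      bg[[paste0("mu_", ct)]] <= 0.85))
  expect_true(all(specs$sd >= 0 & specs$sd <= 0.1))
})

test_that("the heteroskedastic SD* formula hits its endpoints", {
  expect_equal(sd_star(0.1, 0.5), 0.1)
  expect_equal(sd_star(0.1, 1.0), 0)
  expect_equal(sd_star(0.1, 0.0), 0)
  expect_equal(sd_star(0.1, 0.75), 0.05)
  # linear in |0.5 - mu|
  mus <- seq(0, 1, 0.1)
  expect_equal(sd_star(0.08, mus), 0.08 * (1 - abs(0.5 - mus) / 0.5))
})

test_that("truncated-normal profile draws stay in range and match their mean", {
  specs <- data.frame(cpg_id = c("a", "b"), category = "background",
                      sd = c(0.05, 0), mu_NEU = c(0.5, 0.3),
                      mu_MG = c(0.5, 0.3), mu_OLIG = c(0.5, 0.3),
                      mu_AST = c(0.5, 0.3))
  prof <- sample_cell_profiles(specs, 10000L, seed = 9L)
  draws <- prof$NEU["a", ]
  expect_true(all(draws >= 0 & draws <= 1))
  se <- 0.05 / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  # sd 0 is the degenerate point mass at mu
  expect_true(all(prof$MG["b", ] == 0.3))
})

test_that("Dirichlet weights sit on the simplex with the right means", {
  w <- draw_weights(10000L, c(1, 1, 1, 1), seed = 2L)
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))
  expect_true(all(abs(colMeans(w) - 0.25) < 0.015))
  w2 <- draw_weights(10000L, c(1, 2, 2, 2), seed = 3L)
  expect_true(all(abs(colMeans(w2) - c(1, 2, 2, 2) / 7) < 0.015))
})

test_that("pseudo-bulk mixing is the convex combination of cell profiles", {
  profs <- lapply(CELL_TYPES, function(ct)
    matrix(c(0.2, 0.4, 0.6, 0.8)[match(ct, CELL_TYPES)], 3L, 2L,
           dimnames = list(paste0("c", 1:3), c("s1", "s2"))))
  names(profs) <- CELL_TYPES
  w_id <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), 2L, 4L, byrow = TRUE)
  bulk_id <- mix_pseudobulk(profs, w_id)
  expect_true(all(bulk_id[, 1] == 0.2))  # pure NEU sample
  w_eq <- matrix(0.25, 2L, 4L)
  expect_true(all(mix_pseudobulk(profs, w_eq) == 0.5))
  # convexity on random profiles
  set.seed(4)
  profs_r <- lapply(CELL_TYPES, function(ct)
    matrix(runif(6), 3L, 2L, dimnames = list(paste0("c", 1:3), c("s1", "s2"))))
  names(profs_r) <- CELL_TYPES
  w <- draw_weights(2L, c(1, 1, 1, 1))
  bulk <- mix_pseudobulk(profs_r, w)
  lo <- pmin(profs_r[[1]], profs_r[[2]], profs_r[[3]], profs_r[[4]])
  hi <- pmax(profs_r[[1]], profs_r[[2]], profs_r[[3]], profs_r[[4]])
  expect_true(all(bulk >= lo - 1e-12 & bulk <= hi + 1e-12))
  expect_error(mix_pseudobulk(profs_r, w[1, , drop = FALSE]), "match")
})

test_that("weight perturbation preserves the simplex and its noise-free limit", {
  w <- draw_weights(200L, c(1, 1, 1, 1), seed = 6L)
  p0 <- perturb_weights(w, 0)
  expect_equal(p0$weights, w, ignore_attr = TRUE)
  expect_equal(p0$mean_rmse, 0)
  p <- perturb_weights(w, 0.8, seed = 7L)
  expect_true(all(abs(rowSums(p$weights) - 1) < 1e-12))
  expect_true(all(p$weights >= 0))
  expect_gt(p$mean_rmse, 0)
  # additive mode also renormalizes
  pa <- perturb_weights(w, 0.8, seed = 8L, mode = "additive")
  expect_true(all(abs(rowSums(pa$weights) - 1) < 1e-12))
})

test_that("weight-scaled noise at SD 0.6 lands near the calibrated RMSE", {
  set.seed(10)
  w <- rbind(draw_weights(250L, c(1, 1, 1, 1)),
             draw_weights(250L, c(1, 2, 2, 2)))
  rmse <- mean(replicate(10, perturb_weights(w, 0.6)$mean_rmse))
  expect_gt(rmse, 0.09)
  expect_lt(rmse, 0.15)
})

test_that("DMP calling matches per-CpG lm and keeps the null flat", {
  set.seed(12)
  n <- 60L
  group <- rep(c("control", "disease"), each = n / 2)
  bulk <- matrix(runif(5000L * n, 0.3, 0.7), 5000L, n,
                 dimnames = list(sprintf("c%05d", 1:5000), NULL))
  w <- draw_weights(n, c(1, 1, 1, 1))
  res <- call_dmps(bulk, group, weights = w)
  # cross-check a handful of CpGs against stats::lm
  for (i in c(1L, 17L, 4999L)) {
    fit <- lm(bulk[i, ] ~ I(group == "disease") + w[, 1:3])
    expect_equal(res$table$p_value[i], summary(fit)$coefficients[2L, 4L],
                 tolerance = 1e-10)
  }
  # null p-values approximately uniform
  ks <- suppressWarnings(ks.test(res$table$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lt(length(res$dmps), 5L)
})

test_that("DMP calling detects a planted shift and honours exchangeability", {
  set.seed(13)
  n <- 500L
  group <- rep(c("control", "disease"), each = n / 2)
  bulk <- matrix(rnorm(200L * n, 0.5, 0.05), 200L, n,
                 dimnames = list(sprintf("c%03d", 1:200), NULL))
  bulk[1:5, group == "disease"] <- bulk[1:5, group == "disease"] + 0.3
  bulk <- pmin(pmax(bulk, 0), 1)
  res <- call_dmps(bulk, group)
  expect_true(all(sprintf("c%03d", 1:5) %in% res$dmps))
  # permuting sample order leaves the DMP set unchanged
  perm <- sample(n)
  res2 <- call_dmps(bulk[, perm], group[perm])
  expect_setequal(res$dmps, res2$dmps)
  # constant CpG yields p = 1
  bulk[7, ] <- 0.42
  res3 <- call_dmps(bulk, group)
  expect_equal(res3$table$p_value[res3$table$cpg_id == "c007"], 1)
})

test_that("DMP injection follows largest-remainder allocation exactly", {
  cfg <- simulation_config(n_cpgs = 20000L, n_per_group = 3L, seed = 14L)
  ds <- simulate_pseudobulk(cfg, seed = 14L)
  inj <- inject_dmps(ds, 1000L, seed = 15L)
  cat_of <- ds$specs$category[match(inj$designated_dmps, ds$specs$cpg_id)]
  expect_equal(sum(cat_of == "NEU-set"), 500L)
  expect_equal(sum(cat_of == "MG-set"), 200L)
  expect_equal(sum(cat_of == "OLIG-set"), 1L)
  expect_equal(sum(cat_of == "AST-set"), 1L)
  expect_equal(sum(cat_of == "background"), 298L)
  # n = 2: counts conserve under rounding
  inj2 <- inject_dmps(ds, 2L, seed = 16L)
  expect_length(inj2$designated_dmps, 2L)
  cat2 <- ds$specs$category[match(inj2$designated_dmps, ds$specs$cpg_id)]
  expect_equal(sum(cat2 == "NEU-set"), 1L)
  # bulk shifted only in the disease group, still within [0, 1]
  dis <- ds$group == "disease"
  expect_true(all(inj$bulk[inj$designated_dmps, !dis] ==
                    ds$bulk[inj$designated_dmps, !dis]))
  expect_true(all(inj$bulk >= 0 & inj$bulk <= 1))
  # zero effect leaves the data untouched
  inj0 <- inject_dmps(ds, 10L, effect_delta = 0, seed = 17L)
  expect_equal(inj0$bulk, ds$bulk)
  # category exhaustion errors with the category name
  small <- simulate_pseudobulk(small_config(), seed = 18L)
  expect_error(inject_dmps(small, 2000L), "NEU")
})

test_that("datasets are bit-identical under a fixed seed", {
  cfg <- small_config()
  d1 <- simulate_pseudobulk(cfg, seed = 19L)
  d2 <- simulate_pseudobulk(cfg, seed = 19L)
  expect_identical(d1$bulk, d2$bulk)
  expect_identical(d1$weights, d2$weights)
  expect_identical(d1$specs, d2$specs)
  expect_true(all(abs(rowSums(d1$weights) - 1) < 1e-12))
  expect_true(all(d1$bulk >= 0 & d1$bulk <= 1))
})
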
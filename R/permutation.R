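#' Validate a probe annotation table
#'
#' One row per CpG with the three matching covariates used for permutation
#' nulls: probe design chemistry (I/II), CpG-island context and gene
#' context. Vocabularies are configurable; the defaults follow the standard
#' Illumina manifest categories.
#'
#' @param ann data.frame with columns `cpg_id`, `probe_design`,
#'   `island_context`, `gene_context`.
#' @param vocab named list of allowed category values per factor.
#' @return the validated annotation (character columns).
#' @export
validate_annotation <- function(ann,
                                vocab = list(
                                  probe_design = c("I", "II"),
                                  island_context = c("Island", "Shore",
                                                     "Shelf", "OpenSea"),
                                  gene_context = c("TSS", "Body",
                                                   "Intergenic"))) {
  required <- c("cpg_id", names(vocab))
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols))
    stop("annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$cpg_id))
    stop("duplicated cpg_id in annotation", call. = FALSE)
  for (col in names(vocab)) {
    ann[[col]] <- as.character(ann[[col]])
    bad <- setdiff(unique(ann[[col]]), vocab[[col]])
    if (length(bad))
      stop("annotation column ", col, " has value(s) outside vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  ann$cpg_id <- as.character(ann$cpg_id)
  ann
}

#' Matched-probe permutation null for an enrichment odds ratio
#'
#' Draws `n_perm` permuted input sets from the background, each matched to
#' the observed input on the joint distribution of probe design, CpG-island
#' context and gene context (sampling without replacement within each joint
#' stratum), recomputes the Haldane-Anscombe odds ratio against the panel
#' set for each, and reports the empirical p-value
#' (1 + #\{permuted OR >= observed OR\}) / (n_perm + 1).
#'
#' When a stratum holds fewer background probes than the input requires, the
#' matching falls back to coarser strata in a fixed order (drop gene
#' context, then island context); fallbacks are recorded in the result.
#'
#' @param input_cpgs,background,panel_set CpG-ID vectors as in
#'   [build_contingency()].
#' @param annotation probe annotation covering the background
#'   (see [validate_annotation()]).
#' @param n_perm number of permutations (>= 1); default 1000.
#' @param seed integer seed for reproducibility.
#' @param return_sets also keep the drawn CpG IDs of every permutation
#'   (memory-heavy; for diagnostics).
#' @return list classed `permutation_null` with `observed_or`,
#'   `permuted_ors`, `empirical_p`, `n_perm`, `seed`, `fallbacks`, and
#'   `permuted_sets` when requested.
#' @export
matched_permutation_null <- function(input_cpgs, background, panel_set,
                                     annotation, n_perm = 1000L,
                                     seed = NULL, return_sets = FALSE) {
  stopifnot(n_perm >= 1L)
  annotation <- validate_annotation(annotation)
  input_cpgs <- unique(as.character(input_cpgs))
  background <- unique(as.character(background))
  uncovered <- setdiff(background, annotation$cpg_id)
  if (length(uncovered))
    stop(length(uncovered), " background CpG(s) lack annotation", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ann <- annotation[match(background, annotation$cpg_id), ]
  strata_levels <- list(
    full = interaction(ann$probe_design, ann$island_context,
                       ann$gene_context, drop = FALSE),
    no_gene = interaction(ann$probe_design, ann$island_context, drop = FALSE),
    design_only = interaction(ann$probe_design, drop = FALSE))
  in_input <- background %in% input_cpgs

  # resolve, once, the matching level used for each observed input probe:
  # finest stratum whose background count covers the input demand
  level_used <- rep(NA_character_, length(background))
  demand_key <- rep(NA_character_, length(background))
  for (lv in names(strata_levels)) {
    key <- as.character(strata_levels[[lv]])
    need <- table(key[in_input & is.na(level_used)])
    have <- table(key)
    for (k in names(need)) {
      if (need[[k]] <= have[[k]]) {
        sel <- in_input & is.na(level_used) & key == k
        level_used[sel] <- lv
        demand_key[sel] <- k
      }
    }
  }
  if (anyNA(level_used[in_input]))
    stop("input exceeds background even at probe-design-only matching",
         call. = FALSE)
  fallbacks <- unique(level_used[in_input])
  fallbacks <- setdiff(fallbacks, "full")
  if (length(fallbacks))
    message("permutation matching fell back to coarser strata: ",
            paste(fallbacks, collapse = ", "))

  # per (level, stratum) demand and candidate background indices,
  # finest level first so coarser fallback draws exclude finer picks
  demand <- stats::aggregate(
    list(n = rep(1L, sum(in_input))),
    by = list(level = level_used[in_input], key = demand_key[in_input]),
    FUN = sum)
  demand <- demand[order(match(demand$level, names(strata_levels))), ]
  pools <- lapply(seq_len(nrow(demand)), function(r) {
    key <- as.character(strata_levels[[demand$level[r]]])
    which(key == demand$key[r])
  })

  set_member <- background %in% unique(as.character(panel_set))
  tab_obs <- build_contingency(input_cpgs, background, panel_set)
  observed <- odds_ratio_ha(tab_obs)
  n_input <- length(input_cpgs)
  n_bg <- length(background)
  n_set <- sum(set_member)

  or_of_a <- function(a) {
    tab <- c(a = a, b = n_input - a, c = n_set - a,
             d = n_bg - n_input - (n_set - a))
    odds_ratio_ha(tab)$odds_ratio
  }
  permuted_sets <- if (return_sets) vector("list", n_perm)
  permuted <- vapply(seq_len(n_perm), function(p) {
    drawn <- logical(n_bg)
    a <- 0L
    for (r in seq_along(pools)) {
      pool <- pools[[r]][!drawn[pools[[r]]]]
      if (length(pool) < demand$n[r])
        stop("permutation stratum exhausted after finer-level draws",
             call. = FALSE)
      take <- if (length(pool) == demand$n[r]) pool
              else pool[sample.int(length(pool), demand$n[r])]
      drawn[take] <- TRUE
      a <- a + sum(set_member[take])
    }
    if (return_sets) permuted_sets[[p]] <<- background[drawn]
    or_of_a(a)
  }, numeric(1L))

  structure(list(observed_or = observed$odds_ratio,
                 permuted_ors = permuted,
                 empirical_p = (1 + sum(permuted >= observed$odds_ratio)) /
                   (n_perm + 1),
                 n_perm = n_perm, seed = seed, fallbacks = fallbacks,
                 permuted_sets = permuted_sets),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Matched-probe permutation null\n")
  cat(sprintf("  observed OR %.3g; %d permutations; empirical p = %.4g\n",
              x$observed_or, x$n_perm, x$empirical_p))
  if (length(x$fallbacks))
    cat("  matching fallbacks:", paste(x$fallbacks, collapse = ", "), "\n")
  invisible(x)
}
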
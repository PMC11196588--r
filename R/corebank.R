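# Cluster-stratified core-collection construction by stepwise
# redundancy elimination, with diversity-retention evaluation.

#' Per-group core allocation
#'
#' Allocates the target core size to each group proportionally:
#' `count_g = max(1, round_half_up(ratio * size_g))`, so every nonempty
#' group keeps at least one accession. E.g. sizes (169, 26) at ratio 0.1
#' give (17, 3).
#'
#' @param group_sizes named (or unnamed) integer vector of group sizes.
#' @param ratio sampling ratio in (0, 1].
#' @return Integer vector of per-group counts (same names/order).
#' @export
allocate_counts <- function(group_sizes, ratio) {
  if (length(group_sizes) == 0) {
    abort("empty group list", class = "heveacore_error_config")
  }
  stopifnot(ratio > 0, ratio <= 1, all(group_sizes >= 1))
  counts <- pmin(pmax(1L, as.integer(round_half_up(ratio * group_sizes))),
                 as.integer(group_sizes))
  setNames(counts, names(group_sizes))
}

#' Stepwise redundancy-elimination sampling
#'
#' Implements stepwise clustering for core selection: repeatedly find
#' the closest remaining pair and discard its more redundant member —
#' the one with the smaller mean distance to all other remaining samples
#' — until `n_target` samples remain. Ties (equal pair distance, or
#' equal means) are broken by sample order, so the procedure is fully
#' deterministic.
#'
#' @param D an `ibs_dist`, `dist` or distance matrix restricted to one
#'   group, with sample ids as dimnames.
#' @param n_target number of samples to retain (>= 1).
#' @return Character vector of selected sample ids, in original order.
#' @export
stepwise_core_sample <- function(D, n_target) {
  D <- as_dist_matrix(D)
  ids <- rownames(D) %||% paste0("s", seq_len(nrow(D)))
  if (n_target < 1) abort("n_target must be >= 1", class = "heveacore_error_config")
  if (n_target > nrow(D)) {
    abort("n_target exceeds group size", class = "heveacore_error_config")
  }
  alive <- seq_len(nrow(D))
  while (length(alive) > n_target) {
    Dsub <- D[alive, alive, drop = FALSE]
    diag(Dsub) <- Inf
    idx <- which(Dsub == min(Dsub), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    diag(Dsub) <- 0
    mean_i <- sum(Dsub[i, ]) / (length(alive) - 1)
    mean_j <- sum(Dsub[j, ]) / (length(alive) - 1)
    drop_local <- if (mean_i < mean_j) i else if (mean_j < mean_i) j else j
    alive <- alive[-drop_local]
  }
  ids[alive]
}

#' Build a core subset at one sampling ratio
#'
#' Stratifies by the provided group labels, allocates per-group counts
#' with [allocate_counts()], runs [stepwise_core_sample()] on the
#' within-group identity-by-state distances, and recomputes the
#' diversity summary on the core submatrix (allele frequencies
#' re-estimated from the core samples only).
#'
#' @param panel a [genotype_panel()].
#' @param group_labels per-sample labels (vector, named vector or
#'   `sample`/`group` tibble as from [assign_groups()]).
#' @param ratio sampling ratio in (0, 1].
#' @return An object of class `core_subset`: `ratio`, `selected`
#'   (tibble `sample`, `group`), `summary` ([population_summary()] of
#'   the core), `original_summary`, and `retention`
#'   ([retention_rate()]).
#' @export
build_core <- function(panel, group_labels, ratio) {
  labels <- align_labels(panel, group_labels)
  groups <- sort(unique(labels))
  sizes <- setNames(vapply(groups, function(g) sum(labels == g), integer(1)), groups)
  counts <- allocate_counts(sizes, ratio)
  selected <- purrr::map2_dfr(groups, counts, function(g, ng) {
    members <- which(labels == g)
    ids <- if (length(members) == 1) {
      panel$samples[members]
    } else {
      stepwise_core_sample(ibs_distance(panel_subset(panel, samples = members)), ng)
    }
    tibble(sample = ids, group = g)
  })
  core_panel <- panel_subset(panel, samples = selected$sample)
  core_labels <- setNames(selected$group, selected$sample)
  orig_sum <- suppressWarnings(population_summary(panel, labels))
  core_sum <- suppressWarnings(population_summary(core_panel, core_labels))
  structure(
    list(
      ratio = ratio, selected = selected, counts = counts,
      summary = core_sum, original_summary = orig_sum,
      retention = retention_rate(core_sum, orig_sum)
    ),
    class = "core_subset"
  )
}

#' @export
print.core_subset <- function(x, ...) {
  cat(sprintf("<core_subset> ratio %.0f%%: %d accessions (%s)\n",
              100 * x$ratio, nrow(x$selected),
              paste(sprintf("%s: %d", names(x$counts), x$counts), collapse = ", ")))
  invisible(x)
}

#' Diversity sweep across sampling ratios
#'
#' Builds a core subset at each ratio and tabulates, per group and
#' ratio, the number of selected accessions and the mean He, PIC and pi
#' of the core — the classic core-collection evaluation table. A 100%
#' baseline row per group (the original population) is appended.
#'
#' @param panel a [genotype_panel()].
#' @param group_labels per-sample group labels.
#' @param ratios sampling ratios to evaluate.
#' @return A tibble of class `ratio_sweep` with columns `population`,
#'   `ratio_pct`, `n_selected`, `he`, `pic`, `pi`.
#' @export
sweep_ratios <- function(panel, group_labels,
                         ratios = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  labels <- align_labels(panel, group_labels)
  rows <- purrr::map_dfr(ratios, function(r) {
    core <- build_core(panel, labels, r)
    core$summary |>
      dplyr::filter(.data$population != "Mean") |>
      dplyr::mutate(ratio_pct = 100 * r, n_selected = .data$n_samples) |>
      dplyr::select("population", "ratio_pct", "n_selected", "he", "pic", "pi")
  })
  baseline <- suppressWarnings(population_summary(panel, labels)) |>
    dplyr::filter(.data$population != "Mean") |>
    dplyr::mutate(ratio_pct = 100, n_selected = .data$n_samples) |>
    dplyr::select("population", "ratio_pct", "n_selected", "he", "pic", "pi")
  out <- dplyr::arrange(dplyr::bind_rows(rows, baseline),
                        .data$population, .data$ratio_pct)
  structure(out, class = c("ratio_sweep", class(out)))
}

#' Recommend a sampling ratio from a sweep
#'
#' Returns the smallest ratio at which every group retains at least
#' `min_retention` of each of He, PIC and pi relative to its own 100%
#' baseline row — the minimise-size-subject-to-diversity rule. If no
#' ratio qualifies, the ratio with the highest mean retention is
#' returned with a warning.
#'
#' @param sweep a [sweep_ratios()] table (or any tibble with
#'   `population`, `ratio_pct`, `he`, `pic`, `pi` including 100% rows).
#' @param min_retention minimum acceptable retention as a fraction.
#' @return The recommended ratio in percent (e.g. `10`).
#' @export
recommend_ratio <- function(sweep, min_retention = 0.95) {
  stopifnot(nrow(sweep) > 0)
  baseline <- sweep |>
    dplyr::filter(.data$ratio_pct == 100) |>
    dplyr::select("population", base_he = "he", base_pic = "pic", base_pi = "pi")
  cand <- sweep |>
    dplyr::filter(.data$ratio_pct < 100) |>
    dplyr::inner_join(baseline, by = "population") |>
    dplyr::mutate(
      min_ret = pmin(.data$he / .data$base_he, .data$pic / .data$base_pic,
                     .data$pi / .data$base_pi)
    ) |>
    dplyr::group_by(.data$ratio_pct) |>
    dplyr::summarise(worst = min(.data$min_ret), mean_ret = mean(.data$min_ret),
                     .groups = "drop")
  ok <- cand$ratio_pct[cand$worst >= min_retention]
  if (length(ok) > 0) return(min(ok))
  warn("no ratio meets the retention threshold; returning the best-retaining ratio")
  cand$ratio_pct[which.max(cand$mean_ret)]
}
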
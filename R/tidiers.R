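# broom-style tidiers for fitted objects.

#' Tidy an admixture fit
#'
#' @param x an `admixture_fit`.
#' @param ... unused.
#' @return A long tibble: `sample`, `cluster`, `proportion`.
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  as_tibble(x$Q) |>
    dplyr::mutate(sample = rownames(x$Q), .before = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "cluster",
                        values_to = "proportion")
}

#' @rdname tidy.admixture_fit
#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n_iter = x$n_iter,
         converged = x$converged, n_samples = x$n_samples, n_loci = x$n_loci)
}

#' Tidy a PCA result
#'
#' @param x a `pca_result`.
#' @param ... unused.
#' @return A long tibble: `sample`, `component`, `score`.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample", names_to = "component",
                      values_to = "score")
}

#' @rdname tidy.pca_result
#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_components = length(x$explained), n_loci = length(x$loci_used),
         pc1_pct = x$explained[1],
         pc2_pct = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Glance at an Evanno delta-K table
#'
#' @param x an `evanno_dk` tibble.
#' @param ... unused.
#' @return One row: `best_k`, `max_delta_k`, `k_min`, `k_max`.
#' @method glance evanno_dk
#' @export
glance.evanno_dk <- function(x, ...) {
  tibble(
    best_k = best_k(x),
    max_delta_k = if (all(is.na(x$delta_k))) NA_real_ else max(x$delta_k, na.rm = TRUE),
    k_min = min(x$k), k_max = max(x$k)
  )
}
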
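# Maximum-likelihood admixture model (EM) and Evanno delta-K selection.
#
# Each individual i carries ancestry proportions q_i over K source
# populations with allele frequencies p_lk; the two allele draws at a
# locus are independent Bernoulli(sum_k q_ik p_lk). The EM fit plays the
# role STRUCTURE's MCMC plays in classical germplasm studies: the
# maximised log-likelihood per (K, replicate) feeds the Evanno delta-K
# statistic, and the Q matrix gives the membership proportions.

EPS_P <- 1e-9

split_counts <- function(panel) {
  G <- panel$G
  called <- G != 9L
  a <- ifelse(called, G, 0L)        # alt-allele counts
  a[a == 9L] <- 0L
  b <- ifelse(called, 2L - G, 0L)   # ref-allele counts
  list(a = a, b = b, called = called)
}

#' Admixture-model log-likelihood
#'
#' `L = sum over called (i, l) of g_il * log(sum_k q_ik p_lk) +
#' (2 - g_il) * log(sum_k q_ik (1 - p_lk))`, treating the two allele
#' draws as independent. Missing genotypes contribute nothing; a panel
#' with no called genotypes has log-likelihood 0. Mixture frequencies
#' are clamped to `[1e-9, 1 - 1e-9]`, with a message when clamping is
#' exercised under a nonzero allele count.
#'
#' @param panel a [genotype_panel()].
#' @param Q samples x K ancestry-proportion matrix (rows sum to 1).
#' @param P loci x K allele-frequency matrix.
#' @return The log-likelihood (scalar).
#' @export
admixture_loglik <- function(panel, Q, P) {
  cs <- split_counts(panel)
  stopifnot(nrow(Q) == n_samples(panel), nrow(P) == n_loci(panel),
            ncol(Q) == ncol(P))
  M <- Q %*% t(P)
  clamped <- (M < EPS_P & cs$a > 0) | (M > 1 - EPS_P & cs$b > 0)
  if (any(clamped)) {
    inform(sprintf("clamped %d boundary mixture frequencies", sum(clamped)))
  }
  M <- pmin(pmax(M, EPS_P), 1 - EPS_P)
  sum(cs$a * log(M) + cs$b * log1p(-M))
}

#' Fit the admixture model by EM
#'
#' From a seeded random start (Dirichlet(1) rows for Q, uniform P), runs
#' the standard EM updates for the independent-allele-frequency
#' admixture model. The log-likelihood is non-decreasing across
#' iterations; iteration stops when the improvement drops below `tol` or
#' at `max_iter`. For `K = 1` the fit closes in a single M step (Q all
#' ones, P the observed frequencies).
#'
#' @param panel a [genotype_panel()].
#' @param k number of source populations (`1 <= k <=` sample count).
#' @param seed integer seed for the random start.
#' @param max_iter maximum EM iterations.
#' @param tol absolute log-likelihood improvement below which iteration
#'   stops.
#' @return An object of class `admixture_fit`: `k`, `Q`, `P`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `seed`.
#' @export
fit_admixture <- function(panel, k, seed = 1, max_iter = 2000, tol = 1e-6) {
  if (k < 1 || k > n_samples(panel)) {
    abort("k must be between 1 and the number of samples",
          class = "heveacore_error_config")
  }
  cs <- split_counts(panel)
  n <- n_samples(panel); L <- n_loci(panel)
  withr::with_seed(seed, {
    Q <- matrix(rgamma(n * k, 1), n, k)
    Q <- Q / rowSums(Q)
    P <- matrix(runif(L * k, 0.05, 0.95), L, k)
  })
  two_called <- 2 * rowSums(cs$called)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    M <- pmin(pmax(Q %*% t(P), EPS_P), 1 - EPS_P)
    ll_new <- sum(cs$a * log(M) + cs$b * log1p(-M))
    trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
    Astar <- cs$a / M
    Bstar <- cs$b / (1 - M)
    Qn <- Q * (Astar %*% P + Bstar %*% (1 - P))
    rs <- rowSums(Qn)
    Q <- Qn / ifelse(rs > 0, rs, 1)
    Q[rs == 0, ] <- 1 / k   # fully missing samples stay uninformative
    alt_mass <- P * (t(Astar) %*% Q)
    ref_mass <- (1 - P) * (t(Bstar) %*% Q)
    tot <- alt_mass + ref_mass
    P <- ifelse(tot > 0, alt_mass / tot, 0.5)
    P <- matrix(pmin(pmax(P, EPS_P), 1 - EPS_P), L, k)
  }
  dimnames(Q) <- list(panel$samples, paste0("Q", seq_len(k)))
  dimnames(P) <- list(panel$loci$locus_id, paste0("Q", seq_len(k)))
  structure(
    list(k = k, Q = Q, P = P, loglik = ll, loglik_trace = trace,
         n_iter = it, converged = converged, seed = seed,
         n_samples = n, n_loci = L),
    class = "admixture_fit"
  )
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, loglik = %.3f, %d iterations%s\n",
              x$k, x$loglik, x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' Evanno delta-K table
#'
#' Given replicate model-fit scores per K, computes the Evanno
#' statistics: `mean_l` and `sd_l` over replicates,
#' `l_prime(K) = mean_l(K) - mean_l(K-1)`,
#' `abs_l_second(K) = |l_prime(K+1) - l_prime(K)|` and
#' `delta_k = abs_l_second / sd_l`. `delta_k` is defined only at
#' interior K values. Zero replicate standard deviation yields `NA`
#' with a warning. `best_k` (attribute and [glance()]) is the interior K
#' maximising delta-K, `NA` when no finite delta-K exists (e.g. scores
#' perfectly linear in K).
#'
#' @param logliks either a data frame with columns `k` and `loglik` (one
#'   row per replicate) or a named list mapping K to replicate
#'   log-likelihood vectors. K values must form a consecutive grid with
#'   at least 3 levels and >= 2 replicates at interior K.
#' @return A tibble of class `evanno_dk` with columns `k`, `n_rep`,
#'   `mean_l`, `sd_l`, `l_prime`, `abs_l_second`, `delta_k`; attribute
#'   `best_k`.
#' @export
evanno_delta_k <- function(logliks) {
  if (!inherits(logliks, "data.frame")) {
    logliks <- purrr::imap_dfr(logliks, ~ tibble(k = as.integer(.y), loglik = .x))
  }
  stopifnot(all(c("k", "loglik") %in% names(logliks)))
  by_k <- logliks |>
    dplyr::group_by(k = as.integer(.data$k)) |>
    dplyr::summarise(n_rep = dplyr::n(),
                     mean_l = mean(.data$loglik),
                     sd_l = sd(.data$loglik), .groups = "drop") |>
    dplyr::arrange(.data$k)
  ks <- by_k$k
  if (length(ks) < 3) abort("need >= 3 K values", class = "heveacore_error_config")
  if (!all(diff(ks) == 1)) {
    abort("K grid must be consecutive", class = "heveacore_error_config")
  }
  interior <- seq(2, length(ks) - 1)
  if (any(by_k$n_rep[interior] < 2)) {
    abort("need >= 2 replicates at interior K values",
          class = "heveacore_error_config")
  }
  l_prime <- c(NA, diff(by_k$mean_l))
  abs_l_second <- c(NA, abs(diff(l_prime[-1])), NA)
  delta_k <- abs_l_second / by_k$sd_l
  delta_k[c(1, length(ks))] <- NA
  if (any(by_k$sd_l[interior] == 0, na.rm = TRUE)) {
    warn("zero replicate standard deviation at some K; delta-K set to NA there")
    delta_k[by_k$sd_l == 0] <- NA
  }
  out <- by_k |>
    dplyr::mutate(l_prime = l_prime, abs_l_second = abs_l_second,
                  delta_k = delta_k)
  best_k <- if (all(is.na(delta_k)) || max(delta_k, na.rm = TRUE) == 0) {
    NA_integer_
  } else {
    ks[which.max(delta_k)]
  }
  structure(out, class = c("evanno_dk", class(out)), best_k = best_k)
}

#' @rdname evanno_delta_k
#' @param x an `evanno_dk` table.
#' @export
best_k <- function(x) attr(x, "best_k")

#' Replicate admixture fits across a K grid
#'
#' Fits the EM admixture model for every K in `k_min:k_max` with
#' `n_reps` replicate random starts per K (replicate seeds derived
#' deterministically from `seed`), and assembles the Evanno delta-K
#' table from the maximised log-likelihoods.
#'
#' @param panel a [genotype_panel()].
#' @param k_min,k_max K grid bounds.
#' @param n_reps replicates per K.
#' @param seed master seed.
#' @param max_iter,tol passed to [fit_admixture()]. The scan defaults are
#'   looser than a single fit's (500 iterations, tol 1e-4): the delta-K
#'   statistic depends on between-K likelihood differences that are
#'   orders of magnitude larger than the EM tail, so model-selection
#'   runs need not be converged to 1e-6.
#' @return A list of class `admixture_scan`: `logliks` tibble
#'   (`k`, `rep`, `seed`, `loglik`, `converged`), `delta_k`
#'   ([evanno_delta_k()] table), `best_fit` (highest-likelihood fit at
#'   the selected K, or at `k_max`'s best when delta-K is undefined) and
#'   `fits` (all replicate fits).
#' @export
admixture_scan <- function(panel, k_min = 1, k_max = 5, n_reps = 5, seed = 1,
                           max_iter = 500, tol = 1e-4) {
  grid <- expand.grid(rep = seq_len(n_reps), k = k_min:k_max)
  fits <- purrr::map(seq_len(nrow(grid)), function(i) {
    k <- grid$k[i]; r <- grid$rep[i]
    fit_admixture(panel, k,
                  seed = stage_seed(seed, sprintf("admixture_k%d_rep%d", k, r)),
                  max_iter = max_iter, tol = tol)
  })
  logliks <- tibble(
    k = grid$k, rep = grid$rep,
    seed = vapply(fits, `[[`, integer(1), "seed"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  dk <- evanno_delta_k(logliks[c("k", "loglik")])
  kb <- best_k(dk)
  k_star <- if (is.na(kb)) k_max else kb
  cand <- which(grid$k == k_star)
  best_fit <- fits[[cand[which.max(logliks$loglik[cand])]]]
  structure(list(logliks = logliks, delta_k = dk, best_fit = best_fit,
                 fits = fits),
            class = "admixture_scan")
}

#' @export
print.admixture_scan <- function(x, ...) {
  cat(sprintf("<admixture_scan> K = %d..%d, %d replicates each; best K = %s\n",
              min(x$logliks$k), max(x$logliks$k), max(x$logliks$rep),
              as.character(best_k(x$delta_k))))
  invisible(x)
}

#' Membership report from an admixture fit
#'
#' Per-sample ancestry proportions with the hard group call
#' (`argmax` column of Q), sorted by group and then by decreasing
#' membership — the usual layout of a STRUCTURE-style membership
#' barplot. Invariant under column permutations of Q.
#'
#' @param fit an `admixture_fit`.
#' @return A tibble: `sample`, `Q1..Qk`, `group`, `membership`.
#' @export
structure_report <- function(fit) {
  Q <- fit$Q
  group <- max.col(Q, ties.method = "first")
  out <- dplyr::bind_cols(
    tibble(sample = rownames(Q)), as_tibble(Q),
    tibble(group = group, membership = Q[cbind(seq_len(nrow(Q)), group)])
  )
  dplyr::arrange(out, .data$group, dplyr::desc(.data$membership))
}
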
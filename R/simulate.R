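#' Simulation configuration for synthetic genotype panels
#'
#' Defines the shape of a simulated diploid SNP panel: subpopulation
#' sizes, number of biallelic loci, divergence between subpopulations
#' under the Balding–Nichols model, optional Dirichlet admixture, and a
#' missing-data process. Defaults mirror a typical germplasm resequencing
#' panel with two unequal subpopulations (169 and 26 accessions), 99
#' loci, modest divergence and sparse missingness.
#'
#' @param n_samples_per_pop integer vector of subpopulation sizes.
#' @param n_loci number of biallelic loci.
#' @param fst Balding–Nichols divergence parameter in `[0, 1)`; `0`
#'   collapses all subpopulations onto the ancestral frequencies.
#' @param maf_floor minimum ancestral minor-allele frequency in
#'   `(0, 0.5]`; ancestral frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @param admixture_alpha Dirichlet concentration for individual ancestry
#'   proportions; `0` gives unadmixed individuals (one-hot ancestry).
#' @param missing_rate per-genotype probability of a missing call (MCAR).
#' @param n_fully_missing_samples number of samples whose genotypes are
#'   all set missing, emulating a failed library.
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @param chrom_length length in bp of the single synthetic chromosome on
#'   which strictly increasing positions are drawn.
#' @param depth_mean if non-`NULL`, Poisson mean for a simulated
#'   per-genotype DP matrix.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples_per_pop = c(169, 26), n_loci = 99, fst = 0.05,
                       maf_floor = 0.1, admixture_alpha = 0, missing_rate = 0.03,
                       n_fully_missing_samples = 0, seed = 1,
                       chrom_length = 2.5e8, depth_mean = NULL) {
  stopifnot(
    length(n_samples_per_pop) >= 1, all(n_samples_per_pop >= 1),
    n_loci >= 1,
    fst >= 0, maf_floor > 0, maf_floor <= 0.5,
    admixture_alpha >= 0, missing_rate >= 0, missing_rate < 1,
    n_fully_missing_samples >= 0, chrom_length >= n_loci
  )
  if (fst >= 1) {
    abort("fst must be in [0, 1)", class = "heveacore_error_config")
  }
  if (n_fully_missing_samples >= sum(n_samples_per_pop)) {
    abort("n_fully_missing_samples must be smaller than the total sample count",
          class = "heveacore_error_config")
  }
  structure(
    list(
      n_samples_per_pop = as.integer(n_samples_per_pop), n_loci = as.integer(n_loci),
      fst = fst, maf_floor = maf_floor, admixture_alpha = admixture_alpha,
      missing_rate = missing_rate,
      n_fully_missing_samples = as.integer(n_fully_missing_samples),
      seed = as.integer(seed), chrom_length = chrom_length, depth_mean = depth_mean
    ),
    class = "sim_config"
  )
}

#' Simulate a genotype panel with known ground truth
#'
#' Draws, per locus, an ancestral allele frequency uniform on
#' `[maf_floor, 1 - maf_floor]`; per subpopulation `k`, a derived
#' frequency from the Balding–Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst` (for `fst = 0` the
#' ancestral frequency is used unchanged). Each individual's genotype at
#' a locus is `Binomial(2, sum_k q_ik p_lk)` where `q_i` is the
#' individual's ancestry vector — one-hot for `admixture_alpha = 0`,
#' otherwise symmetric-Dirichlet. Missing calls (code 9) are injected
#' MCAR at `missing_rate`, and `n_fully_missing_samples` randomly chosen
#' samples are blanked entirely.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and
#'   `truth` (a `ground_truth` list: `pop_labels`, `q_true`, `p_anc`,
#'   `p_pop`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- length(config$n_samples_per_pop)
  n <- sum(config$n_samples_per_pop)
  L <- config$n_loci
  withr::with_seed(config$seed, {
    pos <- sort(sample.int(config$chrom_length, L))
    p_anc <- runif(L, config$maf_floor, 1 - config$maf_floor)
    if (config$fst > 0 && K > 1) {
      Fst <- config$fst
      p_pop <- vapply(seq_len(K), function(k) {
        rbeta(L, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
      }, numeric(L))
    } else {
      p_pop <- matrix(rep(p_anc, K), ncol = K)
    }
    pop_labels <- rep(seq_len(K), config$n_samples_per_pop)
    if (config$admixture_alpha > 0) {
      g <- matrix(rgamma(n * K, shape = config$admixture_alpha), nrow = n)
      q_true <- g / rowSums(g)
    } else {
      q_true <- matrix(0, n, K)
      q_true[cbind(seq_len(n), pop_labels)] <- 1
    }
    prob <- q_true %*% t(p_pop)        # n x L expected alt-allele frequency
    G <- matrix(rbinom(n * L, 2, prob), n, L)
    if (config$missing_rate > 0) {
      G[runif(n * L) < config$missing_rate] <- 9L
    }
    if (config$n_fully_missing_samples > 0) {
      blank <- sample.int(n, config$n_fully_missing_samples)
      G[blank, ] <- 9L
    }
    DP <- NULL
    if (!is.null(config$depth_mean)) {
      DP <- matrix(rpois(n * L, config$depth_mean), n, L)
    }
    # random ref/alt bases per locus
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  })
  loci <- tibble(
    locus_id = sprintf("snp%03d", seq_len(L)), chrom = "chr1",
    pos = as.integer(pos), ref = ref, alt = unname(alt)
  )
  samples <- sprintf("acc%03d", seq_len(n))
  panel <- genotype_panel(G, loci, sample_ids = samples, DP = DP)
  truth <- structure(
    list(
      pop_labels = setNames(pop_labels, samples),
      q_true = matrix(q_true, n, K, dimnames = list(samples, paste0("pop", seq_len(K)))),
      p_anc = setNames(p_anc, loci$locus_id),
      p_pop = matrix(p_pop, L, K, dimnames = list(loci$locus_id, paste0("pop", seq_len(K))))
    ),
    class = "ground_truth"
  )
  list(panel = panel, truth = truth)
}

#' Write / read simulation ground truth as TSV
#'
#' Two tab-separated tables are written: `<prefix>_samples.tsv` (sample,
#' subpopulation label, ancestry proportions) and `<prefix>_loci.tsv`
#' (locus, ancestral and per-subpopulation allele frequencies). Values
#' round-trip losslessly to at least 12 decimals.
#'
#' @param truth a `ground_truth` as returned by [simulate_panel()].
#' @param path_prefix path prefix for the two TSV files.
#' @return The file paths, invisibly.
#' @export
write_truth <- function(truth, path_prefix) {
  samples <- tibble(
    sample = names(truth$pop_labels),
    pop_label = unname(truth$pop_labels)
  )
  samples <- dplyr::bind_cols(samples, as_tibble(truth$q_true))
  loci <- tibble(locus_id = names(truth$p_anc), p_anc = unname(truth$p_anc))
  loci <- dplyr::bind_cols(loci, as_tibble(truth$p_pop, .name_repair = ~ paste0("p_", .x)))
  f1 <- paste0(path_prefix, "_samples.tsv")
  f2 <- paste0(path_prefix, "_loci.tsv")
  fmt <- function(df) dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ sprintf("%.15g", .x)))
  readr::write_tsv(fmt(samples), f1)
  readr::write_tsv(fmt(loci), f2)
  invisible(c(f1, f2))
}

#' @rdname write_truth
#' @export
read_truth <- function(path_prefix) {
  samples <- readr::read_tsv(paste0(path_prefix, "_samples.tsv"),
                             show_col_types = FALSE)
  loci <- readr::read_tsv(paste0(path_prefix, "_loci.tsv"), show_col_types = FALSE)
  qcols <- grep("^pop[0-9]+$", names(samples), value = TRUE)
  pcols <- grep("^p_pop", names(loci), value = TRUE)
  structure(
    list(
      pop_labels = setNames(as.integer(samples$pop_label), samples$sample),
      q_true = as.matrix(samples[qcols]) |>
        `dimnames<-`(list(samples$sample, qcols)),
      p_anc = setNames(loci$p_anc, loci$locus_id),
      p_pop = as.matrix(loci[pcols]) |>
        `dimnames<-`(list(loci$locus_id, sub("^p_", "", pcols)))
    ),
    class = "ground_truth"
  )
}
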
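#' Allele counts at a locus
#'
#' Counts reference and alternate alleles from coded genotypes. Each
#' code-0 sample contributes two reference alleles, code-2 two alternate
#' alleles, code-1 one of each; missing calls (9) contribute nothing.
#'
#' @param g integer vector of codes in `{0, 1, 2, 9}`.
#' @return Named integer vector `c(n_ref, n_alt)`.
#' @export
#' @examples
#' allele_counts(c(0, 1, 2))  # 3 ref, 3 alt
allele_counts <- function(g) {
  check_codes(g)
  n_ref <- 2L * sum(g == 0L) + sum(g == 1L)
  n_alt <- 2L * sum(g == 2L) + sum(g == 1L)
  if (n_ref + n_alt == 0L) {
    abort("all genotypes missing: allele frequencies undefined",
          class = "heveacore_error_allmissing")
  }
  c(n_ref = n_ref, n_alt = n_alt)
}

#' Expected heterozygosity (gene diversity)
#'
#' `He = 1 - sum(p_i^2)`, which for a biallelic locus is `2p(1-p)`: the
#' probability that two alleles drawn at random (with replacement) from
#' the population differ. No small-sample correction is applied.
#'
#' @param p alternate-allele frequency (vectorised).
#' @return Expected heterozygosity in `[0, 0.5]` for biallelic loci.
#' @export
expected_heterozygosity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Polymorphism information content (Botstein)
#'
#' Biallelic form of `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`:
#' `1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`. Maximum 0.375 at
#' `p = 0.5`.
#'
#' @param p alternate-allele frequency (vectorised).
#' @return PIC in `[0, 0.375]`.
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Site nucleotide diversity from allele counts
#'
#' Average pairwise difference among the called alleles at one site:
#' `pi = n_ref * n_alt / choose(n, 2)` with `n = n_ref + n_alt`. This is
#' the per-site pi reported by VCFtools and equals `(n/(n-1)) * He`, so
#' it slightly exceeds He in finite samples (e.g. 0.5013 vs 0.5000 at
#' `p = 0.5` with 195 fully-called diploids).
#'
#' @param n_ref,n_alt called reference / alternate allele counts.
#' @return Nucleotide diversity.
#' @export
nucleotide_diversity <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  if (any(n < 2)) {
    abort("need at least 2 called alleles to compute pi",
          class = "heveacore_error_lowcount")
  }
  n_ref * n_alt / choose(n, 2)
}

#' Per-locus diversity table
#'
#' Computes, for every locus of a panel, the called-allele counts,
#' alternate-allele frequency, minor-allele frequency, expected
#' heterozygosity, PIC, site nucleotide diversity and missing rate.
#' Loci with no called genotypes are reported with `NA` statistics and a
#' warning. Statistics are kept at full precision; round only when
#' reporting (conventionally 4 decimals).
#'
#' @param panel a [genotype_panel()].
#' @return A tibble with one row per locus.
#' @export
locus_table <- function(panel) {
  G <- panel$G
  called <- G != 9L
  n_called <- 2L * colSums(called)
  alt <- colSums((G == 1L) + 2L * (G == 2L))
  p <- ifelse(n_called > 0, alt / n_called, NA_real_)
  he <- expected_heterozygosity(p)
  pic_v <- pic(p)
  pi_v <- ifelse(n_called >= 2, alt * (n_called - alt) / choose(n_called, 2), NA_real_)
  if (any(n_called == 0)) {
    warn(sprintf("%d locus/loci with no called genotypes: statistics set to NA",
                 sum(n_called == 0)))
  }
  tibble(
    locus_id = panel$loci$locus_id,
    chrom = panel$loci$chrom,
    pos = panel$loci$pos,
    n_called_alleles = as.integer(n_called),
    p = unname(p),
    maf = unname(pmin(p, 1 - p)),
    he = unname(he),
    pic = unname(pic_v),
    pi = unname(pi_v),
    missing_rate = unname(colMeans(!called))
  )
}

#' Per-population diversity summaries
#'
#' Splits the panel by group label, re-estimates allele frequencies
#' within each group, and summarises He, PIC and pi across loci (mean,
#' min, max, unweighted over loci). A final `Mean` row holds the
#' unweighted mean of the group values. Groups with fewer than two
#' samples are still summarised but flagged `low_n`.
#'
#' @param panel a [genotype_panel()].
#' @param group_labels vector of group labels, one per sample, optionally
#'   named by sample id (names are matched to the panel when present).
#' @return A tibble with one row per group plus a `Mean` row.
#' @export
population_summary <- function(panel, group_labels) {
  labels <- align_labels(panel, group_labels)
  groups <- sort(unique(as.character(labels)))
  rows <- purrr::map_dfr(groups, function(g) {
    sub <- panel_subset(panel, samples = which(labels == g))
    lt <- suppressWarnings(locus_table(sub))
    tibble(
      population = g,
      n_samples = n_samples(sub),
      n_loci = sum(!is.na(lt$he)),
      low_n = n_samples(sub) < 2,
      he = mean(lt$he, na.rm = TRUE),
      he_min = min(lt$he, na.rm = TRUE), he_max = max(lt$he, na.rm = TRUE),
      pic = mean(lt$pic, na.rm = TRUE),
      pic_min = min(lt$pic, na.rm = TRUE), pic_max = max(lt$pic, na.rm = TRUE),
      pi = mean(lt$pi, na.rm = TRUE),
      pi_min = min(lt$pi, na.rm = TRUE), pi_max = max(lt$pi, na.rm = TRUE)
    )
  })
  if (any(rows$low_n)) {
    warn(paste0("group(s) with < 2 samples: ",
                paste(rows$population[rows$low_n], collapse = ", ")))
  }
  mean_row <- rows |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean)) |>
    dplyr::mutate(population = "Mean", low_n = FALSE,
                  n_samples = sum(rows$n_samples), n_loci = max(rows$n_loci))
  dplyr::bind_rows(rows, mean_row)
}

align_labels <- function(panel, group_labels) {
  if (inherits(group_labels, "data.frame")) {
    stopifnot(all(c("sample", "group") %in% names(group_labels)))
    group_labels <- setNames(group_labels$group, group_labels$sample)
  }
  if (!is.null(names(group_labels))) {
    pos <- match(panel$samples, names(group_labels))
    if (anyNA(pos)) {
      abort("group_labels names do not cover all panel samples",
            class = "heveacore_error_labels")
    }
    group_labels <- group_labels[pos]
  }
  if (length(group_labels) != n_samples(panel)) {
    abort("need one group label per sample", class = "heveacore_error_labels")
  }
  as.character(group_labels)
}

#' Diversity retention of a core subset
#'
#' Expresses each core-subset statistic as a percentage of the original
#' population's value: `100 * core / original` for He, PIC and pi,
#' matched by population label. Values above 100% indicate the core
#' subset is more diverse than the full collection (common when
#' redundant accessions are removed).
#'
#' @param core,original tibbles as returned by [population_summary()] (or
#'   any tibble with `population`, `he`, `pic`, `pi` columns).
#' @return A tibble of retention percentages per population.
#' @export
retention_rate <- function(core, original) {
  if (!setequal(core$population, original$population)) {
    abort("core and original summaries cover different populations",
          class = "heveacore_error_labels")
  }
  joined <- dplyr::inner_join(
    dplyr::select(core, "population", core_he = "he", core_pic = "pic", core_pi = "pi"),
    dplyr::select(original, "population", orig_he = "he", orig_pic = "pic", orig_pi = "pi"),
    by = "population"
  )
  ratio <- function(a, b) {
    out <- ifelse(b == 0, NA_real_, 100 * a / b)
    if (any(b == 0, na.rm = TRUE)) warn("original statistic is 0; retention set to NA")
    out
  }
  tibble(
    population = joined$population,
    he_retention = ratio(joined$core_he, joined$orig_he),
    pic_retention = ratio(joined$core_pic, joined$orig_pic),
    pi_retention = ratio(joined$core_pi, joined$orig_pi)
  )
}
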
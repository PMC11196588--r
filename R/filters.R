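# Sample/variant/panel-design filters with an auditable report.

new_filter_report <- function(step, samples_in, samples_out,
                              removed_samples, loci_in, loci_out, removed_loci) {
  rep <- list(
    step = step,
    n_samples_in = samples_in, n_samples_out = samples_out,
    n_loci_in = loci_in, n_loci_out = loci_out,
    removed_samples = removed_samples, # tibble: id, reason
    removed_loci = removed_loci        # tibble: id, reason
  )
  stopifnot(
    samples_in == samples_out + nrow(removed_samples),
    loci_in == loci_out + nrow(removed_loci)
  )
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s>\n  samples: %d -> %d (%d removed)\n  loci:    %d -> %d (%d removed)\n",
              x$step, x$n_samples_in, x$n_samples_out, nrow(x$removed_samples),
              x$n_loci_in, x$n_loci_out, nrow(x$removed_loci)))
  invisible(x)
}

# Per-locus summaries on coded genotypes (9 excluded from denominators).
locus_missing_rate <- function(G) colMeans(G == 9L)

locus_maf <- function(G) {
  called <- G != 9L
  alt <- colSums((G == 1L) + 2L * (G == 2L))
  tot <- 2L * colSums(called)
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  pmin(p, 1 - p)
}

#' Remove samples with excessive missingness
#'
#' Drops any sample whose fraction of missing genotype calls (code 9)
#' exceeds `max_sample_missing`. The default `0.999` removes only samples
#' with no usable calls at all (a fully failed library), matching the
#' common practice of excluding 100%-deletion samples while keeping
#' everything else for locus-level filtering.
#'
#' @param panel a [genotype_panel()].
#' @param max_sample_missing maximum tolerated missing fraction, in (0, 1].
#' @return A list with elements `panel` (filtered) and `report`
#'   (a `filter_report`).
#' @export
filter_samples <- function(panel, max_sample_missing = 0.999) {
  stopifnot(max_sample_missing > 0, max_sample_missing <= 1)
  miss <- rowMeans(panel$G == 9L)
  drop <- miss > max_sample_missing
  if (all(drop)) {
    abort("all samples removed by missingness filter",
          class = "heveacore_error_empty")
  }
  removed <- tibble(
    id = panel$samples[drop],
    reason = sprintf("missing fraction %.3f > %.3f", miss[drop], max_sample_missing)
  )
  out <- panel_subset(panel, samples = which(!drop))
  list(
    panel = out,
    report = new_filter_report(
      "filter_samples", n_samples(panel), n_samples(out), removed,
      n_loci(panel), n_loci(out), tibble(id = character(), reason = character())
    )
  )
}

#' Variant-level quality filtering
#'
#' Mirrors a standard post-genotyping filter: individual genotype calls
#' with depth below `min_depth` are masked to missing first, then loci
#' are dropped when their missing fraction exceeds `max_locus_missing` or
#' their minor-allele frequency (over non-missing alleles) falls below
#' `min_af`. Thresholds are inclusive on the keep side (depth >= 20,
#' missing <= 10%, MAF >= 5% survive at the defaults).
#'
#' @param panel a [genotype_panel()].
#' @param min_depth minimum per-genotype depth; calls below it become
#'   missing. Requires a DP matrix when positive; use `0` for panels
#'   without depths.
#' @param max_locus_missing maximum tolerated per-locus missing fraction.
#' @param min_af minimum minor-allele frequency.
#' @return A list with `panel` and `report`, as [filter_samples()].
#' @export
filter_variants <- function(panel, min_depth = 20, max_locus_missing = 0.10,
                            min_af = 0.05) {
  stopifnot(min_depth >= 0, max_locus_missing >= 0, max_locus_missing <= 1,
            min_af >= 0, min_af <= 0.5)
  G <- panel$G
  if (min_depth > 0) {
    if (is.null(panel$DP)) {
      abort("min_depth > 0 requires a DP matrix; pass min_depth = 0 for depth-free panels",
            class = "heveacore_error_dp")
    }
    G[is.na(panel$DP) | panel$DP < min_depth] <- 9L
  }
  masked <- genotype_panel(G, panel$loci, panel$samples, DP = panel$DP)
  miss <- locus_missing_rate(G)
  maf <- locus_maf(G)
  reason <- rep(NA_character_, ncol(G))
  reason[!is.na(maf) & maf < min_af] <- sprintf("MAF %.4f < %.4f", maf[!is.na(maf) & maf < min_af], min_af)
  reason[miss > max_locus_missing] <- sprintf("missing fraction %.3f > %.3f",
                                              miss[miss > max_locus_missing], max_locus_missing)
  reason[is.na(maf) & is.na(reason)] <- "no called alleles"
  drop <- !is.na(reason)
  if (all(drop)) {
    abort("all loci removed by variant filter", class = "heveacore_error_empty")
  }
  removed <- tibble(id = panel$loci$locus_id[drop], reason = reason[drop])
  out <- panel_subset(masked, loci = which(!drop))
  list(
    panel = out,
    report = new_filter_report(
      "filter_variants", n_samples(panel), n_samples(out),
      tibble(id = character(), reason = character()),
      n_loci(panel), n_loci(out), removed
    )
  )
}

#' Select well-spaced, highly informative panel loci
#'
#' Marker-panel design filter: keeps loci with minor-allele frequency
#' strictly above `min_maf` and missing fraction strictly below
#' `max_missing`, then enforces a minimum physical spacing by a greedy
#' left-to-right scan within each chromosome — a locus is kept only if it
#' lies at least `min_spacing_bp` beyond the last kept locus.
#'
#' Note the strict inequalities: this is a design screen (e.g. MAF > 0.3,
#' missing < 0.5), deliberately different from the calling filter in
#' [filter_variants()].
#'
#' @param panel a [genotype_panel()].
#' @param min_maf MAF must strictly exceed this.
#' @param max_missing missing fraction must be strictly below this.
#' @param min_spacing_bp minimum base-pair distance between kept loci.
#' @return A list with `panel` and `report`.
#' @export
select_panel_loci <- function(panel, min_maf = 0.3, max_missing = 0.5,
                              min_spacing_bp = 2e6) {
  maf <- locus_maf(panel$G)
  miss <- locus_missing_rate(panel$G)
  reason <- rep(NA_character_, n_loci(panel))
  reason[is.na(maf) | maf <= min_maf] <- sprintf("MAF <= %.3f", min_maf)
  reason[is.na(reason) & miss >= max_missing] <- sprintf("missing fraction >= %.3f", max_missing)
  keep <- is.na(reason)
  # greedy spacing within chromosome, in position order
  last_kept <- list()
  for (l in seq_len(n_loci(panel))) {
    if (!keep[l]) next
    ch <- panel$loci$chrom[l]
    prev <- last_kept[[ch]]
    if (!is.null(prev) && (panel$loci$pos[l] - prev) < min_spacing_bp) {
      keep[l] <- FALSE
      reason[l] <- sprintf("< %d bp from previous kept locus", as.integer(min_spacing_bp))
    } else {
      last_kept[[ch]] <- panel$loci$pos[l]
    }
  }
  if (!any(keep)) {
    abort("no loci pass the panel-design filter", class = "heveacore_error_empty")
  }
  removed <- tibble(id = panel$loci$locus_id[!keep], reason = reason[!keep])
  out <- panel_subset(panel, loci = which(keep))
  list(
    panel = out,
    report = new_filter_report(
      "select_panel_loci", n_samples(panel), n_samples(out),
      tibble(id = character(), reason = character()),
      n_loci(panel), n_loci(out), removed
    )
  )
}

#' Write a filter report to TSV and JSON
#'
#' @param report a `filter_report`.
#' @param path_prefix files `<prefix>.tsv` (removed records) and
#'   `<prefix>.json` (counts) are written.
#' @return The two paths, invisibly.
#' @export
write_filter_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  removed <- dplyr::bind_rows(
    dplyr::mutate(report$removed_samples, kind = "sample"),
    dplyr::mutate(report$removed_loci, kind = "locus")
  )
  readr::write_tsv(removed, tsv)
  jsonlite::write_json(
    report[c("step", "n_samples_in", "n_samples_out", "n_loci_in", "n_loci_out")],
    json, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(tsv, json))
}
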
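#' Genotype panel container
#'
#' A `genotype_panel` holds a samples-by-loci matrix of coded diploid
#' genotypes together with locus metadata. The coding follows the usual
#' SNP-array convention: `0` = homozygous reference (0/0), `1` =
#' heterozygous (0/1), `2` = homozygous alternate (1/1), `9` = missing
#' call. An optional per-genotype sequencing-depth matrix (`DP`) of the
#' same shape may be attached.
#'
#' @param G integer matrix, samples x loci, entries in `{0, 1, 2, 9}`.
#' @param loci data frame with one row per locus and columns `locus_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`. Positions must be
#'   non-decreasing within each chromosome.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from `rownames(G)` when omitted.
#' @param DP optional numeric matrix of per-genotype read depths,
#'   same dimensions as `G`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `G`, `loci` (tibble), `samples` (character) and `DP`.
#' @export
#'
#' @examples
#' G <- rbind(s1 = c(0L, 1L), s2 = c(2L, 9L))
#' loci <- tibble::tibble(locus_id = c("snp1", "snp2"), chrom = "chr1",
#'                        pos = c(100L, 2e6L), ref = "A", alt = "G")
#' genotype_panel(G, loci)
genotype_panel <- function(G, loci, sample_ids = NULL, DP = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  check_codes(G)
  loci <- as_tibble(loci)
  required <- c("locus_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0) {
    abort(paste0("loci is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "heveacore_error_loci")
  }
  if (nrow(loci) != ncol(G)) {
    abort("nrow(loci) must equal ncol(G)", class = "heveacore_error_loci")
  }
  sample_ids <- sample_ids %||% rownames(G) %||% paste0("S", seq_len(nrow(G)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample ids", class = "heveacore_error_samples")
  }
  if (anyDuplicated(loci$locus_id)) {
    abort("duplicate locus ids", class = "heveacore_error_loci")
  }
  unsorted <- loci |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(is.unsorted(.data$pos)) |>
    dplyr::ungroup()
  if (nrow(unsorted) > 0) {
    abort("locus positions must be non-decreasing within each chromosome",
          class = "heveacore_error_loci")
  }
  dimnames(G) <- list(sample_ids, loci$locus_id)
  if (!is.null(DP)) {
    DP <- as.matrix(DP)
    if (!all(dim(DP) == dim(G))) {
      abort("DP must have the same dimensions as G", class = "heveacore_error_dp")
    }
    dimnames(DP) <- dimnames(G)
  }
  structure(
    list(G = G, loci = loci, samples = sample_ids, DP = DP),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(x$G == 9L)
  cat(sprintf(
    "<genotype_panel> %d samples x %d loci (%.1f%% missing%s)\n",
    nrow(x$G), ncol(x$G), 100 * miss,
    if (is.null(x$DP)) "" else ", DP attached"
  ))
  invisible(x)
}

#' Number of samples / loci in a panel
#' @param panel a [genotype_panel()].
#' @return Integer count.
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_loci <- function(panel) nrow(panel$loci)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param samples sample ids or logical/integer index; `NULL` keeps all.
#' @param loci locus ids or logical/integer index; `NULL` keeps all.
#' @return A `genotype_panel` restricted to the requested rows/columns,
#'   preserving order of the index.
#' @export
panel_subset <- function(panel, samples = NULL, loci = NULL) {
  si <- resolve_index(samples, panel$samples, "sample")
  li <- resolve_index(loci, panel$loci$locus_id, "locus")
  genotype_panel(
    panel$G[si, li, drop = FALSE],
    panel$loci[li, , drop = FALSE],
    sample_ids = panel$samples[si],
    DP = if (is.null(panel$DP)) NULL else panel$DP[si, li, drop = FALSE]
  )
}

resolve_index <- function(idx, universe, what) {
  if (is.null(idx)) return(seq_along(universe))
  if (is.character(idx)) {
    pos <- match(idx, universe)
    if (anyNA(pos)) {
      abort(sprintf("unknown %s id(s): %s", what,
                    paste(idx[is.na(pos)], collapse = ", ")),
            class = "heveacore_error_index")
    }
    return(pos)
  }
  seq_along(universe)[idx]
}
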
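# SNP fingerprinting: greedy selection of a maximally discriminating
# locus subset, digit-code encoding, collision audit and QR payloads.

#' Select fingerprint loci
#'
#' Greedy forward selection of up to `n_max` loci that jointly
#' distinguish the samples. Selection starts from the highest-PIC locus;
#' each subsequent step adds the locus that maximally reduces the number
#' of sample pairs whose partial digit codes are still identical (ties
#' broken by higher PIC, then by locus order). Selection stops when all
#' pairs are resolved or `n_max` loci have been chosen.
#'
#' @param panel a [genotype_panel()].
#' @param n_max maximum number of loci (20 gives the classic 20-digit
#'   fingerprint).
#' @return A list of class `fp_selection`: `loci` (ids in selection
#'   order), `n_unresolved` (sample pairs still sharing a code) and
#'   `resolved` (logical).
#' @export
select_fingerprint_loci <- function(panel, n_max = 20) {
  lt <- suppressWarnings(locus_table(panel))
  if (all(is.na(lt$pic)) || all(lt$pic == 0, na.rm = TRUE)) {
    abort("panel has no polymorphic locus", class = "heveacore_error_empty")
  }
  pic_v <- ifelse(is.na(lt$pic), -Inf, lt$pic)
  n <- n_samples(panel)
  unresolved_pairs <- function(key) {
    sizes <- table(key)
    sum(choose(sizes, 2))
  }
  key <- rep("", n)
  chosen <- integer(0)
  current <- unresolved_pairs(key)
  candidates <- seq_len(n_loci(panel))
  while (length(chosen) < n_max && current > 0) {
    remaining <- setdiff(candidates, chosen)
    if (length(remaining) == 0) break
    new_unres <- vapply(remaining, function(l) {
      unresolved_pairs(paste(key, panel$G[, l]))
    }, numeric(1))
    ord <- order(new_unres, -pic_v[remaining], remaining)
    pick <- remaining[ord[1]]
    chosen <- c(chosen, pick)
    key <- paste(key, panel$G[, pick])
    current <- unresolved_pairs(key)
  }
  structure(
    list(loci = panel$loci$locus_id[chosen], n_unresolved = as.integer(current),
         resolved = current == 0),
    class = "fp_selection"
  )
}

#' @export
print.fp_selection <- function(x, ...) {
  cat(sprintf("<fp_selection> %d loci; %d unresolved pair(s)%s\n",
              length(x$loci), x$n_unresolved,
              if (x$resolved) " (all samples distinguished)" else ""))
  invisible(x)
}

as_locus_ids <- function(loci) {
  if (inherits(loci, "fp_selection")) loci$loci else as.character(loci)
}

#' Encode per-sample fingerprint digit codes
#'
#' Concatenates each sample's coded genotypes at the given loci, in
#' locus order, into a digit string over the alphabet `{0, 1, 2, 9}`
#' (9 = missing). Twenty loci give the customary 20-digit code.
#'
#' @param panel a [genotype_panel()].
#' @param loci locus ids (or an `fp_selection`) defining code positions.
#' @return A tibble with columns `sample` and `code`.
#' @export
encode_codes <- function(panel, loci) {
  ids <- as_locus_ids(loci)
  idx <- match(ids, panel$loci$locus_id)
  if (anyNA(idx)) {
    abort(paste0("unknown locus id(s): ", paste(ids[is.na(idx)], collapse = ", ")),
          class = "heveacore_error_index")
  }
  codes <- apply(panel$G[, idx, drop = FALSE], 1, paste, collapse = "")
  tibble(sample = panel$samples, code = unname(codes))
}

#' Audit fingerprint distinguishability
#'
#' Counts sample pairs whose codes collide. Under the default `strict`
#' policy a missing digit (9) matches only another 9, so two codes
#' collide only if they are string-identical. Under the `lenient`
#' policy a 9 is a wildcard: two codes collide if at every position the
#' digits agree or either is 9.
#'
#' @param codes a tibble as from [encode_codes()], or a named character
#'   vector of equal-length codes.
#' @param policy `"strict"` (default) or `"lenient"`.
#' @return A list: `n_unresolved_pairs` and `collisions` (list of
#'   character vectors of mutually colliding sample ids).
#' @export
distinguishability <- function(codes, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (inherits(codes, "data.frame")) {
    codes <- setNames(codes$code, codes$sample)
  }
  lens <- nchar(codes)
  if (length(unique(lens)) != 1) {
    abort("codes must all have the same length", class = "heveacore_error_codes")
  }
  ids <- names(codes) %||% paste0("s", seq_along(codes))
  if (policy == "strict") {
    groups <- split(ids, codes)
    collide <- groups[lengths(groups) > 1]
    n_pairs <- sum(choose(lengths(collide), 2))
    return(list(n_unresolved_pairs = as.integer(n_pairs),
                collisions = unname(collide)))
  }
  # lenient: pairwise comparison with 9 as wildcard
  M <- do.call(rbind, strsplit(codes, ""))
  n <- nrow(M)
  pair_collides <- function(i, j) {
    all(M[i, ] == M[j, ] | M[i, ] == "9" | M[j, ] == "9")
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) adj[i, j] <- adj[j, i] <- pair_collides(i, j)
  }
  n_pairs <- sum(adj[upper.tri(adj)])
  # group colliding ids into connected components
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j]) { a <- find(i); b <- find(j); if (a != b) comp[a] <- b }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, roots)
  collide <- groups[lengths(groups) > 1]
  list(n_unresolved_pairs = as.integer(n_pairs), collisions = unname(collide))
}

#' QR payload for a fingerprint code
#'
#' The machine-readable payload embedded in a per-accession QR code:
#' `"<sample_id>|<code>"`. The pipe is reserved as the delimiter, so
#' sample ids containing `|` are rejected. Rendering the payload to an
#' image is left to any standard QR encoder; the payload string is the
#' stable artifact.
#'
#' @param sample_id accession identifier (nonempty, no `|`).
#' @param code fingerprint digit string.
#' @return The payload string.
#' @export
qr_payload <- function(sample_id, code) {
  if (!nzchar(sample_id)) abort("empty sample id", class = "heveacore_error_codes")
  if (grepl("|", sample_id, fixed = TRUE)) {
    abort("sample id must not contain the '|' delimiter",
          class = "heveacore_error_codes")
  }
  stopifnot(grepl("^[0129]+$", code))
  paste0(sample_id, "|", code)
}

#' Fingerprint heatmap matrix
#'
#' The samples-by-selected-loci coded matrix (0/1/2/9) underlying a
#' fingerprint heatmap, as a tibble with loci as columns in selection
#' order; optionally written as TSV for downstream plotting.
#'
#' @param panel a [genotype_panel()].
#' @param loci locus ids (or an `fp_selection`).
#' @param path optional TSV output path.
#' @return A tibble: `sample` plus one integer column per locus.
#' @export
heatmap_matrix <- function(panel, loci, path = NULL) {
  ids <- as_locus_ids(loci)
  idx <- match(ids, panel$loci$locus_id)
  if (anyNA(idx)) {
    abort(paste0("unknown locus id(s): ", paste(ids[is.na(idx)], collapse = ", ")),
          class = "heveacore_error_index")
  }
  out <- dplyr::bind_cols(
    tibble(sample = panel$samples),
    as_tibble(panel$G[, idx, drop = FALSE])
  )
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}
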
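# Internal helpers shared across modules.

# Round half away from zero (so 2.5 -> 3), unlike base round()'s banker's
# rounding; used for core-collection allocation.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-stage seed derived from a master seed and a stage name.
# Keeps every stage reproducible independently of execution order.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(master_seed) + (h * 131L)) %% 2147483647L
}

# Valid genotype codes: 0 = ref hom, 1 = het, 2 = alt hom, 9 = missing.
GENO_CODES <- c(0L, 1L, 2L, 9L)

check_codes <- function(g, what = "genotype") {
  bad <- setdiff(unique(as.vector(g)), GENO_CODES)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0 || anyNA(g)) {
    abort(
      sprintf("%s codes must be in {0, 1, 2, 9}; found: %s", what,
              paste(c(bad, if (anyNA(g)) "NA"), collapse = ", ")),
      class = "heveacore_error_codes"
    )
  }
  invisible(g)
}
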
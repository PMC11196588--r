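# End-to-end orchestration: simulate/ingest -> filter -> diversity ->
# structure -> tree/PCA -> core sweep -> fingerprint, with a manifest.

#' Pipeline run configuration
#'
#' Exactly one of `vcf` (input path) or `simulation` (a [sim_config()])
#' must be given. Every stochastic stage derives its own seed
#' deterministically from `seed`, so a re-run with the same
#' configuration reproduces all outputs byte-identically.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param vcf path to an input VCF, or `NULL`.
#' @param simulation a [sim_config()], or `NULL`.
#' @param max_sample_missing,max_locus_missing,min_af,min_depth filter
#'   thresholds ([filter_samples()], [filter_variants()]); `min_depth =
#'   NULL` uses 20 when a DP matrix is present and 0 otherwise.
#' @param k_min,k_max,n_reps admixture scan grid ([admixture_scan()]).
#' @param n_groups number of tree-cut groups ([assign_groups()]).
#' @param ratios core-collection sampling ratios ([sweep_ratios()]).
#' @param min_retention retention threshold ([recommend_ratio()]).
#' @param n_fingerprint fingerprint size ([select_fingerprint_loci()]).
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1, vcf = NULL, simulation = NULL,
                       max_sample_missing = 0.999, max_locus_missing = 0.10,
                       min_af = 0.05, min_depth = NULL,
                       k_min = 1, k_max = 5, n_reps = 5, n_groups = 2,
                       ratios = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       min_retention = 0.95, n_fingerprint = 20) {
  if (is.null(vcf) == is.null(simulation)) {
    abort("exactly one of `vcf` and `simulation` must be supplied",
          class = "heveacore_error_config")
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), vcf = vcf,
         simulation = simulation, max_sample_missing = max_sample_missing,
         max_locus_missing = max_locus_missing, min_af = min_af,
         min_depth = min_depth, k_min = k_min, k_max = k_max, n_reps = n_reps,
         n_groups = n_groups, ratios = ratios, min_retention = min_retention,
         n_fingerprint = n_fingerprint),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: panel acquisition (simulation or VCF import),
#' sample filtering, variant filtering, per-locus and per-population
#' diversity statistics, admixture scan with Evanno delta-K,
#' neighbor-joining tree with group assignment, PCA, core-collection
#' ratio sweep with recommendation, and fingerprint construction. Every
#' stage artifact is written in a standard text format (VCF / TSV /
#' Newick / JSON) under `config$outdir`, and a `manifest.json` records
#' package version, per-stage seeds, timings, record counts and file
#' checksums. A failing stage aborts with the stage named; artifacts of
#' completed stages are retained.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(
    package = "heveacore",
    version = as.character(utils::packageVersion("heveacore")),
    seed = config$seed, stages = list()
  )
  results <- new.env()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "heveacore_error_stage", parent = e)
    })
    manifest$stages[[name]] <<- c(
      list(seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)),
      res
    )
    invisible(res)
  }

  stage("acquire", function() {
    if (!is.null(config$simulation)) {
      sim <- simulate_panel(config$simulation)
      results$panel <- sim$panel
      write_vcf(sim$panel, out("panel.vcf"))
      write_truth(sim$truth, out("truth"))
      list(source = "simulation", n_samples = n_samples(sim$panel),
           n_loci = n_loci(sim$panel),
           outputs = c("panel.vcf", "truth_samples.tsv", "truth_loci.tsv"))
    } else {
      results$panel <- read_vcf(config$vcf)
      list(source = config$vcf, n_samples = n_samples(results$panel),
           n_loci = n_loci(results$panel), outputs = character(0))
    }
  })

  stage("filter_samples", function() {
    fs <- filter_samples(results$panel, config$max_sample_missing)
    results$panel <- fs$panel
    write_filter_report(fs$report, out("filter_samples"))
    list(n_samples = n_samples(fs$panel),
         n_removed = nrow(fs$report$removed_samples),
         outputs = c("filter_samples.tsv", "filter_samples.json"))
  })

  stage("filter_variants", function() {
    md <- config$min_depth %||% (if (is.null(results$panel$DP)) 0 else 20)
    fv <- filter_variants(results$panel, min_depth = md,
                          max_locus_missing = config$max_locus_missing,
                          min_af = config$min_af)
    results$panel <- fv$panel
    write_filter_report(fv$report, out("filter_variants"))
    write_vcf(fv$panel, out("panel_filtered.vcf"))
    list(n_loci = n_loci(fv$panel), n_removed = nrow(fv$report$removed_loci),
         outputs = c("filter_variants.tsv", "filter_variants.json",
                     "panel_filtered.vcf"))
  })

  stage("diversity", function() {
    lt <- locus_table(results$panel)
    readr::write_tsv(lt, out("locus_stats.tsv"))
    list(n_loci = nrow(lt), mean_he = mean(lt$he, na.rm = TRUE),
         outputs = "locus_stats.tsv")
  })

  stage("structure", function() {
    scan <- admixture_scan(results$panel, k_min = config$k_min,
                           k_max = config$k_max, n_reps = config$n_reps,
                           seed = stage_seed(config$seed, "structure"))
    results$scan <- scan
    readr::write_tsv(structure_report(scan$best_fit), out("qmatrix.tsv"))
    readr::write_tsv(as_tibble(scan$delta_k), out("delta_k.tsv"))
    list(best_k = best_k(scan$delta_k), outputs = c("qmatrix.tsv", "delta_k.tsv"))
  })

  stage("tree_pca", function() {
    D <- ibs_distance(results$panel)
    tree <- neighbor_joining(D)
    groups <- assign_groups(tree, k = config$n_groups)
    results$groups <- groups
    writeLines(to_newick(tree), out("tree.nwk"))
    readr::write_tsv(groups, out("groups.tsv"))
    pc <- pca_panel(results$panel)
    readr::write_tsv(pc$scores, out("pca_scores.tsv"))
    readr::write_tsv(
      tibble(component = seq_along(pc$explained), explained_pct = pc$explained),
      out("pca_explained.tsv")
    )
    psum <- suppressWarnings(population_summary(results$panel, groups))
    readr::write_tsv(psum, out("population_summary.tsv"))
    list(n_groups = max(groups$group),
         outputs = c("tree.nwk", "groups.tsv", "pca_scores.tsv",
                     "pca_explained.tsv", "population_summary.tsv"))
  })

  stage("corebank", function() {
    sweep <- sweep_ratios(results$panel, results$groups, config$ratios)
    readr::write_tsv(sweep, out("core_sweep.tsv"))
    rec <- withCallingHandlers(
      recommend_ratio(sweep, config$min_retention),
      warning = function(w) invokeRestart("muffleWarning")
    )
    core <- build_core(results$panel, results$groups, rec / 100)
    writeLines(core$selected$sample, out("core_ids.txt"))
    readr::write_tsv(core$retention, out("core_retention.tsv"))
    list(recommended_ratio_pct = rec, n_core = nrow(core$selected),
         outputs = c("core_sweep.tsv", "core_ids.txt", "core_retention.tsv"))
  })

  stage("fingerprint", function() {
    sel <- select_fingerprint_loci(results$panel, config$n_fingerprint)
    codes <- encode_codes(results$panel, sel)
    readr::write_tsv(codes, out("fingerprint_codes.tsv"))
    writeLines(purrr::map2_chr(codes$sample, codes$code, qr_payload),
               out("qr_payloads.txt"))
    heatmap_matrix(results$panel, sel, out("fingerprint_heatmap.tsv"))
    audit <- distinguishability(codes)
    list(n_loci = length(sel$loci), n_unresolved = audit$n_unresolved_pairs,
         outputs = c("fingerprint_codes.tsv", "qr_payloads.txt",
                     "fingerprint_heatmap.tsv"))
  })

  files <- sort(unique(unlist(purrr::map(manifest$stages, "outputs"))))
  manifest$checksums <- as.list(tools::md5sum(file.path(config$outdir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
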
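#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a diploid, biallelic SNP VCF (as produced by joint genotyping,
#' e.g. GATK GenotypeGVCFs) and codes each call as `0` (0/0), `1` (0/1 or
#' 1/0), `2` (1/1) or `9` (missing or half-call). Phased separators are
#' accepted. Per-genotype depths are attached when a `DP` FORMAT field is
#' present.
#'
#' Multi-allelic records are rejected: split or drop them upstream
#' (e.g. `bcftools norm -m-`) before import.
#'
#' @param path path to a VCF (plain text or bgzip, per `vcfR`).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records", class = "heveacore_error_vcf")
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    abort(
      paste0("multi-allelic record(s) not supported: ",
             paste(sprintf("%s:%s", fix$CHROM[multi], fix$POS[multi]), collapse = ", ")),
      class = "heveacore_error_multiallelic"
    )
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    abort("VCF FORMAT lacks a GT field", class = "heveacore_error_vcf")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  G <- apply(gt, c(1, 2), code_gt)
  # vcfR orients variants as rows; the panel wants samples as rows
  G <- t(G)
  DP <- NULL
  if (any(vapply(strsplit(fmt, ":"), function(f) "DP" %in% f, logical(1)))) {
    DP <- t(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM, fix$POS)[is.na(ids) | ids == "."]
  loci <- tibble(
    locus_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  genotype_panel(G, loci, sample_ids = colnames(gt), DP = DP)
}

code_gt <- function(gt) {
  if (is.na(gt)) return(9L)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  if (gt %in% c(".", "./.")) return(9L)
  alleles <- strsplit(gt, "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2) {
    abort(sprintf("non-diploid genotype call '%s'", gt),
          class = "heveacore_error_ploidy")
  }
  if (any(alleles == ".")) return(9L) # half-calls are treated as missing
  if (!all(alleles %in% c("0", "1"))) {
    abort(sprintf("unsupported allele in genotype call '%s'", gt),
          class = "heveacore_error_vcf")
  }
  sum(alleles == "1")
}

#' Write a genotype panel to VCF v4.2
#'
#' Emits a plain-text VCF with a GT FORMAT field (plus DP when the panel
#' carries depths). Codes map back as `0` -> `0/0`, `1` -> `0/1`,
#' `2` -> `1/1`, `9` -> `./.`, so `read_vcf(write_vcf(p))` reproduces the
#' coded matrix exactly.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `9` = "./.")
  G <- panel$G
  has_dp <- !is.null(panel$DP)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=heveacore",
    sprintf("##contig=<ID=%s>", unique(panel$loci$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  body <- vapply(seq_len(n_loci(panel)), function(l) {
    calls <- gt_str[as.character(G[, l])]
    if (has_dp) {
      dp <- panel$DP[, l]
      calls <- paste0(calls, ":", ifelse(is.na(dp), ".", format(dp, trim = TRUE)))
    }
    paste(c(panel$loci$chrom[l], panel$loci$pos[l], panel$loci$locus_id[l],
            panel$loci$ref[l], panel$loci$alt[l], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", calls),
          collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
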
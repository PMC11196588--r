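write_test_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

vcf_header <- function(samples, format_extra = NULL) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    format_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("VCF genotypes are coded 0/1/2/9 as per the dosage convention", {
  path <- write_test_vcf(c(
    vcf_header(c("s1", "s2", "s3")),
    "chr1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t./.\t1|0\t0/."
  ))
  panel <- read_vcf(path)
  expected <- rbind(s1 = c(0L, 9L), s2 = c(1L, 1L), s3 = c(2L, 9L))
  colnames(expected) <- c("snpA", "snpB")
  expect_identical(panel$G, expected)
  expect_identical(panel$samples, c("s1", "s2", "s3"))
  expect_identical(panel$loci$pos, c(100L, 200L))
})

test_that("malformed VCF inputs raise named errors", {
  multi <- write_test_vcf(c(
    vcf_header("s1"),
    "chr1\t100\tsnpA\tA\tG,T\t.\tPASS\t.\tGT\t0/1"
  ))
  expect_error(read_vcf(multi), class = "heveacore_error_multiallelic")
  expect_error(read_vcf(multi), "chr1:100")
  triploid <- write_test_vcf(c(
    vcf_header("s1"),
    "chr1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0/1"
  ))
  expect_error(read_vcf(triploid), class = "heveacore_error_ploidy")
})

test_that("write_vcf/read_vcf round-trips the coded matrix exactly", {
  sim <- simulate_panel(sim_config(n_samples_per_pop = c(12, 5), n_loci = 20,
                                   missing_rate = 0.1, seed = 4,
                                   depth_mean = 30))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$panel, path)
  back <- read_vcf(path)
  expect_identical(back$G, sim$panel$G)
  expect_identical(back$samples, sim$panel$samples)
  expect_identical(back$loci$pos, sim$panel$loci$pos)
  expect_equal(back$DP, sim$panel$DP, ignore_attr = TRUE)
  # missing calls serialise as ./.
  raw <- readLines(path)
  l <- which(sim$panel$G[1, ] == 9L)[1]
  if (!is.na(l)) expect_match(raw[grep("^chr1", raw)[l]], "\\./\\.")
})

test_that("sample missingness filter drops only samples past the threshold", {
  sim <- simulate_panel(sim_config(n_samples_per_pop = c(20, 6), n_loci = 30,
                                   n_fully_missing_samples = 1, seed = 2))
  fs <- filter_samples(sim$panel)
  expect_equal(n_samples(fs$panel), 25)
  expect_equal(nrow(fs$report$removed_samples), 1)
  # report reconciles: in = out + removed
  expect_equal(fs$report$n_samples_in,
               fs$report$n_samples_out + nrow(fs$report$removed_samples))
  # idempotent
  fs2 <- filter_samples(fs$panel)
  expect_identical(fs2$panel$G, fs$panel$G)
  # clean panel: identity
  clean <- simulate_panel(sim_config(n_samples_per_pop = 10, n_loci = 5,
                                     missing_rate = 0, seed = 3))$panel
  expect_identical(filter_samples(clean)$panel$G, clean$G)
})

test_that("a partially missing sample is removed at a tighter threshold, with reason", {
  G <- rbind(ok = c(0L, 1L, 2L, 0L, 1L),
             bad = c(9L, 9L, 9L, 0L, 1L),
             ok2 = c(2L, 2L, 0L, 1L, 0L))
  panel <- make_panel(G)
  fs <- filter_samples(panel, max_sample_missing = 0.5)
  expect_identical(fs$panel$samples, c("ok", "ok2"))
  expect_match(fs$report$removed_samples$reason, "missing fraction")
  expect_error(filter_samples(make_panel(rbind(a = c(9L, 9L))), 0.5),
               class = "heveacore_error_empty")
})

test_that("variant filter matches a hand enumeration on a 10-locus fixture", {
  # 8 samples x 10 loci; loci engineered to hit each rule
  set.seed(42)
  G <- matrix(0L, 8, 10)
  G[, 1] <- c(0L, 1L, 2L, 0L, 1L, 0L, 0L, 1L)   # polymorphic, no missing -> keep
  G[, 2] <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)   # monomorphic -> drop (MAF 0)
  G[, 3] <- c(9L, 9L, 0L, 1L, 2L, 0L, 1L, 0L)   # 25% missing -> drop
  G[, 4] <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L)   # MAF 1/16 = 0.0625 -> keep
  G[, 5] <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 9L)   # 1 missing (12.5%) -> drop
  G[, 6] <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)   # MAF 0.5 -> keep
  G[, 7] <- c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L)   # MAF 1/16 -> keep
  G[, 8] <- c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L)   # monomorphic alt -> drop
  G[, 9] <- c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)   # MAF 1/16 -> keep
  G[, 10] <- c(9L, 0L, 1L, 2L, 1L, 0L, 2L, 1L)  # 12.5% missing -> drop
  panel <- make_panel(G)
  # independent enumeration of the rule, locus by locus
  keep_oracle <- vapply(1:10, function(l) {
    g <- G[, l]
    miss <- mean(g == 9)
    called <- g[g != 9]
    p <- (sum(called == 1) + 2 * sum(called == 2)) / (2 * length(called))
    maf <- min(p, 1 - p)
    miss <= 0.10 && maf >= 0.05
  }, logical(1))
  fv <- filter_variants(panel, min_depth = 0)
  expect_identical(fv$panel$loci$locus_id, panel$loci$locus_id[keep_oracle])
  expect_equal(fv$report$n_loci_in,
               fv$report$n_loci_out + nrow(fv$report$removed_loci))
  # idempotent
  fv2 <- filter_variants(fv$panel, min_depth = 0)
  expect_identical(fv2$panel$G, fv$panel$G)
})

test_that("low-depth genotypes are masked before locus filtering", {
  G <- rbind(a = c(0L, 1L), b = c(1L, 1L), c = c(2L, 1L), d = c(0L, 1L),
             e = c(1L, 1L), f = c(2L, 1L), g = c(0L, 1L), h = c(1L, 1L),
             i = c(2L, 1L), j = c(0L, 1L))
  DP <- matrix(30, 10, 2)
  DP[1:2, 1] <- 5  # two calls at locus 1 below depth -> 20% missing -> drop
  panel <- genotype_panel(G, tibble::tibble(
    locus_id = c("L1", "L2"), chrom = "chr1", pos = c(1L, 2L),
    ref = "A", alt = "G"), DP = DP)
  fv <- filter_variants(panel, min_depth = 20)
  expect_identical(fv$panel$loci$locus_id, "L2")
  expect_error(filter_variants(make_panel(G), min_depth = 20),
               class = "heveacore_error_dp")
  expect_error(filter_variants(panel, min_depth = 31),
               class = "heveacore_error_empty")
})

test_that("panel-locus selection applies strict thresholds then greedy 2 Mb spacing", {
  # loci at 1.0, 2.5, 3.2 Mb, all MAF 0.5: greedy keeps 1.0 and 3.2
  G <- matrix(1L, 6, 3)
  G[1:3, ] <- 0L
  G[4:6, ] <- 2L
  panel <- make_panel(G, pos = c(1.0e6, 2.5e6, 3.2e6))
  sel <- select_panel_loci(panel)
  expect_identical(sel$panel$loci$pos, as.integer(c(1.0e6, 3.2e6)))
  expect_match(sel$report$removed_loci$reason, "bp from previous")

  # MAF exactly at the boundary is excluded (strict >)
  g_boundary <- c(rep(0L, 4), rep(2L, 3), 1L, 1L, 1L) # p_alt = 9/20 -> maf 0.45
  g_at_03 <- c(rep(0L, 4), rep(1L, 4), rep(2L, 1), 0L) # p_alt = 6/20 = 0.3 exactly
  panel2 <- make_panel(cbind(g_boundary, g_at_03), pos = c(1e6, 5e6))
  sel2 <- select_panel_loci(panel2)
  expect_identical(sel2$panel$loci$locus_id, "L01")

  # single passing locus is kept
  panel3 <- make_panel(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  expect_equal(n_loci(select_panel_loci(panel3)$panel), 1)
})
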
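test_that("allele counting follows the dosage coding, ignoring missing calls", {
  expect_identical(allele_counts(c(0, 1, 2)), c(n_ref = 3L, n_alt = 3L))
  expect_identical(allele_counts(c(9, 9, 0)), c(n_ref = 2L, n_alt = 0L))
  expect_identical(allele_counts(rep(1, 195)), c(n_ref = 195L, n_alt = 195L))
  expect_error(allele_counts(c(9, 9)), class = "heveacore_error_allmissing")
  expect_error(allele_counts(c(0, 3)), class = "heveacore_error_codes")
})

test_that("He and PIC take their textbook values at key frequencies", {
  expect_equal(round(expected_heterozygosity(0.5), 4), 0.5000)
  expect_equal(round(expected_heterozygosity(0.05), 4), 0.0950)
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(round(pic(0.5), 4), 0.3750)
  expect_equal(round(pic(0.05), 4), 0.0905)
  expect_equal(pic(0.05), 0.0904875, tolerance = 1e-12)
  expect_equal(pic(1), 0)
})

test_that("site pi equals direct enumeration of allele pairs", {
  # the analytic maximum with 195 fully-called heterozygous diploids
  expect_equal(round(nucleotide_diversity(195, 195), 4), 0.5013)
  expect_equal(nucleotide_diversity(195, 195), 38025 / 75855)
  expect_equal(nucleotide_diversity(1, 3), 0.5)
  expect_equal(nucleotide_diversity(4, 0), 0)
  expect_error(nucleotide_diversity(1, 0), class = "heveacore_error_lowcount")
  # enumeration oracle across small counts
  for (nr in 0:6) for (na in 0:6) {
    if (nr + na < 2) next
    expect_equal(nucleotide_diversity(nr, na), pi_enumeration(nr, na),
                 info = sprintf("n_ref=%d n_alt=%d", nr, na))
  }
})

test_that("statistics are symmetric in p and ordered PIC <= He <= pi", {
  p <- seq(0, 1, by = 0.01)
  expect_equal(pic(p), pic(1 - p))
  expect_equal(expected_heterozygosity(p), expected_heterozygosity(1 - p))
  expect_true(all(pic(p) <= expected_heterozygosity(p) + 1e-12))
  # pi >= He via the n/(n-1) factor at matching frequency
  n <- 40
  for (alt in 1:(n - 1)) {
    he <- expected_heterozygosity(alt / n)
    expect_gte(nucleotide_diversity(n - alt, alt) + 1e-12, he)
  }
  expect_equal(max(expected_heterozygosity(p)), 0.5)
  expect_equal(max(pic(p)), 0.375)
})

test_that("locus_table matches a brute-force per-column recomputation", {
  set.seed(8)
  G <- matrix(sample(c(0L, 1L, 2L, 9L), 100, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), 10, 10)
  G[, 10] <- c(0L, rep(2L, 9))  # ensure at least 2 called alleles everywhere
  panel <- make_panel(G)
  lt <- locus_table(panel)
  for (l in 1:10) {
    cnt <- allele_counts(G[, l])
    p <- cnt["n_alt"] / sum(cnt)
    expect_equal(lt$p[l], unname(p))
    expect_equal(lt$he[l], unname(expected_heterozygosity(p)))
    expect_equal(lt$pic[l], unname(pic(p)))
    expect_equal(lt$pi[l], unname(nucleotide_diversity(cnt[1], cnt[2])))
    expect_equal(lt$missing_rate[l], mean(G[, l] == 9))
  }
})

test_that("degenerate loci are handled: uniform panel gives zeros, all-missing gives NA", {
  uniform <- make_panel(matrix(0L, 5, 3))
  lt <- locus_table(uniform)
  expect_true(all(lt$he == 0 & lt$pic == 0 & lt$pi == 0))

  one_het <- make_panel(matrix(c(1L, rep(0L, 194)), ncol = 1))
  lt2 <- locus_table(one_het)
  expect_equal(lt2$he, 2 * (1 / 390) * (389 / 390))

  with_gap <- make_panel(cbind(c(0L, 1L, 2L), c(9L, 9L, 9L)))
  expect_warning(lt3 <- locus_table(with_gap), "no called genotypes")
  expect_true(is.na(lt3$he[2]) && is.na(lt3$pi[2]))
})

test_that("population summaries re-estimate frequencies within groups", {
  sim <- simulate_panel(sim_config(n_samples_per_pop = c(15, 15), n_loci = 30,
                                   fst = 0.1, missing_rate = 0, seed = 21))
  labels <- sim$truth$pop_labels
  ps <- population_summary(sim$panel, labels)
  expect_identical(ps$population, c("1", "2", "Mean"))
  # single group equals the locus-table means
  g1 <- panel_subset(sim$panel, samples = which(labels == 1))
  lt1 <- locus_table(g1)
  expect_equal(ps$he[1], mean(lt1$he))
  expect_equal(ps$pic[1], mean(lt1$pic))
  # Mean row is the unweighted mean of group values
  expect_equal(ps$he[3], mean(ps$he[1:2]))
  # two identical groups give identical summaries
  dup <- genotype_panel(rbind(g1$G, `rownames<-`(g1$G, paste0(rownames(g1$G), "b"))),
                        g1$loci)
  ps2 <- population_summary(dup, rep(c("A", "B"), each = n_samples(g1)))
  expect_equal(ps2$he[1], ps2$he[2])
  expect_equal(ps2$pi[1], ps2$pi[2])
  # min <= mean <= max
  expect_true(all(ps$he_min <= ps$he & ps$he <= ps$he_max))
})

test_that("groups with fewer than two samples are flagged low-n", {
  G <- rbind(a = c(0L, 1L), b = c(2L, 1L), c = c(1L, 0L))
  panel <- make_panel(G)
  expect_warning(ps <- population_summary(panel, c("g1", "g1", "solo")),
                 "< 2 samples")
  expect_true(ps$low_n[ps$population == "solo"])
})

test_that("retention rates are percentages of the original statistics", {
  core <- tibble::tibble(population = "G1", he = 0.2899, pic = 0.2357, pi = 0.3015)
  orig <- tibble::tibble(population = "G1", he = 0.2535, pic = 0.2059, pi = 0.2547)
  ret <- retention_rate(core, orig)
  expect_equal(round(ret$he_retention, 1), 114.4)
  # identity
  same <- retention_rate(orig, orig)
  expect_equal(unlist(same[-1]), rep(100, 3), ignore_attr = TRUE)
  # zero original -> NA with warning
  zero <- tibble::tibble(population = "G1", he = 0, pic = 0.1, pi = 0.1)
  expect_warning(r0 <- retention_rate(core, zero), "retention set to NA")
  expect_true(is.na(r0$he_retention))
  expect_error(
    retention_rate(core, dplyr::mutate(orig, population = "G9")),
    class = "heveacore_error_labels"
  )
})
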
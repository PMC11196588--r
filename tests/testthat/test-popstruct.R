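test_that("IBS distance matches hand computation and its boundary cases", {
  G <- rbind(a = c(0L, 1L, 2L), b = c(0L, 0L, 2L), c = c(2L, 9L, 0L))
  d <- ibs_distance(make_panel(G))
  # a-b differ by one allele over 3 shared loci; a-c and b-c are opposite
  # homozygotes at both shared loci
  expect_equal(d$D["a", "b"], 1 / 6)
  expect_equal(d$D["a", "c"], 1)
  expect_equal(d$D["b", "c"], 1)
  expect_equal(diag(d$D), c(a = 0, b = 0, c = 0))
  expect_equal(d$D, t(d$D))
  expect_equal(d$n_shared["a", "c"], 2)

  same <- rbind(x = c(0L, 1L, 2L, 1L), y = c(0L, 1L, 2L, 1L))
  expect_equal(ibs_distance(make_panel(same))$D["x", "y"], 0)

  apart <- rbind(x = rep(0L, 10), y = rep(2L, 10))
  expect_equal(ibs_distance(make_panel(apart))$D["x", "y"], 1)

  disjoint <- rbind(x = c(0L, 9L), y = c(9L, 2L))
  expect_error(ibs_distance(make_panel(disjoint)), class = "heveacore_error_size")
})

quartet_D <- function() {
  # additive distances of the quartet ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["C", "D"] <- 7
  D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

test_that("NJ recovers the 4-taxon additive tree found by least-squares search", {
  D <- quartet_D()
  oracle <- ls_fit_quartet(D)
  expect_setequal(oracle$pair, c("A", "B"))
  expect_lt(oracle$rss, 1e-18)
  tree <- neighbor_joining(D)
  expect_equal(cophenetic(tree)[rownames(D), colnames(D)], D, tolerance = 1e-9)
  expect_equal(sort(tree$edge.length), sort(c(1, 2, 3, 4, 1)), tolerance = 1e-9)
  expect_equal(phangorn::RF.dist(tree, ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")), 0)
})

test_that("three taxa resolve by the closed-form star equations", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- neighbor_joining(D)
  expect_equal(sort(unname(setNames(tree$edge.length,
                                    tree$tip.label[tree$edge[, 2]]))),
               c(1, 2, 3))
  expect_equal(cophenetic(tree)[rownames(D), colnames(D)], D)
  expect_error(neighbor_joining(D[1:2, 1:2]), class = "heveacore_error_size")
})

test_that("NJ is exact on random additive matrices and agrees with ape's NJ", {
  for (seed in 1:20) {
    ra <- random_additive(8, seed)
    tree <- neighbor_joining(ra$D)
    expect_lt(max(abs(cophenetic(tree)[rownames(ra$D), colnames(ra$D)] - ra$D)),
              1e-9)
    expect_equal(phangorn::RF.dist(tree, ra$tree), 0)
    expect_equal(phangorn::RF.dist(tree, ape::nj(ra$D)), 0)
  }
})

test_that("Newick export round-trips and survives an external parser", {
  tree <- read_newick("((A:1,B:2):1,C:3);")
  back <- read_newick(to_newick(tree))
  expect_equal(phangorn::RF.dist(tree, back), 0)
  expect_equal(sort(back$edge.length), sort(tree$edge.length), tolerance = 1e-9)
  # quoted names with spaces
  G <- matrix(sample(c(0L, 1L, 2L), 30, TRUE), 3, 10)
  rownames(G) <- c("acc 1", "acc 2", "plain")
  tr <- neighbor_joining(ibs_distance(make_panel(G)))
  expect_setequal(read_newick(to_newick(tr))$tip.label, rownames(G))
  # NJ output parses in ape (independent parser of our writer)
  ra <- random_additive(8, 3)
  expect_s3_class(ape::read.tree(text = to_newick(neighbor_joining(ra$D))), "phylo")
  expect_error(read_newick("((A:1,B:2"), class = "heveacore_error_newick")
})

test_that("tree cutting recovers simulated subpopulations", {
  aris <- vapply(1:3, function(seed) {
    sim <- simulate_panel(sim_config(n_samples_per_pop = c(60, 30), n_loci = 99,
                                     fst = 0.15, missing_rate = 0.03,
                                     seed = seed))
    tree <- neighbor_joining(ibs_distance(sim$panel))
    g <- assign_groups(tree, k = 2)
    truth <- sim$truth$pop_labels[g$sample]
    mclust::adjustedRandIndex(g$group, truth)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})

test_that("tree cutting handles k = n and degenerate trees", {
  G <- matrix(sample(c(0L, 1L, 2L), 50, TRUE), 5, 10)
  rownames(G) <- paste0("s", 1:5)
  tree <- neighbor_joining(ibs_distance(make_panel(G)))
  singletons <- assign_groups(tree, k = 5)
  expect_equal(sort(unique(singletons$group)), 1:5)

  clones <- make_panel(matrix(1L, 4, 8))
  tr <- neighbor_joining(ibs_distance(clones))
  expect_warning(g <- assign_groups(tr, k = 2), "degenerate")
  expect_equal(unique(g$group), 1L)
})

test_that("PCA separates diverged populations on PC1", {
  sim <- simulate_panel(sim_config(n_samples_per_pop = c(40, 40), n_loci = 99,
                                   fst = 0.3, missing_rate = 0, seed = 17))
  pc <- pca_panel(sim$panel, n_components = 4)
  pc1 <- pc$scores$PC1
  labels <- sim$truth$pop_labels
  expect_true(all(pc1[labels == 1] > 0) != all(pc1[labels == 1] < 0))
  side1 <- pc1[labels == 1] > 0
  side2 <- pc1[labels == 2] > 0
  expect_true(all(side1) && !any(side2) || !any(side1) && all(side2))
})

test_that("PCA explained variances are valid and coordinates well-behaved", {
  sim <- simulate_panel(sim_config(n_samples_per_pop = c(20, 10), n_loci = 50,
                                   seed = 9))
  pc <- pca_panel(sim$panel, n_components = 10)
  expect_true(all(pc$explained >= 0))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 100 + 1e-9)
  # duplicated samples land on identical coordinates
  G2 <- rbind(sim$panel$G, `rownames<-`(sim$panel$G, paste0(sim$panel$samples, "_dup")))
  pc2 <- pca_panel(genotype_panel(G2, sim$panel$loci), n_components = 2)
  n <- n_samples(sim$panel)
  expect_equal(pc2$scores$PC1[1:n], pc2$scores$PC1[(n + 1):(2 * n)])
  # reordering samples leaves coordinates invariant up to sign
  perm <- rev(seq_len(n))
  pc3 <- pca_panel(panel_subset(sim$panel, samples = perm), n_components = 2)
  reord <- pc3$scores$PC1[match(sim$panel$samples, pc3$scores$sample)]
  expect_equal(abs(reord), abs(pc$scores$PC1), tolerance = 1e-8)
  expect_error(pca_panel(make_panel(matrix(0L, 4, 3))),
               class = "heveacore_error_empty")
})
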
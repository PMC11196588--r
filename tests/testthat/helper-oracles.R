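# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own code paths.

# Hudson's FST estimator (ratio of averages across loci) from two
# genotype submatrices coded 0/1/2/9.
hudson_fst <- function(G1, G2) {
  freq <- function(G) {
    called <- G != 9
    alt <- colSums((G == 1) + 2 * (G == 2))
    n <- colSums(called)            # diploid counts
    list(p = alt / (2 * n), n = n)
  }
  f1 <- freq(G1); f2 <- freq(G2)
  keep <- f1$n > 1 & f2$n > 1
  p1 <- f1$p[keep]; p2 <- f2$p[keep]
  n1 <- 2 * f1$n[keep]; n2 <- 2 * f2$n[keep]   # allele counts
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# Average pairwise allelic difference by direct enumeration of all
# C(n, 2) allele pairs at one site.
pi_enumeration <- function(n_ref, n_alt) {
  alleles <- c(rep(0, n_ref), rep(1, n_alt))
  pairs <- combn(length(alleles), 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Brute-force least-squares tree fit over the 3 unrooted 4-taxon
# topologies; returns the best topology's quartet split and its branch
# lengths solved from the additive system.
ls_fit_quartet <- function(D) {
  taxa <- rownames(D)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))  # partner of taxon 1
  fits <- lapply(splits, function(pair) {
    others <- setdiff(1:4, pair)
    i <- pair[1]; j <- pair[2]; k <- others[1]; l <- others[2]
    # additive solution for topology ((i,j),(k,l)) with internal edge m
    bi <- (D[i, j] + (D[i, k] + D[i, l]) / 2 - (D[j, k] + D[j, l]) / 2) / 2
    bj <- D[i, j] - bi
    bk <- (D[k, l] + (D[k, i] + D[k, j]) / 2 - (D[l, i] + D[l, j]) / 2) / 2
    bl <- D[k, l] - bk
    m <- (D[i, k] + D[j, l] + D[i, l] + D[j, k]) / 4 - (D[i, j] + D[k, l]) / 2
    lens <- c(bi, bj, bk, bl, m)
    path <- matrix(0, 4, 4)
    path[i, j] <- path[j, i] <- bi + bj
    path[k, l] <- path[l, k] <- bk + bl
    for (x in pair) for (y in others) {
      bx <- if (x == i) bi else bj
      by <- if (y == k) bk else bl
      path[x, y] <- path[y, x] <- bx + m + by
    }
    list(pair = taxa[pair], lens = lens, rss = sum((path - D)^2))
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

# Random additive distance matrix from a random unrooted binary tree.
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, br = function(nn) runif(nn, 0.05, 1)))
  list(tree = tr, D = cophenetic(tr))
}

# Exhaustive max-min-distance subset search: the size-k subset of rows
# of D maximising the minimum pairwise distance (ties: first in combn
# order).
max_min_subset <- function(D, k) {
  ids <- rownames(D)
  combos <- combn(nrow(D), k)
  score <- apply(combos, 2, function(ix) min(D[ix, ix][upper.tri(D[ix, ix])]))
  ids[combos[, which.max(score)]]
}

# Small panel from an explicit genotype matrix (one chromosome,
# positions 1 Mb apart unless given).
make_panel <- function(G, pos = NULL, chrom = "chr1") {
  G <- as.matrix(G)
  L <- ncol(G)
  loci <- tibble::tibble(
    locus_id = sprintf("L%02d", seq_len(L)), chrom = chrom,
    pos = as.integer(pos %||% (seq_len(L) * 1e6)), ref = "A", alt = "G"
  )
  rownames(G) <- rownames(G) %||% sprintf("s%02d", seq_len(nrow(G)))
  heveacore::genotype_panel(G, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
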
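#' Identity-by-state genetic distance
#'
#' Pairwise distance `d(i, j) = 1 - mean over shared called loci of
#' (2 - |g_i - g_j|) / 2`, i.e. one minus the proportion of alleles
#' identical by state. Identical genotype rows are at distance 0;
#' opposite homozygotes at every locus are at distance 1.
#'
#' @param panel a [genotype_panel()].
#' @return A list of class `ibs_dist`: `samples`, symmetric `D` matrix
#'   with zero diagonal, and `n_shared` matrix of co-called locus counts.
#' @export
ibs_distance <- function(panel) {
  if (n_samples(panel) < 2) {
    abort("need at least 2 samples for a distance matrix",
          class = "heveacore_error_size")
  }
  G <- panel$G
  G[G == 9L] <- NA_integer_
  n <- nrow(G)
  called <- !is.na(G)
  Gz <- G; Gz[!called] <- 0L
  # sum over shared loci of |g_i - g_j| via the identity
  # |a-b| = a + b - 2*min(a,b); computed with three matrix products over
  # the indicator decomposition of the dosage
  shared <- called %*% t(called) * 1.0
  if (any(shared[upper.tri(shared)] == 0)) {
    abort("some sample pair shares no called loci", class = "heveacore_error_size")
  }
  # decompose dosage g into indicators ge1 = (g>=1), ge2 = (g>=2);
  # then |gi - gj| summed = sum |ge1_i-ge1_j| + |ge2_i-ge2_j| over shared loci
  absdiff_ind <- function(M) {
    M[!called] <- 0
    # for 0/1 indicators restricted to shared loci:
    # |a-b| = a(1-b) + b(1-a); mask handled by called products
    Mi <- M * called
    Mi %*% t(called - Mi) + (called - Mi) %*% t(Mi)
  }
  ad <- absdiff_ind((G >= 1) * 1.0) + absdiff_ind((G >= 2) * 1.0)
  D <- ad / (2 * shared)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(panel$samples, panel$samples)
  structure(list(samples = panel$samples, D = D, n_shared = shared),
            class = "ibs_dist")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "ibs_dist")) return(D$D)
  if (inherits(D, "dist")) return(as.matrix(D))
  as.matrix(D)
}

#' Neighbor-joining tree
#'
#' Classical Saitou–Nei neighbor joining: repeatedly join the pair
#' minimising `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`
#' with the standard branch-length formulas, resolving ties by the
#' smallest (row, column) index pair. Exact (topology and branch
#' lengths) on additive distance matrices. Negative branch lengths are
#' clamped to zero at export with a message; raw values are kept in the
#' `raw_edge_length` attribute.
#'
#' @param D an `ibs_dist`, `dist` or symmetric distance matrix with row
#'   and column names (>= 3 taxa).
#' @return An [ape::read.tree()]-style `phylo` object (unrooted).
#' @export
neighbor_joining <- function(D) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa",
                   class = "heveacore_error_size")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", x)
  nodes <- vapply(labels, newick_quote, character(1))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(bi), nodes[j], fmt(bj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
    rownames(D2) <- colnames(D2) <- seq_len(m - 1)
    D <- D2
  }
  # closed-form resolution of the final three nodes
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- D[1, 2] - b1
  b3 <- D[1, 3] - b1
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(b1),
                 nodes[2], fmt(b2), nodes[3], fmt(b3))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- newick_unquote(tree$tip.label)
  if (any(tree$edge.length < 0)) {
    inform(sprintf("clamping %d negative NJ branch length(s) to 0 (min %.3g)",
                   sum(tree$edge.length < 0), min(tree$edge.length)))
    attr(tree, "raw_edge_length") <- tree$edge.length
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

newick_quote <- function(x) {
  if (grepl("[\\s(),:;'\\[\\]]", x, perl = TRUE)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

# ape::read.tree keeps the surrounding quotes of quoted labels; strip them
newick_unquote <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Cut a tree into k groups
#'
#' Partitions the leaves of an unrooted tree by removing its `k - 1`
#' highest-scoring internal branches, where a branch's score is its
#' length weighted by the number of leaf pairs it separates
#' (`length * n_below * (n - n_below)`). The weighting makes the cut
#' prefer deep, balanced splits — the "two major groups" of a germplasm
#' tree — over long but shallow branches that would merely split off a
#' pair of outlier accessions. Pendant branches are used only once
#' internal ones are exhausted, so `k = n` yields singletons. The
#' connected components of the remaining forest define the groups; ties
#' are broken by edge index, so the assignment is deterministic. A tree
#' whose branch lengths are all (near) zero is degenerate: a warning is
#' issued and all samples fall in one group.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param k number of groups (`2 <= k <=` number of leaves).
#' @return A tibble with columns `sample` and `group` (integer, numbered
#'   by first appearance in tip order).
#' @export
assign_groups <- function(tree, k = 2) {
  ntip <- length(tree$tip.label)
  stopifnot(k >= 1, k <= ntip)
  edges <- tree$edge
  len <- tree$edge.length
  if (k == 1 || all(len < 1e-12)) {
    if (all(len < 1e-12) && k > 1) {
      warn("degenerate tree (all branch lengths ~0): assigning a single group")
    }
    return(tibble(sample = tree$tip.label, group = 1L))
  }
  internal <- edges[, 2] > ntip
  n_below <- vapply(seq_len(nrow(edges)), function(e) {
    if (!internal[e]) return(1L)
    length(ape::extract.clade(tree, edges[e, 2])$tip.label)
  }, integer(1))
  score <- len * n_below * (ntip - n_below)
  ord <- order(!internal, -score, seq_along(len)) # internal first, best first
  cut_edges <- ord[seq_len(k - 1)]
  # connected components of the forest after cutting
  keep <- setdiff(seq_along(len), cut_edges)
  n_nodes <- max(edges)
  comp <- seq_len(n_nodes)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in keep) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) comp[a] <- b
  }
  tip_comp <- vapply(seq_len(ntip), find, integer(1))
  group <- as.integer(factor(tip_comp, levels = unique(tip_comp)))
  tibble(sample = tree$tip.label, group = group)
}

#' Variance-standardised principal component analysis
#'
#' Standard population-genetic PCA: each genotype dosage `g` at a locus
#' with alternate-allele frequency `p` is transformed to
#' `(g - 2p) / sqrt(2p(1-p))`; missing entries are set to zero after
#' centring; monomorphic (and fully missing) loci are dropped. The
#' eigendecomposition of the resulting sample covariance gives the
#' coordinates, and explained variance is `100 * lambda_c / sum(lambda)`.
#'
#' @param panel a [genotype_panel()].
#' @param n_components number of components to retain.
#' @return An object of class `pca_result`: `scores` tibble (sample +
#'   `PC1..PCk`), `explained` (percent per retained component) and
#'   `loci_used`.
#' @export
pca_panel <- function(panel, n_components = 10) {
  if (n_samples(panel) < 2) abort("need >= 2 samples", class = "heveacore_error_size")
  G <- panel$G
  G[G == 9L] <- NA_integer_
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("no polymorphic loci", class = "heveacore_error_empty")
  X <- sweep(G[, poly, drop = FALSE], 2, 2 * p[poly], `-`)
  X <- sweep(X, 2, sqrt(2 * p[poly] * (1 - p[poly])), `/`)
  X[is.na(X)] <- 0
  fit <- prcomp(X, center = FALSE, scale. = FALSE)
  lambda <- fit$sdev^2
  nc <- min(n_components, ncol(fit$x))
  scores <- as_tibble(fit$x[, seq_len(nc), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample = panel$samples), scores)
  structure(
    list(
      scores = scores,
      explained = 100 * lambda[seq_len(nc)] / sum(lambda),
      loci_used = panel$loci$locus_id[poly]
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d loci; PC1 %.2f%%, PC2 %.2f%%\n",
              nrow(x$scores), length(x$loci_used),
              x$explained[1], if (length(x$explained) > 1) x$explained[2] else NA))
  invisible(x)
}

#' Newick serialisation
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that
#' round-trip topology and branch lengths to better than 1e-9.
#'
#' @param tree a `phylo` object.
#' @param string a Newick string.
#' @return `to_newick()` returns a Newick string; `read_newick()` a
#'   `phylo`.
#' @export
to_newick <- function(tree) {
  labs <- tree$tip.label
  # placeholder tokens keep write.tree from mangling labels with spaces;
  # originals are re-inserted Newick-quoted
  tree$tip.label <- sprintf("@@%d@@", seq_along(labs))
  s <- ape::write.tree(tree, digits = 12)
  for (i in seq_along(labs)) {
    s <- sub(sprintf("@@%d@@", i), newick_quote(labs[i]), s, fixed = TRUE)
  }
  s
}

#' @rdname to_newick
#' @export
read_newick <- function(string) {
  tree <- tryCatch(ape::read.tree(text = string),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) abort("malformed Newick string", class = "heveacore_error_newick")
  tree$tip.label <- newick_unquote(tree$tip.label)
  tree
}
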
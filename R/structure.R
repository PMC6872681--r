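#' Principal component analysis of a genotype panel
#'
#' GRM-style standardization: each SNP dosage column is centered by `2p`
#' and scaled by `sqrt(2p(1-p))`; missing entries contribute 0 after
#' centering (mean imputation). The individual-by-individual covariance
#' `XX'/L` is eigendecomposed and components ordered by eigenvalue. The
#' panel should be LD-pruned beforehand (e.g. r2 < 0.5) for structure
#' analyses.
#'
#' @param panel a [genotype_panel()].
#' @param n_components number of components to retain (default 10,
#'   capped at individuals - 1).
#' @return list of class `pca_result`: `coordinates` (individuals x
#'   components, unit-norm eigenvectors), `eigenvalues`,
#'   `variance_fraction`, `populations`.
#' @export
pca_panel <- function(panel, n_components = 10) {
  n <- n_individuals(panel)
  if (n_components > n - 1)
    stop("n_components must be <= individuals - 1")
  g <- panel$genotypes
  p <- snp_freq(panel)
  keep <- !is.na(p) & p > 0 & p < 1   # monomorphic SNPs carry no signal
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  L <- ncol(g)
  if (L == 0) stop("no polymorphic SNPs")
  x <- sweep(g, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  k <- tcrossprod(x) / L
  eig <- eigen(k, symmetric = TRUE)
  vals <- eig$values[seq_len(n_components)]
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE]
  dimnames(coords) <- list(panel$individuals$id,
                           paste0("PC", seq_len(n_components)))
  pos <- pmax(eig$values, 0)
  structure(list(coordinates = coords, eigenvalues = vals,
                 variance_fraction = vals / sum(pos),
                 populations = panel$individuals$population),
            class = "pca_result")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via `ape::nj`) on a valid symmetric
#' non-negative distance matrix; exact on additive distances. Negative
#' branch lengths, which NJ can produce on non-additive input, are
#' optionally clamped to zero with the deficit transferred to the adjacent
#' (sibling) edge, the standard post-processing; the number of clamped
#' edges is recorded in attribute `n_clamped`.
#'
#' @param dist a `dist_matrix` (see [dist_matrix()]) or a plain symmetric
#'   matrix with zero diagonal.
#' @param clamp_negative clamp negative branch lengths (default TRUE).
#' @return an `ape` `phylo` tree.
#' @export
neighbor_joining <- function(dist, clamp_negative = TRUE) {
  m <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  if (nrow(m) < 3) stop("need >= 3 labels")
  if (any(m < 0)) stop("distances must be non-negative")
  if (any(abs(m - t(m)) > 1e-12)) stop("distance matrix not symmetric")
  tree <- ape::nj(stats::as.dist(m))
  n_clamped <- 0L
  if (clamp_negative && any(tree$edge.length < 0)) {
    neg <- which(tree$edge.length < 0)
    n_clamped <- length(neg)
    for (e in neg) {
      parent <- tree$edge[e, 1]
      sibs <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      if (length(sibs))
        tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Average an individual-level distance matrix over populations
#'
#' Builds a population-level distance matrix by averaging all between-
#' population individual distances (diagonal zero), for population-level
#' trees.
#'
#' @param dist a `dist_matrix` over individuals.
#' @param pops character vector of population labels aligned with
#'   `dist$labels`.
#' @return a `dist_matrix` over populations.
#' @export
pool_distances <- function(dist, pops) {
  stopifnot(length(pops) == length(dist$labels))
  u <- unique(pops)
  m <- matrix(0, length(u), length(u), dimnames = list(u, u))
  for (a in seq_len(length(u) - 1)) {
    for (b in (a + 1):length(u)) {
      m[a, b] <- m[b, a] <-
        mean(dist$values[pops == u[a], pops == u[b]])
    }
  }
  dist_matrix(u, m)
}

#' Write / read Newick trees
#'
#' Thin wrappers over `ape` serialization; write-then-read round-trips are
#' stable in topology and branch lengths.
#'
#' @param tree a `phylo` tree.
#' @param path file path.
#' @return `write_newick`: the path, invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write PCA coordinates as TSV
#'
#' @param pca a `pca_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pca_tsv <- function(pca, path) {
  df <- data.frame(individual = rownames(pca$coordinates),
                   population = pca$populations,
                   pca$coordinates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
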
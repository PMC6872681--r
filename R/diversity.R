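#' Proportion of polymorphic SNPs within a population
#'
#' Fraction of the panel's SNPs that segregate (within-population MAF > 0)
#' in the given single-population panel. To avoid rare-variant artifacts
#' the SNP set is conventionally pre-filtered at a cohort-level MAF floor
#' (e.g. 0.1) before calling this; `maf_floor` applies that filter here if
#' the panel still carries the full cohort's SNPs.
#'
#' @param panel a single-population [genotype_panel()].
#' @param maf_floor optional within-panel MAF floor applied before
#'   counting (use 0 to evaluate the SNP set as-is).
#' @return fraction in `[0, 1]`.
#' @export
proportion_polymorphic <- function(panel, maf_floor = 0) {
  if (n_snps(panel) == 0) stop("panel has no SNPs")
  if (maf_floor > 0) {
    keep <- snp_maf(panel) > maf_floor
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) stop("no SNPs remain above maf_floor")
    panel <- subset_panel(panel, snps = panel$snps$id[keep])
  }
  maf <- snp_maf(panel)
  mean(maf > 0, na.rm = TRUE)
}

#' Expected and observed heterozygosity
#'
#' Per SNP, observed heterozygosity is the fraction of heterozygous calls
#' among non-missing calls and expected heterozygosity is `2p(1-p)` with
#' `p` the sample allele frequency; both are averaged over SNPs with at
#' least one call.
#'
#' @param panel a single-population [genotype_panel()].
#' @return named list with `h_e` and `h_o`.
#' @export
heterozygosity <- function(panel) {
  g <- panel$genotypes
  called <- colSums(!is.na(g))
  use <- called > 0
  if (!any(use)) stop("no SNPs with any non-missing call")
  p <- snp_freq(panel)[use]
  h_o <- colSums(g[, use, drop = FALSE] == 1L, na.rm = TRUE) / called[use]
  list(h_e = mean(2 * p * (1 - p)), h_o = mean(h_o))
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' allele copies, averaged over SNPs:
#' `a_r = sum_a [1 - C(N - N_a, g) / C(N, g)]` with `N` the non-missing
#' allele copies at the SNP and `N_a` the copies of allele `a`. SNPs with
#' fewer than `g` copies are excluded. For biallelic SNPs `a_r` lies in
#' `[1, 2]`.
#'
#' @param panel a single-population [genotype_panel()].
#' @param g standardized subsample size in allele copies (>= 1); default
#'   is the smallest per-SNP copy count so every SNP is usable.
#' @return mean allelic richness over usable SNPs.
#' @export
allelic_richness <- function(panel, g = NULL) {
  gmat <- panel$genotypes
  n_copies <- 2L * colSums(!is.na(gmat))
  if (is.null(g)) g <- min(n_copies[n_copies > 0])
  if (g < 1) stop("g must be >= 1")
  use <- n_copies >= g
  if (!any(use)) stop("no SNP has >= g allele copies")
  nb <- colSums(gmat[, use, drop = FALSE], na.rm = TRUE)   # copies of b
  n <- n_copies[use]
  na_ <- n - nb
  # P(allele present in subsample of g) = 1 - C(N - N_a, g)/C(N, g)
  miss_prob <- function(n_other) {
    ok <- n_other >= g
    out <- numeric(length(n_other))
    out[ok] <- exp(lchoose(n_other[ok], g) - lchoose(n[ok], g))
    out
  }
  ar <- (1 - miss_prob(n - na_)) + (1 - miss_prob(n - nb))
  mean(ar)
}

#' Method-of-moments inbreeding coefficient per individual
#'
#' `f = (O_hom - E_hom) / (L_used - E_hom)` per individual, with `O_hom`
#' the observed homozygous count over the individual's non-missing SNPs
#' and `E_hom` the small-sample-corrected Hardy-Weinberg expectation
#' `sum_l [1 - 2 p_l (1 - p_l) n_l / (n_l - 1)]` (`n_l` = non-missing
#' allele copies at SNP l in the panel). Individuals for whom
#' `L_used - E_hom` is ~0 (no informative SNPs) get `NA`.
#'
#' @param panel a single-population [genotype_panel()].
#' @return data.frame with `id`, `f`; population mean in attribute
#'   `f_mean`.
#' @export
inbreeding_coefficient <- function(panel) {
  g <- panel$genotypes
  p <- snp_freq(panel)
  n <- 2 * colSums(!is.na(g))
  usable <- n >= 2 & !is.na(p)
  g <- g[, usable, drop = FALSE]
  p <- p[usable]; n <- n[usable]
  e_l <- 1 - 2 * p * (1 - p) * n / (n - 1)
  called <- !is.na(g)
  o_hom <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  e_hom <- as.vector(called %*% e_l)
  l_used <- rowSums(called)
  denom <- l_used - e_hom
  f <- ifelse(abs(denom) < 1e-9, NA_real_, (o_hom - e_hom) / denom)
  out <- data.frame(id = panel$individuals$id, f = f,
                    stringsAsFactors = FALSE)
  attr(out, "f_mean") <- mean(f, na.rm = TRUE)
  out
}

#' Identity-by-state distance matrix
#'
#' Pairwise allele-sharing distance `1 - IBS`: similarity is the number of
#' shared allele copies divided by twice the number of SNPs called in both
#' individuals. Genotype pair (0,2) shares 0 copies, (0,1)/(1,2) share 1,
#' identical codes (including het-het) share 2.
#'
#' @param panel a [genotype_panel()] with >= 2 individuals.
#' @return a `dist_matrix`: list with `labels` and symmetric `values`
#'   matrix in `[0, 1]`, zero diagonal.
#' @export
ibs_distance_matrix <- function(panel) {
  g <- panel$genotypes
  n <- nrow(g)
  if (n < 2) stop("need >= 2 individuals")
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      m <- sum(ok)
      if (m == 0)
        stop("individuals ", rownames(g)[i], " and ", rownames(g)[j],
             " share no jointly called SNPs")
      shared <- sum(2L - abs(gi[ok] - gj[ok]))
      d[i, j] <- d[j, i] <- 1 - shared / (2 * m)
    }
  }
  dist_matrix(rownames(g), d)
}

#' Construct a distance-matrix object
#'
#' @param labels ordered ids.
#' @param values symmetric numeric matrix with zero diagonal.
#' @return a `dist_matrix`.
#' @export
dist_matrix <- function(labels, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels),
            ncol(values) == length(labels))
  if (any(!is.finite(values))) stop("distances must be finite")
  if (any(abs(values - t(values)) > 1e-12)) stop("matrix not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "dist_matrix")
}

#' Per-population diversity summary table
#'
#' Computes, for each population in the panel, the proportion of
#' polymorphic SNPs (on the cohort-level `maf_floor` subset), rarefaction
#' allelic richness at size `g`, mean expected/observed heterozygosity,
#' and the mean inbreeding coefficient.
#'
#' @param panel a multi-population [genotype_panel()].
#' @param maf_floor cohort-level MAF floor for the polymorphism subset
#'   (default 0.1).
#' @param g allele-copy rarefaction size; default twice the smallest
#'   population size.
#' @return data.frame with one row per population and columns
#'   `population`, `n`, `p_n`, `a_r`, `h_e`, `h_o`, `f_mean`.
#' @export
diversity_indices <- function(panel, maf_floor = 0.1, g = NULL) {
  keep <- snp_maf(panel) > maf_floor
  keep[is.na(keep)] <- FALSE
  sub <- subset_panel(panel, snps = panel$snps$id[keep])
  pops <- populations(panel)
  if (is.null(g)) {
    g <- 2L * min(table(panel$individuals$population))
  }
  rows <- lapply(pops, function(pp) {
    pk <- subset_panel(sub, populations = pp)
    het <- heterozygosity(pk)
    fr <- inbreeding_coefficient(pk)
    data.frame(population = pp, n = n_individuals(pk),
               p_n = proportion_polymorphic(pk),
               a_r = allelic_richness(pk, g = g),
               h_e = het$h_e, h_o = het$h_o,
               f_mean = attr(fr, "f_mean"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a square PHYLIP-format distance matrix
#'
#' @param dist a `dist_matrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_phylip_dist <- function(dist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dist$labels)), con)
  for (i in seq_along(dist$labels)) {
    writeLines(paste(c(sprintf("%-10s", dist$labels[i]),
                       sprintf("%.6f", dist$values[i, ])),
                     collapse = " "), con)
  }
  invisible(path)
}
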
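#' popdog: population genomics of SNP-array genotype panels
#'
#' Genotype-based population-genetics toolkit for multi-population
#' biallelic SNP panels: PLINK I/O and quality control, diversity indices,
#' linkage-disequilibrium decay and runs of homozygosity, an ANOVA-style
#' multi-population F_ST estimator, a windowed locus-specific divergence
#' (d_i) selection scan, PCA and neighbor-joining structure summaries,
#' ABBA-BABA D-statistics, and a founder-mosaic genotype simulator with
#' known ground truth.
#'
#' @name popdog-package
#' @keywords internal
"_PACKAGE"

#' Construct a genotype panel
#'
#' The central in-memory container: an individuals-by-SNPs matrix of
#' genotype codes counting copies of the minor allele (`allele_b`), with a
#' SNP map and individual metadata. Missing genotypes are `NA`.
#'
#' @param genotypes integer matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}` counting copies of `allele_b`.
#' @param snps data.frame with columns `id`, `chrom`, `pos_bp`, `allele_a`,
#'   `allele_b`. Positions are 1-based; within a chromosome records must be
#'   sorted by `pos_bp` (use `sort = TRUE` to sort on construction).
#' @param individuals data.frame with columns `id`, `population` and
#'   optionally `sex` (one of `"male"`, `"female"`, `"unknown"`).
#' @param sort logical; sort SNPs by chromosome and position first.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `snps`, `individuals`.
#' @export
genotype_panel <- function(genotypes, snps, individuals, sort = FALSE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (is.null(individuals$sex)) individuals$sex <- "unknown"
  snps$chrom <- as.character(snps$chrom)
  snps$pos_bp <- as.integer(snps$pos_bp)

  if (sort) {
    ord <- order(chrom_rank(snps$chrom), snps$pos_bp)
    snps <- snps[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
    rownames(snps) <- NULL
  }

  if (nrow(individuals) != nrow(genotypes) || nrow(snps) != ncol(genotypes))
    stop("genotype matrix shape does not match individuals x snps")
  if (anyDuplicated(individuals$id))
    stop("individual ids must be unique")
  if (any(!is.na(genotypes) & !(genotypes %in% 0:2)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(is.na(individuals$population) | individuals$population == ""))
    stop("every individual needs a non-empty population label")
  if (any(snps$pos_bp < 1L)) stop("positions must be >= 1")
  if (any(snps$allele_a == snps$allele_b))
    stop("allele_a and allele_b must differ")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos_bp[snps$chrom == ch]
    if (is.unsorted(p))
      stop("SNPs on chromosome ", ch, " are not sorted by position")
  }
  dimnames(genotypes) <- list(individuals$id, snps$id)
  structure(list(genotypes = genotypes, snps = snps,
                 individuals = individuals),
            class = "genotype_panel")
}

# Chromosome ordering: numeric labels first in numeric order, then others
# (X, ...) lexicographically.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(is.na(n), 1e6 + as.numeric(factor(chrom)), n)
  r
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d individuals x %d SNPs (%d chromosomes, %d populations)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(unique(x$snps$chrom)), length(unique(x$individuals$population))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Number of individuals / SNPs in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$genotypes)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) ncol(panel$genotypes)

#' Per-SNP allele-b frequency and call rate
#'
#' Frequencies use non-missing calls only; `snp_call_rate` is the fraction
#' of individuals called per SNP, `individual_call_rate` the fraction of
#' SNPs called per individual.
#'
#' @param panel a `genotype_panel`.
#' @return numeric vector, one entry per SNP (or per individual).
#' @export
snp_freq <- function(panel) {
  colMeans(panel$genotypes, na.rm = TRUE) / 2
}

#' @rdname snp_freq
#' @export
snp_maf <- function(panel) {
  f <- snp_freq(panel)
  pmin(f, 1 - f)
}

#' @rdname snp_freq
#' @export
snp_call_rate <- function(panel) {
  colMeans(!is.na(panel$genotypes))
}

#' @rdname snp_freq
#' @export
individual_call_rate <- function(panel) {
  rowMeans(!is.na(panel$genotypes))
}

#' Subset a genotype panel
#'
#' Restrict a panel by population, individual id, and/or chromosome while
#' preserving order. `autosomes_only = TRUE` drops the X chromosome (any
#' non-numeric chromosome label).
#'
#' @param panel a `genotype_panel`.
#' @param populations character vector of population codes to keep.
#' @param individuals character vector of individual ids to keep.
#' @param chroms character vector of chromosome labels to keep.
#' @param autosomes_only drop SNPs on non-numeric chromosomes (e.g. "X").
#' @param snps character vector of SNP ids to keep.
#' @return the restricted `genotype_panel`.
#' @export
subset_panel <- function(panel, populations = NULL, individuals = NULL,
                         chroms = NULL, autosomes_only = FALSE,
                         snps = NULL) {
  keep_ind <- rep(TRUE, n_individuals(panel))
  if (!is.null(populations)) {
    missing_pop <- setdiff(populations, panel$individuals$population)
    if (length(missing_pop))
      stop("unknown population label(s): ", paste(missing_pop, collapse = ", "))
    keep_ind <- keep_ind & panel$individuals$population %in% populations
  }
  if (!is.null(individuals)) {
    missing_id <- setdiff(individuals, panel$individuals$id)
    if (length(missing_id))
      stop("unknown individual id(s): ", paste(missing_id, collapse = ", "))
    keep_ind <- keep_ind & panel$individuals$id %in% individuals
  }
  keep_snp <- rep(TRUE, n_snps(panel))
  if (!is.null(chroms)) keep_snp <- keep_snp & panel$snps$chrom %in% chroms
  if (autosomes_only) {
    keep_snp <- keep_snp &
      !is.na(suppressWarnings(as.numeric(panel$snps$chrom)))
  }
  if (!is.null(snps)) keep_snp <- keep_snp & panel$snps$id %in% snps
  out_snps <- panel$snps[keep_snp, , drop = FALSE]
  rownames(out_snps) <- NULL
  out_ind <- panel$individuals[keep_ind, , drop = FALSE]
  rownames(out_ind) <- NULL
  genotype_panel(panel$genotypes[keep_ind, keep_snp, drop = FALSE],
                 out_snps, out_ind)
}

#' Population labels present in a panel
#' @param panel a `genotype_panel`.
#' @return character vector in order of first appearance.
#' @export
populations <- function(panel) unique(panel$individuals$population)
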
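#' Per-population allele frequencies and sample sizes
#'
#' For each requested population and SNP: the sample frequency of the
#' panel's `allele_b` from non-missing calls, and the sample size in
#' allele copies (2 x called individuals). Populations with no calls at a
#' SNP get frequency `NA` and size 0.
#'
#' @param panel a [genotype_panel()].
#' @param pops population codes (default: all populations in the panel).
#' @return an `allele_freq_table`: list with matrices `p` and `n`
#'   (populations x SNPs) plus the SNP map.
#' @export
allele_frequencies <- function(panel, pops = NULL) {
  if (is.null(pops)) pops <- populations(panel)
  missing_pop <- setdiff(pops, panel$individuals$population)
  if (length(missing_pop))
    stop("population(s) not in panel: ", paste(missing_pop, collapse = ", "))
  L <- n_snps(panel)
  p <- n <- matrix(0, length(pops), L, dimnames = list(pops, panel$snps$id))
  for (k in seq_along(pops)) {
    g <- panel$genotypes[panel$individuals$population == pops[k], ,
                         drop = FALSE]
    called <- colSums(!is.na(g))
    n[k, ] <- 2 * called
    p[k, ] <- ifelse(called > 0, colSums(g, na.rm = TRUE) / (2 * called),
                     NA_real_)
  }
  structure(list(p = p, n = n, snps = panel$snps),
            class = "allele_freq_table")
}

#' ANOVA-style per-SNP multi-population F_ST
#'
#' The mean-square estimator
#' `F_ST = (MSP - MSG) / (MSP + (n_c - 1) MSG)` with, per SNP over the `s`
#' populations with at least `min_copies` allele copies:
#' * `MSG = sum_i n_i p_i (1 - p_i) / sum_i (n_i - 1)` (within-population
#'   mean square; `msg_denom = "n"` uses `sum_i n_i` instead),
#' * `MSP = sum_i n_i (p_i - pbar)^2 / (s - 1)` (between-population mean
#'   square), `pbar = sum_i n_i p_i / sum_i n_i`,
#' * `n_c = (sum_i n_i - sum_i n_i^2 / sum_i n_i) / (s - 1)`, the
#'   variance-corrected average sample size.
#'
#' Sample sizes `n_i` are in allele copies. SNPs monomorphic across all
#' populations (MSG = MSP = 0) or with fewer than two usable populations
#' are undefined (`NA`). `fst_reported` truncates negative raw values at
#' 0; `fst_raw` is preserved for standardized-divergence scans.
#'
#' @param freqs an [allele_frequencies()] table.
#' @param msg_denom `"n_minus_1"` (default) or `"n"`: the within-
#'   population mean-square denominator reading.
#' @param min_copies minimum allele copies for a population to enter a
#'   SNP's estimate (default 2).
#' @return data.frame of class `fst_components` with per-SNP columns
#'   `snp`, `chrom`, `pos_bp`, `msg`, `msp`, `n_c`, `fst_raw`,
#'   `fst_reported`.
#' @export
per_snp_fst <- function(freqs, msg_denom = c("n_minus_1", "n"),
                        min_copies = 2) {
  msg_denom <- match.arg(msg_denom)
  p <- freqs$p; n <- freqs$n
  use <- n >= min_copies & !is.na(p)
  nu <- n * use
  pu <- ifelse(use, p, 0)
  s_eff <- colSums(use)
  sum_n <- colSums(nu)
  sum_n2 <- colSums(nu^2)
  pbar <- colSums(nu * pu) / sum_n
  denom_g <- if (msg_denom == "n_minus_1") colSums((nu - 1) * use)
             else sum_n
  msg <- colSums(nu * pu * (1 - pu)) / denom_g
  msp <- colSums(nu * (pu - rep(pbar, each = nrow(p)))^2 * use) /
    (s_eff - 1)
  n_c <- (sum_n - sum_n2 / sum_n) / (s_eff - 1)
  denom <- msp + (n_c - 1) * msg
  fst_raw <- ifelse(s_eff >= 2 & denom > 0, (msp - msg) / denom, NA_real_)
  out <- data.frame(snp = freqs$snps$id, chrom = freqs$snps$chrom,
                    pos_bp = freqs$snps$pos_bp,
                    msg = msg, msp = msp, n_c = n_c,
                    fst_raw = fst_raw,
                    fst_reported = pmax(fst_raw, 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("fst_components", "data.frame")
  out
}

#' Mean pairwise F_ST matrix over populations
#'
#' For every population pair, the mean of per-SNP truncated
#' (`fst_reported`) values over defined SNPs; monomorphic SNPs are
#' excluded rather than counted as zero. Autosomal SNPs only by default.
#'
#' @param panel a [genotype_panel()] with >= 2 populations.
#' @param pops population codes (default all).
#' @param autosomes_only restrict to numeric chromosome labels.
#' @param msg_denom passed to [per_snp_fst()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_fst_matrix <- function(panel, pops = NULL, autosomes_only = TRUE,
                                msg_denom = "n_minus_1") {
  if (autosomes_only) panel <- subset_panel(panel, autosomes_only = TRUE)
  if (is.null(pops)) pops <- populations(panel)
  if (length(pops) < 2) stop("need >= 2 populations")
  freqs <- allele_frequencies(panel, pops)
  m <- matrix(0, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (a in seq_len(length(pops) - 1)) {
    for (b in (a + 1):length(pops)) {
      sub <- structure(list(p = freqs$p[c(a, b), , drop = FALSE],
                            n = freqs$n[c(a, b), , drop = FALSE],
                            snps = freqs$snps),
                       class = "allele_freq_table")
      fst <- per_snp_fst(sub, msg_denom = msg_denom)
      vals <- fst$fst_reported[!is.na(fst$fst_raw)]
      if (!length(vals))
        stop("no defined SNPs for pair ", pops[a], "-", pops[b])
      m[a, b] <- m[b, a] <- mean(vals)
    }
  }
  m
}

#' Per-SNP raw F_ST tracks for all population pairs
#'
#' Convenience builder for standardized-divergence scans: a SNPs x pairs
#' matrix of untruncated per-SNP `fst_raw` values.
#'
#' @param panel a [genotype_panel()].
#' @param pops population codes (default all).
#' @param autosomes_only restrict to numeric chromosome labels.
#' @param msg_denom passed to [per_snp_fst()].
#' @return list with `fst` (SNPs x pairs matrix, columns named
#'   `"popA|popB"`), `pairs` (two-column matrix of codes), `snps` (map).
#' @export
pairwise_fst_tracks <- function(panel, pops = NULL, autosomes_only = TRUE,
                                msg_denom = "n_minus_1") {
  if (autosomes_only) panel <- subset_panel(panel, autosomes_only = TRUE)
  if (is.null(pops)) pops <- populations(panel)
  if (length(pops) < 2) stop("need >= 2 populations")
  freqs <- allele_frequencies(panel, pops)
  pr <- t(utils::combn(pops, 2))
  fst <- matrix(NA_real_, n_snps(panel), nrow(pr),
                dimnames = list(panel$snps$id,
                                paste(pr[, 1], pr[, 2], sep = "|")))
  for (q in seq_len(nrow(pr))) {
    sel <- match(pr[q, ], pops)
    sub <- structure(list(p = freqs$p[sel, , drop = FALSE],
                          n = freqs$n[sel, , drop = FALSE],
                          snps = freqs$snps),
                     class = "allele_freq_table")
    fst[, q] <- per_snp_fst(sub, msg_denom = msg_denom)$fst_raw
  }
  list(fst = fst, pairs = pr, snps = panel$snps)
}

#' Four-taxon ABBA-BABA D-statistic with block jackknife
#'
#' Frequency-based D over SNPs ordered by map position:
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` with
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`.
#' The Z-score comes from a delete-one block jackknife over contiguous
#' blocks of `block_snps` SNPs. D > 0 indicates excess allele sharing
#' between P2 and P3 (introgression), D < 0 between P1 and P3.
#'
#' @param panel a [genotype_panel()].
#' @param quartet character vector `c(P1, P2, P3, Outgroup)` of population
#'   codes.
#' @param block_snps jackknife block size in SNPs (default 300).
#' @return a `dstat_result`: list with `quartet`, `d`, `z`, `se`,
#'   `n_blocks`, `n_snps`.
#' @export
d_statistic <- function(panel, quartet, block_snps = 300) {
  stopifnot(length(quartet) == 4)
  freqs <- allele_frequencies(panel, quartet)
  p <- freqs$p
  ok <- colSums(is.na(p)) == 0
  p <- p[, ok, drop = FALSE]
  L <- ncol(p)
  if (L == 0) stop("no SNPs with defined frequencies in all four taxa")
  abba <- (1 - p[1, ]) * p[2, ] * p[3, ] * (1 - p[4, ])
  baba <- p[1, ] * (1 - p[2, ]) * p[3, ] * (1 - p[4, ])
  num <- abba - baba
  den <- abba + baba
  if (sum(den) == 0) stop("D undefined: no ABBA or BABA signal")
  d <- sum(num) / sum(den)
  block <- pmin((seq_len(L) - 1L) %/% block_snps + 1L,
                max(1L, L %/% block_snps))
  m <- max(block)
  z <- se <- NA_real_
  if (m >= 2) {
    bn <- tapply(num, block, sum)
    bd <- tapply(den, block, sum)
    d_loo <- (sum(bn) - bn) / (sum(bd) - bd)
    se <- sqrt((m - 1) / m * sum((d_loo - mean(d_loo))^2))
    z <- d / se
  }
  structure(list(quartet = quartet, d = d, z = z, se = se,
                 n_blocks = m, n_snps = L),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D(%s) = %.4f, Z = %.2f (%d blocks, %d SNPs)\n",
              paste(x$quartet, collapse = ", "), x$d,
              x$z, x$n_blocks, x$n_snps))
  invisible(x)
}
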
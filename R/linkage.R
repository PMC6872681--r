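#' Pairwise genotype-correlation LD
#'
#' For every same-chromosome SNP pair within `max_dist_kb`, computes the
#' squared Pearson correlation of genotype dosages over individuals with
#' both SNPs called (composite LD on genotypes, no phasing). Pairs
#' involving a zero-variance SNP are skipped. No r2 floor is applied.
#'
#' @param panel a single-population [genotype_panel()] (conventionally
#'   pre-filtered at MAF >= 0.05 and call rate >= 0.90).
#' @param max_dist_kb maximum pair distance in kb (default 500).
#' @return data.frame with columns `snp_i`, `snp_j`, `chrom`, `dist_bp`,
#'   `r2`.
#' @export
pairwise_r2 <- function(panel, max_dist_kb = 500) {
  max_bp <- max_dist_kb * 1000
  out <- list()
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    if (length(idx) < 2) next
    g <- panel$genotypes[, idx, drop = FALSE]
    pos <- panel$snps$pos_bp[idx]
    ids <- panel$snps$id[idx]
    cc <- suppressWarnings(
      stats::cor(g, use = "pairwise.complete.obs"))
    L <- length(idx)
    ii <- jj <- integer(0)
    for (a in seq_len(L - 1)) {
      b <- which(pos[(a + 1):L] - pos[a] <= max_bp) + a
      ii <- c(ii, rep(a, length(b))); jj <- c(jj, b)
    }
    if (!length(ii)) next
    r2 <- cc[cbind(ii, jj)]^2
    ok <- !is.na(r2)
    out[[ch]] <- data.frame(
      snp_i = ids[ii[ok]], snp_j = ids[jj[ok]], chrom = rep(ch, sum(ok)),
      dist_bp = pos[jj[ok]] - pos[ii[ok]], r2 = r2[ok],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp_i = character(0), snp_j = character(0),
                      chrom = character(0), dist_bp = integer(0),
                      r2 = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin an LD pair list into a decay curve
#'
#' @param pairs data.frame from [pairwise_r2()].
#' @param bin_width_kb bin width in kb (> 0).
#' @return data.frame of class `decay_curve` with `bin_start_kb`,
#'   `bin_end_kb`, `bin_mid_kb`, `mean_r2` (NA for empty bins), `n_pairs`.
#' @export
decay_curve <- function(pairs, bin_width_kb = 10) {
  if (bin_width_kb <= 0) stop("bin_width_kb must be > 0")
  if (nrow(pairs) == 0) stop("empty pair list")
  w <- bin_width_kb * 1000
  bin <- pmin(floor(pairs$dist_bp / w), ceiling(max(pairs$dist_bp) / w) - 1)
  nb <- max(bin) + 1L
  n_pairs <- tabulate(bin + 1L, nbins = nb)
  sums <- vapply(seq_len(nb) - 1L,
                 function(b) sum(pairs$r2[bin == b]), numeric(1))
  curve <- data.frame(
    bin_start_kb = (seq_len(nb) - 1L) * bin_width_kb,
    bin_end_kb = seq_len(nb) * bin_width_kb,
    bin_mid_kb = (seq_len(nb) - 0.5) * bin_width_kb,
    mean_r2 = ifelse(n_pairs > 0, sums / n_pairs, NA_real_),
    n_pairs = n_pairs)
  class(curve) <- c("decay_curve", "data.frame")
  curve
}

#' Distance at which LD decays to a threshold (e.g. r2 = 0.3)
#'
#' The decay curve's non-empty bins are smoothed to a monotone
#' non-increasing sequence by isotonic regression and the first downward
#' crossing of `threshold` is located by linear interpolation between the
#' flanking bin midpoints. If the smoothed curve never exceeds the
#' threshold the result is 0; if it never falls below, the maximum
#' distance is returned with attribute `censored = TRUE`.
#'
#' @param curve a [decay_curve()].
#' @param threshold r2 threshold in (0, 1); default 0.3.
#' @return distance in kb.
#' @export
r2_threshold_distance <- function(curve, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1)
  use <- !is.na(curve$mean_r2) & curve$n_pairs > 0
  if (!any(use)) stop("decay curve has no populated bins")
  x <- curve$bin_mid_kb[use]
  y <- curve$mean_r2[use]
  sm <- if (length(y) > 1) -stats::isoreg(x, -y)$yf else y
  if (max(sm) < threshold) return(0)
  if (min(sm) >= threshold) {
    out <- max(x)
    attr(out, "censored") <- TRUE
    return(out)
  }
  k <- which(sm < threshold)[1]   # first bin below; k > 1 here
  x1 <- x[k - 1]; x2 <- x[k]; y1 <- sm[k - 1]; y2 <- sm[k]
  x1 + (x2 - x1) * (y1 - threshold) / (y1 - y2)
}

# r2 between two dosage vectors over jointly called individuals
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy windowed LD pruning
#'
#' Left-to-right scan: within each window of `window_snps` SNPs, while any
#' retained pair has r2 >= `r2_max`, the member with the lower MAF is
#' removed (ties: the later position); the window then slides by
#' `step_snps`. The retained set has no intra-window pair at or above
#' `r2_max`.
#'
#' @param panel a [genotype_panel()].
#' @param r2_max removal threshold in (0, 1].
#' @param window_snps window size in SNPs (>= 2).
#' @param step_snps slide step in SNPs.
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(panel, r2_max = 0.5, window_snps = 50,
                     step_snps = 5) {
  stopifnot(r2_max > 0, r2_max <= 1)
  if (window_snps < 2) stop("window_snps must be >= 2")
  maf <- snp_maf(panel)
  keep <- rep(TRUE, n_snps(panel))
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    start <- 1L
    while (start <= length(idx)) {
      win <- idx[start:min(start + window_snps - 1L, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        g <- panel$genotypes[, act, drop = FALSE]
        removed_any <- FALSE
        for (a in seq_len(length(act) - 1)) {
          if (!keep[act[a]]) next
          for (b in (a + 1):length(act)) {
            if (!keep[act[b]]) next
            r2 <- pair_r2(g[, a], g[, b])
            if (!is.na(r2) && r2 >= r2_max) {
              # drop lower MAF; tie -> later position
              drop <- if (maf[act[a]] < maf[act[b]]) act[a]
                      else if (maf[act[b]] < maf[act[a]]) act[b]
                      else act[b]
              keep[drop] <- FALSE
              removed_any <- TRUE
            }
          }
        }
        if (!removed_any) break
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  panel$snps$id[keep]
}
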
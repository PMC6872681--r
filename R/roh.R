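#' Detect runs of homozygosity by the scanning-window vote
#'
#' Per individual and chromosome, a window of `window_snps` consecutive
#' SNPs slides one SNP at a time; a window is homozygous-eligible if it
#' contains at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls. A SNP is in-ROH when the
#' fraction of eligible windows covering it is at least `hit_fraction`.
#' Maximal runs of in-ROH SNPs are emitted as segments when their physical
#' span (1-based inclusive) is at least `min_length_kb` and they contain at
#' least `min_snps` SNPs. Chromosomes with fewer than `window_snps` SNPs
#' yield no calls. Intended for a panel pre-pruned of strong LD
#' (r2 >= 0.8).
#'
#' @param panel a [genotype_panel()].
#' @param window_snps scanning window size (default 50).
#' @param max_het_per_window allowed heterozygous calls per window
#'   (default 1).
#' @param max_missing_per_window allowed missing calls per window
#'   (default 5).
#' @param min_length_kb minimum segment span in kb (default 200).
#' @param min_snps minimum SNPs per segment (default 25).
#' @param hit_fraction minimum fraction of eligible covering windows for a
#'   SNP to be in-ROH (default 0.05).
#' @return data.frame with `individual`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(panel, window_snps = 50, max_het_per_window = 1,
                       max_missing_per_window = 5, min_length_kb = 200,
                       min_snps = 25, hit_fraction = 0.05) {
  segs <- list()
  min_bp <- min_length_kb * 1000
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    L <- length(idx)
    if (L < window_snps) next
    pos <- panel$snps$pos_bp[idx]
    nw <- L - window_snps + 1L
    for (i in seq_len(n_individuals(panel))) {
      g <- panel$genotypes[i, idx]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      ch_cum <- c(0L, cumsum(het))
      cm_cum <- c(0L, cumsum(mis))
      w_het <- ch_cum[(window_snps + 1):(L + 1)] - ch_cum[1:nw]
      w_mis <- cm_cum[(window_snps + 1):(L + 1)] - cm_cum[1:nw]
      elig <- as.integer(w_het <= max_het_per_window &
                           w_mis <= max_missing_per_window)
      ce <- c(0L, cumsum(elig))
      k <- seq_len(L)
      lo <- pmax(1L, k - window_snps + 1L)
      hi <- pmin(k, nw)
      frac <- (ce[hi + 1L] - ce[lo]) / (hi - lo + 1L)
      in_roh <- frac >= hit_fraction
      r <- rle(in_roh)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (s in which(r$values)) {
        a <- starts[s]; b <- ends[s]
        span <- pos[b] - pos[a] + 1L
        if (span >= min_bp && (b - a + 1L) >= min_snps) {
          segs[[length(segs) + 1L]] <- data.frame(
            individual = panel$individuals$id[i], chrom = ch,
            start_bp = pos[a], end_bp = pos[b], n_snps = b - a + 1L,
            n_het = sum(het[a:b]), n_missing = sum(mis[a:b]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(individual = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0)))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Accumulative ROH length per individual
#'
#' Sums segment lengths (`end_bp - start_bp + 1`) per individual.
#' Individuals present in `panel` but without segments get 0.
#'
#' @param segments data.frame from [detect_roh()].
#' @param panel optional [genotype_panel()] supplying the full individual
#'   list (and populations) for zero-filling.
#' @return data.frame with `individual`, `total_bp` (and `population` if
#'   `panel` given).
#' @export
accumulative_roh <- function(segments, panel = NULL) {
  len <- segments$end_bp - segments$start_bp + 1
  tot <- tapply(len, segments$individual, sum)
  if (is.null(panel)) {
    return(data.frame(individual = names(tot),
                      total_bp = as.numeric(tot),
                      stringsAsFactors = FALSE))
  }
  ids <- panel$individuals$id
  out <- data.frame(individual = ids,
                    population = panel$individuals$population,
                    total_bp = as.numeric(tot[ids]),
                    stringsAsFactors = FALSE)
  out$total_bp[is.na(out$total_bp)] <- 0
  out
}
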
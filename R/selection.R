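#' Genome-wide moments of pairwise F_ST
#'
#' Mean and population standard deviation (divisor N) of each pair's
#' untruncated per-SNP F_ST over all defined scan SNPs. Pairs whose track
#' has zero standard deviation are excluded with a warning: they carry no
#' standardizable signal.
#'
#' @param tracks output of [pairwise_fst_tracks()].
#' @return data.frame of class `pair_moments` with `pop_i`, `pop_j`,
#'   `e_fst`, `sd_fst`, `n_snps`.
#' @export
pair_moments <- function(tracks) {
  f <- tracks$fst
  out <- data.frame(pop_i = tracks$pairs[, 1], pop_j = tracks$pairs[, 2],
                    e_fst = NA_real_, sd_fst = NA_real_, n_snps = 0L,
                    stringsAsFactors = FALSE)
  for (q in seq_len(ncol(f))) {
    v <- f[, q][!is.na(f[, q])]
    if (length(v) < 2) stop("pair ", colnames(f)[q],
                            " has < 2 defined SNPs")
    out$e_fst[q] <- mean(v)
    out$sd_fst[q] <- sqrt(mean((v - mean(v))^2))
    out$n_snps[q] <- length(v)
  }
  zero <- out$sd_fst == 0
  if (any(zero)) {
    warning("excluding pair(s) with zero F_ST standard deviation: ",
            paste(colnames(f)[zero], collapse = ", "))
    out <- out[!zero, , drop = FALSE]
  }
  class(out) <- c("pair_moments", "data.frame")
  out
}

#' Per-SNP standardized divergence d_i
#'
#' For each focal breed i, the sum over all other breeds j of the pair's
#' per-SNP F_ST standardized by that pair's genome-wide moments:
#' `d_i = sum_{j != i} (F_ST^ij - E[F_ST^ij]) / sd[F_ST^ij]`.
#' Untruncated per-SNP values are used throughout. A SNP is undefined
#' (`NA`) for breed i when any constituent pairwise value is undefined
#' there.
#'
#' @param tracks output of [pairwise_fst_tracks()].
#' @param moments a [pair_moments()] table (default: computed from
#'   `tracks`).
#' @param breeds focal breeds (default: all populations in `tracks`).
#' @return list with `di` (SNPs x breeds matrix), `snps` (map),
#'   `moments`.
#' @export
di_per_snp <- function(tracks, moments = NULL, breeds = NULL) {
  if (is.null(moments)) moments <- pair_moments(tracks)
  all_pops <- unique(c(tracks$pairs[, 1], tracks$pairs[, 2]))
  if (is.null(breeds)) breeds <- all_pops
  key <- paste(tracks$pairs[, 1], tracks$pairs[, 2], sep = "|")
  mkey <- paste(moments$pop_i, moments$pop_j, sep = "|")
  di <- matrix(NA_real_, nrow(tracks$fst), length(breeds),
               dimnames = list(rownames(tracks$fst), breeds))
  for (i in seq_along(breeds)) {
    b <- breeds[i]
    qs <- which(tracks$pairs[, 1] == b | tracks$pairs[, 2] == b)
    qs <- qs[key[qs] %in% mkey]
    if (!length(qs)) stop("breed ", b, " has no standardizable partner")
    mm <- moments[match(key[qs], mkey), ]
    z <- sweep(tracks$fst[, qs, drop = FALSE], 2, mm$e_fst, "-")
    z <- sweep(z, 2, mm$sd_fst, "/")
    di[, i] <- rowSums(z)  # NA propagates when any pair is undefined
  }
  list(di = di, snps = tracks$snps, moments = moments)
}

#' Aggregate a d_i track into fixed 200-kb windows
#'
#' Windows tile each chromosome on a fixed grid anchored at position 1
#' (`[1, window_bp]`, `[window_bp + 1, 2 window_bp]`, ...). Each window's
#' `mean_di` averages the SNPs with defined d_i inside it; windows with
#' fewer than `min_snps` such SNPs are discarded.
#'
#' @param di_track numeric vector of per-SNP d_i values (NA = undefined).
#' @param snps SNP map (data.frame with `chrom`, `pos_bp`) aligned with
#'   `di_track`.
#' @param window_bp window size in bp (default 200000).
#' @param min_snps minimum defined SNPs per retained window (default 6).
#' @return data.frame of class `scan_windows` with `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `mean_di`.
#' @export
window_scan <- function(di_track, snps, window_bp = 200000L,
                        min_snps = 6) {
  ok <- !is.na(di_track)
  if (!any(ok)) stop("d_i track has no defined SNPs")
  chrom <- snps$chrom[ok]
  win <- (snps$pos_bp[ok] - 1L) %/% window_bp
  key <- paste(chrom, win, sep = ":")
  n <- tapply(di_track[ok], key, length)
  mu <- tapply(di_track[ok], key, mean)
  parts <- strsplit(names(n), ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start_bp = as.numeric(vapply(parts, `[`, "", 2)) * window_bp + 1,
    end_bp = (as.numeric(vapply(parts, `[`, "", 2)) + 1) * window_bp,
    n_snps = as.integer(n), mean_di = as.numeric(mu),
    stringsAsFactors = FALSE)
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_windows", "data.frame")
  out
}

#' Call outlier windows at an empirical percentile
#'
#' Returns the windows whose `mean_di` is at or above the empirical
#' `percentile` of the supplied window distribution (one breed's retained
#' windows). The threshold is the linear-interpolation quantile; ties at
#' the threshold are included. Fewer than 20 windows triggers an
#' unstable-threshold warning.
#'
#' @param windows a [window_scan()] table for one breed.
#' @param percentile upper percentile in (0, 100); default 99.5.
#' @return the called subset of `windows`, with the threshold in
#'   attribute `threshold`.
#' @export
call_outliers <- function(windows, percentile = 99.5) {
  stopifnot(percentile > 0, percentile < 100)
  if (nrow(windows) < 20)
    warning("only ", nrow(windows),
            " windows; empirical percentile threshold is unstable")
  thr <- as.numeric(stats::quantile(windows$mean_di, percentile / 100,
                                    type = 7))
  called <- windows[windows$mean_di >= thr, , drop = FALSE]
  rownames(called) <- NULL
  attr(called, "threshold") <- thr
  called
}

#' Merge grid-adjacent called windows into regions
#'
#' Called windows on the same chromosome whose grid intervals touch
#' (`start == previous end + 1`) merge into one region; isolated windows
#' become single-window regions. `peak_di` is the maximum member mean.
#'
#' @param called a called [window_scan()] subset (fixed-grid windows).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `peak_di`.
#' @export
merge_regions <- function(called) {
  if (nrow(called) == 0)
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_windows = integer(0),
                      peak_di = numeric(0)))
  called <- called[order(chrom_rank(called$chrom), called$start_bp), ,
                   drop = FALSE]
  new_region <- c(TRUE, !(called$chrom[-1] == called$chrom[-nrow(called)] &
                            called$start_bp[-1] ==
                              called$end_bp[-nrow(called)] + 1))
  gid <- cumsum(new_region)
  out <- data.frame(
    chrom = tapply(called$chrom, gid, `[`, 1),
    start_bp = as.numeric(tapply(called$start_bp, gid, min)),
    end_bp = as.numeric(tapply(called$end_bp, gid, max)),
    n_windows = as.integer(tapply(gid, gid, length)),
    peak_di = as.numeric(tapply(called$mean_di, gid, max)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-breed windowed selection scan
#'
#' Full d_i scan over all breeds of a panel: pairwise raw F_ST tracks,
#' genome-wide pair moments, per-SNP d_i, fixed 200-kb window means,
#' per-breed empirical-percentile outlier calling and region merging.
#' Autosomes only.
#'
#' @param panel a multi-population [genotype_panel()].
#' @param breeds focal breeds (default all populations).
#' @param window_bp,min_snps,percentile scan parameters (defaults
#'   200 kb, 6 SNPs, 99.5).
#' @param msg_denom passed to [per_snp_fst()].
#' @return list of class `selection_scan`: per-breed `windows` (with
#'   `called` flag), `regions`, `thresholds`, plus `moments` and scan
#'   metadata.
#' @export
selection_scan <- function(panel, breeds = NULL, window_bp = 200000L,
                           min_snps = 6, percentile = 99.5,
                           msg_denom = "n_minus_1") {
  tracks <- pairwise_fst_tracks(panel, pops = breeds,
                                autosomes_only = TRUE,
                                msg_denom = msg_denom)
  dd <- di_per_snp(tracks, breeds = breeds)
  breeds <- colnames(dd$di)
  windows <- regions <- list()
  thresholds <- numeric(0)
  for (b in breeds) {
    w <- window_scan(dd$di[, b], dd$snps, window_bp = window_bp,
                     min_snps = min_snps)
    called <- call_outliers(w, percentile = percentile)
    w$called <- paste(w$chrom, w$start_bp) %in%
      paste(called$chrom, called$start_bp)
    windows[[b]] <- w
    regions[[b]] <- merge_regions(called)
    thresholds[b] <- attr(called, "threshold")
  }
  structure(list(windows = windows, regions = regions,
                 thresholds = thresholds, moments = dd$moments,
                 breeds = breeds, window_bp = window_bp,
                 min_snps = min_snps, percentile = percentile),
            class = "selection_scan")
}

#' Two-group contrast selection scan
#'
#' Pools populations into a focal and a background group, treats the two
#' groups as two populations, and runs the standardized-divergence scan;
#' with a single pair the statistic reduces to `(F_ST - E) / sd` per SNP.
#' Moments are re-estimated from the two-group track itself.
#'
#' @param panel a [genotype_panel()].
#' @param group_assignment named character vector or list mapping
#'   population codes to `"focal"` or `"background"`; populations not
#'   mentioned are dropped.
#' @param window_bp,min_snps,percentile scan parameters.
#' @param msg_denom passed to [per_snp_fst()].
#' @return list with `windows` (with `called` flag), `regions`,
#'   `threshold`, `moments`.
#' @export
group_contrast_scan <- function(panel, group_assignment,
                                window_bp = 200000L, min_snps = 6,
                                percentile = 99.5,
                                msg_denom = "n_minus_1") {
  ga <- unlist(group_assignment)
  if (!all(ga %in% c("focal", "background")))
    stop("group_assignment values must be 'focal' or 'background'")
  if (anyDuplicated(names(ga)))
    stop("population assigned to both groups: ",
         names(ga)[duplicated(names(ga))][1])
  focal <- names(ga)[ga == "focal"]
  background <- names(ga)[ga == "background"]
  if (!length(focal) || !length(background))
    stop("both groups must be non-empty")
  if (identical(sort(focal), sort(background)))
    stop("focal and background groups are identical")
  sub <- subset_panel(panel, populations = c(focal, background))
  sub$individuals$population <-
    ifelse(sub$individuals$population %in% focal, "focal", "background")
  tracks <- pairwise_fst_tracks(sub, pops = c("focal", "background"),
                                autosomes_only = TRUE,
                                msg_denom = msg_denom)
  dd <- di_per_snp(tracks, breeds = "focal")
  w <- window_scan(dd$di[, "focal"], dd$snps, window_bp = window_bp,
                   min_snps = min_snps)
  called <- call_outliers(w, percentile = percentile)
  w$called <- paste(w$chrom, w$start_bp) %in%
    paste(called$chrom, called$start_bp)
  list(windows = w, regions = merge_regions(called),
       threshold = attr(called, "threshold"), moments = dd$moments)
}
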
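fake_tracks <- function(fst, pairs, chrom = NULL, pos = NULL) {
  L <- nrow(fst)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- seq_len(L)
  colnames(fst) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  list(fst = fst, pairs = pairs,
       snps = data.frame(id = paste0("s", seq_len(L)), chrom = chrom,
                         pos_bp = pos, stringsAsFactors = FALSE))
}

test_that("pair moments use the population standard deviation over defined SNPs", {
  fst <- cbind(c(0, 0.5), c(0.3, 0.3))
  tr <- fake_tracks(fst, rbind(c("a", "b"), c("a", "c")))
  expect_warning(m <- pair_moments(tr), "zero F_ST standard deviation")
  expect_equal(m$e_fst, 0.25)       # the constant a|c pair is excluded
  expect_equal(m$sd_fst, 0.25)      # divisor-N sd of {0, 0.5}
  expect_equal(nrow(m), 1)
})

test_that("d_i sums standardized pairwise divergences per SNP", {
  # hand-set: fst12 = 0.6 with moments (0.2, 0.2); fst13 = 0.2 with
  # moments (0.1, 0.1) -> d_1 = 2 + 1 = 3
  fst <- rbind(c(0.6, 0.2), c(0.2, 0.1), c(NA, 0.1))
  tr <- fake_tracks(fst, rbind(c("b1", "b2"), c("b1", "b3")))
  m <- data.frame(pop_i = c("b1", "b1"), pop_j = c("b2", "b3"),
                  e_fst = c(0.2, 0.1), sd_fst = c(0.2, 0.1),
                  n_snps = c(3L, 3L))
  d <- di_per_snp(tr, moments = m, breeds = "b1")
  expect_equal(unname(d$di[1, "b1"]), 3.0)
  # SNP where every pair sits at its mean -> d_i = 0
  expect_equal(unname(d$di[2, "b1"]), 0)
  # undefined constituent pair -> NA, not zero
  expect_true(is.na(d$di[3, "b1"]))
})

test_that("genome-wide mean d_i is ~0 when all SNPs are defined for all pairs", {
  sim <- simulate_panel(sim_config(n_pops = 4, n_per_pop = 10, n_chrom = 1,
                                   chrom_length_bp = 10e6,
                                   missing_rate = 0, seed = 16))
  tr <- pairwise_fst_tracks(sim$panel)
  # restrict to SNPs defined for every pair so the centering set and the
  # averaging set coincide
  ok <- rowSums(is.na(tr$fst)) == 0
  tr$fst <- tr$fst[ok, , drop = FALSE]
  tr$snps <- tr$snps[ok, , drop = FALSE]
  d <- di_per_snp(tr)
  for (b in colnames(d$di))
    expect_equal(mean(d$di[, b]), 0, tolerance = 1e-10)
})

test_that("window scan tiles a fixed grid and applies the SNP minimum", {
  # 20 SNPs over 3 windows; window 2 has only 5 SNPs -> discarded
  pos <- c(seq(1000, 190000, length.out = 8),
           seq(210000, 390000, length.out = 5),
           seq(410000, 590000, length.out = 7))
  di <- c(rep(1, 8), rep(9, 5), rep(2, 7))
  snps <- data.frame(chrom = "1", pos_bp = as.integer(pos))
  w <- window_scan(di, snps, window_bp = 200000L, min_snps = 6)
  expect_equal(nrow(w), 2)
  expect_equal(w$start_bp, c(1, 400001))
  expect_equal(w$end_bp, c(200000, 600000))
  expect_equal(w$mean_di, c(1, 2))
  expect_equal(w$n_snps, c(8L, 7L))
  # windows whose SNPs share one value average to exactly that value
  w2 <- window_scan(rep(3.5, 20), snps, min_snps = 5)
  expect_true(all(w2$mean_di == 3.5))
  expect_error(window_scan(rep(NA_real_, 3),
                           data.frame(chrom = "1", pos_bp = 1:3)),
               "no defined SNPs")
})

test_that("outlier calling takes the upper empirical percentile with ties", {
  set.seed(17)
  w <- data.frame(chrom = "1", start_bp = seq(1, by = 200000, length.out = 1000),
                  end_bp = seq(200000, by = 200000, length.out = 1000),
                  n_snps = 10L, mean_di = rnorm(1000))
  called <- call_outliers(w, 99.5)
  expect_equal(nrow(called), 5)   # ~0.5% of 1,000
  expect_true(all(called$mean_di >= attr(called, "threshold")))
  expect_gte(min(called$mean_di), sort(w$mean_di, decreasing = TRUE)[6])
  # degenerate: all equal -> everything ties at the threshold
  w_eq <- w; w_eq$mean_di <- 1
  expect_equal(nrow(call_outliers(w_eq, 99.5)), 1000)
  # small scans warn about unstable thresholds
  expect_warning(call_outliers(w[1:10, ], 99.5), "unstable")
})

test_that("region merging joins grid-adjacent windows only", {
  mk <- function(starts) {
    data.frame(chrom = "1", start_bp = starts, end_bp = starts + 199999,
               n_snps = 10L, mean_di = seq_along(starts))
  }
  # pattern [1,1,0,1,0,1] -> 3 regions
  called <- mk(c(1, 200001, 600001, 1000001))
  r <- merge_regions(called)
  expect_equal(nrow(r), 3)
  expect_equal(r$end_bp[1] - r$start_bp[1] + 1, 400000)
  expect_equal(r$n_windows, c(2L, 1L, 1L))
  expect_equal(r$peak_di, c(2, 3, 4))
  # windows on different chromosomes never merge
  called2 <- mk(c(1, 200001)); called2$chrom <- c("1", "2")
  expect_equal(nrow(merge_regions(called2)), 2)
  expect_equal(nrow(merge_regions(called2[0, ])), 0)
})

test_that("planted sweeps are recovered by the per-breed scan", {
  pops <- paste0("breed", 1:10)
  targets <- lapply(1:10, function(i)
    list(pop = pops[i], chrom = ((i - 1) %% 2) + 1,
         start_bp = (10 + 10 * i) * 200000 + 1,
         end_bp = (11 + 10 * i) * 200000, freq_shift = 0.4))
  sim <- simulate_panel(sim_config(
    n_pops = 10, n_per_pop = 12, n_chrom = 2, chrom_length_bp = 25e6,
    fst_param = 0.1, selection_targets = targets, pop_names = pops,
    seed = 42))
  scan <- selection_scan(sim$panel)
  hits <- vapply(1:10, function(i) {
    w <- scan$windows[[pops[i]]]
    t <- targets[[i]]
    any(w$called & w$chrom == as.character(t$chrom) &
          w$start_bp == t$start_bp)
  }, TRUE)
  expect_gte(sum(hits), 8)
  # focal-breed d_i inside planted windows exceeds the genome-wide mean
  tr <- pairwise_fst_tracks(sim$panel)
  d <- di_per_snp(tr)
  t1 <- targets[[1]]
  inside <- d$snps$chrom == as.character(t1$chrom) &
    d$snps$pos_bp >= t1$start_bp & d$snps$pos_bp <= t1$end_bp
  expect_gt(mean(d$di[inside, "breed1"], na.rm = TRUE),
            mean(d$di[, "breed1"], na.rm = TRUE) + 2)
})

test_that("group contrasts reduce to the single-pair standardization", {
  sim <- simulate_panel(sim_config(n_pops = 4, n_per_pop = 10, n_chrom = 2,
                                   chrom_length_bp = 20e6, seed = 18))
  ga <- c(pop1 = "focal", pop2 = "focal",
          pop3 = "background", pop4 = "background")
  res <- group_contrast_scan(sim$panel, ga)
  expect_equal(nrow(res$moments), 1)
  expect_true(all(c("windows", "regions", "threshold") %in% names(res)))
  # called fraction ~0.5% of retained windows (upper-tail cut)
  frac <- sum(res$windows$called) / nrow(res$windows)
  expect_lt(frac, 0.02)
  expect_gt(frac, 0)
  # errors: bad labels, duplicated assignment, empty group
  expect_error(group_contrast_scan(sim$panel, c(pop1 = "x")), "focal")
  expect_error(group_contrast_scan(
    sim$panel, c(pop1 = "focal", pop1 = "background", pop2 = "background")),
    "both groups")
  expect_error(group_contrast_scan(sim$panel, c(pop1 = "focal")),
               "non-empty")
})
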
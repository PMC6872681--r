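test_that("r2 is 1 for duplicated SNPs and invariant to allele recoding", {
  set.seed(71)
  x <- rbinom(30, 2, 0.4)
  g <- cbind(x, x, 2L - x, rbinom(30, 2, 0.5))
  p <- make_panel(g, pos = c(100L, 200L, 300L, 400L))
  pr <- pairwise_r2(p, max_dist_kb = 500)
  get <- function(i, j)
    pr$r2[pr$snp_i == sprintf("s%03d", i) & pr$snp_j == sprintf("s%03d", j)]
  expect_equal(get(1, 2), 1)          # duplicated column
  expect_equal(get(1, 3), 1)          # 2 - x recoding
  expect_equal(get(1, 4), get(2, 4))  # same SNP under either copy
  expect_equal(get(1, 4), get(3, 4))  # recoding-invariant against others
})

test_that("r2 pairs respect the distance cap and skip zero-variance SNPs", {
  set.seed(72)
  g <- cbind(rbinom(20, 2, 0.5), rep(1L, 20), rbinom(20, 2, 0.5))
  p <- make_panel(g, pos = c(1000L, 2000L, 700000L))
  pr <- pairwise_r2(p, max_dist_kb = 500)
  # SNP3 is 699 kb from SNP1: beyond cap; SNP2 has zero variance
  expect_equal(nrow(pr), 0)
  pr2 <- pairwise_r2(p, max_dist_kb = 1000)
  expect_equal(nrow(pr2), 1)
  expect_equal(pr2$dist_bp, 699000L)
})

test_that("independent SNPs show the ~1/n small-sample r2 bias", {
  set.seed(73)
  n <- 50
  g <- matrix(rbinom(n * 200, 2, 0.5), n, 200)
  p <- make_panel(g, pos = seq_len(200) * 100L)
  pr <- pairwise_r2(p, max_dist_kb = 500)
  expect_equal(mean(pr$r2), 1 / (n - 1), tolerance = 0.15)
})

test_that("decay curve bins pairs and the r2 threshold interpolates", {
  pairs <- data.frame(snp_i = "a", snp_j = "b",
                      dist_bp = c(5000, 8000, 15000, 16000),
                      r2 = c(0.5, 0.3, 0.2, 0.2))
  cv <- decay_curve(pairs, bin_width_kb = 10)
  expect_equal(cv$mean_r2, c(0.4, 0.2))
  expect_equal(cv$n_pairs, c(2L, 2L))
  expect_error(decay_curve(pairs, bin_width_kb = 0), "> 0")
  # bins (mid 10 kb, r2 0.4) and (mid 20 kb, r2 0.2): threshold 0.3
  # crosses at 15 kb by linear interpolation
  cv2 <- data.frame(bin_start_kb = c(5, 15), bin_end_kb = c(15, 25),
                    bin_mid_kb = c(10, 20), mean_r2 = c(0.4, 0.2),
                    n_pairs = c(10L, 10L))
  expect_equal(r2_threshold_distance(cv2, 0.3), 15)
  # never above threshold -> 0
  cv3 <- transform(cv2, mean_r2 = c(0.2, 0.1))
  expect_equal(r2_threshold_distance(cv3, 0.3), 0)
  # never below -> max distance, flagged
  cv4 <- transform(cv2, mean_r2 = c(0.9, 0.8))
  out <- r2_threshold_distance(cv4, 0.3)
  expect_equal(as.numeric(out), 20)
  expect_true(attr(out, "censored"))
})

test_that("LD extent r2_0.3 shrinks as the founder pool grows", {
  r03 <- vapply(c(2, 100), function(fp) {
    sim <- simulate_panel(sim_config(n_pops = 1, n_per_pop = 12,
                                     n_chrom = 1, chrom_length_bp = 10e6,
                                     founders_per_pop = fp, seed = 11))
    cv <- decay_curve(pairwise_r2(sim$panel, 500))
    as.numeric(r2_threshold_distance(cv, 0.3))
  }, 0)
  expect_gt(r03[1], r03[2])  # strictly larger LD extent with 2 founders
})

test_that("greedy LD pruning removes the lower-MAF member of tight pairs", {
  set.seed(74)
  x <- rbinom(40, 2, 0.5)
  y <- x; y[1] <- if (x[1] == 0) 1L else 0L  # near-duplicate, lower MAF
  ind <- matrix(rbinom(40 * 3, 2, 0.3), 40, 3)
  g <- cbind(x, y, ind)
  p <- make_panel(g, pos = c(100L, 200L, 300L, 400L, 500L))
  kept <- ld_prune(p, r2_max = 0.5, window_snps = 5, step_snps = 2)
  # exactly one of the duplicated pair is retained
  expect_equal(sum(c("s001", "s002") %in% kept), 1)
  # the retained one is the higher-MAF member
  maf <- snp_maf(p)[1:2]
  expect_true(sprintf("s%03d", which.max(maf)) %in% kept)
  # retained set has no intra-window pair >= r2_max
  sub <- subset_panel(p, snps = kept)
  pr <- pairwise_r2(sub, 500)
  expect_true(all(pr$r2 < 0.5))
  # mutually independent SNPs are untouched
  p_ind <- make_panel(ind, pos = c(100L, 200L, 300L))
  expect_equal(ld_prune(p_ind, r2_max = 0.99, window_snps = 3,
                        step_snps = 1),
               p_ind$snps$id)
  expect_error(ld_prune(p, window_snps = 1), ">= 2")
})

test_that("ROH detection matches construction on simple fixtures", {
  # all-heterozygous individual: no segments
  p_het <- make_panel(matrix(1L, 1, 60), pos = seq_len(60) * 20000L)
  expect_equal(nrow(detect_roh(p_het)), 0)
  # fully homozygous 60-SNP chromosome spanning > 1 Mb: one segment from
  # the first to the last SNP
  p_hom <- make_panel(matrix(0L, 1, 60), pos = seq_len(60) * 20000L)
  segs <- detect_roh(p_hom)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, 20000L)
  expect_equal(segs$end_bp, 1200000L)
  expect_equal(segs$n_snps, 60L)
  # chromosome shorter than the scanning window yields no calls
  p_short <- make_panel(matrix(0L, 1, 40), pos = seq_len(40) * 20000L)
  expect_equal(nrow(detect_roh(p_short)), 0)
})

test_that("het interruptions break tracts per the exhaustive window vote", {
  pos <- seq_len(200) * 10000L
  base <- rep(0L, 200)
  mk <- function(het_at) {
    g <- base; g[het_at] <- 1L
    make_panel(matrix(g, 1), pos = pos)
  }
  for (het_at in list(c(100, 110), c(40, 160), c(90, 91))) {
    g <- base; g[het_at] <- 1L
    segs <- detect_roh(mk(het_at), min_length_kb = 200, min_snps = 25)
    vote <- oracle_roh_in_snp(g, 50, 1, 5, 0.05)
    r <- rle(vote); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    exp_segs <- data.frame(start = starts[r$values], end = ends[r$values])
    exp_segs <- exp_segs[(pos[exp_segs$end] - pos[exp_segs$start] + 1) >=
                           200000 & (exp_segs$end - exp_segs$start + 1) >= 25, ]
    expect_equal(segs$start_bp, pos[exp_segs$start])
    expect_equal(segs$end_bp, pos[exp_segs$end])
  }
  # two hets within one window span break the tract; far apart they do not
  segs_near <- detect_roh(mk(c(90, 91)))
  segs_far <- detect_roh(mk(c(40, 160)))
  expect_gt(nrow(segs_far), 0)
  expect_gt(nrow(segs_near), nrow(segs_far) - 1)  # both defined
})

test_that("emitted ROH segments respect all thresholds when re-checked", {
  sim <- simulate_panel(sim_config(n_pops = 1, n_per_pop = 10, n_chrom = 2,
                                   chrom_length_bp = 10e6,
                                   founders_per_pop = 2,
                                   missing_rate = 0.02, seed = 81))
  segs <- detect_roh(sim$panel)
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$end_bp - segs$start_bp + 1 >= 200000))
  expect_true(all(segs$n_snps >= 25))
  # independent re-check of the vote for every segment SNP
  for (r in seq_len(min(nrow(segs), 10))) {
    ind <- which(sim$panel$individuals$id == segs$individual[r])
    idx <- which(sim$panel$snps$chrom == segs$chrom[r])
    g <- sim$panel$genotypes[ind, idx]
    vote <- oracle_roh_in_snp(g, 50, 1, 5, 0.05)
    covered <- sim$panel$snps$pos_bp[idx] >= segs$start_bp[r] &
      sim$panel$snps$pos_bp[idx] <= segs$end_bp[r]
    expect_true(all(vote[covered]))
  }
})

test_that("ROH output is invariant to individual order and monotone in min length", {
  sim <- simulate_panel(sim_config(n_pops = 1, n_per_pop = 6, n_chrom = 1,
                                   chrom_length_bp = 8e6,
                                   founders_per_pop = 2, seed = 82))
  segs <- detect_roh(sim$panel)
  perm <- sample(n_individuals(sim$panel))
  p2 <- subset_panel(sim$panel,
                     individuals = sim$panel$individuals$id[perm])
  segs2 <- detect_roh(p2)
  key <- function(s) sort(paste(s$individual, s$chrom, s$start_bp, s$end_bp))
  expect_equal(key(segs2), key(segs))
  # lowering the minimum length never removes a segment
  segs_lo <- detect_roh(sim$panel, min_length_kb = 50, min_snps = 25)
  expect_true(all(paste(segs$individual, segs$start_bp) %in%
                    paste(segs_lo$individual, segs_lo$start_bp)))
  # accumulative lengths
  expect_equal(accumulative_roh(segs)$total_bp,
               as.numeric(tapply(segs$end_bp - segs$start_bp + 1,
                                 segs$individual, sum)))
})
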
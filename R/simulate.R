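#' Simulation configuration
#'
#' Defines a multi-population biallelic autosomal SNP panel with known
#' ground truth. Divergence follows the Balding-Nichols model: per-SNP
#' ancestral frequency p ~ Uniform(0.05, 0.95) and population frequency
#' p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F), whose F parameter equals the
#' expected ANOVA-style F_ST. Within-population LD and autozygosity are
#' produced by a founder-mosaic scheme: `founders_per_pop` founder
#' haplotypes are drawn per population and each individual's two haplotypes
#' are recombinant mosaics of them (crossovers Poisson with `recomb_rate`
#' per bp), so few founders mean long shared tracts (high LD, long runs of
#' homozygosity).
#'
#' Defaults emulate a multi-breed SNP-chip panel at desk scale: 12
#' individuals per population, ~12.5 SNPs per 200 kb, between-population
#' F of 0.1, 1 cM/Mb recombination, 2% missingness.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (scalar or vector).
#' @param n_chrom number of autosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param snp_density expected SNPs per bp (default 12.5 per 200 kb).
#' @param fst_param Balding-Nichols F per population in `[0, 1)`
#'   (scalar or vector).
#' @param founders_per_pop founder haplotypes per population (>= 2).
#' @param recomb_rate per-bp crossover probability per copying step.
#' @param missing_rate i.i.d. genotype missingness fraction.
#' @param selection_targets list of lists with elements `pop`, `chrom`,
#'   `start_bp`, `end_bp`, `freq_shift`: SNPs in the interval have the
#'   focal population's frequency shifted by `freq_shift` (clipped to
#'   `[0.02, 0.98]`) before genotypes are drawn.
#' @param pop_names population labels (default pop1, pop2, ...).
#' @param seed integer seed; a fixed seed makes the panel reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, n_per_pop = 12, n_chrom = 2,
                       chrom_length_bp = 25e6,
                       snp_density = 12.5 / 200e3,
                       fst_param = 0.1, founders_per_pop = 20,
                       recomb_rate = 1e-8, missing_rate = 0.02,
                       selection_targets = list(),
                       pop_names = NULL, seed = 1L) {
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst_param <- rep_len(fst_param, n_pops)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pops))
  stopifnot(length(pop_names) == n_pops,
            founders_per_pop >= 2,
            missing_rate >= 0, missing_rate <= 1,
            recomb_rate >= 0, snp_density > 0,
            all(fst_param >= 0))
  if (any(fst_param >= 1))
    stop("fst_param must be < 1 (F = 1 degenerates the Beta distribution)")
  for (t in selection_targets) {
    stopifnot(all(c("pop", "chrom", "start_bp", "end_bp", "freq_shift")
                  %in% names(t)))
    if (!t$pop %in% pop_names)
      stop("selection target population not simulated: ", t$pop)
    if (!as.character(t$chrom) %in% as.character(seq_len(n_chrom)))
      stop("selection target chromosome out of range: ", t$chrom)
    if (t$start_bp < 1 || t$end_bp > chrom_length_bp ||
        t$start_bp > t$end_bp)
      stop("selection target interval outside chromosome bounds")
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                 snp_density = snp_density, fst_param = fst_param,
                 founders_per_pop = founders_per_pop,
                 recomb_rate = recomb_rate, missing_rate = missing_rate,
                 selection_targets = selection_targets,
                 pop_names = pop_names, seed = as.integer(seed)),
            class = "sim_config")
}

bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# one mosaic haplotype: founder alleles copied between Poisson crossovers
mosaic_haplotype <- function(founders, pos, chrom_len, recomb_rate) {
  k <- stats::rpois(1L, recomb_rate * chrom_len)
  nf <- nrow(founders)
  if (k == 0L) return(founders[sample.int(nf, 1L), ])
  cuts <- sort(stats::runif(k, 1, chrom_len))
  src <- sample.int(nf, k + 1L, replace = TRUE)
  seg <- findInterval(pos, cuts) + 1L
  founders[cbind(src[seg], seq_along(pos))]
}

#' Simulate a genotype panel with known truth
#'
#' Draws a panel under a [sim_config()]. The random streams are consumed
#' in a fixed, documented order (map and ancestral frequencies, then
#' population frequencies, then founder haplotypes, then mosaics, then
#' missingness), so a fixed seed yields a bit-identical panel.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [genotype_panel()]) and `truth` (a
#'   `sim_truth`: ancestral and per-population SNP frequencies, realized
#'   selection targets, founder count, seed, config echo).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # --- stage 1: map + ancestral frequencies ---
  chrom <- pos <- integer(0)
  for (c in seq_len(config$n_chrom)) {
    ns <- stats::rpois(1L, config$snp_density * config$chrom_length_bp)
    p_c <- sort(sample.int(config$chrom_length_bp, ns))
    chrom <- c(chrom, rep(c, ns))
    pos <- c(pos, p_c)
  }
  L <- length(pos)
  p_anc <- stats::runif(L, 0.05, 0.95)
  # --- stage 2: population frequencies (+ planted shifts) ---
  pop_freqs <- matrix(0, config$n_pops, L,
                      dimnames = list(config$pop_names, NULL))
  for (k in seq_len(config$n_pops))
    pop_freqs[k, ] <- bn_draw(p_anc, config$fst_param[k])
  realized <- list()
  for (t in config$selection_targets) {
    idx <- which(chrom == as.integer(t$chrom) &
                   pos >= t$start_bp & pos <= t$end_bp)
    if (!length(idx)) {
      warning("selection target on chromosome ", t$chrom, " [",
              t$start_bp, ", ", t$end_bp, "] contains no SNPs; dropped")
      next
    }
    pop_freqs[t$pop, idx] <-
      pmin(pmax(pop_freqs[t$pop, idx] + t$freq_shift, 0.02), 0.98)
    realized <- c(realized, list(t))
  }
  # --- stage 3: founder haplotypes ---
  founders <- lapply(seq_len(config$n_pops), function(k) {
    matrix(stats::rbinom(config$founders_per_pop * L, 1L,
                         rep(pop_freqs[k, ], each = config$founders_per_pop)),
           nrow = config$founders_per_pop)
  })
  # --- stage 4: individual mosaics ---
  n_total <- sum(config$n_per_pop)
  geno <- matrix(0L, n_total, L)
  row <- 0L
  chrom_idx <- split(seq_len(L), chrom)
  for (k in seq_len(config$n_pops)) {
    for (i in seq_len(config$n_per_pop[k])) {
      row <- row + 1L
      for (ci in chrom_idx) {
        h1 <- mosaic_haplotype(founders[[k]][, ci, drop = FALSE],
                               pos[ci], config$chrom_length_bp,
                               config$recomb_rate)
        h2 <- mosaic_haplotype(founders[[k]][, ci, drop = FALSE],
                               pos[ci], config$chrom_length_bp,
                               config$recomb_rate)
        geno[row, ci] <- h1 + h2
      }
    }
  }
  # --- stage 5: missingness ---
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  snps <- data.frame(
    id = sprintf("snp_%d_%d", chrom, pos), chrom = as.character(chrom),
    pos_bp = pos, allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE)
  individuals <- data.frame(
    id = sprintf("%s_ind%02d", rep(config$pop_names, config$n_per_pop),
                 unlist(lapply(config$n_per_pop, seq_len))),
    population = rep(config$pop_names, config$n_per_pop),
    sex = "unknown", stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, snps, individuals)
  truth <- structure(list(ancestral_freqs = p_anc, pop_freqs = pop_freqs,
                          selected_windows = realized,
                          founders_per_pop = config$founders_per_pop,
                          seed = config$seed, config = config),
                     class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Plant selection signals into an existing simulated panel
#'
#' Shifts the focal population's allele frequency inside each target
#' interval by `freq_shift` (clipped to `[0.02, 0.98]`) and regenerates the
#' focal population's genotypes there as two independent Bernoulli
#' haplotype draws at the shifted frequency; the original missingness
#' pattern is preserved. Targets whose interval contains no SNPs are
#' dropped with a warning.
#'
#' @param sim list with `panel` and `truth` as returned by
#'   [simulate_panel()].
#' @param targets list of target lists (`pop`, `chrom`, `start_bp`,
#'   `end_bp`, `freq_shift`).
#' @param seed integer seed for the regeneration draws.
#' @return list with updated `panel` and `truth`.
#' @export
plant_selection <- function(sim, targets, seed = 1L) {
  panel <- sim$panel; truth <- sim$truth
  set.seed(seed)
  for (t in targets) {
    if (!t$pop %in% rownames(truth$pop_freqs))
      stop("unknown target population: ", t$pop)
    if (!as.character(t$chrom) %in% panel$snps$chrom)
      stop("target chromosome absent from panel: ", t$chrom)
    idx <- which(panel$snps$chrom == as.character(t$chrom) &
                   panel$snps$pos_bp >= t$start_bp &
                   panel$snps$pos_bp <= t$end_bp)
    if (!length(idx)) {
      warning("target interval contains no SNPs; dropped")
      next
    }
    if (t$freq_shift == 0) {
      truth$selected_windows <- c(truth$selected_windows, list(t))
      next
    }
    p_new <- pmin(pmax(truth$pop_freqs[t$pop, idx] + t$freq_shift,
                       0.02), 0.98)
    truth$pop_freqs[t$pop, idx] <- p_new
    rows <- which(panel$individuals$population == t$pop)
    g_old <- panel$genotypes[rows, idx, drop = FALSE]
    g_new <- matrix(stats::rbinom(length(rows) * length(idx), 2L,
                                  rep(p_new, each = length(rows))),
                    nrow = length(rows))
    g_new[is.na(g_old)] <- NA_integer_
    panel$genotypes[rows, idx] <- g_new
    truth$selected_windows <- c(truth$selected_windows, list(t))
  }
  list(panel = panel, truth = truth)
}

#' Simulate a four-population panel with optional introgression
#'
#' Frequency-level quartet (P1, P2, P3, Outgroup) for ABBA-BABA
#' calibration: the outgroup and an internal ancestor diverge from a
#' common Uniform(0.05, 0.95) ancestral frequency by Balding-Nichols
#' drift; P3 and the (P1, P2) pair then diverge from the internal
#' ancestor. Introgression P3 -> P2 is modelled at the frequency level,
#' `p2' = (1 - admix_prop) p2 + admix_prop p3`, and genotypes are
#' binomial draws from the final frequencies.
#'
#' @param n_snps number of SNPs (single synthetic autosome).
#' @param n_per_pop individuals per population.
#' @param admix_prop introgression fraction P3 -> P2 in `[0, 1]`
#'   (0 = null, no gene flow).
#' @param drift Balding-Nichols F for each internal branch.
#' @param outgroup_drift Balding-Nichols F for the outgroup branch.
#' @param seed integer seed.
#' @return list with `panel` (populations `P1, P2, P3, OUT`) and `truth`
#'   (the final per-population frequencies and `admix_prop`).
#' @export
simulate_introgression_panel <- function(n_snps = 10000, n_per_pop = 25,
                                         admix_prop = 0, drift = 0.2,
                                         outgroup_drift = 0.3, seed = 1L) {
  stopifnot(admix_prop >= 0, admix_prop <= 1)
  set.seed(seed)
  pos <- sort(sample.int(20L * n_snps, n_snps))
  p <- stats::runif(n_snps, 0.05, 0.95)
  p_o <- bn_draw(p, outgroup_drift)
  p_int <- bn_draw(p, drift)       # ancestor of P1, P2, P3
  p_3 <- bn_draw(p_int, drift)
  p_12 <- bn_draw(p_int, drift)
  p_1 <- bn_draw(p_12, drift)
  p_2 <- (1 - admix_prop) * bn_draw(p_12, drift) + admix_prop * p_3
  freqs <- rbind(P1 = p_1, P2 = p_2, P3 = p_3, OUT = p_o)
  pops <- rownames(freqs)
  geno <- do.call(rbind, lapply(pops, function(k) {
    matrix(stats::rbinom(n_per_pop * n_snps, 2L,
                         rep(freqs[k, ], each = n_per_pop)),
           nrow = n_per_pop)
  }))
  snps <- data.frame(id = paste0("snp", seq_len(n_snps)), chrom = "1",
                     pos_bp = pos, allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  individuals <- data.frame(
    id = sprintf("%s_ind%02d", rep(pops, each = n_per_pop),
                 rep(seq_len(n_per_pop), 4)),
    population = rep(pops, each = n_per_pop),
    sex = "unknown", stringsAsFactors = FALSE)
  list(panel = genotype_panel(geno, snps, individuals),
       truth = list(freqs = freqs, admix_prop = admix_prop, seed = seed))
}
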
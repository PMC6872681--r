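# Independent brute-force oracles and fixture builders, written separately
# from the package code paths they check.

# Minimal panel builder: genotypes as individuals x SNPs matrix.
make_panel <- function(geno, chrom = NULL, pos = NULL, pops = NULL,
                       ids = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); L <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) {
    pos <- integer(L)
    for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch))
  }
  if (is.null(pops)) pops <- rep("p1", n)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  genotype_panel(
    geno,
    data.frame(id = sprintf("s%03d", seq_len(L)), chrom = chrom,
               pos_bp = pos, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE),
    data.frame(id = ids, population = pops, stringsAsFactors = FALSE))
}

# Mean-square F_ST from allele frequencies and copy counts, coded plainly
# from the estimator's definition with explicit loops.
oracle_fst <- function(p, n, msg_denom = "n_minus_1") {
  s <- length(p)
  stopifnot(length(n) == s)
  sum_n <- 0; sum_n2 <- 0; num_pbar <- 0
  for (i in 1:s) {
    sum_n <- sum_n + n[i]
    sum_n2 <- sum_n2 + n[i]^2
    num_pbar <- num_pbar + n[i] * p[i]
  }
  pbar <- num_pbar / sum_n
  msg_num <- 0; msg_den <- 0; msp <- 0
  for (i in 1:s) {
    msg_num <- msg_num + n[i] * p[i] * (1 - p[i])
    msg_den <- msg_den + if (msg_denom == "n_minus_1") n[i] - 1 else n[i]
    msp <- msp + n[i] * (p[i] - pbar)^2
  }
  msg <- msg_num / msg_den
  msp <- msp / (s - 1)
  nc <- (sum_n - sum_n2 / sum_n) / (s - 1)
  den <- msp + (nc - 1) * msg
  if (den <= 0) return(NA_real_)
  (msp - msg) / den
}

# Exhaustive scanning-window ROH vote on one individual / one chromosome.
oracle_roh_in_snp <- function(g, window_snps, max_het, max_miss,
                              hit_fraction) {
  L <- length(g)
  nw <- L - window_snps + 1L
  if (nw < 1) return(rep(FALSE, L))
  elig <- logical(nw)
  for (w in seq_len(nw)) {
    win <- g[w:(w + window_snps - 1)]
    elig[w] <- sum(win == 1, na.rm = TRUE) <= max_het &&
      sum(is.na(win)) <= max_miss
  }
  out <- logical(L)
  for (k in seq_len(L)) {
    covering <- intersect(seq_len(nw), (k - window_snps + 1):k)
    out[k] <- mean(elig[covering]) >= hit_fraction
  }
  out
}

# Rarefaction allelic richness for one SNP by direct combinatorics.
oracle_ar_snp <- function(n_a, n_b, g) {
  n <- n_a + n_b
  pa <- if (n - n_a >= g) choose(n - n_a, g) / choose(n, g) else 0
  pb <- if (n - n_b >= g) choose(n - n_b, g) / choose(n, g) else 0
  (1 - pa) + (1 - pb)
}

# Per-individual inbreeding coefficient by direct looping.
oracle_inbreeding <- function(geno) {
  n_ind <- nrow(geno); L <- ncol(geno)
  p <- numeric(L); n <- numeric(L)
  for (l in seq_len(L)) {
    gl <- geno[, l][!is.na(geno[, l])]
    n[l] <- 2 * length(gl)
    p[l] <- if (length(gl)) sum(gl) / n[l] else NA
  }
  f <- numeric(n_ind)
  for (i in seq_len(n_ind)) {
    o_hom <- 0; e_hom <- 0; l_used <- 0
    for (l in seq_len(L)) {
      if (is.na(geno[i, l]) || n[l] < 2) next
      l_used <- l_used + 1
      if (geno[i, l] != 1) o_hom <- o_hom + 1
      e_hom <- e_hom + 1 - 2 * p[l] * (1 - p[l]) * n[l] / (n[l] - 1)
    }
    f[i] <- (o_hom - e_hom) / (l_used - e_hom)
  }
  f
}

# Frequency ABBA-BABA D by direct summation.
oracle_d <- function(p1, p2, p3, po) {
  num <- den <- 0
  for (l in seq_along(p1)) {
    abba <- (1 - p1[l]) * p2[l] * p3[l] * (1 - po[l])
    baba <- p1[l] * (1 - p2[l]) * p3[l] * (1 - po[l])
    num <- num + abba - baba
    den <- den + abba + baba
  }
  unname(num / den)
}
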
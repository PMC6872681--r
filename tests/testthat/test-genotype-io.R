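test_that("PED/MAP parsing decodes alleles, missing calls and populations", {
  d <- withr::local_tempdir()
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"),
             file.path(d, "t.map"))
  writeLines(c("fam1 ind1 0 0 1 -9 A A G G",
               "fam2 ind2 0 0 2 -9 A G 0 0"),
             file.path(d, "t.ped"))
  p <- read_plink_text(file.path(d, "t.ped"), file.path(d, "t.map"))
  expect_equal(n_individuals(p), 2)
  # rs1: G minor at count 1 of 4 -> genotypes count copies of G
  expect_equal(p$snps$allele_b[1], "G")
  expect_equal(unname(p$genotypes[, 1]), c(0L, 1L))
  # rs2: "0 0" decodes as missing
  expect_true(is.na(p$genotypes["ind2", 2]))
  expect_equal(p$individuals$population, c("fam1", "fam2"))
  expect_equal(p$individuals$sex, c("male", "female"))
})

test_that("PED parsing rejects malformed rows and non-biallelic SNPs", {
  d <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100", file.path(d, "t.map"))
  writeLines(c("f i1 0 0 0 -9 A A", "f i2 0 0 0 -9 A"),
             file.path(d, "t.ped"))
  expect_error(read_plink_text(file.path(d, "t.ped"),
                               file.path(d, "t.map")),
               "malformed PED row at line 2")
  writeLines(c("f i1 0 0 0 -9 A C", "f i2 0 0 0 -9 G G"),
             file.path(d, "t.ped"))
  expect_error(read_plink_text(file.path(d, "t.ped"),
                               file.path(d, "t.map")),
               ">2 alleles")
})

test_that("BED 2-bit decoding matches hand-decoded byte fixture", {
  d <- withr::local_tempdir()
  # 4 individuals x 1 SNP, one genotype byte 0b11011000 = 0xD8:
  # little-endian 2-bit fields: ind1=00 (hom A1), ind2=10 (het),
  # ind3=01 (missing), ind4=11 (hom A2)
  writeLines("1\trs1\t0\t100\tG\tA", file.path(d, "t.bim"))
  writeLines(sprintf("f i%d 0 0 0 -9", 1:4), file.path(d, "t.fam"))
  con <- file(file.path(d, "t.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xD8)), con)
  close(con)
  p <- read_plink_bed(prefix = file.path(d, "t"))
  expect_equal(unname(p$genotypes[, 1]), c(2L, 1L, NA_integer_, 0L))
  expect_equal(p$snps$allele_b, "G")  # BIM A1 slot
})

test_that("BED reader rejects bad magic and truncated bodies", {
  d <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100\tG\tA", file.path(d, "t.bim"))
  writeLines(sprintf("f i%d 0 0 0 -9", 1:4), file.path(d, "t.fam"))
  con <- file(file.path(d, "t.bed"), "wb")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xD8)), con)
  close(con)
  expect_error(read_plink_bed(prefix = file.path(d, "t")), "magic")
  con <- file(file.path(d, "t.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)  # empty body, 1 SNP expected
  close(con)
  expect_error(read_plink_bed(prefix = file.path(d, "t")), "expected")
})

test_that("text and binary round trips preserve a simulated panel exactly", {
  sim <- simulate_panel(sim_config(n_pops = 2, n_per_pop = 6, n_chrom = 2,
                                   chrom_length_bp = 2e6,
                                   missing_rate = 0.05, seed = 3))
  panel <- sim$panel
  d <- withr::local_tempdir()
  write_plink_bed(panel, file.path(d, "rt"))
  back <- read_plink_bed(prefix = file.path(d, "rt"))
  expect_identical(back$genotypes, panel$genotypes)
  expect_equal(back$snps, panel$snps)
  expect_equal(back$individuals$population, panel$individuals$population)

  # text dialect: reader normalizes allele_b to the sample minor allele,
  # so orientation may flip where the written allele_b is the major one;
  # the genotype information must round-trip exactly
  write_plink_text(panel, file.path(d, "rt2"))
  back2 <- read_plink_text(file.path(d, "rt2.ped"), file.path(d, "rt2.map"))
  flip <- back2$snps$allele_b != panel$snps$allele_b
  expected <- panel$genotypes
  expected[, flip] <- 2L - expected[, flip]
  expect_identical(unname(back2$genotypes), unname(expected))
  expect_true(all(snp_freq(panel)[flip] >= 0.5))  # flips only at major b
  expect_equal(back2$snps$pos_bp, panel$snps$pos_bp)
  expect_equal(back2$individuals$population, panel$individuals$population)
})

test_that("population sidecar TSV overrides family-ID populations", {
  sim <- simulate_panel(sim_config(n_pops = 1, n_per_pop = 3, n_chrom = 1,
                                   chrom_length_bp = 5e5, seed = 4))
  d <- withr::local_tempdir()
  write_plink_bed(sim$panel, file.path(d, "pm"))
  writeLines(paste(sim$panel$individuals$id[1], "override", sep = "\t"),
             file.path(d, "pops.tsv"))
  p <- read_plink_bed(prefix = file.path(d, "pm"),
                      pop_map_path = file.path(d, "pops.tsv"))
  expect_equal(p$individuals$population[1], "override")
  expect_equal(p$individuals$population[2], "pop1")
})

test_that("SNP filter applies MAF and call-rate thresholds and is idempotent", {
  # 10 individuals; SNP1 MAF 0.005-like (rare), SNP2 low call rate,
  # SNP3 clean
  g <- cbind(c(1L, rep(0L, 9)),            # maf 0.05
             c(rep(NA_integer_, 2), rep(1L, 8)),  # call rate 0.8
             rep(1L, 10))                  # maf 0.5, full calls
  p <- make_panel(g)
  res <- filter_snps(p, maf_min = 0.10, call_rate_min = 0.90)
  expect_equal(n_snps(res$panel), 1)
  expect_setequal(res$report$removed_snps$reason, c("maf", "call_rate"))
  expect_equal(res$report$n_snps_out, 1)
  # idempotence
  res2 <- filter_snps(res$panel, maf_min = 0.10, call_rate_min = 0.90)
  expect_identical(res2$panel$genotypes, res$panel$genotypes)
  # zero thresholds are the identity
  res0 <- filter_snps(p, maf_min = 0, call_rate_min = 0)
  expect_identical(res0$panel$genotypes, p$genotypes)
  # surviving SNPs re-checked independently
  expect_true(all(snp_maf(res$panel) >= 0.10))
})

test_that("individual filter removes low-call-rate samples", {
  g <- rbind(rep(1L, 20),
             c(rep(NA_integer_, 2), rep(1L, 18)))  # 90% call rate
  p <- make_panel(g)
  res <- filter_individuals(p, call_rate_min = 0.95)
  expect_equal(res$panel$individuals$id, "i01")
  expect_equal(res$report$removed_individuals$id, "i02")
  expect_error(filter_individuals(p, call_rate_min = 1.01))
  res0 <- filter_individuals(p, call_rate_min = 0)
  expect_equal(n_individuals(res0$panel), 2)
})

test_that("subsetting restricts populations and drops the X chromosome", {
  g <- matrix(1L, 4, 4)
  p <- make_panel(g, chrom = c("1", "1", "38", "X"),
                  pops = c("a", "a", "b", "b"))
  sa <- subset_panel(p, populations = "a")
  expect_equal(unique(sa$individuals$population), "a")
  expect_equal(n_snps(sa), 4)
  au <- subset_panel(p, autosomes_only = TRUE)
  expect_equal(au$snps$chrom, c("1", "1", "38"))
  expect_error(subset_panel(p, populations = "zz"), "unknown population")
  all_p <- subset_panel(p, populations = c("a", "b"))
  expect_identical(all_p$genotypes, p$genotypes)
})
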
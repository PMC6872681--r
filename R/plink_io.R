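#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses the classic whitespace-separated PED/MAP pair. The family-ID
#' column is taken as the population label (optionally overridden by a
#' two-column sidecar TSV `individual_id<TAB>population`). Allele "0" is
#' the missing call. `allele_b` is chosen as the minor allele per SNP,
#' ties at frequency 0.5 broken lexicographically.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param pop_map_path optional sidecar TSV overriding populations.
#' @return a [genotype_panel()].
#' @export
read_plink_text <- function(ped_path, map_path, pop_map_path = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) != 4)
    stop("MAP file must have 4 columns, found ", ncol(map))
  names(map) <- c("chrom", "id", "cm", "pos_bp")
  L <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6 + 2L * L)
  if (length(bad))
    stop("malformed PED row at line ", bad[1], ": expected ",
         6 + 2L * L, " fields, found ", nf[bad[1]])
  fm <- do.call(rbind, fields)
  n <- nrow(fm)

  sex <- c(`1` = "male", `2` = "female")[fm[, 5]]
  sex[is.na(sex)] <- "unknown"
  individuals <- data.frame(id = fm[, 2], population = fm[, 1],
                            sex = unname(sex), stringsAsFactors = FALSE)

  a1 <- fm[, 6 + 2 * seq_len(L) - 1, drop = FALSE]
  a2 <- fm[, 6 + 2 * seq_len(L), drop = FALSE]
  geno <- matrix(NA_integer_, n, L)
  allele_a <- allele_b <- character(L)
  for (j in seq_len(L)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    half_missing <- xor(x1 == "0", x2 == "0")
    if (any(half_missing))
      stop("half-missing genotype for SNP ", map$id[j],
           " (line ", which(half_missing)[1], ")")
    obs <- c(x1[x1 != "0"], x2[x2 != "0"])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("SNP ", map$id[j], " has >2 alleles: ",
           paste(alleles, collapse = ","))
    if (length(alleles) == 0) alleles <- c("A", "B")  # fully missing SNP
    if (length(alleles) == 1)
      alleles <- c(alleles, if (alleles == "B") "A" else "B")
    counts <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele is allele_b; tie broken lexicographically (later name)
    minor <- if (counts[2] < counts[1]) 2L else if (counts[1] < counts[2]) 1L else 2L
    allele_b[j] <- alleles[minor]
    allele_a[j] <- alleles[3L - minor]
    g <- (x1 == allele_b[j]) + (x2 == allele_b[j])
    g[x1 == "0"] <- NA_integer_
    geno[, j] <- g
  }
  snps <- data.frame(id = map$id, chrom = map$chrom,
                     pos_bp = as.integer(map$pos_bp),
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, snps, individuals, sort = TRUE)
  apply_pop_map(panel, pop_map_path)
}

apply_pop_map <- function(panel, pop_map_path) {
  if (is.null(pop_map_path)) return(panel)
  if (!file.exists(pop_map_path))
    stop("population map file not found: ", pop_map_path)
  pm <- utils::read.table(pop_map_path, header = FALSE, sep = "\t",
                          colClasses = "character")
  idx <- match(panel$individuals$id, pm[, 1])
  hit <- !is.na(idx)
  panel$individuals$population[hit] <- pm[idx[hit], 2]
  panel
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
write_plink_text <- function(panel, prefix) {
  map <- panel$snps
  utils::write.table(
    data.frame(map$chrom, map$id, 0, map$pos_bp),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  g <- panel$genotypes
  L <- ncol(g)
  sex_code <- c(male = "1", female = "2", unknown = "0")
  calls <- matrix("0", nrow(g), 2L * L)
  for (j in seq_len(L)) {
    a <- panel$snps$allele_a[j]; b <- panel$snps$allele_b[j]
    first <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] >= 1, b, a))
    second <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] == 2, b, a))
    calls[, 2 * j - 1] <- first
    calls[, 2 * j] <- second
  }
  ped <- cbind(panel$individuals$population, panel$individuals$id,
               "0", "0", sex_code[panel$individuals$sex], "-9", calls)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  writeLines(apply(ped, 1, paste, collapse = " "), con)
  invisible(prefix)
}

# byte -> 4 two-bit PLINK codes, individual 1 in the lowest-order bits
plink_byte_lut <- function() {
  b <- 0:255
  cbind(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
        bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L))
}

# PLINK 1 2-bit code -> copies of A1 (allele_b): 00 -> 2, 01 -> NA (missing),
# 10 -> 1 (het), 11 -> 0
plink_code_to_geno <- c(2L, NA_integer_, 1L, 0L)

#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Decodes SNP-major PLINK 1 BED files bit-exactly. The BIM A1 allele is
#' taken as `allele_b` (PLINK's minor-allele slot) and genotype codes count
#' copies of A1.
#'
#' @param bed_path,bim_path,fam_path file paths; alternatively give a
#'   common `prefix`.
#' @param prefix path prefix expanding to `.bed/.bim/.fam`.
#' @param pop_map_path optional sidecar TSV overriding populations.
#' @return a [genotype_panel()].
#' @export
read_plink_bed <- function(bed_path = NULL, bim_path = NULL, fam_path = NULL,
                           prefix = NULL, pop_map_path = NULL) {
  if (!is.null(prefix)) {
    bed_path <- paste0(prefix, ".bed")
    bim_path <- paste0(prefix, ".bim")
    fam_path <- paste0(prefix, ".fam")
  }
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = "character")
  names(bim) <- c("chrom", "id", "cm", "pos_bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); L <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 BED file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major (mode byte 0x01) BED files are supported")
  bps <- ceiling(n / 4)  # bytes per SNP
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bps * L)
    stop("BED body has ", length(body), " bytes; expected ", bps * L)
  lut <- plink_byte_lut()
  codes <- matrix(t(lut[body + 1L, , drop = FALSE]), nrow = 4L * bps)
  geno <- matrix(plink_code_to_geno[codes[seq_len(n), , drop = FALSE] + 1L],
                 nrow = n, ncol = L)

  sex <- c(`1` = "male", `2` = "female")[fam[, 5]]
  sex[is.na(sex)] <- "unknown"
  individuals <- data.frame(id = fam[, 2], population = fam[, 1],
                            sex = unname(sex), stringsAsFactors = FALSE)
  snps <- data.frame(id = bim$id, chrom = bim$chrom,
                     pos_bp = as.integer(bim$pos_bp),
                     allele_a = bim$a2, allele_b = bim$a1,
                     stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, snps, individuals, sort = TRUE)
  apply_pop_map(panel, pop_map_path)
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' SNP-major PLINK 1 layout; `allele_b` is written to the BIM A1 column.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix; writes `.bed`, `.bim`, `.fam`.
#' @return the prefix, invisibly.
#' @export
write_plink_bed <- function(panel, prefix) {
  bim <- data.frame(panel$snps$chrom, panel$snps$id, 0,
                    panel$snps$pos_bp, panel$snps$allele_b,
                    panel$snps$allele_a)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  sex_code <- c(male = "1", female = "2", unknown = "0")
  fam <- data.frame(panel$individuals$population, panel$individuals$id,
                    0, 0, sex_code[panel$individuals$sex], -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  g <- panel$genotypes
  n <- nrow(g); L <- ncol(g)
  # genotype (copies of allele_b = A1) -> 2-bit code
  code <- matrix(1L, n, L)            # default: missing (01)
  code[!is.na(g) & g == 2L] <- 0L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 0L] <- 3L
  bps <- ceiling(n / 4)
  pad <- matrix(0L, 4L * bps - n, L)  # padding bits are zero
  cm <- rbind(code, pad)
  dim(cm) <- c(4L, bps * L)
  bytes <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
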
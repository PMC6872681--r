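#' SNP quality-control filter
#'
#' Retains SNPs with minor allele frequency >= `maf_min` and call rate >=
#' `call_rate_min`, both computed over all individuals (MAF on non-missing
#' calls only). Defaults match common chip-QC practice for multi-breed
#' panels: MAF 0.01 and 90% call rate.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param call_rate_min minimum per-SNP call rate in `[0, 1]`.
#' @return list with elements `panel` (filtered) and `report` (a
#'   `qc_report`: in/out counts and removal reasons).
#' @export
filter_snps <- function(panel, maf_min = 0.01, call_rate_min = 0.90) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            call_rate_min >= 0, call_rate_min <= 1)
  if (n_individuals(panel) == 0) stop("panel has no individuals")
  maf <- snp_maf(panel)
  maf[is.nan(maf)] <- 0  # zero-call SNPs: no estimable frequency
  cr <- snp_call_rate(panel)
  fail_maf <- maf < maf_min
  fail_cr <- cr < call_rate_min
  keep <- !fail_maf & !fail_cr
  reason <- character(0)
  removed <- which(!keep)
  if (length(removed)) {
    reason <- paste0(ifelse(fail_maf[removed], "maf", ""),
                     ifelse(fail_maf[removed] & fail_cr[removed], ";", ""),
                     ifelse(fail_cr[removed], "call_rate", ""))
  }
  report <- qc_report(
    n_snps_in = n_snps(panel), n_snps_out = sum(keep),
    n_individuals_in = n_individuals(panel),
    n_individuals_out = n_individuals(panel),
    removed_snps = data.frame(id = panel$snps$id[removed], reason = reason,
                              stringsAsFactors = FALSE),
    removed_individuals = data.frame(id = character(0),
                                     reason = character(0)))
  list(panel = subset_panel(panel, snps = panel$snps$id[keep]),
       report = report)
}

#' Individual quality-control filter
#'
#' Retains individuals whose genotype call rate (over all SNPs currently in
#' the panel) is >= `call_rate_min`. Default 0.95.
#'
#' @param panel a [genotype_panel()].
#' @param call_rate_min minimum per-individual call rate in `[0, 1]`.
#' @return list with elements `panel` and `report` (see [filter_snps()]).
#' @export
filter_individuals <- function(panel, call_rate_min = 0.95) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1)
  cr <- individual_call_rate(panel)
  keep <- cr >= call_rate_min
  if (!any(keep)) stop("all individuals removed; empty panel")
  removed <- which(!keep)
  report <- qc_report(
    n_snps_in = n_snps(panel), n_snps_out = n_snps(panel),
    n_individuals_in = n_individuals(panel),
    n_individuals_out = sum(keep),
    removed_snps = data.frame(id = character(0), reason = character(0)),
    removed_individuals = data.frame(
      id = panel$individuals$id[removed],
      reason = rep("call_rate", length(removed)),
      stringsAsFactors = FALSE))
  list(panel = subset_panel(panel,
                            individuals = panel$individuals$id[keep]),
       report = report)
}

qc_report <- function(n_snps_in, n_snps_out, n_individuals_in,
                      n_individuals_out, removed_snps,
                      removed_individuals) {
  stopifnot(n_snps_out == n_snps_in - nrow(removed_snps),
            n_individuals_out == n_individuals_in - nrow(removed_individuals))
  structure(list(n_snps_in = n_snps_in, n_snps_out = n_snps_out,
                 n_individuals_in = n_individuals_in,
                 n_individuals_out = n_individuals_out,
                 removed_snps = removed_snps,
                 removed_individuals = removed_individuals),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: SNPs %d -> %d, individuals %d -> %d\n",
              x$n_snps_in, x$n_snps_out,
              x$n_individuals_in, x$n_individuals_out))
  invisible(x)
}

#' Standard panel quality control
#'
#' Applies the SNP filter (MAF, SNP call rate) and then the individual
#' call-rate filter, in that order; individual call rates are computed on
#' the SNP set present before SNP filtering.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min,snp_call_rate_min,ind_call_rate_min thresholds
#'   (defaults 0.01, 0.90, 0.95).
#' @return list with `panel`, `snp_report`, `individual_report`.
#' @export
qc_panel <- function(panel, maf_min = 0.01, snp_call_rate_min = 0.90,
                     ind_call_rate_min = 0.95) {
  # individual call rates on the pre-filter SNP set
  ind_cr <- individual_call_rate(panel)
  s <- filter_snps(panel, maf_min, snp_call_rate_min)
  keep <- ind_cr >= ind_call_rate_min
  if (!any(keep)) stop("all individuals removed; empty panel")
  removed <- which(!keep)
  ind_report <- qc_report(
    n_snps_in = n_snps(s$panel), n_snps_out = n_snps(s$panel),
    n_individuals_in = n_individuals(s$panel),
    n_individuals_out = sum(keep),
    removed_snps = data.frame(id = character(0), reason = character(0)),
    removed_individuals = data.frame(
      id = panel$individuals$id[removed],
      reason = rep("call_rate", length(removed)),
      stringsAsFactors = FALSE))
  out <- subset_panel(s$panel,
                      individuals = panel$individuals$id[keep])
  list(panel = out, snp_report = s$report, individual_report = ind_report)
}
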
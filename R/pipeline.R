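#' Default pipeline configuration
#'
#' Returns the full analysis configuration with conventional chip-QC and
#' scan defaults pre-filled (MAF 0.01, SNP call rate 0.90, individual call
#' rate 0.95; LD decay within 500 kb; ROH 50-SNP window / 200 kb minimum
#' on an r2 >= 0.8 pruned set; structure analyses on an r2 < 0.5 pruned
#' set; 200-kb scan windows, >= 6 SNPs, 99.5th percentile). Override any
#' element via `...` or supply a YAML file to [run_pipeline()].
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged shallowly per stage).
#' @return a nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "popdog_out",
    stages = c("qc", "diversity", "linkage", "roh", "fst", "scan",
               "structure"),
    simulate = NULL,     # sim_config() arguments; NULL -> read plink
    plink = NULL,        # list(prefix=, format="bed"|"text", pop_map=)
    qc = list(maf_min = 0.01, snp_call_rate_min = 0.90,
              ind_call_rate_min = 0.95),
    diversity = list(maf_floor = 0.1),
    linkage = list(maf_min = 0.05, max_dist_kb = 500, bin_width_kb = 10,
                   r2_threshold = 0.3),
    roh = list(prune_r2 = 0.8, window_snps = 50, max_het_per_window = 1,
               max_missing_per_window = 5, min_length_kb = 200,
               min_snps = 25, hit_fraction = 0.05),
    fst = list(msg_denom = "n_minus_1"),
    scan = list(window_kb = 200, min_snps = 6, percentile = 99.5),
    structure = list(prune_r2 = 0.5, n_components = 5),
    dstat = list(quartets = list(), block_snps = 300)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order — input (simulation
#' or PLINK files), QC, diversity indices, LD decay, ROH, pairwise F_ST,
#' the per-breed d_i selection scan, and structure summaries (PCA +
#' neighbor-joining tree) — writing deterministic per-stage TSV outputs
#' and a JSON reproducibility manifest to `config$out_dir`. Reruns with
#' the same configuration and seed reproduce identical outputs for all
#' deterministic stages.
#'
#' @param config a configuration list from [default_config()], or a path
#'   to a YAML file with the same structure.
#' @return the run manifest (invisibly a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- do.call(default_config, yaml::read_yaml(config))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("popdog")),
                   config = config, stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  # --- input ---
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_panel(do.call(sim_config, sim_args))
    panel <- sim$panel
    truth_path <- file.path(config$out_dir, "sim_truth.json")
    jsonlite::write_json(
      list(seed = sim$truth$seed,
           founders_per_pop = sim$truth$founders_per_pop,
           selected_windows = sim$truth$selected_windows),
      truth_path, auto_unbox = TRUE, digits = NA)
  } else if (!is.null(config$plink)) {
    pm <- config$plink$pop_map
    if (!is.null(pm) && !file.exists(pm))
      stop("population map file not found: ", pm)
    panel <- if (identical(config$plink$format, "text")) {
      read_plink_text(paste0(config$plink$prefix, ".ped"),
                      paste0(config$plink$prefix, ".map"),
                      pop_map_path = pm)
    } else {
      read_plink_bed(prefix = config$plink$prefix, pop_map_path = pm)
    }
  } else {
    stop("config must provide either 'simulate' or 'plink' input")
  }
  manifest$stages$input <- list(n_snps = n_snps(panel),
                                n_individuals = n_individuals(panel))

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    st <- t_stage(fn())
    st$value$seconds <- st$seconds
    manifest$stages[[name]] <<- st$value
    invisible(NULL)
  }

  # --- qc ---
  if ("qc" %in% config$stages) {
    st <- t_stage(qc_panel(panel, config$qc$maf_min,
                           config$qc$snp_call_rate_min,
                           config$qc$ind_call_rate_min))
    panel <- st$value$panel
    manifest$stages$qc <- list(
      n_snps_out = n_snps(panel),
      n_individuals_out = n_individuals(panel),
      n_snps_removed = nrow(st$value$snp_report$removed_snps),
      n_individuals_removed =
        nrow(st$value$individual_report$removed_individuals),
      seconds = st$seconds)
  }
  auto <- subset_panel(panel, autosomes_only = TRUE)

  run_stage("diversity", function() {
    div <- diversity_indices(panel, maf_floor = config$diversity$maf_floor)
    write_tsv(div, file.path(config$out_dir, "diversity.tsv"))
    dm <- ibs_distance_matrix(panel)
    write_phylip_dist(dm, file.path(config$out_dir, "ibs_dist.phy"))
    list(n_populations = nrow(div))
  })

  run_stage("linkage", function() {
    res <- list()
    for (pp in populations(auto)) {
      sub <- subset_panel(auto, populations = pp)
      keep <- snp_maf(sub) >= config$linkage$maf_min &
        snp_call_rate(sub) >= 0.90
      keep[is.na(keep)] <- FALSE
      sub <- subset_panel(sub, snps = sub$snps$id[keep])
      pairs <- pairwise_r2(sub, max_dist_kb = config$linkage$max_dist_kb)
      if (nrow(pairs) == 0) next
      curve <- decay_curve(pairs,
                           bin_width_kb = config$linkage$bin_width_kb)
      write_tsv(curve, file.path(config$out_dir,
                                 paste0("ld_decay_", pp, ".tsv")))
      res[[pp]] <- as.numeric(
        r2_threshold_distance(curve, config$linkage$r2_threshold))
    }
    write_tsv(data.frame(population = names(res),
                         r2_threshold_kb = unlist(res)),
              file.path(config$out_dir, "r2_threshold.tsv"))
    list(r2_threshold_kb = res)
  })

  run_stage("roh", function() {
    kept <- ld_prune(auto, r2_max = config$roh$prune_r2)
    pruned <- subset_panel(auto, snps = kept)
    segs <- detect_roh(pruned,
                       window_snps = config$roh$window_snps,
                       max_het_per_window = config$roh$max_het_per_window,
                       max_missing_per_window =
                         config$roh$max_missing_per_window,
                       min_length_kb = config$roh$min_length_kb,
                       min_snps = config$roh$min_snps,
                       hit_fraction = config$roh$hit_fraction)
    write_tsv(segs, file.path(config$out_dir, "roh_segments.tsv"))
    write_tsv(accumulative_roh(segs, pruned),
              file.path(config$out_dir, "roh_per_individual.tsv"))
    list(n_snps_pruned_set = length(kept), n_segments = nrow(segs))
  })

  run_stage("fst", function() {
    m <- pairwise_fst_matrix(auto, msg_denom = config$fst$msg_denom)
    write_tsv(data.frame(population = rownames(m), m, check.names = FALSE),
              file.path(config$out_dir, "pairwise_fst.tsv"))
    list(n_pairs = sum(upper.tri(m)))
  })

  scan_result <- NULL
  run_stage("scan", function() {
    scan <- selection_scan(auto,
                           window_bp = config$scan$window_kb * 1000,
                           min_snps = config$scan$min_snps,
                           percentile = config$scan$percentile,
                           msg_denom = config$fst$msg_denom)
    scan_result <<- scan
    for (b in scan$breeds) {
      write_tsv(scan$windows[[b]],
                file.path(config$out_dir,
                          paste0("scan_windows_", b, ".tsv")))
      write_tsv(scan$regions[[b]],
                file.path(config$out_dir,
                          paste0("scan_regions_", b, ".tsv")))
    }
    list(n_windows = sum(vapply(scan$windows, nrow, 0L)),
         n_called = sum(vapply(scan$windows,
                               function(w) sum(w$called), 0L)),
         n_regions = sum(vapply(scan$regions, nrow, 0L)),
         thresholds = as.list(scan$thresholds))
  })

  run_stage("structure", function() {
    kept <- ld_prune(auto, r2_max = config$structure$prune_r2)
    pruned <- subset_panel(auto, snps = kept)
    pca <- pca_panel(pruned,
                     n_components = min(config$structure$n_components,
                                        n_individuals(pruned) - 1))
    write_pca_tsv(pca, file.path(config$out_dir, "pca.tsv"))
    dm <- ibs_distance_matrix(pruned)
    tree <- neighbor_joining(dm)
    write_newick(tree, file.path(config$out_dir, "nj_tree.nwk"))
    list(n_snps_pruned_set = length(kept),
         pc1_variance_fraction = pca$variance_fraction[1])
  })

  run_stage("dstat", function() {
    rows <- lapply(config$dstat$quartets, function(q) {
      r <- d_statistic(auto, unlist(q),
                       block_snps = config$dstat$block_snps)
      data.frame(p1 = r$quartet[1], p2 = r$quartet[2], p3 = r$quartet[3],
                 outgroup = r$quartet[4], d = r$d, z = r$z,
                 n_blocks = r$n_blocks, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab))
      write_tsv(tab, file.path(config$out_dir, "dstat.tsv"))
    list(n_quartets = length(config$dstat$quartets))
  })

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
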
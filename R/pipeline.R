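pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "invadepop_run",
    stages = c("simulate", "qc", "sex", "ldscan", "structure",
               "diversity", "sweep"),
    input = list(vcf = NULL, samples = NULL, repeats_bed = NULL,
                 indels_bed = NULL),
    simulate = list(n_populations = 2, samples_per_population = 25,
                    chrom_lengths = c(chr2 = 4e6, chrX = 1e6),
                    x_chrom = "chrX", snp_density = 1e-3,
                    divergence = 0.05, founder_theta = 0.8,
                    n_founders = 30, block_snps = 20, mean_depth = 16,
                    extra_missing_rate = 0.002,
                    inversion = list(enabled = TRUE, chrom = "chr2",
                                     start = 5e5, end = 2e6, freq = 0.3,
                                     arrangement_divergence = 0.15,
                                     target_pops = "pop2"),
                    sweep = list(enabled = TRUE, chrom = "chr2",
                                 core_rel_pos = 0.75, freq = 0.6,
                                 carrier_span = 5e5,
                                 residual_mutation_rate = 0.01,
                                 target_pops = "pop2")),
    qc = list(min_reads = 7, max_reads = 100, min_mean_depth = 10,
              max_mean_depth = 50, indel_margin = 20,
              min_mean_coverage = 7, max_missing = 0.10),
    sex = list(ratio_threshold = 0.8, reference_pop = "pop1"),
    ldscan = list(population = "pop2", r2_threshold = 0.75,
                  window_size = 1e5, min_run = 10,
                  distances_kb = c(100, 200, 300, 400, 500),
                  distance_tolerance = 0.05),
    structure = list(prune_r2 = 0.2, window_snps = 100, min_mac_pca = 3,
                     min_mac_fst = 4, n_components = 4),
    diversity = list(window = 5000),
    sweep = list(scan_pop = "pop2", min_maf = 0.05, cutoff = 0.05,
                 bin_width = 0.05, min_bin = 10, pod_n = 10000,
                 pod_q = 0.999, window = 1000, step = 500,
                 top_fraction = 0.01))
}

check_range <- function(cfg, path, lo, hi) {
  v <- cfg
  for (k in path) v <- v[[k]]
  if (!is.null(v) && is.numeric(v) && (any(v < lo) || any(v > hi))) {
    stop(sprintf("config field '%s' out of range [%s, %s]",
                 paste(path, collapse = "."), lo, hi), call. = FALSE)
  }
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills every unset field with the
#' default analysis parameters (genotype DP in [7,100], site mean depth
#' 10-50, 20-bp indel margin, 7x/10% individual QC, 0.8 sex ratio,
#' 0.75/100-kb/10-window inversion rule, MAC >= 3 for PCA pruning and
#' MAC > 3 for FST, 5-kb diversity windows, 1-kb/500-bp/top-1%
#' intersection, 10,000-SNP 99.9% POD), rejects unknown keys with a
#' suggestion, and range-checks thresholds.
#'
#' @param config path to a YAML file, or a nested list.
#' @return The normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  merge_known <- function(def, user, where = "") {
    if (!is.list(user)) return(user)
    unknown <- setdiff(names(user), names(def))
    if (length(unknown)) {
      hint <- vapply(unknown, function(u) {
        m <- agrep(u, names(def), max.distance = 2, value = TRUE)
        if (length(m)) sprintf(" (did you mean '%s'?)", m[1]) else ""
      }, "")
      stop("unknown config key", if (nzchar(where)) paste0(" in ", where),
           ": ", paste0(unknown, hint, collapse = ", "), call. = FALSE)
    }
    for (k in names(user)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(user[[k]])) {
        merge_known(def[[k]], user[[k]], paste0(where, k, "."))
      } else user[[k]]
    }
    def
  }
  cfg <- merge_known(defaults, config)
  if (!is.null(cfg$simulate$chrom_lengths)) {
    cfg$simulate$chrom_lengths <- unlist(cfg$simulate$chrom_lengths)
  }
  check_range(cfg, c("ldscan", "r2_threshold"), 0, 1)
  check_range(cfg, c("structure", "prune_r2"), 0, 1)
  check_range(cfg, c("sweep", "top_fraction"), 0, 1)
  check_range(cfg, c("sweep", "pod_q"), 0, 1)
  check_range(cfg, c("qc", "max_missing"), 0, 1)
  check_range(cfg, c("sex", "ratio_threshold"), 0, 10)
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stop("unknown stage name: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Subset a haplotype panel to given sites and samples
#'
#' @param panel a `haplotype_panel`.
#' @param site_keep logical or integer index into `panel$sites`.
#' @param sample_ids sample ids to retain (default all).
#' @return The subset panel.
#' @export
subset_panel <- function(panel, site_keep = NULL, sample_ids = NULL) {
  if (!is.null(site_keep)) {
    panel$hap <- panel$hap[, site_keep, drop = FALSE]
    panel$sites <- panel$sites[site_keep, , drop = FALSE]
    rownames(panel$sites) <- NULL
  }
  if (!is.null(sample_ids)) {
    keep_ind <- which(panel$samples$id %in% sample_ids)
    keep_hap <- panel$hap_sample %in% keep_ind
    panel$hap <- panel$hap[keep_hap, , drop = FALSE]
    panel$hap_sample <- match(panel$samples$id[panel$hap_sample[keep_hap]],
                              panel$samples$id[keep_ind])
    panel$hap_index <- panel$hap_index[keep_hap]
    panel$samples <- panel$samples[keep_ind, , drop = FALSE]
    rownames(panel$samples) <- NULL
  }
  panel
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline from one configuration
#'
#' Stage order: simulate (or read input VCF) -> genotype/site/individual
#' QC -> sex assignment and polarization -> long-range-LD inversion scan
#' (whose called regions mask the structure-stage analyses) -> kinship /
#' inbreeding / PCA / FST -> windowed diversity -> selection scan and
#' outlier-window intersection.  All outputs are written under one run
#' directory and a JSON manifest records per-stage files, checksums and
#' record counts; the manifest is written even when a stage fails, with
#' the failing stage recorded.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param resume when TRUE, a stage whose recorded output files already
#'   exist under an identical configuration is not rewritten.
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), resume = FALSE) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(artifact = "invadepop",
                   version = as.character(utils::packageVersion("invadepop")),
                   config = cfg, config_hash = digest_config(cfg),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list(), status = "running")
  mf_path <- file.path(out, "manifest.json")
  if (resume && file.exists(mf_path)) {
    prev <- tryCatch(jsonlite::read_json(mf_path, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) && identical(prev$config_hash, digest_config(cfg)) &&
        identical(prev$status, "ok") &&
        all(file.exists(file.path(out, unlist(lapply(
          prev$stages, function(s) names(s$files))))))) {
      return(invisible(prev))
    }
  }
  finish_stage <- function(name, files, n_records) {
    manifest$stages[[name]] <<- list(
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
      n_records = n_records,
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }
  state <- new.env()
  res <- tryCatch({
    for (stage in cfg$stages) {
      run_stage(stage, cfg, state, out, finish_stage)
    }
    manifest$status <- "ok"
    NULL
  }, error = function(e) e)
  if (!is.null(res)) {
    manifest$status <- "failed"
    manifest$failed_stage <- state$current_stage %||% "unknown"
    manifest$error <- conditionMessage(res)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (!is.null(res)) stop(res)
  invisible(manifest)
}

digest_config <- function(cfg) {
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # stable 32-hex hash via md5 of the serialized config
  tmp <- tempfile(); writeLines(as.character(s), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, cfg, state, out, finish_stage) {
  state$current_stage <- stage
  switch(stage,
    simulate = {
      sc <- cfg$simulate
      conf <- sim_config(n_populations = sc$n_populations,
                         samples_per_population = sc$samples_per_population,
                         chrom_lengths = sc$chrom_lengths,
                         x_chrom = sc$x_chrom, snp_density = sc$snp_density,
                         divergence = sc$divergence,
                         founder_theta = sc$founder_theta,
                         n_founders = sc$n_founders,
                         block_snps = sc$block_snps,
                         mean_depth = sc$mean_depth,
                         extra_missing_rate = sc$extra_missing_rate,
                         seed = derive_seed(cfg$seed, "simulate"))
      sim <- simulate_structured_panel(conf)
      if (isTRUE(sc$inversion$enabled)) {
        set.seed(derive_seed(cfg$seed, "inversion"))
        sim <- inject_inversion(sim$panel, sim$truth,
                                chrom = sc$inversion$chrom,
                                start = sc$inversion$start,
                                end = sc$inversion$end,
                                freq = sc$inversion$freq,
                                arrangement_divergence =
                                  sc$inversion$arrangement_divergence,
                                target_pops = sc$inversion$target_pops)
        names(sim) <- c("panel", "truth")
      }
      if (isTRUE(sc$sweep$enabled)) {
        set.seed(derive_seed(cfg$seed, "sweep"))
        on_c <- which(sim$panel$sites$chrom == sc$sweep$chrom)
        core_pos <- sim$panel$sites$pos[on_c][
          which.min(abs(sim$panel$sites$pos[on_c] -
                          sc$sweep$core_rel_pos *
                          sc$chrom_lengths[[sc$sweep$chrom]]))]
        sim <- inject_sweep(sim$panel, sim$truth, chrom = sc$sweep$chrom,
                            core_pos = core_pos, freq = sc$sweep$freq,
                            carrier_span = sc$sweep$carrier_span,
                            residual_mutation_rate =
                              sc$sweep$residual_mutation_rate,
                            target_pops = sc$sweep$target_pops)
      }
      set.seed(derive_seed(cfg$seed, "depth"))
      cohort <- attach_read_depth(sim$panel, mean_depth = sc$mean_depth,
                                  extra_missing_rate = sc$extra_missing_rate)
      state$panel <- sim$panel; state$truth <- sim$truth
      state$cohort <- cohort
      fdir <- file.path(out, "fixture")
      paths <- write_fixture(cohort, sim$truth, fdir)
      finish_stage("simulate", unname(paths), ncol(cohort$geno))
    },
    qc = {
      if (is.null(state$cohort)) {
        state$cohort <- read_vcf(cfg$input$vcf, cfg$input$samples)
      }
      co <- state$cohort
      co <- filter_genotypes_by_depth(co, cfg$qc$min_reads, cfg$qc$max_reads)
      repeats <- if (!is.null(cfg$input$repeats_bed)) {
        read_bed(cfg$input$repeats_bed)
      } else NULL
      indels <- if (!is.null(cfg$input$indels_bed)) {
        read_bed(cfg$input$indels_bed)
      } else NULL
      co <- filter_sites(co, cfg$qc$min_mean_depth, cfg$qc$max_mean_depth,
                         indel_positions = indels,
                         indel_margin = cfg$qc$indel_margin,
                         repeat_mask = repeats)
      co <- filter_individuals(co, cfg$qc$min_mean_coverage,
                               cfg$qc$max_missing)
      state$cohort <- co
      f <- file.path(out, "qc_report.tsv")
      qc_counts <- data.frame(
        stage = c("genotype_depth_set_missing", "sites_removed",
                  "individuals_removed", "sites_final",
                  "individuals_final"),
        n = c(co$log$genotype_depth$genotypes_set_missing,
              co$log$site_filter$removed_total,
              co$log$individual_filter$n_removed,
              ncol(co$geno), nrow(co$geno)))
      write_tsv(qc_counts, f)
      finish_stage("qc", f, ncol(co$geno))
    },
    sex = {
      co <- assign_sex(state$cohort, cfg$sex$ratio_threshold)
      co <- polarize_by_reference_population(co, cfg$sex$reference_pop)
      state$cohort <- co
      f <- file.path(out, "assigned_sex.tsv")
      write_tsv(co$samples[, c("id", "population", "reported_sex",
                               "assigned_sex", "depth_ratio")], f)
      finish_stage("sex", f, nrow(co$samples))
    },
    ldscan = {
      set.seed(derive_seed(cfg$seed, "ldscan"))
      fl <- long_range_ld_scan(state$cohort, cfg$ldscan$population,
                               distances_kb = cfg$ldscan$distances_kb,
                               distance_tolerance =
                                 cfg$ldscan$distance_tolerance,
                               r2_threshold = cfg$ldscan$r2_threshold,
                               window_size = cfg$ldscan$window_size,
                               seed = derive_seed(cfg$seed, "ldscan"))
      regions <- call_inversion_regions(fl, cfg$ldscan$min_run)
      state$inversion_regions <- regions
      f1 <- file.path(out, "ld_window_flags.tsv")
      write_tsv(do.call(rbind, fl$windows), f1)
      f2 <- file.path(out, "inversion_regions.bed")
      write_bed(regions, f2)
      finish_stage("ldscan", c(f1, f2), nrow(regions))
    },
    structure = {
      co <- mask_regions(state$cohort, state$inversion_regions %||%
                           interval_set())
      state$cohort_masked <- co
      kin <- king_kinship(co)
      fco <- inbreeding_coefficient(co)
      set.seed(derive_seed(cfg$seed, "structure"))
      pruned <- ld_prune(co, cfg$structure$prune_r2,
                         cfg$structure$window_snps,
                         cfg$structure$min_mac_pca)
      auto_pruned <- pruned[co$sites$chrom[pruned] != co$x_chrom]
      pca <- pca_cohort(co, auto_pruned, cfg$structure$n_components)
      fst <- wc_fst(co, co$samples$population,
                    min_mac = cfg$structure$min_mac_fst)
      state$fst <- fst
      f <- c(kinship = file.path(out, "kinship.tsv"),
             inbreeding = file.path(out, "inbreeding.tsv"),
             pca = file.path(out, "pca_coords.tsv"),
             eig = file.path(out, "pca_eigenvalues.tsv"),
             fst = file.path(out, "fst_per_snp.tsv"))
      write_tsv(as.data.frame(kin), f[["kinship"]])
      write_tsv(fco, f[["inbreeding"]])
      write_tsv(data.frame(id = rownames(pca$coords), pca$coords),
                f[["pca"]])
      write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                           eigenvalue = pca$eigenvalues), f[["eig"]])
      write_tsv(fst$per_snp, f[["fst"]])
      finish_stage("structure", unname(f), nrow(kin))
    },
    diversity = {
      co <- state$cohort
      pops <- unique(co$samples$population)
      tracks <- list()
      for (p in pops) {
        tracks[[paste0("pi_", p)]] <- windowed_pi(co, p, cfg$diversity$window)
        tracks[[paste0("tajd_", p)]] <-
          windowed_tajimas_d(co, p, cfg$diversity$window)
        if (!is.null(co$dp)) {
          tracks[[paste0("depth_", p)]] <-
            windowed_relative_depth(co, p, cfg$diversity$window)
        }
      }
      if (length(pops) >= 2) {
        tracks[["dxy"]] <- windowed_dxy(co, pops[1], pops[2],
                                        cfg$diversity$window)
      }
      f <- file.path(out, "diversity_windows.tsv")
      long <- do.call(rbind, lapply(names(tracks), function(nm) {
        tr <- tracks[[nm]]
        stat_col <- intersect(c("pi", "dxy", "D", "rel_depth"), names(tr))[1]
        data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                   track = nm, value = tr[[stat_col]],
                   stringsAsFactors = FALSE)
      }))
      write_tsv(long, f)
      state$diversity <- tracks
      finish_stage("diversity", f, nrow(long))
    },
    sweep = {
      co <- state$cohort
      panel <- state$panel %||% co$panel
      if (is.null(panel)) stop("no phased haplotypes available", call. = FALSE)
      keep_sites <- paste(panel$sites$chrom, panel$sites$pos) %in%
        paste(co$sites$chrom, co$sites$pos)
      panel_qc <- subset_panel(panel, keep_sites, co$samples$id)
      scan_panel <- subset_panel(
        panel_qc, NULL,
        co$samples$id[co$samples$population %in% cfg$sweep$scan_pop])
      aa <- co$sites$aa[match(paste(scan_panel$sites$chrom,
                                    scan_panel$sites$pos),
                              paste(co$sites$chrom, co$sites$pos))]
      aa[which(co$sites$aa_tie[match(paste(scan_panel$sites$chrom,
                                           scan_panel$sites$pos),
                                     paste(co$sites$chrom,
                                           co$sites$pos))])] <- NA
      track_ihs <- ihs_scan(scan_panel, aa, cfg$sweep$min_maf,
                            cfg$sweep$cutoff)
      track_ihs <- standardize_ihs(track_ihs, cfg$sweep$bin_width,
                                   cfg$sweep$min_bin)
      pac <- population_allele_counts(co)
      keep <- colSums(pac$copies >= 1) == nrow(pac$alt) &
        colMeans(pac$alt / pmax(pac$copies, 1)) > 0
      xtx <- differentiation_score(pac$alt[, keep, drop = FALSE],
                                   pac$copies[, keep, drop = FALSE],
                                   chrom = pac$chrom[keep],
                                   pos = pac$pos[keep])
      pod <- pod_threshold(pac$alt[, keep, drop = FALSE],
                           pac$copies[, keep, drop = FALSE],
                           n_simulated = cfg$sweep$pod_n,
                           quantile_level = cfg$sweep$pod_q,
                           seed = derive_seed(cfg$seed, "pod"))
      fst_track <- state$fst$per_snp
      tr_ihs <- data.frame(chrom = track_ihs$chrom, pos = track_ihs$pos,
                           score = track_ihs$ihs_abs)
      tr_fst <- data.frame(chrom = fst_track$chrom, pos = fst_track$pos,
                           score = fst_track$fst)
      tr_xtx <- data.frame(chrom = xtx$chrom, pos = xtx$pos,
                           score = xtx$score)
      inter <- outlier_window_intersection(
        list(fst = tr_fst, xtx = tr_xtx, ihs = tr_ihs),
        co$chrom_lengths, cfg$sweep$window, cfg$sweep$step,
        cfg$sweep$top_fraction)
      f <- c(ihs = file.path(out, "ihs.tsv"),
             xtx = file.path(out, "differentiation.tsv"),
             pod = file.path(out, "pod_threshold.tsv"),
             bed = file.path(out, "intersection.bed"),
             wf = file.path(out, "intersection_windows.tsv"))
      write_tsv(as.data.frame(track_ihs), f[["ihs"]])
      write_tsv(as.data.frame(xtx), f[["xtx"]])
      write_tsv(data.frame(threshold = pod$threshold, f_hat = pod$f_hat,
                           quantile = cfg$sweep$pod_q,
                           n_simulated = cfg$sweep$pod_n), f[["pod"]])
      write_bed(inter$intersection, f[["bed"]])
      write_tsv(inter$window_flags, f[["wf"]])
      state$intersection <- inter
      finish_stage("sweep", unname(f), nrow(inter$intersection))
    },
    stop("unknown stage name: ", stage, call. = FALSE)
  )
  invisible(NULL)
}
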
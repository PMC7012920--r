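#' Default configuration of the synthetic study
#'
#' The defaults encode the study conditions of the simulated cross: 200 F2
#' individuals on a 10 x 30-Mb genome, ~25 crossovers per gamete with 20%
#' bias, the six-locus epistatic architecture, 25-member extreme pools
#' (phenotype > 0.7 vs exactly 0), 30x pooled depth with 1% read error, the
#' 0.3/0.7 co-segregation filter, 200-kb/20-kb windows, and the five-window
#' candidate interval.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(n_chrom = 10, chrom_length = 30e6, markers_per_chrom = 5000,
       n_individuals = 200, mean_crossovers = 25, bias = 0.2,
       pool_size = 25, high_threshold = 0.7, low_value = 0,
       depth = 30, error_rate = 0.01, depth_model = "fixed",
       min_depth = 5, filter_low = 0.3, filter_high = 0.7,
       filter_mode = "both-pools",
       window = 200000, step = 20000,
       ci_levels = c(0.95, 0.99), n_sims = 1000, k_windows = 5,
       bin_size = 10,
       pool_strategy = "rank",
       dip_region_length = 20001, insertion_halo = 100, dip_factor = 0.2,
       smooth_window = 50, ratio_threshold = 0.5, dip_min_length = 50)
}

merge_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] running", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic study
#'
#' Chains every pipeline stage under one seed: marker map and gametes, F2
#' genotypes and phenotypes, extreme pools, pooled reads, SNP-index /
#' filtering / window deltas / confidence envelope / candidate interval,
#' LOD scan and peak summaries, a per-base depth fixture with a planted
#' insertion inside the candidate interval, dip detection, and a ranked
#' candidate report against a small synthetic gene annotation. All stage
#' outputs are written to `outdir` as `#`-headed TSVs plus a JSON run
#' manifest recording the configuration, seed, package version, output
#' files, and the two method peaks. Stage seeds are derived from `seed` by
#' fixed offsets, so the same seed reproduces byte-identical outputs.
#'
#' Note on pooling: the strict extreme-pool rule (`pool_strategy =
#' "threshold"`) requires at least `pool_size` individuals above
#' `high_threshold`; under the default architecture a 200-individual F2
#' rarely provides 25 such individuals (see the package vignette), so the
#' umbrella command defaults to `pool_strategy = "rank"`, which takes the
#' most extreme individuals per side.
#'
#' @param config named list overriding [default_config()] entries; an
#'   unknown key raises a schema error naming the key.
#' @param outdir output directory (created if needed).
#' @param seed integer master seed (default 1).
#' @param verbose log stage progress and seeds to stderr (default TRUE).
#' @return Invisibly, a list with the main in-memory objects (`pop`,
#'   `pools`, `windows`, `interval`, `lod`, `peaks`, `dips`, `report`,
#'   `manifest`).
#' @export
run_all <- function(config = list(), outdir = tempfile("poolmap_run_"),
                    seed = 1, verbose = TRUE) {
  cfg <- merge_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  outputs <- character(0)
  emit <- function(writer, obj, f) {
    writer(obj, path(f))
    outputs[[length(outputs) + 1]] <<- f
  }
  if (verbose) message(sprintf("[run_all] seed %d, outdir %s", seed, outdir))

  ms <- stage("popsim", verbose, {
    default_marker_set(cfg$n_chrom, cfg$chrom_length, cfg$markers_per_chrom)
  })
  arch <- stage("popsim", verbose, default_trait_architecture(ms))
  pop <- stage("popsim", verbose, {
    if (verbose) message(sprintf("[popsim] gamete seeds %d/%d", seed + 1,
                                 seed + 2))
    eggs <- simulate_gametes(ms, cfg$n_individuals, cfg$mean_crossovers,
                             cfg$bias, seed = seed + 1)
    pollen <- simulate_gametes(ms, cfg$n_individuals, cfg$mean_crossovers,
                               cfg$bias, seed = seed + 2)
    assign_phenotypes(make_f2_population(ms, eggs, pollen, seed = seed + 3),
                      arch)
  })
  emit(write_marker_map, ms, "marker_map.tsv")
  emit(write_genotypes, pop, "genotypes.tsv")
  emit(write_phenotypes, pop, "phenotypes.tsv")

  pools <- stage("pools", verbose, {
    if (verbose) message(sprintf("[pools] seed %d, strategy %s", seed + 4,
                                 cfg$pool_strategy))
    select_pools(pop$phenotypes, cfg$high_threshold, cfg$low_value,
                 cfg$pool_size, seed = seed + 4,
                 insufficient = if (cfg$pool_strategy == "rank") "rank"
                                else "error")
  })
  depths <- stage("pool_reads", verbose, {
    if (verbose) message(sprintf("[pool_reads] seeds %d/%d", seed + 5,
                                 seed + 6))
    rbind(simulate_pool_reads(pop, pools$high, cfg$depth, cfg$error_rate,
                              seed = seed + 5, depth_model = cfg$depth_model),
          simulate_pool_reads(pop, pools$low, cfg$depth, cfg$error_rate,
                              seed = seed + 6, depth_model = cfg$depth_model))
  })
  emit(write_allele_depths, depths, "allele_depths.tsv")
  stage("pool_reads", verbose,
        write_pool_vcf(ms, depths, path("pools.vcf")))
  outputs <- c(outputs, "pools.vcf")

  qtl <- stage("qtlseq", verbose, {
    idx_a <- compute_snp_index(depths, "A", cfg$min_depth)
    idx_b <- compute_snp_index(depths, "B", cfg$min_depth)
    idx_a <- filter_cosegregating(idx_a, cfg$filter_low, cfg$filter_high,
                                  cfg$filter_mode)
    idx_b <- filter_cosegregating(idx_b, cfg$filter_low, cfg$filter_high,
                                  cfg$filter_mode)
    w <- window_deltas(idx_a, idx_b, cfg$window, cfg$step,
                       chrom_lengths = ms)
    if (verbose) message(sprintf("[qtlseq] envelope seed %d", seed + 7))
    w <- confidence_envelope(w, cfg$pool_size, cfg$n_sims, cfg$ci_levels,
                             seed = seed + 7)
    iv <- find_candidate_interval(w, cfg$k_windows,
                                  snp_positions = idx_a[idx_a$pool ==
                                    idx_a$pool[1], c("chrom", "pos")])
    list(idx_a = idx_a, windows = w, interval = iv)
  })
  emit(write_tsv_hash, as.data.frame(qtl$idx_a), "snp_index_refA.tsv")
  emit(write_window_stats, qtl$windows, "windows.tsv")
  emit(write_tsv_hash, as.data.frame(qtl$interval), "interval.tsv")

  lod <- stage("linkage", verbose, lod_scan(pop, cfg$bin_size))
  emit(write_tsv_hash, lod, "lod.tsv")

  peaks <- stage("peaks", verbose, {
    w <- qtl$windows
    i <- which.max(w$delta_combined)
    list(qtlseq = list(chrom = w$chrom[i],
                       pos = (w$start[i] + w$end[i]) / 2,
                       delta_combined = w$delta_combined[i]),
         linkage = as.list(peak_summary(lod)))
  })

  dip_bundle <- stage("depthscan", verbose, {
    if (verbose) message(sprintf("[depthscan] seed %d", seed + 8))
    iv <- qtl$interval
    mid <- round((iv$refined_start + iv$refined_end) / 2)
    prof <- simulate_depth_profiles(cfg$dip_region_length, cfg$depth,
                                    insertion_pos =
                                      (cfg$dip_region_length + 1) / 2,
                                    insertion_halo = cfg$insertion_halo,
                                    dip_factor = cfg$dip_factor,
                                    chrom = iv$chrom, seed = seed + 8)
    offset <- mid - (cfg$dip_region_length + 1) / 2
    prof$pos <- prof$pos + offset
    dips <- detect_depth_dips(prof, cfg$smooth_window, cfg$ratio_threshold,
                              cfg$dip_min_length)
    list(profile = prof, dips = dips, center = mid)
  })
  emit(write_tsv_hash, as.data.frame(dip_bundle$profile), "depth_profile.tsv")
  emit(write_tsv_hash, as.data.frame(dip_bundle$dips), "dip_calls.tsv")

  report <- stage("candidates", verbose, {
    iv <- qtl$interval
    mid <- dip_bundle$center
    # synthetic demo annotation: one pathway gene over the planted insertion,
    # one unannotated gene elsewhere in the interval
    ann <- data.frame(
      gene_id = c("synthetic_myb_repressor", "synthetic_gene_2"),
      chrom = iv$chrom,
      start = c(mid - 400, iv$refined_start + 1000),
      end = c(mid + 400, iv$refined_start + 3000),
      strand = "+")
    ptab <- data.frame(gene_id = "synthetic_myb_repressor",
                       pathway_role = "negative_regulator")
    report_candidates(qtl$interval, dip_bundle$dips, ann,
                      pathway_table = ptab)
  })
  emit(write_tsv_hash, report, "candidate_report.tsv")

  manifest <- list(
    package = "poolmap",
    version = as.character(utils::packageVersion("poolmap")),
    seed = seed,
    config = cfg,
    outputs = outputs,
    peaks = peaks)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  outputs <- c(outputs, "manifest.json")

  invisible(list(marker_set = ms, architecture = arch, pop = pop,
                 pools = pools, depths = depths, windows = qtl$windows,
                 interval = qtl$interval, lod = lod, peaks = peaks,
                 dips = dip_bundle$dips, report = report,
                 manifest = manifest, outdir = outdir))
}
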
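# shared fixture builders; everything is generated in code at test time

small_marker_set <- function(n_chrom = 10, chrom_length = 3e6,
                             markers_per_chrom = 100) {
  default_marker_set(n_chrom, chrom_length, markers_per_chrom)
}

# wrap an explicit genotype matrix (0/1/2 B-allele counts) as a population
as_f2_population <- function(ms, g) {
  storage.mode(g) <- "integer"
  structure(list(marker_set = ms, genotypes = g,
                 phenotypes = rep(NA_real_, nrow(g)),
                 gamete_crossovers = NULL),
            class = "f2_population")
}

# six-locus architecture that also fits maps with fewer than 10 chromosomes:
# loci are spread evenly over the marker backbone
small_arch <- function(ms) {
  mk <- ms$markers
  pick <- mk[round(seq(1, nrow(mk), length.out = 8))[2:7], ]
  trait_architecture(data.frame(
    chrom = pick$chrom, pos = pick$pos,
    mode = c("dominant_suppressor", rep("recessive_direct", 5)),
    effect = c(0, 0.6, 0.1, 0.1, 0.1, 0.1),
    causal_parent = c("B", rep("A", 5))), ms)
}

sim_small_population <- function(seed = 1, n = 200, ms = small_marker_set()) {
  eggs <- simulate_gametes(ms, n, seed = seed)
  pollen <- simulate_gametes(ms, n, seed = seed + 1000)
  pop <- make_f2_population(ms, eggs, pollen, seed = seed + 2000)
  arch <- if (nrow(ms$chromosomes) >= 10) default_trait_architecture(ms)
          else small_arch(ms)
  assign_phenotypes(pop, arch)
}

# long-format allele-depth table for two pools at shared positions
depth_table <- function(pos, a_hi, b_hi, a_lo, b_lo, chrom = "A01") {
  rbind(data.frame(chrom = chrom, pos = pos, pool = "high",
                   countA = a_hi, countB = b_hi),
        data.frame(chrom = chrom, pos = pos, pool = "low",
                   countA = a_lo, countB = b_lo))
}

# hand-built window_stats table for interval-extraction tests
make_windows <- function(starts, delta, chrom = "A01", window = 200000,
                         step = 20000, n_snps = 10, depth = 30) {
  df <- data.frame(chrom = chrom, start = starts, end = starts + window - 1,
                   partial = FALSE, n_snps_ref_a = n_snps,
                   n_snps_ref_b = n_snps, mean_depth = depth,
                   mean_high_ref_a = NA_real_, mean_low_ref_a = NA_real_,
                   mean_high_ref_b = NA_real_, mean_low_ref_b = NA_real_,
                   delta_ref_A = delta / 2, delta_ref_B = -delta / 2,
                   delta_combined = delta)
  attr(df, "window") <- window
  attr(df, "step") <- step
  class(df) <- c("window_stats", "data.frame")
  df
}
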
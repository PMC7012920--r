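test_that("SNP-index is the reference-allele read fraction", {
  d <- depth_table(pos = c(100, 200, 300),
                   a_hi = c(12, 30, 2), b_hi = c(18, 0, 1),
                   a_lo = c(15, 15, 10), b_lo = c(15, 15, 10))
  idx <- compute_snp_index(d, "A", min_depth = 5)
  hi <- idx[idx$pool == "high", ]
  expect_equal(hi$snp_index, c(0.4, 1.0, NA))
  expect_equal(hi$depth, c(30, 30, 3))
  # index times depth recovers an integer read count
  ok <- !is.na(idx$snp_index)
  expect_equal(idx$snp_index[ok] * idx$depth[ok], idx$ref_count[ok])

  idx_b <- compute_snp_index(d, "B", min_depth = 5)
  expect_equal(idx_b$snp_index[idx_b$pool == "high"], c(0.6, 0.0, NA))
  expect_error(compute_snp_index(d, "Z"), "unknown reference parent")
})

test_that("SNP-index matches a per-row brute-force oracle", {
  set.seed(101)
  n <- 1000
  d <- depth_table(pos = seq_len(n),
                   a_hi = rpois(n, 12), b_hi = rpois(n, 12),
                   a_lo = rpois(n, 12), b_lo = rpois(n, 12))
  idx <- compute_snp_index(d, "A", min_depth = 5)
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    tot <- d$countA[i] + d$countB[i]
    if (tot < 5) NA_real_ else d$countA[i] / tot
  }, numeric(1))
  expect_equal(idx$snp_index, oracle, tolerance = 1e-10)
})

test_that("co-segregation filter removes same-side-extreme markers only", {
  d <- depth_table(pos = c(1, 2, 3, 4) * 100,
                   a_hi = c(4, 19, 10, 29), b_hi = c(16, 1, 10, 1),
                   a_lo = c(5, 10, 8, 28), b_lo = c(15, 10, 12, 2))
  idx <- compute_snp_index(d, "A", min_depth = 5)
  # marker 1: 0.20 / 0.25  -> both below 0.3, removed
  # marker 2: 0.95 / 0.50  -> extreme in one pool only, retained
  # marker 3: 0.50 / 0.40  -> mid-range, retained
  # marker 4: ~0.97 / 0.93 -> both above 0.7, removed
  f <- filter_cosegregating(idx, 0.3, 0.7)
  expect_setequal(unique(f$pos), c(200, 300))

  mid <- depth_table(pos = 1:5, a_hi = rep(15, 5), b_hi = rep(15, 5),
                     a_lo = rep(12, 5), b_lo = rep(18, 5))
  idx_mid <- compute_snp_index(mid, "A")
  expect_equal(nrow(filter_cosegregating(idx_mid)), nrow(idx_mid))

  expect_error(filter_cosegregating(idx, 0.7, 0.3), "low must be < high")
  # either-pool mode also drops the one-sided extreme marker 2
  expect_setequal(unique(filter_cosegregating(idx, mode = "either-pool")$pos),
                  300)
  expect_setequal(unique(filter_cosegregating(idx, mode = "keep-extreme")$pos),
                  c(100, 200, 400))
})

test_that("window averaging is the arithmetic mean of marker deltas", {
  # three markers with per-marker delta_ref_A 0.2, 0.4, 0.6
  d <- depth_table(pos = c(1000, 2000, 3000),
                   a_hi = c(18, 21, 24), b_hi = c(12, 9, 6),
                   a_lo = c(12, 9, 6), b_lo = c(18, 21, 24))
  ia <- compute_snp_index(d, "A")
  ib <- compute_snp_index(d, "B")
  w <- window_deltas(ia, ib, window = 5000, step = 5000,
                     chrom_lengths = data.frame(chrom = "A01", length = 5000))
  expect_equal(nrow(w), 1)
  expect_equal(w$delta_ref_A, 0.4)
  expect_equal(w$delta_combined, 0.8)
  expect_equal(w$n_snps_ref_a, 3)
})

test_that("window means agree with a brute-force double loop", {
  set.seed(77)
  pos <- sort(sample(1e6, 400))
  d <- depth_table(pos = pos,
                   a_hi = rpois(400, 15), b_hi = rpois(400, 15),
                   a_lo = rpois(400, 15), b_lo = rpois(400, 15))
  ia <- compute_snp_index(d, "A")
  ib <- compute_snp_index(d, "B")
  w <- window_deltas(ia, ib, window = 100000, step = 25000,
                     chrom_lengths = data.frame(chrom = "A01", length = 1e6))
  hi <- ia[ia$pool == "high", ]
  lo <- ia[ia$pool == "low", ]
  for (i in sample(nrow(w), 25)) {
    inw <- function(t) t$pos >= w$start[i] & t$pos <= w$end[i] &
      !is.na(t$snp_index)
    mh <- mean(hi$snp_index[inw(hi)])
    ml <- mean(lo$snp_index[inw(lo)])
    if (is.nan(mh) || is.nan(ml)) {
      expect_true(is.na(w$delta_ref_A[i]))
    } else {
      expect_equal(w$delta_ref_A[i], mh - ml, tolerance = 1e-10)
    }
  }
  # shared-marker identity of the orientation convention
  expect_equal(w$delta_combined, 2 * w$delta_ref_A, tolerance = 1e-12)
})

test_that("deltas respect their ranges; opposite fixed pools attain +2", {
  ms <- small_marker_set(n_chrom = 2, chrom_length = 1e6,
                         markers_per_chrom = 60)
  pop <- sim_small_population(seed = 55, n = 60, ms = ms)
  pools <- select_pools(pop$phenotypes, pool_size = 10,
                        insufficient = "rank", seed = 56)
  d <- rbind(simulate_pool_reads(pop, pools$high, seed = 57),
             simulate_pool_reads(pop, pools$low, seed = 58))
  ia <- compute_snp_index(d, "A")
  ib <- compute_snp_index(d, "B")
  w <- window_deltas(ia, ib, window = 200000, step = 20000,
                     chrom_lengths = ms)
  expect_true(all(abs(w$delta_ref_A) <= 1, na.rm = TRUE))
  expect_true(all(abs(w$delta_ref_B) <= 1, na.rm = TRUE))
  expect_true(all(abs(w$delta_combined) <= 2, na.rm = TRUE))

  # fully informative fixture: high pool fixed AA, low pool fixed BB
  ms1 <- small_marker_set(n_chrom = 1, chrom_length = 1e5,
                          markers_per_chrom = 20)
  pop1 <- as_f2_population(ms1, rbind(matrix(0L, 5, 20), matrix(2L, 5, 20)))
  d1 <- rbind(simulate_pool_reads(pop1, pool_sample("high", 1:5),
                                  error_rate = 0, seed = 59),
              simulate_pool_reads(pop1, pool_sample("low", 6:10),
                                  error_rate = 0, seed = 60))
  i1a <- compute_snp_index(d1, "A")
  i1b <- compute_snp_index(d1, "B")
  w1 <- window_deltas(i1a, i1b, window = 1e5, step = 1e5,
                      chrom_lengths = ms1)
  expect_equal(w1$delta_ref_A, 1)
  expect_equal(w1$delta_ref_B, -1)
  expect_equal(w1$delta_combined, 2)
})

test_that("five neighboring 200-kb/20-kb windows intersect in 120 kb", {
  starts <- seq(1, 1800001, by = 20000)
  delta <- rep(0.1, length(starts))
  delta[40:44] <- 1.5                       # the peak run
  w <- make_windows(starts, delta)
  iv <- find_candidate_interval(w, k = 5)
  expect_equal(iv$raw_start, starts[44])
  expect_equal(iv$raw_end, starts[40] + 200000 - 1)
  expect_equal(iv$raw_end - iv$raw_start + 1, 120000)
  expect_equal(iv$peak_delta, 1.5)
})

test_that("candidate interval degenerates, refines, and errors correctly", {
  starts <- seq(1, 400001, by = 20000)
  delta <- rep(0.2, length(starts)); delta[7] <- 1.0
  w <- make_windows(starts, delta)
  iv1 <- find_candidate_interval(w, k = 1)
  expect_equal(c(iv1$raw_start, iv1$raw_end),
               c(starts[7], starts[7] + 200000 - 1))

  delta5 <- rep(0.2, length(starts)); delta5[7:11] <- 1.0
  w5 <- make_windows(starts, delta5)
  iv5 <- find_candidate_interval(w5, k = 5)
  snps <- data.frame(chrom = "A01",
                     pos = c(iv5$raw_start - 37, iv5$raw_start + 5,
                             iv5$raw_end - 5, iv5$raw_end + 21))
  ivr <- find_candidate_interval(w5, k = 5, snp_positions = snps)
  expect_equal(ivr$refined_start, iv5$raw_start - 37)
  expect_equal(ivr$refined_end, iv5$raw_end + 21)

  expect_error(find_candidate_interval(make_windows(starts[1:3],
                                                    c(1, 1, 1)), k = 5),
               "consecutive windows")
})

test_that("interval ties are broken by the summed delta", {
  starts <- seq(1, 800001, by = 20000)
  delta <- rep(0, length(starts))
  delta[5:9] <- c(1, 1, 1, 1, 1)            # min 1, sum 5
  delta[20:24] <- c(1, 1, 2, 1, 1)          # min 1, sum 6 -> wins
  w <- make_windows(starts, delta)
  iv <- find_candidate_interval(w, k = 5)
  expect_equal(iv$raw_start, starts[24])
})

test_that("confidence envelope widens when depth is halved", {
  starts <- seq(1, 500001, by = 100000)
  w <- make_windows(starts, rep(0, length(starts)), window = 100000,
                    step = 100000, n_snps = 5, depth = 30)
  e30 <- confidence_envelope(w, pool_size = 25, n_sims = 4000,
                             levels = 0.95, seed = 13)
  e15 <- confidence_envelope(w, pool_size = 25, n_sims = 4000,
                             levels = 0.95, seed = 13, depth = 15)
  w30 <- stats::median(e30$ci_high_95 - e30$ci_low_95)
  w15 <- stats::median(e15$ci_high_95 - e15$ci_low_95)
  expect_gt(w15, w30)
  # envelope is symmetric-ish around zero and bounded by the delta range
  expect_true(all(e30$ci_low_95 < 0 & e30$ci_high_95 > 0))
  expect_true(all(abs(e30$ci_high_95) <= 2))
})

test_that("windows without markers or depth carry a missing envelope", {
  starts <- c(1, 100001)
  w <- make_windows(starts, c(0, 0), window = 100000, step = 100000,
                    n_snps = 5, depth = 30)
  w$n_snps_ref_a[1] <- 0L
  w$mean_depth[2] <- NA_real_
  e <- confidence_envelope(w, n_sims = 200, levels = 0.95, seed = 3)
  expect_true(all(is.na(e$ci_low_95)))
  expect_error(confidence_envelope(w, n_sims = 50), "n_sims")
})
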
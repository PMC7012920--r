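#' Per-SNP SNP-index for each pool
#'
#' The SNP-index of a marker in a pool is the fraction of that pool's reads
#' carrying the reference parent's allele. Markers whose total read count in
#' a pool falls below `min_depth` are flagged missing (`NA`) and excluded
#' from all downstream window averages.
#'
#' @param depths allele-depth data.frame (`chrom`, `pos`, `pool`, `countA`,
#'   `countB`), typically both pools stacked (see [simulate_pool_reads()],
#'   [read_allele_depths()]).
#' @param reference_parent `"A"` or `"B"`: whose allele counts go in the
#'   numerator.
#' @param min_depth minimum total reads per marker per pool (default 5).
#' @return A `snp_index_table` data.frame: `chrom`, `pos`, `pool`, `depth`,
#'   `ref_count`, `snp_index`, with the reference parent stored in
#'   `attr(, "reference_parent")`.
#' @export
compute_snp_index <- function(depths, reference_parent = c("A", "B"),
                              min_depth = 5) {
  reference_parent <- as.character(reference_parent)[1]
  if (!reference_parent %in% c("A", "B"))
    stop("unknown reference parent: ", reference_parent)
  stopifnot(all(c("chrom", "pos", "pool", "countA", "countB") %in%
                names(depths)))
  total <- depths$countA + depths$countB
  ref <- if (reference_parent == "A") depths$countA else depths$countB
  idx <- ifelse(total >= min_depth & total > 0, ref / total, NA_real_)
  out <- data.frame(chrom = depths$chrom, pos = depths$pos,
                    pool = depths$pool, depth = total,
                    ref_count = ref, snp_index = idx)
  attr(out, "reference_parent") <- reference_parent
  class(out) <- c("snp_index_table", "data.frame")
  out
}

snp_index_wide <- function(idx, high_pool = "high", low_pool = "low") {
  pools <- unique(idx$pool)
  if (!all(c(high_pool, low_pool) %in% pools))
    stop("snp-index table must contain pools '", high_pool, "' and '",
         low_pool, "'")
  hi <- idx[idx$pool == high_pool, c("chrom", "pos", "depth", "snp_index")]
  lo <- idx[idx$pool == low_pool, c("chrom", "pos", "depth", "snp_index")]
  m <- merge(hi, lo, by = c("chrom", "pos"), suffixes = c("_high", "_low"),
             all = FALSE, sort = FALSE)
  m[order(m$chrom, m$pos), , drop = FALSE]
}

#' Remove co-segregating markers by the 0.3/0.7 index filter
#'
#' Markers whose SNP-index is extreme on the same side in *both* pools carry
#' no inter-pool segregation signal (both pools co-segregate one genotype,
#' e.g. a mis-called parental variant) and are removed. Alternative modes:
#' `"either-pool"` drops a marker whose index is outside `[low, high]` in
#' either pool, and `"keep-extreme"` retains only markers that are extreme in
#' at least one pool.
#'
#' @param idx a `snp_index_table` containing both pools.
#' @param low,high filter bounds (defaults 0.3 and 0.7; `low < high`).
#' @param mode filtering rule (see Details); default `"both-pools"`.
#' @param high_pool,low_pool pool labels (defaults `"high"`, `"low"`).
#' @return The filtered `snp_index_table` (rows of both pools removed for a
#'   filtered marker). Markers with a missing index are never treated as
#'   extreme.
#' @export
filter_cosegregating <- function(idx, low = 0.3, high = 0.7,
                                 mode = c("both-pools", "either-pool",
                                          "keep-extreme"),
                                 high_pool = "high", low_pool = "low") {
  mode <- match.arg(mode)
  if (low >= high) stop("invalid parameter: low must be < high")
  w <- snp_index_wide(idx, high_pool, low_pool)
  a <- w$snp_index_high
  b <- w$snp_index_low
  lo_a <- !is.na(a) & a < low;  hi_a <- !is.na(a) & a > high
  lo_b <- !is.na(b) & b < low;  hi_b <- !is.na(b) & b > high
  drop <- switch(mode,
    "both-pools" = (lo_a & lo_b) | (hi_a & hi_b),
    "either-pool" = lo_a | hi_a | lo_b | hi_b,
    "keep-extreme" = !(lo_a | hi_a | lo_b | hi_b))
  bad <- paste(w$chrom, w$pos)[drop]
  out <- idx[!(paste(idx$chrom, idx$pos) %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_parent") <- attr(idx, "reference_parent")
  class(out) <- class(idx)
  out
}

sliding_windows <- function(chrom_lengths, window, step) {
  out <- lapply(seq_len(nrow(chrom_lengths)), function(i) {
    len <- chrom_lengths$length[i]
    start <- seq.int(1L, len, by = step)
    end <- pmin(start + window - 1, len)
    data.frame(chrom = chrom_lengths$chrom[i], start = start, end = end,
               partial = (end - start + 1) < window)
  })
  do.call(rbind, out)
}

window_mean <- function(wdf, pos, val, chrom) {
  # per window: mean of non-missing val; uses cumulative sums per chromosome
  n <- nrow(wdf)
  mean_out <- rep(NA_real_, n)
  count_out <- integer(n)
  for (ch in unique(wdf$chrom)) {
    wi <- which(wdf$chrom == ch)
    mi <- which(chrom == ch & !is.na(val))
    if (!length(mi)) next
    p <- pos[mi]
    v <- val[mi]
    o <- order(p)
    p <- p[o]; v <- v[o]
    cs <- c(0, cumsum(v))
    lo <- findInterval(wdf$start[wi] - 1L, p)
    hi <- findInterval(wdf$end[wi], p)
    cnt <- hi - lo
    s <- cs[hi + 1] - cs[lo + 1]
    count_out[wi] <- cnt
    mean_out[wi] <- ifelse(cnt > 0, s / cnt, NA_real_)
  }
  list(mean = mean_out, n = count_out)
}

#' Sliding-window delta(SNP-index) statistics
#'
#' Averages the per-marker SNP-indices of each pool in sliding windows and
#' forms, per reference parent, `delta_ref = mean(high pool) - mean(low
#' pool)` (range `[-1, 1]`). The combined statistic is `delta_combined =
#' delta_ref_A - delta_ref_B` (range `[-2, 2]`): both terms are oriented so
#' that high-pool enrichment for parent A's alleles is positive, which on
#' complementary orientations is the two-reference sum printed as "-2 to +2".
#' When both reference sets contain the same markers and reads this reduces
#' algebraically to `2 * delta_ref_A`.
#'
#' @param idx_ref_a `snp_index_table` computed with reference parent A.
#' @param idx_ref_b `snp_index_table` computed with reference parent B (may
#'   cover a different marker set, as with dual variant-calling passes).
#' @param window window size in bp (default 200000).
#' @param step window increment in bp (default 20000; `window >= step > 0`).
#' @param chrom_lengths data.frame (`chrom`, `length`) or a [marker_set()];
#'   defaults to the furthest marker per chromosome.
#' @param high_pool,low_pool pool labels.
#' @return A `window_stats` data.frame with one row per window: `chrom`,
#'   `start`, `end` (1-based inclusive), `partial` (flag for the shorter
#'   terminal windows), per-reference marker counts and pool means,
#'   `delta_ref_A`, `delta_ref_B`, `delta_combined`. Windows with no usable
#'   marker in a reference set carry `NA` deltas. `window` and `step` are
#'   stored as attributes.
#' @export
window_deltas <- function(idx_ref_a, idx_ref_b, window = 200000, step = 20000,
                          chrom_lengths = NULL, high_pool = "high",
                          low_pool = "low") {
  if (!(window >= step && step > 0))
    stop("invalid parameter: need window >= step > 0")
  wa <- snp_index_wide(idx_ref_a, high_pool, low_pool)
  wb <- snp_index_wide(idx_ref_b, high_pool, low_pool)
  if (is.null(chrom_lengths)) {
    all_mk <- rbind(wa[c("chrom", "pos")], wb[c("chrom", "pos")])
    chrom_lengths <- stats::aggregate(pos ~ chrom, all_mk, max)
    names(chrom_lengths) <- c("chrom", "length")
  } else if (inherits(chrom_lengths, "marker_set")) {
    chrom_lengths <- chrom_lengths$chromosomes
  }
  wdf <- sliding_windows(chrom_lengths, window, step)
  if (!nrow(wdf)) return(empty_window_stats(window, step))

  mh_a <- window_mean(wdf, wa$pos, wa$snp_index_high, wa$chrom)
  ml_a <- window_mean(wdf, wa$pos, wa$snp_index_low, wa$chrom)
  mh_b <- window_mean(wdf, wb$pos, wb$snp_index_high, wb$chrom)
  ml_b <- window_mean(wdf, wb$pos, wb$snp_index_low, wb$chrom)
  dp_a <- window_mean(wdf, wa$pos,
                      (wa$depth_high + wa$depth_low) / 2, wa$chrom)

  wdf$n_snps_ref_a <- pmin(mh_a$n, ml_a$n)
  wdf$n_snps_ref_b <- pmin(mh_b$n, ml_b$n)
  wdf$mean_depth <- dp_a$mean
  wdf$mean_high_ref_a <- mh_a$mean
  wdf$mean_low_ref_a <- ml_a$mean
  wdf$mean_high_ref_b <- mh_b$mean
  wdf$mean_low_ref_b <- ml_b$mean
  wdf$delta_ref_A <- mh_a$mean - ml_a$mean
  wdf$delta_ref_B <- mh_b$mean - ml_b$mean
  wdf$delta_combined <- wdf$delta_ref_A - wdf$delta_ref_B
  rownames(wdf) <- NULL
  attr(wdf, "window") <- window
  attr(wdf, "step") <- step
  class(wdf) <- c("window_stats", "data.frame")
  wdf
}

empty_window_stats <- function(window, step) {
  wdf <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), partial = logical(0))
  attr(wdf, "window") <- window
  attr(wdf, "step") <- step
  class(wdf) <- c("window_stats", "data.frame")
  wdf
}

#' Null-simulation confidence envelope for window deltas
#'
#' For each window, simulates `n_sims` null replicates under no
#' trait-genotype association: each replicate draws `pool_size` F2 genotypes
#' per pool from the 1:2:1 distribution, samples binomial reads at the
#' window's mean depth for each of its markers, and computes the combined
#' delta. The `(1 - level)/2` and `(1 + level)/2` percentiles of the null
#' deltas give the envelope. Windows sharing a marker count and (rounded)
#' mean depth share one simulation.
#'
#' @param windows a `window_stats` data.frame from [window_deltas()].
#' @param pool_size individuals per pool under the null (default 25).
#' @param n_sims null replicates per window class (default 1000, minimum
#'   100).
#' @param levels confidence levels (default `c(0.95, 0.99)`).
#' @param seed optional integer seed.
#' @param depth per-window mean read depth; defaults to the `mean_depth`
#'   column of `windows`. Windows with zero/missing depth or no markers get a
#'   missing envelope.
#' @param shared_markers if `TRUE` (default, the synthetic-data layout) the
#'   two reference sets are the same markers and reads, so the null combined
#'   delta is exactly twice the parent-A delta; if `FALSE` the two reference
#'   terms are simulated independently.
#' @return `windows` with columns `ci_low_<level>` / `ci_high_<level>` added
#'   (level in percent, e.g. `ci_low_95`).
#' @export
confidence_envelope <- function(windows, pool_size = 25, n_sims = 1000,
                                levels = c(0.95, 0.99), seed = NULL,
                                depth = NULL, shared_markers = TRUE) {
  stopifnot(inherits(windows, "window_stats"))
  if (n_sims < 100) stop("n_sims must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(depth)) depth <- windows$mean_depth
  depth <- round(rep_len(depth, nrow(windows)))
  n_snps <- pmax(windows$n_snps_ref_a,
                 if (shared_markers) 0L else windows$n_snps_ref_b)
  usable <- !is.na(depth) & depth >= 1 & n_snps >= 1

  key <- paste(n_snps, depth)
  combos <- unique(key[usable])
  qlo <- matrix(NA_real_, nrow(windows), length(levels))
  qhi <- matrix(NA_real_, nrow(windows), length(levels))
  null_delta <- function(ns, dp) {
    # one replicate: pooled allele freq per pool, then ns binomial markers
    p_hi <- stats::rbinom(n_sims, 2L * pool_size, 0.5) / (2 * pool_size)
    p_lo <- stats::rbinom(n_sims, 2L * pool_size, 0.5) / (2 * pool_size)
    ih <- stats::rbinom(n_sims * ns, dp, rep(p_hi, each = ns)) / dp
    il <- stats::rbinom(n_sims * ns, dp, rep(p_lo, each = ns)) / dp
    d_a <- colMeans(matrix(ih, ns)) - colMeans(matrix(il, ns))
    if (shared_markers) return(2 * d_a)
    p_hi2 <- stats::rbinom(n_sims, 2L * pool_size, 0.5) / (2 * pool_size)
    p_lo2 <- stats::rbinom(n_sims, 2L * pool_size, 0.5) / (2 * pool_size)
    ih2 <- stats::rbinom(n_sims * ns, dp, rep(p_hi2, each = ns)) / dp
    il2 <- stats::rbinom(n_sims * ns, dp, rep(p_lo2, each = ns)) / dp
    d_b <- colMeans(matrix(ih2, ns)) - colMeans(matrix(il2, ns))
    d_a - d_b   # second term already oriented as parent-A depletion
  }
  for (cb in combos) {
    sel <- which(usable & key == cb)
    ns <- n_snps[sel[1]]
    dp <- depth[sel[1]]
    d <- null_delta(ns, dp)
    for (j in seq_along(levels)) {
      pr <- c((1 - levels[j]) / 2, (1 + levels[j]) / 2)
      q <- stats::quantile(d, pr, names = FALSE)
      qlo[sel, j] <- q[1]
      qhi[sel, j] <- q[2]
    }
  }
  for (j in seq_along(levels)) {
    windows[[sprintf("ci_low_%g", levels[j] * 100)]] <- qlo[, j]
    windows[[sprintf("ci_high_%g", levels[j] * 100)]] <- qhi[, j]
  }
  windows
}

#' Extract the candidate interval from window statistics
#'
#' Finds, over all chromosomes, the run of `k` consecutive windows (starts
#' exactly one step apart) maximizing the minimum `delta_combined` (ties
#' broken by the summed delta, then by leftmost position) and returns the
#' genomic intersection of the run: `[start of last window, end of first
#' window]`. With a 200-kb window and 20-kb step, five neighboring windows
#' intersect in exactly 120 kb. When marker positions are supplied the
#' bounds are refined by snapping outward to the nearest retained SNP at or
#' beyond each raw bound.
#'
#' @param windows a `window_stats` data.frame.
#' @param k number of consecutive windows to intersect (default 5).
#' @param snp_positions optional data.frame (`chrom`, `pos`) of retained
#'   SNPs used for boundary refinement.
#' @return A one-row `candidate_interval` data.frame: `chrom`, `raw_start`,
#'   `raw_end`, `refined_start`, `refined_end`, `peak_delta`.
#' @export
find_candidate_interval <- function(windows, k = 5, snp_positions = NULL) {
  stopifnot(inherits(windows, "window_stats"), k >= 1)
  step <- attr(windows, "step")
  best <- NULL
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    n <- nrow(w)
    if (n < k) next
    d <- w$delta_combined
    for (i in seq_len(n - k + 1)) {
      run <- i:(i + k - 1)
      if (k > 1 && any(diff(w$start[run]) != step)) next
      if (anyNA(d[run])) next
      cand <- list(chrom = ch,
                   score_min = min(d[run]), score_sum = sum(d[run]),
                   raw_start = w$start[run[k]], raw_end = w$end[run[1]],
                   peak = max(d[run]))
      if (is.null(best) ||
          cand$score_min > best$score_min ||
          (cand$score_min == best$score_min &&
           cand$score_sum > best$score_sum)) {
        best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no chromosome carries ", k,
         " consecutive windows with usable deltas")
  if (best$raw_end < best$raw_start)
    stop("window span shorter than (k - 1) steps; intersection is empty")
  rs <- best$raw_start
  re <- best$raw_end
  if (!is.null(snp_positions)) {
    p <- snp_positions$pos[snp_positions$chrom == best$chrom]
    left <- p[p <= best$raw_start]
    right <- p[p >= best$raw_end]
    if (length(left)) rs <- max(left)
    if (length(right)) re <- min(right)
  }
  out <- data.frame(chrom = best$chrom,
                    raw_start = best$raw_start, raw_end = best$raw_end,
                    refined_start = rs, refined_end = re,
                    peak_delta = best$peak)
  class(out) <- c("candidate_interval", "data.frame")
  out
}

#' Plot window deltas with confidence tracks
#'
#' Base-graphics plot of `delta_combined` along one chromosome, with any
#' envelope columns drawn as red lines.
#'
#' @param x a `window_stats` data.frame.
#' @param chrom chromosome to plot (default: first).
#' @param ... passed to [plot()].
#' @export
plot.window_stats <- function(x, chrom = NULL, ...) {
  if (is.null(chrom)) chrom <- x$chrom[1]
  w <- x[x$chrom == chrom, , drop = FALSE]
  mid <- (w$start + w$end) / 2
  plot(mid / 1e6, w$delta_combined, type = "l",
       xlab = sprintf("%s position (Mb)", chrom),
       ylab = expression(Delta * "(SNP-index), combined"),
       ylim = c(-2, 2), ...)
  abline(h = 0, col = "grey")
  for (nm in grep("^ci_(low|high)_", names(w), value = TRUE))
    lines(mid / 1e6, w[[nm]], col = "red", lty = 2)
  invisible(x)
}
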
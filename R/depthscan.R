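#' Simulate per-base depth profiles for two pools
#'
#' Emulates the coverage signature of a large insertion segregating with one
#' pool: both pools' per-base depths are Poisson with rate `base_depth`, and
#' within `insertion_pos` +/- `insertion_halo` the affected pool's rate is
#' multiplied by `dip_factor` (the halo models reads that span an insertion
#' absent from the reference and fail to map).
#'
#' @param region_length length of the simulated region in bp.
#' @param base_depth mean depth outside the halo (default 30).
#' @param insertion_pos 1-based position of the insertion (must lie in the
#'   region); `NULL` plants nothing.
#' @param insertion_halo halo half-width in bp (default 100).
#' @param dip_factor multiplicative depth collapse in `[0, 1]`; 1 = no
#'   signal, 0 = total dropout (default 0.2).
#' @param affected_pool which pool carries the dip (default `"high"`).
#' @param pools the two pool labels (default `c("high", "low")`).
#' @param chrom chromosome name for the output (default `"A07"`).
#' @param seed optional integer seed.
#' @return A `depth_profile` data.frame: `chrom`, `pos`, one integer depth
#'   column per pool; pool labels kept in `attr(, "pools")`.
#' @export
simulate_depth_profiles <- function(region_length, base_depth = 30,
                                    insertion_pos = NULL,
                                    insertion_halo = 100, dip_factor = 0.2,
                                    affected_pool = "high",
                                    pools = c("high", "low"),
                                    chrom = "A07", seed = NULL) {
  stopifnot(region_length >= 1, base_depth > 0, length(pools) == 2)
  if (dip_factor < 0 || dip_factor > 1)
    stop("dip_factor must be in [0, 1]")
  if (!is.null(insertion_pos) &&
      (insertion_pos < 1 || insertion_pos > region_length))
    stop("insertion_pos outside the region")
  if (!affected_pool %in% pools)
    stop("affected_pool must be one of the pool labels")
  if (!is.null(seed)) set.seed(seed)
  pos <- seq_len(region_length)
  rate <- matrix(base_depth, region_length, 2,
                 dimnames = list(NULL, pools))
  if (!is.null(insertion_pos)) {
    halo <- pos >= insertion_pos - insertion_halo &
            pos <= insertion_pos + insertion_halo
    rate[halo, affected_pool] <- base_depth * dip_factor
  }
  out <- data.frame(chrom = chrom, pos = pos,
                    p1 = stats::rpois(region_length, rate[, 1]),
                    p2 = stats::rpois(region_length, rate[, 2]))
  names(out)[3:4] <- pools
  attr(out, "pools") <- pools
  class(out) <- c("depth_profile", "data.frame")
  out
}

running_mean <- function(x, w) {
  # centered moving average with truncated edges
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect pool-contrast depth dips
#'
#' Smooths each pool's depth with a centered moving average, forms the
#' pseudocount-stabilized ratio `(smoothed affected + pseudocount) /
#' (smoothed other + pseudocount)`, and reports maximal runs where the ratio
#' stays below `ratio_threshold` for at least `min_length` bp. Both pools
#' are tested as the affected pool, so detection is label-symmetric.
#'
#' @param profile a `depth_profile` (columns `chrom`, `pos`, one depth
#'   column per pool).
#' @param smooth_window moving-average width in bp (default 50).
#' @param ratio_threshold dip call threshold on the smoothed ratio
#'   (default 0.5).
#' @param min_length minimum dip length in bp (default 50).
#' @param pseudocount added to both smoothed depths (default 1).
#' @return A `dip_calls` data.frame, one row per call: `chrom`, `start`,
#'   `end`, `affected_pool`, `mean_ratio` (inside the call), `flank_ratio`
#'   (mean over `2 * smooth_window` bp on each side). Zero rows when no dip
#'   is found.
#' @export
detect_depth_dips <- function(profile, smooth_window = 50,
                              ratio_threshold = 0.5, min_length = 50,
                              pseudocount = 1) {
  stopifnot(inherits(profile, "depth_profile") || is.data.frame(profile))
  if (smooth_window < 1) stop("smooth_window must be >= 1")
  pools <- attr(profile, "pools")
  if (is.null(pools)) pools <- setdiff(names(profile), c("chrom", "pos"))
  stopifnot(length(pools) == 2)
  calls <- list()
  for (ch in unique(profile$chrom)) {
    sub <- profile[profile$chrom == ch, , drop = FALSE]
    sm <- lapply(pools, function(p) running_mean(sub[[p]], smooth_window))
    names(sm) <- pools
    if (any(vapply(sm, function(s) all(s == 0), logical(1))))
      warning("a pool has zero depth everywhere on ", ch,
              "; ratios rely on the pseudocount")
    for (i in 1:2) {
      aff <- pools[i]
      oth <- pools[3 - i]
      r <- (sm[[aff]] + pseudocount) / (sm[[oth]] + pseudocount)
      below <- r < ratio_threshold
      rl <- rle(below)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      keep <- rl$values & rl$lengths >= min_length
      for (j in which(keep)) {
        seg <- starts[j]:ends[j]
        fl <- c(max(1, starts[j] - 2 * smooth_window):max(1, starts[j] - 1),
                min(nrow(sub), ends[j] + 1):
                  min(nrow(sub), ends[j] + 2 * smooth_window))
        calls[[length(calls) + 1]] <- data.frame(
          chrom = ch,
          start = sub$pos[starts[j]], end = sub$pos[ends[j]],
          affected_pool = aff,
          mean_ratio = mean(r[seg]),
          flank_ratio = mean(r[unique(fl)]))
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               affected_pool = character(0), mean_ratio = numeric(0),
               flank_ratio = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("dip_calls", "data.frame")
  out
}
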
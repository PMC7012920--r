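#' Single-marker LOD scan over an F2 population
#'
#' Fits, at each marker (or marker bin), the phenotype on an additive dosage
#' plus a dominance indicator by least squares, and scores the marker with
#' `LOD = (n/2) * log10(RSS0 / RSS1)` against the intercept-only model. For
#' a three-level genotype factor this saturated model's residual sum of
#' squares equals the within-genotype-class sum of squares, which is how the
#' scan is computed (vectorized over markers). Perfect fits are kept finite
#' by flooring `RSS1` at `1e-12 * RSS0`. Missing genotypes are dropped
#' marker-wise.
#'
#' @param pop an `f2_population` with phenotypes assigned.
#' @param bin_size number of consecutive markers merged into one test by
#'   per-individual majority genotype (default 1 = no binning; ties take the
#'   smallest code).
#' @return A `lod_profile` data.frame: `chrom`, `pos`, `lod`, `additive`
#'   (half the BB-minus-AA class mean difference), `dominance` (AB class
#'   mean minus the homozygote midpoint), `n` (individuals used). A constant
#'   phenotype yields an all-zero profile with a warning.
#' @export
lod_scan <- function(pop, bin_size = 1) {
  stopifnot(inherits(pop, "f2_population"), bin_size >= 1)
  if (all(is.na(pop$phenotypes)))
    stop("phenotypes are not assigned")
  y <- pop$phenotypes
  g <- pop$genotypes
  mk <- pop$marker_set$markers

  if (bin_size > 1) {
    binned <- bin_genotypes(g, mk, bin_size)
    g <- binned$g
    mk <- binned$mk
  }

  const <- stats::var(y, na.rm = TRUE)
  if (is.na(const) || const == 0) {
    warning("constant phenotype: returning an all-zero LOD profile")
    out <- data.frame(chrom = mk$chrom, pos = mk$pos, lod = 0,
                      additive = NA_real_, dominance = NA_real_,
                      n = sum(!is.na(y)))
    class(out) <- c("lod_profile", "data.frame")
    return(out)
  }

  m <- ncol(g)
  lod <- additive <- dominance <- rep(NA_real_, m)
  nn <- integer(m)
  chunk <- 2000L
  for (s in seq(1L, m, by = chunk)) {
    cols <- s:min(s + chunk - 1L, m)
    gs <- g[, cols, drop = FALSE]
    ok <- !is.na(gs) & !is.na(y)
    ym <- matrix(y, nrow(gs), ncol(gs))
    ym[!ok] <- 0
    y2 <- ym^2
    n_tot <- colSums(ok)
    sy <- colSums(ym)
    syy <- colSums(y2)
    rss1 <- syy
    cls_mean <- matrix(NA_real_, 3, ncol(gs))
    for (c0 in 0:2) {
      ind <- (gs == c0) & ok
      n_c <- colSums(ind)
      s_c <- colSums(ym * ind)
      rss1 <- rss1 - ifelse(n_c > 0, s_c^2 / pmax(n_c, 1), 0)
      cls_mean[c0 + 1, ] <- ifelse(n_c > 0, s_c / pmax(n_c, 1), NA_real_)
    }
    rss0 <- syy - ifelse(n_tot > 0, sy^2 / pmax(n_tot, 1), 0)
    floor1 <- 1e-12 * rss0
    l <- ifelse(n_tot > 0 & rss0 > 0,
                (n_tot / 2) * log10(rss0 / pmax(rss1, floor1)), 0)
    lod[cols] <- pmax(l, 0)
    nn[cols] <- n_tot
    additive[cols] <- (cls_mean[3, ] - cls_mean[1, ]) / 2
    dominance[cols] <- cls_mean[2, ] - (cls_mean[1, ] + cls_mean[3, ]) / 2
  }
  out <- data.frame(chrom = mk$chrom, pos = mk$pos, lod = lod,
                    additive = additive, dominance = dominance, n = nn)
  class(out) <- c("lod_profile", "data.frame")
  out
}

bin_genotypes <- function(g, mk, bin_size) {
  key <- paste(mk$chrom,
               ave(seq_len(nrow(mk)), mk$chrom,
                   FUN = function(i) (seq_along(i) - 1) %/% bin_size))
  groups <- split(seq_len(nrow(mk)), factor(key, unique(key)))
  gb <- matrix(NA_integer_, nrow(g), length(groups))
  pos <- numeric(length(groups))
  chrom <- character(length(groups))
  for (j in seq_along(groups)) {
    cols <- groups[[j]]
    sub <- g[, cols, drop = FALSE]
    # per-individual majority genotype; ties -> smallest code
    cnt0 <- rowSums(sub == 0L, na.rm = TRUE)
    cnt1 <- rowSums(sub == 1L, na.rm = TRUE)
    cnt2 <- rowSums(sub == 2L, na.rm = TRUE)
    maj <- max.col(cbind(cnt0, cnt1, cnt2), ties.method = "first") - 1L
    maj[cnt0 + cnt1 + cnt2 == 0] <- NA_integer_
    gb[, j] <- maj
    mid <- cols[ceiling(length(cols) / 2)]
    pos[j] <- mk$pos[mid]
    chrom[j] <- mk$chrom[mid]
  }
  list(g = gb, mk = data.frame(chrom = chrom, pos = pos))
}

#' Genome-wide peak of a LOD profile
#'
#' @param profile a `lod_profile` from [lod_scan()].
#' @return A one-row data.frame `chrom`, `pos`, `lod`, `no_signal`. Ties are
#'   broken by the leftmost genomic coordinate (profile order, then
#'   position); an all-zero profile returns the first marker flagged
#'   `no_signal = TRUE`.
#' @export
peak_summary <- function(profile) {
  if (!nrow(profile)) stop("empty LOD profile")
  lod <- profile$lod
  if (all(lod == 0 | is.na(lod))) {
    out <- data.frame(chrom = profile$chrom[1], pos = profile$pos[1],
                      lod = 0, no_signal = TRUE)
    return(out)
  }
  mx <- max(lod, na.rm = TRUE)
  cand <- which(lod == mx)
  ord <- order(match(profile$chrom[cand], unique(profile$chrom)),
               profile$pos[cand])
  i <- cand[ord[1]]
  data.frame(chrom = profile$chrom[i], pos = profile$pos[i], lod = lod[i],
             no_signal = FALSE)
}

#' Permutation threshold for the genome-wide maximum LOD
#'
#' Permutes phenotype labels `n_perm` times, rescans, and returns the
#' `1 - alpha` quantile of the permuted genome-wide maxima - the standard
#' genome-wide significance threshold for a scan.
#'
#' @param pop an `f2_population` with phenotypes.
#' @param n_perm number of permutations (default 200).
#' @param alpha genome-wide error rate (default 0.05).
#' @param bin_size passed to [lod_scan()].
#' @param seed optional integer seed.
#' @return list with `threshold` and the vector `max_lods`.
#' @export
lod_permutation_threshold <- function(pop, n_perm = 200, alpha = 0.05,
                                      bin_size = 1, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  mx <- numeric(n_perm)
  perm <- pop
  for (i in seq_len(n_perm)) {
    perm$phenotypes <- sample(pop$phenotypes)
    mx[i] <- max(lod_scan(perm, bin_size = bin_size)$lod, na.rm = TRUE)
  }
  list(threshold = stats::quantile(mx, 1 - alpha, names = FALSE),
       max_lods = mx)
}
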
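#' Simulate recombinant gametes
#'
#' Draws gamete haplotypes from an A x B cross. Each gamete receives a total
#' crossover count drawn uniformly from the closed integer range
#' `[round(mean_crossovers * (1 - bias)), round(mean_crossovers * (1 + bias))]`
#' (so the default 25 with 20% bias gives 20..30). Crossovers are apportioned
#' to chromosomes by multinomial sampling proportional to chromosome length
#' and placed uniformly; the starting parental phase of each chromosome is an
#' independent fair coin (independent assortment).
#'
#' @param ms a [marker_set()].
#' @param n_gametes number of gametes to draw.
#' @param mean_crossovers genome-wide mean crossover count per gamete
#'   (default 25).
#' @param bias half-width of the uniform crossover-count range as a fraction
#'   of the mean, in `[0, 1)` (default 0.2). `bias = 0` fixes the count.
#' @param seed optional integer seed.
#' @return A list of class `gamete_set`: `haplotypes`, an integer matrix
#'   (`n_gametes` x markers; 0 = parent A allele, 1 = parent B allele), and
#'   `crossovers`, a list of per-gamete data.frames (`chrom`, `pos`).
#' @export
simulate_gametes <- function(ms, n_gametes, mean_crossovers = 25, bias = 0.2,
                             seed = NULL) {
  stopifnot(inherits(ms, "marker_set"), n_gametes >= 1)
  if (mean_crossovers < 0)
    stop("invalid parameter: mean_crossovers must be >= 0")
  if (bias < 0 || bias >= 1)
    stop("invalid parameter: bias must be in [0, 1)")
  if (n_markers(ms) == 0) stop("marker set is empty")
  if (!is.null(seed)) set.seed(seed)

  chroms <- ms$chromosomes
  nc <- nrow(chroms)
  lo <- round(mean_crossovers * (1 - bias))
  hi <- round(mean_crossovers * (1 + bias))
  rng <- seq.int(lo, hi)
  n_co <- rng[sample.int(length(rng), n_gametes, replace = TRUE)]

  mk_chrom <- factor(ms$markers$chrom, levels = chroms$chrom)
  mk_idx <- split(seq_len(n_markers(ms)), mk_chrom)
  mk_pos <- split(ms$markers$pos, mk_chrom)

  hap <- matrix(0L, n_gametes, n_markers(ms))
  co_rec <- vector("list", n_gametes)
  pr <- chroms$length / sum(chroms$length)
  for (g in seq_len(n_gametes)) {
    per_chrom <- as.integer(stats::rmultinom(1, n_co[g], pr))
    phase <- sample(0:1, nc, replace = TRUE)
    rec <- vector("list", nc)
    for (ch in seq_len(nc)) {
      k <- per_chrom[ch]
      if (k > 0) {
        bp <- sort(stats::runif(k, 0, chroms$length[ch]))
        flips <- findInterval(mk_pos[[ch]], bp)
        hap[g, mk_idx[[ch]]] <- (phase[ch] + flips) %% 2L
        rec[[ch]] <- data.frame(chrom = chroms$chrom[ch], pos = bp)
      } else {
        hap[g, mk_idx[[ch]]] <- phase[ch]
      }
    }
    rec <- rec[!vapply(rec, is.null, logical(1))]
    co_rec[[g]] <- if (length(rec)) do.call(rbind, rec) else
      data.frame(chrom = character(0), pos = numeric(0))
  }
  structure(list(haplotypes = hap, crossovers = co_rec,
                 marker_set = ms),
            class = "gamete_set")
}

#' Crossover counts of a gamete set
#'
#' @param gametes a `gamete_set` from [simulate_gametes()].
#' @return Integer vector of genome-wide crossover counts, one per gamete.
#' @export
crossover_counts <- function(gametes) {
  vapply(gametes$crossovers, nrow, integer(1))
}

as_haplotypes <- function(x) {
  if (inherits(x, "gamete_set")) x$haplotypes else as.matrix(x)
}

#' Combine egg and pollen gametes into an F2 population
#'
#' Pairs egg and pollen haplotypes into diploid F2 genotypes. When the two
#' gamete sets have the same size every haplotype is used exactly once
#' (pollen order is randomly permuted against the eggs); otherwise each
#' individual pairs one uniformly resampled egg with one uniformly resampled
#' pollen haplotype.
#'
#' @param ms a [marker_set()].
#' @param eggs,pollen `gamete_set` objects or 0/1 haplotype matrices with one
#'   column per marker.
#' @param seed optional integer seed.
#' @return An object of class `f2_population`: `marker_set`, `genotypes`
#'   (integer matrix individuals x markers, counting parent-B alleles:
#'   0 = AA, 1 = AB, 2 = BB), `phenotypes` (NA until
#'   [assign_phenotypes()]), and `gamete_crossovers` (kept for testing).
#' @export
make_f2_population <- function(ms, eggs, pollen, seed = NULL) {
  stopifnot(inherits(ms, "marker_set"))
  he <- as_haplotypes(eggs)
  hp <- as_haplotypes(pollen)
  if (ncol(he) != n_markers(ms) || ncol(hp) != n_markers(ms))
    stop("haplotype marker dimension does not match the marker set")
  if (nrow(he) < 1 || nrow(hp) < 1)
    stop("need at least one egg and one pollen haplotype")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(he)
  if (nrow(hp) == n) {
    ie <- seq_len(n)
    ip <- sample(n)
  } else {
    ie <- sample(nrow(he), n, replace = TRUE)
    ip <- sample(nrow(hp), n, replace = TRUE)
  }
  geno <- he[ie, , drop = FALSE] + hp[ip, , drop = FALSE]
  storage.mode(geno) <- "integer"
  co <- list(
    egg = if (inherits(eggs, "gamete_set")) eggs$crossovers[ie] else NULL,
    pollen = if (inherits(pollen, "gamete_set")) pollen$crossovers[ip] else NULL)
  structure(list(marker_set = ms, genotypes = geno,
                 phenotypes = rep(NA_real_, n),
                 gamete_crossovers = co),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat("f2_population:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "markers;",
      if (all(is.na(x$phenotypes))) "phenotypes unset" else
        sprintf("phenotypes in [%.2f, %.2f]", min(x$phenotypes),
                max(x$phenotypes)), "\n")
  invisible(x)
}

#' Genotype codes as AA/AB/BB labels
#'
#' @param pop an `f2_population`.
#' @return Character matrix of genotype codes.
#' @export
genotype_codes <- function(pop) {
  g <- pop$genotypes
  matrix(c("AA", "AB", "BB")[g + 1L], nrow(g), ncol(g))
}

#' Define a trait architecture
#'
#' A trait architecture lists the causal loci of the simulated trait. Two
#' modes exist: `recessive_direct` loci add their `effect` to the phenotype
#' when the individual is homozygous for the causal parent's allele, and a
#' `dominant_suppressor` locus forces the phenotype to zero as soon as one
#' suppressor allele (the allele of `causal_parent`) is present - a dominant
#' epistatic mask over all direct loci.
#'
#' @param loci data.frame with columns `chrom`, `pos`, `mode`
#'   (`"recessive_direct"` or `"dominant_suppressor"`), `effect` (fraction of
#'   the phenotype; must be > 0 iff the mode is `recessive_direct`), and
#'   `causal_parent` (`"A"` or `"B"`).
#' @param ms optional [marker_set()]; when given, every locus must sit on a
#'   marker position.
#' @return The validated data.frame with class `trait_architecture`.
#' @export
trait_architecture <- function(loci, ms = NULL) {
  loci <- as.data.frame(loci)
  stopifnot(all(c("chrom", "pos", "mode", "effect", "causal_parent") %in%
                names(loci)))
  if (!all(loci$mode %in% c("recessive_direct", "dominant_suppressor")))
    stop("mode must be 'recessive_direct' or 'dominant_suppressor'")
  if (!all(loci$causal_parent %in% c("A", "B")))
    stop("causal_parent must be 'A' or 'B'")
  direct <- loci$mode == "recessive_direct"
  if (any(loci$effect[direct] <= 0) || any(loci$effect[!direct] != 0))
    stop("effect must be > 0 exactly for recessive_direct loci")
  if (!is.null(ms)) {
    found <- locus_marker_index(loci, ms, error = FALSE)
    if (anyNA(found))
      stop("architecture locus not on a marker position: ",
           paste(sprintf("%s:%d", loci$chrom[is.na(found)],
                         loci$pos[is.na(found)]), collapse = ", "))
  }
  class(loci) <- c("trait_architecture", "data.frame")
  loci
}

locus_marker_index <- function(loci, ms, error = TRUE) {
  key <- paste(ms$markers$chrom, ms$markers$pos)
  idx <- match(paste(loci$chrom, loci$pos), key)
  if (error && anyNA(idx))
    stop("trait locus not found in the marker set: ",
         paste(sprintf("%s:%s", loci$chrom[is.na(idx)], loci$pos[is.na(idx)]),
               collapse = ", "))
  idx
}

#' Default six-locus epistatic architecture
#'
#' One dominant suppressor on the second chromosome (suppressor allele
#' carried by parent B, the non-trait parent, so the F1 is fully suppressed),
#' a 60%-effect recessive direct locus on the fourth chromosome, and four
#' 10%-effect recessive direct loci on chromosomes 1, 6, 8 and 10. Each locus
#' sits on the marker closest to its chromosome midpoint.
#'
#' @param ms a [marker_set()] with at least 10 chromosomes (or as many as the
#'   default placements require).
#' @return A [trait_architecture()].
#' @export
default_trait_architecture <- function(ms) {
  chroms <- ms$chromosomes$chrom
  want <- c(2, 4, 1, 6, 8, 10)
  want <- want[want <= length(chroms)]
  if (length(want) < 6)
    stop("default architecture needs 10 chromosomes; got ", length(chroms))
  mid_marker <- function(ch) {
    mk <- ms$markers[ms$markers$chrom == ch, ]
    if (!nrow(mk)) stop("no markers on chromosome ", ch)
    mk$pos[which.min(abs(mk$pos - ms$chromosomes$length[
      ms$chromosomes$chrom == ch] / 2))]
  }
  loci <- data.frame(
    chrom = chroms[c(2, 4, 1, 6, 8, 10)],
    pos = vapply(chroms[c(2, 4, 1, 6, 8, 10)], mid_marker, numeric(1)),
    mode = c("dominant_suppressor", rep("recessive_direct", 5)),
    effect = c(0, 0.6, 0.1, 0.1, 0.1, 0.1),
    causal_parent = c("B", rep("A", 5)))
  rownames(loci) <- NULL
  trait_architecture(loci, ms)
}

#' Assign phenotypes under a trait architecture
#'
#' The phenotype is 0 whenever the individual carries at least one suppressor
#' allele at a `dominant_suppressor` locus; otherwise it is the sum of
#' `effect` over the `recessive_direct` loci at which the individual is
#' homozygous for the causal parent's allele. Under the default architecture
#' parent A scores 1.0 and both parent B and the F1 score 0.
#'
#' @param pop an `f2_population`.
#' @param arch a [trait_architecture()].
#' @return `pop` with the `phenotypes` element filled (values in `[0, 1]`
#'   when direct effects sum to 1).
#' @export
assign_phenotypes <- function(pop, arch) {
  stopifnot(inherits(pop, "f2_population"))
  idx <- locus_marker_index(arch, pop$marker_set)
  g <- pop$genotypes[, idx, drop = FALSE]  # B-allele counts per locus
  sup <- which(arch$mode == "dominant_suppressor")
  dir <- which(arch$mode == "recessive_direct")
  suppressed <- rep(FALSE, nrow(g))
  for (j in sup) {
    carries <- if (arch$causal_parent[j] == "B") g[, j] > 0L else g[, j] < 2L
    suppressed <- suppressed | carries
  }
  phen <- rep(0, nrow(g))
  for (j in dir) {
    hom <- if (arch$causal_parent[j] == "A") g[, j] == 0L else g[, j] == 2L
    phen <- phen + arch$effect[j] * hom
  }
  phen[suppressed] <- 0
  pop$phenotypes <- unname(phen)
  pop
}

#' Construct a pool sample
#'
#' @param label pool label, conventionally `"high"` or `"low"`.
#' @param members integer indices of the pooled individuals.
#' @return An object of class `pool_sample` with `label`, `members`, `size`.
#' @export
pool_sample <- function(label, members) {
  members <- as.integer(members)
  if (anyDuplicated(members)) stop("duplicated pool members")
  structure(list(label = as.character(label), members = members,
                 size = length(members)),
            class = "pool_sample")
}

#' Select phenotype-extreme pools
#'
#' The high pool is drawn uniformly from individuals with phenotype strictly
#' above `high_threshold`; the low pool from individuals with phenotype equal
#' to `low_value`. With `insufficient = "error"` (the default) a side with
#' fewer than `pool_size` qualifying individuals raises an informative error;
#' `insufficient = "rank"` instead falls back to the `pool_size` most extreme
#' individuals on that side (highest phenotypes for the high pool, phenotypes
#' closest to `low_value` for the low pool), keeping the pools disjoint.
#'
#' @param phenotypes numeric phenotype vector.
#' @param high_threshold lower open bound for the high pool (default 0.7).
#' @param low_value exact phenotype of the low pool (default 0).
#' @param pool_size members per pool (default 25).
#' @param seed optional integer seed.
#' @param insufficient `"error"` or `"rank"` (see Details).
#' @return list with elements `high` and `low`, each a [pool_sample()].
#' @export
select_pools <- function(phenotypes, high_threshold = 0.7, low_value = 0,
                         pool_size = 25, seed = NULL,
                         insufficient = c("error", "rank")) {
  insufficient <- match.arg(insufficient)
  stopifnot(pool_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  hi_cand <- which(phenotypes > high_threshold)
  if (length(hi_cand) >= pool_size) {
    hi <- sample(hi_cand, pool_size)
  } else if (insufficient == "rank") {
    hi <- order(phenotypes, decreasing = TRUE)[seq_len(pool_size)]
  } else {
    stop(sprintf(paste0("high pool: only %d individuals have phenotype > ",
                        "%g (need %d)"),
                 length(hi_cand), high_threshold, pool_size))
  }
  lo_cand <- setdiff(which(phenotypes == low_value), hi)
  if (length(lo_cand) >= pool_size) {
    lo <- sample(lo_cand, pool_size)
  } else if (insufficient == "rank") {
    rest <- setdiff(order(abs(phenotypes - low_value)), hi)
    if (length(rest) < pool_size)
      stop("low pool: fewer than pool_size individuals remain")
    lo <- rest[seq_len(pool_size)]
  } else {
    stop(sprintf("low pool: only %d individuals have phenotype == %g (need %d)",
                 length(lo_cand), low_value, pool_size))
  }
  list(high = pool_sample("high", hi), low = pool_sample("low", lo))
}

#' Simulate pooled sequencing reads over a pool
#'
#' At each marker, `depth` reads are drawn; each read samples a pool member
#' uniformly, then one of its two allele copies uniformly, then is flipped to
#' the other allele with probability `error_rate`. This is equivalent to a
#' binomial draw per marker at the pool's error-adjusted allele frequency,
#' which is how it is implemented.
#'
#' @param pop an `f2_population`.
#' @param pool a [pool_sample()].
#' @param depth reads per marker (default 30).
#' @param error_rate per-read allele flip probability in `[0, 0.5)`
#'   (default 0.01).
#' @param seed optional integer seed.
#' @param depth_model `"fixed"` draws exactly `depth` reads per marker;
#'   `"poisson"` draws a Poisson(`depth`) count.
#' @return An allele-depth data.frame with columns `chrom`, `pos`, `pool`,
#'   `countA`, `countB`.
#' @export
simulate_pool_reads <- function(pop, pool, depth = 30, error_rate = 0.01,
                                seed = NULL,
                                depth_model = c("fixed", "poisson")) {
  depth_model <- match.arg(depth_model)
  stopifnot(inherits(pop, "f2_population"), inherits(pool, "pool_sample"))
  if (depth < 1) stop("depth must be >= 1")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (pool$size == 0) stop("empty pool")
  if (!is.null(seed)) set.seed(seed)
  g <- pop$genotypes[pool$members, , drop = FALSE]
  p_b <- colMeans(g) / 2
  p_b <- p_b * (1 - error_rate) + (1 - p_b) * error_rate
  m <- ncol(g)
  dp <- if (depth_model == "fixed") rep.int(as.integer(depth), m) else
    stats::rpois(m, depth)
  count_b <- stats::rbinom(m, dp, p_b)
  data.frame(chrom = pop$marker_set$markers$chrom,
             pos = pop$marker_set$markers$pos,
             pool = pool$label,
             countA = dp - count_b,
             countB = count_b)
}
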
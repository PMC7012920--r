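test_that("crossover counts stay inside the bias range", {
  ms <- small_marker_set(n_chrom = 10, markers_per_chrom = 20)
  g <- simulate_gametes(ms, 200, mean_crossovers = 25, bias = 0.2, seed = 11)
  cc <- crossover_counts(g)
  expect_true(all(cc >= 20 & cc <= 30))

  g0 <- simulate_gametes(ms, 50, mean_crossovers = 25, bias = 0, seed = 12)
  expect_true(all(crossover_counts(g0) == 25))

  expect_error(simulate_gametes(ms, 5, bias = 1), "bias")
  expect_error(simulate_gametes(ms, 5, mean_crossovers = -1), "mean_crossovers")
})

test_that("mean crossovers per chromosome is ~2.5 on a 10-chromosome genome", {
  ms <- small_marker_set(n_chrom = 10, markers_per_chrom = 20)
  g <- simulate_gametes(ms, 200, mean_crossovers = 25, bias = 0.2, seed = 21)
  per_chrom <- sum(crossover_counts(g)) / (200 * 10)
  expect_lt(abs(per_chrom - 2.5), 0.2)
})

test_that("gamete simulation is reproducible under a fixed seed", {
  ms <- small_marker_set(n_chrom = 3, markers_per_chrom = 50)
  g1 <- simulate_gametes(ms, 20, seed = 33)
  g2 <- simulate_gametes(ms, 20, seed = 33)
  expect_identical(g1$haplotypes, g2$haplotypes)
  expect_identical(g1$crossovers, g2$crossovers)
})

test_that("uniform parental gametes give a monomorphic F2", {
  ms <- small_marker_set(n_chrom = 2, markers_per_chrom = 10)
  pop <- make_f2_population(ms, matrix(0L, 10, 20), matrix(0L, 10, 20),
                            seed = 1)
  expect_true(all(pop$genotypes == 0L))
  expect_true(all(genotype_codes(pop) == "AA"))
  expect_equal(nrow(pop$genotypes), 10)
  expect_error(make_f2_population(ms, matrix(0L, 5, 19), matrix(0L, 5, 20)),
               "dimension")
})

test_that("200 egg + 200 pollen recombinant gametes segregate 1:2:1", {
  ms <- small_marker_set(n_chrom = 10, markers_per_chrom = 50)
  eggs <- simulate_gametes(ms, 200, seed = 41)
  pollen <- simulate_gametes(ms, 200, seed = 42)
  pop <- make_f2_population(ms, eggs, pollen, seed = 43)
  expect_equal(nrow(pop$genotypes), 200)
  n0 <- colSums(pop$genotypes == 0L)
  n1 <- colSums(pop$genotypes == 1L)
  n2 <- colSums(pop$genotypes == 2L)
  e <- 200 * c(0.25, 0.5, 0.25)
  x2 <- (n0 - e[1])^2 / e[1] + (n1 - e[2])^2 / e[2] + (n2 - e[3])^2 / e[3]
  p <- stats::pchisq(x2, df = 2, lower.tail = FALSE)
  # tolerate up to 1% of markers below the p > 0.001 bar
  expect_lt(mean(p <= 0.001), 0.01)
})

test_that("trait model anchors: parents, F1, and the additive rule", {
  ms <- small_marker_set()
  arch <- default_trait_architecture(ms)
  m <- ncol_g <- nrow(ms$markers)
  pop <- as_f2_population(ms, rbind(rep(0L, m),   # parent A (trait parent)
                                    rep(2L, m),   # parent B (suppressor)
                                    rep(1L, m)))  # F1
  pop <- assign_phenotypes(pop, arch)
  expect_equal(pop$phenotypes, c(1, 0, 0))

  # no suppressor allele, homozygous causal at the 60% locus and one 10%
  # locus, heterozygous elsewhere -> 0.6 + 0.1
  g <- rep(1L, m)
  key <- paste(ms$markers$chrom, ms$markers$pos)
  at <- function(i) match(paste(arch$chrom[i], arch$pos[i]), key)
  g[at(1)] <- 0L                      # suppressor locus: AA, no B allele
  g[at(2)] <- 0L                      # 60% locus hom causal
  g[at(3)] <- 0L                      # one 10% locus hom causal
  pop2 <- assign_phenotypes(as_f2_population(ms, rbind(g)), arch)
  expect_equal(pop2$phenotypes, 0.7)

  bad <- arch
  bad$pos[1] <- bad$pos[1] + 1
  expect_error(assign_phenotypes(pop, bad), "not found")
})

test_that("phenotypes of a simulated F2 stay in [0, 1]", {
  pop <- sim_small_population(seed = 5)
  expect_true(all(pop$phenotypes >= 0 & pop$phenotypes <= 1))
})

test_that("extreme pools are disjoint, sized, and threshold-obeying", {
  phen <- c(rep(0.8, 30), rep(0.75, 5), rep(0, 40), rep(0.3, 50))
  pools <- select_pools(phen, seed = 2)
  expect_s3_class(pools$high, "pool_sample")
  expect_equal(pools$high$size, 25)
  expect_equal(pools$low$size, 25)
  expect_length(intersect(pools$high$members, pools$low$members), 0)
  expect_true(all(phen[pools$high$members] > 0.7))
  expect_true(all(phen[pools$low$members] == 0))

  expect_error(select_pools(c(rep(0.8, 30), rep(0.1, 40))), "low pool")
  expect_error(select_pools(c(rep(0.6, 100), rep(0, 100))), "high pool")

  ranked <- select_pools(c(rep(0.6, 100), rep(0, 100)),
                         insufficient = "rank", seed = 3)
  expect_equal(ranked$high$size, 25)
  expect_length(intersect(ranked$high$members, ranked$low$members), 0)
})

test_that("pooled reads have fixed depth and exact support on fixed pools", {
  ms <- small_marker_set(n_chrom = 1, markers_per_chrom = 50)
  pop <- as_f2_population(ms, matrix(0L, 30, 50))
  pool <- pool_sample("high", 1:25)
  rd <- simulate_pool_reads(pop, pool, depth = 30, error_rate = 0, seed = 4)
  expect_true(all(rd$countA == 30L))
  expect_true(all(rd$countB == 0L))
  expect_true(all(rd$countA + rd$countB == 30L))

  expect_error(simulate_pool_reads(pop, pool_sample("x", integer(0))),
               "empty pool")
  expect_error(simulate_pool_reads(pop, pool, error_rate = 0.5), "error_rate")
})

test_that("pooled read allele fraction matches the pool allele frequency", {
  ms <- small_marker_set(n_chrom = 1, chrom_length = 2e6,
                         markers_per_chrom = 1500)
  # 1:2:1 pool at every marker -> allele-A frequency 0.5
  g <- matrix(rep(c(0L, 1L, 1L, 2L), each = 1), 4, 1500)
  pop <- as_f2_population(ms, g)
  pool <- pool_sample("high", 1:4)
  rd <- simulate_pool_reads(pop, pool, depth = 30, error_rate = 0, seed = 9)
  frac <- sum(rd$countA) / sum(rd$countA + rd$countB)
  se <- sqrt(0.25 / (1500 * 30))   # binomial, aggregated over markers
  expect_lt(abs(frac - 0.5), 3 * se)

  # depth -> infinity converges to the true pool frequency per marker
  g2 <- matrix(sample(0:2, 8 * 200, TRUE, prob = c(1, 2, 1) / 4), 8, 200)
  ms2 <- small_marker_set(n_chrom = 1, chrom_length = 2e5,
                          markers_per_chrom = 200)
  pop2 <- as_f2_population(ms2, g2)
  rd2 <- simulate_pool_reads(pop2, pool_sample("high", 1:8), depth = 1e4,
                             error_rate = 0, seed = 10)
  truth <- 1 - colMeans(g2) / 2
  est <- rd2$countA / (rd2$countA + rd2$countB)
  expect_lt(mean(abs(est - truth)), 0.01)
  expect_lt(max(abs(est - truth)), 0.03)
})

test_that("pool read simulation is reproducible under a fixed seed", {
  pop <- sim_small_population(seed = 6, n = 40,
                              ms = small_marker_set(2, 1e6, 50))
  pool <- pool_sample("low", 1:10)
  expect_identical(simulate_pool_reads(pop, pool, seed = 8),
                   simulate_pool_reads(pop, pool, seed = 8))
})
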
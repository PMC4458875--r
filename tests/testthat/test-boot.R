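# Bootstrap machinery: z -> P conversion, the pool sampler, and the
# rotate-one/randomize-two null for peaks and genes.

test_that("z_to_p matches independent oracles across the z range", {
  expect_identical(z_to_p(0)$p_one_sided, 0.5)
  # standard normal quantile identity, oracle = numeric integration
  z05 <- 1.6448536
  expect_equal(z_to_p(z05)$p_one_sided,
               stats::integrate(stats::dnorm, z05, 50)$value,
               tolerance = 1e-6)
  expect_equal(z_to_p(z05)$p_one_sided, 0.05, tolerance = 1e-6)
  # deep tail: Mills-ratio series oracle, 6 significant digits; log10_p
  # stays finite and accurate past the double-precision underflow at z = 40
  for (z in c(10, 23.36, 30, 40)) {
    res <- z_to_p(z)
    if (oracle_tail_p(z) > 1e-300)
      expect_equal(res$p_one_sided, oracle_tail_p(z), tolerance = 1e-6)
    expect_equal(res$log10_p, oracle_tail_log10(z), tolerance = 1e-6)
    expect_true(is.finite(res$log10_p))
  }
  # direction and bounds
  expect_gt(z_to_p(-2)$p_one_sided, 0.5)
  expect_true(all(z_to_p(c(-5, 0, 5))$p_one_sided > 0))
})

test_that("sample_random_peakset emits fixed-width peaks from the pool", {
  # one chromosome so summit values identify pool peaks uniquely
  pool <- make_spaced_pool(40L, n_chroms = 1L)
  u <- merge_union(list(pool), 200L)
  set.seed(1)
  ps <- sample_random_peakset(u, 40L, width = 400L)
  expect_identical(sort(ps$summit), sort(u$summit))  # permutation at k = n
  expect_true(all(ps$end - ps$start == 400L))
  expect_true(all(ps$summit == (ps$start + ps$end) %/% 2L))
  expect_error(sample_random_peakset(u, 41L), "exceeds pool size")
  # uniform inclusion frequency at k = n/2
  set.seed(2)
  inc <- mean(replicate(2000, u$summit[1L] %in%
                          sample_random_peakset(u, 20L)$summit))
  expect_lt(abs(inc - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("C++ cluster statistic agrees with the R merge route", {
  for (r in 1:30) {
    set.seed(r)
    sets <- lapply(c("A", "B", "C"), function(lab) {
      n <- sample(5:40, 1L)
      s <- sort(sample.int(20000L, n))
      peak_set(sample(c("chr1", "chr2"), n, replace = TRUE),
               s, s + 400L, s + 200L, label = lab)
    })
    window <- sample(c(50L, 200L, 500L), 1L)
    codes <- regstage:::chrom_codes(sets[[1L]], sets[[2L]], sets[[3L]])
    cpp <- regstage:::cluster_full_count(
      unlist(codes), unlist(lapply(sets, `[[`, "summit")),
      rep(0:2, vapply(sets, nrow, integer(1L))), 3L, window)
    expect_identical(cpp, r_full_overlap(sets, window),
                     info = paste("replicate", r))
  }
})

test_that("bootstrap_peak_overlap matches the inclusion-probability oracle", {
  sizes <- c(chr1 = 5e5)
  spec <- c(ABC = 30L, A = 100L, B = 100L, C = 100L)
  ps <- sim_peak_sets(spec, sizes, seed = 17)
  cfg <- analysis_config(n_bootstrap = 4000L, rng_seed = 3)
  b <- bootstrap_peak_overlap(ps$sets, cfg)
  expect_identical(b$observed, 30L)
  # null mean oracle: pool N = 330 clusters, each set keeps 130 peaks; with
  # one set fixed, E[three-way] = 130 * (130/330)^2
  oracle <- 130 * (130 / 330)^2
  mc_se <- sd(b$null_stats) / sqrt(cfg$n_bootstrap)
  expect_lt(abs(b$null_mean - oracle), max(4 * mc_se, 0.2))
  # bit-exact reproducibility given (seed, iterations)
  b2 <- bootstrap_peak_overlap(ps$sets, cfg)
  expect_identical(b$null_stats, b2$null_stats)
  expect_identical(b$z, b2$z)
})

test_that("bootstrap_gene_overlap matches the hypergeometric oracle", {
  universe <- sprintf("u%04d", 1:500)
  set.seed(5)
  gs <- replicate(3, sample(universe, 100), simplify = FALSE)
  cfg <- analysis_config(n_bootstrap = 3000L, rng_seed = 7)
  b <- bootstrap_gene_overlap(gs, universe, cfg)
  expect_identical(b$observed, length(Reduce(intersect, gs)))
  oracle <- 100 * (100 / 500)^2   # m * (m/N)^2 with one set fixed
  mc_se <- sd(b$null_stats) / sqrt(cfg$n_bootstrap)
  expect_lt(abs(b$null_mean - oracle), max(4 * mc_se, 0.2))
  # disjoint sets: observed 0, depleted (z < 0)
  gs2 <- list(universe[1:50], universe[51:100], universe[101:150])
  b2 <- bootstrap_gene_overlap(gs2, universe,
                               analysis_config(n_bootstrap = 500L,
                                               rng_seed = 2))
  expect_identical(b2$observed, 0L)
  expect_lt(b2$z, 0)
  expect_error(bootstrap_gene_overlap(list(c("zz", "u0001"), gs2[[2L]],
                                           gs2[[3L]]), universe, cfg),
               "not contained")
})

test_that("degenerate nulls are flagged, not silently converted", {
  universe <- sprintf("u%03d", 1:50)
  cfg <- analysis_config(n_bootstrap = 100L, rng_seed = 1)
  expect_warning(
    b <- bootstrap_gene_overlap(list(universe, universe, universe),
                                universe, cfg),
    "degenerate")
  expect_identical(b$observed, 50L)
  expect_true(is.na(b$z) && is.na(b$p_one_sided))
})

test_that("rotations are interleaved round-robin into one pooled null", {
  sizes <- c(chr1 = 3e5)
  ps <- sim_peak_sets(c(ABC = 10L, A = 30L, B = 30L, C = 30L), sizes,
                      seed = 4)
  b <- bootstrap_peak_overlap(ps$sets,
                              analysis_config(n_bootstrap = 99L,
                                              rng_seed = 5))
  expect_identical(tabulate(b$rotation + 1L, 3L), rep(33L, 3L))
  expect_identical(length(b$null_stats), 99L)
})

test_that("planted three-way enrichment increases z monotonically", {
  # more planted shared clusters (same pool size) must never lower z
  sizes <- c(chr1 = 5e5)
  zs <- vapply(c(10L, 40L), function(k) {
    spec <- c(ABC = k, A = 100L - k, B = 100L - k, C = 100L - k)
    ps <- sim_peak_sets(spec, sizes, seed = 23)
    bootstrap_peak_overlap(ps$sets,
                           analysis_config(n_bootstrap = 1500L,
                                           rng_seed = 11))$z
  }, numeric(1L))
  expect_gt(zs[2L], zs[1L])
})
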
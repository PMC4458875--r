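# Synthetic-data generators: determinism and planted ground truth.

test_that("sim_genome is deterministic with ~uniform composition", {
  g1 <- sim_genome(2, 1e4, 7)
  g2 <- sim_genome(2, 1e4, 7)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1), as.character(sim_genome(2, 1e4, 8))))
  expect_identical(unname(chrom_sizes(g1)), c(10000L, 10000L))

  # GC of a 1e6-nt chromosome: binomial sd = sqrt(0.25/1e6) = 5e-4
  big <- sim_genome(1, 1e6, 3)
  gc <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 1e6
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("planted Venn structure is recovered exactly by summit clustering", {
  sizes <- c(chr1 = 3e5, chr2 = 3e5)
  spec <- c(ABC = 50L, AB = 20L, A = 30L, B = 10L, C = 40L)
  ps <- sim_peak_sets(spec, sizes, summit_jitter_sd = 0, seed = 5)
  vc <- venn_counts(merge_union(ps$sets, 200))
  expect_identical(vc$counts[names(spec)], spec)
  expect_identical(sum(vc$counts), sum(spec))

  # jitter 0: every co-planted pair has identical summits
  ov <- summit_overlap(ps$sets$A, ps$sets$B, 0)
  expect_identical(ov$count, sum(spec[c("ABC", "AB")]))
})

test_that("Venn recovery holds across random specs with jitter <= 50", {
  sizes <- c(chr1 = 4e5)
  sigs <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  for (r in 1:40) {
    set.seed(r)
    spec <- stats::setNames(sample(1:12, 7, replace = TRUE), sigs)
    ps <- sim_peak_sets(spec, sizes, summit_jitter_sd = sample(0:50, 1),
                        seed = r)
    vc <- venn_counts(merge_union(ps$sets, 200))
    expect_identical(vc$counts[order(names(vc$counts))],
                     spec[order(names(spec))],
                     info = paste("spec replicate", r))
  }
})

test_that("infeasible peak specs are rejected", {
  expect_error(sim_peak_sets(c(A = 1000L), c(chr1 = 5e4), seed = 1),
               "infeasible")
})

test_that("sim_tags conserves counts and concentrates mass at summits", {
  sizes <- c(chr1 = 3e5)
  ps <- sim_peak_sets(c(A = 20L), sizes, seed = 2)
  st <- sim_tags(ps$sets$A, sizes, tags_per_peak = 100L,
                 background_tags = 500L, pileup_sd = 50, seed = 3)
  expect_identical(tag_total(st$tags), 20L * 100L + 500L)

  # no background: > 95% of tags within 2 sd of the nearest summit
  st0 <- sim_tags(ps$sets$A, sizes, tags_per_peak = 200L,
                  background_tags = 0L, pileup_sd = 50, seed = 4)
  d <- vapply(st0$tags$pos, function(p) min(abs(p - ps$sets$A$summit)),
              numeric(1L))
  expect_gt(mean(d <= 100), 0.95)
})

test_that("sim_expression plants recoverable codes and respects the filter", {
  se <- sim_expression(300, noise_sd = 0, frac_unexpressed = 0.2, seed = 6)
  fc <- fold_changes(se$expr, stage_comparisons(se$expr))
  codes <- trinarize(fc)
  planted <- se$truth$planted_pattern_codes[codes$gene_id]
  expressed <- filter_expressed(se$expr)
  # noise-free: 100% recovery on expressed genes
  keep <- codes$gene_id %in% expressed
  expect_true(all(codes$code[keep] == planted[keep]))
  # unexpressed genes sit below the floor and are filtered
  expect_identical(sort(setdiff(codes$gene_id, expressed)),
                   sort(se$truth$unexpressed))
  # noise-free planted "12"-style digits give exact fold changes
  i <- which(planted == "12" & keep)[1L]
  if (!is.na(i))
    expect_equal(unname(fc[codes$gene_id[i], ]), c(2, 0), tolerance = 1e-12)
  expect_error(sim_expression(10, codes = stats::setNames(rep("3x", 10),
                                                          sprintf("g%05d", 1:10)),
                              seed = 1),
               "digits 0, 1, 2")
})

test_that("sim_motif_sequences plants pairs at exact spacings", {
  # single planted pair: recovered at distance exactly 15 in every peak
  w1 <- make_coloc_world(seed = 11, n_pool = 60L, n_target = 10L,
                         spacing = 15L)
  hits1 <- scan_peaks(w1$target, w1$genome, w1$pwms)
  for (nm in w1$target$name) {
    h <- hits1[hits1$peak == nm, ]
    ca <- h$center[h$motif_id == "M1"]; cb <- h$center[h$motif_id == "M2"]
    expect_true(any(abs(outer(ca, cb, "-")) == 15L), info = nm)
  }
  expect_identical(pair_count(hits1, "M1", "M2", 20L), nrow(w1$target))

  # spacing 25 never counts at pairing distance 20
  w <- make_coloc_world(seed = 11, n_pool = 80L, n_target = 10L,
                        spacing = 15L, extra_pair_spacing = 25L)
  hits <- scan_peaks(w$target, w$genome, w$pwms)
  expect_identical(pair_count(hits, "M1", "M2", 20L), length(w$target1))
  expect_identical(pair_count(hits, "M3", "M4", 20L), 0L)
  expect_identical(pair_count(hits, "M3", "M4", 25L), length(w$target2))
  # overlap guard
  expect_error(
    sim_motif_sequences(w$genome, w$target,
                        pairs = list(list(motif_a = w$pwms[[1L]],
                                          motif_b = w$pwms[[2L]],
                                          spacing = 5L,
                                          peaks = w$target$name[1L]))),
    "overlaps")
})

test_that("generators are pure functions of (parameters, seed)", {
  sizes <- c(chr1 = 2e5)
  p1 <- sim_peak_sets(c(AB = 10L, A = 5L), sizes, summit_jitter_sd = 20,
                      seed = 9)
  p2 <- sim_peak_sets(c(AB = 10L, A = 5L), sizes, summit_jitter_sd = 20,
                      seed = 9)
  expect_identical(p1$sets, p2$sets)
  e1 <- sim_expression(50, noise_sd = 0.4, seed = 9)
  e2 <- sim_expression(50, noise_sd = 0.4, seed = 9)
  expect_identical(e1$expr$values, e2$expr$values)
  t1 <- sim_tags(p1$sets$A, sizes, 10, 100, 30, seed = 9)
  t2 <- sim_tags(p1$sets$A, sizes, 10, 100, 30, seed = 9)
  expect_identical(t1$tags, t2$tags)
})
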
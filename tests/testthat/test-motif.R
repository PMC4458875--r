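# PWM scanning, motif density, pair counting, co-localization bootstrap.

test_that("scan finds planted consensus instances at their planted offsets", {
  g <- sim_genome(1, 2e4, 3)
  pk <- make_spaced_pool(5L, spacing = 2000L, n_chroms = 1L, label = "t")
  p1 <- pwm_from_consensus("ACCGGATA", "M1")
  ms <- sim_motif_sequences(g, pk,
                            singles = list(list(motif = p1,
                                                peaks = pk$name)),
                            seed = 4)
  hits <- scan_peaks(pk, ms$genome, list(p1))
  tr <- ms$truth
  for (i in seq_len(nrow(tr))) {
    s <- pk$summit[pk$name == tr$peak[i]]
    expect_true(any(hits$peak == tr$peak[i] &
                      hits$center == tr$center_a[i] - s))
  }
})

test_that("a uniform PWM scores 0 everywhere and yields no positive hits", {
  g <- sim_genome(1, 1e4, 5)
  pk <- peak_set("chr1", 4800L, 5200L, 5000L, "p", label = "u")
  flat <- pwm(matrix(1, 4, 6), "flat")
  expect_equal(flat$max_score, 0)
  hits <- scan_peaks(pk, g, list(flat), threshold_bits = 0.1)
  expect_identical(nrow(hits), 0L)
  # at threshold 0 every position scores exactly 0 and is reported
  hits0 <- scan_peaks(pk, g, list(flat), threshold_bits = 0, prune = FALSE)
  expect_identical(nrow(hits0), 2L * (401L - 6L + 1L))
  expect_true(all(hits0$score == 0))
})

test_that("C++ scanning agrees with the R scoring oracle on both strands", {
  set.seed(6)
  for (r in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    p <- pwm_from_consensus(paste(sample(c("A", "C", "G", "T"), 7, TRUE),
                                  collapse = ""), "m", strength = 20)
    enc <- regstage:::encode_dna(seq)
    for (lom in list(p$logodds, regstage:::pwm_revcomp_logodds(p))) {
      r_scores <- unname(regstage:::score_positions(enc, lom))
      cpp <- regstage:::pwm_scan_hits(enc, lom, 0.5 * p$max_score)
      expect_identical(cpp$pos, unname(which(r_scores >= 0.5 * p$max_score)))
      expect_equal(cpp$score, r_scores[cpp$pos], tolerance = 1e-12)
    }
  }
})

test_that("scanning is strand-symmetric under reverse complementation", {
  g <- sim_genome(1, 1e4, 9)
  p <- pwm_from_consensus("ACGGTACG", "m")
  hits_fwd <- scan_genome(g, list(p))
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  hits_rc <- scan_genome(rc, list(p))
  # a hit starting at s maps to start 10000 - s - 8 with flipped strand
  expect_identical(sort(10000L - hits_fwd$start - 8L), sort(hits_rc$start))
  expect_identical(sum(hits_fwd$strand == "+"), sum(hits_rc$strand == "-"))
  expect_equal(sort(hits_fwd$score), sort(hits_rc$score))
})

test_that("motif_density conserves hits and localizes planted offsets", {
  hits <- structure(data.frame(peak = rep("p1", 5L), motif_id = "M",
                               center = c(0L, 1L, 2L, -3L, 150L),
                               strand = "+", score = 1,
                               stringsAsFactors = FALSE),
                    class = c("MotifHits", "data.frame"), window = 200L)
  d <- motif_density(hits, bin = 10L)
  expect_identical(sum(d$M), 5L)
  expect_identical(d$M[d$bin_center == 5], 3L)    # bin [0, 10)
  expect_identical(d$M[d$bin_center == -5], 1L)
  expect_identical(d$M[d$bin_center == 155], 1L)
})

test_that("pair_count uses inclusive center distance and is symmetric", {
  mk_hits <- function(centers_a, centers_b) {
    structure(data.frame(
      peak = "p1",
      motif_id = c(rep("A", length(centers_a)), rep("B", length(centers_b))),
      center = c(centers_a, centers_b), strand = "+", score = 1,
      stringsAsFactors = FALSE), class = c("MotifHits", "data.frame"))
  }
  expect_identical(pair_count(mk_hits(100L, 115L), "A", "B", 20L), 1L)
  expect_identical(pair_count(mk_hits(100L, 120L), "A", "B", 20L), 1L)
  expect_identical(pair_count(mk_hits(100L, 121L), "A", "B", 20L), 0L)
  expect_identical(pair_count(mk_hits(100L, 115L), "B", "A", 20L), 1L)
  # self pairs need two distinct instances
  h <- mk_hits(c(100L, 110L), integer(0L))
  expect_identical(pair_count(h, "A", "A", 20L), 1L)
  expect_identical(pair_count(mk_hits(100L, integer(0L)), "A", "A", 20L), 0L)
  # monotone in max_dist
  counts <- vapply(c(5L, 15L, 25L), function(d)
    pair_count(mk_hits(100L, 115L), "A", "B", d), integer(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("overlapping same-motif hits are greedily pruned by score", {
  hits <- data.frame(peak = "p1", motif_id = "M",
                     center = c(100L, 103L, 120L),
                     strand = "+", score = c(5, 9, 7),
                     stringsAsFactors = FALSE)
  p <- pwm_from_consensus("ACGTACGT", "M")
  pruned <- regstage:::prune_hits(hits, list(p))
  # 103 beats 100 (overlap within L = 8); 120 is clear of 103
  expect_identical(sort(pruned$center), c(103L, 120L))
})

test_that("co-localization bootstrap flags the planted pair only", {
  w <- make_coloc_world(seed = 301, n_pool = 400L, n_target = 50L,
                        spacing = 15L, extra_pair_spacing = 25L)
  cfg <- analysis_config(n_bootstrap = 400L, rng_seed = 301)
  cl <- bootstrap_colocalization(w$target, w$pool, w$genome, w$pwms, cfg)
  z <- stats::setNames(cl$pairs$z, cl$pairs$pair)
  expect_gt(z[["M1|M2"]], 3)
  expect_lte(z[["M3|M4"]], 3)   # planted at 25 bp, never within 20
  others <- setdiff(names(z), c("M1|M2", "M3|M4"))
  expect_true(all(is.na(z[others]) | z[others] <= 3))
  expect_identical(unname(which.max(cl$z_matrix["M1", ])),
                   unname(which(colnames(cl$z_matrix) == "M2")))
  # matrix is symmetric with canonical pair indexing
  expect_equal(cl$z_matrix, t(cl$z_matrix))
})

test_that("an empty target set yields zero observed counts and z <= 0", {
  w <- make_coloc_world(seed = 77, n_pool = 60L, n_target = 5L)
  empty <- peak_set(character(0L), integer(0L), integer(0L), integer(0L),
                    character(0L), label = "none")
  cfg <- analysis_config(n_bootstrap = 100L, rng_seed = 5)
  cl <- bootstrap_colocalization(empty, w$pool, w$genome, w$pwms, cfg)
  expect_true(all(cl$pairs$observed == 0L))
  expect_true(all(is.na(cl$pairs$z) | cl$pairs$z <= 0))
})
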
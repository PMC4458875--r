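# Domain types and format readers/writers.

test_that("narrowPeak reading applies the summit-offset and midpoint rules", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t600\tp1\t0\t.\t5\t3\t2\t250",
               "chr1\t100\t600\tp2\t0\t.\t5\t3\t2\t-1",
               "chr2\t0\t10\tp3\t7\t.\t1\t1\t1\t9"), f)
  ps <- read_narrowpeak(f, label = "x")
  expect_s3_class(ps, "PeakSet")
  expect_identical(ps$summit[ps$name == "p1"], 350L)   # start + offset
  expect_identical(ps$summit[ps$name == "p2"], 350L)   # midpoint fallback
  expect_identical(ps$summit[ps$name == "p3"], 9L)
  expect_identical(peak_label(ps), "x")
  # sorted by (chrom, summit)
  expect_identical(ps$chrom, sort(ps$chrom))
})

test_that("malformed narrowPeak lines fail with the line number", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t600\tp1\t0\t.\t5\t3\t2\t250",
               "chr1\t100\t600\tp2\t0\t.\t5\t3\t2\tzz"), f)
  expect_error(read_narrowpeak(f), "line 2")
  writeLines("chr1\t100\t600\tp1\t0\t.\t5\t3\t2\t900", f)
  expect_error(read_narrowpeak(f), "summit outside interval")
  writeLines("chr1\t600\t100\tp1\t0\t.\t5\t3\t2\t10", f)
  expect_error(read_narrowpeak(f), "invalid interval")
})

test_that("peak round trip write -> read preserves all fields", {
  ps <- peak_set(c("chr2", "chr1", "chr1"), c(10L, 500L, 0L),
                 c(400L, 900L, 120L), c(300L, 777L, 60L),
                 name = c("a", "b", "c"), score = c(1.5, 2, 3),
                 label = "rt")
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(ps, f)
  ps2 <- read_narrowpeak(f, label = "rt")
  expect_identical(ps2[, c("chrom", "start", "end", "summit", "name")],
                   ps[, c("chrom", "start", "end", "summit", "name")])
  expect_equal(ps2$score, ps$score)
})

test_that("peak_set enforces interval and summit invariants", {
  expect_error(peak_set("chr1", 10, 10, 10), "start < end")
  expect_error(peak_set("chr1", 10, 20, 25), "summit outside")
  expect_error(peak_set("", 10, 20, 15), "empty chrom")
})

test_that("gene models derive strand-aware TSSs from BED6 and GTF", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000\tg1\t0\t+",
               "chr1\t1000\t5000\tg2\t0\t-"), f)
  g <- read_genes(f)
  expect_identical(g$tss[g$gene_id == "g1"], 1000L)
  expect_identical(g$tss[g$gene_id == "g2"], 4999L)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "1001", "5000", ".", "+", ".",
                   'gene_id "g3";', sep = "\t"), gtf)
  g3 <- read_genes(gtf)
  expect_identical(g3$start, 1000L)  # 1-based inclusive -> 0-based half-open
  expect_identical(g3$end, 5000L)
  expect_identical(g3$tss, 1000L)

  writeLines(c("chr1\t1\t10\tg1\t0\t+", "chr1\t1\t10\tg1\t0\t-"), f)
  expect_error(read_genes(f), "duplicate gene_id")
  writeLines("chr1\t1\t10\tg1\t0\t.", f)
  expect_error(read_genes(f), "strand")
})

test_that("expression loader aligns metadata and rejects defects", {
  vals <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(rnorm(12, 8), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  write.table(data.frame(gene_id = rownames(m), m), vals, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("label\tstage\tinduced\treplicate",
               paste(paste0("s", 1:4), rep(c("HE", "HE2"), 2),
                     FALSE, rep(1:2, each = 2), sep = "\t")), meta)
  em <- read_expression(vals, meta)
  expect_identical(dim(em), c(3L, 4L))
  expect_identical(em$samples$label, colnames(em$values))

  # sample without metadata
  writeLines(c("label\tstage\tinduced\treplicate",
               paste(paste0("s", 1:3), "HE", FALSE, 1, sep = "\t")), meta)
  expect_error(read_expression(vals, meta), "no metadata")

  # non-numeric cell named precisely
  m2 <- m; m2[2, 3] <- NA
  write.table(data.frame(gene_id = rownames(m2), m2), vals, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("label\tstage\tinduced\treplicate",
               paste(paste0("s", 1:4), "HE", FALSE, 1:4, sep = "\t")), meta)
  expect_error(read_expression(vals, meta), "g2.*s3")

  # duplicate gene rows
  write.table(data.frame(gene_id = c("g1", "g1", "g3"), m), vals,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(vals, meta), "duplicate gene row")
})

test_that("expression round trip preserves values and metadata", {
  se <- sim_expression(20, noise_sd = 0.3, seed = 4)
  vals <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  write_expression(se$expr, vals, meta)
  back <- read_expression(vals, meta, stage_order = se$expr$stage_order)
  expect_equal(back$values, se$expr$values, tolerance = 1e-12)
  expect_identical(back$samples$stage, se$expr$samples$stage)
})

test_that("JASPAR PFM parsing handles both layouts and rejects defects", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001 test",
               "A [ 10 0 0 5 2 1 ]",
               "C [ 0 10 0 5 2 1 ]",
               "G [ 0 0 10 0 3 4 ]",
               "T [ 0 0 0 0 3 4 ]",
               ">plain",
               "1 2 3 4", "4 3 2 1", "1 1 1 1", "2 2 2 2"), f)
  pw <- read_jaspar(f)
  expect_named(pw, c("MA0001", "plain"))
  expect_identical(pw$MA0001$length, 6L)
  expect_identical(pw$plain$length, 4L)
  expect_true(all(abs(colSums(pw$MA0001$probs) - 1) < 1e-12))

  writeLines(c(">bad", "1 2 3", "1 2", "1 2 3", "1 2 3"), f)
  expect_error(read_jaspar(f), "unequal length")
  expect_error(pwm(matrix(-1, 4, 5)), "negative")
})

test_that("all-equal counts with uniform background score 0 everywhere", {
  p <- pwm(matrix(3, 4, 5), "uniform")
  expect_true(all(abs(p$logodds) < 1e-12))
  expect_equal(p$max_score, 0)
})

test_that("PWM round trip through JASPAR text preserves counts", {
  p <- pwm_from_consensus("ACGGTA", "m")
  f <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar(list(p), f)
  back <- read_jaspar(f)[["m"]]
  expect_equal(unname(back$counts), unname(p$counts))
})

test_that("tag BED round trip reduces fragments to midpoints", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t5\t6", "chr2\t0\t101"), f)
  tg <- read_tags_bed(f, label = "t")
  expect_identical(tag_total(tg), 3L)
  expect_identical(tg$pos, c(5L, 150L, 50L))  # sorted by (chrom, pos)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_tags_bed(tg, f2)
  expect_identical(read_tags_bed(f2)$pos, tg$pos)
})

test_that("derived seeds are stable, stream-specific and < 2^31", {
  s1 <- derive_seed(42L, "sim_genome")
  expect_identical(s1, derive_seed(42L, "sim_genome"))
  expect_false(s1 == derive_seed(42L, "sim_tags"))
  expect_true(s1 > 0 && s1 < 2^31)
})
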
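# Shared fixtures and independent brute-force oracles.
# Oracles deliberately avoid the code paths they check: plain per-element
# loops, no IRanges, no C++.

# a pool of n spaced summits (gaps > 2*window + width, so clusters never chain)
make_spaced_pool <- function(n, spacing = 1000L, n_chroms = 5L,
                             width = 400L, label = "pool") {
  per <- ceiling(n / n_chroms)
  chrom <- rep(paste0("chr", seq_len(n_chroms)), each = per)[seq_len(n)]
  pos <- rep(600L + (seq_len(per) - 1L) * spacing, times = n_chroms)[seq_len(n)]
  peak_set(chrom, pos - width %/% 2L, pos + width - width %/% 2L, pos,
           label = label)
}

# brute-force peak-to-gene allocation, one peak at a time
oracle_annotate <- function(peaks, genes, cfg) {
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]; ch <- peaks$chrom[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pick <- function(idx) {
      if (!length(idx)) return(NULL)
      d <- abs(s - g$tss[idx])
      idx[order(d, g$gene_id[idx])][1L]
    }
    lo <- ifelse(g$strand == "+", g$tss - cfg$promoter_upstream,
                 g$tss - cfg$promoter_downstream)
    hi <- ifelse(g$strand == "+", g$tss + cfg$promoter_downstream,
                 g$tss + cfg$promoter_upstream)
    best <- pick(which(s >= lo & s <= hi)); cat_ <- "promoter"
    if (is.null(best)) {
      best <- pick(which(s >= g$start & s < g$end)); cat_ <- "intragenic"
    }
    if (is.null(best)) {
      best <- pick(which(abs(s - g$tss) <= cfg$intergenic_max_dist))
      cat_ <- "intergenic"
    }
    if (is.null(best))
      return(data.frame(name = peaks$name[i], gene_id = NA_character_,
                        category = "unassigned", distance = 0L,
                        stringsAsFactors = FALSE))
    data.frame(name = peaks$name[i], gene_id = g$gene_id[best],
               category = cat_,
               distance = as.integer(
                 if (g$strand[best] == "+") s - g$tss[best]
                 else g$tss[best] - s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$category <- factor(out$category,
                         levels = c("promoter", "intragenic", "intergenic",
                                    "unassigned"))
  out
}

# brute-force composite profile: every (peak, tag) combination is examined
# directly (no sorted search, no tabulate), bins incremented one at a time
oracle_profile <- function(tags, peaks, cfg) {
  flank <- cfg$profile_flank; bin <- cfg$profile_bin
  nbins <- (2L * flank) %/% bin
  acc <- numeric(nbins)
  for (i in seq_len(nrow(peaks))) {
    off <- tags$pos[tags$chrom == peaks$chrom[i]] - peaks$summit[i]
    off <- off[off >= -flank & off < flank]
    for (o in off) {
      b <- (o + flank) %/% bin + 1L
      acc[b] <- acc[b] + 1
    }
  }
  (acc / nrow(peaks)) / (tag_total(tags) / 1e6)
}

# count clusters containing every set, via merge_union (R route)
r_full_overlap <- function(sets, window) {
  u <- merge_union(sets, window)
  full <- paste(sort(vapply(sets, peak_label, character(1L))), collapse = "")
  sum(u$signature == full)
}

# asymptotic upper-tail normal probability (Mills-ratio series); independent
# of pnorm, accurate to ~z^-6 relative error for large z
oracle_tail_p <- function(z) {
  stats::dnorm(z) / z * (1 - 1 / z^2 + 3 / z^4 - 15 / z^6)
}

# same series in the log10 domain (works past double underflow)
oracle_tail_log10 <- function(z) {
  (-z^2 / 2 - log(z) - 0.5 * log(2 * pi) +
     log1p(-1 / z^2 + 3 / z^4 - 15 / z^6)) / log(10)
}

# small motif co-localization world. The M1/M2 pair is planted at `spacing`
# in one group of target peaks; when `extra_pair_spacing` is given, the
# M3/M4 pair is planted in a second, disjoint target group (one pair per
# peak, so planted instances are never overwritten and unplanted motif
# pairs never co-occur in a target peak). All non-target pool peaks carry
# independent singles of every motif, giving every pair a live null.
make_coloc_world <- function(seed, n_pool = 400L, n_target = 50L,
                             spacing = 15L, extra_pair_spacing = NULL) {
  pwms <- list(pwm_from_consensus("ACCGGATA", "M1"),
               pwm_from_consensus("TTGCACCA", "M2"),
               pwm_from_consensus("CAGGTAAC", "M3"),
               pwm_from_consensus("GCTTAGGC", "M4"))
  genome <- sim_genome(1, max(1e4, n_pool * 1200 + 2000), seed)
  pool <- make_spaced_pool(n_pool, spacing = 1200L, n_chroms = 1L)
  set.seed(seed)
  n2 <- if (is.null(extra_pair_spacing)) 0L else n_target
  picked <- sample(pool$name, n_target + n2)
  t1 <- picked[seq_len(n_target)]
  t2 <- picked[seq_len(n2) + n_target]
  others <- setdiff(pool$name, picked)
  pairs <- list(list(motif_a = pwms[[1L]], motif_b = pwms[[2L]],
                     spacing = spacing, peaks = t1))
  if (n2 > 0L)
    pairs <- c(pairs, list(list(motif_a = pwms[[3L]], motif_b = pwms[[4L]],
                                spacing = extra_pair_spacing, peaks = t2)))
  ms <- sim_motif_sequences(genome, pool, pairs = pairs,
                            singles = lapply(pwms, function(p)
                              list(motif = p, peaks = others)),
                            seed = seed)
  tg <- pool[pool$name %in% picked, , drop = FALSE]
  target <- peak_set(tg$chrom, tg$start, tg$end, tg$summit, tg$name,
                     label = "target")
  list(genome = ms$genome, pool = pool, target = target,
       target1 = t1, target2 = t2, pwms = pwms, truth = ms$truth)
}

# expression matrix with every 3-digit trinary code planted `per_code` times
full_code_expression <- function(per_code = 31L, noise_sd = 0,
                                 seed = 1L) {
  combos <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  codes <- apply(combos, 1L, paste, collapse = "")
  codes <- rep(codes, each = per_code)
  names(codes) <- sprintf("g%05d", seq_along(codes))
  sim_expression(length(codes),
                 stages = c("HE", "HE2", "progenitor", "myeloid_progenitor"),
                 codes = codes, noise_sd = noise_sd, seed = seed)
}
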
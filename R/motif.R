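# PWM scanning in peak windows, motif density, pairwise co-localization
# counting, and the bootstrap z-score matrix for motif spacing.
#
# Scanning strategy: each chromosome is scored once per PWM (both strands,
# log2 odds against the background), and per-peak hits are recovered by
# interval lookup into the genome-wide hit table. A single scan therefore
# serves the observed peaks and every bootstrap draw, which keeps the
# co-localization null affordable.

# integer-encode a chromosome sequence: A=1 C=2 G=3 T=4 (other -> NA)
encode_dna <- function(chars_or_string) {
  s <- if (length(chars_or_string) == 1L) utf8ToInt(chars_or_string)
       else utf8ToInt(paste(chars_or_string, collapse = ""))
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("a")] <- 1L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("g")] <- 3L; code[utf8ToInt("t")] <- 4L
  code[s]
}

# score every start position of one strand-matrix over an encoded sequence
score_positions <- function(enc, lom) {
  L <- ncol(lom)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0L))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- lom[, j][enc[j:(j + n - 1L)]]
    v[is.na(v)] <- -Inf  # ambiguous base never matches
    sc <- sc + v
  }
  sc
}

#' Scan a genome for PWM hits
#'
#' Scores both strands at every position with log2 odds against the PWM
#' background and reports positions at or above `threshold_bits` (default:
#' `cfg` fraction of the motif's maximum attainable score). Hit positions
#' are instance centers, 0-based.
#'
#' @param genome a `DNAStringSet`.
#' @param pwms list of [pwm()] objects (or a single one).
#' @param threshold_bits numeric threshold in bits; `NULL` uses
#'   `scan_threshold_frac * max_score` per motif.
#' @param scan_threshold_frac fraction used when `threshold_bits` is `NULL`.
#' @return data frame: `motif_id`, `chrom`, `start`, `center`, `strand`,
#'   `score`.
#' @export
scan_genome <- function(genome, pwms, threshold_bits = NULL,
                        scan_threshold_frac = 0.8) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  out <- list()
  for (ch in names(genome)) {
    enc <- encode_dna(as.character(genome[[ch]]))
    enc[is.na(enc)] <- 0L
    for (p in pwms) {
      thr <- if (is.null(threshold_bits)) scan_threshold_frac * p$max_score
             else threshold_bits
      for (strand in c("+", "-")) {
        lom <- if (strand == "+") p$logodds else pwm_revcomp_logodds(p)
        hit <- pwm_scan_hits(enc, lom, thr)
        if (!length(hit$pos)) next
        start0 <- hit$pos - 1L
        out[[length(out) + 1L]] <- data.frame(
          motif_id = p$motif_id, chrom = ch, start = start0,
          center = motif_center(start0, p$length), strand = strand,
          score = hit$score, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(motif_id = character(0L), chrom = character(0L),
                      start = integer(0L), center = integer(0L),
                      strand = character(0L), score = numeric(0L),
                      stringsAsFactors = FALSE)
  res[order(res$chrom, res$center, res$motif_id), , drop = FALSE]
}

# assign genome-wide hits to peak windows [summit - window, summit + window]
# (instance fully inside the window); returns MotifHit table with offsets
hits_in_peaks <- function(gw, peaks, pwms, window) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  len <- vapply(pwms, `[[`, integer(1L), "length")
  names(len) <- vapply(pwms, `[[`, character(1L), "motif_id")
  out <- list()
  for (ch in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == ch)
    gh <- gw[gw$chrom == ch, , drop = FALSE]
    if (!nrow(gh)) next
    L <- unname(len[gh$motif_id])
    # instance must lie fully inside [summit - window, summit + window]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(gh$start + 1L, gh$start + L),
      IRanges::IRanges(peaks$summit[ip] - window + 1L,
                       peaks$summit[ip] + window + 1L),
      type = "within")
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- ip[S4Vectors::subjectHits(ov)]
    out[[length(out) + 1L]] <- data.frame(
      peak = peaks$name[si], motif_id = gh$motif_id[qi],
      center = gh$center[qi] - peaks$summit[si], strand = gh$strand[qi],
      score = gh$score[qi], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(peak = character(0L), motif_id = character(0L),
                      center = integer(0L), strand = character(0L),
                      score = numeric(0L), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$peak, res$motif_id, res$center), , drop = FALSE]
}

# greedy non-overlap pruning per (peak, motif): keep by descending score
prune_hits <- function(hits, pwms) {
  if (!nrow(hits)) return(hits)
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  len <- vapply(pwms, `[[`, integer(1L), "length")
  names(len) <- vapply(pwms, `[[`, character(1L), "motif_id")
  keep <- unlist(lapply(split(seq_len(nrow(hits)),
                              paste(hits$peak, hits$motif_id, sep = "\r")),
                        function(idx) {
    if (length(idx) == 1L) return(idx)
    L <- len[hits$motif_id[idx[1L]]]
    ord <- idx[order(-hits$score[idx], hits$center[idx])]
    taken <- integer(0L)
    for (i in ord) {
      if (!length(taken) ||
          all(abs(hits$center[i] - hits$center[taken]) >= L))
        taken <- c(taken, i)
    }
    taken
  }), use.names = FALSE)
  res <- hits[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find motif occurrences in windows around peak summits
#'
#' Scans the +/-`window` bp sequence window around each summit (instances
#' must lie fully inside) on both strands and reports hit centers as
#' offsets from the summit. Overlapping hits of the same motif are greedily
#' pruned by descending score, so tandem self-overlaps are not double
#' counted in pair statistics.
#'
#' @param peaks a `PeakSet`.
#' @param genome a `DNAStringSet`.
#' @param pwms list of [pwm()] objects.
#' @param window half-width, bp (the published scan uses 200).
#' @param threshold_bits,scan_threshold_frac see [scan_genome()].
#' @param prune prune overlapping same-motif hits?
#' @param genome_hits optional precomputed [scan_genome()] table to reuse.
#' @return data frame with class `"MotifHits"`: `peak`, `motif_id`,
#'   `center` (offset from summit), `strand`, `score`.
#' @export
scan_peaks <- function(peaks, genome, pwms, window = 200L,
                       threshold_bits = NULL, scan_threshold_frac = 0.8,
                       prune = TRUE, genome_hits = NULL) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (is.null(genome_hits))
    genome_hits <- scan_genome(genome, pwms, threshold_bits,
                               scan_threshold_frac)
  hits <- hits_in_peaks(genome_hits, peaks, pwms, as.integer(window))
  if (prune) hits <- prune_hits(hits, pwms)
  structure(hits, class = c("MotifHits", "data.frame"), window = window)
}

#' Histogram of motif-center offsets around summits
#'
#' @param hits a [scan_peaks()] result.
#' @param bin bin width, bp.
#' @param window half-width used for the scan (defaults to the attribute).
#' @param n_peaks number of peaks scanned, for per-peak normalization.
#' @return data frame: `bin_center`, one count column per motif, plus
#'   per-peak normalized columns (`<motif>_per_peak`) when `n_peaks` given.
#' @export
motif_density <- function(hits, bin = 10L,
                          window = attr(hits, "window") %||% 200L,
                          n_peaks = NULL) {
  edges <- seq(-window, window + bin, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  motifs <- sort(unique(hits$motif_id))
  out <- data.frame(bin_center = centers)
  for (m in motifs) {
    cc <- hits$center[hits$motif_id == m]
    idx <- findInterval(cc, edges, rightmost.closed = FALSE)
    out[[m]] <- tabulate(idx, nbins = length(centers))
    if (!is.null(n_peaks)) out[[paste0(m, "_per_peak")]] <- out[[m]] / n_peaks
  }
  out
}

# canonical pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Count peaks containing a close motif pair
#'
#' A peak is counted if it holds at least one (a, b) hit pair whose
#' center-to-center distance is <= `max_dist` (inclusive). For `a == b`,
#' two distinct instances are required.
#'
#' @param hits a [scan_peaks()] result.
#' @param motif_a,motif_b motif ids.
#' @param max_dist bp (the published pairing distance is 20).
#' @return integer count of peaks.
#' @export
pair_count <- function(hits, motif_a, motif_b, max_dist = 20L) {
  sub <- hits[hits$motif_id %in% c(motif_a, motif_b), , drop = FALSE]
  if (!nrow(sub)) return(0L)
  sum(vapply(split(sub, sub$peak), function(h) {
    ca <- h$center[h$motif_id == motif_a]
    cb <- h$center[h$motif_id == motif_b]
    if (motif_a == motif_b) {
      if (length(ca) < 2L) return(FALSE)
      d <- abs(outer(ca, ca, "-"))
      any(d[upper.tri(d)] <= max_dist)
    } else {
      length(ca) > 0L && length(cb) > 0L &&
        any(abs(outer(ca, cb, "-")) <= max_dist)
    }
  }, logical(1L)))
}

# per-peak indicator matrix: peak x pair, TRUE if peak holds a close pair
pair_indicator <- function(hits, motif_ids, max_dist, peak_names) {
  keys <- outer(motif_ids, motif_ids, pair_key)
  keys <- sort(unique(keys[upper.tri(keys, diag = TRUE)]))
  ind <- matrix(FALSE, length(peak_names), length(keys),
                dimnames = list(peak_names, keys))
  pf <- factor(hits$peak, levels = peak_names)
  cen <- lapply(motif_ids, function(m) {
    sel <- !is.na(pf) & hits$motif_id == m
    split(hits$center[sel], pf[sel])
  })
  names(cen) <- motif_ids
  for (pr in keys) {
    ab <- strsplit(pr, "|", fixed = TRUE)[[1L]]
    ca <- cen[[ab[1L]]]
    if (ab[1L] == ab[2L]) {
      ind[, pr] <- vapply(ca, function(a)
        length(a) >= 2L && min(diff(sort(a))) <= max_dist, logical(1L))
    } else {
      cb <- cen[[ab[2L]]]
      ind[, pr] <- mapply(function(a, b)
        length(a) > 0L && length(b) > 0L &&
          min(abs(outer(a, b, "-"))) <= max_dist,
        ca, cb)
    }
  }
  ind
}

#' Bootstrap z scores for motif-pair co-localization
#'
#' For every motif pair, the observed statistic is the number of target
#' peaks holding the two motifs within `cfg$pair_distance` bp
#' (center-to-center). The null re-draws peak sets of matching population
#' (width `cfg$random_peak_width`, i.e. the same +/-`window` scan geometry)
#' from the pool of distal peaks and recounts; z is
#' (observed - null mean) / null sd. Pairs whose null never fires have
#' undefined z (`NA`).
#'
#' @param target_peaks `PeakSet` under test.
#' @param pool `UnionPeaks` or `PeakSet` of candidate (distal) peaks; the
#'   published pool is the union of all distal peaks of every sample.
#' @param genome a `DNAStringSet`.
#' @param pwms list of [pwm()] objects (>= 2 for a meaningful matrix).
#' @param cfg an [analysis_config()]; uses `pair_distance`,
#'   `summit_window`, `n_bootstrap`, `sample_with_replacement`, `rng_seed`,
#'   `scan_threshold_frac`.
#' @return list with class `"ColocalizationMatrix"`: `pairs` (data frame
#'   `pair`, `observed`, `null_mean`, `null_sd`, `z`, `p`), `z_matrix`
#'   (motif x motif), `cluster_order` (hclust leaf order of motifs),
#'   `n_iterations`, `seed`.
#' @export
bootstrap_colocalization <- function(target_peaks, pool, genome, pwms,
                                     cfg = analysis_config()) {
  stopifnot(inherits(target_peaks, "PeakSet"), nrow(target_peaks) >= 0L)
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  motif_ids <- vapply(pwms, `[[`, character(1L), "motif_id")
  window <- cfg$summit_window
  gw <- scan_genome(genome, pwms,
                    scan_threshold_frac = cfg$scan_threshold_frac)
  obs_hits <- scan_peaks(target_peaks, genome, pwms, window = window,
                         scan_threshold_frac = cfg$scan_threshold_frac,
                         genome_hits = gw)
  pool_ps <- if (inherits(pool, "UnionPeaks")) union_as_peakset(pool)
             else pool
  pool_hits <- scan_peaks(pool_ps, genome, pwms, window = window,
                          scan_threshold_frac = cfg$scan_threshold_frac,
                          genome_hits = gw)
  ind <- pair_indicator(pool_hits, motif_ids, cfg$pair_distance,
                        pool_ps$name)
  obs_ind <- pair_indicator(obs_hits, motif_ids, cfg$pair_distance,
                            target_peaks$name)
  observed <- colSums(obs_ind)
  k <- nrow(target_peaks)
  nulls <- withr::with_seed(
    derive_seed(cfg$rng_seed, "bootstrap_colocalization"), {
      vapply(seq_len(cfg$n_bootstrap), function(i) {
        idx <- sample.int(nrow(ind), k,
                          replace = cfg$sample_with_replacement)
        colSums(ind[idx, , drop = FALSE])
      }, numeric(ncol(ind)))
    })
  if (is.null(dim(nulls))) nulls <- matrix(nulls, nrow = 1L)
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1L, sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  p <- ifelse(is.na(z), NA_real_, pnorm(z, lower.tail = FALSE))
  pairs <- data.frame(pair = colnames(ind), observed = as.integer(observed),
                      null_mean = null_mean, null_sd = null_sd,
                      z = z, p = p, stringsAsFactors = FALSE)
  zmat <- matrix(NA_real_, length(motif_ids), length(motif_ids),
                 dimnames = list(motif_ids, motif_ids))
  for (i in seq_len(nrow(pairs))) {
    ab <- strsplit(pairs$pair[i], "|", fixed = TRUE)[[1L]]
    zmat[ab[1L], ab[2L]] <- zmat[ab[2L], ab[1L]] <- pairs$z[i]
  }
  cluster_order <- motif_ids
  if (length(motif_ids) >= 3L) {
    zc <- zmat; zc[is.na(zc)] <- 0
    hc <- hclust(dist(zc), method = "complete")
    cluster_order <- motif_ids[hc$order]
  }
  structure(list(pairs = pairs, z_matrix = zmat,
                 cluster_order = cluster_order,
                 n_iterations = cfg$n_bootstrap, seed = cfg$rng_seed),
            class = "ColocalizationMatrix")
}

#' @export
print.ColocalizationMatrix <- function(x, ...) {
  cat("ColocalizationMatrix (", x$n_iterations, "iterations )\n")
  print(x$pairs[order(-rank(x$pairs$z, na.last = FALSE)), ])
  invisible(x)
}
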
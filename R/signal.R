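# Tag counting over union peaks, per-million normalization, composite
# tag-density profiles around summits, and ChIP-sample correlation.

#' Count tags falling in union peaks
#'
#' A tag is counted in a union peak iff its position lies in the
#' representative interval `[start, end)`; when union intervals overlap
#' (rare after merging), a tag goes to the first peak in sorted order.
#'
#' @param tags a `TagSet`.
#' @param union a `UnionPeaks` (or `PeakSet`) counting frame.
#' @return integer vector of counts, one per union peak, with the tag total
#'   as attribute `total`.
#' @export
count_tags <- function(tags, union) {
  stopifnot(inherits(tags, "TagSet"), is.data.frame(union))
  counts <- integer(nrow(union))
  for (ch in unique(union$chrom)) {
    iu <- which(union$chrom == ch)
    tp <- tags$pos[tags$chrom == ch]
    if (!length(tp)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(tp + 1L, width = 1L),
      IRanges::IRanges(union$start[iu] + 1L, union$end[iu]),
      select = "first")
    tb <- table(hits[!is.na(hits)])
    counts[iu[as.integer(names(tb))]] <- as.integer(tb)
  }
  attr(counts, "total") <- tag_total(tags)
  counts
}

#' Build a count matrix over union peaks for several tag sets
#'
#' @param tag_sets list of `TagSet`s (sample labels taken from each set).
#' @param union a `UnionPeaks` counting frame.
#' @param scale normalized counts are `raw / total * scale` (default per
#'   million).
#' @return list with class `"CountMatrix"`: `raw`, `normalized` (matrices
#'   union peaks x samples), `totals`.
#' @export
count_matrix <- function(tag_sets, union, scale = 1e6) {
  stopifnot(length(tag_sets) >= 1L)
  labels <- vapply(tag_sets, peak_label, character(1L))
  if (anyDuplicated(labels)) stop("tag set labels must be unique")
  raw <- vapply(tag_sets, count_tags, integer(nrow(union)), union = union)
  if (nrow(union) == 1L) raw <- matrix(raw, nrow = 1L)
  totals <- vapply(tag_sets, tag_total, integer(1L))
  dimnames(raw) <- list(sprintf("u%06d", seq_len(nrow(union))), labels)
  normalized <- sweep(raw, 2L, totals / scale, "/")
  structure(list(raw = raw, normalized = normalized, totals = totals,
                 scale = scale),
            class = "CountMatrix")
}

#' Composite tag-density profile around peak summits
#'
#' For each peak, tag offsets from the summit are histogrammed in
#' `cfg$profile_bin`-bp bins over +/-`cfg$profile_flank` (bins are
#' left-closed, `[edge, edge + bin)`); bin counts are averaged across peaks
#' and divided by (total tags / 1e6), so the profile is a mean per-peak,
#' per-million density that is invariant under uniform duplication of tags.
#'
#' @param tags a `TagSet`.
#' @param peaks a `PeakSet` of reference summits.
#' @param cfg an [analysis_config()] (defaults: 50-bp bins, +/-5000 bp,
#'   i.e. 200 bins).
#' @return data frame with class `"ProfileMatrix"`: `bin_center`,
#'   `density`; attributes `n_peaks`, `total_tags`, `flank`, `bin`.
#' @export
composite_profile <- function(tags, peaks, cfg = analysis_config()) {
  stopifnot(inherits(tags, "TagSet"), inherits(peaks, "PeakSet"),
            nrow(peaks) >= 1L)
  flank <- cfg$profile_flank; bin <- cfg$profile_bin
  nbins <- (2L * flank) %/% bin
  acc <- numeric(nbins)
  for (ch in unique(peaks$chrom)) {
    tp <- tags$pos[tags$chrom == ch]
    if (!length(tp)) next
    for (s in peaks$summit[peaks$chrom == ch]) {
      lo <- findInterval(s - flank - 1L, tp) + 1L  # first pos >= s - flank
      hi <- findInterval(s + flank - 1L, tp)       # last pos <= s + flank - 1
      if (hi < lo) next
      off <- tp[lo:hi] - s
      acc <- acc + tabulate((off + flank) %/% bin + 1L, nbins = nbins)
    }
  }
  density <- (acc / nrow(peaks)) / (tag_total(tags) / 1e6)
  out <- data.frame(bin_center = seq(-flank + bin / 2, flank - bin / 2,
                                     by = bin),
                    density = density)
  structure(out, class = c("ProfileMatrix", "data.frame"),
            n_peaks = nrow(peaks), total_tags = tag_total(tags),
            flank = flank, bin = bin)
}

#' Pearson correlation and clustering of ChIP samples
#'
#' Correlates normalized read counts over union peaks and clusters samples
#' with Euclidean distance and complete linkage (the convention for TF
#' binding data; expression matrices use average linkage via
#' [sample_correlation()]).
#'
#' @param counts a [count_matrix()].
#' @return a `SampleCorrelation` (see [sample_correlation()]).
#' @export
peak_sample_correlation <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  sample_correlation(counts$normalized, linkage = "complete")
}

#' Compare two composite profiles
#'
#' Bin-wise difference and ratio of two identically binned profiles; the
#' headline statistic is the mean density of each profile over the central
#' +/-500 bp and their ratio (second over first).
#'
#' @param p1,p2 [composite_profile()] results with identical binning.
#' @param central_flank bp half-width of the headline window.
#' @return list with `table` (bin_center, density_1, density_2, diff,
#'   ratio) and `central` (means, difference, ratio).
#' @export
profile_compare <- function(p1, p2, central_flank = 500L) {
  stopifnot(inherits(p1, "ProfileMatrix"), inherits(p2, "ProfileMatrix"))
  if (!identical(p1$bin_center, p2$bin_center))
    stop("profile binning mismatch")
  tab <- data.frame(bin_center = p1$bin_center,
                    density_1 = p1$density, density_2 = p2$density,
                    diff = p2$density - p1$density,
                    ratio = ifelse(p1$density > 0,
                                   p2$density / p1$density, NA_real_))
  ctr <- abs(tab$bin_center) <= central_flank
  m1 <- mean(tab$density_1[ctr]); m2 <- mean(tab$density_2[ctr])
  list(table = tab,
       central = list(mean_1 = m1, mean_2 = m2, diff = m2 - m1,
                      ratio = if (m1 > 0) m2 / m1 else NA_real_))
}
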
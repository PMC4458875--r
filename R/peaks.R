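# Summit-proximity peak comparison, union merging, Venn decomposition and
# peak-to-gene allocation.
#
# Overlap between two peaks is defined by summit proximity: summits on the
# same chromosome within +/- `window` bp ("within" read as the closed
# interval, so |delta| == window still overlaps). Merging is single-linkage
# clustering of all summits at that threshold; chaining (A-B-C merged even
# though A and C are > window apart) is accepted and documented.

#' Count peaks of one set with a summit-overlapping partner in another
#'
#' Directional: returns how many peaks in `a` have at least one peak in `b`
#' whose summit lies within `window` bp on the same chromosome, plus each
#' `a` peak's nearest partner. Swap the arguments for the other direction.
#'
#' @param a,b `PeakSet`s.
#' @param window bp, inclusive bound on |summit difference|.
#' @return list with `count` and `pairs` (data frame: `name_a`, `name_b`,
#'   `delta`, restricted to overlapping peaks, nearest partner only).
#' @export
summit_overlap <- function(a, b, window = 200L) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  res <- lapply(split(seq_len(nrow(a)), a$chrom), function(ia) {
    ib <- which(b$chrom == a$chrom[ia[1L]])
    if (!length(ib)) return(NULL)
    bs <- b$summit[ib]  # sorted within chrom by PeakSet invariant
    sa <- a$summit[ia]
    lo <- findInterval(sa, bs)
    cand_lo <- pmax(lo, 1L)
    cand_hi <- pmin(lo + 1L, length(bs))
    d_lo <- abs(sa - bs[cand_lo])
    d_hi <- abs(sa - bs[cand_hi])
    use_hi <- d_hi < d_lo
    nearest <- ifelse(use_hi, cand_hi, cand_lo)
    delta <- pmin(d_lo, d_hi)
    keep <- delta <= window
    if (!any(keep)) return(NULL)
    data.frame(name_a = a$name[ia[keep]], name_b = b$name[ib[nearest[keep]]],
               delta = delta[keep], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(pairs))
    pairs <- data.frame(name_a = character(0L), name_b = character(0L),
                        delta = integer(0L), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(count = nrow(pairs), pairs = pairs)
}

#' Merge peak sets into union peaks by single-linkage summit clustering
#'
#' All peaks from all sets are pooled and clustered: consecutive summits on
#' a chromosome belong to one cluster while each gap is <= `window`. Each
#' cluster becomes one union peak whose representative summit is the floor
#' of the member-summit median and whose interval spans the members. The
#' signature records which sets contributed (sorted labels, concatenated).
#' The result is invariant to the order in which sets are supplied.
#'
#' @param sets list of `PeakSet`s (or a single `PeakSet`).
#' @param window bp linkage threshold.
#' @return data frame with class `"UnionPeaks"`: `chrom`, `start`, `end`,
#'   `summit`, `signature`, `n_members`; attribute `members` holds the
#'   per-cluster member table, attribute `labels` the input set labels.
#' @export
merge_union <- function(sets, window = 200L) {
  if (inherits(sets, "PeakSet")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "PeakSet")))
  labels <- vapply(sets, peak_label, character(1L))
  if (anyDuplicated(labels)) stop("peak set labels must be unique")
  all_pk <- do.call(rbind, lapply(sets, function(s) {
    data.frame(label = peak_label(s), chrom = s$chrom, summit = s$summit,
               start = s$start, end = s$end, name = s$name,
               stringsAsFactors = FALSE)
  }))
  ord <- order(all_pk$chrom, all_pk$summit)
  all_pk <- all_pk[ord, , drop = FALSE]
  n <- nrow(all_pk)
  new_cluster <- c(TRUE, all_pk$chrom[-1L] != all_pk$chrom[-n] |
                     all_pk$summit[-1L] - all_pk$summit[-n] > window)
  cid <- cumsum(new_cluster)
  idx <- split(seq_len(n), cid)
  up <- data.frame(
    chrom = vapply(idx, function(i) all_pk$chrom[i[1L]], character(1L)),
    start = vapply(idx, function(i) min(all_pk$start[i]), integer(1L)),
    end = vapply(idx, function(i) max(all_pk$end[i]), integer(1L)),
    summit = vapply(idx, function(i)
      as.integer(floor(median(all_pk$summit[i]))), integer(1L)),
    signature = vapply(idx, function(i)
      paste(sort(unique(all_pk$label[i])), collapse = ""), character(1L)),
    n_members = lengths(idx),
    stringsAsFactors = FALSE)
  rownames(up) <- NULL
  structure(up, class = c("UnionPeaks", "data.frame"),
            members = lapply(idx, function(i) all_pk[i, , drop = FALSE]),
            labels = labels, window = window)
}

#' @export
print.UnionPeaks <- function(x, ...) {
  cat(sprintf("UnionPeaks: %d clusters from sets {%s}\n", nrow(x),
              paste(attr(x, "labels"), collapse = ", ")))
  print(table(x$signature))
  invisible(x)
}

#' Venn decomposition of union peaks
#'
#' Counts union clusters per membership signature (each cluster counted
#' once) and, per input set, the percentage of its clusters shared with at
#' least one other set.
#'
#' @param union a `UnionPeaks` object from [merge_union()].
#' @return list with `counts` (named integer vector by signature) and
#'   `percent_shared` (named numeric vector by set label).
#' @export
venn_counts <- function(union) {
  stopifnot(inherits(union, "UnionPeaks"))
  counts <- table(union$signature)
  labels <- attr(union, "labels")
  shared <- vapply(labels, function(lab) {
    has <- grepl(lab, union$signature, fixed = TRUE)
    if (!any(has)) return(NA_real_)
    100 * sum(has & nchar(union$signature) > nchar(lab)) / sum(has)
  }, numeric(1L))
  list(counts = c(counts), percent_shared = shared)
}

#' Allocate peaks to genes
#'
#' The allocation point is the peak summit. A summit is `promoter` if it
#' lies in the strand-aware promoter window (2,000 bp upstream to 500 bp
#' downstream of the TSS, inclusive); `intragenic` if not in a promoter but
#' inside a gene body; `intergenic` if within 100 kb of the nearest TSS;
#' otherwise `unassigned`. Precedence is promoter > intragenic >
#' intergenic. Ties are broken by smallest |summit - TSS|, then
#' lexicographic gene id. The reported distance is summit minus TSS, signed
#' in the direction of transcription (positive = downstream).
#'
#' @param peaks a `PeakSet`.
#' @param genes a `GeneModels` data frame.
#' @param cfg an [analysis_config()].
#' @return data frame with class `"PeakGeneAssignment"`: `name`, `gene_id`
#'   (NA when unassigned), `category`, `distance`.
#' @export
annotate_peaks <- function(peaks, genes, cfg = analysis_config()) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(genes, "GeneModels"))
  up <- cfg$promoter_upstream; down <- cfg$promoter_downstream
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  category <- rep("unassigned", n)
  distance <- rep(0L, n)
  # strand-aware promoter windows, 0-based inclusive bounds
  prom_lo <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  prom_hi <- ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  signed_dist <- function(summit, gi)
    ifelse(genes$strand[gi] == "+", summit - genes$tss[gi],
           genes$tss[gi] - summit)
  pick_best <- function(hit_peak, hit_gene, summit) {
    # among candidate genes per peak: min |summit - tss|, then gene_id
    d <- abs(summit[hit_peak] - genes$tss[hit_gene])
    ord <- order(hit_peak, d, genes$gene_id[hit_gene])
    keep <- ord[!duplicated(hit_peak[ord])]
    list(peak = hit_peak[keep], gene = hit_gene[keep])
  }
  for (ch in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == ch)
    ig <- which(genes$chrom == ch)
    if (!length(ig)) next
    s <- peaks$summit[ip]
    pts <- IRanges::IRanges(start = s + 1L, width = 1L)
    # promoter
    hp <- IRanges::findOverlaps(
      pts, IRanges::IRanges(prom_lo[ig] + 1L, prom_hi[ig] + 1L))
    if (length(hp)) {
      best <- pick_best(S4Vectors::queryHits(hp),
                        ig[S4Vectors::subjectHits(hp)], s)
      rows <- ip[best$peak]
      gene_id[rows] <- genes$gene_id[best$gene]
      category[rows] <- "promoter"
      distance[rows] <- signed_dist(peaks$summit[rows], best$gene)
    }
    # intragenic: gene body [start, end), excluding already-assigned
    open <- which(category[ip] == "unassigned")
    if (length(open)) {
      hb <- IRanges::findOverlaps(
        IRanges::IRanges(s[open] + 1L, width = 1L),
        IRanges::IRanges(genes$start[ig] + 1L, genes$end[ig]))
      if (length(hb)) {
        best <- pick_best(S4Vectors::queryHits(hb),
                          ig[S4Vectors::subjectHits(hb)], s[open])
        rows <- ip[open[best$peak]]
        gene_id[rows] <- genes$gene_id[best$gene]
        category[rows] <- "intragenic"
        distance[rows] <- signed_dist(peaks$summit[rows], best$gene)
      }
    }
    # intergenic: nearest TSS within the cap (ties: |dist| then gene_id)
    open <- which(category[ip] == "unassigned")
    if (length(open)) {
      dmat_best <- vapply(open, function(j) {
        d <- abs(s[j] - genes$tss[ig])
        k <- which(d == min(d))
        k <- k[order(genes$gene_id[ig[k]])][1L]
        c(ig[k], d[k])
      }, numeric(2L))
      ok <- dmat_best[2L, ] <= cfg$intergenic_max_dist
      rows <- ip[open[ok]]
      gi <- dmat_best[1L, ok]
      gene_id[rows] <- genes$gene_id[gi]
      category[rows] <- "intergenic"
      distance[rows] <- signed_dist(peaks$summit[rows], gi)
    }
  }
  out <- data.frame(name = peaks$name, gene_id = gene_id,
                    category = factor(category,
                                      levels = c("promoter", "intragenic",
                                                 "intergenic", "unassigned")),
                    distance = as.integer(distance),
                    stringsAsFactors = FALSE)
  structure(out, class = c("PeakGeneAssignment", "data.frame"))
}

#' Non-promoter (distal) subset of a peak set
#'
#' Motif analyses operate on distal peaks only; this extracts the peaks
#' whose allocation category is not `promoter`.
#'
#' @param peaks the `PeakSet` that was annotated.
#' @param assignments the matching [annotate_peaks()] result.
#' @return a `PeakSet` (label suffixed `"_distal"`).
#' @export
distal_subset <- function(peaks, assignments) {
  stopifnot(inherits(peaks, "PeakSet"),
            inherits(assignments, "PeakGeneAssignment"))
  distal <- assignments$name[assignments$category != "promoter"]
  keep <- peaks[peaks$name %in% distal, , drop = FALSE]
  peak_set(keep$chrom, keep$start, keep$end, keep$summit, keep$name,
           keep$score, label = paste0(peak_label(peaks), "_distal"))
}

#' Convert union peaks to a plain PeakSet
#'
#' Representative summits/intervals of union clusters as a `PeakSet`, e.g.
#' for use as a bootstrap sampling pool or a counting frame.
#'
#' @param union a `UnionPeaks` object.
#' @param label set label.
#' @return a [peak_set()].
#' @export
union_as_peakset <- function(union, label = "union") {
  stopifnot(inherits(union, "UnionPeaks"))
  peak_set(union$chrom, union$start, union$end, union$summit,
           name = sprintf("u%06d", seq_len(nrow(union))), label = label)
}
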
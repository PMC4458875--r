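# Expressed-gene filtering, fold changes, differential calls, trinary
# pattern coding/grouping and sample correlation.

#' Filter to expressed genes
#'
#' A gene is expressed if its log2 intensity reaches
#' `cfg$expressed_min_log2` (default 6.5) in at least one sample; the bound
#' is inclusive ("equal to or greater").
#'
#' @param m an `ExpressionMatrix`.
#' @param cfg an [analysis_config()].
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(m, cfg = analysis_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- apply(m$values, 1L, max) >= cfg$expressed_min_log2
  rownames(m$values)[keep]
}

#' Define comparisons from consecutive stage transitions
#'
#' Builds the ordered comparison list "each stage vs the previous one" from
#' the sample metadata, optionally restricted to one induction arm.
#'
#' @param m an `ExpressionMatrix`.
#' @param induced restrict to samples with this induction flag (`NA`: all).
#' @return list of comparisons, each `list(label, num, den)` where
#'   `num`/`den` are sample labels (numerator = later stage).
#' @export
stage_comparisons <- function(m, induced = NA) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  smp <- m$samples
  if (!is.na(induced)) smp <- smp[smp$induced == induced, , drop = FALSE]
  stages <- m$stage_order[m$stage_order %in% smp$stage]
  if (length(stages) < 2L) stop("need at least two stages with samples")
  lapply(seq_len(length(stages) - 1L), function(i) {
    list(label = paste0(stages[i], "->", stages[i + 1L]),
         num = smp$label[smp$stage == stages[i + 1L]],
         den = smp$label[smp$stage == stages[i]])
  })
}

#' Per-gene log2 fold changes for a list of comparisons
#'
#' `log2fc = mean(numerator samples) - mean(denominator samples)` on the
#' log2 scale (the geometric-mean fold change on the linear scale).
#'
#' @param m an `ExpressionMatrix`.
#' @param comparisons list of `list(label, num, den)`; see
#'   [stage_comparisons()].
#' @param genes optional gene subset (e.g. from [filter_expressed()]).
#' @return matrix of class `"FoldChangeTable"`, genes x comparisons.
#' @export
fold_changes <- function(m, comparisons, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(comparisons) >= 1L)
  vals <- m$values
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  fc <- vapply(comparisons, function(cmp) {
    if (!length(cmp$num) || !length(cmp$den))
      stop("empty sample group in comparison '", cmp$label, "'")
    miss <- setdiff(c(cmp$num, cmp$den), colnames(vals))
    if (length(miss)) stop("unknown sample '", miss[1L], "' in comparison '",
                           cmp$label, "'")
    rowMeans(vals[, cmp$num, drop = FALSE]) -
      rowMeans(vals[, cmp$den, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) fc <- matrix(fc, nrow = 1L)
  dimnames(fc) <- list(rownames(vals),
                       vapply(comparisons, `[[`, character(1L), "label"))
  structure(fc, class = c("FoldChangeTable", class(fc)))
}

# per-(gene, comparison) trinary digit: 1 up, 0 down, 2 invariant
trinary_digits <- function(fc, pvalues = NULL, cfg = analysis_config()) {
  thr <- log2(cfg$fold_threshold)
  sig <- if (is.null(pvalues)) TRUE else {
    stopifnot(length(pvalues) == nrow(fc))
    matrix(pvalues <= cfg$p_cutoff, nrow(fc), ncol(fc))
  }
  d <- matrix(2L, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  d[fc >= thr & sig] <- 1L
  d[fc <= -thr & sig] <- 0L
  d
}

#' Call differentially expressed genes per comparison
#'
#' Up: `log2fc >= log2(fold_threshold)` ("at least two-fold", inclusive);
#' down symmetric; otherwise invariant. When per-gene p-values are
#' supplied, a call additionally requires `p <= cfg$p_cutoff`.
#'
#' @param fc a [fold_changes()] table.
#' @param pvalues optional numeric vector aligned to the rows of `fc`.
#' @param cfg an [analysis_config()].
#' @return named list per comparison: `list(up = ids, down = ids)`.
#' @export
call_differential <- function(fc, pvalues = NULL, cfg = analysis_config()) {
  d <- trinary_digits(fc, pvalues, cfg)
  out <- lapply(seq_len(ncol(d)), function(j)
    list(up = rownames(d)[d[, j] == 1L],
         down = rownames(d)[d[, j] == 0L]))
  names(out) <- colnames(d)
  out
}

#' Trinary pattern codes
#'
#' One digit per comparison, in the order supplied: `1` upregulated, `0`
#' downregulated, `2` invariant.
#'
#' @inheritParams call_differential
#' @return data frame with class `"PatternCode"`: `gene_id`, `code`.
#' @export
trinarize <- function(fc, pvalues = NULL, cfg = analysis_config()) {
  d <- trinary_digits(fc, pvalues, cfg)
  code <- apply(d, 1L, paste, collapse = "")
  structure(data.frame(gene_id = rownames(d), code = unname(code),
                       stringsAsFactors = FALSE),
            class = c("PatternCode", "data.frame"))
}

#' Group genes by exact pattern code
#'
#' The full census always reports every populated code. Retained
#' ("changing") groups are the non-all-invariant codes holding more than
#' `cfg$min_group_size` genes (strict `>` by default; set
#' `min_group_inclusive` in the config for `>=`).
#'
#' @param codes a [trinarize()] result.
#' @param cfg an [analysis_config()].
#' @param fc optional [fold_changes()] table for per-group quartile
#'   summaries.
#' @return list with class `"PatternGroups"`: `census` (named counts),
#'   `groups` (code -> gene ids), `retained` (codes), `summaries` (per
#'   retained code, quartile matrix of log2 fold changes per comparison).
#' @export
group_patterns <- function(codes, cfg = analysis_config(), fc = NULL) {
  stopifnot(inherits(codes, "PatternCode"))
  if (length(unique(nchar(codes$code))) > 1L)
    stop("pattern codes have differing lengths")
  groups <- split(codes$gene_id, codes$code)
  census <- vapply(groups, length, integer(1L))
  all2 <- strrep("2", nchar(codes$code[1L]))
  big <- if (cfg$min_group_inclusive) census >= cfg$min_group_size
         else census > cfg$min_group_size
  retained <- setdiff(names(census)[big], all2)
  summaries <- NULL
  if (!is.null(fc)) {
    summaries <- lapply(retained, function(cd) {
      sub <- fc[groups[[cd]], , drop = FALSE]
      apply(sub, 2L, quantile, probs = c(0.25, 0.5, 0.75))
    })
    names(summaries) <- retained
  }
  structure(list(census = census, groups = groups, retained = retained,
                 summaries = summaries),
            class = "PatternGroups")
}

#' @export
print.PatternGroups <- function(x, ...) {
  cat(sprintf("PatternGroups: %d populated codes over %d genes; %d retained\n",
              length(x$census), sum(x$census), length(x$retained)))
  print(sort(x$census, decreasing = TRUE))
  invisible(x)
}

#' Pearson correlation of samples with hierarchical clustering
#'
#' Correlates sample columns and clusters them agglomeratively on Euclidean
#' distance. Average linkage is the default used for expression intensities;
#' pass `linkage = "complete"` for TF binding count matrices. Leaf order is
#' made deterministic by reordering the dendrogram against the column
#' labels.
#'
#' @param values numeric matrix (rows = features, columns = samples), an
#'   `ExpressionMatrix`, or a `CountMatrix` (normalized counts are used).
#' @param linkage `hclust` method, `"average"` or `"complete"` (or any
#'   other `hclust` method).
#' @return list with class `"SampleCorrelation"`: `cor` (matrix), `hclust`,
#'   `order` (leaf labels in dendrogram order).
#' @export
sample_correlation <- function(values, linkage = "average") {
  if (inherits(values, "ExpressionMatrix")) values <- values$values
  if (inherits(values, "CountMatrix")) values <- values$normalized
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  v <- apply(values, 2L, sd)
  if (any(v == 0))
    stop("zero-variance sample: ", colnames(values)[v == 0][1L])
  cm <- cor(values, method = "pearson")
  hc <- hclust(dist(t(values), method = "euclidean"), method = linkage)
  dnd <- stats::reorder(as.dendrogram(hc), match(hc$labels, sort(hc$labels)),
                        agglo.FUN = mean)
  structure(list(cor = cm, hclust = hc,
                 order = labels(dnd)),
            class = "SampleCorrelation")
}

#' @export
print.SampleCorrelation <- function(x, ...) {
  cat("SampleCorrelation over", ncol(x$cor), "samples; leaf order:\n  ",
      paste(x$order, collapse = ", "), "\n")
  invisible(x)
}
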
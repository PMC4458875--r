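#' Construct a peak set
#'
#' A `PeakSet` is a data frame of ChIP-seq peaks, each with an explicit
#' summit (the base of maximal enrichment). The summit — not the interval —
#' is the atom of every overlap and profile computation in this package.
#' Coordinates are 0-based half-open; the summit is an absolute 0-based
#' position with `start <= summit < end`. Peaks are stored sorted by
#' (chrom, summit).
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open interval bounds.
#' @param summit absolute 0-based summit positions; if `NULL`, interval
#'   midpoints (floor) are used.
#' @param name peak identifiers (generated if missing).
#' @param score optional numeric score.
#' @param label single string naming the set (e.g. `"HE"`).
#' @return data frame with class `"PeakSet"` and attribute `label`.
#' @export
peak_set <- function(chrom, start, end, summit = NULL, name = NULL,
                     score = NA_real_, label = "peaks") {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.null(summit)) summit <- (start + end) %/% 2L
  summit <- as.integer(summit)
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("%s_%d", label, seq_len(n))
  stopifnot(length(start) == n, length(end) == n, length(summit) == n,
            length(name) == n)
  bad <- which(!(start >= 0L & start < end))
  if (length(bad)) stop("invalid interval at row ", bad[1L],
                        ": need 0 <= start < end")
  bad <- which(!(summit >= start & summit < end))
  if (length(bad)) stop("summit outside interval at row ", bad[1L])
  if (any(!nzchar(chrom))) stop("empty chrom name")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   summit = summit, name = as.character(name),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$summit), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"), label = label)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peaks on %d chromosome(s)\n",
              peak_label(x), nrow(x), length(unique(x$chrom))))
  print.data.frame(head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Label of a peak or tag set
#' @param x a `PeakSet` or `TagSet`.
#' @return character label.
#' @export
peak_label <- function(x) attr(x, "label") %||% "peaks"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct gene models
#'
#' Strand-aware gene bodies with a derived transcription start site:
#' `tss = start` on the plus strand, `end - 1` on the minus strand
#' (0-based). Gene ids must be unique.
#'
#' @param chrom,start,end 0-based half-open gene bodies.
#' @param gene_id unique identifiers.
#' @param strand `"+"` or `"-"` (required; allocation rules are strand-aware).
#' @return data frame with class `"GeneModels"` and a `tss` column.
#' @export
gene_models <- function(chrom, start, end, gene_id, strand) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  gene_id <- as.character(gene_id)
  strand <- as.character(strand)
  stopifnot(length(start) == length(chrom), length(end) == length(chrom),
            length(gene_id) == length(chrom), length(strand) == length(chrom))
  if (any(!(start >= 0L & start < end))) stop("invalid gene interval")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) stop("duplicate gene_id: ", dup[1L])
  tss <- ifelse(strand == "+", start, end - 1L)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   gene_id = gene_id, strand = strand,
                   tss = as.integer(tss), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$tss), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("GeneModels", "data.frame"))
}

#' Construct a tag set
#'
#' Aligned-fragment positions reduced to a single base each (the fragment
#' midpoint), sorted by (chrom, pos). `total_count` is the number of tags
#' and is the denominator of all per-million normalizations.
#'
#' @param chrom,pos tag chromosomes and 0-based positions.
#' @param label sample label.
#' @return data frame with class `"TagSet"`, attributes `label`, `total_count`.
#' @export
tag_set <- function(chrom, pos, label = "tags") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 0L)) stop("negative tag position")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("TagSet", "data.frame"),
            label = label, total_count = nrow(df))
}

#' Total tag count of a TagSet
#' @param x a `TagSet`.
#' @export
tag_total <- function(x) attr(x, "total_count") %||% nrow(x)

#' @export
print.TagSet <- function(x, ...) {
  cat(sprintf("TagSet '%s': %d tags\n", peak_label(x), tag_total(x)))
  invisible(x)
}

#' Construct an expression matrix
#'
#' Log2 intensities for genes (rows) across ordered stage/condition samples
#' (columns), with aligned sample metadata. Missing values are rejected:
#' the upstream array preprocessing this package consumes produces complete
#' matrices, so an NA here is a data defect, not something to impute.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample labels.
#' @param samples data frame with columns `label`, `stage`, `induced`,
#'   `replicate`; one row per column of `values`, matched by `label`.
#' @param stage_order optional character vector giving the developmental
#'   ordering of stages; defaults to order of first appearance.
#' @return list with class `"ExpressionMatrix"`: `values`, `samples`,
#'   `stage_order`.
#' @export
expression_matrix <- function(values, samples, stage_order = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(samples))
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample labels as colnames")
  if (anyNA(values)) stop("expression matrix contains missing values")
  need <- c("label", "stage", "induced", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$label)) stop("duplicate sample labels in metadata")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  absent <- setdiff(colnames(values), samples$label)
  if (length(absent)) stop("sample '", absent[1L], "' has no metadata")
  samples <- samples[match(colnames(values), samples$label), , drop = FALSE]
  rownames(samples) <- NULL
  samples$induced <- as.logical(samples$induced)
  if (is.null(stage_order)) stage_order <- unique(as.character(samples$stage))
  if (!all(samples$stage %in% stage_order))
    stop("sample stage outside the configured stage order")
  structure(list(values = values, samples = samples,
                 stage_order = stage_order),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples; stages: %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$stage_order, collapse = " -> ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)
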
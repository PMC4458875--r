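# Readers/writers for every external format the pipeline touches.
# Internal convention everywhere: 0-based, half-open; GTF converted on read.

read_tsv_table <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, sep = "\t", header = FALSE, comment.char = "#",
             stringsAsFactors = FALSE, quote = "", ...)
}

#' Read ChIP-seq peaks (ENCODE narrowPeak or BED6+summit)
#'
#' Accepts 10-column ENCODE narrowPeak (summit = start + column-10 offset)
#' or a 7-column BED6-plus-summit-offset dialect. An offset of -1 means "no
#' summit called" and falls back to the interval midpoint (floor).
#'
#' @param path file path.
#' @param label set label (defaults to the file stem).
#' @return a [peak_set()].
#' @export
read_narrowpeak <- function(path,
                            label = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_tsv_table(path)
  if (!ncol(df) %in% c(7L, 10L))
    stop("expected 7 or 10 columns (narrowPeak/BED6+summit) in ", path,
         ", got ", ncol(df))
  off_col <- ncol(df)
  for (col in c(2L, 3L, off_col)) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) stop("malformed line ", bad[1L], " in ", path,
                          ": column ", col, " is not an integer")
    df[[col]] <- v
  }
  start <- df[[2L]]; end <- df[[3L]]; offset <- df[[off_col]]
  if (any(start < 0L | start >= end))
    stop("malformed line ", which(start < 0L | start >= end)[1L],
         " in ", path, ": invalid interval")
  summit <- ifelse(offset == -1L, (start + end) %/% 2L, start + offset)
  bad <- which(summit < start | summit >= end)
  if (length(bad)) stop("summit outside interval at line ", bad[1L],
                        " in ", path)
  score <- if (ncol(df) == 10L) suppressWarnings(as.numeric(df[[7L]]))
           else suppressWarnings(as.numeric(df[[5L]]))
  peak_set(df[[1L]], start, end, summit = summit, name = as.character(df[[4L]]),
           score = score, label = label)
}

#' Write a PeakSet as ENCODE narrowPeak
#' @param x a `PeakSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  stopifnot(inherits(x, "PeakSet"))
  out <- data.frame(x$chrom, x$start, x$end, x$name, 0L, ".",
                    ifelse(is.na(x$score), 0, x$score), -1, -1,
                    x$summit - x$start)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GTF-lite
#'
#' BED6: 0-based half-open, `name` = gene id, strand required.
#' GTF: only `gene` features are used; 1-based inclusive coordinates are
#' converted to 0-based half-open; the gene id is taken from the
#' `gene_id "..."` attribute.
#'
#' @param path file path; format chosen by extension (`.gtf`/`.gff` vs BED)
#'   unless `format` is given.
#' @param format `"bed"`, `"gtf"` or `NULL` (auto).
#' @return a [gene_models()] data frame.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  df <- read_tsv_table(path)
  if (format == "bed") {
    if (ncol(df) < 6L) stop("BED6 required (strand is mandatory) in ", path)
    if (!all(df[[6L]] %in% c("+", "-")))
      stop("missing or invalid strand at line ",
           which(!df[[6L]] %in% c("+", "-"))[1L], " in ", path)
    gene_models(df[[1L]], df[[2L]], df[[3L]], df[[4L]], df[[6L]])
  } else {
    df <- df[df[[3L]] == "gene", , drop = FALSE]
    if (!nrow(df)) stop("no 'gene' features in ", path)
    if (!all(df[[7L]] %in% c("+", "-")))
      stop("missing strand on a gene feature in ", path)
    ids <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df[[9L]])
    gene_models(df[[1L]], as.integer(df[[4L]]) - 1L, as.integer(df[[5L]]),
                ids, df[[7L]])
  }
}

#' Write gene models as BED6
#' @param x a `GeneModels` data frame.
#' @param path output file.
#' @export
write_genes_bed <- function(x, path) {
  stopifnot(inherits(x, "GeneModels"))
  out <- data.frame(x$chrom, x$start, x$end, x$gene_id, 0L, x$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned tags from BED
#'
#' Each BED interval is an aligned fragment; it is reduced to its midpoint
#' (floor), the package's tag-position convention for density computations.
#'
#' @param path BED3+ file.
#' @param label sample label.
#' @return a [tag_set()].
#' @export
read_tags_bed <- function(path,
                          label = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_tsv_table(path)
  if (ncol(df) < 3L) stop("BED3 required in ", path)
  start <- as.integer(df[[2L]]); end <- as.integer(df[[3L]])
  if (anyNA(start) || anyNA(end)) stop("malformed BED line in ", path)
  tag_set(df[[1L]], (start + end) %/% 2L, label = label)
}

#' Write tags as single-base BED intervals
#' @param x a `TagSet`.
#' @param path output file.
#' @export
write_tags_bed <- function(x, path) {
  stopifnot(inherits(x, "TagSet"))
  out <- data.frame(x$chrom, x$pos, x$pos + 1L)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' @param path_values TSV: first column gene id, remaining columns log2
#'   intensities with sample labels in the header row.
#' @param path_meta TSV with header `label`, `stage`, `induced`, `replicate`.
#' @param stage_order optional explicit stage ordering.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path_values, path_meta, stage_order = NULL) {
  vals <- read.table(path_values, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     quote = "", comment.char = "#")
  meta <- read.table(path_meta, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     quote = "", comment.char = "#")
  ids <- as.character(vals[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene row: ", ids[duplicated(ids)][1L])
  m <- as.matrix(vals[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) stop("non-numeric value at gene '", ids[bad[1L, 1L]],
                        "', sample '", colnames(m)[bad[1L, 2L]], "'")
    m <- array(as.numeric(m), dim(m), dimnames = dimnames(m))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing value at gene '", ids[bad[1L, 1L]], "', sample '",
         colnames(m)[bad[1L, 2L]], "' (no imputation is performed)")
  }
  rownames(m) <- ids
  expression_matrix(m, meta, stage_order = stage_order)
}

#' Write an expression matrix and its metadata
#' @param x an `ExpressionMatrix`.
#' @param path_values,path_meta output TSV paths.
#' @export
write_expression <- function(x, path_values, path_meta) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE)
  write.table(out, path_values, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, path_meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path_values)
}

#' Read position frequency matrices in JASPAR PFM text format
#'
#' Accepts both the bracketed (`A [ 3 5 ... ]`) and plain four-row count
#' layouts; records start at `>` header lines.
#'
#' @param path PFM file.
#' @param background,pseudocount passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' record headers in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(header, "\\s+")[[1L]][1L]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L)
      stop("motif '", id, "' must have 4 count rows, got ", length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
      ln <- gsub("[\\[\\]]", "", ln, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
      if (anyNA(v)) stop("non-numeric count in motif '", id, "'")
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("rows of unequal length in motif '", id, "'")
    counts <- do.call(rbind, rows)
    out[[id]] <- pwm(counts, motif_id = id, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in JASPAR PFM text format
#' @param pwms list of `PWM` objects.
#' @param path output file.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id), con)
    for (i in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[i],
                         paste(format(p$counts[i, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#' @param genome a `DNAStringSet`.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome sizes of a genome
#' @param genome a `DNAStringSet` (or named integer vector, returned as-is).
#' @return named integer vector of lengths.
#' @export
chrom_sizes <- function(genome) {
  if (is.numeric(genome)) {
    stopifnot(!is.null(names(genome)))
    return(stats::setNames(as.integer(genome), names(genome)))
  }
  stats::setNames(Biostrings::width(genome), names(genome))
}

# TSV writer with a provenance comment line (config hash + seed)
write_output_tsv <- function(df, path, cfg = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# regstage %s config=%s seed=%s",
                     as.character(packageVersion("regstage")),
                     if (is.null(cfg)) "NA" else config_hash(cfg),
                     if (is.null(seed)) "NA" else seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
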
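# Join bound-gene sets with expression responses: direct-target fractions
# and two-digit response classes.

RESPONSE_LABELS <- c("00" = "still_downregulated",
                     "01" = "reversed",
                     "02" = "not_downregulated",
                     "10" = "reversed",
                     "11" = "still_upregulated",
                     "12" = "not_upregulated",
                     "20" = "downregulated",
                     "21" = "upregulated",
                     "22" = "unresponsive")

#' Genes bound by at least one peak
#'
#' Unique gene ids of all assignments whose category is not `unassigned`
#' (set semantics: a gene with several peaks counts once).
#'
#' @param assignments an [annotate_peaks()] result.
#' @return character vector of gene ids.
#' @export
bound_gene_set <- function(assignments) {
  stopifnot(inherits(assignments, "PeakGeneAssignment"))
  sort(unique(assignments$gene_id[assignments$category != "unassigned"]))
}

#' Split differentially expressed genes into direct targets and the rest
#'
#' A direct target is a differentially expressed gene that also carries a
#' peak under the allocation rules. Reports, per direction, the bound and
#' unbound counts and the bound fraction, plus the reverse view: the
#' fraction of bound genes that respond at all.
#'
#' @param degs list with `up` and `down` character vectors of gene ids.
#' @param bound character vector from [bound_gene_set()].
#' @return list with per-direction `counts` (bound, unbound, fraction_bound)
#'   and `fraction_bound_responsive`.
#' @export
direct_target_split <- function(degs, bound) {
  stopifnot(is.list(degs), all(c("up", "down") %in% names(degs)))
  bound <- unique(bound)
  per_dir <- lapply(degs[c("up", "down")], function(g) {
    g <- unique(g)
    nb <- sum(g %in% bound)
    list(bound = nb, unbound = length(g) - nb,
         fraction_bound = if (length(g)) nb / length(g) else NA_real_)
  })
  responsive <- unique(c(degs$up, degs$down))
  list(up = per_dir$up, down = per_dir$down,
       fraction_bound_responsive =
         if (length(bound)) sum(bound %in% responsive) / length(bound)
         else NA_real_)
}

#' Classify bound genes by their two-digit expression response
#'
#' The first digit is a gene's trajectory over a transition without
#' induction, the second its trajectory with induction; the concatenated
#' code maps to a fixed label table (e.g. `12` = was upregulated, no longer
#' upregulated under induction = "not_upregulated"). By default the report
#' is restricted to bound genes and the unresponsive code `22` is excluded,
#' leaving at most eight populated classes; the full nine-code census is
#' always returned alongside.
#'
#' @param codes_uninduced,codes_induced [trinarize()] results (single-digit
#'   codes for the same transition) covering the same genes.
#' @param bound character vector of bound gene ids ([bound_gene_set()]);
#'   ignored when `all_genes = TRUE`.
#' @param all_genes classify every gene instead of bound genes only.
#' @param exclude_unresponsive drop code `22` from the default report.
#' @return list with class `"ResponseClasses"`: `classes` (data frame
#'   `gene_id`, `code`, `label`), `counts` (default report), `census`
#'   (all nine codes).
#' @export
classify_response <- function(codes_uninduced, codes_induced, bound = NULL,
                              all_genes = FALSE,
                              exclude_unresponsive = TRUE) {
  stopifnot(inherits(codes_uninduced, "PatternCode"),
            inherits(codes_induced, "PatternCode"))
  if (any(nchar(codes_uninduced$code) != 1L) ||
      any(nchar(codes_induced$code) != 1L))
    stop("response classification needs single-digit codes (one transition)")
  only <- c(setdiff(codes_uninduced$gene_id, codes_induced$gene_id),
            setdiff(codes_induced$gene_id, codes_uninduced$gene_id))
  if (length(only))
    stop("gene '", only[1L], "' present in one code table only")
  genes <- codes_uninduced$gene_id
  if (!all_genes) {
    if (is.null(bound)) stop("supply `bound` or set all_genes = TRUE")
    genes <- intersect(genes, bound)
  }
  code <- paste0(
    codes_uninduced$code[match(genes, codes_uninduced$gene_id)],
    codes_induced$code[match(genes, codes_induced$gene_id)])
  classes <- data.frame(gene_id = genes, code = code,
                        label = unname(RESPONSE_LABELS[code]),
                        stringsAsFactors = FALSE)
  census <- table(factor(classes$code, levels = names(RESPONSE_LABELS)))
  counts <- census
  if (exclude_unresponsive) counts <- counts[names(counts) != "22"]
  structure(list(classes = classes, counts = c(counts), census = c(census),
                 labels = RESPONSE_LABELS),
            class = "ResponseClasses")
}

#' @export
print.ResponseClasses <- function(x, ...) {
  cat("ResponseClasses over", nrow(x$classes), "genes\n")
  for (cd in names(x$counts))
    cat(sprintf("  %s (%s): %d\n", cd, RESPONSE_LABELS[cd], x$counts[cd]))
  invisible(x)
}
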
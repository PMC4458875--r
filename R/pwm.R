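#' Construct a position weight matrix
#'
#' Counts are converted to per-column probabilities with a background-
#' weighted pseudocount, `p[b,j] = (n[b,j] + pc * bg[b]) / (N[j] + pc)`,
#' and scored as log2 odds against the background. With uniform background
#' and all-equal counts every position scores 0 bits — the scanner's
#' symmetry anchor.
#'
#' @param counts 4 x L non-negative numeric matrix, rows A, C, G, T.
#' @param motif_id motif identifier.
#' @param background length-4 probabilities (A, C, G, T), summing to 1.
#' @param pseudocount positive pseudocount mass per column.
#' @return list with class `"PWM"`: `motif_id`, `counts`, `probs`,
#'   `logodds` (bits), `background`, `pseudocount`, `length`, `consensus`,
#'   `max_score`.
#' @export
pwm <- function(counts, motif_id = "motif",
                background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4L) stop("PWM length must be >= 4")
  if (any(counts < 0)) stop("negative PWM count")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 probabilities summing to 1")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  rownames(counts) <- DNA_BASES
  denom <- colSums(counts) + pseudocount
  probs <- sweep(counts + pseudocount * matrix(background, 4L, ncol(counts)),
                 2L, denom, "/")
  logodds <- log2(probs / background)
  consensus <- paste(DNA_BASES[apply(probs, 2L, which.max)], collapse = "")
  structure(list(motif_id = as.character(motif_id), counts = counts,
                 probs = probs, logodds = logodds,
                 background = as.numeric(background),
                 pseudocount = as.numeric(pseudocount),
                 length = ncol(counts), consensus = consensus,
                 max_score = sum(apply(logodds, 2L, max))),
            class = "PWM")
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': length %d, consensus %s, max score %.2f bits\n",
              x$motif_id, x$length, x$consensus, x$max_score))
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' Convenience constructor for synthetic motifs: the consensus base gets
#' `strength` counts per column, every other base 1.
#'
#' @param consensus DNA string over ACGT.
#' @param motif_id identifier.
#' @param strength count mass on the consensus base.
#' @return a [pwm()].
#' @export
pwm_from_consensus <- function(consensus, motif_id = consensus,
                               strength = 97) {
  bases <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(bases %in% DNA_BASES)) stop("consensus must be over ACGT")
  counts <- matrix(1, nrow = 4L, ncol = length(bases),
                   dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(bases, DNA_BASES), seq_along(bases))] <- strength
  pwm(counts, motif_id = motif_id)
}

# reverse-complement log-odds matrix (scan minus strand on forward sequence)
pwm_revcomp_logodds <- function(p) {
  lo <- p$logodds
  lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
}

# center position of a motif instance starting at 0-based position `start`
motif_center <- function(start, len) start + (len - 1L) %/% 2L
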
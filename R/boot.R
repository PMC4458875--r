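# Bootstrap significance machinery for multi-set peak overlaps and
# gene-list overlaps.
#
# The null model mirrors the published scheme: a pool of candidate sites
# (by default the union clusters of the actual sets), null peak sets of
# fixed width drawn from the pool with populations matching the actual
# sets, and a rotate-one/randomize-two design — iteration i keeps actual
# set (i mod 3) and replaces the other two — with all iterations pooled
# into a single empirical null whose mean and sd give the z score.

#' Convert a z score to a one-sided (upper-tail) normal P value
#'
#' Uses R's erfc-backed normal tail plus the log-space branch, so the
#' linear-scale value underflows gracefully while `log10_p` stays exact to
#' well past z = 40 (p ~ 1e-350).
#'
#' @param z finite numeric vector of z scores.
#' @return list with `p_one_sided` and `log10_p` (both vectorized).
#' @export
#' @examples
#' z_to_p(0)$p_one_sided    # 0.5
#' z_to_p(23.36)$log10_p    # about -120.26
z_to_p <- function(z) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  list(p_one_sided = pnorm(z, lower.tail = FALSE),
       log10_p = pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10))
}

#' Draw a random fixed-width peak set from a pool
#'
#' Draws `k` pool entries (without replacement by default) and emits each
#' as a `width`-bp peak centered on the pool peak's representative summit.
#' Uses the current RNG state; seed with `set.seed()` or let the bootstrap
#' drivers seed for you.
#'
#' @param pool a `UnionPeaks` or `PeakSet` supplying candidate summits.
#' @param k number of peaks to draw.
#' @param width emitted peak width, bp.
#' @param replace draw with replacement?
#' @param label label of the emitted set.
#' @return a [peak_set()].
#' @export
sample_random_peakset <- function(pool, k, width = 400L, replace = FALSE,
                                  label = "random") {
  stopifnot(is.data.frame(pool), !is.null(pool$summit))
  n <- nrow(pool)
  if (!replace && k > n)
    stop("k = ", k, " exceeds pool size ", n, " without replacement")
  idx <- sample.int(n, k, replace = replace)
  ctr <- pool$summit[idx]
  half <- as.integer(width) %/% 2L
  peak_set(pool$chrom[idx], ctr - half, ctr - half + as.integer(width),
           summit = ctr, name = sprintf("%s_%d", label, seq_len(k)),
           label = label)
}

new_bootstrap_result <- function(observed, stats, rotation, n_iter, seed,
                                 what) {
  null_mean <- mean(stats)
  null_sd <- sd(stats)
  if (!is.finite(null_sd) || null_sd == 0) {
    warning("degenerate null (sd = 0) in ", what,
            "; z and p are undefined")
    z <- NA_real_; p <- NA_real_; lp <- NA_real_
  } else {
    z <- (observed - null_mean) / null_sd
    zp <- z_to_p(z)
    p <- zp$p_one_sided; lp <- zp$log10_p
  }
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p_one_sided = p, log10_p = lp,
                 n_iterations = n_iter, seed = seed,
                 null_stats = stats, rotation = rotation, what = what),
            class = "BootstrapResult")
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat(sprintf("Bootstrap %s: observed = %d, null = %.2f +/- %.2f (n = %d)\n",
              x$what, x$observed, x$null_mean, x$null_sd, x$n_iterations))
  if (is.na(x$z)) cat("  z undefined (degenerate null)\n")
  else cat(sprintf("  z = %.2f, one-sided P = %.3g (log10 P = %.2f)\n",
                   x$z, x$p_one_sided, x$log10_p))
  invisible(x)
}

# shared: map chroms of pool + sets to common integer codes
chrom_codes <- function(...) {
  lv <- unique(unlist(lapply(list(...), function(d) unique(d$chrom))))
  lapply(list(...), function(d) match(d$chrom, lv) - 1L)
}

#' Bootstrap significance of a multi-set peak overlap
#'
#' The observed statistic is the number of union clusters (single-linkage
#' summit clustering at `cfg$summit_window`) containing every input set.
#' Null iterations rotate through the sets: one actual set is kept, the
#' others are replaced by random fixed-width peak sets of matching
#' population drawn from the pool; all iterations form one pooled empirical
#' null. The identical statistic function is applied to observed and null
#' configurations.
#'
#' @param sets list of (typically 3) `PeakSet`s.
#' @param cfg an [analysis_config()]; uses `summit_window`,
#'   `random_peak_width`, `n_bootstrap`, `sample_with_replacement`,
#'   `rng_seed`.
#' @param pool sampling pool: a `UnionPeaks`/`PeakSet`, or `NULL` to use
#'   the union clusters of `sets` (the published default).
#' @return a `BootstrapResult`.
#' @export
bootstrap_peak_overlap <- function(sets, cfg = analysis_config(),
                                   pool = NULL) {
  stopifnot(length(sets) >= 2L,
            all(vapply(sets, inherits, logical(1L), "PeakSet")),
            all(vapply(sets, nrow, integer(1L)) > 0L))
  if (is.null(pool)) pool <- merge_union(sets, cfg$summit_window)
  codes <- do.call(chrom_codes, c(list(pool), sets))
  pool_code <- codes[[1L]]
  set_codes <- codes[-1L]
  observed <- cluster_full_count(
    unlist(set_codes), unlist(lapply(sets, `[[`, "summit")),
    rep(seq_along(sets) - 1L, vapply(sets, nrow, integer(1L))),
    length(sets), cfg$summit_window)
  nulls <- withr::with_seed(
    derive_seed(cfg$rng_seed, "bootstrap_peak_overlap"),
    boot_overlap_null(pool_code, pool$summit,
                      set_codes, lapply(sets, `[[`, "summit"),
                      cfg$summit_window, cfg$n_bootstrap,
                      cfg$sample_with_replacement))
  new_bootstrap_result(observed, nulls$stats, nulls$rotation,
                       cfg$n_bootstrap, cfg$rng_seed, "peak overlap")
}

#' Bootstrap significance of a multi-set gene overlap
#'
#' Observed statistic: size of the intersection of all gene sets. The null
#' keeps one set per rotation and replaces the others by uniform draws of
#' matching size from the universe (without replacement by default).
#'
#' @param gene_sets list of character vectors; each must be contained in
#'   `universe`.
#' @param universe character vector of candidate gene ids.
#' @param cfg an [analysis_config()].
#' @return a `BootstrapResult`.
#' @export
bootstrap_gene_overlap <- function(gene_sets, universe,
                                   cfg = analysis_config()) {
  stopifnot(length(gene_sets) >= 2L)
  universe <- unique(as.character(universe))
  N <- length(universe)
  member <- lapply(gene_sets, function(g) {
    g <- unique(as.character(g))
    if (!all(g %in% universe)) stop("gene set not contained in universe")
    m <- logical(N); m[match(g, universe)] <- TRUE; m
  })
  sizes <- vapply(member, sum, integer(1L))
  observed <- sum(Reduce(`&`, member))
  k <- length(member)
  stats <- integer(cfg$n_bootstrap)
  rotation <- integer(cfg$n_bootstrap)
  withr::with_seed(derive_seed(cfg$rng_seed, "bootstrap_gene_overlap"), {
    acc <- integer(N)
    for (it in seq_len(cfg$n_bootstrap)) {
      keep <- (it - 1L) %% k
      acc[] <- 0L
      acc[member[[keep + 1L]]] <- 1L
      for (s in seq_len(k)) {
        if (s == keep + 1L) next
        idx <- sample.int(N, sizes[s],
                          replace = cfg$sample_with_replacement)
        acc[idx] <- acc[idx] + 1L
      }
      stats[it] <- sum(acc == k)
      rotation[it] <- keep
    }
  })
  new_bootstrap_result(observed, stats, rotation, cfg$n_bootstrap,
                       cfg$rng_seed, "gene overlap")
}
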
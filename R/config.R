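#' Analysis configuration
#'
#' Collects every numeric parameter of the pipeline in one validated object.
#' Defaults follow the published protocol the package re-implements:
#' peak overlap requires summits within +/-200 bp; bootstrap null peak sets
#' are 400 bp wide and resampled 50,000 times; motif pairs are counted at a
#' center-to-center distance of <= 20 bp; genes are expressed at log2
#' intensity >= 6.5 in at least one sample; differential calls require at
#' least a two-fold change (and, when p-values are supplied, p <= 0.001);
#' pattern groups are retained when they hold more than 30 genes; composite
#' profiles use 50-bp bins over +/-5000 bp; promoters span 2,000 bp upstream
#' to 500 bp downstream of the TSS; intergenic allocation reaches at most
#' 100 kb.
#'
#' @param summit_window bp; two summits overlap iff |delta| <= this (inclusive).
#' @param random_peak_width bp; width of bootstrap null peaks.
#' @param n_bootstrap number of bootstrap iterations.
#' @param pair_distance bp; max center-to-center distance for a motif pair.
#' @param fold_threshold linear fold-change threshold (> 1) for up/down calls.
#' @param expressed_min_log2 log2 intensity floor for the expressed-gene filter.
#' @param p_cutoff p-value cutoff applied when p-values are provided.
#' @param min_group_size pattern groups must hold more than this many genes
#'   (strict by default, see `min_group_inclusive`).
#' @param min_group_inclusive if `TRUE`, retain groups with count >= min_group_size.
#' @param profile_flank bp flank around summits for composite profiles.
#' @param profile_bin bp bin width for composite profiles.
#' @param intergenic_max_dist bp; max summit-to-TSS distance for intergenic
#'   allocation (inclusive).
#' @param promoter_upstream bp upstream of the TSS included in the promoter.
#' @param promoter_downstream bp downstream of the TSS included in the promoter.
#' @param scan_threshold_frac PWM hit threshold as a fraction of the motif's
#'   maximum attainable log-odds score.
#' @param sample_with_replacement if `TRUE`, bootstrap peak/gene draws are
#'   taken with replacement; default is without replacement (subset sampling).
#' @param rng_seed integer master seed for all stochastic steps.
#' @return A list with class `"regstage_config"`.
#' @export
#' @examples
#' cfg <- analysis_config(n_bootstrap = 2000)
#' cfg$summit_window
analysis_config <- function(summit_window = 200L,
                            random_peak_width = 400L,
                            n_bootstrap = 50000L,
                            pair_distance = 20L,
                            fold_threshold = 2.0,
                            expressed_min_log2 = 6.5,
                            p_cutoff = 0.001,
                            min_group_size = 30L,
                            min_group_inclusive = FALSE,
                            profile_flank = 5000L,
                            profile_bin = 50L,
                            intergenic_max_dist = 100000L,
                            promoter_upstream = 2000L,
                            promoter_downstream = 500L,
                            scan_threshold_frac = 0.8,
                            sample_with_replacement = FALSE,
                            rng_seed = 1L) {
  cfg <- list(
    summit_window = as.integer(summit_window),
    random_peak_width = as.integer(random_peak_width),
    n_bootstrap = as.integer(n_bootstrap),
    pair_distance = as.integer(pair_distance),
    fold_threshold = as.numeric(fold_threshold),
    expressed_min_log2 = as.numeric(expressed_min_log2),
    p_cutoff = as.numeric(p_cutoff),
    min_group_size = as.integer(min_group_size),
    min_group_inclusive = isTRUE(min_group_inclusive),
    profile_flank = as.integer(profile_flank),
    profile_bin = as.integer(profile_bin),
    intergenic_max_dist = as.integer(intergenic_max_dist),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    scan_threshold_frac = as.numeric(scan_threshold_frac),
    sample_with_replacement = isTRUE(sample_with_replacement),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$summit_window > 0L, cfg$random_peak_width > 0L,
    cfg$n_bootstrap > 0L, cfg$pair_distance > 0L,
    cfg$fold_threshold > 1, cfg$profile_flank > 0L, cfg$profile_bin > 0L,
    cfg$profile_flank %% cfg$profile_bin == 0L,
    cfg$intergenic_max_dist > 0L,
    cfg$promoter_upstream > 0L, cfg$promoter_downstream > 0L,
    cfg$scan_threshold_frac > 0, cfg$scan_threshold_frac <= 1
  )
  class(cfg) <- "regstage_config"
  cfg
}

#' @export
print.regstage_config <- function(x, ...) {
  cat("regstage analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Derive a child RNG seed from a master seed and a stream key
#'
#' Each stochastic operation draws from its own RNG stream derived from the
#' master seed and the operation name, so generators never couple through
#' shared draws. The derivation is a 31-bit polynomial string hash folded
#' with the master seed; it is stable across platforms.
#'
#' @param seed integer master seed.
#' @param key character stream name (e.g. `"sim_genome"`).
#' @return A positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.character(key), length(key) == 1L, nchar(key) > 0L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(((h + abs(as.numeric(seed))) %% m) + 1)
}

# hash of a config (or any list) for output provenance comments
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", derive_seed(0L, txt))
}
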
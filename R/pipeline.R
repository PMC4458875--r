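# End-to-end orchestration: synthetic input bundle -> every analysis stage
# -> TSV outputs plus a reproducibility manifest.

#' Default simulation settings for the end-to-end pipeline
#'
#' Small enough to run in seconds, large enough that every stage has
#' signal: three peak sets with a planted Venn structure, strand-aware
#' genes, summit pileups, two expression arms (+/- induction) with planted
#' trinary codes, and one planted motif pair.
#'
#' @param n_genes number of genes (and expression rows).
#' @param membership_spec planted Venn spec for [sim_peak_sets()].
#' @return list of simulation parameters for [run_pipeline()].
#' @export
pipeline_sim_defaults <- function(n_genes = 150L,
                                  membership_spec = c(ABC = 50L, AB = 20L,
                                                      AC = 15L, BC = 10L,
                                                      A = 60L, B = 50L,
                                                      C = 40L)) {
  list(n_chroms = 2L, chrom_length = 500000L, n_genes = n_genes,
       gene_length = 3000L, gene_gap = 1500L,
       membership_spec = membership_spec,
       stages = c("HE", "HE2", "progenitor"),
       tags_per_peak = 40L, background_tags = 2000L, pileup_sd = 50,
       noise_sd = 0.2, n_motif_pair_peaks = 30L, motif_spacing = 15L)
}

#' Run the full pipeline on a simulated input bundle
#'
#' Generates every input type with planted truth, writes the bundle under
#' `out_dir/inputs`, reads it back through the package's own parsers, then
#' runs: union merge and Venn decomposition; peak- and gene-overlap
#' bootstraps; peak-to-gene allocation; expressed-gene filtering, fold
#' changes, trinary coding and pattern grouping; response classification of
#' bound genes; motif-pair co-localization on distal peaks; composite
#' profiles and ChIP-sample correlation. Every table is written as TSV with
#' a provenance header; a JSON manifest lists config, seeds, input digests
#' and outputs.
#'
#' @param out_dir output directory (created).
#' @param cfg an [analysis_config()]; `cfg$rng_seed` drives every stage.
#' @param sim simulation settings, see [pipeline_sim_defaults()].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(out_dir, cfg = analysis_config(),
                         sim = pipeline_sim_defaults()) {
  seed <- cfg$rng_seed
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  inp <- function(...) file.path(out_dir, "inputs", ...)
  outp <- function(...) file.path(out_dir, ...)
  outputs <- character(0L)
  emit <- function(df, name) {
    path <- outp(name)
    write_output_tsv(df, path, cfg, seed)
    outputs <<- c(outputs, path)
    path
  }

  ## --- simulate + write the input bundle ------------------------------
  genome <- sim_genome(sim$n_chroms, sim$chrom_length, seed)
  sizes <- chrom_sizes(genome)
  ps <- sim_peak_sets(sim$membership_spec, sizes, summit_jitter_sd = 25,
                      summit_window = cfg$summit_window, seed = seed)
  genes <- sim_genes(sim$n_genes, sizes, gene_length = sim$gene_length,
                     min_gap = sim$gene_gap, seed = seed)
  tags <- lapply(names(ps$sets), function(lab)
    sim_tags(ps$sets[[lab]], sizes, sim$tags_per_peak, sim$background_tags,
             sim$pileup_sd, label = lab, seed = seed)$tags)
  names(tags) <- names(ps$sets)
  expr_un <- sim_expression(sim$n_genes, sim$stages, noise_sd = sim$noise_sd,
                            frac_unexpressed = 0.1, induced = FALSE,
                            seed = seed)
  expr_in <- sim_expression(sim$n_genes, sim$stages, noise_sd = sim$noise_sd,
                            frac_unexpressed = 0.1, induced = TRUE,
                            seed = seed + 1L)
  pwms <- list(pwm_from_consensus("ACCGGATA", "M1"),
               pwm_from_consensus("TTGCACCA", "M2"))
  annA0 <- annotate_peaks(ps$sets[[1L]], genes, cfg)
  distalA <- distal_subset(ps$sets[[1L]], annA0)
  planted <- head(distalA$name, sim$n_motif_pair_peaks)
  msim <- sim_motif_sequences(genome, distalA,
                              pairs = list(list(motif_a = pwms[[1L]],
                                                motif_b = pwms[[2L]],
                                                spacing = sim$motif_spacing,
                                                peaks = planted)),
                              window = cfg$summit_window, seed = seed)
  genome <- msim$genome

  write_genome(genome, inp("genome.fa"))
  for (lab in names(ps$sets))
    write_narrowpeak(ps$sets[[lab]], inp(paste0("peaks_", lab, ".narrowPeak")))
  write_genes_bed(genes, inp("genes.bed"))
  for (lab in names(tags))
    write_tags_bed(tags[[lab]], inp(paste0("tags_", lab, ".bed")))
  write_expression(expr_un$expr, inp("expr_uninduced.tsv"),
                   inp("meta_uninduced.tsv"))
  write_expression(expr_in$expr, inp("expr_induced.tsv"),
                   inp("meta_induced.tsv"))
  write_jaspar(pwms, inp("motifs.pfm"))
  truth <- list(planted_overlap_counts = as.list(ps$truth$planted_overlap_counts),
                planted_pattern_codes_uninduced =
                  as.list(expr_un$truth$planted_pattern_codes),
                planted_pattern_codes_induced =
                  as.list(expr_in$truth$planted_pattern_codes),
                planted_motif_pairs = msim$truth,
                seed = seed)
  jsonlite::write_json(truth, inp("truth.json"), auto_unbox = TRUE)

  ## --- read the bundle back through the package parsers ---------------
  genome <- read_genome(inp("genome.fa"))
  sets <- lapply(names(ps$sets), function(lab)
    read_narrowpeak(inp(paste0("peaks_", lab, ".narrowPeak")), label = lab))
  names(sets) <- names(ps$sets)
  genes <- read_genes(inp("genes.bed"))
  tags <- lapply(names(ps$sets), function(lab)
    read_tags_bed(inp(paste0("tags_", lab, ".bed")), label = lab))
  names(tags) <- names(ps$sets)
  expr_un <- read_expression(inp("expr_uninduced.tsv"),
                             inp("meta_uninduced.tsv"),
                             stage_order = sim$stages)
  expr_in <- read_expression(inp("expr_induced.tsv"),
                             inp("meta_induced.tsv"),
                             stage_order = sim$stages)
  pwms <- read_jaspar(inp("motifs.pfm"))

  ## --- peaks ----------------------------------------------------------
  union <- merge_union(sets, cfg$summit_window)
  venn <- venn_counts(union)
  emit(data.frame(signature = names(venn$counts),
                  count = as.integer(venn$counts)), "venn_counts.tsv")

  ## --- bootstrap significance -----------------------------------------
  bp <- bootstrap_peak_overlap(sets, cfg)
  ann <- lapply(sets, annotate_peaks, genes = genes, cfg = cfg)
  gene_sets <- lapply(ann, bound_gene_set)
  universe <- genes$gene_id
  bg <- bootstrap_gene_overlap(gene_sets, universe, cfg)
  emit(data.frame(test = c("peak_overlap", "gene_overlap"),
                  observed = c(bp$observed, bg$observed),
                  null_mean = c(bp$null_mean, bg$null_mean),
                  null_sd = c(bp$null_sd, bg$null_sd),
                  z = c(bp$z, bg$z),
                  p_one_sided = c(bp$p_one_sided, bg$p_one_sided),
                  log10_p = c(bp$log10_p, bg$log10_p),
                  iterations = cfg$n_bootstrap, seed = seed),
       "bootstrap_overlap.tsv")

  ## --- annotation -----------------------------------------------------
  annA <- ann[[1L]]
  emit(as.data.frame(annA), "peak_gene_assignments.tsv")

  ## --- expression -----------------------------------------------------
  expressed <- filter_expressed(expr_un, cfg)
  cmp_un <- stage_comparisons(expr_un)
  fc_un <- fold_changes(expr_un, cmp_un, genes = expressed)
  codes_un <- trinarize(fc_un, cfg = cfg)
  groups <- group_patterns(codes_un, cfg, fc = fc_un)
  emit(codes_un, "pattern_codes.tsv")
  emit(data.frame(code = names(groups$census),
                  n_genes = as.integer(groups$census),
                  retained = names(groups$census) %in% groups$retained),
       "pattern_census.tsv")
  sc <- sample_correlation(expr_un, linkage = "average")
  emit(data.frame(sample = rownames(sc$cor), round(sc$cor, 6L)),
       "expression_sample_correlation.tsv")

  ## --- integration ----------------------------------------------------
  expressed_both <- intersect(expressed, filter_expressed(expr_in, cfg))
  fc1_un <- fold_changes(expr_un, cmp_un[1L], genes = expressed_both)
  fc1_in <- fold_changes(expr_in, stage_comparisons(expr_in)[1L],
                         genes = expressed_both)
  resp <- classify_response(trinarize(fc1_un, cfg = cfg),
                            trinarize(fc1_in, cfg = cfg),
                            bound = gene_sets[[1L]])
  emit(resp$classes, "response_classes.tsv")
  emit(data.frame(code = names(resp$census),
                  label = unname(RESPONSE_LABELS[names(resp$census)]),
                  n_genes = as.integer(resp$census)),
       "response_class_counts.tsv")
  dts <- direct_target_split(
    list(up = codes_un$gene_id[substr(codes_un$code, 1L, 1L) == "1"],
         down = codes_un$gene_id[substr(codes_un$code, 1L, 1L) == "0"]),
    gene_sets[[1L]])
  emit(data.frame(direction = c("up", "down"),
                  bound = c(dts$up$bound, dts$down$bound),
                  unbound = c(dts$up$unbound, dts$down$unbound),
                  fraction_bound = c(dts$up$fraction_bound,
                                     dts$down$fraction_bound)),
       "direct_targets.tsv")

  ## --- motifs ---------------------------------------------------------
  distal <- distal_subset(sets[[1L]], annA)
  coloc_cfg <- cfg
  coloc_cfg$n_bootstrap <- min(cfg$n_bootstrap, 500L)
  coloc <- bootstrap_colocalization(distal, distal, genome, pwms, coloc_cfg)
  emit(coloc$pairs, "motif_colocalization.tsv")

  ## --- signal ---------------------------------------------------------
  prof <- composite_profile(tags[[1L]], sets[[1L]], cfg)
  emit(as.data.frame(prof), "composite_profile.tsv")
  cm <- count_matrix(tags, union)
  pc <- peak_sample_correlation(cm)
  emit(data.frame(sample = rownames(pc$cor), round(pc$cor, 6L)),
       "chip_sample_correlation.tsv")

  ## --- manifest -------------------------------------------------------
  inputs <- list.files(inp(), full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("regstage")),
    config = unclass(cfg), config_hash = config_hash(cfg), seed = seed,
    input_digests = as.list(tools::md5sum(inputs)),
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' `regstage <command> [--out DIR] [--seed S] [--iters N] [--config FILE]
#' [--peaks a.narrowPeak,b.narrowPeak,...] [--genes genes.bed]
#' [--genesets a.txt,b.txt,c.txt --universe u.txt]
#' [--values expr.tsv --meta meta.tsv]`
#'
#' Commands: `simulate` (write an input bundle), `peaks` (Venn counts and,
#' with `--genes`, peak-to-gene assignments), `boot` (peak-overlap
#' bootstrap on `--peaks`, or gene-overlap on `--genesets`/`--universe`),
#' `expr` (pattern codes and census from `--values`/`--meta`), and
#' `run-all` (the full simulated end-to-end pipeline). YAML config values
#' (a flat `params` block mirroring [analysis_config()] argument names) are
#' applied first, then overridden by flags.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly.
#' @export
regstage_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: regstage <simulate|peaks|boot|expr|run-all>",
                 "[--out DIR] [--seed S] [--iters N] [--config FILE]",
                 "[--peaks F,F,...] [--genes F] [--genesets F,F,...]",
                 "[--universe F] [--values F] [--meta F]")
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]; args <- args[-1L]
  opt <- list(out = "regstage_out", seed = 1L, iters = NULL, config = NULL,
              peaks = NULL, genes = NULL, genesets = NULL, universe = NULL,
              values = NULL, meta = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) stop(usage, call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  params <- list()
  if (!is.null(opt$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for --config")
    y <- yaml::read_yaml(opt$config)
    params <- y$params %||% y
  }
  params$rng_seed <- as.integer(opt$seed)
  if (!is.null(opt$iters)) params$n_bootstrap <- as.integer(opt$iters)
  cfg <- do.call(analysis_config, params)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  split_arg <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]
  t0 <- Sys.time()
  if (cmd == "run-all") {
    run_pipeline(opt$out, cfg)
  } else if (cmd == "simulate") {
    sim <- pipeline_sim_defaults()
    genome <- sim_genome(sim$n_chroms, sim$chrom_length, cfg$rng_seed)
    ps <- sim_peak_sets(sim$membership_spec, chrom_sizes(genome),
                        summit_jitter_sd = 25, seed = cfg$rng_seed)
    write_genome(genome, file.path(opt$out, "genome.fa"))
    for (lab in names(ps$sets))
      write_narrowpeak(ps$sets[[lab]],
                       file.path(opt$out, paste0("peaks_", lab, ".narrowPeak")))
    jsonlite::write_json(
      list(planted_overlap_counts = as.list(ps$truth$planted_overlap_counts),
           seed = cfg$rng_seed),
      file.path(opt$out, "truth.json"), auto_unbox = TRUE)
  } else if (cmd == "peaks") {
    if (is.null(opt$peaks)) stop("peaks: --peaks required", call. = FALSE)
    sets <- lapply(split_arg(opt$peaks), read_narrowpeak)
    union <- merge_union(sets, cfg$summit_window)
    venn <- venn_counts(union)
    write_output_tsv(data.frame(signature = names(venn$counts),
                                count = as.integer(venn$counts)),
                     file.path(opt$out, "venn_counts.tsv"), cfg, cfg$rng_seed)
    if (!is.null(opt$genes)) {
      genes <- read_genes(opt$genes)
      for (s in sets)
        write_output_tsv(as.data.frame(annotate_peaks(s, genes, cfg)),
                         file.path(opt$out, paste0("assignments_",
                                                   peak_label(s), ".tsv")),
                         cfg, cfg$rng_seed)
    }
  } else if (cmd == "boot") {
    if (!is.null(opt$peaks)) {
      sets <- lapply(split_arg(opt$peaks), read_narrowpeak)
      b <- bootstrap_peak_overlap(sets, cfg)
    } else if (!is.null(opt$genesets) && !is.null(opt$universe)) {
      gs <- lapply(split_arg(opt$genesets), readLines)
      b <- bootstrap_gene_overlap(gs, readLines(opt$universe), cfg)
    } else stop("boot: --peaks or --genesets/--universe required",
                call. = FALSE)
    write_output_tsv(
      data.frame(observed = b$observed, null_mean = b$null_mean,
                 null_sd = b$null_sd, z = b$z, p_one_sided = b$p_one_sided,
                 log10_p = b$log10_p, iterations = b$n_iterations,
                 seed = b$seed),
      file.path(opt$out, "bootstrap.tsv"), cfg, cfg$rng_seed)
  } else if (cmd == "expr") {
    if (is.null(opt$values) || is.null(opt$meta))
      stop("expr: --values and --meta required", call. = FALSE)
    m <- read_expression(opt$values, opt$meta)
    expressed <- filter_expressed(m, cfg)
    fc <- fold_changes(m, stage_comparisons(m), genes = expressed)
    codes <- trinarize(fc, cfg = cfg)
    groups <- group_patterns(codes, cfg, fc = fc)
    write_output_tsv(codes, file.path(opt$out, "pattern_codes.tsv"),
                     cfg, cfg$rng_seed)
    write_output_tsv(
      data.frame(code = names(groups$census),
                 n_genes = as.integer(groups$census),
                 retained = names(groups$census) %in% groups$retained),
      file.path(opt$out, "pattern_census.tsv"), cfg, cfg$rng_seed)
  } else stop(usage, call. = FALSE)
  message(sprintf("[regstage] %s finished in %.1f s", cmd,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(0L)
}
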
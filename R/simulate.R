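# Synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of (parameters, seed): it draws from a
# private RNG stream derived from the master seed and the generator name
# (derive_seed), so adding draws to one generator never perturbs another.

#' Simulate a genome of i.i.d. uniform ACGT sequence
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome, bp (>= 10 kb).
#' @param seed master seed.
#' @return `DNAStringSet` named `chr1..chrN`.
#' @export
sim_genome <- function(n_chroms = 2L, chrom_length = 1e6, seed = 1L) {
  stopifnot(n_chroms >= 1L, chrom_length >= 1e4)
  chrom_length <- as.integer(chrom_length)
  withr::with_seed(derive_seed(seed, "sim_genome"), {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(DNA_BASES, chrom_length, replace = TRUE), collapse = "")
    }, character(1L))
  })
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  Biostrings::DNAStringSet(seqs)
}

# place n anchors with pairwise gap >= min_gap inside [margin, size - margin)
# across chromosomes; returns data.frame(chrom, pos)
place_anchors <- function(n, sizes, min_gap, margin, slack = 200L) {
  slot <- min_gap + slack
  capacity <- pmax(0L, (sizes - 2L * margin) %/% slot)
  if (sum(capacity) < n)
    stop("infeasible: genome holds at most ", sum(capacity),
         " anchors at spacing ", min_gap, " but ", n, " requested")
  slots <- data.frame(
    chrom = rep(names(sizes), capacity),
    idx = unlist(lapply(capacity, seq_len), use.names = FALSE) - 1L,
    stringsAsFactors = FALSE)
  pick <- slots[sort(sample.int(nrow(slots), n)), , drop = FALSE]
  pos <- margin + pick$idx * slot +
    sample.int(slack + 1L, n, replace = TRUE) - 1L
  data.frame(chrom = pick$chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Simulate peak sets with a planted Venn structure
#'
#' Plants one genomic anchor per membership cluster: a cluster with
#' signature `"ABC"` contributes one peak to each of the sets A, B and C,
#' with summits jittered around the anchor by a truncated normal
#' (|jitter| <= summit_window/2). Anchors for distinct clusters are spaced
#' by more than `2*summit_window + width`, so single-linkage summit
#' clustering at `summit_window` recovers the planted membership exactly:
#' within-cluster summit distances are <= summit_window and between-cluster
#' distances exceed it.
#'
#' @param membership_spec named integer vector: names are membership
#'   signatures over single-letter set labels (e.g.
#'   `c(ABC = 50, AB = 20, A = 30)`), values are cluster counts.
#' @param sizes named chromosome sizes (see [chrom_sizes()]).
#' @param summit_jitter_sd sd (bp) of summit jitter around the anchor.
#' @param width peak width, bp.
#' @param summit_window clustering window the construction must defeat.
#' @param seed master seed.
#' @return list with `sets` (named list of [peak_set()]) and `truth`
#'   (`planted_overlap_counts`, `anchors`, `seed`).
#' @export
sim_peak_sets <- function(membership_spec, sizes, summit_jitter_sd = 0,
                          width = 400L, summit_window = 200L, seed = 1L) {
  stopifnot(length(membership_spec) >= 1L, !is.null(names(membership_spec)))
  labels <- sort(unique(unlist(strsplit(names(membership_spec), ""))))
  n_anchor <- sum(membership_spec)
  width <- as.integer(width)
  min_gap <- 2L * as.integer(summit_window) + width + 1L
  margin <- width + as.integer(summit_window)
  withr::with_seed(derive_seed(seed, "sim_peak_sets"), {
    anchors <- place_anchors(n_anchor, chrom_sizes(sizes), min_gap, margin)
    anchors$signature <- sample(rep(names(membership_spec),
                                    times = membership_spec))
    half <- as.integer(summit_window) %/% 2L
    sets <- lapply(labels, function(lab) {
      in_set <- grepl(lab, anchors$signature, fixed = TRUE)
      a <- anchors[in_set, , drop = FALSE]
      jit <- if (summit_jitter_sd > 0) {
        pmin(pmax(as.integer(round(rnorm(nrow(a), 0, summit_jitter_sd))),
                  -half), half)
      } else integer(nrow(a))
      summit <- a$pos + jit
      peak_set(a$chrom, summit - width %/% 2L, summit + width - width %/% 2L,
               summit = summit,
               name = sprintf("%s_%s", lab, rownames(a)),
               label = lab)
    })
  })
  names(sets) <- labels
  list(sets = sets,
       truth = list(planted_overlap_counts = membership_spec,
                    anchors = anchors, seed = seed))
}

#' Simulate tag pileups around peak summits plus uniform background
#'
#' For each enriched peak, `tags_per_peak` tag positions are drawn
#' Normal(summit, `pileup_sd`), rounded and clamped to the chromosome;
#' `background_tags` positions are uniform over the genome.
#'
#' @param peaks a `PeakSet` whose summits carry the pileups.
#' @param sizes named chromosome sizes.
#' @param tags_per_peak tags per enriched peak.
#' @param background_tags total uniform background tags.
#' @param pileup_sd sd of the pileup, bp (> 0).
#' @param enriched names of peaks carrying pileups (default: all).
#' @param label sample label.
#' @param seed master seed.
#' @return list with `tags` (a [tag_set()]) and `truth`
#'   (`planted_enrichment_peaks`, `seed`).
#' @export
sim_tags <- function(peaks, sizes, tags_per_peak = 50L,
                     background_tags = 0L, pileup_sd = 50,
                     enriched = NULL, label = "tags", seed = 1L) {
  stopifnot(inherits(peaks, "PeakSet"), pileup_sd > 0)
  sizes <- chrom_sizes(sizes)
  if (is.null(enriched)) enriched <- peaks$name
  pk <- peaks[peaks$name %in% enriched, , drop = FALSE]
  withr::with_seed(derive_seed(seed, paste0("sim_tags:", label)), {
    n_fg <- nrow(pk) * tags_per_peak
    fg_chrom <- rep(pk$chrom, each = tags_per_peak)
    fg_pos <- as.integer(round(rnorm(n_fg, rep(pk$summit, each = tags_per_peak),
                                     pileup_sd)))
    fg_pos <- pmin(pmax(fg_pos, 0L), sizes[fg_chrom] - 1L)
    bg_chrom <- if (background_tags > 0L)
      sample(names(sizes), background_tags, replace = TRUE,
             prob = sizes / sum(sizes)) else character(0L)
    bg_pos <- if (background_tags > 0L)
      as.integer(floor(runif(background_tags) * sizes[bg_chrom])) else integer(0L)
  })
  list(tags = tag_set(c(fg_chrom, bg_chrom), c(fg_pos, bg_pos), label = label),
       truth = list(planted_enrichment_peaks = pk$name, seed = seed))
}

#' Simulate gene models
#'
#' Non-overlapping gene bodies with random strand, for exercising the
#' peak-to-gene allocation rules.
#'
#' @param n_genes number of genes.
#' @param sizes named chromosome sizes.
#' @param gene_length gene body length, bp.
#' @param min_gap minimum gap between gene starts, bp.
#' @param seed master seed.
#' @return a [gene_models()] data frame.
#' @export
sim_genes <- function(n_genes, sizes, gene_length = 5000L,
                      min_gap = 15000L, seed = 1L) {
  withr::with_seed(derive_seed(seed, "sim_genes"), {
    anchors <- place_anchors(n_genes, chrom_sizes(sizes),
                             as.integer(min_gap), as.integer(gene_length))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  })
  gene_models(anchors$chrom, anchors$pos, anchors$pos + as.integer(gene_length),
              sprintf("g%05d", seq_len(n_genes)), strand)
}

#' Simulate a log2 expression matrix with planted trinary patterns
#'
#' Each gene carries a trinary code with one digit per stage transition:
#' digit `1` adds `+effect_log2` to the stage mean across that transition,
#' `0` adds `-effect_log2`, `2` adds nothing. Observations are the stage
#' mean plus i.i.d. Normal(0, `noise_sd`) noise. A fraction of genes can be
#' pinned below the expressed-gene floor at all stages to exercise the
#' expression filter.
#'
#' @param n_genes number of genes.
#' @param stages ordered character vector of stage names (>= 2).
#' @param codes named character vector gene_id -> code (digits in 0/1/2,
#'   one per transition); if `NULL`, codes are drawn uniformly from all
#'   `3^k` combinations.
#' @param effect_log2 per-transition effect size in log2 units (default 2:
#'   a four-fold change, leaving one log2 unit of margin above the two-fold
#'   calling threshold).
#' @param noise_sd observation noise sd in log2 units.
#' @param baseline log2 intensity of the first stage for expressed genes.
#' @param n_reps replicates per stage.
#' @param frac_unexpressed fraction of genes pinned below the expression
#'   floor (flat at `unexpressed_level`).
#' @param unexpressed_level log2 level of unexpressed genes.
#' @param induced logical recorded in the sample metadata (the +/-induction
#'   arm this matrix represents).
#' @param seed master seed.
#' @return list with `expr` (an [expression_matrix()]) and `truth`
#'   (`planted_pattern_codes`, `unexpressed`, `seed`).
#' @export
sim_expression <- function(n_genes = 1000L,
                           stages = c("HE", "HE2", "progenitor"),
                           codes = NULL, effect_log2 = 2.0, noise_sd = 0.2,
                           baseline = 8.0, n_reps = 3L,
                           frac_unexpressed = 0, unexpressed_level = 4.5,
                           induced = FALSE, seed = 1L) {
  stopifnot(length(stages) >= 2L, effect_log2 >= 0, noise_sd >= 0)
  k <- length(stages) - 1L
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  withr::with_seed(derive_seed(seed, paste0("sim_expression:", induced)), {
    if (is.null(codes)) {
      codes <- vapply(seq_len(n_genes), function(i)
        paste(sample(c("0", "1", "2"), k, replace = TRUE), collapse = ""),
        character(1L))
      names(codes) <- gene_ids
    } else {
      gene_ids <- names(codes)
      n_genes <- length(codes)
    }
    if (any(nchar(codes) != k))
      stop("code length must equal the number of stage transitions (", k, ")")
    if (any(!grepl("^[012]+$", codes)))
      stop("codes must use digits 0, 1, 2 only")
    digit <- matrix(as.integer(unlist(strsplit(codes, ""))),
                    nrow = n_genes, byrow = TRUE)
    delta <- matrix(0, n_genes, k)
    delta[digit == 1L] <- effect_log2
    delta[digit == 0L] <- -effect_log2
    cum <- delta
    if (k > 1L) for (j in 2:k) cum[, j] <- cum[, j - 1L] + delta[, j]
    means <- cbind(rep(baseline, n_genes), baseline + cum)
    n_unexpr <- floor(frac_unexpressed * n_genes)
    unexpr <- if (n_unexpr > 0L) sample(gene_ids, n_unexpr) else character(0L)
    means[gene_ids %in% unexpr, ] <- unexpressed_level
    labels <- as.vector(outer(seq_len(n_reps), stages, function(r, s)
      paste0(s, "_r", r, if (induced) "_dox" else "")))
    vals <- means[, rep(seq_along(stages), each = n_reps), drop = FALSE]
    vals <- vals + rnorm(length(vals), 0, noise_sd)
    dimnames(vals) <- list(gene_ids, labels)
  })
  samples <- data.frame(
    label = labels,
    stage = rep(stages, each = n_reps),
    induced = induced,
    replicate = rep(seq_len(n_reps), times = length(stages)),
    stringsAsFactors = FALSE)
  list(expr = expression_matrix(vals, samples, stage_order = stages),
       truth = list(planted_pattern_codes = codes, unexpressed = unexpr,
                    seed = seed))
}

#' Plant motif instances and motif pairs into a genome
#'
#' For each designated peak, the consensus of `motif_a` is written at a
#' uniform random offset inside the +/-`window` scan window around the
#' summit, and (for pairs) the consensus of `motif_b` at a center-to-center
#' distance of exactly `spacing` bp downstream. Other peaks are untouched.
#' Instances that would overlap (`spacing < ceiling((La + Lb)/2)`) are an
#' error.
#'
#' @param genome a `DNAStringSet`.
#' @param peaks a `PeakSet` (provides summits and chromosomes).
#' @param pairs list of plantings, each a list with `motif_a`, `motif_b`
#'   ([pwm()] objects), `spacing` (bp) and either `peaks` (character names)
#'   or `n_peaks` (sampled from `peaks`).
#' @param singles list of single-motif plantings, each a list with `motif`
#'   and `peaks`/`n_peaks`.
#' @param window half-width of the scan window, bp.
#' @param seed master seed.
#' @return list with `genome` (modified copy) and `truth` (data frame of
#'   planted instances: peak, motif ids, centers, spacing).
#' @export
sim_motif_sequences <- function(genome, peaks, pairs = NULL, singles = NULL,
                                window = 200L, seed = 1L) {
  stopifnot(inherits(peaks, "PeakSet"))
  window <- as.integer(window)
  seqs <- lapply(as.character(genome), utf8ToInt)  # mutable int encoding
  truth <- list()
  write_instances <- function(chroms, centers, p) {
    cons <- utf8ToInt(p$consensus)
    starts <- centers - (p$length - 1L) %/% 2L
    for (ch in unique(chroms)) {
      st <- starts[chroms == ch]
      idx <- rep(st, each = p$length) + seq_len(p$length)  # 1-based
      seqs[[ch]][idx] <<- rep(cons, times = length(st))
    }
  }
  resolve_peaks <- function(spec) {
    nm <- if (!is.null(spec$peaks)) spec$peaks
          else peaks$name[sample.int(nrow(peaks), spec$n_peaks)]
    rows <- match(nm, peaks$name)
    if (anyNA(rows)) stop("unknown peak '", nm[is.na(rows)][1L], "'")
    list(name = nm, chrom = peaks$chrom[rows], summit = peaks$summit[rows])
  }
  # uniform center range so an instance fits fully in [summit-w, summit+w]
  c_lo <- function(summit, len) summit - window + (len - 1L) %/% 2L
  c_hi <- function(summit, len) summit + window - (len - (len - 1L) %/% 2L - 1L)
  withr::with_seed(derive_seed(seed, "sim_motif_sequences"), {
    for (sp in pairs %||% list()) {
      la <- sp$motif_a$length; lb <- sp$motif_b$length
      if (sp$spacing < ceiling((la + lb) / 2))
        stop("spacing ", sp$spacing, " overlaps motif instances (min ",
             ceiling((la + lb) / 2), ")")
      pk <- resolve_peaks(sp)
      lo <- c_lo(pk$summit, la)
      hi <- pmin(c_hi(pk$summit, la), c_hi(pk$summit, lb) - sp$spacing)
      ca <- lo + as.integer(floor(runif(length(lo)) * (hi - lo + 1L)))
      cb <- ca + as.integer(sp$spacing)
      write_instances(pk$chrom, ca, sp$motif_a)
      write_instances(pk$chrom, cb, sp$motif_b)
      truth[[length(truth) + 1L]] <- data.frame(
        peak = pk$name, motif_a = sp$motif_a$motif_id,
        motif_b = sp$motif_b$motif_id, center_a = ca, center_b = cb,
        spacing = sp$spacing, stringsAsFactors = FALSE)
    }
    for (sg in singles %||% list()) {
      p <- sg$motif
      pk <- resolve_peaks(sg)
      lo <- c_lo(pk$summit, p$length); hi <- c_hi(pk$summit, p$length)
      cc <- lo + as.integer(floor(runif(length(lo)) * (hi - lo + 1L)))
      write_instances(pk$chrom, cc, p)
      truth[[length(truth) + 1L]] <- data.frame(
        peak = pk$name, motif_a = p$motif_id, motif_b = NA_character_,
        center_a = cc, center_b = NA_integer_, spacing = NA_integer_,
        stringsAsFactors = FALSE)
    }
  })
  out <- Biostrings::DNAStringSet(vapply(seqs, intToUtf8, character(1L)))
  names(out) <- names(genome)
  list(genome = out,
       truth = do.call(rbind, truth) %||%
         data.frame(peak = character(0L)))
}
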
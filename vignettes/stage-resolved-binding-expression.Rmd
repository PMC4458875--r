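---
title: "Methods: stage-resolved integration of TF binding and expression response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved integration of TF binding and expression response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(regstage)
```

# Scope and model

`regstage` analyses ChIP-seq peak sets obtained for one transcription
factor at successive developmental stages together with log2 expression
matrices measured across those stages, with and without induction of the
factor. The package deliberately starts *after* read alignment, peak
calling and array preprocessing: its inputs are called peaks with summits
(narrowPeak), aligned-tag positions (BED), gene models (BED6/GTF), complete
log2 intensity matrices (TSV) and PWMs (JASPAR PFM). Everything upstream —
aligners, peak callers, LIMMA model fitting, de novo motif discovery — is
out of scope and consumed as data.

The analysis has three layers:

1. **Binding geometry.** Overlap between peaks is defined purely by summit
   proximity: summits within ±`summit_window` bp (default 200, closed
   interval) on one chromosome. Multi-set comparison merges all summits by
   single-linkage clustering at this threshold into *union peaks*, each
   carrying the signature of contributing sets; Venn counts are cluster
   counts per signature.
2. **Resampling significance.** Observed multi-set overlaps (of peaks, or
   of bound-gene sets) are compared with an empirical null built by keeping
   one actual set and redrawing the others from a pool of candidate sites
   at matching population. The summary is a z-score against the pooled
   null mean/s.d. and its one-sided upper-tail normal P.
3. **Expression response.** Per stage transition each gene receives a
   trinary digit (1 up / 0 down / 2 invariant, two-fold threshold); digit
   strings group genes into patterns; the digit pair (uninduced, induced)
   for a transition classifies bound genes into response classes
   (`00` still_downregulated … `21` upregulated).

# Parameters

All numeric parameters live in one `analysis_config()` object:

| parameter | default | unit | role |
|---|---|---|---|
| `summit_window` | 200 | bp | summit overlap / clustering threshold (inclusive) |
| `random_peak_width` | 400 | bp | width of bootstrap null peaks |
| `n_bootstrap` | 50,000 | — | bootstrap iterations (tests use 100–4,000) |
| `pair_distance` | 20 | bp | max center-to-center distance of a motif pair |
| `fold_threshold` | 2.0 | linear | differential call, applied as log2fc ≥ 1 (inclusive) |
| `expressed_min_log2` | 6.5 | log2 | expressed-gene floor, inclusive, any sample |
| `p_cutoff` | 0.001 | — | applied only when per-gene p-values are supplied |
| `min_group_size` | 30 | genes | pattern group retained if count > 30 (strict) |
| `profile_flank` / `profile_bin` | 5,000 / 50 | bp | composite profile geometry (200 bins) |
| `intergenic_max_dist` | 100,000 | bp | summit→TSS cap, inclusive |
| `promoter_upstream` / `promoter_downstream` | 2,000 / 500 | bp | strand-aware promoter window |
| `scan_threshold_frac` | 0.8 | — | PWM hit threshold as fraction of max log-odds |
| `rng_seed` | 1 | — | master seed; per-operation streams are derived from it |

Defaults are the published protocol values of the study this pipeline
re-implements; `scan_threshold_frac` is our own operating point because the
original tool's per-motif thresholds are unpublished.

# Null designs

**Peak overlap.** The sampling pool defaults to the union clusters of the
actual sets (the published construction: a fixed pool with set-sized
draws). Each iteration *i* keeps actual set `i mod 3` and replaces the
other two by `random_peak_width`-bp peaks centered on pool summits, drawn
without replacement by default (with-replacement is a config flag; the
original description does not say which). All iterations are pooled into
one null (per-rotation statistics are retained in the result). The same
statistic function — the C++ single-linkage cluster count — is applied to
the observed and every null configuration; using different code paths for
the two would bias z, so the R merge route is only a cross-check in the
test suite.

The pool can also be passed explicitly. This matters for calibration
experiments: when three sets are drawn uniformly from an external frame of
candidate sites, the null is self-consistent only if the bootstrap samples
from that same frame. With the union-of-sets pool, independent random sets
of size *n* from a larger frame have observed three-way overlap ≈ n³/N²
but null mean ≈ n(n/N\*)² with N\* the (much smaller) union — a strongly
negative z by construction. The package therefore exposes `pool =` and the
calibration tests use it; real analyses of jointly-called peak sets use
the default.

**z → P.** `z_to_p()` wraps R's erfc-backed normal tail with the log-space
branch, so the linear P underflows gracefully (≈ z > 38) while `log10_p`
remains exact; the suite checks both against an independent Mills-ratio
series to six significant digits up to z = 40. At z = 23.36 the one-sided
tail is 5.4532e−121. A null with zero variance (e.g. identical sets equal
to the universe) yields `z = NA` plus a warning, never a fabricated value.

**Motif co-localization.** Hits are PWM log2-odds matches on both strands
within ±`summit_window` of the summit, instances fully inside the window,
overlapping same-motif hits greedily pruned by score (tandem repeats would
otherwise double-count). A peak counts for pair (a, b) if any two distinct
instances are within `pair_distance` center-to-center (the stated distance
is between centers, so that is what is implemented; edge distance is not).
The null redraws peak sets of matching size from the distal pool; because
random windows are re-scanned sequence, the genome is scanned once per PWM
and per-peak pair indicators are precomputed, making each null iteration a
row-subset sum.

# Allocation rules and tie-breaks

The allocation point of a peak is its summit (the best estimate of the
binding position; the original wording does not fix an anchor). Promoter
windows are strand-aware and inclusive at both ends: `+` strand
`[tss − 2000, tss + 500]`, `−` strand mirrored. Precedence is promoter >
intragenic > intergenic; within a category, ties go to the smallest
|summit − TSS| and then to the lexicographically smallest gene id, making
the assignment deterministic. "Within 100 kb" is read as ≤ 100,000 bp.
Reported distances are signed in the direction of transcription.
Implementation uses IRanges interval joins; the test suite holds it
bit-identical to a per-peak brute-force loop on 10³-peak instances.

Similarly deliberate boundary readings, each unit-tested: "equal to or
>6.5" is ≥ 6.5; "at least twofold" is log2fc ≥ 1 inclusive; "more than a
minimum of 30 genes" is strictly > 30 (a config flag switches to ≥, since
the wording is ambiguous); the all-invariant code (`22…2`) is never a
"changing pattern" and is excluded from retention. "Eight classes" of the
two-digit response scheme is read as the nine digit pairs minus the
unresponsive `22`; both the 8-class report and the full 9-class census are
returned.

# The synthetic world

The generators produce every input type with planted truth:

- `sim_peak_sets()` plants one anchor per membership cluster and spaces
  anchors by more than `2·summit_window + width`, with summit jitter
  truncated at ±`summit_window/2`. Consequence: within-cluster summit
  distances never exceed the window and between-cluster distances always
  do, so single-linkage clustering recovers the planted Venn *exactly*.
  Real peak sets do chain (A–B–C merged although A and C are distant);
  the package accepts chaining and the tests exercise it separately — a
  green Venn-recovery test certifies the clustering logic, not the absence
  of chaining in real data.
- `sim_expression()` adds ±`effect_log2` (default 2, i.e. four-fold) per
  transition so the planted mean sits one log2 unit beyond the two-fold
  threshold; with `noise_sd = 0.2` and 3 replicates the per-digit
  misclassification probability is negligible (< 1e−9), which is why the
  ≥99 % recovery criterion is expected to hold with margin.
- `sim_tags()` draws Normal(summit, `pileup_sd`) pileups plus uniform
  background — no fragment-length, mappability or GC structure.
- `sim_motif_sequences()` writes motif consensus instances into uniform
  ACGT sequence: pairs at exact center-to-center spacings in designated
  peaks, independent singles elsewhere. For the specificity experiment the
  15-bp pair and the 25-bp pair are planted in *disjoint* target subsets,
  one pair per peak. Two pairs in one window would (a) occasionally
  overwrite each other and (b) constrain instance offsets to a narrower
  range than the pool's singles, slightly biasing unplanted cross-pair
  distances — enough to make "no unplanted pair exceeds z = 3" a random
  event rather than a property. With disjoint planting, unplanted pairs
  never co-occur in a target peak and the claim is decidable.
- Every generator draws from a private RNG stream derived from
  (master seed, operation name), so adding draws to one generator never
  shifts another; all outputs are byte-identical across runs for a fixed
  seed.

What the generators do **not** emulate: sequencing error, read-length
effects, probe-level microarray noise, copy-number or mappability
artifacts, correlated gene programs, and motif instances degenerate from
their consensus. Green acceptance tests therefore establish correctness of
the pipeline's logic and calibration of its resampling nulls on idealized
data — not robustness to every artifact of real libraries.

# Numerical and implementation choices

- Coordinates are 0-based half-open everywhere inside the package; GTF is
  converted on read, IRanges only at internal boundaries. Summits are
  absolute 0-based positions.
- Tag positions are fragment midpoints (the upstream density-map recipe
  does not state its anchor; the midpoint is deterministic and strand-free,
  adequate at 50-bp binning).
- Profile bins are left-closed `[edge, edge + 50)`; densities are mean per
  peak divided by (total tags / 10⁶). The per-million scale is our
  readability choice on top of the published bare total-count division; it
  cancels in every ratio and correlation.
- Union-peak representative summit is the floor of the member-summit
  median; counting frames use the representative merged interval so all
  samples share one frame.
- Hierarchical clustering: Euclidean distance with average linkage for
  expression, complete linkage for TF binding matrices (the published
  conventions); dendrogram leaves are reordered against sorted labels so
  output order is deterministic.
- `sim_genome` sequences are i.i.d. uniform ACGT; the motif scanner treats
  any non-ACGT base as unmatchable (−∞ contribution).
- Bootstrap kernels (cluster statistic, null loop, PWM scoring) are Rcpp;
  they use R's RNG, so `set.seed`-style reproducibility extends through
  the compiled code.

# Validation protocol (what the test suite runs)

Production bootstraps use 50,000 iterations; the validation protocol runs
2,000 iterations × 200 replicate seeds for null calibration (z mean within
±0.2, s.d. within [0.7, 1.4], planted 50-cluster enrichment z > 5
always), 1,000 iterations × 20 seeds for motif specificity, and scales the
"random Venn specs" property to 40 specs — all chosen to keep the full
suite within minutes on one CPU without weakening any threshold. Every
number the README or this vignette quotes is computed by the test suite or
`scripts/acceptance.R` at run time.

# Known limitations

- Single-linkage chaining can merge distant summits in dense regions; the
  union count is then smaller than perfect-matching alternatives. Both the
  cluster-level counts (canonical here) and the per-set directional counts
  (`summit_overlap`) are exposed.
- The gene-overlap null treats genes as exchangeable; no expression-level
  or gene-length matching.
- The motif null preserves peak population but not sequence composition
  beyond what the pool windows contain.
- P values from z assume an approximately normal null; for very sparse
  pair counts the discreteness makes z conservative-to-noisy, and pairs
  whose null never fires are reported as `NA` rather than forced.
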
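# regstage

Stage-resolved integration of transcription-factor ChIP-seq binding with
gene-expression response.

## The problem

When an oncogenic transcription factor such as a RUNX1 fusion protein is
induced at successive stages of blood development (haemogenic endothelium →
haematopoietic progenitors → myeloid progenitors), two questions recur:

1. **Does the factor bind the same sites and genes at each stage?** Peaks
   called at different stages must be compared, and the significance of
   their overlap quantified against a realistic null.
2. **Which bound genes actually respond?** Expression trajectories across
   stages, with and without induction, must be summarized and joined to
   the binding data.

`regstage` implements this analysis as a reusable, tested R pipeline, and
ships a synthetic-data generator with planted ground truth so every stage
can be validated end to end.

## The statistics at its core

- **Summit-proximity overlap.** Two peaks overlap iff their summits lie
  within ±200 bp on the same chromosome (closed bound). Peak sets are
  merged by single-linkage clustering of summits at that threshold; each
  cluster is one *union peak* with a membership signature (e.g. `ABC`),
  giving Venn counts directly.
- **Bootstrap overlap significance.** For sets A, B, C with union pool of
  size N, each null iteration keeps one actual set (rotating round-robin)
  and replaces the other two by random 400-bp peak sets of matching
  population drawn from the pool. With observed three-way overlap *s* and
  pooled null mean μ and s.d. σ over 50,000 iterations,
  `z = (s − μ)/σ` and `P = 1 − Φ(z)` (computed in log space, so P values
  far below double underflow are still reported as log₁₀ P).
- **Peak-to-gene allocation.** The summit is assigned to a gene if it lies
  in the strand-aware promoter window (−2,000 bp … +500 bp around the
  TSS), else inside the gene body (*intragenic*), else to the nearest TSS
  within 100 kb (*intergenic*); precedence promoter > intragenic >
  intergenic.
- **Trinary expression codes.** Per stage transition, a gene is `1`
  (≥ two-fold up), `0` (≥ two-fold down) or `2` (invariant); the digit
  string over ordered transitions groups genes into at most 3ᵏ patterns
  (27 for three transitions). Pairing the uninduced digit with the induced
  digit yields response classes such as `12` = "not upregulated" for bound
  genes.
- **Motif co-localization.** PWM hits (log₂-odds vs background) are
  collected within ±200 bp of summits; a peak counts for a motif pair if
  two instances lie within 20 bp center-to-center. A bootstrap over random
  pool peak sets converts pair counts into a z-score matrix.
- **Composite profiles.** Mean per-peak tag density in 50-bp bins over
  ±5,000 bp around summits, normalized per million tags.

## Worked example

```r
library(regstage)

g  <- sim_genome(2, 3e5, 42); sz <- chrom_sizes(g)
ps <- sim_peak_sets(c(ABC = 50, AB = 20, A = 30, B = 10, C = 40), sz,
                    summit_jitter_sd = 25, seed = 42)
venn_counts(merge_union(ps$sets, 200))$counts
#>   A  AB ABC   B   C
#>  30  20  50  10  40        # planted Venn recovered exactly

cfg <- analysis_config(n_bootstrap = 2000, rng_seed = 42)
bootstrap_peak_overlap(ps$sets, cfg)
#> Bootstrap peak overlap: observed = 50, null = 32.08 +/- 3.40 (n = 2000)
#>   z = 5.27, one-sided P = 6.92e-08 (log10 P = -7.16)

se <- sim_expression(900, noise_sd = 0.2, seed = 42)
fc <- fold_changes(se$expr, stage_comparisons(se$expr))
group_patterns(trinarize(fc), cfg)
#> PatternGroups: 9 populated codes over 900 genes; 8 retained
#>  02  11  10  12  22  00  21  01  20
#> 115 106 105 102 102 101  91  90  88

z_to_p(23.36)$p_one_sided
#> [1] 5.453231e-121
```

The planted Venn counts come back exactly because the generator spaces
anchor sites so that summit clustering cannot chain distinct clusters; the
observed three-way overlap (50) sits 5.3 null s.d. above the resampling
mean; 900 genes with planted trinary codes populate all 9 two-transition
patterns, and every group except all-invariant `22` is retained under the
">30 genes" rule; `z_to_p` reproduces the deep-tail P value for z = 23.36.

A full simulated end-to-end run (twelve TSV outputs plus a reproducibility
manifest):

```r
run_pipeline("out_dir", analysis_config(n_bootstrap = 2000, rng_seed = 1))
```

or from the shell:

```sh
inst/cli/regstage run-all --out out_dir --seed 1 --iters 2000
```

## Layout

- `R/` — core types and I/O, synthetic generators, peak operations,
  bootstrap machinery, expression coding, binding×expression integration,
  motif scanning/co-localization, signal profiles, pipeline + CLI.
- `src/` — Rcpp kernels: summit clustering, the bootstrap null loop, PWM
  window scoring.
- `vignettes/stage-resolved-binding-expression.Rmd` — the methods
  vignette: model, parameters, null designs, generator assumptions and
  limitations.
- `tests/testthat/` — unit, property and oracle tests per module plus
  `test-acceptance.R` (one test per acceptance criterion).
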
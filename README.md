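# riboqc

Quality control and RNase digestion diagnostics for ribosome profiling
(ribo-seq), with a synthetic footprint simulator built around an explicit
digestion-completeness model.

## The problem

Ribosome profiling sequences the ~28 nt mRNA fragments (ribosome-protected
footprints, RPFs) that an 80S ribosome shields from RNase digestion. The
step that defines data quality is the digestion itself: when the RNase
concentration in the lysate is too low — typical for low-input samples such
as brain slices, where enzyme amounts are scaled to RNA input — digestion is
incomplete. Incompletely digested libraries show a characteristic syndrome:

* footprints are **longer** than the canonical ~28 nt;
* footprints are **GC-rich** relative to the ~50% GC of completely digested
  RPFs (even though mammalian CDS is ~60% GC);
* triplet **frame periodicity degrades**;
* more reads fall **outside the CDS** (5'UTR/3'UTR contamination);
* expression estimates acquire **batch effects** that can dominate the
  biological signal on PC1 of a sample PCA.

`riboqc` computes the sequence-level diagnostics that expose this syndrome,
plans RNase titration experiments to locate the optimal digestion condition,
and ships a simulator that generates footprints with a tunable digestion
completeness so every metric can be validated against ground truth without
sequencing data.

## The core metrics and model

For footprints mapped to CDS, the package computes the per-position base
composition; the **windowed GC** is the mean G+C fraction over 5'-anchored
positions 10–20 (1-based, inclusive),

    GC_win = 100 / 11 * sum_{p=10}^{20} [ f_G(p) + f_C(p) ],

where `f_b(p)` is the fraction of reads of length ≥ p carrying base `b` at
position `p`. The **length peak** is the mode of the footprint length
histogram. P-site offsets per read length are estimated by the start-codon
metagene method (argmax over offsets `o ∈ [L/4, L/2]` of the 5'-end density
at `CDS_start − o`), frames as `(P-site − CDS_start) mod 3`. For a
`fold`-fold titration with steps `k = 1..K` the per-step enzyme amount is
`base · fold^(k−1)` and the decision readout is the Pearson correlation of
`GC_win` and of the length peak against `log_fold` concentration — strongly
negative under a digestion-completeness gradient.

The simulator inverts this logic: a completeness parameter `c ∈ (0, 1]`
drives modal length `28 + round(5·(1−c))`, a GC acceptance tilt
`exp(β·(1−c)·(GC−0.5))`, frame fidelity `floor + (0.9−floor)·c`, and UTR
contamination `0.3·(1−c)`, plus RNase A+T1 end biases (5' A enrichment, 3'
C/T/G cut preference), 8 nt UMIs and geometric PCR duplication. See the
methods vignette (`vignettes/digestion-qc.Rmd`) for every parameter and the
reasoning behind the defaults.

## Worked example: reading a titration series

Simulate a 5-step titration in which digestion completeness rises with
RNase concentration, then ask the package which condition to use:

```r
library(riboqc)
library(dplyr)

tx <- generate_transcriptome(150, cds_gc_target = 0.50, seed = 100)
grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)   # completeness per concentration step
res <- purrr::map_dfr(seq_along(grid), function(i) {
  sim <- simulate_footprints(tx, digestion_params(completeness = grid[i],
                                                  seed = 100 + i),
                             n_reads = 20000)
  fp <- mark_duplicates(load_sim_footprints(sim)) |> filter(category == "unique")
  glance(qc_report(fp, tx, sample_id = paste0("conc", i))) |> mutate(step = i)
})
res |> select(step, gc_window_mean, length_peak, frame_f0, cds_fraction)
#>    step gc_window_mean length_peak frame_f0 cds_fraction
#> 1     1           57.6          32    0.525        0.754
#> 2     2           55.9          31    0.626        0.817
#> 3     3           53.9          30    0.722        0.879
#> 4     4           52.1          29    0.819        0.937
#> 5     5           49.9          28    0.915        0.999

correlate_metrics(res, fold = 5)
#>     r_gc r_length
#> 1 -0.999       -1

recommend_condition(res)
#>   step qualified rationale
#> 1    5      TRUE lowest step meeting GC 49.9% (target 50 +/- 2) and modal
#>                  length 28 nt (target 28-29) without monosome disassembly
```

Reading the table: at the lowest concentration the footprints are long
(32 nt), GC-rich (57.6%), poorly framed (53% in-frame) and 25% of them sit
outside the CDS — the full incomplete-digestion syndrome. Both diagnostics
fall essentially linearly on the log5 concentration axis (r ≤ −0.99), and
the highest step reaches the complete-digestion signature (~50% GC, 28 nt),
so it is recommended.

`plot_composition()`, `plot_length_distribution()`, `plot_titration()` and
`autoplot()` on `qc_report` / `pca_top_variable()` objects give the
corresponding figures. A thin command-line wrapper with `simulate`, `prep`,
`dedup`, `qc`, `titrate` and `expr` subcommands is installed at
`inst/cli/riboqc.R`.

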
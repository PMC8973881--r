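# ipdkin

Kinetic signals in single-molecule real-time (SMRT) sequencing are
ambiguous: a raised interpulse duration (IPD) — the time between the
fluorescence pulses of consecutively incorporated nucleotides — can mean a
covalently modified base (e.g. N6-methyladenine slowing the polymerase) or
a purely sequence-intrinsic effect of the local context (G-quadruplex-prone
runs, quasi-palindromes and other non-B DNA). `ipdkin` implements the
analysis that separates the two: pair a **native** sample with a
**whole-genome-amplified (WGA)** negative control in which covalent marks
have been erased, and call a locus or motif modified only when its kinetic
signal is present in the native sample but absent from the WGA sample.

For a motif with focal base $b$ (say the adenine of GATC), the package
computes

- the **ratio of increase**
  $\;\overline{\mathrm{IPD}}_{\text{motif},b} \,/\,
  \overline{\mathrm{IPD}}_{\text{genome},b}$ — the sequence-context effect,
  present in native *and* WGA samples, tested with a Wilcoxon rank-sum
  against all same-base sites; and
- the **native/WGA fold**
  $\;\overline{\mathrm{IPD}}_{\text{native}} \,/\,
  \overline{\mathrm{IPD}}_{\text{WGA}}$ over the focal loci — the
  modification signal, with a rank-sum p-value.

Around these sit the full workflow: per-site aggregation of read-level
IPDs (neighbour-match validity, robust log2-Tukey outlier trimming,
coverage ≥ 25 per strand, MapQ > 127 alignment filtering), IUPAC motif
scanning and per-position profiles with flanks, top/bottom-1% extreme-IPD
locus detection with 41-bp FASTA window export for motif discovery,
genomic-feature enrichment (two-sided binomial, BH q-values), and
concordance statistics (Pearson r, R², RMSE on log2 IPDs; replicate
log2-ratio vs. minimum coverage). A calibrated synthetic kinetics
generator — log-normal pulses around per-base mean IPDs (A 1.38, C 0.95,
G 1.00, T 0.65), Poisson per-strand coverage, planted motifs with known
context and modification multipliers — makes every analysis testable with
ground truth and no sequencing data.

## Worked example

Simulate a 30 kb genome with 100 planted GATC sites whose focal adenine is
modified (8.57× slower in the native sample only), sequence both
conditions at coverage 30 per strand, aggregate, and compare:

```r
library(ipdkin)

sim <- generate_genome(30000, gc_fraction = 0.36,
                       plant_specs = list(plant_spec("GATC", focal_offset = 1,
                                                     count = 100,
                                                     mod_multiplier = 8.57)),
                       seed = 1)
cfg    <- kinetics_config()
native <- simulate_reads(sim, sim$planted, cfg, mode = "native", seed = 2)
wga    <- simulate_reads(sim, sim$planted, cfg, mode = "wga",    seed = 3)

nat_sites <- aggregate_sites(native)
wga_sites <- aggregate_sites(wga)

genome_base_means(wga_sites)
#> # A tibble: 4 × 3
#>   ref_base mean_ipd n_sites
#>   <chr>       <dbl>   <int>
#> 1 A           1.37    15277
#> 2 C           0.945    8549
#> 3 G           0.995    8667
#> 4 T           0.645   15290

compare_native_wga(nat_sites, wga_sites, planted_loci(sim))
#> # A tibble: 1 × 6
#>   n_loci n_skipped mean_native mean_wga native_wga_fold native_wga_p
#>    <int>     <int>       <dbl>    <dbl>           <dbl>        <dbl>
#> 1     60        40        11.5     1.36            8.49     3.56e-21
```

The per-base means come back at their configured values (the WGA sample
carries no modification signal), and the native/WGA comparison at the
planted loci recovers the 8.57-fold slowdown (8.49 here, n = 60 loci
surviving the coverage filter in both samples) at p ≈ 4·10⁻²¹ — a
modification call. Running the same comparison between two WGA replicates
returns a fold of ≈ 1.

The full study-shaped workflow is one call:

```r
cfg <- system.file("extdata", "demo_config.json", package = "ipdkin")
summary <- run_pipeline(cfg, "demo_run")
```

which simulates paired native/WGA data with a planted modified GATC and a
null ATGCAT motif, and reports GATC — and only GATC — as modified
(native/WGA fold 2.59 over all 235 scanned GATC focal loci, p ≈ 2·10⁻⁵,
against a ratio of increase of ≈ 1.0 in the WGA sample), plus extreme-loci,
replicate-concordance and per-stage outputs under `demo_run/`. Profiles,
histograms and replicate-ratio tables all have `autoplot()` methods;
result objects have `tidy()`/`glance()` methods.

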
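# ClearQuant

Depth-resolved signal-intensity quantification for tissue optical-clearing
studies.

## The problem

Tissue optical clearing (immersion in agents such as BABB — benzyl alcohol
+ benzyl benzoate — or glycerol) renders specimens transparent so that
multiphoton autofluorescence (AF) and second harmonic generation (SHG)
imaging can reach deeper structures. Judging *how well* a protocol clears
requires a depth-resolved measurement: light attenuates through tissue
approximately by the Beer–Lambert law,

    I(z) = I0 · exp(−μ_eff · z),

so a clearing protocol is better when the effective attenuation μ_eff is
smaller and signal survives deeper. ClearQuant is for imaging labs and
methods developers who need to turn z-stacks from such experiments into a
defensible, reproducible group comparison.

## What the package computes

For every experiment (one z-stack, one channel):

1. **Depth–intensity profile** — per-slice mean intensity (whole frame or
   ROI mask), depth of slice *k* = *k* · Δz.
2. **Normalization** — depth / z_max (the stack's maximum imaging depth)
   and intensity / 255, putting every experiment on the unit square.
3. **Reproducing-kernel smoothing** — a meshfree approximant
   y_h(u) = Σᵢ Ψᵢ(u) yᵢ built from a cubic B-spline kernel and a linear
   basis (partition of unity, exact linear reproduction), evaluated on the
   common grid u = 0, 0.005, …, 1 (201 points).
4. **AUC** — the area under the normalized intensity curve, a
   dimensionless transparency statistic in [0, 1].
5. **Group statistics** — per-group summaries (n, mean ± SD, median,
   Q1/Q3), Shapiro–Wilk-gated one-/two-way ANOVA (type-II SS) or aligned
   rank transform for non-normal data, Tukey HSD or Holm-adjusted rank
   contrasts post hoc, and `*` / `**` / `***` significance stars.

A Beer–Lambert study simulator (`syntheticSpec()`, `simulateStudy()`) with
hierarchical specimen/region variability, detector noise and 8-bit
quantization makes every stage testable without raw imaging data, and
`fitMuEff()` recovers attenuation coefficients from profiles.

## Worked example

Simulate a six-group clearing-by-fixation study (BABB / glycerol /
uncleared × fixed / unfixed, AF + SHG channels, 3 specimens × 3 regions
per group) and analyze it end-to-end:

```r
library(ClearQuant)

cfg <- runConfig(outdir = "demo", seed = 42,
                 stats = list(factors = c("clearing", "fixation")))
sim <- runSimulate(cfg)                    # writes profiles.csv, design.csv
cfg$input  <- sim$profile_csv
cfg$design <- sim$design_csv
res <- runAnalyze(cfg)                     # writes auc.csv, curves.csv, ...

subset(res$summaries, channel == "AF")
```

```
  group n    mean      sd  median      q1      q3
   BABB 9 0.13085 0.01540 0.13260 0.12143 0.14433
 BABB-F 9 0.06608 0.01726 0.07562 0.04530 0.07778
    GLY 9 0.01712 0.00161 0.01708 0.01644 0.01824
  GLY-F 9 0.05674 0.01945 0.04794 0.04361 0.06776
     NC 9 0.00680 0.00111 0.00659 0.00597 0.00765
   NC-F 9 0.00757 0.00069 0.00788 0.00723 0.00806
```

BABB-cleared tissue retains by far the most signal at depth (mean AF-AUC
0.131), glycerol is intermediate (0.017) and uncleared tissue is nearly
opaque (0.007); fixation lowers BABB's AUC but raises glycerol's — a
crossover. The statistics report reflects exactly that: the residuals are
non-normal (Shapiro–Wilk p = 0.005), so the pipeline routes to the aligned
rank transform,

```r
res$stats$AF$main
```

```
            effect statistic df1 df2        p stars
          clearing    198.50   2  48 6.15e-24   ***
          fixation      5.76   1  48 2.03e-02     *
 clearing:fixation    252.75   2  48 3.27e-26   ***
```

i.e. a dominant clearing effect and a strong clearing-by-fixation
interaction. Every output CSV carries a provenance header with the package
version and a hash of the analysis configuration; rerunning with the same
seed and config reproduces the tables byte for byte.

A thin CLI over the same functions ships in `inst/scripts/clearquant`
(subcommands `extract`, `analyze`, `simulate`, `report`; YAML configs via
`--config`, all defaults shown by `--print-config`).

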
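# neuropilr

Morphometry of densely reconstructed cortical neuropil from volume
electron microscopy, built around an adult-versus-aged comparison of
layer-1 somatosensory cortex: does aging thin out synapses, and if so,
what happens to the synaptic surface budget, the excitatory/inhibitory
balance, and the correlations that tie spine, bouton and synapse sizes
together?

The package implements the full measurement layer over two kinds of
input — point annotations of synapses in large imaged stacks, and
triangle-mesh reconstructions of everything inside 5 × 5 × 5 µm
sub-volumes — plus a synthetic neuropil generator with exact ground truth
so every estimator is testable without any image data.

## What it computes

* **Unbiased synapse densities** in a counting brick with three inclusion
  and three exclusion planes: per-category censuses (asymmetric /
  symmetric × spine / shaft × single / multi-synaptic bouton),
  multi-synaptic-bouton censuses, and the inhibitory/excitatory ratio
  E/I = (symmetric density)/(asymmetric density).
* **Synapse sizes** from the maximum-diameter proxy: the caliper width of
  the contact mesh on the serial section (slab of configurable pitch,
  default 6 nm) where it appears largest; quadratic OLS calibration
  `area = a₀ + a₁d + a₂d²` against true contact area; log-normal peak
  fits `f(x) = A·exp(−ln²(x/c)/2w²)` to binned size histograms; and
  perforation counts from exact mesh topology (boundary loops / Euler
  characteristic).
* **Sub-volume morphometry**: neurite length densities (centerlines
  clipped exactly to the box), synapses per unit neurite length,
  asymmetric synaptic surface per µm of axon/dendrite and per µm³,
  complete-object size summaries, compartment volume fractions, and a
  mitochondria census including the donut (toroidal) fraction.
* **Vesicle profiles**: exact center-to-membrane distances, 30-nm binned
  profiles normalized by contact area, per-bouton vesicle densities.
* **Group statistics**: mean ± SEM summaries, pooled/Welch t-tests,
  two-sample KS tests, linear fits, regression-slope comparison via the
  pooled interaction model, and percent-change arithmetic.

The published per-animal measurement tables ship as plain-text fixtures
(decimal commas normalized at ingest), so the group-level arithmetic is
reproducible offline; `reproduce_paper()` recomputes every derivable
quantity and flags the few printed values that do not follow from the
printed tables.

## Worked example

```r
library(neuropilr)

t1 <- load_table1()                      # per-animal densities, 6 animals
dens <- t1$n_included / t1$volume_um3
group_summary(dens[t1$group == "adult"], "adult")
#> adult: 1.407 +/- 0.00602 (mean +/- sem, n = 3)
group_summary(dens[t1$group == "aged"], "aged")
#> aged: 1.173 +/- 0.013 (mean +/- sem, n = 3)

ei_ad <- mean(ei_ratio(t1[t1$group == "adult", ]))   # 0.1232
ei_ag <- mean(ei_ratio(t1[t1$group == "aged", ]))    # 0.0785
percent_change(ei_ad, ei_ag)
#> [1] 36.31401
```

Aged layer 1 holds about 16% fewer synapses per µm³, and the loss is
relatively larger for symmetric (inhibitory-type) contacts, so the
inhibitory-to-excitatory density ratio drops by roughly a third.

The same pipeline runs on synthetic data with known truth:

```r
cfg <- neuropil_config()                 # adult study conditions
st  <- simulate_stack(cfg, seed = 11)
cen <- density_census(st$markers, st$brick)
round(cen$total, 3)                      # programmed total is 1.392
#> [1] 1.418

sv <- simulate_subvolume(cfg, seed = 21)
round(length_density(sv$sub, "axon"), 2) # programmed 8.15 um/um^3
#> [1] 8.18
```

The numbered scripts under `analysis/` chain these steps into the full
workflow (simulate → census → sizes → sub-volume metrics → vesicles →
reproduction table) and write their tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

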
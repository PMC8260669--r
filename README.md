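# paleoevo

Molecular-evolution inference for plant genomes: structural detection and
Jukes–Cantor dating of intact LTR retrotransposons, superfamily/lineage
classification, collinear (syntenic) block detection, syntenic-depth tests
for whole-genome duplication (WGD), and Ks/4dTv distributions with kernel
peak detection — together with a synthetic-genome simulator that plants
elements of known age, paralog pairs of known Ks, and a known collinear
layout, so every estimator ships with ground-truth recovery tests.

It is aimed at researchers studying genome evolution in lineages such as
the Cactaceae, where a recent WGD and massive LTR-RT expansion dominate
genome structure, and at method developers who want an oracle-checkable
reference implementation of this classic analysis stack.

## The methods at the core

* **Insertion dating.** An LTR-RT inserts with two identical long terminal
  repeats. Given the observed divergence λ between an element's two LTRs,
  the JC-corrected distance is `K = −(3/4)·ln(1 − 4λ/3)` and the insertion
  time is `T = K / (2r)`, with `r = 7.0e−9` substitutions/site/year by
  default. Elements with λ ≥ 0.75 are saturated and excluded.
* **Detection.** Seed-and-extend direct-repeat search with target-site
  duplication and TG…CA terminus refinement, gapped-identity scoring, and
  greedy conflict resolution.
* **Synteny.** Dynamic-programming anchor chaining in gene-rank coordinates
  (MCScanX-style), blocks of ≥5 pairs by default; syntenic depth per
  reference gene, with modal depth 2 diagnostic of a 1:2 copy ratio.
* **Ks/Ka and 4dTv.** Nei–Gojobori pathway counting with JC correction on
  codon-aware alignments; raw fourfold-degenerate transversion proportion;
  Gaussian-KDE peak detection over pair distributions; declarative WGD/WGT
  event calls.

## Worked example

Simulate a genome with 60 planted elements (20 each at 0.5, 2 and 5 Myr),
detect them, and date the insertions:

```r
library(paleoevo)

cfg <- sim_config(seed = 42, r = 7e-9, ltr_length = 300)
sim <- simulate_ltr_genome(cfg, ages = c(5e5, 2e6, 5e6), n_per_age = 20)
det <- scan_ltr_pairs(sim$genome, min_sep = 500, max_sep = 5000)
rec <- date_elements(det, sim$genome, r = 7e-9)
head(rec[rec$status == "ok", ], 3)
#>   element_id aligned_sites mismatches  lambda      K T_years status
#> 1   cand0001           300          2 0.00667 0.0067  478320     ok
#> 2   cand0002           300          0 0.00000 0.0000       0     ok
#> 3   cand0003           300          0 0.00000 0.0000       0     ok
```

All 60 planted elements are recovered (58 with exactly the planted
coordinates), and the mean estimated ages per planted class are 0.35, 1.80
and 5.44 Myr. Each 300-bp LTR pair at 0.5 Myr carries only ~2 expected
mismatches, so means over 20 elements are noisy; at the 500-elements-per-age
scale of the test suite, recovery lands within 5% of every planted age.

Peaks in a paralog-divergence distribution:

```r
w <- simulate_wgd(simulate_genes(120, cfg), cfg, copies = 2,
                  ks_target = c(0.7, 0.3))
ks <- w$truth$pairs$ks_true
detect_peaks(ks)
#> <peak_call> 2 peak(s) from 240 values (bw=0.06058)
#>   at: 0.298, 0.699
```

the two planted duplication rounds resurface as modes at ≈0.3 and ≈0.7.

A command-line entry point mirroring these functions is installed at
`inst/cli/paleoevo` (`paleoevo simulate | ltr-scan | ltr-date |
ltr-classify | synteny | ksdist | wgd-report | pipeline`); `--seed`
propagates to every stochastic stage and reruns are byte-identical.

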
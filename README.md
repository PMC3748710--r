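# chromassay

Quantification toolkit for in vitro chromatin assembly and remodeling
assays, with a ground-truthed synthetic-data generator for end-to-end
validation.

## The problem

ATP-dependent motor proteins (Chd1, ISWI-family factors) cooperate with
histone chaperones to assemble nucleosomes on DNA and to space them into
periodic arrays. Dissecting *assembly* from *spacing/remodeling*
experimentally relies on three gel-based readouts, each of which needs
careful, convention-laden quantification:

* **Partial MNase digestion ladders.** MNase cuts linker DNA between
  nucleosomes; periodic arrays give sharp di-/tri-nucleosome bands, random
  arrays a smear. The **spacing index** summarizes a lane's densitometry
  trace as

  SI = ½ (P₂ + P₃) − V

  where P₂ and P₃ are the di- and tri-nucleosome peak heights and V the
  valley minimum between them. Higher SI = more periodic chromatin. Only
  comparable across lanes of one gel.

* **DNA supercoiling assay.** Nucleosome formation on relaxed circular DNA
  with topoisomerase I drives ΔLk ≈ −1 per nucleosome. Percent
  supercoiling = 100 · SC / (SC + Rel + N), with nicked DNA counted in the
  total but never in the supercoiled amount.

* **Kinetics.** Initial rates per nM motor; first-order progress curves
  y = y₀ + A(1 − e^(−kt)) with t₁/₂ = ln2/k; single-exponential
  nucleosome-sliding fits; Michaelis–Menten ATPase fits
  k_obs = k_cat[S]/(K_m + [S]) after basal correction; and mutant/wild-type
  relative rates with quadrature error propagation.

The package also simulates the whole measurement chain — hard-core
nucleosome arrays, linker-only MNase digestion with trimming, semi-log gel
mobility with mass-proportional staining, supercoiled/relaxed/nicked lanes,
and the sequential two-step assembly → spacing kinetic scheme — returning
exact ground truth alongside every simulated observable. See
`vignettes/chromassay-methods.Rmd` for models, assumptions, and defaults.

## Worked example

```r
library(chromassay)

# a lane from regularly spaced arrays vs one from random arrays
lane <- simulate_mnase_lane("spaced", seed = 42)
compute_spacing_index(subtract_background(lane, window = 300))
#> <spacing_index_result> 'spaced': P2=1.4e+03 (at 571), P3=1.13e+03 (at 482), V=0 (at 521)
#>   spacing index = 1266
compute_spacing_index(subtract_background(
  simulate_mnase_lane("random", seed = 42), window = 300))
#> <spacing_index_result> 'random': P2=623 (at 589), P3=515 (at 493), V=202 (at 534)
#>   spacing index = 367.8
```

The spaced-array lane scores ~3.4× higher: distinct di-/tri-nucleosome
bands with an empty valley, versus the residual smear of random arrays.
Peak positions (571, 482 px) sit at the calibrated migrations of the
347 bp and 547 bp trimmed di-/tri-nucleosome fragments.

```r
# supercoiling quantification against generator ground truth
sc <- simulate_supercoiling_lane(0.6, nick_fraction = 0.2, seed = 7)
attr(sc, "truth")$percent_supercoiling
#> [1] 49
quantify_supercoiling(subtract_background(sc, window = 200))
#> <supercoiling_result> 'lane': SC=5.062e+04 Rel=3.168e+04 N=2.131e+04 -> 48.86% supercoiling

# two-step kinetics: the overall process is slower than either step
f <- fit_first_order(simulate_two_step(two_step_params(),
                                       observable = "overall_spacing", seed = 9))
f
#> <kinetic_fit> first_order: k = 0.1669 +/- 0.018 /min, A = 67.21 +/- 3, t1/2 = 4.153 min, r^2 = 0.9801
two_step_half_time(0.25, 0.6)   # exceeds ln2/0.25 = 2.77 and ln2/0.6 = 1.16
#> [1] 4.577912

# relative rate with propagated uncertainty
relative_rate(0.045, 2.2, 0.009, 0.2, digits = 1)
#> <relative_rate> 2 +/- 0.4 % (unrounded 2.045 +/- 0.4494)
```

The recovered 48.86% supercoiling is within one point of the lane's exact
sampled truth (49%); the fitted overall half-time (4.15 min) exceeds both
individual half-times, the kinetic signature of a sequential two-step
mechanism.

## Command line

```sh
inst/cli/chromassay simulate lane --seed 3 --out lane.csv
inst/cli/chromassay spacing-index --profiles lane.csv \
    --background rolling_minimum:300 --out spacing.csv
inst/cli/chromassay supercoil --profiles a.csv,b.csv --reference amp_pnp --out sc.csv
inst/cli/chromassay kinetics relative --mutant 0.045 --reference 2.2 \
    --mutant-se 0.009 --reference-se 0.2 --digits 1
inst/cli/chromassay demo --seed 1 --out demo_out/
```

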
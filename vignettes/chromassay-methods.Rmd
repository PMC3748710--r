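---
title: "chromassay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromassay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromassay)
```

## Scope

`chromassay` quantifies the three gel-based readouts used to dissect
ATP-dependent chromatin assembly from ATP-dependent remodeling (spacing):

1. **partial MNase digestion ladders**, summarized by the di-/tri-nucleosome
   *spacing index*;
2. **DNA supercoiling assay lanes**, summarized by *percent supercoiling*;
3. **kinetic measurements** — initial rates, first-order progress curves,
   single-exponential nucleosome-sliding fits, Michaelis–Menten ATPase fits
   with basal correction, and mutant/wild-type relative rates with
   propagated uncertainty.

A synthetic-data generator produces ground-truthed nucleosome arrays, MNase
digests, rendered gel lanes, supercoiling lanes, and two-step kinetic time
courses, so every analysis stage is validated against known truth without
any external data.

## The spacing index

Partial MNase digestion of chromatin cuts accessible linker DNA and leaves a
ladder of mono-, di-, tri-nucleosome fragments. On a densitometry trace of
such a ladder, let $P_2$ and $P_3$ be the peak heights of the di- and
tri-nucleosome bands and $V$ the minimum of the valley between them. The
spacing index is

$$\mathrm{SI} = \tfrac{1}{2}(P_2 + P_3) - V.$$

Periodic arrays give sharp, well-separated bands (large $\mathrm{SI}$);
randomly positioned nucleosomes give a smear (near-zero $\mathrm{SI}$). The
index is invariant under additive intensity shifts and scales linearly with
intensity, so it is **only comparable across lanes run and imaged under
identical electrophoretic conditions** — the package never compares indices
across gels on its own.

Notational caveat: primary descriptions of this statistic label the valley
inconsistently ("V2" in one place, "V3" in another); `chromassay` calls it
simply `V`.

Operational choices the statistic itself does not pin down (all exposed as
arguments):

* **Band windows.** Either given explicitly in migration units or derived
  from the semi-log mobility calibration: an MNase-trimmed fragment of $k$
  nucleosomes spans $k$ footprints plus $k-1$ linkers, i.e. expected lengths
  $k\,r - \ell$ for repeat $r$ and linker $\ell = r - f$; windows are
  centred at the corresponding migrations with half-width 20% of the di–tri
  spacing.
* **Peak height, not area** — the statistic is defined in heights.
* **Valley** — global minimum strictly between the two detected peak
  positions, ties broken toward the midpoint.
* **Background** — `rolling_minimum` is implemented as a morphological
  opening (running minimum then running maximum over the same window).
  Opening is exactly idempotent, never exceeds the signal, and — unlike a
  bare running minimum — does not sit $\sim 2\sigma$ below zero in flat
  noisy regions, which would otherwise bias integrals taken downstream. The
  window must be wider than the widest feature to preserve: for ladder
  lanes that means wider than the di–tri band spacing (~90 px at default
  calibration), or the inter-peak valley is absorbed into the baseline. The
  demo pipeline uses 300 px. Smoothing before peak reading is deliberately
  off by default.

## Percent supercoiling

Nucleosome formation on relaxed closed-circular DNA in the presence of
topoisomerase I changes the linking number by roughly $-1$ per nucleosome.
After deproteinization, lanes resolve supercoiled (SC), relaxed-topoisomer
(Rel), and nicked open-circular (N) species. The package computes

$$\%\,\mathrm{SC} = 100 \times \frac{\mathrm{SC}}{\mathrm{SC} +
\mathrm{Rel} + \mathrm{N}}.$$

Nicked DNA cannot be assigned to chromatin or naked DNA from the gel, so it
is counted in the denominator but never in the numerator; increasing only
the nicked signal therefore strictly decreases the percentage. Species
intensities are trapezoidal integrals over disjoint migration windows; the
relaxed "species" window spans the whole topoisomer cluster. Intermediate
topoisomers belong to whichever window contains them — windows must tile
without overlap. Changes in percent supercoiling (`delta_supercoiling`)
require identical windows in sample and reference; the reference (matched
AMP-PNP lane or zero-time lane) is an explicit argument, never guessed.

## Kinetic models

* **Initial rate**: OLS slope over the first $n$ points, divided by motor
  protein concentration (units: observable per minute per nM).
* **First-order / single-exponential**: $y = y_0 + A(1 - e^{-kt})$ by
  nonlinear least squares (`stats::nls`, port algorithm) with deterministic
  multi-start — $k_0$ from a log-linear regression of the residual
  amplitude, plus $0.5\times$ and $2\times$ perturbations. $t_{1/2} =
  \ln 2 / k$ holds exactly for every returned fit. The baseline $y_0$ is
  fitted by default because gel-derived observables carry lane-dependent
  baselines; simulations with a known zero baseline may pin it.
* **Michaelis–Menten**: observed ATPase rates are basal-corrected as
  $k_\mathrm{obs} - k_\mathrm{basal}$ before fitting
  $k_\mathrm{obs} = k_\mathrm{cat}[S]/(K_m + [S])$. (A literal reading of
  the originating protocol would subtract the stimulated rate *from* the
  basal rate, which yields negative activities; the package uses the only
  direction consistent with positive turnover numbers.) Substrate
  concentrations above 500 nM only warn — the assay's usual range — and
  non-positive corrected rates abort the fit loudly.
* **Relative rates**: $100 \times k_\mathrm{mut}/k_\mathrm{wt}$ with SE
  propagated in quadrature on relative errors,
  $\mathrm{SE}_\% = \% \sqrt{(\mathrm{SE}_m/m)^2 + (\mathrm{SE}_w/w)^2}$,
  and display rounding half-away-from-zero to the printed precision. The
  propagation method for published ATPase uncertainties is not documented
  upstream; quadrature reproduces published sliding-rate uncertainties but
  differs slightly (±3.7 vs ±3) for one ATPase entry, so only central
  values are treated as reproducible.

## The synthetic world

The generator encodes one fixed "stated world"; its defaults were chosen
once, on the grounds below, and are not tuned against test outcomes.

* **Template**: 3,000 bp circular plasmid (typical assay plasmids are a few
  kb; the exact size is unstated upstream and is configuration, not a
  constant). Footprint 147 bp — the canonical core-particle length. Repeat
  200 bp, a typical assembled-array repeat.
* **Random arrays** are exact samples of the uniform hard-core measure
  (every configuration with all dyad distances $\ge$ footprint
  equiprobable), via constructive gap decomposition on the circle. This is
  deliberately *not* sequential insertion, whose stationary measure
  differs; tests compare against an independent whole-configuration
  rejection sampler.
* **Spaced arrays**: dyads at phase + $i\cdot$repeat with Gaussian jitter
  (default sd 5 bp), clamped so the exclusion holds.
* **MNase**: linker-only cutting, at most one uniformly placed cut per
  linker per digestion round (probability 0.5 by default), optional
  trimming back to the outermost footprint boundaries. Cut probability 1
  with trimming reproduces the extensive-digestion core-particle limit.
  Note that *untrimmed* inter-cut fragments spanning $k$ nucleosomes have
  modal length $k\,r$, while *trimmed* fragments peak at $k\,r - \ell$;
  window derivation assumes trimmed digests (the realistic case).
* **Gel rendering**: migration $= a + b\log_{10}(\mathrm{bp})$, $b < 0$;
  each species is a Gaussian band with area proportional to count ×
  length (mass-proportional intercalating-dye staining); additive Gaussian
  noise (sd 5) and linear drift (20 units full scale). Lanes pool 60
  molecules by default.
* **Supercoiling lanes**: 1,000 plasmids per lane; nicking independent of
  assembly; assembled closed circles at the supercoiled position with
  binomially sampled nucleosome counts, unassembled closed circles spread
  over a relaxed topoisomer cluster ($\Delta Lk$ 0, ±1). Stain intensity
  100 units/molecule: ethidium-stained plasmid bands sit far above camera
  noise, and this SNR is required for the ±2-point recovery the
  quantification promises at default noise.
* **Two-step kinetics**: assembly $k_1 = 0.25\,\mathrm{min}^{-1}$, spacing
  $k_2 = 0.6\,\mathrm{min}^{-1}$, amplitude 60, per-point noise 5% of
  amplitude — consistent with progress curves whose first-order fits have
  $r^2 > 0.95$, as reported for this class of assay. The overall observable
  is the terminal species of sequential $A \to B \to C$, with the
  degenerate equal-rates closed form $1 - e^{-kt}(1 + kt)$.

What the generator does **not** emulate: sequence-dependent positioning
energetics, partial topoisomer intermediates between Rel and SC, lane
distortions/smiles, saturation of stain or detector, and correlated
(non-white) densitometry noise. A green test therefore establishes that the
analysis recovers the truth of *this* world, not that it is robust to every
real-gel artifact.

## Simulation designs used in validation

Parameter-recovery studies simulate the *protocol*, not just the noise
model: each simulated experiment averages three replicate series (these
assays report means of $N = 3$) over a time grid that resolves the rise of
the curve, and fits the generating model (zero baseline pinned where the
generator has none). A single 11-point series at 5% noise carries a
relative Fisher information on $k$ of only ~8–13%, so demanding ±10%
recovery from it would fail for any estimator; the replicated design is the
statistically honest reading of the recovery requirement.

The half-time ordering check for the two-step scheme
($t_{1/2}^{\mathrm{overall}} > \max(t_{1/2}^{k_1}, t_{1/2}^{k_2})$, the
kinetic signature of a sequential mechanism) is verified on a closed-form
basis over a rate grid, with root bracketing on the terminal-species
solution — no simulation noise involved.

## Degenerate inputs and numerical choices

* Packing failures (too many nucleosomes for the template) are explicit
  errors, never silent truncation.
* A circular template with no cuts yields an *empty* fragment sample, and
  rendering an empty sample is an error (distinct from a flat lane).
* Flat profiles have spacing index exactly 0; coincident di/tri peaks are a
  degenerate-profile error; a window that misses the profile support is a
  band-not-found error, distinct from a zero-height band.
* Zero total signal in supercoiling windows is an undefined-result error,
  not 0%.
* Non-convergent fits raise errors carrying the collected optimizer
  messages; no silent default parameters.
* All randomness flows from one integer seed per operation; outputs are
  bitwise reproducible given the seed.

## Known limitations

* No 2-D gels, chloroquine topoisomer counting, lane-finding from
  unannotated images, or nucleosome-number estimation from topoisomer
  distributions.
* Gel images are supported as numeric matrices or ASCII PGM only; no
  binary TIFF/PNG reader is available in the supported dependency set.
* Indices and percentages are comparable within one gel/run only; the
  package does not model inter-gel calibration.
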
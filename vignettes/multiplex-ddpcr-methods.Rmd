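---
title: "Methods: amplitude-coded multiplex ddPCR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplitude-coded multiplex ddPCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddplexr)
```

## The measurement model

Droplet digital PCR partitions a reaction into roughly 15,000–20,000
water-in-oil droplets, runs end-point PCR in each, and reads two end-point
fluorescence channels per droplet. If target molecules distribute
independently among droplets, the copy count per droplet is Poisson with
mean $\lambda$, so the fraction of positive droplets is
$p = 1 - e^{-\lambda}$ and the concentration follows from the inverted
relation

$$\hat\lambda = -\ln(1 - \hat p), \qquad
  C = \frac{\hat\lambda}{V_d}, \qquad
  \text{copies/reaction} = C \cdot V_r,$$

with droplet volume $V_d = 0.85\,\mathrm{nL}$ and reaction volume
$V_r = 20\,\mu\mathrm{L}$ by default. Only *accepted* droplets enter $\hat
p$; no dead-volume correction is applied, because the estimate is defined
on the read partitions.

Amplitude coding extends this to four targets in two channels: two assays
per channel are run at different primer/probe concentrations so their
positive clusters sit at distinct amplitude levels ("low" and "high"), and
droplets containing both same-channel targets form a third cluster above
the two, because end-point fluorescence of co-occupied droplets adds. With
three separation lines per channel the 2-D amplitude plane is cut into a
$4 \times 4$ grid: 15 positive cells (every non-empty subset of the four
targets) plus the all-negative cell. A target's positive cells are the 8
cells whose band on its channel contains it — bands $\{1,3\}$ for the
low-amplitude target, $\{2,3\}$ for the high one.

## Automatic line placement

The placement contract is: each line sits in the low-density valley
between two adjacent clusters ("in the middle between the clusters"). The
algorithm, per channel:

1. **Density valleys (primary).** A Gaussian kernel density estimate of
   the channel's amplitudes (Silverman's rule-of-thumb bandwidth, 512-point
   grid) is scanned for local maxima. Because sparse clusters (a
   double-positive cluster may hold fewer than ten droplets) produce a
   jagged estimate, modes are merged unless the valley between them drops
   below `valley_ratio` (default 0.5) of the lower peak — a relative
   prominence rule. If exactly one mode per expected band remains, each
   line is placed at the midpoint of the density minimum (of its flat
   plateau, when the inter-cluster density underflows to zero) between
   consecutive modes.
2. **1-D k-means (fallback).** If the mode count disagrees with the band
   count, k-means with $k$ = bands is run with deterministic
   initialisation and lines are placed midway between consecutive sorted
   centres. Quantile-based starting centres are tried first; in a typical
   well more than 95% of droplets are negative, so all quantile centres can
   land inside the negative cloud and Lloyd's algorithm then converges to a
   degenerate split of that cloud. Degeneracy is detected by requiring
   consecutive centres to be at least `resolution_floor` apart, and the
   fallback retries once with centres spaced evenly over the amplitude
   range, which is a good starting grid precisely because amplitude-coded
   clusters span the range roughly evenly.
3. **Refusal.** If the amplitude spread is below `resolution_floor`
   (default 1000 amplitude units — well above the width of a lone negative
   cluster, well below any real cluster spacing on this amplitude scale),
   or neither method resolves the requested bands, the channel raises an
   "insufficient cluster structure" error instead of guessing. This
   mirrors bench practice: wells with missing clusters cannot anchor
   automatic placement and need either manual lines (`set_line()`) or a
   grid carried over from a positive control.

The tie-break for an amplitude exactly on a line is the upper band; lines
live in near-empty valleys, so the choice is immaterial but must be fixed
for determinism. No spectral cross-talk compensation is applied between
channels.

Wells near the detection limit, or with an absent target, are analysed with
a grid derived from a positive control well — `simulate_dilution_series()`
does this automatically, proposing the grid on the undiluted control and
applying it to every series well. One-dimensional amplitude data cannot
distinguish *which* cluster is missing (an empty double-positive band and
an absent low-amplitude target both leave three modes), which is why the
package refuses rather than extrapolates.

## Confidence intervals

The interval is computed on the positive fraction $p$ and transformed to
the concentration scale through $-\ln(1-p)\,V_r/V_d$, which is monotone and
therefore preserves coverage. The default strategy is the Wilson score
interval: it is well-behaved at the extreme $p$ values routine in ddPCR
(a handful of positives among 15,000 droplets), never leaves $[0,1]$, and
always brackets the point estimate. A Wald ("normal") alternative is
provided as a named strategy. Coverage at the 95% level, checked by
simulation over $\lambda \in [0.01, 1]$ at 15,000 droplets, sits at the
nominal rate (the test suite asserts the empirical coverage falls in
$[0.92, 0.98]$ over 500 wells).

Saturated wells ($p = 1$) are reported with `lambda = Inf`, a flagged
`saturated` column and a finite lower bound only; they are data, not
errors, but must be excluded from downstream statistics.

## Performance rule set

* **Repeatability**: RSD $= 100 \cdot s/\bar x$ with the $n-1$ standard
  deviation.
* **aLOQ**: smallest mean measured copy number among levels with RSD
  $\le$ 25%. Outlier removal by the $1.5 \times$ IQR fence (quartiles by
  linear interpolation at position $(n-1)q$, i.e. `quantile type = 7` — the
  convention must be fixed for the rule to be reproducible) is optional,
  because published practice removes an outlying replicate before the RSD
  rule in borderline cases.
* **aLOD**: a replicate is positive at $\ge$ 3 positive droplets; a level
  detects when at most `max_negative_replicates` (default 1) replicates are
  negative. The default generalises the 14-of-15-replicates design to any
  replicate count rather than hard-coding 14.
* **Trueness**: signed percent bias $100(m - r)/r$; **proficiency**:
  $z = (m - a)/\sigma$ passing strictly below $|z| = 2$ (the boundary is
  evaluated with a $10^{-9}$ guard so that values that are exactly 2 up to
  floating-point round-off fail, as the strict rule intends).
* **Linearity**: OLS of measured on assigned copies on the linear scale
  (the scale of the dynamic-range plots), log10 optional; $R^2$ is the
  squared Pearson correlation. When recomputing a trueness table from
  *rounded* published means, note that biases can differ by 0.1 percentage
  points from values computed on the unrounded data; the package therefore
  anchors only rows that are stable under rounding.
* **Unit conversion**: copy-number ratio = mass fraction $\times$ factor
  (0.5 consensus, 0.4 male GM parent, 0.6 female); the two directions are
  exact inverses.
* **Labelling flags**: GM% $\ge$ 0.9 and $\ge$ 0.1 are flagged; no further
  regulatory logic.

## The droplet simulator

`simulate_well()` emulates exactly the data-generating process the
analysis assumes, with per-droplet ground truth so that classification and
quantification can be scored:

* occupancy: per target, full Poisson with
  $\lambda = (\text{copies}/V_r)\,V_d$ — multiple copies per droplet are
  allowed, but amplitude depends only on presence/absence, matching
  end-point chemistry;
* amplitude: per channel, baseline + additive increments of the
  same-channel targets present + Gaussian noise (baseline SD for empty
  droplets, cluster SD for occupied ones). Defaults — baseline 800 (SD 60),
  low increment 2200, high increment 4800, cluster SD 150 — are arbitrary
  instrument-like values chosen so cluster spacing/SD ratios resemble a
  well-run two-channel reader;
* rain: a `rain_fraction` subset of positive droplets is drawn uniformly
  between baseline and the droplet's full cluster mean on each positive
  channel. Real rain has no published quantitative distribution; the
  uniform law is a deliberate stand-in, isolated behind the configuration,
  that reproduces the failure mode that matters — high-amplitude rain
  falling into the low-amplitude target's band and registering as false
  positives there.

What the simulator does **not** emulate: droplet volume variability,
PCR-efficiency and inhibition effects, copy-number-dependent amplitude,
cross-channel spectral bleed, and instrument drift between wells. Passing
tests therefore demonstrate the correctness of the statistics and the
classification logic under the assumed model, not robustness to every
instrument artifact; on real data the manual-correction path and the
control-well workflow carry that weight.

## Problem sizes and numerical choices

The test suite and the acceptance script use wells of 15,000 droplets (the
typical accepted-droplet count of the platform), 4-plex layouts at 500
copies/reaction for recovery runs (100 wells), 500 simulated wells for
interval coverage, and 15-replicate dilution series over factors spanning
1 to 0.002 of a 1000-copy base for the aLOQ/aLOD/linearity workflow —
sizes chosen to match the validation designs the rules come from.
Per-well seeds are derived deterministically from a master seed
(`seed + 1000*level + replicate`), so every simulated experiment is
bit-reproducible. Simulation at 500 copies/reaction and 15,000 droplets
carries an intrinsic ~5.6% relative sampling error on each target's
estimate (binomial counting statistics), which bounds how often a perfect
analysis can land within any fixed relative distance of the truth; the
recovery tests should be read with that floor in mind.

All package errors are classed conditions (`ddplexr_error` subclasses), so
callers can distinguish "insufficient cluster structure" from I/O or
validation failures programmatically; the CLI maps them to exit codes
(0 success, 1 failed wells/run, 2 invalid configuration).
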
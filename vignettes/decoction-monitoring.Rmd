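---
title: "Methods: simulated ORT-MS decoction monitoring and SBTEF endpoint selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated ORT-MS decoction monitoring and SBTEF endpoint selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoctr)
```

`decoctr` models one experiment: a herbal decoction boiling for 240 minutes
while an online electrospray ion-trap instrument records full scans
(m/z 100–1500) at about 5 Hz, and an analyst asks when to stop cooking.
This vignette explains the models, the tunable parameters, what the
synthetic data do and do not emulate, and the numerical and design choices
that were genuinely open.

## The kinetic model

All compound classes are short linear first-order chains, solved either by
the Bateman closed form or an ODE integrator.

The central chain is the aconitum alkaloid cascade

$$M \xrightarrow{k_d} A \xrightarrow{k_1} B \xrightarrow{k_2} C,$$

where $M$ is undissolved herb material, $A$ the dissolved diester-type
(toxic) alkaloid, $B$ the monoester-type (bioactive) alkaloid, and $C$ the
aminoalcohol end product.  Assumptions: isothermal boiling (rates constant
in time), first-order steps, no back-reactions, and a well-stirred vessel.
The 30-minute pre-heating soak is collapsed into `f0`, the fraction of the
pool dissolved at $t = 0$ (default 0.15 — the soak visibly pre-dissolves
material but no quantitative value is reported, so a modest fraction is
chosen once and kept).  Co-decoction matrix effects are represented purely
as multiplicative rate modifiers (`inhibition` divides $k_2$), because the
underlying chemistry (complexation, competitive pathways) is hypothesised,
not measured.

The companion classes reuse the same machinery:

* **Stable compounds** (atractylenolides, fuzitine, songorine):
  dissolution only, $v(t) = M_0(1 - (1-f_0)e^{-k_d t})$.
* **Declining glycosides** (paeoniflorin in co-decoction): dissolution
  plus one phenomenological first-order loss.
* **Rising hydrolysis products** (gallic acid, ellagic acid) and
  **conversion products** (zingerone, 6-shogaol): an absorbing final
  compartment fed by a dissolving precursor pool.
* **Biphasic intermediates** (pentagalloylglucose): a multi-stage release
  cascade feeding the observed compartment, which is itself consumed.  The
  published values imply a rise that is still slow at 100 min yet peaks
  sharply near 180 min; a single release step cannot produce that delay,
  so `simulate_biphasic_intermediate()` accepts a vector of release rates
  (the calibrated scenario uses ten equal stages, reflecting progressive
  hydrolysis of higher galloylglucoses).
* **Transient dip** (aconine in co-decoction): a Gaussian-in-time loss
  factor, an explicitly phenomenological reproduction of a dip whose
  mechanism is speculative.

## Calibration of the Zhenwu Decoction scenario

`zwd_anchors()` lists the published signal-intensity anchors (start, peak,
end and timed points per compound and system).  Calibration was performed
once, by least squares against those anchors, and the resulting parameter
file (`zwd_scenario_params.csv`) is versioned; `build_zwd_scenario()` only
evaluates it, so the ground truth is deterministic and seed-independent.

Two calibration targets come from published qualitative observations
rather than printed intensities, and both were fixed before any endpoint
was computed: the co-decoction diester crosses half its peak near 105 min
(diester levels are reported to become low after roughly 100–150 min of
decoction), and co-decoction benzoylmesaconine falls out of its
90%-of-maximum band just after 150 min (the monoesters reportedly hold a
stable concentration plateau between 100 and 150 min).  These two facts
are what anchor the endpoint decision; they are scenario conditions, not
tuning knobs.

```{r anchors}
head(zwd_anchors())
```

## The simulated instrument

`render_stream()` renders one scan per clock tick
(`floor(scan_rate_hz * duration_min * 60)` scans; 72,000 at the 5 Hz /
240 min defaults, the reported device throughput).  Each compound
deposits `response_factor * concentration` in a single integer m/z channel
(unit-resolution ion trap; no isotope envelopes, adducts, chromatography or
MS/MS).  Noise is multiplicative lognormal with unit mean and CV
`noise_cv` (default 0.05) plus an optional additive exponential baseline —
no noise model is reported for the device, so defaults are modest and configurable.
Positive and negative polarities are separate runs, mirroring the original per-polarity replicate design.  What passing tests on these streams shows is that
the *pipeline arithmetic* is right; they say nothing about matrix effects,
ionisation drift, or m/z interferences in real decoctions.

## Signal processing and fitting

EIC extraction sums intensities within ±0.5 m/z (sum, not max: exactly one
deposited channel per compound).  Boxcar smoothing uses points = 3 with
symmetric shrink at the edges, so output length equals input length and
the first/last points are unchanged; fitting happens on the smoothed
series block-averaged to a 0.2-min grid (1200 points), which matches the
plotting density of the published figures and keeps nonlinear fits
desk-scale.

Gaussian-sum fits are Levenberg–Marquardt with data-driven initialisation
(local maxima seed the centres) and five deterministic perturbed restarts;
widths are bounded positive.  Fourier fits profile the fundamental
frequency `w` over a fixed candidate grid (anchored at one period per
window and at the dominant FFT frequency), solve the linear coefficients
exactly for each candidate, then polish `w` by bounded 1-D optimisation.
Zero-variance signals are flagged degenerate rather than fitted ($R^2$ is
undefined there).  Model selection maximises adjusted $R^2$ with ties
(within 1e-6) broken by parameter count, then by a fixed family/order
key, so it is invariant to input order.

## The SBTEF decision

The five dimensions are applied lexicographically — safety as an
overriding constraint, then bioactivity maximisation, then
time/energy/cost as tie-breakers.  The published schema describes exactly
that priority ordering in prose (toxic levels must be acceptable first,
actives kept high and stable second, and only then is the shortest and
cheapest cook preferred) but assigns no numeric weights, so the strict
lexicographic reading is the package's interpretation.  A weighted-sum mode exists
(`sbtef_config(weights = …)`) but is off by default, and safety remains a
hard constraint in both modes.

* `theta_safety = 0.5` of each toxin's fitted peak.  No numeric toxicity
  threshold is published; 0.5 is the package's most consequential free
  parameter (prominently configurable), chosen so the worked scenario's
  safe window opens near 100 min, consistent with the reported detox window.
* `delta_bioactivity = 0.10`: a monoester counts as "in its high-efficacy
  range" while within 10% of its own curve maximum.  Primary actives gate
  the score to zero outside their band; secondary actives (gallic and
  ellagic acid, 6-shogaol, zingerone, pentagalloylglucose) contribute
  `curve(t)/max` so later times win while they still rise.
* Endpoint search grid 1 min, the granularity at which endpoints are reported; energy is
  `power_kw * t / 60` (default 0.3 kW) and cost adds labour time.

With the calibrated co-decoction scenario this yields: safe window opening
at ~105 min, bioactivity gate closing at ~150 min, secondaries still
rising in between — endpoint 150 min.

```{r endpoint, eval = FALSE}
sc <- build_zwd_scenario("CO", seed = 1)
lib <- zwd_compound_library()
curves <- purrr::map(c("pos", "neg"), function(mode) {
  stream <- render_stream(sc, lib, acquisition_config(mode = mode, seed = 1))
  proc <- process_stream(stream, lib)
  purrr::map2(proc$id, proc$eic, function(id, eic) {
    fit <- fit_kinetics(eic)
    tibble::tibble(compound_id = id, time_min = 0:240,
                   value = pmax(predict(fit, 0:240), 0))
  })
}) |> purrr::flatten() |> dplyr::bind_rows()
decide_endpoint(curves)
```

## Numerical choices

* Closed-form Bateman sums are used only for chains of at most four
  pairwise-distinct rates; ties and longer chains go to `deSolve::lsoda`
  (rtol 1e-10).  Long chains of near-equal rates make the Bateman
  denominators catastrophically small, so the closed form is not offered
  there.  The $k_1 = k_2$, fully dissolved case keeps its explicit
  $t e^{-kt}$ form to avoid 0/0.
* In the closed-form path the terminal compartment is obtained by mass
  conservation, so $M+A+B+C = M_0$ holds to machine precision; the
  numeric path conserves to the integrator tolerance (tested at 1e-6).
* Degenerate inputs: empty streams, zero pools, flat signals, zero
  reference values and empty active lists all raise typed conditions
  (`decoctr_*_error`) rather than returning silent NAs.
* Problem sizes: module tests run on coarse grids (0.5–2 min); the
  end-to-end checks render the full 72,000-scan streams in both
  polarities and fit all 18 compounds, which completes in well under a
  minute on a single core.

## Known limitations

* The generator reproduces phenomenological classes, not reaction
  chemistry: no temperature profile, pH, complexation, or Fuling
  (no characteristic bioactive components are monitored for it).
* "Safety" is signal-relative (fraction of a fitted peak), not a
  pharmacological dose threshold.
* Printed start/peak/end intensities are treated as fitted-curve values;
  whether the originals were raw, smoothed or fitted is not stated.
* The scenario's response factors and the absolute scales of compounds
  without printed intensities are package choices; only the anchored
  values and the relative changes carry evidential weight.
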
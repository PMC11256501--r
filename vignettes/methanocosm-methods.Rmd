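---
title: "Methods behind methanocosm: chamber fluxes, Keeling plots, guilds, and rank-based factorial tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind methanocosm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanocosm)
```

`methanocosm` implements the quantitative analysis chain of a factorial soil
microcosm incubation probing how warming and flooding shift net CH~4~
exchange: closed-chamber flux estimation and cumulative emissions,
Keeling-plot isotopic source partitioning with methanogenic-pathway
classification, CH~4~-cycling guild and niche-occupancy summaries of
amplicon count tables, qPCR absolute quantification, and
aligned-rank-transform (ART) factorial ANOVA. A synthetic-data generator
emulates the full experiment so every stage can be exercised, verified and
calibrated without any external data. This vignette records the models, the
tunable parameters, and the design decisions where the methodology was
genuinely open.

## Closed-chamber flux estimation

A sealed jar of volume $V$ (L) over $m$ grams of dry soil accumulates (or
depletes) headspace CH~4~. Each analyzer reading, a mixing ratio $x$ in ppm
(µmol CH~4~ per mol of headspace gas), is converted to a CH~4~ mass by the
ideal gas law,

$$ \mathrm{CH_4}\,[\mu g] \;=\; x \cdot M \cdot \frac{P\,V}{R\,T}, $$

with $M = 16.043$ g mol$^{-1}$, $P$ in atm, $T$ in K and
$R = 0.082$ L atm mol$^{-1}$ K$^{-1}$ (the rounded convention of field flux
work, kept deliberately so that simulated and estimated quantities share one
constant). Because ppm is µmol/mol, the product is in micrograms directly.

The flux is the OLS slope of mass against time over the stabilized window,
scaled to a soil-specific hourly rate:

$$ F \;=\; \frac{\hat\beta_1 \,[\mu g\,s^{-1}] \cdot 3600}{m}
   \quad [\mu g\ \mathrm{CH_4}\ g_{dw}^{-1}\,h^{-1}], $$

multiplied by $12.011/16.043$ when results are reported per mass of carbon
(`mass_basis = "C"`, the default reporting convention "µg C–CH~4~
g dw$^{-1}$ h$^{-1}$"). Negative slopes are preserved: they are net CH~4~
consumption. Note the scaling *divides* by soil mass — the only reading of
the flux formula that produces the stated per-gram unit.

Design choices:

* **Trim window.** Closed-loop measurement needs roughly a minute to
  stabilize after capping; `trim_window()` drops everything in the first
  100 s (strictly: readings at $t \le 100$ s) and keeps readings to 600 s.
  At the 10-s cadence this turns 60 readings into the 50 used for the fit.
* **QC.** `qc_flux()` flags fits with $r^2$ at or below 0.9 (strict
  inequality at the boundary). Failures are retained and flagged, never
  silently dropped; `daily_treatment_flux(qc_drop = TRUE)` excludes them
  explicitly. Weak fluxes near the analyzer noise floor legitimately fail
  this bound — that is the QC doing its job, not an error state.
* **Degenerate input.** A zero-variance mass response has $r^2$ defined as
  0; identical time stamps are a singular-fit error.

Daily treatment fluxes are arithmetic means over replicates;
`cumulative_emission()` integrates them over the experiment by the
trapezoidal rule, $\sum_i \tfrac12 (f_i + f_{i+1}) \cdot 24\,(d_{i+1}-d_i)$,
which is exact for the piecewise-linear interpolation it defines (a constant
0.001 µg g$^{-1}$ h$^{-1}$ over 30 d integrates to exactly 0.72
µg g$^{-1}$). Missing sampling days are interpolated across.

## Keeling plots and pathway classification

Isotopic compositions use delta notation,
$\delta = (R_{sample}/R_{std} - 1) \times 10^3$ ‰, against VPDB for
$^{13}$C/$^{12}$C and VSMOW for $^2$H/$^1$H (VSMOW is the standard hydrogen
reference and the one adopted here). When a source with signature
$\delta_{src}$ accumulates above an atmospheric background
$(C_{bg}, \delta_{bg})$, conservative mixing gives

$$ \delta_{mix} \;=\; \delta_{src} +
   C_{bg}\,(\delta_{bg} - \delta_{src}) \cdot \frac{1}{C_{tot}}, $$

a straight line in $1/C_{tot}$ whose intercept is the mean-source delta.
`keeling_intercept()` fits this line by OLS — the simplest fitter, adequate
when concentration error is small relative to the spanned range; the fitting
step is isolated so a geometric-mean variant could be swapped in. At least
three samples spanning at least two distinct concentrations are required;
the background air sample is an ordinary point on the line.

`classify_pathway()` places the source signature on the dual-isotope
diagram. Defaults (per mil): hydrogenotrophic production in
$\delta^{13}C \in [-110, -60]$, $\delta^2H \in [-250, -170]$; acetoclastic
in $\delta^{13}C \in [-60, -50]$, $\delta^2H \in [-400, -250]$. Membership
is inclusive and the shared $\delta^{13}C = -60$ ‰ edge resolves to the
hydrogenotrophic box (the lower-$\delta^{13}C$ box claims the boundary — a
documented tie-break, not a scientific claim). Signatures enriched beyond
*both* oxidation thresholds (defaults: the upper production-box edges,
$\delta^{13}C > -50$ and $\delta^2H > -170$) are labelled
`oxidation-enriched`, since residual CH~4~ left by oxidation is enriched in
both heavy isotopes. Everything else is `mixed/indeterminate`, with signed
per-axis distances to each box reported so "how far outside" is always
quantified. All thresholds are configuration, not constants baked into the
logic: oxidation is defined only qualitatively by enrichment, so its
thresholds especially should be read as a convention.

## Count-table summaries

Tables are integer matrices, samples × taxa, with semicolon-delimited
taxonomy strings per taxon.

* **Rarefaction** (`rarefy_counts()`): subsampling without replacement
  (multivariate hypergeometric, via `vegan::rrarefy`) to a common depth,
  default 29,300 reads; shallower samples are dropped and reported, never
  partially rarefied. Seeded for reproducibility.
* **Guild extraction** (`extract_guilds()`): case-insensitive exact match
  of any taxonomy rank token against curated methanogen and methanotroph
  name lists (taxa with reported *mcr*ABC or *pmo*CAB/*mmo*X capability,
  respectively). A name on both lists is a configuration error; matching is
  by whole token, so "Methylocystis" never matches a substring of another
  genus. Summed per-sample relative abundances are returned — the usual
  "total methanogens (%)" response variable.
* **CLAM niche classification** (`clam_classify()`): each taxon's pooled
  counts $(y_A, y_B)$ in two disjoint sample groups are tested against the
  supermajority threshold $\pi = 2/3$: the taxon is a specialist of A when
  the one-sided exact binomial test rejects at level $\alpha$
  ($P(Y \ge y_A \mid n, \pi) \le \alpha$ with $n = y_A + y_B$), a
  specialist of B symmetrically, a generalist when neither rejects.
  $\alpha$ (default 0.05) is the individual-test level applied directly to
  each one-sided test. The two readings of the "coverage limit of 10" are
  both available: a raw total-count floor (`count_floor`, default) or
  eligibility by whether any classification is attainable at the taxon's
  total (`min_classifiable`, the smallest $n$ with $\pi^n \le \alpha$,
  i.e. 8 at the defaults). Taxa below the limit are labelled too rare, not
  dropped. Equal sampling effort between the groups is assumed — satisfied
  by balanced designs rarefied to a common depth. CLAM is applied to
  rarefied counts by default; nothing prevents passing raw counts, and the
  choice is the caller's.

## qPCR absolute quantification

`fit_standard_curve()` regresses Cq on $\log_{10}$ template copies over a
dilution series (default seven decades, $10^0$–$10^6$ copies) and reports
amplification efficiency by the universal convention
$E = 10^{-1/slope} - 1$ (slope $-3.3219$ cycles/decade = perfect doubling =
100%). Non-negative slopes flag the curve invalid. `quantify_copies()`
inverts the curve, $copies = 10^{(Cq - b_0)/b_1}$, averaging replicate Cq on
the cycle scale first (cycler-software convention; averaging copies instead
is one flag away), and scales by the grams of dry soil represented in one
reaction. That scale factor is assembled explicitly by `soil_equivalent()`
from the extraction chain (default 0.25 g soil extracted, 100 µL elution,
1 µL template, no dilution → 2.5 mg soil per reaction); there are no hidden
conversion factors. Replicate Cq scatter above a gate (default 0.5 cycles)
flags, never drops, the estimate.

## Aligned-rank-transform factorial ANOVA

Factorial responses here (cumulative fluxes, guild relative abundances,
gene copy numbers) are small-sample and rarely normal, so treatment effects
are tested by ART. For each effect of the full factorial model, the
response is *aligned* — the estimated contributions of every other effect
are subtracted, using the coefficient partition of the full fixed-effects
fit under sum-to-zero contrasts — then ranked with mid-ranks, and a full
factorial ANOVA is fitted to the ranks, of which only the aligned effect's
F test is retained. The classical diagnostic holds by construction: for
balanced designs, the aligned response has zero marginal means for every
stripped effect (verified to 1e-9 in the tests).

Two modelling choices are deliberate. Replicate microcosms are independent
jars, so the model is fixed-effects with no random replicate term. And the
per-effect F uses marginal (type III style) sums of squares under
sum-to-zero contrasts, which coincide with the classical decomposition for
balanced data and remain well-defined when cells are unbalanced; an empty
cell is an explicit error naming the cell. Two-way use is
`art_anova(response ~ temperature * flooding, data)` per site; three-way
adds the sampling day, matching the convention of fitting per-site models.

## The synthetic experiment

`gen_experiment()` emulates the study conditions end to end: 3 sites × 2
temperatures (27/30 °C) × 2 flooding levels × 4 replicate jars, sampled on
days 0, 1, 3, 6, 9, 13, 17, 23, 30; 1.5 L jars holding 400 g fresh soil at
30% gravimetric moisture (280 g dry); chamber series of 60 readings at 10-s
cadence over 600 s. Everything is deterministic under the config seed.

* **Chamber series** follow baseline + transient + linear accumulation +
  Gaussian noise. The closing transient is a single exponential with a 30-s
  timescale, so it is negligible after the 100-s trim; the linear slope is
  the exact algebraic inverse of the ideal-gas flux arithmetic (generators
  and estimators share the physical model, never code). Reading noise
  defaults to 0.005 ppm, the ppb-level precision of a cavity-enhanced
  analyzer; default per-jar true fluxes span roughly −0.002 to +0.005
  µg C g$^{-1}$ h$^{-1}$ — wet jars emit (ramping upward over the
  incubation), dry jars consume, warming amplifies emission and suppresses
  consumption, and jars differ by a lognormal factor emulating field-point
  heterogeneity. At these settings strong emission series pass the 0.9 QC
  bound comfortably while weak consumption series sit near the noise floor
  and often fail it — the same asymmetry a real campaign shows.
* **Isotope sets** place samples on exact two-member mixing lines above a
  1.9 ppm background with typical tropospheric signatures (−47.2 ‰
  $\delta^{13}$C, −86 ‰ $\delta^2$H), wet treatments sourcing depleted
  production-range CH~4~ and dry treatments an oxidation-enriched residue,
  with 0.2 ‰ measurement noise.
* **Count tables** draw multinomial samples (≈35,000 reads) from lognormal
  taxon abundances; a configurable taxon fraction carries curated guild
  names at reduced abundance (CH~4~-cycling guilds are rare in soil), and
  configurable specialist taxa are enriched in one flooding group.
* **qPCR tables** use per-gene standard curves with slopes in the
  92–108% efficiency range and 0.1-cycle noise, and unknowns centred on the
  copy-number magnitudes typical of these soils (e.g. *mcr*A around
  $10^{6.5}$ copies g$^{-1}$ in floodplain, $10^{2.5}$ in upland forest
  soil).

What the generator does **not** emulate: sequencing reads and ASV
inference, chimeras, taxonomy misassignment, compositional correlations
between taxa, soil chemistry, chamber leaks, or non-linear (saturating)
accumulation. Passing tests therefore demonstrate that the estimators
recover what they claim from data obeying their assumptions — not that
those assumptions hold in any particular field dataset.

## Verification and problem sizes

Every estimator is checked against an independent oracle: OLS fits against
closed-form normal equations; Keeling intercepts against the exact mixing
identity (noiseless recovery to 1e−6 ‰, unbiasedness over 1,000 noisy
replicates); CLAM against direct enumeration of exact binomial tails for
all count pairs with totals ≤ 60; rarefaction against the hypergeometric
expectation; trapezoidal integration against a fine-grid Riemann sum; ART
against its zero-marginal-means diagnostic and a 1,000-replicate null
calibration of per-effect type-I error (nominal 0.05, accepted within
[0.03, 0.07]). The noiseless chamber round trip (generate → trim → fit)
recovers the true flux to 1e−9 relative error with the transient switched
off; with the default transient, the 100-s trim leaves a bias around
exp(−110/30) of the transient amplitude, ~2 orders below the reading noise.
Simulation sizes (100-series QC sweeps, 1,000-replicate calibrations,
24 × 300 count tables) were chosen so the whole suite verifies the
distributional claims at useful power while running in minutes on one core.

## Known limitations

* The Keeling fitter is plain OLS; with large, heteroscedastic
  concentration ranges a Miller–Tans or geometric-mean regression can
  differ. The interface isolates the fitter for that reason.
* CLAM's binomial formulation assumes equal effort between groups; unequal
  group sizes require pre-scaling that the function intentionally does not
  guess.
* ART's F tests are asymptotic in spirit; at n = 4 replicates per cell the
  null calibration shows mild liberality on interactions (still within the
  accepted band).
* The pathway diagram classifies the *mean source*; concurrent production
  and oxidation shift the intercept along mixing/fractionation lines the
  box logic cannot decompose — such points land in `mixed/indeterminate`
  or `oxidation-enriched` by design.
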
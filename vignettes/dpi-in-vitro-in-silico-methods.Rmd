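---
title: "Methods: from cascade-impactor data to predicted salbutamol pharmacokinetics"
author: "dpipk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cascade-impactor data to predicted salbutamol pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpipk)
```

# Scope and overall structure

`dpipk` implements an in vitro-in silico workflow for carrier-based dry
powder inhalers (DPIs) of salbutamol sulphate. Cascade-impactor (NGI)
stage-mass measurements are reduced to aerodynamic descriptors; a
deterministic one-dimensional typical-path lung model converts the fitted
aerodynamic size distribution and a breathing pattern into regional
deposition fractions; a pulmonary-absorption PBPK model converts deposition
into plasma concentration and urinary excretion profiles; and correlation
screening relates powder descriptors to the predicted performance. A
synthetic-data module generates every input with the statistical structure
the analysis assumes, so the whole chain is testable without instrument
files.

# Impactor reduction

The emitted dose (ED) is the recovered drug mass excluding the
device/capsule residue. Only stages 1-7 and the micro-orifice collector
(MOC) carry size information; induction-port and pre-separator mass counts
toward ED but not toward the sized distribution, because the archival
impactor calibration defines no cut-off for those locations at arbitrary
flows. Stage cut-off diameters scale with flow as
$d_{50}(Q) = d_{50}(60\,\mathrm{L/min})\,(60/Q)^{x}$ with per-stage
exponents from the archival calibration (bundled as
`extdata/ngi_cutoffs_60lpm.csv`); the calibration window is 15-100 L/min
and use outside it warns rather than errors.

The cumulative undersize fraction at each cut-off is regressed as
$\Phi^{-1}(F)$ on $\ln d$ (probit/log-probability fit). The MMAD is the
diameter at probit zero — the mass *median*, the log-normal convention used
throughout even where summary tables elsewhere gloss MMAD as a "mean" — and
$\mathrm{GSD} = \exp(1/\text{slope})$. Fractions within $10^{-7}$ of 0 or 1
are excluded: beyond roughly $5\sigma$ the quantile derivative amplifies
double-precision rounding past any useful information, and such points are
equally uninformative in real data. Fine particle mass (FPM) integrates the
*fitted* line over the 1-5 µm band (not a piecewise-linear interpolation of
the raw fractions), keeping FPM consistent with the reported MMAD/GSD; the
fine particle fraction is $100 \times \mathrm{FPM}/\mathrm{ED}$. Replicates
are reduced run-by-run and then averaged (mean, SD, n).

# Powder descriptors

All descriptor operations are deterministic closed forms: the Kelvin radius
in its magnitude convention $r_k = 2\sigma V/(R T \ln(p_0/p))$ (positive
radii; the adsorbed-layer thickness is supplied by the caller, since the
instrument's proprietary layer-thickness reduction is out of scope); the
Heywood diameter $d_e = \sqrt{3.08\,WL/\pi}$; the shape coefficient
$\alpha = \mathrm{SSA}\,\rho_s d_e + N$ as printed in its source, with the
multiplicative reading $\alpha = \mathrm{SSA}\,\rho_s d_e N$ available
behind an explicit `variant` switch because the additive form is
dimensionally fragile and the original formula is ambiguous; diametral
tensile strength $2P/(\pi D t)$; shear-cell/compressibility/permeability
profile summaries (window mean and endpoint difference); and
pressure-titration deltas signed so that de-agglomeration (Dv0.1 falling,
fines rising) is positive. Units are SI internally with conventional
reporting units (µm, N/mm², m²/g) at the interface.

# Lung deposition model

The deposition stage is a deterministic typical-path analogue of stochastic
whole-lung dosimetry codes: a symmetric 24-generation airway tree (bundled,
rescaled to the subject's FRC by $(\mathrm{FRC}/4800)^{1/3}$), with
per-generation efficiencies for inertial impaction (bifurcation-angle
Stokes-number kernel), gravitational sedimentation (inclined-tube settling)
and Brownian diffusion (Gormley-Kennedy). The aerosol is discretized into
128 log-uniform mass bins spanning MMAD $\times$ GSD$^{\pm 4}$ (results are
stable to &lt;1% above 128 bins). Each bin passes the extra-thoracic filter,
travels down the tree, deposits what remains in the acinus during the
breath-hold (sedimentation + diffusion in terminal-duct geometry), and
retraces the tree and throat on exhalation at the exhalation flow. Because
every step multiplies a survival factor, ET + TB + AL + exhaled = 1 to
machine precision.

The extra-thoracic filter is an empirical impaction-parameter efficiency
$\eta = 1 - [1 + (d_{ae}^2 Q / c)^{p}]^{-1}$ with $c = 30.5$ µm² L/min and
$p = 1.10$. This is deliberately far stronger than oral-only mouth-throat
correlations: the reference exposure is an oronasally augmented, high-flow
(~97 L/min) DPI inhalation, and $c$ was calibrated once so that the
reference aerosol (MMAD 1.83 µm, GSD 3.60, density 1.33 g/mL, 4520 mL over
2.8 s, 10.3 s hold, 9.7 s exhalation) reproduces the published 79.2%
extra-thoracic fraction of the reference product. The resulting lower-airway
fraction is 14.8%, inside the 10-20% band stated for the product; exact
agreement with the published 12.6%/79.2% split is not expected from a
typical-path geometry and is not asserted anywhere.

One shape property deserves a caveat. The classic deposition-versus-size
curve — rising from a sub-micron minimum to a 1-5 µm maximum, then falling —
appears under resting tidal breathing (we test 750 mL, 2 s in/out, no hold).
Under the reference pattern the 10.3 s breath-hold deposits nearly all mass
that reaches the acinus, so the fine-side decline moves below 0.5 µm and
lung fraction becomes monotone decreasing in MMAD over [0.5, 10] µm. The
unimodality test therefore pins the tidal pattern, and the validation band
test pins the reference pattern.

# PBPK model

Deposited drug enters three lining-fluid compartments (extra-thoracic ET,
tracheobronchial TB, alveolar AL), each holding undissolved and dissolved
drug. Dissolution is a Noyes-Whitney term with the measured lung-fluid
solubility (384.7 mg/mL); at that solubility it is effectively instantaneous
and its rate constant is capped at $3.6\times10^4$ h$^{-1}$ purely so the
solver never sees sub-millisecond half-lives — the cap is invisible at
reporting resolution. Absorption flux is $P_{app} \times SA \times f_u
\times C_{dissolved}$ per region, with the measured bronchiolar
($8.53\times10^{-7}$ cm/s, used for ET and TB) and alveolar
($1.59\times10^{-5}$ cm/s) permeabilities and unbound fractions 0.20 (ET)
and 0.15 (AL). Mucociliary transport moves TB lining material to ET
(0.4 h$^{-1}$) and ET material to the gut (0.1 h$^{-1}$). Of the
extra-thoracic deposit, 65% is swallowed and 30% expectorated at time zero;
with first-pass extraction fixed at 100% (the charcoal-block assumption)
swallowed drug is a presystemic sink, so only the 5% ET remainder, TB and AL
can reach plasma. TB and AL absorption enters the lung tissue compartment
and hence *arterial* blood; ET absorption enters venous blood.

Systemic disposition is perfusion-limited over eleven tissues (bundled 77 kg
physiology; gut and spleen drain through the liver). Tissue-to-plasma
partition coefficients come from the published composition-based equations
for an ionizable base — neutral-lipid/phospholipid partitioning of the
neutral species, pH-driven accumulation in intracellular water, and
acidic-phospholipid binding of the cation with an affinity back-calculated
from the blood-to-plasma ratio (0.96, which for salbutamol implies no excess
blood-cell binding, so that term truncates to zero). Renal (4.2 mL/min/kg)
and hepatic (5.44 mL/min/kg) clearance act on the arterial plasma
concentration, which makes the asymptotic renal share exactly
$CL_r/(CL_r + CL_h)$ — the component values are used rather than the
rounded printed total (9.62 vs 9.64 mL/min/kg), a discrepancy we document
but do not resolve. Plasma concentration is reported venous; cumulative
urine integrates the renal flux.

Two reporting conventions follow the source tables: reported Cmax is on the
$10^{-4}$ µg/mL scale and AUC(0-12 h) on the $10^{-3}$ µg·h/mL scale (the
printed "10³" exponent is inconsistent with the Cmax scale and is treated as
a sign typo). The tmax range is read in hours as printed.

## Calibrated physiology defaults

Regional lining volumes, effective absorptive areas and mucociliary rates
are not published for this model; they are the designated calibration
surface, fitted once against the reference product's observed plasma
pharmacokinetics and then frozen in `lung_disposition_params()` and
`extdata/salbutamol_diskus.cfg`:

| knob | value | note |
|---|---|---|
| AL area / volume | 15000 cm² / 15 mL | effective area, about an order below anatomical — stands for the accessible fraction |
| TB area / volume | 2400 cm² / 5 mL | close to anatomical conducting-airway area |
| ET area / volume | 1500 cm² / 1.2 mL | effective, includes oropharyngeal and proximal mucosa exposure |
| TB→ET, ET→gut transfer | 0.4, 0.1 h⁻¹ | slow-phase mucociliary clearance |

With these values the validation run (600 µg, 12.6% lung / 79.2% ET, lung
split TB:AL in the deposition model's own proportion because the reference
split is unpublished) gives Cmax $7.64\times10^{-4}$ µg/mL (observed
6.48-8.27), tmax 0.212 h (0.17-0.50), AUC(0-12) $1.99\times10^{-3}$
µg·h/mL (1.790-2.209) and a 30-min urine-to-plasma-Cmax mass ratio of 3.76
(calibration range 3.09-4.05). The ratio deserves a remark: had clearance
been driven by the venous (sampling-site) concentration the ratio could
never exceed $CL_r \times 0.5\,\mathrm{h} / 3.78\,\mathrm{L} = 2.57$; it is
the arterial entry of pulmonary-absorbed drug that exposes the kidney to
more than venous Cmax during the absorption phase and makes the published
range reachable at the published renal clearance.

# Synthetic data

The NGI generator apportions the sized mass by log-normal CDF differences
at the flow-correct cut-offs, with stage 1 additionally collecting the mass
coarser than its own cut-off, so the cumulative undersize of a noise-free
run equals the untruncated log-normal CDF and the probit fit recovers the
generating parameters to machine precision. Per-surface multiplicative
log-normal noise (mean-one) emulates replicate scatter; 5% CV and n = 3
mirror the replication level of the study design. The descriptor generator
draws jointly Gaussian property/outcome pairs with a target correlation.
One integer seed drives named substreams (one per material and replicate),
so extending a design never perturbs existing draws. What the generator
does *not* emulate: inter-stage mass cross-talk, wall losses, recovery
failures, non-log-normal (bimodal carrier/drug) distributions, or any
mechanistic link from powder descriptors to aerodynamic outcomes beyond the
imposed correlation — so passing tests demonstrate the pipeline's
statistical and numerical correctness, not formulation science.

# Numerical choices and limitations

Integration uses `deSolve::lsoda` at rtol $10^{-8}$/atol $10^{-12}$ on a
fixed grid (5 ms-scale steps over the first hour, 0.05 h after); halving the
tolerances moves Cmax by under $10^{-6}$ relative. Cmax/tmax are refined by
a local quadratic through the grid maximum; AUC is trapezoidal on the grid.
Problem sizes used throughout (128 aerosol bins, 48 synthetic runs, n = 3
replicates, 50-200 replicate Monte-Carlo checks) were chosen as the smallest
sizes at which all quantities are stable to well under their test
tolerances. Known limitations: symmetric airway geometry (no
inter-subject or intra-lung path variability), no hygroscopic growth or
charge effects, no oral (GI) absorption mechanism beyond the presystemic
sink, no transporters or enzymes, single-subject physiology, and descriptor
tables whose correlation structure is imposed rather than mechanistic.
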
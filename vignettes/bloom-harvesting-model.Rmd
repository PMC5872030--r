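---
title: "Modelling bloom harvesting: separation, mass balance and scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bloom harvesting: separation, mass balance and scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efloatr)
```

`efloatr` models the harvesting of an algal bloom from a eutrophic
water body as a chain of small, individually testable computations:
flocculant dose selection, flotation kinetics, a recoverable-resource
mass balance, compositional summaries (FAME saturation classes,
microbial diversity), and a techno-economic scale-up of a modular
flotation unit. This vignette records the models, their assumptions,
the tunable parameters, and the design choices made where the design
was genuinely open.

## Separation model

Removal efficiency is always the normalised concentration drop
$E = 100\,(1 - c_t/c_0)$, with chlorophyll a acting as the proxy for
photosynthetic biomass. Replicate noise can leave $c_t$ marginally
above $c_0$; an overshoot of at most 0.5 percentage points (pp) is
clamped to zero, anything larger is treated as a data error rather
than silently truncated. The 0.5 pp default matches the scale of
replicate standard deviations in jar-test data.

**Dose–response.** Jar-test dose grids are coarse (a handful of doses
over 1–9 mg/L) and not guaranteed monotone, so the curve is
piecewise-linear with no smoothing and no extrapolation beyond the
measured range. Operating-dose selection takes the *maximum* point as
the smallest dose whose efficiency is within 1 pp of the curve
maximum — replicate scatter makes finer distinctions meaningless — and
the *sub-maximum* point as the measured dose nearest a user-chosen
reduced target (default use case: ~70 %), ties broken toward the
lower, cheaper dose. Selection is a scan over measured points only;
interpolated doses are never proposed, because a jar test validates
points, not the line between them.

**Flotation kinetics.** Flotation harvesting is summarised with the
standard first-order rate model
$E(t) = E_\infty\,(1 - e^{-kt})$, with $E_\infty$ the asymptotic
harvesting efficiency (%) and $k$ (min⁻¹) the rate constant.
Published flotation data for this process are sampled points, not a
stated curve form; first-order kinetics is the field's default for
bubble–floc capture and is the minimal saturating model. Fitting is
nonlinear least squares (Levenberg–Marquardt, tolerances 1e-14, bounds
$E_\infty \in [0,100]$, $k \ge 0$). Two special paths keep the
contract exact: an all-zero series returns $E_\infty = 0$ directly,
and a two-point series is solved exactly by eliminating $E_\infty$ and
root-finding $k$ on the remaining one-dimensional equation
(bisection-grade `uniroot` at 1e-12 tolerance), so the fit
interpolates both points to machine precision. A decrease of more than
2 pp between consecutive times triggers a warning (physically,
efficiency should be non-decreasing) but fitting proceeds.

**Paired comparison.** The bacteria-effect comparison (natural vs
reduced bacterial load at the same doses) uses the classical paired
t statistic with a two-sided p-value. When every difference is zero
the statistic is degenerate; we define $p = 1$ by convention rather
than erroring, so screening loops over many dose levels never abort on
a tie.

## Resource-recovery mass balance

The standing biomass stock is $M = C_{dw} \times V$ with $C_{dw}$ the
dry-weight concentration (g/L) and $V$ the photic-zone volume (m³) —
numerically kg = g/L × m³. Because bloom volume is uncertain, $V$ is
carried as a low/high range. Recoverable constituent mass is

$$m = M \times w \times E/100,$$

with $w$ the constituent mass fraction (g per g dry biomass; printed
µg/mg values are converted at ingest, ×10⁻³) and $E$ the flotation
harvesting efficiency. Protein may be derived from elemental nitrogen
as $w_{prot} = 4.78 \times w_N$ — the algal-specific
nitrogen-to-protein factor, lower than the classical 6.25 because of
non-protein nitrogen — and a derived fraction above 1 g/g is rejected
as an impossible composition.

Two modelling assumptions are inherited deliberately: chlorophyll-a
removal is equated with bulk biomass removal (flotation harvests flocs
containing the whole community, so the pigment proxy is applied to
total dry weight), and no downstream extraction or purification losses
are modelled — the outputs are *recoverable* masses at the point of
skimming, upper bounds on usable product.

All results are kept at full precision; presentation rounding (integer
kg for lipids, 2 dp for phosphate and protein) happens only in print
methods and report checks. For the bundled scenario the two
high-volume protein endpoints recompute ~0.04 % above their published
counterparts (385.85 vs 385.69 kg; 318.58 vs 318.50 kg), a rounding
of intermediates in the source tables; the package reports its own
self-consistent arithmetic and checks the endpoints that agree
exactly.

## FAME profile

FAME shorthand (`C18:3n3`, `C18:1 cis`, `C20:5 n-3`) is parsed by a
single anchored regular expression into chain length, double-bond
count, optional omega position and optional geometry; the omega token
is accepted with or without a dash because supplier mix sheets vary.
Classification is purely by double-bond count: 0 → SFA, 1 → MUFA,
≥2 → PUFA. Group yields are plain sums (mg per g biomass) and the
relative profile normalises by total FAME mass, so it sums to 100 by
construction; a duplicated species name is ambiguous input and an
error. Detections are optionally filtered to species seen in at least
3 of the technical replicates (configurable), mirroring standard
true-hit practice for GC-FID panels.

## Community diversity

OTU tables (counts × samples with rank-prefixed lineage strings) are
aggregated to a chosen rank; OTUs with no assignment at that rank pool
into `unmatched`. For display, a taxon is retained if it reaches the
threshold (default 1 %) in *at least one* sample — the rule that keeps
a taxon visible in every column of a stacked-bar figure once it clears
the threshold anywhere — and the remainder pools into `other (<1%)`.
Percentages are per-sample and sum to 100 exactly.

Diversity is the Shannon index $H' = -\sum p_i \ln p_i$ over nonzero
relative abundances. Natural log is used (the ecological default; no
base was mandated by the use case) and no rarefaction is applied
before computing $H'$ — depths in the intended inputs are similar
across samples, and a rarefaction layer would add a stochastic step to
an otherwise deterministic summary. $0 \le H' \le \ln S$ with equality
at a single taxon and at perfect evenness; tests verify both bounds,
scale invariance, and agreement with an independent implementation
(`vegan::diversity`).

## Techno-economic scale-up

The full-scale unit is a modular pontoon treating `batch_volume_L`
(default 24 000 L) per cycle. The component models:

- **Air demand**: linear in treated volume at the laboratory-derived
  specific rate of 1 mL·min⁻¹ per litre — 24 L/min for a 24 000 L
  batch.
- **Compressor derating**: free-air delivery × a derating fraction
  (0.25 at 3 bar(g)); the derated flow is compared with the demand to
  flag design feasibility. The reference 7.1 cfm machine converts at
  the fixed factor 28.3168 to 201.05 L/min and derates to 50.26 L/min
  (reported as 50), comfortably above the 24 L/min demand.
- **Batch cycle**: treat + fill + drain (default 30 + 48 + 48 =
  126 min); the 48-min fill of 24 000 L implies a 500 L/min pump.
- **Energy cost**: kW × h × tariff (default £0.15/kWh).
- **Flocculant**: dose × volume → kg × unit price (£30/kg chitosan
  default).
- **Ledger**: the batch count `total_volume / batch_volume` is kept
  *fractional* for costing — a part-filled final batch costs its
  pro-rata share, and the reference whole-pond costs only reproduce
  with 312.5 batches — while a separate scheduling figure uses the
  ceiling. Per-item full cost is per-batch OPEX × batch count; items
  without a stated per-batch OPEX derive it from power × duty ×
  tariff. Totals are exact sums (conservation is tested to 1e-9), and
  rounding to whole currency units happens only at presentation.
- **Solar sizing**: panels = ⌈load / (rating × derate)⌉, area =
  panels × per-panel footprint. The load is an explicit argument
  rather than the equipment-list total, because which loads a solar
  array should carry (the 16 kW skimmer clearly exceeds a 6–8 panel
  array) is an open design question in the source scenario.

Two source-data inconsistencies are resolved explicitly. The published
compressor per-batch OPEX (£0.83) is an order of magnitude above what
its stated 1.1 kW rating derives (£0.0825 at 30 min and £0.15/kWh);
the ledger takes the published figure as a given input, and the
derivation path remains available through `energy_cost()`. The skimmer
is quoted at both 27 kW and 16 kW in different places; 16 kW is used
because it reproduces the published £1.20/batch energy cost. Doses
quoted as mg·mL⁻¹ in one place and mg·L⁻¹ in another are treated as
mg·L⁻¹ throughout (the only reading consistent with the 1–9 mg/L jar
tests).

## Synthetic-data generators

Each generator emulates the statistical structure one pipeline stage
assumes, under a fixed seed:

- **Dose–response**: Hill curve
  $E(d) = E_{max} d^h / (EC_{50}^h + d^h)$ — the minimal saturating
  dose–response form, since only sampled points are published — plus
  additive Gaussian noise on the percentage scale, truncated to
  [0, 100].
- **Flotation**: the first-order model above, same noise scheme.
  Defaults ($E_\infty = 92$, $k = 0.95$) plateau near the observed
  ~91 % with ~85 % harvested by 2 min, the observed high-dose
  behaviour.
- **Community**: Dirichlet-multinomial counts whose mean gives a
  chosen share to the top taxon (cyanobacterial dominance ≈ 0.97
  pre-harvest vs ≈ 0.3 post-harvest in the motivating comparison) and
  splits the rest evenly; concentration parameter 100 gives realistic
  sample-to-sample variation at 50 000 reads per sample, a typical
  amplicon depth.
- **Composition**: truncated-normal mass fractions around the measured
  point estimates (lipid 0.1037, phosphate 0.00902, protein
  0.32545 g/g).

What passing tests on these generators shows — and does not show:
parameter recovery at zero noise verifies the fitting code against the
generating model exactly, and seeded noisy recovery verifies
robustness at realistic noise (2 pp replicate scatter), but none of
this validates the *model forms* against real blooms. Real
dose–response curves can be non-monotone (overdosing restabilises
flocs, visible as the efficiency dip at high dose in jar-test data),
real flotation series have autocorrelated errors, and real communities
are not exchangeable Dirichlet draws. The generators are for testing
the computational chain, not for simulating ecology.

## Problem sizes and numerical choices

The test and validation runs use small problem sizes chosen to
exercise every code path: dose grids of 3–8 points, flotation series
of 2–10 points, communities of 10 taxa × 50 000 reads with 20
replicate seeds for the dominance comparison, and the 12 000-record
scale of the pond mass balance. All headline case-study numbers are
desk-scale closed-form arithmetic and run in well under a second.

Tolerances: unit round-trips are exact to 1e-9 relative; noiseless
kinetics/Hill recovery to 1e-6; ledger conservation to 1e-9;
comparisons against published values are made at each value's own
printed precision (integer kg, 2–3 decimal currency), never tighter.

## Known limitations

- No zeta-potential or charge-neutralisation chemistry: dose selection
  is empirical, from measured points only.
- No hydraulics: bubble size, oscillator physics and tank geometry are
  outside scope; the air-demand rule is a fixed specific rate.
- No NPV, inflation or seasonal utilisation in the cost model; it is a
  single-treatment ledger.
- The Chl-a-equals-biomass proxy and the absence of downstream-loss
  models mean recovery figures are upper bounds.
- The diversity component summarises provided OTU tables; read
  processing, clustering and chimera removal belong to upstream
  pipelines.
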
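---
title: "Meso-activity soil-exposure modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meso-activity soil-exposure modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatr)
```

## The problem

Time-activity data used in exposure assessment usually stop at the
macro-activity level: a person was "farming" for some hours. Soil contact,
however, varies enormously *within* farming — transplanting seedlings by
hand on one's knees is not watering from a standing position — and it
varies again by season, weather, and the habits of the individual worker.
`eatr` models soil-contaminant dose at this intermediate, meso-activity
resolution: a grid of tasks crossed with seasons, each cell carrying its
own work schedule and its own parameter adjustments.

## Dose equations and units

Two exposure pathways are modelled. Incidental ingestion:

$$ADD = \frac{C \times IR \times EF}{BW}$$

with soil concentration $C$ in mg contaminant per mg soil, intake rate
$IR$ in mg soil/day, dimensionless exposure factor $EF \in [0,1]$, and
body weight $BW$ in kg. Dermal contact:

$$DA_{event} = C' \times CF \times AF \times ABS, \qquad
ADD = \frac{DA_{event} \times SA \times EF_{freq} \times ED \times EV}
{BW \times AT}$$

Here the concentration $C'$ is carried in mg/kg with an explicit
conversion factor $CF$ (kg/mg) rather than silently pre-converted, because
the conversion factor is a named input of the standard dermal guidance
equation and keeping it visible makes parameter files auditable. The
dermal equation multiplies exposure frequency ($EF_{freq}$), exposure
duration ($ED$) *and* event frequency ($EV$) simultaneously, exactly as
the guidance form is written; the unit convention that makes this
dimensionally coherent — $EF_{freq}$ in days/year, $ED$ in years, $EV$ in
events/day, $AT$ in days — is adopted throughout and documented on
`add_dermal()`. All doses are averaged over a one-year averaging time in
the bundled scenarios.

The exposure factor is the product of three schedule fractions,

$$EF = \frac{h}{24}\cdot\frac{d}{7}\cdot\frac{w}{52},$$

which is monotone in each field and bounded in $[0,1]$ by construction. A
10 h/day, 6 day/week, 50 week/year schedule gives $EF = 0.34$. Guidance
texts sometimes quote 0.16 for the default 8 h/5 d/50 wk occupational
schedule even though the triple product is 0.229; the package never
reproduces that value from a schedule — where a scenario needs it, it is
carried as an explicit baseline `exposure_factor` input, on the view that
a formula should not be bent to match a number whose derivation is not
stated.

## The EAT-R factor system

Ten qualitative factors, grouped into Environmental (natural;
social/built), Activity (crop type; growing practices; ergonomic
positioning), Timing (season; day of week; time of day) and Receptor
(behavioral; biological) classes, describe *why* exposure varies. Because
no study has yet quantified their magnitudes, the package deliberately
carries no factor-effect lookup table: modifier values are supplied by the
analyst. What the package does enforce is *which* quantitative input each
factor may touch — e.g. natural conditions may alter intake rate and the
soil-to-skin adherence factor, the social/built environment only the
exposure factor, biology may alter intake rate, skin surface area and body
weight. `validate_modifier()` rejects anything outside the mapping and
reports the permitted set:

```{r}
validate_modifier(modifier("social_built", "adherence_factor",
                           "multiply", 2))
```

Modifiers either multiply a baseline input or override it. Within a cell,
multiplies compose commutatively, overrides apply last, and at most one
override per parameter is allowed — a deterministic algebra chosen because
the framework describes factor interactions qualitatively without giving
an interaction calculus. Classes apply in the fixed order environmental →
activity → timing → receptor; with commutative multiplies and unique
overrides the order is a naming convention, not a numerical choice.
Interactions (say, season × day-of-week) are expressible only as
explicitly scoped per-cell modifiers; the package generates no automatic
interaction terms.

One reconciliation was needed: the factor mapping gives the timing class
the *exposure factor* and *averaging time*, while the dermal models vary
per-cell contact *frequency*. The package therefore treats per-cell
exposure (factor or frequency) as a property of the schedule — days/week ×
weeks/year, or an explicit per-cell value — not as a modifier, so the
mapping is never violated and each pathway draws its own exposure quantity
from the same schedule row. PPE and attire effects on exposed skin ride on
the biological factor's surface-area permission, the receptor-class route
to that parameter.

## The sensitivity cascade

`run_cascade()` evaluates five nested levels, ten models across the two
pathways. The `traditional` level ignores all structure: one cell, baseline
inputs. Every other level evaluates the full task × season grid and
activates modifier classes cumulatively (`meso_activity` → activity,
`plus_timing` → + timing, `plus_environment` → + environmental,
`plus_receptor` → + receptor and the receptor's body weight). Cells absent
from the schedule table are true zero-dose cells, not missing values, so a
winter with no field work contributes exactly zero.

Two invariants are enforced and tested rather than assumed: seasonal
subtotals equal the sum of their cells and the annual total equals the sum
of subtotals, bit-identically against a brute-force summation oracle; and
removing every modifier of the highest active class reproduces the
next-lower level exactly. Comparisons between levels report the percent
difference, ratio and order-of-magnitude gap
($\mathrm{round}(\log_{10}$ ratio$)$); division by a zero total yields a
flagged undefined comparison instead of an exception so reports stay
serialisable. Note that under this definition a ratio of 2.5 is a gap of
0 — "an order of magnitude" in prose can be looser than the statistic.

## The bundled demonstration scenarios

`reference_scenario()` provides twelve named fixtures: `model_1` …
`model_10` (the cascade models, odd = ingestion, even = dermal) and
`grower_A` / `grower_B` (receptor-level scenarios for both pathways). The
demonstration's full raw parameter tables are not published, so these are
**inferred-parameter encodings, not authoritative parameterisations**: a
synthetic, mutually consistent baseline is fixed (219 mg/kg soil
concentration, 100 mg/day intake, 80 kg body weight, exposure factor 0.16,
adherence 0.07 mg/cm²-event, 3527 cm² exposed skin, 250 contact-days/yr,
with the dermal absorption fraction back-solved so the traditional dermal
dose is exactly 1.26e-7 mg/kgBW/day), and each cell's exposure factor /
contact frequency and each modifier magnitude are back-computed from the
reported per-cell doses. Grower body weights (64 kg and 88 kg) are
likewise synthetic, chosen as plausible values for the described age/sex
bands. Expected values keep the printed three significant figures, so
regression checks allow about 2% for printed rounding; internal arithmetic
is always full double precision, with three significant figures applied
only at the reporting surface.

Two reported numbers are knowingly not reproduced: a seasonal dermal range
quoted with an exponent inconsistent with its own table (7.9e-7 vs a
maximum subtotal of 7.88e-8), and one receptor dermal total (8.02e-9)
that disagrees with both its own cell sum and the accompanying text
(8.20e-9) — the cell sum is used.

## The scenario generator

`generate_scenario()` produces random grids with the statistical structure
the framework assumes, so every pipeline stage is testable without any
external data. Schedule draws use the qualitative working ranges growers
describe — 1–17 h/day and 3–7 days/week, up to 13 worked weeks per
13-week season — as uniform *defaults*, explicitly not fitted
distributions. All draws are integer-lattice based (whole hours/days/weeks;
multipliers on a 0.01 grid) from a single seeded stream per grid, which
makes generation reproducible across platforms and lets serialised configs
round-trip to deeply equal grids. Exposure-factor multipliers default to a
1.25 cap so that no admissible stack of factor-distinct modifiers can push
an exposure factor past 1; resolution would fail loudly if one did, since
every resolved cell is re-validated against the type invariants. What the
generator does *not* emulate: correlation between tasks, multi-worker
populations, or any empirical distribution of factor magnitudes — passing
tests on generated grids demonstrates structural correctness
(validation, additivity, nesting, determinism), not realism of dose
magnitudes for any particular farm.

## Numerical and operational choices

* Subtotals and totals are plain `sum()`s at double precision; no
  compensated summation is needed at these magnitudes and the brute-force
  oracle tests guarantee bit-identity.
* Report CSVs serialise doses both at three significant figures (the
  table convention) and at 17 significant digits, so re-reading the
  full-precision column reproduces totals bit-identically.
* JSON is the exact round-trip configuration format; YAML (15-digit
  precision) is the human-editing format. Parsing, schema and I/O failures
  raise distinct condition classes, which the CLI maps to exit codes
  0/1/2/3 (ok / usage / validation / regression mismatch).
* Zero-exposure cells are explicit zeros; comparisons against zero totals
  are flagged in-band.
* Problem sizes throughout the tests are small by design — grids of 2–3
  tasks and 2–4 seasons, hundreds to a thousand generated scenarios —
  because every quantity involved is closed-form arithmetic; the full
  suite is a matter of seconds.

## Limitations

The package computes exposure doses, not risks: no toxicity values,
hazard quotients or cancer slope factors. The inhalation pathway is not
modelled. Modifier magnitudes are analyst inputs; nothing here infers them
from field data. Uncertainty is handled only through scenario comparison,
not probabilistic propagation — a Monte-Carlo layer over the same grid
abstraction would be the natural extension.
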
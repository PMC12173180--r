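---
title: "Methods: from FAME composition to fuel properties and back through simulation"
author: "famefuel"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famefuel)
```

# Scope and data model

`famefuel` implements the desk-computable analysis chain used when a
microalgal culture is evaluated as a biodiesel feedstock: the laboratory
produces a FAME composition table (weight percent per shorthand species,
from GC analysis), replicate harvest weights, and OD680 growth series; the
package turns those into saturation-class totals, predicted fuel
properties with standard-compliance verdicts, productivity metrics and
per-time-point treatment statistics. Everything upstream of these tables —
peak integration, extraction chemistry, transesterification — is out of
scope by design: the package starts where the instrument output ends.

The central containers are plain S3 lists around data frames: a
`fame_species` (parsed shorthand: carbons, double bonds, optional omega
locant, geometry, qualifier, weight percent), a `fame_profile` (one
sample's species table), and a `biodiesel_properties` vector. Growth and
harvest data are ordinary data frames with fixed column names, which keeps
them trivially readable from CSV and writable by any tool.

# Parsing lipid shorthand

Published composition tables are notationally inconsistent: the same table
can print `C18:1n9t`, `16:1n7c`, `C18:2ω6`, `C20:3c` and `C18:3 alpha`.
The parser therefore accepts a liberal input dialect — optional leading
`C`, `n` or `ω` as the omega marker, a geometry letter directly after the
double-bond count or after the locant, and a trailing word kept as a
qualifier — while emitting exactly one canonical output dialect
(`C{C}:{D}[n{ω}][c|t]`). The invariant the tests enforce is that
`format(parse(x))` re-parses to an equal species for every token in the
bundled table and for fuzzed valid tokens.

Two parsing rules deserve justification:

- `ND` ("not detected") cells are treated as *species absent*, never as a
  zero-weight species. Composition tables distinguish ND from a true 0.0,
  and a phantom zero species would silently change species counts.
- Tokens whose double-bond count reaches the chain length (e.g. `C1:5`)
  are rejected as chemically impossible rather than carried through.

Weight percents are never renormalized to 100: the bundled compositions
sum to ~97% and the published class totals are raw sums, so renormalizing
would change every downstream property. The profile validator allows a
total of at most 100.5 to catch unit errors without rejecting rounded
tables.

# The property correlations

The package evaluates the standard empirical composition-to-property
correlations (see the README for the formula list). Molecular weights use
fixed atomic masses (C 12.011, H 1.008, O 15.999) rather than a live
constants table, trading negligible accuracy for bit-level
reproducibility across environments.

Choices that were genuinely open:

- **LCSF subset.** The cold-filter-plugging-point chain is
  CFPP = 3.1417·LCSF − 16.477. The full LCSF definition weighs
  C20:0/C22:0/C24:0 as well, but evaluating it on the bundled PW
  composition (which contains 0.3% C22:0) gives CFPP 7.0 °C where the
  published table prints 5.6 °C; the C16:0/C18:0 subset reproduces the
  printed value exactly for both media. The subset is therefore the
  default and the five-term form is available via `full = TRUE`, with both
  reported by `predict_biodiesel()`.
- **Rounding lives in the report layer.** Engine functions return full
  precision; `round_for_report()` applies the print conventions (CN, SV,
  IV, DU, HHV integer; CP/CFPP one decimal; density two decimals). This
  keeps compositions of functions exact and makes the rounding policy a
  single, testable place.
- **Compliance boundaries.** The EN 14214 cetane floor is printed as
  "\>51" and is implemented strictly (CN = 51 fails); the iodine ceiling
  "≤120" is non-strict. The ASTM D6751 saponification ceiling of
  370 mg KOH/g is shipped as a second standard spec.

## Known discrepancy with the published property table

Applying the correlations above to the bundled compositions reproduces the
published cloud point, CFPP and saturation-class totals at print
precision, and the published cetane numbers are exactly what the CN
correlation yields from the published SV/IV pairs. The published SV, IV,
DU, HHV and density themselves, however, are *not* reproduced from the
compositions (engine vs published for PW: SV 188.9 vs 179, IV 79.1 vs 72,
DU 89.6 vs 74, HHV 40.5 vs 35): the source evidently used unstated species
subsets or model variants. The package's position is to report the
standard-form values and flag the gap — `run_table3_demo()` writes a
`discrepancies.csv` marking every property whose engine value differs from
the bundled reference by more than 2% — rather than to tune constants
until the printed numbers appear. A correlation tuned to one table is
worthless for the next strain.

# Cultivation metrics

The productivity arithmetic is deliberately plain: per-replicate
concentration quotients, arithmetic means, and sample standard deviation
(n−1). The "±" in published productivity values rarely states which
dispersion it is; sample sd is chosen and documented here. Negative
volumetric productivity (a declining culture) is legal and produces a
warning, not an error. Every returned quantity carries a `unit` attribute
(`"g/L/day"`, `"g/m2/day"`, `"mg/L"`) which the test suite audits, a
lightweight alternative to a units package.

One subtlety the tests encode: an areal productivity computed from a
*rounded* volumetric productivity of 0.05 g/L/day over 35 L / 0.172 m²
gives 10.17 g/m²/day, while the published 10.3 arises from the unrounded
V (0.0506 reproduces it). The engine always computes from unrounded
inputs; reports note the rounding chain.

# Treatment statistics

`compare_treatments()` runs a per-time-point one-way ANOVA
(`stats::aov`), Tukey HSD (`stats::TukeyHSD`), and summarizes the pairwise
decisions as a compact letter display built by the insert-and-absorb
algorithm, implemented in the package: start with all treatments in one
letter column; for each significantly different pair, split every column
containing both; absorb columns that became subsets; assign letters to the
columns sorted by their alphabetically first member, so output is
deterministic. The display's defining property — two treatments share a
letter exactly when their Tukey-adjusted p ≥ α — is verified against
brute-force pairwise logic on generated instances with up to five
treatments.

Defaults: α = 0.05; the two-sample test is the classic equal-variance
t-test (a `var_equal = FALSE` switch gives Welch); time points are tested
independently with no across-time multiplicity correction, matching how
growth-curve figures are conventionally annotated. Two degenerate cases
get explicit conventions: all-identical observations yield p = 1 and a
shared letter, and a two-zero-variance-group t-test yields p = 1 when the
means agree. With exactly two treatments, Tukey's adjusted p collapses to
the equal-variance t-test p (studentized range with two means), which the
tests confirm numerically.

# The synthetic-data generators

The generators exist so every analysis stage has statistically realistic
input with known ground truth:

- **Growth**: logistic OD680 trajectories
  OD(t) = K·od0·e^{rt}/(K + od0(e^{rt}−1)) plus Gaussian measurement noise
  truncated at zero. The logistic is the canonical saturating growth form
  for batch cultures; nothing in the analysis stages assumes it, so it is
  swappable. Defaults emulate a 15-day experiment sampled every 3 days
  with three biological replicates and noise sd 0.02 OD units — the
  sampling design of small-bottle optimization trials.
- **Composition**: a Dirichlet-type perturbation around a base profile
  (gamma shapes proportional to the base fractions, renormalized to the
  base total), preserving the species set and centering on the base; the
  concentration parameter sets tightness (default 200, roughly
  instrument-level variation of a few percent relative on major peaks).
- **Harvests**: OD times a linear OD-to-dry-weight factor times the
  sampled volume. No published calibration exists for the strain the
  bundled data comes from, so `od_to_dw` is a free simulation parameter
  (default 0.9 g/L per OD in the pipeline config), not an estimate.

Seeding is counter-based: the global seed expands to one stream per
treatment, so adding or removing a treatment never shifts another
treatment's draws, and every generator is a pure function of
(spec, seed).

What the simulators deliberately do not model: light attenuation and
nutrient kinetics, grazer contamination, flocculation, OD nonlinearity at
high density, and non-Gaussian instrument error. Passing recovery tests on
simulated data therefore demonstrates the correctness of the arithmetic
and statistics, not field-scale predictive validity.

# Numerical choices and problem sizes

- Noiseless simulate-then-analyze recovery of a programmed volumetric
  productivity is exact to 1e-12 (pure arithmetic, no tolerance hiding).
- The ANOVA type-I calibration runs 1000 null replicates of a 3×3 design
  and requires the rejection rate to land in 0.05 ± 0.02, about three
  binomial standard errors.
- Monte-Carlo recovery of productivity under 5% multiplicative noise uses
  200 replicates (mean within 2% of truth); the composition
  law-of-large-numbers check uses 1000 Dirichlet draws. These sizes give
  comfortable statistical margins while keeping the full suite fast
  enough to run on every change.
- Letter-display brute-force verification uses dozens of randomized
  instances across 2–5 treatments with mixed effect sizes, so both
  significant and non-significant pairs are exercised.

# Limitations

The property correlations are empirical fits with their own domains of
validity; extrapolating to compositions far from vegetable-oil-like FAME
mixtures (very long chains, unusual polyunsaturates) is unsupported. The
compliance checker covers the thresholds the bundled standards table
carries (CN, IV, SV, density); kinematic viscosity and oxidation
stability are not modeled. The statistics module implements fixed-effects
one-way comparisons only — no repeated-measures structure across time
points, which mirrors common practice in the field but understates
within-culture correlation.
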
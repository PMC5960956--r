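---
title: "Methods: fermentation balances and responder screens in anoxic microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fermentation balances and responder screens in anoxic microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutferm)
```

This vignette documents the models, conventions and numerical choices
behind `gutferm`, in the spirit of a methods section: what is computed,
under which assumptions, and where the design was genuinely open.

## 1. Gas and liquid speciation

A sealed microcosm partitions each volatile analyte across three pools:
headspace gas, dissolved gas, and — for CO₂ — bicarbonate.

**Headspace.** The ideal gas law: `n = x · P · V_hs / (R · T)` with `x`
the measured mixing ratio, `P` absolute headspace pressure (kPa), `V_hs`
the headspace volume (ml), giving µmol directly. Non-ideal behaviour at
≤1.7 atm and room temperature is well below chromatography repeatability
and is ignored.

**Dissolved gas.** Bunsen-style solubility coefficients α (volume of
gas at STP per volume of water at 1 atm partial pressure):
`n_aq = α · (p/1 atm) · V_liq / V_m(STP)`. The shipped constants are
interpolated to 22 °C — the midpoint of a 21–24 °C room-temperature
incubation — from standard tables: H₂ 0.0179, CO₂ 0.829, N₂ 0.0153,
O₂ 0.0306, CH₄ 0.0335. At equal partial pressure CO₂ therefore
dissolves ≈46× more than H₂, which is why the bicarbonate correction
matters for CO₂ and is negligible for H₂. The source edition of the
solubility tables used in the original campaign is not recoverable, so
the constants are externalized in `physical_constants()` and every
function takes them as an argument. Gas–liquid equilibrium is assumed
instantaneous at each sampling time; no kinetics.

**Bicarbonate.** Henderson–Hasselbalch with the first dissociation
constant: `HCO₃⁻ = CO₂(aq) · 10^(pH − pKa)`, pKa defaulting to 6.35
(25 °C freshwater value; no ionic-strength correction, as no activity
model is available for the matrix). The second dissociation is
neglected: at pH ≤ 8 the carbonate pool is <1% of bicarbonate. Requesting
a CO₂ total without supplying pH is a hard error — silently omitting the
(often dominant) bicarbonate pool is the classic mistake this module
exists to prevent.

**Normalization.** Totals are divided by the fresh weight of gut
content. In the standard geometry (27-ml tube, 10 ml liquid, 1 g fresh
weight, leaving 17 ml headspace) 1 µmol/g_FW corresponds to 0.1 mM of
microcosm liquid; `to_millimolar()`/`from_millimolar()` are exact
inverses.

**Pressure convention.** Vials "pressurized to 60 kPa" are read as 60
kPa overpressure, i.e. 161.325 kPa absolute, the serum-vial convention;
measured per-time-point pressures take precedence when supplied, since
syringe sampling withdraws gas.

## 2. Biomass chemistry and the electron currency

The recovery accounting treats electrons as a conserved currency. For a
substrate with elemental formula per carbon, the **degree of reduction
per carbon** is `γ = 4 − C_ox`, where the mean carbon oxidation state
`C_ox` solves the charge balance under a fixed oxidation-state
convention. The convention adopted (and verified to reproduce all four
published constants for these substrates) is:

* H +1, O −2, N −3, S −2;
* K, Mg, Ca always excluded from the balance (mineral counter-ions);
* P excluded for biomass and protein formulas, but counted at +5 for
  nucleic acids, where the phosphodiester backbone is integral to the
  per-nucleotide unit; net charge 0 throughout.

Under this convention the full yeast biomass formula
(CH₁.₆₁₃O₀.₅₅₇N₀.₁₅₈P₀.₀₁₂S₀.₀₀₃K₀.₀₂₂Mg₀.₀₀₃Ca₀.₀₀₁) gives
C_ox = −0.019 and γ = 4.019 exactly, and the RNA per-nucleotide unit
(C₉.₅H₁₁.₇₅N₃.₇₅O₇P) gives C_ox = +8.5/9.5 = +0.895 (printed +0.9) and
γ = 3.105 (printed 3.1).

**The protein exception.** The same convention yields γ = 4.134 for the
bovine-serum-albumin formula, while the published constant is 4.145
(C_ox −0.145). No simple sulfur oxidation state reconciles the two
(S ≈ −1.15 would be required), so the discrepancy is not guessed away:
substrate presets accept an explicit `n_r_C` override, the shipped
`bsa_protein` preset carries the published 4.145 with provenance
`"printed-override"`, and the convention-computed 4.134 is retained
alongside. Recovery arithmetic therefore matches the published tables
while the computed value stays inspectable.

**Products.** Fermentation products are registered with integer carbon
and electron counts; for a neutral CcHhOo compound the electron count is
`4c + h − 2o` (acid anions are represented by their undissociated
neutral acids, giving acetate 2/8, butyrate 4/20, methyl butyrate 5/26,
H₂ 0/2, CO₂ 1/0, etc.). The registry is self-consistent: every entry
satisfies the formula.

**Atomic weights** are the IUPAC 2021 conventional values in a single
constants table; these reproduce the published per-carbon molar masses
26.2 (yeast) and 24.2 (E. coli) g·mol⁻¹ to one decimal.

## 3. Net profiles and recovery accounting

Net product amounts are treatment-arm replicate means minus control-arm
replicate means at strictly matched time points — no interpolation, as
both arms of a campaign share one sampling grid ({0, 6, 12, 20, 30} h or
{0, 10, 20, 30} h). Negative nets are retained in the series but
excluded (not clipped and summed) from recoveries, matching the
"no net increase" dash convention of published recovery tables.

Recoveries at the end of incubation (the final grid point by default):
`C% = n_net · c_X / n_c_S · 100` and `e⁻% = n_net · γ_X / (n_c_S · n_r_C)
· 100`. Totals are sums of *unrounded* included entries; display rounds
to one decimal. A compound is excluded when its end net is at or below
an exclusion tolerance, default 0.5 µmol/g_FW — a measurement-noise
floor chosen here, since the source material states none; it is a
parameter, and the synthetic-data closure tests set it to 0.

A product is flagged **transient** when its net exceeds the tolerance at
an interior time point but not at the end — the formate pattern, where
an intermediate is produced and then consumed by secondary processes.
Transients appear in the net profiles but contribute nothing to
end-of-incubation recoveries.

**Ribose basis.** For RNA substrates an alternative accounting asks what
the recoveries would be if only the RNA-derived ribose (5 of the 9.5
unit carbons, carrying 20 electrons as the free pentose) were
fermentable: carbon totals divide by 5/9.5 and electron totals by
20/(n_r_C·9.5). The electron fraction deliberately uses the substrate's
*effective* n_r_C (the published 3.1 by default) for consistency with
the table being rescaled. Because the published totals are themselves
sums of rounded entries, the rescaled values reproduce the published
parentheticals only within ≈0.1.

**Known inconsistency.** The published protein-treatment totals
(40.4/42.1) do not equal the sum of their printed entries (40.7/42.3);
likewise three of the fifteen printed carbon/electron pairs disagree
with the conversion identity by one last-digit unit, because printed
carbon entries are rounded to one decimal before the identity can be
applied. Both facts are asserted as such in the test suite rather than
smoothed over.

## 4. Responder screen

Relative abundances are computed per sample after removing global
singletons (taxa with a single read across the whole table), the
standard guard against sequencing artifacts. Near-identical phylotypes
(pairwise identity at or above a threshold, default 0.97) are merged by
**single linkage**: connected components of the threshold graph, with
counts summed and the most abundant member lending its label. Single
linkage is the defensible reading of "pairs found in a similarity matrix
were merged" absent any description of re-comparison of merged groups;
the merge threshold is exposed because campaigns have used both 99%
(lysate experiment) and 97% (protein/RNA experiments) clustering
cutoffs upstream.

A taxon is **responsive** when its treatment-arm relative abundance
exceeds the paired control by a threshold in at least one sampling
period — 5 percentage points at the family level, 2 at the phylotype
level. The increase is an absolute difference of percentages, not a
fold change: the screen targets taxa that become quantitatively
important, and ratios would let rare-taxon noise explode. Intermediate
time points are typically pooled samples (one value per arm and period)
while the final point has replicates; `arm_abundance_series()` averages
whatever replicates a period provides and evaluates the rule on that
single value. Time-averaged abundances are arithmetic means over the
post-0 h periods.

Diversity summaries: Shannon `H = −Σ p ln p` in nats (natural log by
convention; the base is not stated in the source material), analytic
rarefaction `E[S_d] = Σ_i (1 − C(N−n_i, d)/C(N, d))` evaluated with
log-binomials for stability, and classic Chao1
`S_obs + F1²/(2F2)` with the `F1(F1−1)/2` correction when no doubletons
exist. "Expected phylotypes" is mapped to Chao1 — the standard
expected-richness companion to observed counts; note this is an
interpretation, and that vegan's `estimateR` implements the
small-sample-corrected variant, which differs.

## 5. The synthetic-data module

The generators state a world and emit what instruments would record of
it; they are first-class, tested code, not fixtures.

**Microcosm tables.** A `fermentation_scenario` fixes a substrate, true
carbon-yield fractions per product (Σ ≤ 1, with the implied electron
fractions also validated against 1), an H₂ electron yield, transient
peak fractions, a control-arm baseline, and the incubation conditions.
Time courses are three-parameter logistics normalized to rise from
exactly 0 at the start to exactly 1 at the final grid point (only end
points enter the recovery table, so the configured yields must be hit
exactly there); transients are differences of two logistics normalized
to peak at 1 and return to 0. Gases are inverted through the speciation
model — the total is linear in the mixing ratio, so the inversion is
closed-form — and organics are emitted as mM. Noise is multiplicative
Gaussian per observation (default 5% relative SD, typical GC/HPLC
repeatability), truncated at 0, applied last. With noise off, the full
pipeline (speciate → net → recovery) returns the configured yields to
better than 1e−9 relative error; this closure is a standing test.

**Count tables.** A `community_scenario` fixes a background composition
(defaults in the test fixtures emulate a gut community: a few dominant
families, a long tail), designated responders with per-period target
increases in percentage points, a sequencing depth (default 50,000) and
a Dirichlet overdispersion concentration (default 200; 0 disables).
Treatment-arm proportions elevate the responders and renormalize the
background; impossible targets fail at scenario construction. Draws are
multinomial; `expected = TRUE` emits noiseless expected counts for
deterministic rule checks. Truth labels carry each taxon's maximum true
increase.

**What a green test does not establish.** The generators emulate the
*structure* of real campaigns (arms, grids, replicates, pooling, noise
magnitudes), not their biology: no growth dynamics, no cross-feeding, no
compositional coupling between products, no chimeras or classification
error in counts. Green closure tests establish that the bookkeeping is
exact and the detector behaves as specified on its stated input model —
not that any particular biological claim is reproduced.

**Randomness.** Every generator takes an explicit seed and draws its
streams in a documented order (arms outer, replicates, time points,
analytes inner), so fixed seeds give byte-identical tables.

## 6. Known limitations

* No carbonate-precipitation or tissue-carbonate modelling; CO₂ totals
  at high pH in calcifying systems would be underestimated.
* No statistical testing of product or abundance differences — the
  screen is a threshold rule, deliberately.
* The solubility and pKa constants are point values at 22 °C; campaigns
  at other temperatures must supply their own `physical_constants()`.
* De novo sequence alignment and classification are out of scope; the
  similarity matrix driving phylotype merging is an input.
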
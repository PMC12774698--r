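---
title: "Methods: sum-composition lipid annotation and mixed-effects analysis"
author: "lipidsum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sum-composition lipid annotation and mixed-effects analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsum)
```

# Scope and model of the data

`lipidsum` implements an untargeted lipidomics workflow that starts from a
*picked* LC-MS feature table (feature id, m/z, polarity, retention time, one
peak-area column per sample) and ends at differential statistics. Peak
picking, alignment and gap filling are upstream (XCMS territory) and out of
scope. Annotation is at the *sum-composition* level: a species is
`CLASS(C:db)`, total radyl carbons and total double bonds, with no
sn-position or individual chain resolution.

The intended study design is longitudinal organoid lipidomics: donor-derived
lines of two genotypes (CTRL and ALD, the X-linked adrenoleukodystrophy
condition in which very-long-chain fatty acids accumulate), two tissue
regions (cortical hCO, spinal hSO), several timepoints in days, and a few
replicate samples per line and timepoint.

# Candidate enumeration and mass arithmetic

Each lipid class is a generic formula in which the radyl substituents are
abstracted: we store `base_formula`, the elemental composition at the formal
reference point of zero radyl carbons and zero double bonds, so that

```
neutral_formula(C, db) = base_formula + C x CH2 - db x H2
```

Base formulas are *anchored*: each was derived by subtracting `C x CH2 -
db x H2` from a species of independently known composition (the class's
internal standard where one exists, a literature composition otherwise), and
the anchor is carried in the shipped config (`anchor_c`, `anchor_db`,
`anchor_formula`) so the derivation is checkable at test time. The class
table is an editable TSV, not code.

Monoisotopic masses use IUPAC/CODATA values fixed to at least six decimals,
with `D` as the deuterium label (the CE standard is deuterated, d7). Adduct
m/z is

```
m/z = (n_M x M + s x m(delta) - z x m_e) / |z|
```

including the electron mass `m_e`; at the sub-ppm accuracy of an Orbitrap
operated at resolution 280,000 the electron term (~0.5 mDa) matters.
Enumeration covers *all* integer carbon totals — odd chains occur in real
data (e.g. CE(35:1)) — and the default unsaturation constraint is
`db <= floor(C / 2)`, configurable.

Shipped defaults cover 32 classes (CE, PC, PE and their ether/plasmalogen
forms, PG, PS, PA, PI, DG, TG, CL, lysophospholipids, sphingomyelins,
ceramides and hexosylceramides, sulfatides SM4, gangliosides GM1-GM3, free
fatty acids). Carbon and double-bond ranges are chosen to cover the VLCFA
tail (1-chain classes to C >= 36-40, 2-chain to C60, TG to C80). Adduct
defaults: choline-containing and neutral sphingolipids ionize positive
([M+H]+, [M+Na]+; [M+HCOO]- negative), glycerides and CE as ammonium/sodium
adducts, acidic classes negative ([M-H]-). All of this is configuration.

# Feature matching

A feature is assigned the candidate of its polarity with smallest |ppm
error| within the tolerance (default 5 ppm); `ambiguity_count` records how
many candidates were in tolerance, exact ties break by (class, adduct)
lexicographic order, and retention-time windows are an optional boolean gate
(no RT prediction — the original workflow's RT libraries came from injected
standards we do not have). One annotation per feature; where several
features map to one species, quantification keeps the single feature with
smallest |ppm error| per polarity, preferring the class's primary polarity.

Known near-isobars exist by construction of the (CH2, H2) lattice: for
example `[M+H]+` of PC(C:db) lies ~3 ppm from `[M+Na]+` of PC(C+2:db+3).
The matcher resolves these by nearest-ppm with the ambiguity count exposed;
the annotation round-trip checks therefore use classes and primary adducts
whose candidates are verified to be > 30 ppm apart (CE, PC, TG), which is
what "well-separated" means operationally.

# Semi-quantification

Abundances are semi-quantitative arbitrary units: analyte peak area divided
by the same-sample peak area of the class's internal standard, multiplied
by the spiked amount (nmol). The shipped mix holds the 16 standards of the
wet-lab protocol with their amounts (e.g. 2.0 nmol PC(14:0/14:0) = PC(28:0),
2.5 nmol deuterated CE(16:0)-d7, 2.125 nmol SM(d18:1/12:0) = SM[d](30:1)).
Classes without a dedicated standard map to a configured fallback (sphingoid
classes to SM[d](30:1); gangliosides and sulfatides likewise). This
normalization is exactly invariant to per-sample multiplicative detector
drift, which the tests assert.

Replicates aggregate to one profile per (line, region, timepoint) by the
element-wise median; for an even number of replicates the median is the mean
of the central pair. Visual/trajectory analyses run on these line medians.

Missing-value policy: a species absent in a sample is 0 in the abundance
table; before any log transform, zeros are replaced per species by half its
smallest nonzero value, and all-zero species are flagged and skipped.

# Trajectory analyses

*Class Z-scores.* Class abundance is the sum of member species; each class
row is Z-scored across all (line, timepoint) cells with the sample SD
(n - 1). Constant rows become zero and are flagged. Z-scoring is invariant
to per-class affine rescaling.

*Fold-change curves.* Per species, log2(mean comparison / mean reference)
on line-median abundances; species are binned by (chain count of the class,
total carbons or total double bonds); per-bin means are LOESS-smoothed.
Classes with 4 chains (CL) are excluded from the 1/2/3-chain curves.
Species with a nonpositive group mean are excluded and reported. Swapping
the contrast groups negates the curves exactly.

*LOESS.* Implemented in the package as Cleveland local regression —
tricube weights over the `floor(span x n)` nearest neighbours, local
polynomial of degree 0-2 — because the smoother is load-bearing for the
curve results and we want an implementation we can check against an
independent reference; the test suite demands agreement with
`stats::loess(surface = "direct")` to 1e-6 and exact reproduction of
polynomials up to the local degree. Defaults: span 0.75, degree 2.

*PCA.* `stats::prcomp` on log-transformed, species-centered data
(covariance PCA). Per-species unit scaling (correlation PCA) is available
via `scale = TRUE`; the default is unscaled because class abundances span
orders of magnitude, and on log scale the variance structure is already
comparable — scaling is left as an explicit user choice.

# Differential testing

Per lipid, a linear mixed-effects model on natural-log abundance with a
fixed genotype effect and a random intercept per donor line:

* per-timepoint mode: `log(y) ~ genotype + (1 | line)` within one timepoint;
* overall mode: `log(y) ~ genotype + timepoint + (1 | line)` across all
  timepoints (no genotype x timepoint interaction — the reported quantity is
  a single overall group difference).

Estimation is REML via `lme4`/`lmerTest`. Effects are reported on the
natural-log scale and as log2 fold changes; positive means higher in ALD.

*Inference.* The default p-value uses the Satterthwaite t approximation
rather than a Wald z. With a dozen donor lines the effective degrees of
freedom for the genotype contrast are about 10, and a normal reference
distribution rejects a true null at ~0.078 instead of 0.05; Satterthwaite
restores nominal calibration, which the acceptance suite verifies against
a 500-lipid null simulation (target 0.05 +/- 0.02). `method = "wald"` is
retained for comparison.

*Degenerate fits.* If the mixed fit fails, the model falls back to ordinary
least squares and is flagged `fixed_only`; the same happens structurally for
line-median data in per-timepoint mode (one observation per line, random
intercept unidentifiable — the model is then exactly the two-sample t
setting). Singular fits (line variance estimated at zero) are kept and
flagged `singular`; their Satterthwaite df is close to the OLS df, which is
the right behaviour when the data show no line effect. Both replicate-level
(default) and line-median data levels are exposed because the upstream
convention is ambiguous.

*FDR.* Benjamini-Hochberg per contrast across all species
(`stats::p.adjust`), order-preserving.

# Synthetic data: what it emulates, and what it does not

The generator is first-class, tested code and defines the study conditions:

* design: 3 CTRL and 9 ALD lines, 3 replicates, days 50/100/150/200 (hCO;
  use days 50/100 for hSO), matching the study scale;
* noise: lognormal — additive Normal on log scale — with per-(line, species)
  random intercepts (SD 0.2) and residual SD 0.3 (natural log). Intercepts
  are drawn independently per line *and* species, so each lipid's mixed
  model sees its own line effects; a shared per-line intercept across all
  species would instead put a common offset on every fold change, which is
  neither what the per-lipid model assumes nor what the curve analyses
  could average away;
* trajectories: qualitative class-level log2 timepoint profiles (membrane
  phospholipids and storage lipids high early; lyso-species, SM and Cer
  rising mid; gangliosides/sulfatides/Hex2Cer rising late), linearly
  interpolated over the requested timepoints, config-driven and not a
  quantitative claim;
* disease signature: a hinge in total chain length, log2 FC =
  `0.1 x max(0, C - C0)` per carbon with C0 = 26 / 46 / 62 for 1/2/3-chain
  classes — the VLCFA enrichment pattern;
* spectra: one feature per (species, primary adduct) with multiplicative
  Normal ppm error (default SD 2 ppm); internal-standard features at a
  fixed base area; analyte areas set so normalization recovers the
  abundance table exactly; decoys placed uniformly at least 3 tolerances
  away from every candidate.

All draws come from one seeded generator in documented order, so a seed
reproduces everything bitwise, and the returned truth object (species
effects, trajectories, line intercepts, baselines) suffices to recompute
every expected value.

What it does *not* emulate: chromatographic peak shape, isotope envelopes,
in-source fragmentation, ion suppression, batch effects, missingness
mechanisms, or response-factor differences between analyte and standard.
Passing tests therefore demonstrate correctness of the pipeline's
arithmetic and statistics under its own model assumptions, not robustness
to those instrumental effects.

# Numerical choices and problem sizes

Tolerances: mass table fixed to >= 6 decimals; additivity of masses holds to
machine precision (1e-9 Da asserted); adduct arithmetic includes the
electron mass; default match tolerance 5 ppm; LOESS agreement with the
reference implementation asserted at 1e-6; noiseless quantification
recovery asserted at 1e-12 relative. Ties in candidate matching break
lexicographically and are surfaced via `ambiguity_count`.

The test and acceptance runs use deliberately modest problem sizes chosen
as a sensible desk-scale default: the full shipped database (~15k
candidates, ~8k species) for enumeration and curve analyses; 2+2-line
studies for round-trip checks; 200 replications for effect recovery and
500 single-lipid null fits for calibration; fold-change curves on the full
12-line, 4-timepoint default design. The per-bin noise analysis in the
acceptance suite (e.g. TG bins of ~17 species with per-bin mean log2-FC SD
~0.066) is documented in the curve test itself: flatness below the hinge
is a property of the smoothed curve, not of individual noisy bins.

# Known limitations

* Sum-composition annotation cannot distinguish isomeric species (e.g.
  LPC(C:db) vs ether PC(O-C:db) at identical mass); ambiguity counts and
  optional RT windows are the only guards.
* Semi-quantification assumes equal response factors within a class and
  ignores class-specific ionization efficiency; values are arbitrary units,
  not molar quantities.
* The overall-difference model assumes a constant genotype effect across
  timepoints; an interaction term is deliberately out of the default
  output.
* Identification aids from samples with known metabolic defects, isotope
  pattern scoring and MS/MS annotation are out of scope.
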
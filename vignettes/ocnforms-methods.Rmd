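---
title: "Intact-mass proteoform assignment and half-life estimation for osteocalcin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intact-mass proteoform assignment and half-life estimation for osteocalcin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocnforms)
```

## The scientific problem

Osteocalcin (OCN) is a small bone-derived peptide hormone. The mature mouse
chain is 46 residues long, carries up to three vitamin-K-dependent
gamma-carboxyglutamate (Gla) residues, one intramolecular disulfide, and — in
the mouse but not the human protein — a mucin-type core-1 *O*-glycan on a
serine in the N-terminal region (S8). In top-down (intact-protein) mass
spectrometry, every combination of these modifications produces a distinct
neutral monoisotopic mass, so a deconvoluted mass list is effectively a
census of proteoforms. `ocnforms` automates the two computational tasks such a
study rests on:

1. **Proteoform assignment** — explaining each observed neutral mass as a
   combination of modification deltas on the mature chain, and aggregating
   the relative abundances into proteoform-class ledgers (glycosylated vs
   not, by oligosaccharide, by Gla count).
2. **Half-life estimation** — fitting first-order decay models to plasma
   concentration time courses, ex vivo (decay from the spike-in at *t* = 0)
   and in vivo (declining phase after the post-injection peak), since the
   biological pay-off of the glycan is a longer circulating half-life.

## Mass model

All masses are monoisotopic and computed from elemental compositions using
IUPAC atomic masses (H 1.0078250319, C 12 exactly, N 14.0030740,
O 15.9949146, S 31.9720707; proton 1.007276467). A chain's mass is the sum
of residue masses plus one water; each disulfide bond removes two hydrogens.
The modification alphabet is:

| modification | formula | delta (Da) | default bound |
|---|---|---|---|
| Gla | +CO2 | 43.98983 | number of Gla-eligible Glu (3 for OCN) |
| HexNAc (GalNAc) | C8H13NO5 | 203.07937 | min(2, glycosites) |
| Hex (Gal) | C6H10O5 | 162.05282 | min(2, glycosites) |
| NeuAc (NANA) | C11H17NO8 | 291.09542 | 2 per Hex |
| oxidation | +O | 15.99491 | 2 |
| disulfide | −H2 | −2.01565 | per listed bond |

Two conventions matter and are fixed package-wide:

* **Disulfide formed by default.** The single OCN disulfide is treated as
  formed in every theoretical mass; the fully carboxylated, disulfide-formed
  mouse chain computes to 5243.459 Da, matching the 5243.45 Da reference
  value to better than 0.01 Da, which is what fixed the convention. A
  `disulfides = FALSE` flag gives the reduced chain.
* **Uncarboxylated base.** Assignment deltas are measured from the
  *uncarboxylated*, disulfide-formed chain (5111.490 Da for mouse), and Gla
  is an ordinary alphabet member. This matches the reporting convention in
  which "Glycosylation" with no Gla term means zero Gla.

Isotope envelopes are computed by convolving per-element isotope
distributions (exponentiation by squaring over atom counts), aggregated by
nominal neutron offset with probability-weighted centroid masses. With
`prune_threshold = 0` the probabilities sum to 1 exactly; the synthetic
spectrum generator prunes at 1e-5 for speed.

## Assignment procedure

For each observation, the delta from the base mass is matched by a bounded
depth-first search over modification count vectors, pruning any branch whose
remaining mass range cannot reach the target. The ppm tolerance is relative
to the full proteoform mass (how instrument accuracy is quoted), not the
delta. The default is **10 ppm**: quoted fragment-level accuracy for this
kind of data is ~5 ppm, but the internal spread among deconvoluted intact
masses of the same series reaches 8–9 ppm, and 10 ppm admits all printed
rows of the packaged tables. It is a configurable argument, not a constant.

Candidates are ranked **parsimony-first**: fewest total modification copies,
then smallest |ppm error|, then a lexicographic composition key so that ties
are deterministic. Parsimony matters in practice: a core-1 glycan
(HexNAc + Hex + NeuAc, 656.228 Da) is only 36 mDa away from the
two-site composition 2×HexNAc + Hex + 2×Gla (656.191 Da), which falls inside
a 10 ppm window at 5.8 kDa; the three-unit glycan wins on count. The core-1
structural constraint (`Hex ≤ HexNAc`, `NeuAc ≤ 2·Hex`, occupied sites
bounded by the glycosite inventory) prunes chemically impossible
combinations and can be relaxed with `core1 = FALSE`.

Masses with no in-tolerance composition fall back to a **residual**
assignment: among compositions leaving a leftover of 0–250 Da (the window
covers the adduct/unidentified-modification spread seen in bone extracts),
the largest-mass one anchors the assignment and the leftover is reported as
residual mass. The anchor maximizes explained mass; where several
interpretations tie, the parsimony ranking breaks the tie. These residual
rows *represent* partially explained proteoform ranges, they do not resolve
them — the class ledgers only need the anchor's glycan content, which is
stable across the qualifying anchors in the packaged tables.

```{r assignment-example}
mouse <- ocn_mouse()
tab3 <- read_peaklist(system.file("extdata", "table3_bone_homogenate.tsv",
                                  package = "ocnforms"))
asg <- assign_masses(tab3, mouse, tolerance_ppm = 10)
as.data.frame(asg)[, c("neutral_mass_da", "status", "composition",
                       "oligosaccharide", "ppm_error")]
aggregate_abundance(asg)
```

The bone-homogenate ledger reproduces the published class totals exactly
(glycosylated 99.07%, non-glycosylated 0.93%). For the osteoblast
supernatant table the aggregation returns the *row sums* (83.86 / 16.09),
which differ from the printed class headers (83.88 / 16.12) by the rounding
of unprinted precision in the source; the package reports the internally
consistent row sums and does not force agreement.

## Kinetics model

Concentration decays are modeled as first order,
C(t) = C0 · 2^(−t/t½), equivalently C0 · e^(−kt) with t½ = ln 2 / k.

* `normalize_to_baseline()` scales each replicate independently so its
  baseline record is 100% — matching the practice of expressing every
  plasma/serum course as percent of its own T0 (or, in vivo, of its 30-min
  maximum).
* `fit_first_order()` defaults to ordinary least squares of log C on t
  pooled across replicates. The log-linear fit was chosen as the default
  because it is closed-form, robust, and exactly right under the
  multiplicative (lognormal) error that ELISA readouts show; nonlinear least
  squares (`method = "nls"`, Levenberg–Marquardt) is available as a
  cross-check and agrees to < 2% on clean data. Confidence intervals come
  from a seeded nonparametric bootstrap over replicates (default 1000
  resamples) — replicates (independent plasmas or animals) are the
  exchangeable unit, not individual time points.
* `fit_declining_phase()` discards everything before the peak time (default
  30 min), renormalizes each replicate to its peak value, and fits the
  remainder — the declining-phase convention for post-injection curves. The
  fit is provably invariant to pre-peak data.
* A preparation is flagged **stable** when the analytic 95% CI of the decay
  rate includes zero or the fitted half-life exceeds four times the
  observation window; this mirrors calling a glycosylated preparation
  "stable over 5 h" rather than quoting a meaningless long half-life.

Times are minutes everywhere; concentrations ng/ml.

## What the synthetic generator emulates

`simulate_mass_list()` draws observed masses as theoretical mass × (1 + ε)
with ε ~ Normal(0, ppm_sd·1e−6) — calibration error is multiplicative on the
mass scale — and abundances as truth weights × lognormal noise renormalized
to 100%. `simulate_decay()` uses the exact first-order mean with
multiplicative lognormal noise per record (mean-1 parameterization,
sdlog = sqrt(log(1 + CV²))); the in vivo absorption phase is modeled as a
linear rise to C0 at the peak time, because only the declining phase is ever
fitted. `simulate_spectrum()` renders isotope envelopes of each mixture
component at the requested charges with Gaussian peak shapes at a stated
resolving power (default 70,000, typical of an Orbitrap survey scan).

Default study designs follow the experiments the package addresses: ex vivo
spikes of 100 ng/ml sampled hourly over 0–300 min in n = 4 independent
plasmas; in vivo injections sampled at 15/30/60/90/120 min in n = 5 animals
with a 30-min peak; 5% CV measurement noise, a typical ELISA figure. Seeds
are explicit arguments, generators restore the ambient RNG state, and equal
seeds give identical bytes.

What the generator deliberately does **not** emulate: chromatographic
artifacts, charge-state-dependent deconvolution errors, ELISA calibration
nonlinearity (4PL), matrix effects, or inter-animal pharmacokinetic
heterogeneity beyond multiplicative noise. Passing the recovery suites
therefore shows the estimators are correct and calibrated *under the stated
noise model*, not that any particular biological dataset satisfies that
model.

## Calibration of the half-life estimators

Because the in vivo source curves are not re-fittable from printed text, the
estimators are validated by parameter recovery: 200 simulated studies per
truth (half-lives 108, 120 and 182 min — the reported non-glycosylated in
vivo, non-glycosylated ex vivo, and glycosylated in vivo values), with the
median recovered half-life required within 5% of truth and 90% of estimates
within 15%. Two hundred simulations keep the whole suite under a few
seconds while bounding the Monte-Carlo error on the median well below the
tolerance; the acceptance script uses the same 200-study design.

```{r recovery-example}
rs <- recovery_study(decay_truth(t_half = 120), n_sim = 200, seed = 1)
rs$median
```

## Numerical choices and degenerate inputs

* Enumeration prunes with a 1e-12 Da slack so boundary compositions are kept
  regardless of floating-point summation order; the DFS is tested for exact
  set equality against a naive Cartesian-product oracle.
* `nls` on noiseless data has exactly zero residuals, which breaks the
  Gauss–Newton implementation in `stats::nls`; the package uses
  Levenberg–Marquardt (`minpack.lm::nlsLM`) instead.
* Flat curves (k ≤ 0 after fitting) report `t_half = Inf` with the stable
  flag rather than a negative half-life.
* A zero or missing baseline record, all-zero concentrations, fewer than two
  time points, empty peak lists and malformed site inventories are all
  explicit errors naming the offending replicate, column or position.

## Known limitations

* Site localization is bookkeeping only: the mass math cannot distinguish
  which Ser/Thr carries the glycan; S8 is knowledge injected through the
  site inventory.
* The residual mechanism is descriptive; alternative anchors inside the
  window are not enumerated in the output (only the largest-mass one), so
  residual rows should not be over-interpreted beyond their class.
* Only protons are supported as charge carriers, and the element table
  covers CHNOS; exotic adducts (Na+, K+) surface as residual mass, which is
  how the packaged tables also treat them.
* The two-adduct fraction conditions on HexNAc count ≥ 2 from rank-1
  assignments; mixtures engineered so that a two-adduct and a one-adduct
  composition collide in mass would be mis-ledgered — no such collision
  exists within the default alphabet at 10 ppm.
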
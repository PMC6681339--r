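---
title: "Methods: quantitative characterization of the CoCUN ubiquitin-binding domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative characterization of the CoCUN ubiquitin-binding domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocun)
```

# Scope

CoCUN ("cousin of CUBAN") is the C-terminal 50-residue ubiquitin-binding
domain of N4BP1 (residues 847–896 of the full-length protein). Its
solution-state characterization rests on five quantitative analyses, each of
which this package implements as reusable, tested code:

1. secondary-structure assignment from backbone chemical shifts
   (chemical-shift-index style),
2. interface mapping by chemical-shift perturbation (CSP) of ¹H–¹⁵N HSQC
   peaks under two-state fast exchange,
3. one-site isothermal titration calorimetry (ITC) simulation and fitting,
4. circular dichroism (CD) difference spectroscopy with a transparent
   helix-content estimator,
5. pairwise sequence alignment and scanning for the short hydrophobic
   motifs that define CUE-like ubiquitin-binding domains.

Each analysis stage is paired with a seeded synthetic-data generator that
emulates the corresponding experiment, so the full pipeline is exercised by
tests without any instrument data. The packaged chemical-shift table
(`cocun_shift_table()`) holds the published assignments of the domain: 44
amide-assigned rows over a declared length of 50 (three further assignments
reported in the original study, presumably prolines reached through
non-amide protons, are not tabulated there; the package reports both counts
and does not reconcile them).

# Chemical-shift tables

Tables are tab-separated with one row per assigned residue (`A1`, `Q2`, …)
and up to six nucleus columns (N, HN, HA, HB, HG, HD). Conventions:

* Missing cells are written `_` (as in the printed table) or left blank and
  are stored as *absent* — never as 0. Rows with partially missing data
  (e.g. a missing Hβ) are kept as-is; no imputation is performed.
* Parenthesised qualifiers such as `0.08 (Hγ2)` are preserved in a
  per-cell annotation table, including the serine row carrying an Hδ
  qualifier that serine cannot have — the source is preserved verbatim
  rather than "corrected".
* The Unicode minus sign is accepted on input; ASCII hyphen-minus is
  written on output.
* Numbering is 1-based and local by default, with an explicit offset (846
  for CoCUN) mapping to full-length numbering; `renumber()` is exactly
  invertible.

Positions with no record are filled with `X` when the sequence is rebuilt.
Three unassigned positions whose identity is nonetheless attested (P20 from
the Phe-Pro motif, V48/L49 from the C-terminal LSxx(L/V)L motif) ship as a
documented patch sidecar (`cocun_sequence_patches()`) rather than being
hard-coded: positions 34, 36 and 50 genuinely stay unknown.

# Chemical-shift-index secondary structure

## Model

The secondary shift Δδ = δ~obs~ − δ~rc~ of the Hα proton (and of the amide
¹⁵N) deviates systematically from zero inside regular secondary structure:
upfield (negative) in helices, downfield (positive) in strands. `csi_index()`
digitizes Δδ against a dead band: index −1 below −threshold, +1 above
+threshold, else 0. Defaults: 0.10 ppm for Hα and 1.5 ppm for ¹⁵N, the
customary dead-band half-widths for the two nuclei.

Two random-coil reference sets are packaged. The default, `"wishart1995"`,
is the GGXGG-peptide compilation of Wishart, Bigam, Holm, Hodges & Sykes
(J. Biomol. NMR 5, 67–81, 1995), the modern standard for computing secondary
shifts. The alternative `"csi"` set is the Hα table of the original
chemical-shift-index digitization (Wishart, Sykes & Richards, Biochemistry
31, 1647, 1992); because that index was Hα-canonical, its ¹⁵N entries are
taken from the 1995 compilation. We default to the 1995 values because they
were measured as true random-coil references rather than tuned as
classification mid-points, and they are the basis of most current
secondary-shift software.

The governing nucleus is Hα where assigned, with ¹⁵N as fallback
(configurable). Hα is primary because the packaged table assigns it more
densely and because raw ¹⁵N deviations carry strong residue-type and
nearest-neighbour dependence that make single-nucleus ¹⁵N classification
unreliable without sequence corrections, which are out of scope. The
helix sign convention is upfield-negative for both nuclei. Strand-like
indices (+1) are computed and reported but never promoted to segments: the
domain is a three-helix bundle and the assignment data contain only
isolated strand-like values.

## Segments

`segments_from_index()` extracts maximal runs of index −1. Two parameters
matter:

* `min_run = 4` — the shortest helical tract worth reporting; the shortest
  published tract in this domain is 7 residues.
* `max_interior_zeros = 1` — each *interior gap* of index-0 or unassigned
  residues inside a run may be at most this long. We interpret the slack
  per gap (rather than as a total budget per segment) because single
  unassigned or borderline residues are frequent and independent of one
  another; a +1 index always terminates a run, and segment ends are always
  index −1.

## What the packaged table gives

On the packaged assignments, with all defaults, the package finds exactly
three helical segments — 5–10, 24–32 and 38–41 — against the published
tracts 6–12, 23–32 and 37–45. The first two agree well (71% and 90% of the
published tract lengths). The third is systematically short: the Hα shifts
of Y37 (+0.55 ppm), A43 (+0.35 ppm) and S45 (+0.11 ppm) deviate *downfield*
of random coil inside the published α3 tract, which a single-nucleus Hα
index cannot override. Downfield Hα outliers inside genuine helices are a
known effect of aromatic ring currents and local structural context; the
original assignment combined ¹⁵N shifts with NOE patterns and dihedral
restraints and was therefore not limited by them. This is a documented
limitation of shift-only classification on this data set, not a tunable.

Helix content is segment coverage over a denominator that the published
figure (47%) leaves unstated. The package reports both conventions: 19/50 =
38% of the declared chain length, and 19/44 = 43.2% of the assigned
residues. Neither is forced toward the published figure. (For reference,
direct coverage of the three *published* tracts is 26/50 = 52%.)

# Chemical-shift perturbation

Under fast exchange the observed peak is the population-weighted average of
free and bound positions, with the bound fraction given by one-site mass
action:

$$f_b = \frac{(P_t + L_t + K_D) - \sqrt{(P_t + L_t + K_D)^2 - 4 P_t L_t}}{2 P_t}.$$

The combined perturbation per residue is
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$ with
the conventional nitrogen scaling α = 0.14 (Williamson's review value;
configurable — the appropriate value was not printed in the original CSP
references, so the de-facto standard is exposed as a parameter).

Interface residues are selected by the 1σ rule: Δδ above one population
standard deviation of the profile. A second mode, mean + 1σ, is exposed
because restraint-generation protocols use "above the average"; both are
explicit and the default is plain σ. Whether σ should be computed with or
without the outlier residues themselves is an open choice; the package
always uses all residues present in both peak lists (no zero-filling of
missing residues, no iterative trimming), and documents that choice here.

For docking-restraint preparation, `select_active_passive()` applies the
standard active/passive partition: active = perturbed above the mean *and*
solvent-exposed (relative accessibility ≥ 0.4 by default); passive =
exposed spatial neighbours of the active set. Solvent exposure and the
adjacency are inputs — the package deliberately contains no structure
engine.

# One-site ITC

## Forward model

For cell volume $V_0$ and per-injection volumes $v_i$, the perfusion
(constant-volume displacement) model dilutes the cell contents by
$(1 - v_i/V_0)$ per injection, so with $d_i = \prod_{j \le i}(1 - v_j/V_0)$
the titrand and titrant concentrations are $M_i = M_0 d_i$ and
$X_i = X_{syr}(1 - d_i)$. The cumulative heat after injection $i$ is
$Q_i = n M_i V_0 \Delta H\, \Theta_i$ with $\Theta_i$ the fraction of the
$n M_i$ sites occupied, and the per-injection heat is

$$q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}
      + q_\mathrm{off}\, v_i X_{syr},$$

whose middle term compensates the heat carried out by the displaced volume
and whose last term is a dilution-heat baseline per mole injected. The cell
volume is not stated in the published experiment; 200 µL (the nominal
active volume of the instrument family used) is the default and is
recorded in the output. The stepwise finite-mixing bookkeeping in the test
suite confirms the multiplicative displacement model to fractions of a
percent over a 38 × 1 µL schedule.

## Fitting

`fit_one_site()` minimizes least squares over (n, K~D~, ΔH, q~off~) with
Levenberg–Marquardt (`minpack.lm`). Numerical choices:

* The optimizer works on a rescaled parameterization — log K~D~, kJ/mol
  enthalpies, µJ heats — because in raw SI units the Jacobian columns span
  ~10 orders of magnitude and steep (high-c) isotherms become numerically
  rank-deficient. Standard errors are mapped back by the delta method.
* Starting values are automatic: stoichiometry from the molar ratio at
  which half the total heat has evolved, enthalpy from the first per-mole
  heats, K~D~ at one fifth of the cell concentration, offset from the last
  per-mole heats.
* The first injection is discarded by default (the customary equilibration
  discard; configurable).
* Non-convergence is always flagged, never silent; a Wiseman c-value
  $nM_0/K_D$ outside [0.1, 1000] attaches a warning; all-zero data return
  ΔH = 0 with K~D~ marked unidentifiable (infinite standard error).
* Stoichiometry is fitted free by default: the published analysis reports
  a 1:1 molar ratio without stating whether n was fixed, and fitting it
  free is the more stringent check (the recovery tests require the free n
  to come back at 1.00 ± 0.05).

The synthetic noise model is additive Gaussian per injection with σ equal
to a fraction (default 2%) of the largest absolute heat. Parameter-recovery
studies use 20 replicates of the 38-injection schedule per direction; at
the 2% noise level the K~D~ estimator shows a small finite-noise bias (a
few percent, shrinking below 2% at 0.5% noise), the expected curvature
effect of a nonlinear fit, which the tests characterize explicitly.

# CD difference spectroscopy

Spectra carry explicit unit tags — raw rotatory power in millidegrees, or
mean residue ellipticity
$[\theta] = \theta_{mdeg} / (10\, c\, l\, N)$
(molar concentration c, path length l in cm, N residues) — and conversions
require complete metadata and round-trip exactly. The binding experiment
measures the spectrum of an equimolar mixture and of both components
alone; `complex_induced_changes()` forms
$(\mathrm{mixture} - B) - A$, the conformational change induced by complex
formation (identically equal, by construction, to the complementary
subtraction — the package computes both and documents the identity). A
non-interacting pair gives a zero trace to machine precision; this mirrors
the null result obtained with the ubiquitin-like protein NEDD8, which the
domain does not bind. Subtraction restricts to the overlapping wavelength
range and interpolates linearly; at the native 0.2 nm step, higher-order
interpolation is immaterial.

Helix content from CD uses a deliberately transparent single-wavelength
estimator instead of re-implementing basis-set deconvolution servers
(K2D3, DICHROWEB/CONTIN and the like, which are external black boxes):
$f_H = ([\theta]_{222} - \theta_C)/(\theta_H - \theta_C)$ with the
length-corrected helix limit $\theta_H = -39500(1 - 2.57/N)$ and coil limit
$\theta_C = 2220 - 53T$ (T in °C). This is the standard two-state 222 nm
estimate; it is documented as *not* the published deconvolution, and the
synthetic CD generator builds component spectra anchored at 222 nm so that
the estimator inverts exactly on generated data.

# Alignment and motifs

Pairwise global alignment uses Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment` (BLOSUM62, gap open 10, gap extension 0.5 —
EMBOSS-needle-like defaults; the published comparison used SMART/Clustal
without printing parameters, so reproducible documented defaults are
exposed instead). Identity is the fraction of identical alignment columns;
similarity additionally counts substitutions with positive BLOSUM62 score
(the basis of the published "similarity" figure is unstated; positive
score is the common convention and Clustal strong/weak groups are computed
for the consensus line). Alignment-path tie-breaking is delegated to the
alignment library; scores are verified in the test suite against an
exhaustive enumeration oracle over every sequence pair of length ≤ 4 on a
three-letter alphabet, under both stringent and permissive gap penalties.
Reproducing the published ~40%/47% identity/similarity against the CUBAN
domain of KHNYN requires the external UniProt sequences, which are not
shipped; both candidate comparison windows are supported once sequences
are supplied.

Motif scanning reports every starting position (overlaps allowed) of the
FP and FW pairs, the C-terminal hydrophobic motif φxx(I/L/V)L (φ ∈
FWYLIMV) and its CoCUN/CUBAN variant LSxx(L/V)L. On the patched domain
sequence the FP pair sits at local position 19 (F865–P866 in full-length
numbering) and LSxx(L/V)L at 44–49.

# Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* each analysis
assumes: helical secondary shifts plus Gaussian noise; fast-exchange peak
movement under one-site mass action with interface-only bound-state
offsets; per-injection heats from the one-site isotherm with proportional
Gaussian noise; additive CD mixtures with an optional interaction
perturbation. One seed gives bit-identical output, and every generator is
the right inverse of its analysis stage at zero noise.

They do **not** emulate: spectral lineshapes, peak overlap or assignment
ambiguity; intermediate/slow exchange; ¹⁵N residue-type shift dispersion
beyond the random-coil table; ITC baseline drift, first-injection
artefacts or heat-of-mixing structure beyond a constant per-mole offset;
CD wavelength-dependent noise or absorbance flattening. Passing the
round-trip tests therefore demonstrates the correctness of the inference
machinery under its own model assumptions, not robustness to every
pathology of real instrument data.

# Problem sizes and runtime choices

The recovery studies use 20 replicates per titration direction of the full
38-injection schedule; the exhaustive alignment oracle covers all 14 400
ordered pairs of length ≤ 4 over a three-letter alphabet; the segment
extractor is checked against window enumeration for every index vector of
length 7. These sizes make every oracle exact or statistically
well-resolved while keeping the whole suite around a minute on one CPU.

# Known limitations

* Hα-based CSI underestimates helices containing downfield Hα outliers
  (see the α3 discussion above); a consensus Hα/¹⁵N index with
  neighbour-corrected ¹⁵N references would be the natural extension.
* The CD helix estimator is a two-state 222 nm model; it does not separate
  β-sheet from coil and should not be compared quantitatively against
  deconvolution-server outputs.
* The ITC model is strictly one-site; multi-site or sequential schemes,
  and global NMR+ITC fits, are out of scope.
* No structure engine: solvent accessibilities and spatial adjacency for
  the active/passive partition must be supplied.
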
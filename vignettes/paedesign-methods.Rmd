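---
title: "Methods: composite-index scoring, similarity-field QSAR and derivative screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite-index scoring, similarity-field QSAR and derivative screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`paedesign` models the trade-off at the heart of plasticizer design: a
phthalic acid ester (PAE) that insulates well tends to be lipophilic, and
lipophilicity drives both bioconcentration and toxicity. The package
scores compounds on all three endpoints at once, learns a 3D
structure–activity model for the combined score, and uses that model to
design and screen derivatives of diallyl phthalate (DAP). This vignette
documents the models, their assumptions, the tunable parameters and the
numerical choices; it states no result that the package's tests and
acceptance script do not themselves compute.

## 1. The comprehensive effect index

Raw endpoints live on incommensurate scales (relative permittivity near
1 F/m, fish LC50 spanning 1e-5 to 124 mg/L, logBCF 0.4 to 3.9), so each
column is min-max normalized in its *indicator direction*:

* positive indicator (larger raw value is better):
  $q_{ij} = (v_{ij} - \min_j v_{ij}) / (\max_j v_{ij} - \min_j v_{ij})$
* negative indicator (smaller is better):
  $q_{ij} = (\max_j v_{ij} - v_{ij}) / (\max_j v_{ij} - \min_j v_{ij})$

Permittivity and LC50 are positive indicators (higher permittivity means
stronger insulation; a higher lethal concentration means lower acute
toxicity), logBCF is negative. The two formulas are complementary
(`positive + negative = 1` columnwise), both map the column extremes to
{0, 1}, and both are invariant to positive affine rescaling of the raw
column — properties the test suite asserts on synthetic tables. A
constant column has no information under either formula and is rejected
as a degenerate range.

The comprehensive effect value of compound $j$ is the weighted sum
$I_j = \sum_i w_i q_{ij}$ with weights given as the ratio 25:23:52
(insulation : toxicity : bioconcentration) and normalized by their sum.
With weights on the simplex and $q \in [0,1]$, $I \in [0,1]$, is monotone
in every indicator and permutation-equivariant over compounds.

Two data quirks are handled explicitly rather than silently:

* The published normalized insulation column cannot be recovered from the
  raw permittivities by either min-max formula (it contains two 1.00
  entries, which a min-max map cannot produce from distinct raw values).
  The transformation behind it is unrecoverable, so `index_pipeline()`
  accepts an externally supplied normalized column for any endpoint
  (`overrides`), and reproduction runs use the printed column as input.
* One compound's printed bioconcentration indicator (DIHXP, 0.18) is
  inconsistent with its raw logBCF being the column maximum (which forces
  0.00 under the negative formula). It is treated as a misprint: the
  pipeline computes 0.00, and the reproduction test excludes that single
  cell.

Display convention: indicators and $I$ are reported at 2 decimals and the
toxicity indicator additionally on a ×1000 scale at 3 decimals, matching
the source tables; all internal computation is full precision, and
rounding is applied only at report time.

## 2. Molecule preparation

Conformers must be reproducible for the field descriptors to be
reproducible, so 3D embedding uses a seeded distance-geometry method
(ETKDG) followed by MMFF94 minimization (gradient tolerance 1e-4, cap
10,000 iterations, convergence status reported), delegated to RDKit via a
bundled Python helper. The default seed, 20220309, is recorded in every
molecule's metadata. Partial charges are Gasteiger PEOE — topology-only,
hence conformation-independent, which the tests assert; the Hückel
π-refinement some packages layer on top is deliberately omitted, PEOE
being the dominant term. Atomic hydrophobicity uses the Wildman–Crippen
contribution scheme (the per-atom increments sum to the scheme's own
whole-molecule logP, which serves as the test oracle). Van der Waals
radii come from the Bondi element table. Hydrogen-bond flags are
rule-based: donor = H bonded to N or O; acceptor = N or O with an
available lone pair (nonpositive formal charge; not a four-coordinate N).

Alignment is rigid. The 12-atom benzene-1,2-dicarboxylate core shared by
every phthalate is located by colored subgraph isomorphism (carbon,
carbonyl oxygen and bridging oxygen are distinct colors, so ester and
carbonyl oxygens cannot swap), symmetry-equivalent matches are broken by
a deterministic canonical order, and the mapped atoms are superposed by
the Kabsch closed form (SVD with determinant correction). The template
defaults to DMP — the compound with the highest composite index — and is
configurable. Flexible alignment and conformer ensembles are out of
scope: one minimized conformer per molecule, rigid superposition only.
This is the main reason published lattice-model statistics obtained with
a commercial modeling stack are not expected to be numerically
reproducible here (see §5).

## 3. Similarity-index fields and PLS

Fields are evaluated on an axis-aligned lattice covering all aligned
molecules with a 2 Å margin at 2 Å spacing (defaults; both exposed). At
lattice point $j$ the similarity index of molecule $m$ for field kind $k$
is

$$A_k(j) = -\sum_{i \in m} w_{probe,k}\, w_{ik}\, e^{-\alpha d_{ij}^2}$$

with attenuation $\alpha = 0.3$ Å⁻² and a unit probe (radius 1 Å, charge
+1, hydrophobicity +1, donor +1, acceptor +1) — the conventional defaults
for similarity-index fields. Atom weights $w_{ik}$ are: steric $r_{vdW}^3$
(a volume proxy), electrostatic the partial charge, hydrophobic the
atomic logP increment, donor/acceptor the 0/1 flags. Gaussian attenuation
makes the fields smooth and additive with no singularities, so no
energy-style cutoff is needed; a symmetric clamp (e.g. the 30 kcal/mol ≈
125.4 kJ/mol convention inherited from Lennard-Jones/Coulomb fields) is
available but off by default, because it has no effect on bounded
Gaussian fields at these parameter values and distorts them at extreme
ones.

Per kind, the descriptor block is column-centered and divided by its
block-wide pooled standard deviation (root mean column variance), giving
every field kind unit pooled variance — the standard block-scaling that
stops high-variance kinds from dominating the regression. Scaling
metadata is stored so prediction-time molecules are transformed
identically. An optional minimum-sigma filter drops columns with
standard deviation below 0.05 (block-scaled units) to remove numerically
dead columns; tests that compare against brute-force oracles run with
the filter off.

The regression is PLS1 by NIPALS: deterministic, X columns and y centered
internally, y not scaled (X scaling is the block scaling above).
Leave-one-out cross-validation refits everything — including centering —
inside each fold; $PRESS(c) = \sum_i (y_i - \hat y_{(-i)})^2$,
$q^2 = 1 - PRESS/TSS$, $SEP = \sqrt{PRESS/(N - c - 1)}$. The component
count is chosen as the q²-maximizer (ties to the smallest count, for
parsimony); a SEP-minimizing selector is also implemented since the two
conventions coexist in the QSAR literature. Fit statistics follow the
molecular-design conventions, with the component count in the degrees of
freedom: $SEE = \sqrt{RSS/(N - c - 1)}$ and
$F = (r^2/c)/((1 - r^2)/(N - c - 1))$. Field contributions are
$\sum |b_j| \cdot sd_j$ per block, normalized to percentages, and contour
maps threshold the per-point $sd_j \cdot b_j$ values at the 80th/20th
percentiles (strict inequalities with a sign condition, so an all-zero
coefficient vector marks nothing).

## 4. Derivative design and screening

DAP offers two modification sites with replaceable hydrogens: the
aromatic ring position ortho to the ester pair (site 1) and the terminal
allyl carbon of one side chain (site 2). Products are built by SMILES
substitution into site-annotated scaffold templates, deduplicated by
canonical SMILES, and named `DAP-<site>-<group>` /
`DAP-1-<g1>-2-<g2>` exactly as in the source tables so fixture joins are
exact. The substituent library unions the twelve groups named in the
design discussion with the two (COOCH3, CH=CH2) that appear only in
derivative names — fourteen in all, configurable, with an allow-list to
reproduce any published shortlist (how the published 56-molecule subset
was chosen from the full combinatorial space is not stated anywhere, so
the enumerator does not guess it).

The screening rule keeps derivatives with ΔI > 0, Δinsulation ≥ 0,
Δtoxicity-endpoint > 0 and ΔlogBCF < 0 relative to DAP. The toxicity
term deserves a note: the predicted toxicity endpoint is LC50-like
(larger = less toxic), which is the only reading under which the
published table of 30 "reduced-toxicity" derivatives — whose toxicity
changes are all positive — is internally consistent. Percent changes
divide by the *magnitude* of the reference,
$(x - x_{ref})/|x_{ref}| \times 100$, which keeps signs meaningful for
negative references (binding free energies) and reproduces the published
delta tables cell-for-cell. The binding-energy report computes each
molecule's field-induced shift $\Delta G_{5V} - \Delta G_{0V}$ and flags
molecules whose shift exceeds the reference's — the insulation-enhancement
criterion. Docking scores and MM-PBSA energies are consumed as data,
never computed: receptors, docking and molecular dynamics under electric
fields are out of scope.

## 5. What the synthetic generators emulate — and what they do not

`generate_endpoint_table()` draws endpoint columns uniformly from
configurable ranges (defaults spanning the real 13-PAE table) and pins
both range endpoints onto compounds, so every column's extremes and the
expected normalized 0/1 entries are known exactly.

`generate_qsar_dataset()` emulates what a scaffold-aligned QSAR training
series looks like to the field engine: a shared random point-set scaffold
(8 atoms in a 3 Å half-width box), per-molecule redraws of the atomic
properties at 3 "substituent" positions, and a small coordinate jitter
(0.05 Å) for imperfect alignment. The activity is
$y = X\beta + \varepsilon$ with a sparse $\beta$ (4 columns, unit
magnitude, random sign) drawn on high-variance columns constrained to be
mutually distinguishable (pairwise |r| < 0.8) — columns of a Gaussian
field are locally near-collinear, and opposite signs on collinear columns
would cancel, making the recovery target ill-posed by construction rather
than by any fault of the estimator. Defaults use 10 molecules and noise
σ = 0.02 (activity units); the shipped seeds are 20220309 and the two
integers following it.

Passing tests on these data show that the estimation machinery is
correct: fields match brute-force summation, LOO matches an explicit
per-fold loop bit-for-bit, PLS matches an independent implementation to
1e-6, q² clears 0.5 at small noise, and the sign pattern of
STDEV×COEFF at the true support is recovered when the model capacity
(components) covers the true dimensionality. They do *not* show that a
10-molecule model of real compounds generalizes: real conformers, real
alignment choices and real activity noise are all harder than the
emulation. Consistent with that, the package makes no claim of
reproducing the published model statistics (q² 0.747, r² 0.929, SEE
0.100, F 26.209, or the contribution percentages): those depend on the
commercial stack's conformers, alignment and defaults, which are not
recoverable — and the printed F is in any case inconsistent with r² =
0.929 at c = 6 under every standard convention at either plausible N
(with $N = 10$: $F = (0.929/6)/(0.071/3) \approx 6.5$). The package
documents its own convention and flags the discrepancy instead of
matching the number. On the real 13-PAE fixture the pipeline is exercised
end-to-end in the tests (13 molecules, ~1,700 lattice points, five field
kinds, LOO to 8 components — a few seconds of compute), and the resulting
contribution pattern is reported by the example code, not asserted.

## 6. Numerical choices and degenerate inputs

* Ties in component selection go to the smallest count; ties among
  symmetry-equivalent scaffold matches go to the lexicographically
  smallest atom-index mapping.
* Degenerate inputs fail loudly: constant endpoint columns, constant y,
  fewer than 3 alignment pairs, collinear alignment pairs, all columns
  filtered, a zero percent-change reference, a missing reference
  compound.
* LOO PRESS sums per-fold squared errors with R's long-double
  accumulator (`sum()` over the stored vector), so an explicit-loop
  reimplementation reproduces it exactly.
* The embedding seed, grid geometry, α, probe weights, block-scaling
  constants and filter threshold are all recorded in model/block metadata
  for exact prediction-time replay.

## 7. Known limitations

* The insulation indicator column is supplied data (its published
  transformation is unrecoverable), so insulation enters the composite
  index exactly as printed.
* One minimized conformer per molecule; no ensembles, no flexible
  alignment. Derivative predictions inherit whatever bias that single
  conformer carries.
* Donor/acceptor flags are rule-based and coarse (no geometry-dependent
  strengths, no tautomer handling).
* The branched-isomer expansions of several PAE abbreviations (DIHP,
  DIHXP, DIPP, DTDP among them) are editorial choices, marked as such in
  the fixture.
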
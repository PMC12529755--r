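---
title: "Covariance-based detection of interface interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-based detection of interface interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covcontact)
```

## The model

Given an MD trajectory of a two-protein complex, covcontact asks which
residue pairs across the interface move together (candidate attractive
contacts) or in opposition (candidate repulsive contacts), and then
verifies each candidate geometrically, frame by frame.

For residue $i$ of protein 1 and residue $j$ of protein 2, each
represented by one atom (C$_\alpha$ by default), the interprotein
covariance element is the ensemble average of the dot product of their
displacement vectors,

$$ c(i,j) \;=\; \langle \Delta\mathbf{R}_i^{(1)} \cdot
   \Delta\mathbf{R}_j^{(2)} \rangle, \qquad
   \Delta\mathbf{R} = \mathbf{R} - \langle\mathbf{R}\rangle , $$

in Å², and its normalization (the cross-correlation) is

$$ C(i,j) \;=\; \frac{c(i,j)}{\sqrt{c(i,i)\,c(j,j)}} \in [-1, 1] . $$

$C = 1$ means completely correlated motion, $C = -1$ completely
anticorrelated motion, values near zero independent motion. Two
interacting residues hold a preferred separation and move in concert,
giving $C > 0$; a like-charged pair confined at the interface undergoes
push–pull motion, giving a persistently negative element.

Three points of interpretation the implementation commits to:

* **Ensemble-average estimator.** The $\langle\cdot\rangle$ notation is
  read as a plain average over frames (divide by $n$); an `unbiased`
  flag switches to $n-1$. For the frame counts at which covariance
  estimates are usable the difference is far below the estimator noise.
* **Degenerate normalization.** A frozen residue ($c(i,i)=0$) carries no
  correlation signal and makes the quotient undefined; its elements are
  defined as 0 and a warning is emitted. Normalized values are clamped
  to $[-1,1]$ only to absorb floating-point rounding (elements exceeding
  the bound by more than $10^{-6}$ additionally warn, since that would
  indicate a real numerical problem).
* **Superposition.** Whether frames should be rigid-body superposed
  before computing displacements is genuinely open: raw coordinates
  conflate global diffusion of the complex with internal motion, while
  superposition slightly mixes the two proteins' motions through the
  fit. The default is `superpose = TRUE` (iterative fit of every frame
  onto a refined mean of the whole complex, via `bio3d::fit.xyz`),
  with the flag exposed everywhere; a test demonstrates that an
  injected rigid drift inflates raw covariance and is invisible after
  superposition. Below 3 atoms a rigid-body fit is underdetermined and
  superposition is skipped with a warning rather than silently removing
  the only motion such a toy system has.

## Spatial filtering

Correlation alone is not evidence of contact: transitive coupling
($i$ with $k$, $k$ against $j$) produces long-range elements for pairs
that never touch. The close-contact filter therefore keeps element
$(i,j)$ only if the inter-residue distance on the trajectory-averaged
structure is within 11 Å for positive elements and 13 Å for negative
ones, zeroing everything else. The asymmetric cutoffs mirror common
nonbonded-interaction settings in MD (12 Å cutoff, switching from
10 Å): attractive contacts act at short range, while the push–pull
signature of confined like-charge pairs extends slightly further.
Distances are measured between the representative atoms of the current
representation (C$_\alpha$–C$_\alpha$ by default), on the same averaged
structure the displacements were measured from; the boundary is
inclusive (`<=`). Retained values are copied bit-for-bit, which makes
the filter idempotent and lets tests compare the filtered workflow
against the exhaustive scan exactly.

The same distance rule, with a single cutoff, is available as a
*prefilter*: `build_prefilter_mask()` marks pairs within a cutoff on a
static reference (the averaged structure, or any single frame via
`single_frame_structure()`), and `compute_covariance()` then never
computes masked-out elements. This matters only for memory and time on
large interfaces; a test verifies masked and unmasked values agree on
every kept pair. `count_significant_elements()` reports how many
normalized elements fall below −0.08 or above 0.1 — strict
inequalities, so a value exactly at a threshold does not count — which
is the bookkeeping used to quantify how much a prefilter shrinks the
matrix.

## Interaction classification

Each surviving pair is classified on every frame:

| type | rule | default |
|---|---|---|
| salt bridge | basic side-chain N to acidic side-chain O | ≤ 6 Å |
| hydrogen bond | donor–acceptor distance, and D–H···A deviation from linearity | ≤ 3.5 Å, ≤ 30° |
| hydrophobic | side-chain carbon to side-chain carbon | ≤ 8 Å |
| repulsion, like charge | basic N to basic N, or acidic O to acidic O | ≤ 12 Å |
| repulsion, hydrophobic–polar | aliphatic side-chain C to charged/polar side-chain heteroatom | ≤ 12 Å |

The occupancy of a pair/type is the percentage of evaluated frames in
which the rule holds. All boundaries are inclusive; every cutoff is a
function argument.

Decisions the rules leave open, and what this package does:

* **Angle convention.** The 30° criterion is interpreted as the
  deviation of the D–H···A arrangement from linearity (angle at the
  hydrogen ≥ 150°), the standard convention in MD analysis tools paired
  with a 3.5 Å donor–acceptor cutoff; a literal D–H–A angle of ≤ 30° at
  that distance is geometrically impossible. The cutoff is exposed as
  `hbond_angle_deg`.
* **Atom sets.** Basic nitrogens are LYS NZ and ARG NE/NH1/NH2, plus
  both histidine ring nitrogens only for the protonated tautomer names
  (HSP/HIP). Acidic oxygens are ASP OD1/OD2 and GLU OE1/OE2. Chain
  termini (charged N-terminal amine, OXT) are excluded by default, with
  a flag. These follow common force-field protonation conventions.
* **Aliphatic vs aromatic.** The hydrophobic-contact rule uses all
  side-chain carbons (aromatic rings included); the hydrophobic–polar
  *repulsion* rule requires an *aliphatic* hydrophobic residue
  (ALA/VAL/LEU/ILE/MET/PRO) on one side, so aromatics do not trigger
  it. "Charged or polar" on the other side means
  ASP/GLU/LYS/ARG/HIS/SER/THR/ASN/GLN/TYR, anchored at their
  charged-group or polar side-chain heteroatoms. The rule statement
  names no atoms, so these anchors are a package decision, echoed in
  the run manifest.
* **Sign gating.** Attractive classifiers run on positive-$C$ pairs and
  repulsive classifiers on negative-$C$ pairs, since the correlation
  sign is what nominated the pair; `all_types = TRUE` cross-evaluates
  everything and warns about (rather than drops) detections that
  contradict the sign.
* **Missing atoms.** A truncated side chain (named atoms absent) skips
  the pair with a warning; a donor without hydrogens in the topology is
  skipped with a warning; glycine simply never matches the hydrophobic
  rule. Warnings are raised once per pair, not once per frame.

`brute_force_scan()` applies all five classifiers to *every*
interprotein pair with no covariance step. It is quadratic in interface
size and exists as the correctness oracle: on every pair the filtered
workflow retains, occupancies must match the exhaustive scan
bit-for-bit, and the test suite enforces exactly that, along with a
monotonicity property (growing any cutoff never lowers any occupancy).

## Synthetic generators

The package is testable without external trajectories because both ends
of the workflow have generators with known ground truth.

**Coupled beads.** `generate_coupled_trajectory()` draws per-frame,
per-axis displacements from a multivariate Gaussian. Planted pairs are
realized through per-component latent factors: each connected component
of the coupling graph gets a standard-normal factor per axis, and a
residue with loading $a=\sqrt{|\rho|}$ (sign from 2-colouring the
component) moves as $\sigma(s\,a\,F + \sqrt{1-a^2}\,\varepsilon)$. The
same correlation on all three axes makes the normalized 3D covariance
of a planted pair exactly $\rho$ in expectation — the closed form the
estimator tests rely on. The construction is positive semidefinite for
free, and it reduces to an exact bivariate Gaussian for disjoint pairs.
Its two built-in restrictions are deliberate: mixed $|\rho|$ within one
component, or sign assignments that cannot be 2-coloured, are rejected
as infeasible rather than approximated. A side effect worth knowing:
all cross pairs within one component acquire the component's
correlation, so fixtures that need an exact planted-pair count use
complete bipartite components. The default layout places components
60 Å apart, members on a 1.2 Å sub-grid, partners separated along $x$
by the pair's equilibrium distance — so planted pairs sit inside the
contact cutoffs and every unplanted pair sits beyond 13 Å.

**Toy all-atom motifs.** `generate_allatom_interface()` builds one
residue pair per requested motif from idealized templates (PDB v3 atom
names, explicit polar hydrogens, side chain pointing at the partner).
The criterion is toggled off by rigidly retracting the partner's side
chain, leaving both C$_\alpha$ atoms in place, so close-contact
retention (which looks at the averaged structure) is independent of
occupancy and the reported occupancy equals the planted fraction
exactly: `round(occupancy * n_frames)` leading frames satisfy the
criterion. Correlation signs are planted by a common random translation
of both residues (attractive) or an anticorrelated in-plane push–pull
that leaves the separation axis quiet (clashes), plus a small
independent jitter (0.02 Å) kept far below every geometric margin so
deterministic occupancies survive the noise.

What these generators do *not* emulate: force-field energetics,
anharmonic or multi-state dynamics, water, correlated backbone
context, or realistic side-chain rotamers. Passing tests therefore
demonstrate that the workflow's bookkeeping — estimator, filter logic,
classifier geometry, occupancy accounting — is correct, not that the
physical interpretation of any particular real trajectory is.

## Numerical choices and degenerate inputs

* Covariance is accumulated by BLAS cross-products on the centered
  frames-by-coordinates matrix; the masked path computes row-by-row
  over kept columns only. The two paths agree to machine precision
  (tested at $10^{-12}$; they may differ in the last ulp).
* Ties in `enumerate_contact_pairs()` are broken lexicographically by
  residue label, so orderings are reproducible across platforms.
* Multi-model PDB is read/written through bio3d at the format's
  0.001 Å precision; round-trip tests use a 10⁻³ Å tolerance. DCD is
  read through bio3d; XTC is not supported (no installed reader) and
  raises an informative error suggesting conversion.
* Alternate locations keep altloc A or blank; other variants are
  dropped with a message. A C$_\alpha$-less amino-acid residue is
  dropped from the calpha representation with a warning naming it.
* All randomness is seeded explicitly; identical seeds give
  bit-identical trajectories, and the pipeline itself uses no RNG, so
  identical inputs give identical outputs.

## Problem sizes used by the test suite

The suite runs entirely on generated data, sized to exercise each claim
while staying desk-scale: bound checks on 1,000 random 2×2 fixtures;
estimator checks at 10,000 frames; filter-oracle equivalence on 30×30
interfaces; the recall scenario on a 20×25 interface (500 candidate
pairs, 80 planted as coupled-and-close in four complete-bipartite
clusters, 5,000 frames); occupancy exactness at 8,000 frames per motif.

## Limitations

* Single dominant binding mode assumed. A trajectory that switches
  interfacial states should be split (e.g. by clustering) and each
  state analysed separately; analysing the pooled ensemble yields a
  population-weighted covariance in which state-specific contacts are
  attenuated.
* The distance filter is static (averaged structure); a pair that is
  only transiently in contact can be missed if its average separation
  is outside the cutoff.
* No energetic scoring, no water-mediated contacts, no π-stacking or
  cation–π detection.
* Hydrogen-bond detection requires hydrogens in the topology, as MD
  trajectories normally provide.
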
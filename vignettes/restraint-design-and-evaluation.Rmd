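---
title: "Designing and vetting ambiguous interaction restraints for zinc-finger-DNA docking"
author: "zfAIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and vetting ambiguous interaction restraints for zinc-finger-DNA docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfAIR)
```

## The problem

Classical three-Cys2His2 zinc-finger proteins (Zif268, Sp1, YY1, WT1, ...)
bind DNA by threading their three recognition helices along the major
groove, so that the protein *wraps around* the double helix.  Generating a
complex model for such a system by information-driven docking is harder
than for a single-domain binder: the interface restraints must be divided
over three domains, and an uneven division biases the rigid-body search
away from the wrap-around binding mode even when every restraint is
individually correct.

zfAIR implements everything around the docking engine itself: building the
canonical B-DNA partner, formulating ambiguous interaction restraints
(AIRs) per zinc finger, pre-screening their geometric balance about the
DNA helix axis, and evaluating the docked models that an engine returns.
The engine (rigid-body sampling, flexible refinement, force-field
energies) is deliberately out of scope: `cmdPrescreen()` emits
engine-ready inputs and `cmdEvaluate()` consumes engine outputs.

## The restraint model

An AIR joins an *active* residue of the protein to one or more bases of
the DNA (plus optional *passive*, surface-neighbour selections).  It is
satisfied when the effective distance between the heavy-atom selections is
below an upper bound, by default 2.0 Angstrom.  The effective distance is
the standard ambiguous-restraint sum

$$ d_\mathrm{eff} = \Big( \sum_{m \in A}\sum_{n \in B} d_{mn}^{-6}
   \Big)^{-1/6}, $$

a soft minimum: it never exceeds the shortest pairwise distance, and every
additional nearby atom pair shortens it.  We use the pure sum, without an
atom-count normalisation: only this form preserves the
"$d_\mathrm{eff} \le \min d$" property that the mismatch analysis relies
on (a normalised mean could report a violation for a satisfied contact).
The exponent is configurable for sensitivity checks.

Violations enter as a flat-bottom harmonic,
$E_\mathrm{AIR} = k \sum_i \max(0, d_{\mathrm{eff},i} - d_0)^2$, with
$k = 50$ kcal mol^-1 A^-2, the usual docking-engine convention.  Since the
engine's own force constant is not part of this package's inputs,
$E_\mathrm{AIR}$ values are used for internal comparison (matched versus
mismatched restraints, population splitting), never for comparison against
published score tables.

In *pairwise* mode each AIR joins exactly one residue to one base and
passive sets are empty; this restricted combinatorics is the package's
default, because unrestricted active/passive combinations across three
domains let finger 1 restraints pair with finger 3 bases and vice versa.
`expandNonPairwise()` provides the conventional expansion (passive =
surface neighbours within 6.5 Angstrom at >= 15% relative solvent
accessibility, both community-standard defaults) for the case where
pairwise knowledge is not available.

## Two restraints per domain

`selectTwoPerDomain()` implements the minimal-information heuristic: per
finger, keep two pairwise AIRs, one at each end of the recognition helix -
the candidate closest to canonical position -1 and the candidate closest
to +6, with ties broken toward the smaller residue number.  The halves are
split at the midpoint between the two anchors; a domain whose candidates
all sit on one half cannot cover both helix ends and raises an error that
asks for a different interaction pair (the workflow's back-loop).

Canonical helix positions are derived from the Cys2His2 motif
(C-x(2,4)-C-x(12)-H-x(3,5)-H): position +1 is placed seven residues after
the second zinc-binding cysteine.  An offset of seven reproduces the
family's canonical DNA-contacting anchors for Zif268 (Arg18, Arg46, Arg74
at position -1, with +6 at Arg24, Thr52, Arg80); smaller offsets would
place the helix inside the zinc-binding loop and misclassify the helix
halves.  The offset is an explicit argument of `annotateZincFingers()`
for proteins with unusual architecture.

## Canonical B-DNA and the helix axis

`buildBDNADuplex()` replaces the interactive modelling step usually done
in commercial software.  Embedded standard-geometry nucleotide templates
(planar regular-polygon rings, idealised sugar-phosphate offsets, paired
C1' atoms symmetric about the axis) are stacked by rotating 36.0 degrees
and rising 3.38 Angstrom per step - Arnott-style B-form fiber values.
Both are configurable through `fiberParameters()`; no sequence-dependent
step variation is modelled, since the docking protocol this package
supports starts from explicitly canonical DNA.  The construction axis is
the global z axis, which doubles as ground truth for the axis-fitting
tests.  The templates are idealised, not crystallographic: ring geometry
and backbone offsets are approximate, the base pairs are exactly planar,
and inter-residue backbone connectivity is cosmetic.  Every quantity the
package computes from the duplex (C1' midpoints, twist/rise recovery,
azimuths, contacts, SASA) is insensitive to these approximations, but the
duplex is not a substitute for a refined starting structure in an actual
docking run.

The two strands are merged into a single chain renumbered 1..2n (strand 1
first, then the complement, both 5' to 3'), the numbering convention the
restraint tables use.  `fitHelixAxis()` fits the least-squares line
through the base-pair midpoints (mean of paired C1' atoms), oriented 5' to
3' along strand 1; for an unknown complex the axis simply comes from the
built canonical duplex, which by construction equals the z axis.

## Projection view and balance

Because AIR residues and their bases are close in space, only the protein
residues are projected: each restraint contributes one point (its active
residue's C-alpha) in the plane perpendicular to the helix axis, recorded
as azimuth and radius.  The azimuth origin is the projection of the
first-midpoint-to-first-C1' vector - arbitrary, but fixed and recorded
with the axis, so views are comparable across structures.

`assessDistribution()` calls a set *balanced* when (i) every domain
carries the same number of restraints, (ii) no residue deviates from its
domain's circular-mean azimuth by more than 60 degrees, and (iii) the set
spans at least 120 degrees in total (otherwise the restraints sit on one
side of the DNA).  The two thresholds are not physical constants; they are
configurable (`balanceConfig()`) and their defaults were chosen once so
that an equally divided, major-groove-tracking set classifies as balanced
while a 7/5/6 division or a single residue rotated far out of its cluster
does not.  Domain sectors are derived from the per-domain circular means
rather than fixed angles, since the sector boundaries depend on where the
protein sits along the DNA.

## Evaluating docked models

* **Contacts and F_nat.**  A residue-base contact is any heavy-atom cross
  distance at or below 5.0 Angstrom; hydrogen-bonded and nonbonded
  contacts are counted identically.  F_nat is the fraction of reference
  contacts recovered by a model.
* **iRMSD.**  Interface residues are taken from the reference (any heavy
  atom within 10 Angstrom of the partner, the CAPRI convention); all
  shared heavy atoms of those residues are superposed with the closed-form
  least-squares rotation (`kabschSuperpose()`, with a determinant guard
  against improper rotations) and the RMSD reported.
* **SASA and BSA.**  Shrake-Rupley sphere sampling with fixed radii
  (C 1.70, N 1.55, O 1.52, P 1.80, S 1.80), probe 1.4 Angstrom and a
  deterministic 960-point golden-spiral per atom; BSA is
  SASA(protein) + SASA(DNA) - SASA(complex).  Algorithmic variance between
  SASA implementations is on the order of a percent, so published BSA
  values are only ever compared with a matching tolerance.
* **Wrap-around.**  Published analyses of the wrap-around binding mode are
  visual; zfAIR operationalises it: project the C-alpha azimuths of the
  protein residues in contact with DNA, accumulate the occupied azimuthal
  coverage treating gaps under 120 degrees as covered (three fingers
  sample the circle sparsely), and call the model wrapped when coverage
  reaches 180 degrees *and* all three domains contribute contacts.  The
  coverage is always reported so borderline models can be audited, and all
  three thresholds live in `wrapConfig()`.
* **Ranking and populations.**  Engine scores are parsed
  (`parseHaddockScores()`), never recomputed - no force field is in
  scope.  `rescoreAndRank()` sorts ascending with a stable tie-break and
  keeps the 10 best by default; `populationTable()` splits the sorted
  restraint energies at gaps above 10 kcal mol^-1, which cleanly separates
  the matched (low, tight) population from mismatch populations without
  assuming their number.

## What the synthetic fixtures do and do not show

`makeWrappedComplex()` emulates the geometry that matters to every metric
in scope: an ideal duplex, three mini-helical pseudo-fingers (C-alpha
trace plus a side-chain pseudo-atom, each carrying a real Cys2His2
sequence motif so the annotation code runs on them) placed at prescribed
azimuths, with the canonical contact positions (-1, +2, +3, +6) touching
their own three-to-four-base-pair subsite at a 1.8 Angstrom closest
approach.  That offset is chosen so a pairwise restraint on a designed
contact is satisfied at the 2.0 Angstrom bound, mirroring the
matched/mismatched dichotomy: rotating one domain away
(`makeMismatchedDecoy()`) violates exactly that domain's restraints and
breaks the wrap-around classification while the others stay matched.

The pseudo-fingers are geometric objects, not folded zinc fingers: no
packing, no electrostatics, no realistic side chains, no groove-following
path along the DNA.  Tests passing on these fixtures therefore validate
the *computations* (contact counting, superposition, surface areas,
azimuthal bookkeeping, restraint energies) - they say nothing about how a
real docking engine samples, and fixture BSA or E_AIR magnitudes are not
comparable to values from crystallographic complexes.

## Numerical choices and degenerate inputs

Alternate locations collapse to the highest occupancy (ties keep the
first).  Hydrogens are kept on reading but excluded from every metric;
zinc ions ride along as HETATM annotations and never enter restraints or
metrics.  Coincident atoms make the effective distance singular and raise
an error rather than returning infinity.  Collinear point sets flag the
superposition as degenerate.  An odd nucleotide count or a non-complementary
pair stops the duplex bookkeeping with the first offending pair named.
On-axis points get azimuth 0 by convention.  All generators are
seed-deterministic and restore the caller's RNG state.

Problem sizes throughout the test suite are fixture-scale by choice - a
12-base-pair duplex (486 atoms), a 73-residue pseudo-protein, ensembles of
a handful of models - so the whole suite, including the brute-force
oracles (double-loop effective distances, O(N^2) contact scans, an
exhaustive Euler-angle grid for the superposition), runs in about a
minute.  The surface sampler drops to 120-240 points per atom inside
pipeline tests; the 960-point default is used wherever a single area is
quoted.

## Known limitations

mmCIF, multi-model ensembles beyond model 1, and structure repair are out
of scope.  The balance and wrap-around thresholds are calibrated on the
package's own fixture geometry, not fitted to docking ensembles.  The
B-DNA templates are idealised (see above).  Interaction tables must be
supplied; the package does not derive them from predictors, and contact
tables are distance-based rather than hydrogen-bond-geometry based.
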
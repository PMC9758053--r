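---
title: "Designing obligate ABC helical-bundle heterotrimers with BundleForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing obligate ABC helical-bundle heterotrimers with BundleForge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BundleForge)
```

## The design problem

A heterotrimer of three distinct chains A, B and C that assembles only in
1:1:1 stoichiometry must out-compete every alternative species its
components could form. For two chains there are four alternatives (A, B,
AA, BB); for three chains, under the listing convention that omits
homotypic dimers, there are fifteen (A, B, C, AB, AC, BC, AAA, BBB, CCC,
AAB, ABB, AAC, ACC, BBC, BCC). `enumerateSpecies()` does this bookkeeping;
the two conventions differ only in whether homotypic dimers are counted,
and both are supported explicitly because published counts use both.

Specificity is engineered implicitly (negative design): buried hydrogen-bond
networks and bulky aromatics make the target core uniquely packable, so the
pipeline's job is to find backbones that can host such networks.

## Crick backbones

`buildHelix()` evaluates the generalized Crick parameterization of a helix
winding around a supercoil axis. Per helix the sampled parameters are the
supercoil radius $R$ (Å), the supercoil phase $\Delta\phi_0$ (fixed on the
0/60/.../300° lattice), the helical phase $\Delta\phi_1$ (degrees), and the
axial offset $Z_{off}$ (Å, zero for the first helix, which anchors the
frame). The twists are held at their ideal values
$\omega_0 = -2.85^\circ$ and $\omega_1 = 102.85^\circ$ per residue, giving a
left-handed supercoil with $360/102.85 = 3.5$ residues per turn and hence an
exact seven-residue (heptad) periodicity over two turns. The minor-helix
radius (2.26 Å) and rise per residue (1.51 Å) are conventional
ideal-α-helix constants; the pitch angle follows from
$\sin\alpha = R\,\omega_0 / d$ with $\omega_0$ in radians per residue.
These two constants are not published by any specific generator we mirror;
they are the standard textbook values, and the backbone invariant suite
(CA–CA $3.80 \pm 0.15$ Å, φ/ψ within $(-60 \pm 20, -45 \pm 20)^\circ$)
guards them.

Full backbones are completed by transferring an ideal α-helical residue
frame (built once by internal-coordinate chain construction at
φ = −60°, ψ = −45°) onto each CA triplet of the Crick trace. This is
simpler than per-atom Crick phases and satisfies the φ/ψ invariant.
Antiparallel helices are produced by a 180° rotation about the radial axis
through the helix midpoint, which preserves $R$ and the phase lattice;
residue numbering still runs N→C. $Z_{off}$ is applied last, as a pure
translation, so it is exactly additive.

```{r crick}
h <- buildHelix(CrickParams(R = 7, dphi0 = 0, dphi1 = -20, length = 21))
range(sqrt(rowSums(diff(caCoords(h))^2)))
```

## Sampling grids and the staged six-helix search

`coiledCoilGrid()` reproduces the published coiled-coil search ranges:
$\Delta\phi_1 \in [-100, 100]$ in 20° steps (11 values), $R \in [6.5, 7.5]$
in 0.25 Å steps (5 values), $Z_{off} \in \{-1.5, 0, 1.5\}$ for helices 2
and 3, with 77-residue helices — $55^3 \cdot 9 = 1{,}497{,}375$
combinations. Grids are generated as integer index × step (drift-free,
endpoints inclusive) and enumerated lexicographically, so a search is
resumable by index. `stepwiseBundleSearch()` implements the staged
six-helix protocol: stage 1 samples the three inner helices (R 6.5–7.25,
step 0.375) plus one outer helix at 60° (R 12.25–13.25, step 0.5) and keeps
the backbones whose network test passes; stages 2 and 3 sample only the
newly added outer helix (phases 180° and 300°, same ranges as the fourth
helix — the published protocol states the fifth and sixth helices reuse
those ranges) against the retained parents. Survivors are deduplicated on
parameters rounded to three decimals, a reproducible alternative to
hash-order-dependent dedup.

## Heptad register, masks and layers

`assignRegister()` anchors letter *a* on the residue whose CA→CB vector
points most directly at the bundle axis, choosing among the seven cyclic
offsets the one with the best mean axis alignment over all *a* positions —
a whole-chain criterion that is robust to local noise. Core-facing letters
are *a*, *d* and *g*: *g* participates in packed cores at trimeric
interfaces, which is why it is included by default (it is configurable).
The geometric threshold is implicit in the arg-max form; no numeric angle
cutoff is needed.

`buildSearchMask()` centres an N/P heptad pattern (N = nonpolar,
P = polar-searchable) on the chain, ties broken toward the N terminus —
the published patterns ("N-P-N-P-N-P-N-P-N" for the 11-heptad coiled coil,
"N-P-P-P-N" for the 5-heptad bundle helices) are described as core
patterns without an explicit offset, so centring is our choice and is
deliberately deterministic.

`layerSequence()` is rule-based, not energy-based: network residues are
frozen, remaining core positions take nonpolar residues with at least two
phenylalanines per design (placed at the most buried core positions),
N-heptad cores are fully nonpolar, surface letters b/c/f alternate Glu/Lys
by residue parity, and boundary positions default to alanine. The
alphabets (core {A,I,L,V,F,M,W}, surface {E,K,R,D,Q,N,S,T}, boundary =
union minus Trp) are standard layer-design sets; only the two-Phe rule is a
published constraint.

## The Monte Carlo network search

`enumerateRotamers()` builds polar sidechains by internal coordinates on a
discrete chi grid: staggered sp3 chis {−60, 60, 180}, sp2 terminal chis
{−90, 0, 90}, ring chis on a 30° grid (half-range for Tyr by ring-flip
symmetry), with an extra-rotamer mode adding ±20° sub-rotamers around each
sp3 value. The allowed set is all polar residues plus Asp/Glu
(S, T, N, Q, H, Y, W, D, E); Lys and Arg are excluded by default — the
published search alphabet is "all polar plus acidic charged" and the
published networks use only the former set — but a flag restores them.

Hydrogen bonds are geometric: donor–acceptor heavy-atom distance in
[2.6, 3.3] Å, antecedent–donor–acceptor angle ≥ 120° (the hydrogen is
implicit at ideal geometry), antecedent–acceptor–donor angle ≥ 90°. The
reference energy function behind the original search is out of scope; a
geometric definition is transparent, configurable and testable against an
exhaustive oracle. Clashes are hard-sphere: any heavy-atom pair closer
than 2.8 Å (sidechain–backbone, excluding the rotamer's own residue, or
sidechain–sidechain).

`mcNetworkSearch()` precomputes every placement and the pairwise
hydrogen-bond/clash graph once (position pairs beyond 16 Å are skipped as
unreachable), then runs cheap graph-walk trials: seed a random placement,
repeatedly extend with a random hydrogen-bonded, clash-free placement at an
unused position until stuck, keep the result if it spans the required
chains with the required size. Each trial is seeded as `seed + trial`, so
results are deterministic and monotone in the trial count; deduplication is
on the position→residue-type map. Cross-network rules (three networks per
trimer, at least two Trp/Tyr among them, at least two networks contributing
one each) are evaluated on combinations of position-disjoint networks by
`selectNetworkSets()`. `networkSatisfaction()` requires every buried polar
heavy atom to have a partner; burial uses an axis-distance proxy (buried if
closer to the supercoil axis than outer-helix radius + 3 Å), which is
adequate for parametric bundles and avoids a solvent-accessibility engine.

## Loops, trimming, fusions and rings

`trimChains()` removes whole heptads (by default from the C terminus; the
published protocol staggers termini but does not name the end, so the end
is configurable) and renumbers from 1 — trimming chains A and B of a
77-residue trimer by four and two heptads gives the 49/63/77 chain lengths.
`hairpinPairings()` encodes the clockwise (A–D; B–E; C–F) and
counterclockwise (A–F; B–E; C–D) hairpin closures;
`loopFeasibility()` replaces explicit loop building (torsion-bin types,
fragment checks and secondary-structure prediction are out of scope) with a
span rule: a loop of L residues (2–5) can bridge termini up to
$3.3 (L+1)$ Å apart — an extended-chain bound — after trying terminal
adjustments of −3..+2 residues.

`enumerateSplices()` is the rigid fusion step: for every deletion pair
within the limits (up to a heptad on a trimer block, up to a full repeat on
a repeat-protein block) it superposes overlapping terminal helical windows
on N/CA/C atoms and returns solutions by ascending overlap RMSD; the
minimum overlap of 8 residues (> one helical turn) is our choice, made
once. Residues within 5 Å of a junction are flagged for re-assignment by
the layer rules rather than re-optimized energetically.

`buildRing()` propagates an asymmetric unit by the composed junction
transform and applies the three ring filters under their conventional score
file names: `chain_len` (sequence length), `score0` (internal clashing,
counted as inter-copy backbone heavy-atom pairs under 3.0 Å) and
`close_err`. The closure error is defined here as the RMSD between the
unit's CA atoms and their image under the n-fold composed transform — the
original field is named but not defined in print, and this probe-based form
is dimensionally Å, lever-arm aware, non-negative, and zero exactly when
the composition is the identity on the probe. A pure axial offset of
$\delta$ per step accumulates to exactly $n\delta$, which the tests pin.

```{r ring}
wedge <- makeFixture("c3-wedge")
ringScoreTable(list(buildRing(wedge$model, wedge$transform, 3)))
```

## What the synthetic fixtures do and do not show

All test inputs are generated in code. The planted-triad fixture is a
21-residue C3 bundle (R = 7 Å, $\Delta\phi_1 = -20^\circ$) on which a
Ser/Thr/Asn network spanning all three chains demonstrably exists — the
generator re-discovers it by Monte Carlo and re-verifies every bond with
`detectHBonds()` before the fixture is accepted. The c3-wedge and toy
repeat-protein blocks are labelled synthetic: the wedge's junction
transform is the exact 120° rotation, and the repeat block's helices are
not loop-connected. Passing tests therefore demonstrate the correctness of
the geometry, search and filter machinery on idealized inputs; they do not
demonstrate that any particular sequence folds or assembles — experimental
success rates are not computable quantities, and nothing here attempts
them. Real crystal-structure comparison requires external coordinate files
and runs only when they are supplied.

## Problem sizes and determinism

The test suite runs the full machinery at reduced scale — 14–77-residue
helices, the planted-triad search at 300–1,000 trials with a three-type
alphabet, staged searches on few-spec grids — chosen so the whole suite
re-derives every claim in well under a minute while exercising the same
code paths as a production run (`trials = 100000` with the full nine-type
alphabet is the production default, and the precompute-then-walk design is
what makes it tractable). All randomness flows from single integer seeds;
identical inputs give bitwise-identical backbones and identical network
lists.

## Known limitations

No energy function: packing quality, electrostatics and solvation are
proxied by hard spheres, axis-distance burial and alphabet rules. No
sequence optimization beyond the layer rules; no loop coordinates; no
structure-prediction filters. The register criterion assumes a roughly
straight bundle axis per model (supply the axis explicitly for fused or
ring geometries). These boundaries are deliberate: the package implements
the parametric sampling, network search and assembly logic of the design
pipeline, and stops where heavyweight external engines would begin.
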
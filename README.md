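# BundleForge

BundleForge implements the computational pipeline for designing **obligate
ABC heterotrimers** — three-chain protein assemblies (coiled coils and
six-helix bundles) engineered so that only the 1:1:1 ABC species forms.
It is aimed at protein designers and structural bioinformaticians who want
the parametric backbone sampling, hydrogen-bond-network search and
assembly-topology logic of that design approach in a scriptable, fully
deterministic form.

## What it computes

**Negative-design bookkeeping.** A two-chain AB design competes with 4
alternative species (A, B, AA, BB); a three-chain ABC design with 15
(A, B, C, AB, AC, BC, AAA, BBB, CCC, AAB, ABB, AAC, ACC, BBC, BCC).
`enumerateSpecies()` enumerates these multisets under either listing
convention.

**Crick backbones.** `buildHelix()` / `assembleBundle()` generate
poly-alanine bundles from the generalized Crick parameterization: per helix
the supercoil radius *R*, supercoil phase Δφ₀ (lattice 0/60/.../300°),
helical phase Δφ₁ and axial offset *Z*off, with ideal twists
ω₀ = −2.85 and ω₁ = 102.85 °/residue, giving a left-handed supercoil with
360/ω₁ = 3.5 residues per turn and exact heptad (7-residue) periodicity.

**Grid sampling and the staged search.** `coiledCoilGrid()` reproduces the
published coiled-coil grid (Δφ₁ −100..100° step 20, *R* 6.5–7.5 Å step
0.25, *Z*off ∈ {−1.5, 0, 1.5} for helices 2–3): 55³·9 = 1,497,375
backbones. `stepwiseBundleSearch()` runs the three-stage six-helix search
(inner helices + one outer, then the fifth, then the sixth helix, each
stage filtered by a network-test callback).

**Hydrogen-bond networks.** `mcNetworkSearch()` places polar rotamers
(S, T, N, Q, H, Y, W, D, E by default) on N/P-masked core positions and
finds connected inter-chain networks by seeded Monte Carlo growth, with
geometric bond criteria, hard-sphere clashes, per-network span/size rules,
cross-network aromatic rules and satisfaction filtering
(`networkSatisfaction()`).

**Register, layers, trimming, loops.** `assignRegister()` (heptad letters
a–g from CB orientation), `buildSearchMask()` (patterns such as
N-P-N-P-N-P-N-P-N), `layerSequence()` (rule-based core/boundary/surface
assignment with ≥2 core phenylalanines), `trimChains()` (heptad trims:
77/77/77 → 49/63/77), `hairpinPairings()` and `loopFeasibility()`.

**Fusions and rings.** `enumerateSplices()` rigidly joins building blocks
by helical-overlap superposition; `buildRing()` propagates a fused unit
into C2–C5 rings and filters on the three score fields `chain_len`,
`score0` (inter-copy clash count) and `close_err` (RMSD of the n-fold
transform from identity, measured on the unit's CA atoms).

## Worked example

```r
library(BundleForge)

gridSize(coiledCoilGrid())
#> 1497375

spec <- BundleSpec(lapply(c(0, 120, 240), function(p)
  CrickParams(R = 7, dphi0 = p, dphi1 = -20, length = 21)))
bundle <- assembleBundle(spec)
bundle
#> BackboneModel: 3 chains (A:21, B:21, C:21), 315 atoms

mask <- buildSearchMask(assignRegister(bundle), "NPN")
nets <- mcNetworkSearch(bundle, mask,
  networkConstraints(minResidues = 3, spanChains = c("A", "B", "C"),
                     nNetworks = 1, minAromatics = 0,
                     minAromaticNetworks = 0),
  trials = 500, seed = 0, types = c("S", "T", "N"), extraRotamers = TRUE)
nets[[1]]
#> HBNetwork: 3 residues on chains ABC; 2 H-bonds; 0 aromatics
nets[[1]]@placements
#>   chain resi type   chis
#> 1     B   10    N  80,90
#> 2     C   10    N 60,-90
#> 3     A   10    N 40,-90

enumerateSpecies(c("A", "B", "C"), 3, c("A", "B", "C"), "paper-trimer")
#> SpeciesSet: 15 alternative species over {A,B,C}, max size 3 (paper-trimer)
```

The network above is an Asn triad at position 10 of each chain — one
asparagine per chain, hydrogen-bonded across all three interfaces, exactly
the kind of buried polar layer the design strategy uses to enforce the ABC
assembly. The 1,497,375 is the full published coiled-coil search grid; the
15 species are what the ABC design is selected *against*.

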
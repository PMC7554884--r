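---
title: "Topological water networks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological water networks: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twnring)
```

## The model

`twnring` treats binding-site hydration as a graph problem. Each explicit
water in a snapshot is a rigid three-site molecule (one oxygen, two
hydrogens, fixed internal geometry); a pair of waters is hydrogen-bonded
when its TIP3P interaction energy — nine Coulomb site–site terms plus one
oxygen–oxygen Lennard-Jones term — is at or below −2.25 kcal·mol⁻¹. That
threshold sits at the minimum of the water–water pair-energy distribution,
so it separates genuinely bonded pairs from thermal contacts. A topological
water network (TWN) is then a *chordless* cycle of 3–6 waters in this
graph, classified R3–R6 by size and represented by the mass-weighted center
of mass of all its atoms.

The analysis makes three physical assumptions worth stating explicitly:

* **Rigid three-site waters.** Energies are evaluated on the coordinates as
  given; no minimization, no flexible or four-site water models. Frames
  whose waters lack hydrogens are rejected rather than rebuilt, because the
  energy criterion needs donor geometry.
* **Energy criterion on the full pair potential.** The −2.25 kcal·mol⁻¹ test
  is applied to the complete Coulomb + LJ value, not the Coulomb part alone;
  the threshold is the documented minimum of that full pair potential.
* **Snapshots, not trajectories.** Each PDB MODEL is analysed
  independently; a ring recurring in several frames counts once per frame,
  which is what an occupancy table over 100 extracted frames tallies.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `q_O`, `q_H` | −0.834, +0.417 | e | TIP3P partial charges |
| `A`, `C` | 582000, 595 | kcal·Å¹²/mol, kcal·Å⁶/mol | TIP3P O–O Lennard-Jones |
| `coulomb_constant` | 332.0636 | kcal·Å·mol⁻¹·e⁻² | makes e²/Å come out in kcal/mol; the pair potential is written without units, and this standard electrostatics constant is what makes the −2.25 criterion meaningful |
| `hbond_energy_criterion` | −2.25 | kcal/mol | pair-potential minimum |
| `cutoff` | 3.5 | Å | O–O prefilter; no rigid TIP3P pair beyond 3.5 Å reaches −2.25, so this only removes hopeless candidates from the O(n²) energy pass (exposed for auditing) |
| `distance_tolerance` | 1.0 | Å | site-matching correspondence tolerance, typical for pocket-atom equivalence |
| region radius helper | 3.0 | Å | default sphere radius around ligand fragment centroids |

Minimum-image treatment of periodic boxes is supported but **off** by
default: binding-site analyses operate far from box edges, and rings that
span periodic images are of no interest there.

## Numerical and algorithmic choices

* **Ring perception.** "Water ring" is formalised as a chordless simple
  cycle. Without chord filtering, a hexagon with one cross-bond would be
  counted both as the 6-cycle and as its two sub-rings; with it, only the
  two smaller rings survive, matching chemical ring-perception practice.
  The enumerator grows paths from each minimal node and prunes any
  extension that touches a non-adjacent path member, which enforces
  chordlessness incrementally; the test-suite checks exact agreement with
  an exhaustive subset-enumeration oracle on hundreds of random graphs.
* **Canonical ring form.** Among all rotations/reflections of the member
  sequence, the lexicographically smallest; this makes deduplication and
  order-independence testable (`enumerate_rings` output is invariant to
  water storage order).
* **Center of mass.** All 3·n atoms, mass-weighted (O 15.999, H 1.008 Da,
  from an internal element table since PDB carries no masses). An
  oxygen-centroid mode (`com_mode = "oxygen"`) exists for sensitivity
  checks; "center of mass" is the primary definition.
* **USR moments.** μ₁ = mean, μ₂ = *population* standard deviation,
  μ₃ = signed cube root of the third central moment. This keeps all twelve
  components in Å, so the unweighted Manhattan sum in the similarity score
  is dimensionally coherent, and preserves the sign of skew. The reference
  order is frozen as ctd, cst, fct, ftf; any fixed order gives identical
  similarities as long as both descriptors use it. Ties for
  nearest/farthest reference points break at the lowest point index.
* **Ratio rounding.** Occupancy percentages round half-away-from-zero to
  one decimal (print convention of occupancy tables); base R's
  round-half-even would print 0.25 → 0.2. Ratios are taken over *assigned*
  rings only; rings outside every region are excluded from the denominator
  and reported separately, so the table always sums to 100 ± rounding.
* **Site matching.** The "largest possible matching" between two pockets is
  approximated: element-typed triplets whose sorted side lengths agree
  within 2×tolerance (each matched endpoint may be off by the tolerance,
  so pairwise distances may differ by twice it) seed a least-squares
  (Kabsch) superposition, extended greedily by closest same-element pairs
  within tolerance, refit twice, best over both seed directions. Greedy
  extension is not guaranteed optimal; on small random sites the test-suite
  requires it to reach the optimum found by an exhaustive-seed,
  optimal-assignment oracle. A search that has matched every atom of the
  smaller site stops early, so self-comparison is fast and scores exactly 1.
* **Degenerate inputs.** USR descriptors need ≥ 2 points (error below) and
  are flagged degenerate below 4; the TWN–ligand similarity requires ≥ 4
  points per side and names the offending side in its error. Coincident
  interaction sites raise a singular-geometry error rather than returning
  Inf.

## The synthetic data generator

`plant_spec()` / `generate_frames()` emulate the *detection problem*, not
liquid water: regular n-gon rings with the canonical 2.75 Å O–O hydrogen-
bond spacing, each water donating one O–H along the ring edge, planted in a
sparse box of randomly oriented noise waters (rejection-sampled to keep
oxygens ≥ 2.5 Å apart), with optional per-water rigid Gaussian jitter.
Defaults — two trimers and one hexamer per frame, 20 noise waters in a
40 Å box, 10 frames, zero jitter — constitute the canonical planted-truth
scenario the tests recover exactly.

Two generator details are deliberate design decisions:

* **Bent trimer bonds.** An O–H aimed *exactly* along a trimer edge leaves
  only ~1 kcal·mol⁻¹ of margin below the bonding criterion (the 60°
  interior angle forces the donor hydrogen close to the acceptor's
  hydrogen), and a 0.05 Å jitter then breaks ~15% of edges. Real trimer
  hydrogen bonds are bent, so the R3 donor O–H is tilted 20° outward in the
  ring plane, giving ~−5.6 kcal·mol⁻¹ per edge and robust recovery under
  small jitter. R4–R6 donate straight along the edge (~−6 kcal·mol⁻¹).
* **Rigid jitter.** Jitter translates each water as a rigid body rather
  than perturbing atoms independently, consistent with the rigid water
  model; internal geometry is never distorted.

What a green planted-truth test establishes: the pipeline finds exactly the
rings that satisfy the stated energy/topology definitions, with correct
classes, counts and centers, and degrades gracefully with noise. What it
does **not** establish: anything about real hydration thermodynamics,
water residence times, or the occupancy pattern of any particular protein —
those depend on the MD ensemble fed in, which this package consumes but
never generates.

## Known limitations

* PDB snapshots only; no GRO/XTC/DCD readers.
* Hydrogen positions on waters are required, never rebuilt.
* The site matcher approximates the maximum matching; adversarial
  geometries can in principle defeat the greedy extension even with both
  seed directions (bounded in tests to ≥ 90% of the exhaustive optimum on
  small sites; in practice it attains it).
* Published occupancy percentages for specific kinases depend on the
  original simulation and region geometry, which are not recoverable from
  the analysis definitions alone; this package reproduces the *arithmetic*
  of such tables exactly, and one printed value (34.2% where the row's own
  counts give 34.1%) appears to have been hand-adjusted so columns sum to
  100.0 — the operation here follows the defined rounding.
* Electro-shape and other charge-aware USR variants are out of scope.

## A compact end-to-end check

```{r example}
spec <- plant_spec(random_seed = 7)
rings <- analyze_frames(generate_frames(spec))
table(rings$ring_class)

centers <- t(vapply(spec$rings_to_plant, function(r) r$center, numeric(3)))
twn_distribution(rings, region_spec(c("A", "B", "C"), centers, rep(3, 3)))

site <- make_toy_site(20, seed = 1)
binding_site_similarity(site, site)$score
```
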
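---
title: "Modeling assembly/disassembly pathway compatibility from occupancy data"
author: "OccuPath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling assembly/disassembly pathway compatibility from occupancy data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OccuPath)
```

## The model and its assumptions

A mechanism is a fixed **association order** of *n* single-letter factor
codes paired with one of the *n*! **dissociation orders**. Each mechanism
forces DNA through a cycle of bound-factor subsets: assembly intermediates
S₁ ⊂ … ⊂ Sₙ (the first *k* associating factors), then disassembly
intermediates shedding factors in dissociation order, back to the empty
state. Under steady-state cycling, the measured percent occupancy of factor
*i* is the summed dwell fraction of the cycle states containing *i*.

The inference rests on assumptions inherited from the data type, stated
here because they bound what a "compatible" call means:

* occupancy (scaled fold-over-background) is proportional to the fraction
  of DNA molecules bound — crosslinking efficiency is handled by per-factor
  0–100% scaling and by modeling group medians rather than single genes;
* one mechanism underlies all genes of a group;
* the association order is an external constraint (taken from biochemistry),
  not inferred; the method *excludes* dissociation orders rather than
  proving one.

### The two rules

`rule1Allows()`: if *j* associates before *i* and dissociates after *i*,
every occupied state containing *i* contains *j*, hence unconditionally
occ(i) ≤ occ(j). A strict violation rejects the mechanism; equality is
allowed (it is physically attainable).

`rule2Allows()`: for a middle factor *m* with occ(m) > occ(a) + occ(b)
(strict), *a* associating before and *b* after *m*, the states containing
*m* but neither *a* nor *b* must carry positive dwell, which exists only if
*m* dissociates after both.

`isCompatible()` is their conjunction. All comparisons carry a tolerance of
1e-9 on the percent scale so preprocessing round-off cannot flip a call.

### The linear-feasibility oracle

`lpFeasible()` asks exactly the dwell-fraction question: is there f(S) ≥ 0
over the occupied states with Σ_{S∋i} f(S) = occ(i) for every factor
(optionally Σ f ≤ 100, the DNA-total cap, off by default because the 0–100%
per-factor scaling keeps it non-binding on archetype inputs)? A phase-1 LP
(minimize the sum of downward slacks, `boot::simplex`) decides it; the call
is *feasible* iff the optimal slack sum is ≤ 1e-7. A feasible verdict
returns a witnessing dwell assignment; an infeasible one returns a Farkas
vector y (y'A ≤ 0 over states, y·occ > 0), so every verdict is
self-certifying and the test suite verifies the certificates by direct
arithmetic rather than trusting the solver.

### How well do the rules approximate the oracle?

For n ≤ 3 the rules and the LP agree **exhaustively** on the full 5%-step
occupancy grid (21³ vectors × 6 mechanisms; 0 divergences — the acceptance
suite recomputes this). For n ≥ 4 they provably do not coincide: the rules
are *necessary* conditions but miss some four-way constraints. A concrete
counterexample found by `compareRulesToOracle()` and checkable by hand:
association A→B→C→D, dissociation D→A→B→C, occupancies
(39.7, 60.7, 37.1, 31.7). Both rules pass, yet the occupied states
{A, AB, ABC, ABCD, BC, C} admit the Farkas vector y = (−1, +1, −1, +1):
occ(B) + occ(D) ≤ occ(A) + occ(C) is forced, and the data violate it.
Random scans find ~0.1–0.4% divergent (vector, mechanism) cells for
n = 4..6, and even the 4-factor archetype chart contains one such cell
((H,H,L,H) × dissociation B→P→H→T), where the kinetic fit sides with the
LP. All divergences observed are one-sided (rules over-accept, never
over-reject); `compareRulesToOracle()` warns whenever a divergence appears
instead of absorbing it. Practical advice: use the rules for speed, the
oracle for verdicts on four or more factors.

## Kinetic validation

`buildKineticModel()` turns a mechanism into 2n irreversible mass-action
reactions over the free factors and the distinct DNA states; DNA and each
protein start at concentration 10 (arbitrary units; `dnaTotal = 1`
reproduces the reduced-DNA variant, which tests confirm leaves the
classification unchanged). The steady state is computed by damped Newton
iteration on the reduced system (conservation laws substituted), warm-started
across objective evaluations; stiff integration (`deSolve::lsoda`, horizon
doubling, failure is explicit) is the fallback, and an independently coded
full-species integration serves as the oracle in the tests.

`estimateParameters()` emulates a random-search fitter: `nRestarts`
(default 20) seeded uniform draws of log₁₀ rate constants in [−4, 4], each
refined by Nelder–Mead (iteration cap 300 per dimension, plus up to three
polish restarts of the simplex from the incumbent — without the polish,
~8-dimensional searches occasionally stall two orders of magnitude above
the floor). The objective is

E = Σᵢ wᵢ (xᵢ − yᵢ)², xᵢ = (1 − Occᵢ/100)·10,

compared on the free-protein concentration scale, with measured occupancy
floored at 0.1% (the practical lower limit of the assay). Weights default
to wᵢ = 1: the automatic weighting of the original fitting software is not
recoverable, and the classification rests on the *gap* in log₁₀E, not its
absolute scale (a mean-square option exists). Fitted rate constants are
reported but not interpretable — the system is deliberately
under-determined.

Across chart cells log₁₀E is strongly bimodal: on the three-factor
archetype chart compatible cells reach ≤ −4.7 (typically ≈ −10) and
incompatible cells sit at ≥ +0.48. The default threshold −2.1 is the
2-means midpoint of that gap, frozen at build time and user-overridable
(`gapThreshold()` recomputes it for any fit set). Fits are exactly
reproducible under a fixed seed; log₁₀E of an exact fit is floored at −12.

## Preprocessing parameters

| Parameter | Default | Meaning |
|---|---|---|
| `upperPercentile` | 99 | fold at rank ⌈0.99·N⌉ maps to 100% (98 is the robustness variant) |
| `cutoff` | 10 (%) | below → L, at or above → H (ties to H, reading "below 10% … low, all others high" literally); 15% and three-tier 10/20% variants supported |
| consolidation | on for n ≥ 4 | >100-gene children exempt; <10-gene children force a merge; otherwise a >4:1 split merges; merged group takes the larger child's label |

Fold-over-background divides probe signal by the replicate-combined
background strain (each replicate normalized to its grand median, then
per-probe median) and then by the median ratio over tail-to-tail intergenic
probes, so factor-free regions sit at exactly 1. Scaling subtracts the
background fold (1) from both the value and the 99th-percentile anchor —
the only reading under which the anchor maps to exactly 100%. Factor IP
replicates are combined by per-probe median (the combination rule is stated
only for background replicates; scaling removes any global factor).
Consolidation is applied incrementally as factors are added (skipped for
two- and three-factor models, matching the procedure it implements). Genes
lacking a usable TSS probe are dropped with a message.

## What the synthetic generator emulates — and what it does not

`syntheticConfig()` defaults describe the targeted study design: ~20,000
probes, one TSS probe for each of 5,743 genes, archetype H/L patterns at
L = 5% / H = 40%. Values the design leaves unstated were chosen once:
2,000 T-T probes, 2 IP + 3 background replicates, lognormal noise
σ = 0.1 (multiplicative noise is the microarray convention; no noise model
is stated), background level 100, 9-fold signal at 100% occupancy,
per-gene jitter sd 1.0 (a 5σ margin between L = 5% and the 10% cutoff, so
planted labels are recoverable — ≥95% recovery at σ = 0.1 is part of the
generator's definition), and a 250-gene fully-occupied top tier. The top
tier anchors the percentile scaling: the 99th-percentile probe must fall
inside it, otherwise the scale is set by the H tier and every L gene
inflates past the cutoff (the test configuration keeps the top tier at
2% of probes for the same reason). Per-factor crosslinking scales κ are
planted and verifiably cancelled by the scaling.

Not emulated: probe-level spatial structure, sequence effects on
crosslinking, transcription-driven polymerase occupancy in gene bodies,
platform-specific normalization. Passing tests therefore show the
*pipeline arithmetic* is right, not that real arrays are this well behaved.

## Numerical choices and degenerate inputs

* LP feasibility tolerance 1e-7 (slack sum); residual reported as the sum of
  squared violations, which equals Σocc² for the degenerate no-states cycle.
* Steady-state convergence: Newton to ‖RHS‖∞ ≤ 1e-11·(1 + k·D·P);
  integration fallback to relative derivative norm < 1e-9, horizon doubling
  to 1e10, explicit error beyond that.
* A Farkas certificate is omitted when infeasibility arises only under the
  DNA-total cap (the mixed system's certificate has an extra component).
* Mechanism numbering is canonical-lexicographic over dissociation
  permutations written in association-rank indices (1-based): mechanism 1
  dissociates in association order, mechanism n! in reverse. The key file
  (`mechanismKey()`, `writeMechanismKey()`) makes any numbering
  interoperable; figure-panel numbers from other sources are not matched.
* Simultaneous dissociation ("(E,F)") is represented only by the set of
  strict permutations it covers; ties are never a distinct mechanism object.
* The input dialect writes the cluster name after the occupancies; a
  leading-name layout is auto-detected on parse failure. Encoding UTF-8,
  Unix newlines, ASCII `-1`.

## Problem sizes used in the shipped checks

The test suite runs the exhaustive rules/oracle comparison at the 5%-grid
for n ≤ 3 (≈56k LP cells), 1,000 random cells each for n = 4..6, the full
48-cell three-factor kinetic chart plus 12 four-factor spot checks at 20
restarts, and synthetic datasets of 6,000 probes / 1,720 genes. The
acceptance script fits 20 four-factor cells at 20 restarts. These sizes
were chosen as desk-scale: they complete in minutes on one CPU while
keeping every claim exhaustive where exhaustiveness is the claim (n ≤ 3)
and sampled elsewhere.

## Known limitations

* The rules are incomplete for n ≥ 4 (measured above); the LP oracle is the
  authoritative decider there.
* Boolean output by design: no probabilities or rankings over compatible
  mechanisms, and no inference of association orders.
* Kinetic classification depends on an optimization heuristic; it is
  validated cell-by-cell against the LP on every tested surface, but a
  stalled fit on an untested cell would misreport compatible as
  incompatible (the bimodal gap makes this visible in log₁₀E).
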
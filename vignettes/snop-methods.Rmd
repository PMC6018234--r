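---
title: "Models and methods behind the snop toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the snop toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snop)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices, and what the simulator does and does not capture.

## The purification being modeled

Stoichiometrically normalizing oligonucleotide purification (SNOP) attaches
a cleavable 5′ tag — a universal sequence, a strong/weak alternating
barcode, and a deoxyuracil — to every desired oligo product. A single
capture probe synthesized with a degenerate S/W randomer presents all
barcode complements at roughly equal concentration. Because the probe is
the limiting reagent, each probe instance captures a similar amount of its
cognate precursor regardless of input concentration (stoichiometric
normalization), and because synthesis errors are correlated within a
molecule, selecting for perfect tags enriches for perfect products
(purification). Cleavage at the deoxyuracil releases the products.

## Hybridization thermodynamics

`duplex_dG()` computes two-state duplex free energies from the unified
DNA/DNA nearest-neighbor parameter set shipped as a plain-text table
(`inst/extdata/nn_dna_unified.tsv`: per-stack ΔH in kcal/mol and ΔS in
cal/(mol·K), plus terminal initiation terms split by G/C vs A/T closing
pairs), with the monovalent-salt entropy correction
`ΔS_salt = ΔS(1 M) + 0.368 · (N − 1) · ln[Na+]`. Defaults are the capture
conditions: 60 °C and 0.5 M Na⁺, both configurable via `thermo_params()`.
Deoxyuracil is scored as thymine — it base-pairs identically — and the
probed tag excludes the dU (the probe complements universal + barcode
only).

Two deliberate simplifications, both configurable and both documented
extension points:

* **Mismatches.** Non-cognate tag–probe pairings are penalized by a single
  scalar per internal mismatch (default 3 kcal/mol) rather than a full
  mismatch nearest-neighbor table. The design goal is rank-correct
  discrimination — a one-mismatch tag must bind measurably worse than a
  cognate tag and monotonically worse with more mismatches — not wet-lab
  mismatch energetics.
* **Secondary structure.** Tag accessibility is scored by an exhaustive
  complementary-segment scan (stems of at least `s_min = 4` bp, hairpin
  loops of at least 3 nt, at least one arm overlapping the tag) with a
  penalty proportional to the longest occluding stem:
  `stem_penalty_per_bp · (L − s_min + 1)` kcal/mol. This is deliberately
  not a minimum-free-energy folding algorithm: the scan is brute-force
  verifiable, monotone in stem length, and desk-scale. One practical
  consequence found while testing: with a poly-A product the barcode/dU
  junction itself can form a short self-complementary stem (e.g. `TTAA`
  pairing `TTAA` once dU is read as T), so "structure-free" is a property
  of the whole precursor, not of the parts.

The reaction free energy of precursor *i* against probe instance *j* is

ΔG°rxn(i, j) = duplex ΔG(universal + barcode_i) +
  m(i, j) · mismatch_penalty + accessibility_penalty(i),

where `m(i, j)` counts barcode positions at which the instance differs.
`crosstalk_matrix()` tabulates all pairs; the diagonal holds the cognate
values that panel design optimizes.

## Barcodes and panel design

Barcodes alternate strong (C/G) and weak (A/T) bases starting strong, so
every barcode has identical base composition and the cognate duplex
energies cluster tightly (a property the test suite checks against random
6-mers). The index encoding is fixed — bit `B − p` of the index selects the
base at position `p`, `0 → C/A`, `1 → G/T` — which makes enumeration
deterministic and makes degenerate blocks (products assigned `2^d`
consecutive instances) expressible as one barcode with S/W letters at the
trailing `d` positions. Block sizes must be powers of 2; `2^d` instances
give a product roughly `2^d`-fold the median concentration.

`optimize_assignment()` minimizes the fitness score

S = population SD(ΔG°rxn, cognate) + range(ΔG°rxn, cognate)

(population, not sample, SD: the score describes the whole finite panel).
Starting from a random assignment, each iteration proposes swapping the
barcodes of two products — or, when spare barcodes exist, moving one
product to an unused barcode with probability 0.5 — and accepts only strict
improvements; the best assignment seen is returned, so the best-score
trajectory never increases. Pure accept-only-improvement chains stall in
local optima of the swap neighborhood (measured: the brute-force optimum is
reached in only ~40% of runs on 4-product/8-barcode problems); the chain
therefore restarts from a fresh random assignment after 50 (or 10·N)
proposals without improvement, which preserves the acceptance rule and
reaches the brute-force optimum in ≥ 99% of seeded runs at 5000 iterations.
Default 500 iterations, seed required (default 1) for byte-reproducible
designs.

The default universal sequence is a fixed 17-mer screened so that neither
it nor any universal + barcode tag (B = 6 or 8) contains a stem of 4+ bp
and it cannot dimerize with itself over more than 4 nt. `validate_panel()`
additionally flags product pairs sharing a reverse-complementary stretch of
15+ nt ("daisy-chain" capture risk) and products with 10+ nt
complementarity to the universal region; warnings are advisory because
splitting incompatible panels is out of scope.

## Competitive hybridization equilibrium

`solve_competitive_equilibrium()` treats capture as two-state duplex
formation at the thermodynamic limit: `K_ij = exp(−ΔG°rxn,ij / RT)`
(R = 1.987×10⁻³ kcal/(mol·K)), with mass action
`bound_ij = K_ij · free_i · free_j` and mass balance per species. The wet
reaction may not fully equilibrate, so these are limit predictions of the
normalization mechanism, not kinetic simulations (strand-displacement
kinetics and bead-surface effects are out of scope).

Numerics: free concentrations are iterated with Jacobi-style updates under
geometric (log-space) damping — linear damping oscillates at the
`K ≈ 10¹⁵–10²⁰` spreads cognate-versus-mismatched tags produce, and
Gauss–Seidel alternation cycles on symmetric strong-binding problems. If
the fixed point has not met the tolerance (max relative mass-balance
violation < 10⁻⁹) after 10,000 iterations, the solver switches to exact
coordinate sweeps: each probe balance is monotone in its own free
concentration once the free precursors are eliminated, so it is solved by
bisection. The suite checks both paths against a closed-form quadratic
(1×1) and a nested-bisection oracle (2×2). Default concentrations follow
the wet protocol's scale: 4× precursor excess over each cognate probe
instance, which in the strong-binding limit captures exactly 25% of each
precursor.

## What the simulator emulates

`synthesize_molecules()` builds each molecule base by base in synthesis
order (3′ → 5′). Per coupling: deletion with probability `f · p_del`,
substitution `f · p_sub`, insertion `f · p_ins`, and chain termination
(loss of the remaining 5′ prefix) with `f · p_trunc`. The per-molecule zone
factor `f` is drawn from a two-point mixture — good zones `f = 1`, bad
zones `f = 8` with weight 0.15 — and is the package's model of the
correlated-error phenomenon: uneven surface chemistry damages all regions
of a molecule at once. Defaults (`p_del = 3×10⁻³`, `p_trunc = 2×10⁻³`,
`p_sub = 5×10⁻⁴`, `p_ins = 2×10⁻⁴`) were chosen once to put the perfect
fraction of a 94-nt precursor near 55–60%, the realistic ballpark for
column synthesis at ~99.5% coupling efficiency; they are settings of the
study conditions, not fitting knobs, and no claim is made of matching any
measured per-class error spectrum.

Two structural points about this model:

* **Truncation couples the regions mechanically.** Because synthesis runs
  3′ → 5′, a molecule that carries any tag at all necessarily completed its
  product region first. Conditioning on a perfect tag therefore excludes
  product-destroying truncations and raises the conditional probability of
  a perfect product even with zero zone variance. The independence property
  (uniform zones → no tag/product correlation) consequently holds — and is
  tested — for the per-base deletion/substitution/insertion process with
  termination disabled; the correlation property (zone variance > 0 →
  perfect tags predict perfect products) is tested under the full model,
  where both the zone factor and the termination structure push the same
  direction.
* **Capture is collapsed to a discrimination factor.** In
  `snop_capture_and_cleave()` a molecule's capture weight relative to a
  perfect-tag molecule is `δ^k` for `k` tag errors (default `δ = 0.05`,
  consistent with single-base variants cutting binding sharply), and
  molecules compete only for their cognate probe instance, each instance
  capturing up to its capacity by weighted sampling without replacement.
  This is an O(n) stand-in for a per-molecule equilibrium solve; the
  equilibrium module remains the quantitative crosstalk model at panel
  level. Cleavage at the deoxyuracil is modeled as perfect and complete;
  molecules whose dU was deleted, substituted, or truncated away are not
  releasable.

`emit_reads()` emulates a fully overlapped paired-end run after trimming:
both mates cover the whole molecule, with independent per-base errors
(default 10⁻³). It does not model adaptor ligation, index PCR, or their
artifacts — which is why measured purities on real libraries are expected
to sit below what the synthesis error model alone implies.

## Sequencing analysis

Pairs are kept only when the forward read exactly equals the reverse
complement of the reverse read (`consensus_filter()`); intrinsic sequencing
errors almost never strike both mates identically, so retention is
≈ `(1 − e)^(2L)`. Consensus reads are aligned end to end against every
panel reference by unit-cost global edit alignment (compiled
Needleman–Wunsch; matches free, substitutions and single-base gaps cost 1).
Best reference by cost; ties go to the lowest reference index with an
ambiguity flag; reads costing more than `max_cost = 25` are "unaligned" —
a result, not an error. Traceback prefers diagonal moves, which places gap
runs at the smallest compatible reference positions, so a lost 5′ prefix
reports as a deletion at reference start even when its placement is
ambiguous.

Error classes: `perfect` (no edits); `trunc5` (single deletion run at
reference start); single-run internal `deletion` / `insertion` /
`substitution`; everything else `mixed`, sized by total affected
nucleotides; `gross` marks 6+ affected (configurable). Purity is
perfect/aligned per oligo; the gross-excluded variant drops gross reads
from the denominator. Relative concentration divides each oligo's aligned
count by its count in a reference library sequenced from a nominally
equimolar pool (cancelling ligation and flow-cell biases; the scaling
constant is fixed at 1), then by the panel median — exactly 1 for odd panel
sizes, and the standard midpoint median is used for even sizes. Inequality
is summarized by the Gini coefficient
`G = Σᵢⱼ |xᵢ − xⱼ| / (2 n² x̄)` (computed via the equivalent sorted form)
and the Lorenz curve of cumulative shares.

## Problem sizes and reproducibility

The shipped tests and examples run 4–8-plex panels with ~10³ molecules per
precursor and 10⁴–10⁵ simulated read pairs or molecules — sizes chosen so a
full design → simulate → analyze cycle completes in seconds while leaving
the statistical assertions (3σ binomial checks at n = 10⁵) well powered.
Every random operation takes an explicit seed, stage seeds are derived from
the master seed, and a fixed seed reproduces byte-identical designs, FASTQ
files, and manifests.

## Known limitations

* Equilibrium-limit capture only: no strand-displacement kinetics, no
  bead-surface or wash-step partitioning.
* The capture simulator ignores precursor-to-noncognate-probe crosstalk, so
  its normalization is idealized — simulated product Gini values (~0.01–0.2)
  undercut what nonselective binding produces in real pools.
* The mismatch penalty is a scalar and the structure model is a stem scan;
  both favor testability over base-resolved accuracy.
* Coordinates are 1-based inclusive throughout, the R convention.
* Library-preparation artifacts (index PCR errors, adaptor dimers) are not
  modeled; purity estimates from real runs include them, simulated ones do
  not.
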
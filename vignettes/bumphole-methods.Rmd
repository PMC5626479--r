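---
title: "Methods: fixed-backbone multistate design of obligate heterodimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-backbone multistate design of obligate heterodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bumphole)
```

## The problem

A homodimeric protein-protein interface is to be replaced by an obligate
heterodimer: two variants, X and Y, that bind each other well but cannot bind
themselves. The motivating system is the histone H3-H3 C-terminal four-helix
bundle at the core of the (H3-H4)2 tetramer, where the hydrophobic cluster
formed by L109, A110, L126 and L130 of both H3 copies holds the two protomers
together. Engineering complementary "bumps" (large side chains) on one
partner and "holes" (small side chains) on the other favors the X/Y
heterodimer while leaving each homodimer with either a steric clash (two
bumps) or a packing cavity (two holes).

`bumphole` implements this as a multistate fixed-backbone design
calculation: for each candidate sequence pair it packs side chains and scores
four states on the same backbone - the heterodimer X/Y, the homodimers X/X
and Y/Y, and the wild type - and ranks pairs by the specificity gap.

## Energy model

The score is purely steric: a united heavy-atom 12-6 Lennard-Jones potential

$$E_{ij}(r) = 4\,\varepsilon_{ij}\left[\left(\frac{\sigma_{ij}}{r}\right)^{12}
 - \left(\frac{\sigma_{ij}}{r}\right)^{6}\right]$$

with Lorentz-Berthelot combining
($\sigma_{ij} = s\,(\sigma_i + \sigma_j)/2$,
$\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$). Parameters for 15
united-atom classes ship as `lj_params.tsv` with a residue/atom-name mapping
in `atom_classes.tsv`. There is no electrostatics, hydrogen bonding or
solvation: the design rationale this package implements (clash versus void)
is steric, and a van der Waals term is its minimal faithful model.

Tunable knobs (`energy_options()`), all in kcal/mol or Angstrom:

* `radius_scale = 0.9` - radii softening, standard fixed-backbone practice;
  compensates for the rigid backbone and discrete rotamers.
* `repulsion_cap = 10` - per-atom-pair cap, so a single overlap cannot
  dominate a whole-state ranking and energies stay finite at any geometry.
* `cutoff = 8` - interaction cutoff; the LJ term is negligible beyond.
* `clash_cut = 3` - a cross-protomer atom pair at or above this value marks
  a homodimer as failing by steric clash.
* `void_cut = 1` - a clash-free homodimer whose energy exceeds the wild
  type's by at least this much fails by packing deficit (void).

Scored pairs are all inter-residue pairs plus intra-residue pairs more than
three bonds apart (1-2/1-3/1-4 exclusions apply within a residue only).
Rigid-rotamer internal energy is omitted; it is constant per rotamer and
cancels in every state comparison. The template constant consequently
includes capped covalent-neighbor contacts between bonded residues; it is
identical in all states and drops out of gaps and stabilities.

## Rotamers and side-chain construction

Side chains are built on each design site's backbone frame (N, CA, C) by
sequential torsion construction from an ideal internal-coordinate table
(`topology.tsv`): CB is placed tetrahedrally with L-amino-acid handedness,
then each atom follows from bond length, bond angle and a torsion that is
either fixed (ring and terminal geometry) or one of the chi angles. Built
coordinates reproduce requested chi angles exactly (the test suite asserts
0.5 degrees; the realized deviation is at machine precision). Ring closures
are idealized; the unbuilt closing bonds come out within ~0.03 A of their
nominal lengths, adequate for steric scoring.

The shipped rotamer set (`rotamers.tsv`, `"compact_v1"`) is a compact
backbone-independent library: canonical gauche-/trans/gauche+ combinations
per residue type with approximate literature frequencies, 68 rotamers in
total. This is deliberately small - the target application is a hydrophobic
interface core of a few positions - and the loader is pluggable for richer
libraries. An optional sub-rotamer expansion (chi1/chi2 offsets, default off)
multiplies each base rotamer; it softens fixed-backbone artifacts but also
blunts the discrete bump-hole signal (see the fixture section), so the
package default keeps it off. Proline and glycine build correctly but are
excluded from design alphabets by default because their backbone coupling
violates the fixed-backbone assumption.

## The pairwise energy matrix and GMEC search

For a design region (each design position on both chains, plus all fixed
atoms within `environment_cutoff = 8` A of any design-site CA/CB),
`compute_energy_matrix()` stores

* `E_template` - the fixed-atom constant,
* `E_self[p]` - each placement against the whole template, and
* `E_pair[p,q]` - placements at distinct sites against each other,

so that any complete assignment's energy is exact bookkeeping:
`E_template + sum(E_self) + sum(E_pair)`. The test suite verifies this
reconstruction against a direct all-atom recomputation to 1e-6 kcal/mol for
every assignment on two-helix fixtures.

`gmec()` finds the global minimum-energy conformation for a fixed sequence:
exhaustive vectorized enumeration when the rotamer product space is at most
`enum_bound` (2e5), otherwise Goldstein singles dead-end elimination -
rotamer r at site i is eliminated when some competitor s satisfies
$E_{self}(r) - E_{self}(s) + \sum_{j \ne i} \min_t [E(r,t) - E(s,t)] > 0$ -
iterated to a fixed point, followed by exhaustive search over survivors
(refused above `hard_bound`). Ties break lexicographically by site order and
placement index, making every result bit-reproducible.

## States, gap, stability, failure modes

`score_states()` builds one matrix over the union alphabet and solves four
constrained GMECs on the same backbone. Homodimer protomers are packed with
independent rotamers: sequence symmetry does not imply conformational
symmetry. The heterodimer is scored as the better of its two threadings
(X on chain X / Y on chain Y, and vice versa); the two labelings describe
the same molecular species, and taking the minimum makes all scores exactly
symmetric under relabeling - a property the test suite asserts.

* specificity gap: `gap = min(E_XX, E_YY) - E_XY`, positive when the
  heterodimer is preferred over both homodimers;
* stability: `stability = E_XY - E_WT`, how much heterodimer packing costs
  relative to the wild-type interface.

`enumerate_designs()` ranks sequence space by descending gap after excluding
candidates with `stability > delta_stab` (default +2 kcal/mol: a specificity
gap is worthless if the heterodimer itself is ruined). Exhaustive mode scores
every unordered pair up to a configured budget; heuristic mode runs seeded
multi-start coordinate ascent (objective: gap, with a soft penalty of 10x
any stability excess) and scores every pair it visits. Both are
deterministic given the seed.

`classify_failure_mode()` diagnoses a homodimer: "clash" if any
cross-protomer atom-pair term in its packed structure reaches `clash_cut`;
otherwise "void" if its energy deficit against the wild type reaches
`void_cut`; otherwise "none".

`heterodimer_fraction()` maps the two homodimer gaps to an expected
heterodimer fraction under equimolar, fully dimerized mass-action mixing
with Boltzmann weights at temperature T (default 303 K):
$f = 2 / (2 + e^{-\Delta_{XX}/RT} + e^{-\Delta_{YY}/RT})$, which is 1/2 at
equal energies (the heterodimer has multiplicity 2 of the 4 ordered
pairings) and approaches 1 for large gaps. This is an interpretive
convenience, not a fitted thermodynamic model.

## Synthetic fixtures: what they emulate and what they do not

`make_synthetic_bundle()` generates ideal poly-alanine alpha-helices
(internal-coordinate construction at phi/psi = -57/-47, giving 1.56 A rise
and ~99.4 degrees per residue; consecutive CA-CA 3.81 A) with parallel axes
and alternating orientation. It exercises parsing, geometry and energetics
with no download. Note that with CA atoms ~2.28 A off-axis, the minimum
inter-helix CA-CA distance is below the axis spacing by up to twice that
radius; tests assert against the actual geometry.

`synthetic_h3_bundle()` is a constructed stand-in for the H3-H3 four-helix
bundle: two chains of two antiparallel helices each (residues 102-116 and
120-134), C2-symmetric about the bundle axis, with the wild-type interface
identities (L109, A110, L126, L130) at interface-facing positions and
alanine elsewhere. Its geometry realizes the bump-hole contact topology of
the real interface - position 110 of each chain points into the groove
flanked by the partner chain's 126 and 130 side chains - and the bundle size
(helix axes on a 13 A square) was calibrated once so the wild-type leucine
core packs snugly but strain-free. On this analog, the engineered pair
(X = 126A/130V, Y = 109I/110W/130I) partitions as designed with the default
thresholds: positive gap, Y/Y fails by clash (the two tryptophans cannot
both occupy the core), X/X fails by void (~8 kcal/mol packing deficit).

What the analog does not show: it is an idealized, parallel-axis,
poly-alanine-shell construction with no experimental coordinates, so
absolute energies, the precise gap magnitude, and behavior under sub-rotamer
expansion (which lets the two Y/Y tryptophans relax past each other on this
smooth backbone) do not transfer to the real nucleosome structure. Passing
tests on the analog demonstrate that the pipeline's logic is correct, not
that the historical design calculation is reproduced coordinate-for-
coordinate. On this analog the designed heterodimer costs ~4.8 kcal/mol
against the wild type - an idealized shell under-rewards tryptophan burial -
so analog design-enumeration examples use a widened stability window
(`delta_stab = 6`) as run configuration; the package default remains +2.

## Problem sizes and numerical choices

The test suite and the acceptance script keep problem sizes at desk scale:
matrix-faithfulness checks enumerate all assignments of a {A, L} alphabet at
2-4 sites (up to 625 assignments); search correctness uses 100 random
matrices up to 4 sites x 6 rotamers plus fixture-derived matrices;
design-space enumeration is exhaustive at 2 positions x 7 residue types
(1225 unordered pairs) and heuristic (seeded multi-start ascent) at 4
positions, where the full pair space (~2.9 million) is enumerable in
principle but not worth the wall-clock cost in an interpreted runtime.

Degenerate inputs are handled explicitly: empty atom sets score zero;
overlapping atoms are distance-guarded and capped rather than infinite; a
zero-site matrix evaluates to its template constant; empty placement sets,
chi-arity mismatches, wild-type mismatches and oversized search spaces are
errors with actionable messages. All randomness (fixture phases, heuristic
starts) flows from explicit seeds; everything else is deterministic,
including tie-breaks.

## Limitations

* Fixed backbone, discrete rotamers, steric-only score: no electrostatics,
  solvation, entropy, or backbone relaxation; energies are rankings, not
  binding free energies.
* The compact rotamer library is adequate for buried hydrophobic cores;
  polar surface positions would need a richer library and an electrostatic
  term.
* The partition-fraction model assumes complete, equimolar dimerization.
* The synthetic analog supports logic-level validation only; conclusions
  about the real nucleosome interface require the experimental structure.
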
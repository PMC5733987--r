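---
title: "In-silico characterization of secreted phytases: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico characterization of secreted phytases: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protchar)
```

`protchar` bundles, as one tested pipeline, the standard desk-scale workup
applied to candidate industrial enzymes — here the two secreted *Aspergillus
niger* phytases, a monomeric 3-phytase A and a homodimeric 3-phytase B.
This vignette explains each model, the tunable parameters and their
defaults, what the synthetic fixtures do and do not establish, and the
design choices made where conventions genuinely diverge.

## Composition-based physicochemistry

A `CompositionTable` (residue counts plus length) is sufficient input for
molecular weight, pI, charge tallies, GRAVY and the aliphatic index; this
is what lets a *printed* composition table stand in for an unavailable
sequence. The constants are vendored as versioned TSVs with a SHA-256
manifest verified at load (`load_tables()`), so a silently corrupted table
fails loudly rather than shifting results.

**Molecular weight** sums average residue masses (ExPASy set) plus one
water; an empty composition returns 18.02 Da by construction.

**Theoretical pI** finds the zero of the Henderson–Hasselbalch net charge
by bisection on pH ∈ [0, 14], stopping at |Q| < 1e-4. The pKa set is the
Bjellqvist/ProtParam one: C-terminus 3.55; side chains D 4.05, E 4.45,
C 9.0, Y 10.0 (acidic) and H 5.98, K 10.0, R 12.0 (basic); the N-terminal
pKa depends on the N-terminal *residue* (A 7.59, M 7.0, S 6.93, P 8.36,
T 6.82, V 7.44, E 7.7, otherwise 7.5), which is why composition-only calls
take an explicit `nterm_residue`. Q(pH) is strictly decreasing, so the root
is unique; the test suite checks bisection against a pure dense-grid scan
on 1000 random compositions at 1e-3. Residue-specific *C-terminal* pKa
adjustments for Asp/Glu termini (a refinement some implementations carry)
are deliberately not modeled: the composition-only contract has no
C-terminal identity, and both reference proteins reproduce to ±0.01 pH
without it.

**Charge tallies** count Asp+Glu as negative and Arg+Lys as positive.
Histidine contributes to the charge *curve* (pKa 5.98) but is excluded from
the positive *tally*, matching the arithmetic of the published table
(19 Arg + 15 Lys = 34). Note the published percentages are truncated rather
than rounded (51/444 = 11.4865 prints as 11.48); tests therefore compare at
±0.01.

**Instability index** needs the sequence: II = (10/L)·Σ DIWV(xᵢ, xᵢ₊₁) over
the L−1 dipeptides, with the published 400-entry dipeptide weight matrix,
and the conventional reading "unstable iff II > 40". **Half-life** is a
pure N-end-rule lookup in three contexts (mammalian reticulocytes in vitro,
yeast and *E. coli* in vivo).

## Profiles, sequons, motifs, antigenicity

Sliding-window profiles use the ProtScale convention: arithmetic window
mean assigned to the center, no edge padding, so a length-L chain yields
L − w + 1 values. The hydropathy default is Kyte–Doolittle with window 9.
The accessibility slot is pluggable; the default ships Janin's (1978)
accessible-residue fractions, chosen as a reasonable published scale —
the accessibility extrema of the reference tables were *not* used to
calibrate it, and accessibility values are not acceptance-tested. Extrema
reporting compares scores at 3 decimals (printed precision) so equal-scored
maxima are both retained, in ascending position order.

Sequon scanning implements Asn-Xaa-Ser/Thr with Xaa ≠ Pro, overlapping hits
all reported; proline is *not* excluded at the +3 position (the stated rule
is followed verbatim; neural-network "potential" scores of sequon servers
are out of scope). The catalytic-motif finder matches RHGXRXP and reports
the nearest downstream His-Asp dyad — the nucleophile/proton-donor pair of
the histidine acid phosphatase family.

Antigenicity follows Kolaskar–Tongaonkar: window-7 mean propensity per
center, whole-protein mean over centers, and the published decision rule —
threshold 1.0 when the protein mean is ≥ 1.0, else the protein mean, with
strict exceedance. The published method leaves the minimum determinant
length and end handling unstated; we default to `min_len = 8` (the common
implementation choice) and note that the first/last three residues have no
window center and can never be part of a determinant. Both choices are
parameters, not hidden constants.

## Structure-based stages

The PDB reader is deliberately minimal: fixed columns for coordinates
(31–54), tolerant trailing fields, first MODEL only, altloc resolved to
highest occupancy (ties: 'A', then blank), author numbering kept verbatim,
HETATM groups (ligands, NAG, waters) representable. PDBQT poses parse
through the same path with elements derived from atom names. Hydrogens are
kept when present, but all distance rules are defined on heavy atoms,
matching hydrogen-free crystal structures.

**Glycation.** For each lysine NZ, the minimum distance to Asp OD1/OD2 and
Glu OE1/OE2 (acid class) and to His ND1/NE2, Arg NE/NH1/NH2 and *other*
lysine NZ atoms (base class) is computed atom-to-atom — nearby charged side
chains lower the ε-NH₂ pKa and catalyze Amadori chemistry, so proximity is
the predictor. A lysine is called glycable when the class minimum is
strictly below 10 Å: the published record includes 9.89 and 9.97 Å cases as
glycable and excludes a lysine at > 23.84 Å, supporting a strict 10 Å
bound. Candidates are restricted to the analyzed chain by default
(`include_interchain = FALSE`). The bundled per-lysine fixture transcribes
the published distance table (per-class minima; "> x Å" rows stored as
censored bounds); deriving calls from it reproduces the published totals
(14 of 15 and 10 of 12 glycable) and the cross-method agreement with the
sequence-based external predictor (9/24 = 37.5% and 9/10 = 90%) exactly.
`compare_predictions` requires both call sets to cover the same lysine
universe and reports both directional fractions.

**Secondary structure.** A simplified Kabsch–Sander assigner: amide H
positions are synthesized 1.01 Å from N anti-parallel to the preceding
C=O (the DSSP convention; the alternative bisector placement differs by
hundredths of an Å and does not change assignments on our fixtures),
hydrogen bonds are pairs with E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH −
1/r_CN) < −0.5 kcal/mol, helices need two consecutive i→i+4 turns (3₁₀ and
π turns folded into H), sheets are residues in parallel/antiparallel bridge
patterns, everything else is coil, and helix wins where labels overlap.
Three states only, because the reference characterization reports three
categories. Prolines donate no H-bond; chain breaks (C–N > 2.5 Å) suppress
H synthesis across the gap; residues with incomplete backbones are labeled
coil and excluded from percentages.

**Interfaces and poses.** Interface residues are residue pairs across two
chains with heavy-atom minimum ≤ 4.0 Å. Pose hydrogen bonds pair N/O donors
(explicit H within 1.25 Å, or a name-based synthesizable-H rule for
standard residues; het-group donors require explicit H) with N/O acceptors
at ≤ 3.5 Å, applying the ≥ 120° D-H…A test only when an H position exists.
The 3.5 Å / 120° defaults are common practice — the reference work states
none — and pose *generation* (docking searches, grid maps, kcal/mol
scores) is explicitly out of scope: the module analyzes given poses, and
per-residue summaries keep the residue multiset convention (one entry per
bond).

## Synthetic data: what a green test establishes

All fixtures are pure functions of their parameters (and a seed where
randomness exists). `random_sequence` permutes an exact composition
multiset, optionally pinning the first residue — composition-derived
quantities are invariant under the permutation, which is precisely the
property the composition-only pipeline relies on. Toy structures place
atoms at *stated* geometry: a Lys NZ exactly d Å from an Asp OD1, one
inter-chain pair at exactly d Å, a donor–H–acceptor triple at stated
distance and angle, ideal helices (φ = −57°, ψ = −47°) whose construction
guarantees i→i+4 hydrogen bonds, lone strands (φ = −139°, ψ = 135°) that
cannot form bridges, and a β-hairpin joined by a type II′-like turn
(60°,−120°/−80°,0°) added so the bridge-detection path has a positive
control. The defaults mirror the stated world of the reference record (10 Å
glycation cutoff, window 9/7 profiles, 444/460-residue compositions).

What these fixtures do *not* emulate: crystallographic noise, missing
atoms and alternate conformations beyond the minimal cases tested,
long-range sheet topology of real folds, solvent, or the energetics of real
docking poses. A green suite therefore establishes algorithmic correctness
against brute-force oracles and the printed reference values — not
predictive validity of, e.g., the 10 Å glycation rule itself. Checks that
require the real PDB entries or accession sequences (instability index
45.41/33.66, Kolaskar means 1.0304/1.0234, window-9 hydropathy extrema,
43/12/45 secondary-structure percentages) are excluded from the offline
test run by design; the operations they exercise are covered by synthetic
equivalents.

## Numerical choices and degenerate inputs

* Bisection tolerance |Q| < 1e-4 with a 1e-9 interval guard; a composition
  negative even at pH 0 returns 0 (degenerate but defined).
* Profile extrema tie detection at 3 decimals; ties break to the lowest
  position.
* Empty compositions error for per-length quantities and return one water
  for mass; length-0/1 sequences error for the dipeptide index.
* Strict inequalities at classification boundaries: 9.99 Å is glycable,
  10.00 Å is not; propensity exactly at threshold is not antigenic.
* Reports round to printed precision in TSV but keep full precision in
  JSON; `params.json` omits the output path so reruns are byte-identical.

## Known limitations

* The pI model ignores cystine formation and any C-terminal residue pKa
  specificity; both proteins carry disulfides that ProtParam also ignores.
* The secondary-structure assigner is a 3-state simplification; it does not
  reproduce full 8-state DSSP (bends, turns, isolated-bridge distinctions)
  and its percentages on real structures should be read with a few points
  of tolerance.
* Glycation calls consume printed per-class *minimum* distances when run
  from the bundled fixture; whether those printed values are global minima
  in the deposited structures cannot be verified offline.
* The pose module trusts the given coordinates; protonation states and
  donor/acceptor ambiguity of histidine are resolved by name-based rules,
  not pKa calculations.
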
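---
title: "Methods: crosslink-calibrated model evaluation with xlcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crosslink-calibrated model evaluation with xlcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlcal)
```

## Scope and model

`xlcal` evaluates candidate protein structure models against DSSO
crosslinking mass-spectrometry data and the accompanying biophysical
measurements. The underlying physical picture is simple: DSSO reacts
with primary amines, bridging two lysine side chains whose N-ζ atoms
can approach within the reagent's spacer arm (~10 Å). Every confidently
identified crosslinked peptide pair therefore asserts an upper bound on
one inter-atomic distance in the native structure. A model that places
many crosslinked pairs beyond their bound contradicts the data; a model
consistent with all of them is retained. The package takes models,
sequences and identification tables as given — fold prediction,
docking, database search and FDR control happen upstream — and makes
the calibration step reproducible and quantitative.

## From PSM tables to residue pairs

Search engines report crosslinks at the peptide-spectrum-match level;
one physical lysine pair is typically supported by several PSMs, often
at different charge states and in both A–B and B–A orientations.
`dedupe_to_residue_pairs()` collapses these to canonically ordered
unique pairs ((protein, position) lexicographic), retaining the PSM
count and charge-state set as evidence strength. Positions are 1-based
full-protein coordinates throughout; when a foreign table reports
peptide-relative positions, `map_peptide_to_sequence()` locates the
peptide (all overlapping occurrences) and ambiguous placements are
rejected rather than guessed, since a wrongly mapped restraint is worse
than a missing one. Lysine validation is advisory by default because
real tables legitimately contain protein N-terminus links; a strict
mode rejects non-lysine links. Rows failing the q-value threshold (off
by default — upstream pipelines already filter at 1% FDR) or carrying
non-positive positions are dropped and counted, never silently fixed.

## The restraint policy

`restraint_policy()` encodes three numbers that matter:

* `intra_max = 10` Å — one-sided bound for intramolecular links,
  applied to N-ζ–N-ζ distances. The bound is one-sided because the
  spacer arm sets a *maximum* reach; two lysines can be arbitrarily
  close and still crosslink.
* `inter_min = 10`, `inter_max = 20` Å — the band used for
  intermolecular links during docking. Both bounds are enforced, but a
  below-lower-bound violation is flagged `lower_bound` separately: a
  short distance does not contradict the chemistry the way an overlong
  one does, and downstream consumers may choose to ignore that class.
* `fallback_pad = 13` Å — when a model truncates a lysine side chain
  (template-based models often do), evaluation falls back to Cα atoms
  and the bounds widen by two extended lysine side chains
  (2 × 6.5 ≈ 13 Å), giving the documented 23 Å Cα–Cα ceiling for
  intramolecular links. Missing atoms are *data* (`atom_used =
  "missing"`), never errors, and such restraints are excluded from
  sums.

All three are configurable; the defaults are the study conditions for
every test in the package.

## Decoy ranking and the consistency verdict

Docking with distance restraints yields a handful of candidate poses.
`rank_decoys()` orders them by the *sum* of restrained distances —
"minimal distances between lysines" read as a scale-continuous
criterion rather than a count of satisfied restraints, because a sum
distinguishes two models that both satisfy everything. A mean-based key
is available for decoy sets with unequal evaluable restraints. Ties
break by violation count, then maximum violation, then input order; a
model with any unevaluable restraint ranks after fully evaluated ones
but is not disqualified (side-chain truncation should not eliminate an
otherwise good pose). `consistency_report()` emits the loop's verdict:
PASS when every evaluated violation is within tolerance (0 Å by
default), otherwise FAIL with the violated restraints worst-first —
the artifact handed back to the next modeling round.

## Superposition and RMSD conventions

`kabsch()` computes the closed-form least-squares rotation via SVD of
the 3×3 cross-covariance, with the usual determinant correction so
reflections are never returned. Nearly collinear inputs leave the
rotation underdetermined about the common axis; they are flagged
`degenerate` rather than rejected, since the RMSD is still meaningful.

Residue pairing between two models uses Needleman–Wunsch global
alignment of the extracted sequences (identity scoring, gap open 10,
extend 0.5). Only the pairing topology is consumed; the constants
merely make gaps expensive relative to matches so truncations align as
terminal gaps. Pairing is chain-by-chain on shared chain identifiers.

Two RMSD reporting modes mirror common practice:

* *no outlier rejection* — a single pass over all pairs;
* *iterative refinement* — superpose, compute per-residue Cα
  residuals, drop residues with residual above `cutoff_sigma` (default
  2.0) times the residual standard deviation measured about zero (the
  RMS residual of the current fit), re-superpose, for at most
  `max_cycles` (default 5). Measuring spread about zero rather than
  about the mean residual is deliberate: residuals are non-negative
  deviations from the fit's own prediction, and a mean-centred
  threshold degenerates when residuals are homogeneous (it would
  reject arbitrarily many near-identical pairs). Under the RMS rule a
  planted 10% displaced subset is rejected in one cycle while pure
  Gaussian noise is left essentially intact, and the refined RMSD is
  provably non-increasing across cycles.

An "all-atom RMSD" is reported over a Cα-fitted superposition: the
transform comes from Cα pairs, the RMSD from all identically named
atoms of the surviving residues. This two-stage convention matches how
all-atom deviations are usually quoted after a Cα alignment.

## Surface areas

SASA uses the Shrake–Rupley construction: each atom's expanded sphere
(van der Waals radius + 1.4 Å probe) is sampled at `n_points = 960`
deterministic generalized-spiral points, and points inside any
neighbour's expanded sphere are occluded. Bondi-type radii (C 1.70,
N 1.55, O 1.52, S 1.80 Å) ship as a configurable table; models are
assumed hydrogen-free. The point lattice is expressed in a
molecule-intrinsic frame (principal axes of the coordinate cloud, signs
fixed by third moments) so the total is invariant under rigid motion of
the model to floating-point precision — a property a world-fixed
lattice cannot offer at finite point counts. At 960 points a single
atom's area is exact to ≪ 0.5% and 20-atom clusters agree with a
10,000-point computation within 2%.

`buried_surface()` computes, for each component of a partition of the
complex's chains, the SASA of the component alone and of the same atoms
inside the complex, on one shared lattice frame (computed from the
complex). Sharing the frame makes burial exactly zero for
non-interacting components and makes the accounting identity
Σ buried = Σ isolated − complex hold to rounding error. The
burial-vs-affinity check is a Spearman correlation with a permutation
p-value: exhaustive over all n! pairings for n ≤ 8 (the regime of a
handful of complexes), seeded resampling above that.

## Sequence regions: inserts, hydropathy, charge

An insert region is detected in a multiple sequence alignment as a
maximal run of ≥ `min_length` (default 5) columns sharing the same
nonempty proper subset of all-gap members, with the remaining members
at least `min_occupancy` (default 0.9) non-gap over the run. Keying
runs on the exact gap-member signature keeps the rule unambiguous
(changing membership splits a run) and the occupancy check guards
degenerate alignments. Column intervals are converted to 1-based
positions in each carrier's ungapped sequence, which is how such
regions are quoted (e.g. a 21-residue loop at positions 230–250).

Hydropathy profiles are centred sliding-window means (default window 9,
shrinking at the termini) over the Kyte–Doolittle scale; window 1
returns raw per-residue values. The scale is a data table and
replaceable. Net charge is a sequence-level Henderson–Hasselbalch sum
over D, E, H, K, R side chains (pKa 3.9 / 4.1 / 6.0 / 10.5 / 12.5) at
pH 7.4, termini off by default because regions of interest are internal
stretches. This is explicitly a *proxy* for electrostatic character —
a real potential surface needs the 3D structure and a
Poisson–Boltzmann solver, which are out of scope.

## SPR kinetics

The 1:1 Langmuir model is used throughout: association
R(t) = R_eq (1 − e^−(C·ka + kd)·t) with
R_eq = C·ka·Rmax / (C·ka + kd), then dissociation
R(t) = R(t_a)·e^−kd(t − t_a). `fit_1to1()` fits ka, kd and Rmax
globally over all curves of a titration by Levenberg–Marquardt on
log-parameters (positivity by construction). Initialization is
data-driven: kd from the log-linear slope of the highest-concentration
dissociation tail, Rmax from 1.5× the largest observed plateau, ka from
a coarse log-grid (10²–10⁹ M⁻¹s⁻¹, half-decade steps) minimizing the
residual sum with the other two fixed. On noiseless 5-concentration
sets this recovers the generating rates to optimizer precision
(≪ 0.1%); at 2% of Rmax Gaussian noise the median KD error stays
around 1%. Mass-transport-limited and bivalent schemes are deliberately
excluded — the data this package targets were analyzed 1:1.

The default synthetic titration spans 0.1×, 0.3×, 1×, 3×, 10× KD
(3–5 concentrations per analyte is the practical norm), 240 s
association and 240 s dissociation — the latter matching the typical
4-minute buffer wash. Blocking experiments are normalized pointwise
against a negative-control sensorgram interpolated onto the test grid,
with sub-floor control samples masked rather than divided. KD fold
differences are reported both as the raw ratio and rounded to one
significant figure, the convention behind statements like "10-fold
lower affinity".

## Synthetic fixtures: what they do and do not show

All tests run on generated data. `make_helix_model()` builds ideal
α-helical Cα traces (rise 1.5 Å, 100°/residue, radius 2.3 Å) with
pseudo-N-ζ atoms 6.4 Å radially outward from lysine Cα positions —
a geometric stand-in for an extended side chain, documented as such.
`make_bundle_fixture()` assembles eight such helices (four of 35
residues, four of 8) into a single-chain bundle with lysines every
third residue, dense enough to plant 14 intramolecular crosslinks
within DSSO reach. `make_crosslink_table()` samples lysine pairs whose
model N-ζ distance satisfies the policy and emits PSM-redundant rows
with varied charges and alternating orientation; by construction the
deduplicated table is fully satisfied on the generating model (the
planted-truth closure every end-to-end test relies on). Decoys apply
proper rigid transforms to one chain; displacement steps in the
ranking tests (20, 45, 75 Å along the separation axis) are spaced so
every restrained distance provably grows with displacement, making the
expected ranking analytic rather than empirical.

What passing these tests shows: the arithmetic, bookkeeping and
optimization are correct on inputs whose ground truth is known exactly.
What it does not show: performance on real models (side-chain
conformers, loops, missing density), real PSM tables (search-engine
quirks, ambiguous peptides) or real sensorgrams (drift, bulk shifts,
mass transport). The fixtures make no claim of chemical realism.

## Numerical choices and degenerate inputs

* Restraint distances are exact Euclidean norms; reports are
  order-independent and match a brute-force oracle to < 1e-9 Å.
* `summarize_restraints()` over zero evaluated restraints yields an NA
  fraction, not a division error.
* Kabsch requires ≥ 3 pairs; outlier rejection stops rather than
  divides when the residual RMS underflows, and erroring out when
  fewer than 3 pairs survive names the cutoff as the cause.
* Altloc collapse keeps the highest occupancy (ties: file order);
  `"first"` is available for pathological files.
* PDB coordinates are written `%8.3f`; round trips are exact at that
  precision. Only single-character chain identifiers are legal.
* Permutation p-values are exhaustive up to n = 8 (40,320
  permutations), seeded Monte Carlo beyond.
* Problem sizes in the test suite — 100 random restraint fixtures, 20
  ranking seeds, 30 superposition draws, 50 noiseless and 20 noisy
  kinetic fits, 960-point SASA lattices — were chosen so each property
  is exercised across its input space while the whole suite completes
  in about a minute.

## Known limitations

* Restraints are hard bounds; no probabilistic (e.g. log-normal
  reach) scoring.
* The PDB reader handles single-model, protein-only ATOM records;
  mmCIF, HETATM ligands and hydrogens are out of scope.
* Insert detection assumes a trustworthy alignment; it locates gap
  structure, it does not correct it.
* The net-charge and hydropathy comparisons are sequence proxies and
  say nothing about the spatial arrangement of the residues.
* Published structural headline numbers tied to undeposited model
  coordinates cannot be recomputed here; the package's guarantees are
  the property checks above, on fixtures it can generate itself.
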
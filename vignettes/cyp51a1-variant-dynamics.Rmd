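---
title: "Methods: desk-scale analysis of CYP51A1 variant dynamics"
author: "cyp51md"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale analysis of CYP51A1 variant dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp51md)
```

# Scope and scientific setting

CYP51A1 (lanosterol 14α-demethylase) demethylates lanosterol at its C30
centre; catalysis requires the substrate to sit over the heme iron and the
enzyme to form a productive complex with its redox partner POR. Molecular
dynamics studies of CYP51A1 missense variants therefore monitor three
structural observables — the hydrogen-bond anchoring of the lanosterol
hydroxyl in the active site, the heme-Fe–C30 distance, and
trajectory-average binding enthalpies of the protein with lanosterol and
with POR — alongside a docking step in which candidate CYP51A1–POR poses
are screened by the positions of key interface residues, and a variant
survey that classifies human missense variants with SIFT and PolyPhen-2.

`cyp51md` implements that post-processing layer. Running the simulations
themselves (force fields, solvation, docking searches, or the predictors
SIFT and PolyPhen-2) is out of scope: energies, trajectories, poses and
prediction scores are *inputs*. Because the upstream simulations are not
reproducible at desk scale, a synthetic generator with known ground truth
stands in for them; what that does and does not establish is discussed at
the end.

# Hydrogen-bond occupancy

A hydrogen bond is scored per frame by a pure distance criterion: the bond
is present when the probe–partner distance is at most the cut-off
(`hbondCriterion`, default 2.4 Å, inclusive). No angular term is applied.
Two readings of the criterion are supported:

* `donor_acceptor` (default): the distance is measured from the hydroxyl
  oxygen (the donor heavy atom) to the partner heavy atom. 2.4 Å is
  unusually short for heavy-atom pairs, but it is implemented literally as
  the package's reference criterion.
* `hydrogen_acceptor`: the distance is measured from the hydroxyl
  hydrogen, for workflows that read the same cut-off as a
  hydrogen–acceptor distance.

Shipping both modes, with the literal heavy-atom reading as default, covers
the two defensible interpretations without inventing a third; the cut-off
itself is a free parameter for sensitivity analyses.

Partner atoms default to the backbone amide nitrogen and carbonyl oxygen of
every standard amino-acid residue (`candidatePartners`), since the ligand
hydroxyl bonds predominantly to backbone amide groups; side-chain acceptors
can be added by selection expression. A bond is attributed to the residue
owning the partner atom, and several bonded atoms of one residue in one
frame count once. The occupancy of residue *r* is

τ<sub>HB</sub>(r)/τ<sub>0</sub> = 100 × (frames in the window with ≥ 1 bond
to *r*) / (frames in the window),

with τ<sub>0</sub> the *full* analysis window. This makes every occupancy
lie in [0, 100] while the per-structure sum is unconstrained (the hydroxyl
may be unbonded or multiply bonded in a frame), which is the behaviour a
bounded, per-residue occupation statistic must have. The alternative
convention (normalising by bonded frames only) is not used because it can
exceed interpretability bounds when bonds are rare. The analysis window
defaults to the second half of the trajectory — the usual production-window
convention in which the first half is treated as equilibration — and is
stated explicitly in every result object (1-based inclusive frame
positions). Reports round to 0.1%; objects keep full precision.

# Heme-Fe–C30 distance

`distanceSeries` computes the per-frame Euclidean distance between two
single-atom selections over the entire trajectory; selections that resolve
zero or several atoms are errors rather than silent choices. Summaries use
the sample (n−1) standard deviation. The running-average overlay used in
plots has a configurable window (default 100 frames); it is cosmetic and
enters no statistic. Synthetic frames are unwrapped coordinates, so no
periodic-boundary imaging is performed.

# Binding enthalpy

The binding enthalpy is the difference of trajectory-average internal
energies,

E<sub>b</sub> = ⟨U<sub>cmplx</sub>⟩ − ⟨U<sub>m1</sub>⟩ − ⟨U<sub>m2</sub>⟩,

with each term computed from its own simulation — hence the three series
may have different lengths, and no framewise pairing is assumed. More
negative E<sub>b</sub> is more favourable. Because per-frame energies are
autocorrelated, the standard error of each mean is estimated by block
averaging (`blockStandardError`): the series is split into `n_blocks`
contiguous blocks (default 10, the conventional first choice when the
correlation time is unknown) and the error is sd(block means)/√n_blocks;
the three errors combine in quadrature. A series shorter than two blocks
contributes zero error, which keeps degenerate inputs (constants, single
frames) exact instead of undefined. `compareVariants` sorts results by
E<sub>b</sub> and flags |E<sub>b</sub>| < 2·se as "indistinguishable from
zero" — the statistic behind statements like a variant having essentially
no binding enthalpy toward POR.

# Pose ranking

The docking protocol this formalises screens rigid CYP51A1–POR poses by the
positions of key interface residues: on CYP51A1 K127, A172, K175, K364,
K442, R452 and N459 (chosen by homology to P450s with characterised
reductase interfaces), and on POR residues 92, 93 and 142, of which only 92
has an asserted identity (Glu) — 93 and 142 carry wildcards, and an
unexpected residue name is a warning, not an error, so homologous
structures can be scored. For every cross-chain key-residue pair,
`contactScore` takes the minimum heavy-atom distance; a pair is in contact
below 5.0 Å, a common heavy-atom interface convention adopted because the
original pose choice is described positionally without a stated cut-off.
Poses are ranked by contact count, then by the summed per-pair minima
(smaller = tighter interface), then by label, making the ranking a
deterministic permutation of its input. A positional score was chosen over
a weighted pseudo-energy deliberately: it mirrors how the pose selection is
actually described, and it is auditable pair by pair (`per_pair`).

# Variant tables

The package bundles five curated TSV tables: phenotype-associated CYP51A1
variants, human-SNP/in-vitro-mutant pairs, the twelve variants predicted
damaging by both predictors outside the catalytic regions, the 33 missense
records in conserved regions (SRS1–6, the POR interface, azole-contact
positions), and the reference hydroxyl-occupancy table with eleven
per-residue entries over four structures (WT, R277L, R431H, D152G).
Residue numbering follows NP_000777.1.

Printed predictor labels are stored verbatim and never overwritten;
classification is recomputed from the printed scores with the standard
conventions (SIFT ≤ 0.05 damaging; PolyPhen-2 ≥ 0.957 probably damaging,
≥ 0.453 possibly damaging, else benign — the HumDiv bin edges, chosen
because the tables' own labels are consistent with them in the clear
cases). The two views are kept separate because curated tables of this kind
contain internal inconsistencies — the same numeric score printed under
different bins in different rows — and `consistencyCheck` reports exactly
those disagreements without resolving them. Termination (`*`, `Ter`) and
deletion (`delX`) variants carry class `unknown` unless scores are printed.
Population frequencies are stored as metadata only.

```{r variants}
t4 <- loadVariantTable(variantFixturePath("table4_conserved_regions"))
countByRegion(t4)
consistencyCheck(t4)[, c("protein_change", "tool", "score",
                         "printed_label", "computed_class")]
```

# The synthetic generator: what it emulates

The generator reproduces the *statistical* structure the analyses consume,
nothing more:

* **Hydrogen bonds** (`genHbondTrajectory`): each target residue follows an
  independent two-state Markov chain whose stationary probability is the
  occupancy target and whose stay correlation (`persistence`, default 0,
  i.e. independent frames) makes the effect of autocorrelation on effective
  sample size testable. The hydroxyl oxygen is fixed at the origin and only
  partner atoms move between two exact radii (2.2 Å bonded / 6.0 Å
  unbonded, bracketing the 2.4 Å criterion) — the simplest geometry that
  realises the criterion exactly.
* **Energies and distances** (`genAR1Series`, `genDistanceTrajectory`):
  stationary Gaussian AR(1) processes parameterised by their stationary
  mean and sd with x₁ = μ, emulating equilibrated production-run
  observables. Default panel settings use sd 5 (energy units) with lag-1
  correlation 0.5 for energies, and sd 0.3 Å for distances — fluctuation
  scales typical of equilibrated single-observable traces.
* **Poses** (`genPoseSet`): one planted pose realising an exact number of
  key-pair contacts (planted atoms within 4.5 Å, inside the 5 Å scoring
  cut-off) among otherwise well-separated chains, plus decoys whose B chain
  is randomly rotated and translated to ≥ 15 Å interface separation, with
  bounded retries.
* **The variant panel** (`variantPanelScenarios`) fixes the qualitative
  study picture as ground truth: lanosterol binding ordered WT (−50) <
  R277L (−45) < R431H (−25) < D152G (−20); POR binding with WT most
  favourable (−60), R431H close (−55), R277L weakened (−30) and D152G set
  to exactly zero so the near-zero flag has a true positive; Fe–C30
  distance means 6.0/6.3/10.0/10.2 Å putting R431H and D152G about 4 Å
  above the wild type. Zero is the defensible encoding of "almost zero
  binding enthalpy", and the ±0.3 Å within-group/≈4 Å between-group
  structure encodes "stable distances, clearly separated".

All generators are seed-deterministic (identical inputs give byte-identical
outputs). What closed-loop tests on these data establish is that the
*estimators* are correct: occupancies converge to their targets at the
binomial rate, E<sub>b</sub> recovers the planted mean difference within
its stated error, the planted pose wins the ranking. What they do **not**
establish is anything about real force fields: there are no sterics, no
water, no coupled motions between residues, and no correlation between the
hydrogen-bond state and the distance or energy processes. Conclusions about
real CYP51A1 variants still require real trajectories.

# Numerical and design notes

* Coordinates are Å, times ps, residue numbering 1-based as in PDB records.
  Multi-model PDB is the canonical trajectory carrier (inspectable,
  desk-scale; binary formats like DCD/XTC are out of scope), parsed through
  bio3d with a pre-scan that turns inconsistent per-model atom counts into
  an error naming the offending model. PDB round-trips are exact to the
  format's 3 decimals; the XYZ writer uses 6 decimals; energy CSVs are
  written with 17 significant digits so doubles round-trip bit-exactly.
* The selection grammar is equality tests joined by `and`/`or` with
  parentheses (`and` binds tighter); no ranges. It is deliberately minimal:
  resolving FE, C30, hydroxyl and key-residue atoms needs nothing more, and
  a grammar error quotes the offending token instead of guessing.
* Parsers never silently drop frames; frame counts in equal frame counts
  out, or an error is raised.
* Energy units are metadata only (default label kcal/mol); every statistic
  is unit-agnostic.
* The CLI is a thin shell over the library (identical outputs by
  construction), writes results to files only, logs to stderr, records
  seed/config/version metadata next to each result, and exits nonzero
  without partial output on any error.

The shipped tests and the acceptance script use deliberately modest problem
sizes — 2 000-frame occupancy runs, 5 000-frame energy/distance series, 10
decoys per pose set, 20–100 seeded replicates per property — chosen so the
binomial/AR(1) error bounds they assert are comfortably resolvable while a
full run stays in the minutes range on a single core.

# Known limitations

* The 2.4 Å criterion's heavy-atom reading is strict; occupancy values are
  sensitive to this choice, which is why the criterion object is explicit
  everywhere.
* Block averaging with a fixed block count is a heuristic; for strongly
  correlated series the error is underestimated unless blocks exceed the
  correlation time. The block count is exposed for that reason.
* The standard error of a ranked comparison ignores correlation between
  variants (each is simulated separately, so independence is exact here but
  only approximate for real replicate simulations).
* The pose score counts residue-pair contacts; it does not model
  electrostatic complementarity and will not discriminate poses that
  satisfy the same contacts in different orientations.
* Variant classification reproduces the standard thresholds; it cannot
  adjudicate which bin convention produced a table's printed labels, and
  `consistencyCheck` therefore reports, rather than repairs, mismatches.
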
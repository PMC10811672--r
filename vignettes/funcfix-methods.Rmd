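---
title: "Methods: fixed-position design masks and variant characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-position design masks and variant characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcfix)
```

# The problem

Inverse-folding sequence design optimizes a sequence for a backbone with
no notion of function. When the goal is to improve a natural protein's
expression or stability *without* losing its activity, the design space
must be constrained: positions that carry function are pinned to their
native identity and only the remainder is redesigned. `funcfix`
implements the two constraint sources that work for liganded enzymes and
binding proteins — contact distance to the bound ligand, and
evolutionary conservation — plus the downstream triage and
characterization analyses that decide which designs were worth making.

# Building the fixed set

## Ligand first shell

`ligand_shell()` selects every polymer residue with at least one heavy
(non-hydrogen) atom within `cutoff` of any heavy ligand atom. Three
choices are deliberate:

* **Heavy-atom contact distance, not Cα–Cα.** "Within 7 Å of the
  ligand" is read as a contact criterion; side chains reach toward the
  ligand, and a Cα criterion would miss long side chains whose
  functional atoms touch the binding site. Hydrogens are ignored
  because deposited crystal structures mostly lack them, and including
  them in predicted models would make the selection depend on
  protonation conventions.
* **Waters and monoatomic ions are not ligands by default.**
  Crystallographic waters would turn most of a protein surface into
  "shell"; flags re-enable both for the rare case where a structural
  water or metal is the functional center.
* **Highest-occupancy altloc only.** Distances are computed on a single
  conformer; mixing alternate conformations would double-count atoms.

The 7 Å default is the conventional first functional shell for a buried
cofactor; it is a parameter, not a constant, and the shell is monotone
in it (a property the test suite checks across cutoffs).

## Conservation

`conservation_scores()` scores each ungapped parent position as the
fraction of alignment rows that carry the parent's residue at that
column. This "parent-identity frequency" is the simplest statistic
consistent with ranking *each amino-acid identity at each position* by
conservation: it asks exactly the question the design step needs
answered — "how strongly does evolution insist on the residue the
parent has here?" — rather than the related but different question of
column diversity. A normalized-entropy alternative is available via
`metric = "entropy"` for comparison; the default stays frequency.

Gap characters count in the denominator and never the numerator. A
column deleted in half the family is weak evidence of essentiality no
matter how uniform the aligned half is; deletions are evidence of
dispensability.

`top_conserved(profile, percent)` fixes the `ceiling(percent/100 * n)`
top-scoring positions. Ceiling rounding errs toward fixing one more
position rather than one fewer — the conservative direction when the
purpose of fixing is to preserve function. Ties break by ascending
position index, which makes the output deterministic and the
selections nested: the 30% set is contained in the 50% set is contained
in the 70% set, so a sweep over percentages explores a nested family of
design spaces.

## Mask assembly and emission

`build_mask()` unions any number of selections (shell, conserved,
catalytic, manual), tracks per-position provenance, and keeps the
invariant that fixed and free positions partition the design chains.
`emit_fixed_positions()` writes the backend dialect
`{"name": {"chain": [positions...]}}` with sorted keys and ascending
lists, so identical masks produce byte-identical files — important when
mask files live in version control alongside design runs. Positions use
1-based sequential numbering along each chain (the numbering the design
backend consumes); human-readable reports carry the author residue
numbers alongside.

# Triage

Designs come back from the structure predictor as models with
per-residue confidence (pLDDT, stored in the B-factor column by
convention). `filter_candidates()` passes a design when

* mean pLDDT `> plddt_min` (default 85.0), the unweighted mean of
  per-residue values — the community convention when a single number is
  reported per model; and
* Cα RMSD to the parent `< rmsd_max` (default 1.0 Å), minimized over
  rigid motions.

Both inequalities are strict: a design sitting exactly on a threshold
fails. The superposition is the Kabsch least-squares solution via SVD,
with the reflection corrected by flipping the smallest singular
direction so the rotation is always proper; collinear degenerate input
is flagged but still returns an RMSD. Region-wise RMSD (e.g. over a
remodeled loop) superposes and measures on the *same* residue subset —
mixing a global fit with a subset measurement produces numbers that
depend on the rest of the protein, which defeats the purpose of a
region-wise comparison.

Length mismatches are a hard error, never silent truncation: the
workflow's designs are fixed-length sequence redesigns, so a length
mismatch means the inputs are mispaired.

# Kinetics

`mm_fit()` fits v = kcat·E·S/(Km+S) by unweighted nonlinear least
squares (no weighting scheme is assumed for the input rates).
Initialisation is a deterministic multi-start: Km starts on a
decade-spaced grid extending one decade beyond the observed substrate
range, kcat from the maximum observed rate; the start with the lowest
residual sum of squares wins. This costs a few extra fits and removes
the classic failure mode of single-start Michaelis–Menten fitting —
convergence to a boundary when the initial Km guess is on the wrong
side of the data. Tables with all-equal substrate concentrations are
rejected as unidentifiable rather than fitted.

Catalytic efficiency kcat/Km and fold improvement over a parent are
thin arithmetic on fitted (or published) parameters;
`kinetic_params()` wraps printed values in the same object so both
routes share code.

`melt_tm()` fits a two-state transition with linear folded and unfolded
baselines, y(T) = b_f(T) + (b_u(T) − b_f(T)) · (1 + e^{(Tm−T)/w})^{−1}.
A transition is only reported when (i) the fitted amplitude at the
midpoint exceeds 5× the residual noise, (ii) the sigmoid at least
halves the residual sum of squares of a plain line, and (iii) the
midpoint lies inside the scanned range; otherwise the result is "no
transition, Tm above the last scanned temperature" — the honest answer
for a protein still folded at the end of the scan, and deliberately not
a number that could be averaged. When the nonlinear fit fails to
converge the midpoint falls back to the maximum-|dy/dT| temperature of
a smoothed, *detrended* curve (detrending is what prevents a sloping
baseline from masquerading as a transition), flagged
`method = "derivative"`. Tm is invariant to affine rescaling of the
signal axis, so ellipticity, normalized fraction folded, or any linear
transform of either give the same midpoint.

# Ensembles

`per_residue_rmsf()` computes, per residue, the RMS deviation of the Cα
from its across-frame mean, after `superpose_frames()` removes global
rigid motion by fitting every frame onto the first. Fluctuations are
Cα-only: per-residue backbone flexibility is the quantity of interest,
and side-chain RMSF mixes in rotamer exchange. The dyad analysis treats
the distance between two named atoms (e.g. a catalytic Cys thiol S and
His ring N) as an internal coordinate — no superposition — and reports
the fraction of frames at or below a cutoff as the catalytically
competent population. The cutoff is a *required* argument: proton
transfer geometry depends on the pair chosen (NE2 vs ND1, S vs SG
naming), and a silent default would bake in a choice the user must own.
4.0 Å is a reasonable starting point for a Cys–His pair. pLDDT spread
across a prediction ensemble uses the population (divide-by-n) standard
deviation, so a two-model ensemble with values {80, 90} reports a
spread of 5.

# The synthetic-data generators

Every analysis has a generator with planted truth
(`make_toy_structure`, `make_toy_msa`, `make_rate_table`,
`make_melt_curve`, `make_ensemble`, `make_candidates`), all
deterministic per seed and all leaving the caller's RNG stream
untouched. The planted conditions mirror the study setting the package
serves: kinetic tables are generated from published-scale parameters
(kcat of order 10⁻³–10⁻² min⁻¹, Km of order 1–10 μM, E = 0.5 μM, eight
substrate levels spanning 0.2–10× Km, 5% relative noise where noise is
wanted); melt curves use a 20–95 °C scan with midpoints in the 80s and
2% amplitude noise; ensembles plant per-residue σ of a few tenths of an
Å over hundreds of frames and bimodal dyad distances (3.5/6.0 Å) with
fixed occupancies. Where the study setting does not pin a value (assay
enzyme concentration, substrate range, ensemble depth), the defaults
above are the package's own choices of a realistic regime, made once.

What the generators do *not* emulate matters for interpreting green
tests: toy structures are Cα-trace helices with point-atom ligands, so
parsing, numbering, shell geometry and superposition are exercised, but
not side-chain packing, altloc frequency, or the atom-naming quirks of
real depositions; synthetic MSAs have exact column frequencies and no
phylogenetic correlation; kinetic noise is i.i.d. multiplicative, with
no inner-filter effects or substrate depletion; ensembles have no
correlated collective motions. Passing tests demonstrate the statistics
are computed correctly under their stated models — not that real
crystal structures, alignments, or assay data are free of the upstream
artifacts those models omit.

Test problem sizes (hundreds of frames, 50–100 replicate seeds,
153-residue shell fixtures) were chosen so the full suite runs in well
under a minute while keeping Monte-Carlo checks comfortably inside
their tolerances.

# Known limitations

* Sequence identity is positional (designs preserve length); comparing
  length-variant constructs needs an external aligner first.
* The mmCIF reader handles the `atom_site` category as exposed by the
  underlying parser; exotic categories (multi-datablock files) are out
  of scope.
* The conservation score ignores residue similarity (a Leu→Ile column
  scores as unconserved at the parent identity); the entropy metric
  softens but does not remove this.
* No attempt is made to reproduce a specific predictor's pLDDT values;
  triage consumes whatever confidences the user's predictor wrote.
* Binary trajectory formats are not parsed; convert to multi-model PDB
  upstream.
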
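# funcfix

Tools for the *function-preserving* stage of deep-learning protein
redesign, and for analysing the characterization data that ranks the
resulting variants.

Inverse-folding networks such as ProteinMPNN redesign a protein's
sequence for a given backbone, but they are purely structural: they know
nothing about catalysis or ligand binding. The standard remedy is to
hold a subset of positions fixed during design — the residues that carry
function. `funcfix` builds that fixed-position set from two signals:

- **ligand first shell** — every residue with a heavy atom within a
  cutoff (default 7 Å) of any heavy atom of the bound ligand or
  substrate;
- **evolutionary conservation** — each parent position scored by the
  fraction of alignment rows retaining the parent residue, with the top
  *X*% (typically 30/50/70%, selections nested by construction) fixed.

The union (plus any manually supplied catalytic residues) is emitted in
the ProteinMPNN fixed-position JSON dialect. After the external design
and structure-prediction backends run, `funcfix` triages the candidates:
a design passes when its mean pLDDT exceeds `plddt_min` (default 85.0)
**and** its Cα RMSD to the parent structure, after Kabsch superposition,
is below `rmsd_max` (default 1.0 Å) — strict inequalities in both.

For the wet-lab follow-up it fits the standard models:

- Michaelis–Menten kinetics, v = k<sub>cat</sub>·E·S/(K<sub>m</sub>+S),
  by multi-start nonlinear least squares, reporting k<sub>cat</sub>
  (min⁻¹), K<sub>m</sub> (μM), the catalytic efficiency
  k<sub>cat</sub>/K<sub>m</sub> (μM⁻¹ min⁻¹) and fold improvement over a
  parent;
- thermal melts as a two-state sigmoid with sloping baselines (midpoint
  T<sub>m</sub>; flat scans are reported as "no transition, T<sub>m</sub>
  greater than the last scanned temperature" rather than a number);
- benchtop activity retention and linear turnover rates;
- conformational-ensemble statistics: per-residue Cα RMSF after
  superposition, region rigidity, and catalytic-dyad distance
  populations (fraction of frames with d ≤ cutoff, e.g. the Cys–His
  d<sub>N–SH</sub> of a protease).

A fixtures module generates synthetic structures, alignments,
candidates, rate tables, melt curves and ensembles with planted ground
truth, so the entire pipeline runs and is tested without any downloads.

## Worked example

```r
library(funcfix)

## synthetic ligand-bound structure with three planted first-shell contacts
toy <- make_toy_structure(60, c(5.2, NA, NA, NA, NA, NA, NA, NA, 6.1,
                                NA, NA, NA, 6.6), seed = 42)
shell <- ligand_shell(toy$structure, "LIG", cutoff = 7.0)
shell$positions$seq_index
#> [1]  1  9 13

## add the top-50% most conserved positions and build the mask
msa  <- make_toy_msa(strrep("A", 60), 20, rep(c(1, 0.8, 0.5, 0.25), 15),
                     seed = 42)$msa
prof <- conservation_scores(msa)
mask <- build_mask(toy$structure, list(shell, top_conserved(prof, 50)),
                   design_chains = "A")
mask
#> design mask: 30 fixed / 30 free (50.0% fixed) on chain(s) A
emit_fixed_positions(mask, "design1")
#> {"design1":{"A":[1,2,5,6,9,10,13,14, ...

## kinetics of a variant measured at 8 substrate levels (5% noise)
fit <- mm_fit(make_rate_table(0.014, 1.4, enzyme_conc = 0.5,
                              noise_rel = 0.05, seed = 42))
fit
#> Michaelis-Menten parameters
#>   kcat    = 0.0144 min^-1 (se 0.00032)
#>   Km      = 1.44 uM (se 0.12)
#>   kcat/Km = 0.01 uM^-1 min^-1
#>   R^2     = 0.9933
fold_improvement(fit, kinetic_params(0.0023, 6, label = "parent"))
#> [1] 26.1

melt_tm(make_melt_curve(84, noise = 0.02, seed = 42))
#> Tm = 84.1 C (se 0.27)  [sigmoid fit]
```

The fitted kcat/Km of 0.01 μM⁻¹ min⁻¹ against a parent at
0.0023/6 ≈ 0.00038 gives the ~26-fold efficiency gain; the melt fit
recovers the planted 84 °C midpoint within its standard error.

A thin command-line wrapper over the same functions is installed at
`inst/cli/funcfix.R` (subcommands `mask`, `triage`, `kinetics`,
`ensemble`, `simulate`); the design backends run between `mask` and
`triage`, with the JSON/TSV/FASTA files as the contract at both edges.

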
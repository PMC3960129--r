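# thermpot

Temperature-dependent statistical potentials for predicting protein
melting temperatures within homologous families.

## The problem

The melting temperature Tm — at which half of a protein population is
unfolded — is the standard measure of thermal stability, and it is only
loosely coupled to thermodynamic stability: two homologs with the same
folding free energy ΔG at room temperature can melt 50 °C apart.
Predictors that score a structure with a single, temperature-independent
energy function therefore estimate thermal resistance poorly. `thermpot`
is for structural bioinformaticians and protein engineers who have a
target structure and measured Tm values for some of its homologs, and
want a fast knowledge-based Tm estimate plus the machinery to study
which interactions carry the temperature dependence.

## The method

Proteins with known or estimated Tm are split at the median into a
mesostable and a thermostable dataset (plus the undivided "average"
set), each culled to below 25% pairwise sequence identity and
characterized by the mean Tm of its members. From each dataset, four
knowledge-based potentials are derived by Boltzmann inversion of motif
frequencies

&nbsp;&nbsp;ΔW(c, s) = −ln [ f̃(s|c) / f(s) ],&emsp;
f̃(s|c) = (σ f(s) + m_c f(s|c)) / (σ + m_c),

where the sequence motif c is an amino acid or amino-acid pair, the
structure motif s is either one of seven backbone (φ,ψ) torsion domains
(two torsion potentials, sequence window ≤ 8) or a binned side-chain
geometric-center distance (two distance potentials, 25 × 0.2 Å bins over
3–8 Å plus underflow/overflow, neighbor-smoothed with weights λ^|k|),
and the shrinkage σ drives sparsely observed motifs to zero energy.
Potentials are averaged over two σ values and the three rules used to
estimate missing Tm from the host's environmental temperature (global
regression, per-family regression, identity transfer).

Scoring a protein against the three potential sets gives per-residue
folding free-energy terms ΔG(T_meso), ΔG(T_thermo), ΔG(T_avg). Tm is
predicted by linear least squares (minimizing the RMS deviation σ
between predicted and experimental Tm) either from the ΔG(T_avg) terms
— the classical thermodynamic-stability route — or from the difference
terms ΔΔG = ΔG(T_meso) − ΔG(T_thermo), which isolate the
temperature-coupled interactions. Jack-knife cross-validation and an
iterative worst-predicted-exclusion procedure quantify generalization.

A fully seeded synthetic-family generator (structures, sequences,
metadata in standard PDB/FASTA/TSV) plants temperature-dependent
contact propensities with known ground truth, so the entire pipeline is
testable without any external data.

## Worked example

```r
library(thermpot)

cfg <- generator_config(seed = 42)          # 2 families x 14 proteins, 60 residues
sf  <- generate_family(cfg)                 # structures + sequences + metadata
rep <- tm_pipeline(sf$records, chains = sf$chains, exclude_worst = 3)
rep
#> tm_report: 28 proteins (16 with measured Tm)
#>   deltaDeltaG  direct: sigma   7.77 C, r  0.82 | jack-knife: sigma  11.90 C, r  0.58
#>                after excluding 3 worst: sigma   6.42 C, r  0.92
#>   deltaG_A     direct: sigma  11.54 C, r  0.54 | jack-knife: sigma  15.27 C, r  0.12
#>                after excluding 3 worst: sigma   9.29 C, r  0.35
```

The 16 proteins with measured Tm are predicted from their homologs'
potentials. The free-energy-difference mode (`deltaDeltaG`)
cross-validates at σ ≈ 12 °C with r ≈ 0.6, while the classical
average-potential mode (`deltaG_A`) barely correlates (r ≈ 0.1) — the
generated data carry a purely temperature-coupled contact signal (a
salt-bridge-like D–R enrichment that grows with Tm, compensated by a
shrinking L–I contact) and no overall-stability signal, so only the
temperature-dependent route can see it. Excluding the 3 worst-predicted
proteins tightens σ to 6.4 °C (r 0.92), mirroring how outlier proteins
(e.g. ligand-bound ones, whose interactions the potentials cannot see)
are diagnosed.

The same workflow is scriptable from the shell via `exec/thermpot`
(`simulate`, `build-datasets`, `derive-potentials`, `score`, `fit`,
`crossval`), e.g.

```sh
Rscript exec/thermpot simulate --seed 1 --out sim
Rscript exec/thermpot build-datasets --table sim/proteins.tsv \
    --fasta sim/sequences.fasta --out ds
Rscript exec/thermpot derive-potentials --datasets ds --pdb-dir sim/pdb --out pots
Rscript exec/thermpot score --table sim/proteins.tsv --pdb-dir sim/pdb \
    --potentials pots --out features.tsv
Rscript exec/thermpot crossval --features features.tsv --table sim/proteins.tsv \
    --mode deltaDeltaG --out cv
```

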
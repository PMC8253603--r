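# structmat

Scoring matrices for MHC class II peptide binders, built from structural
observables of conformational ensembles.

## The problem

Peptides presented by MHC class II receptors bind through a nine-residue
core that sits in the groove formed by the receptor's α and β chains.
Sequence-based predictors rank binders well, but detecting the *sign* of
the activity change caused by a single-point mutation in the core is much
harder. `structmat` implements a structure-derived alternative: count the
interactions each core amino acid actually makes in a conformational
ensemble of the bound complex, and turn those counts into a
position-specific scoring matrix.

For an observable *o* (main-chain hydrogen bonds or non-bonded contacts
within 4 Å), the average observable for amino acid *j* at core position
*i* over runs α and frames *f* is

```
O_ij = (1/Nf) Σ_α Σ_f o_ijαf
```

and the scoring energy is the position-normalized log transform

```
E_ij = −ln( O_ij / Σ_j O_ij )        so that  Σ_j exp(−E_ij) = 1 .
```

Because each simulation run contributes the amino acids of its own
peptide, the natural amino-acid frequencies of the cohort weight the
matrix implicitly. A mutation wt→mut at core position *i* is predicted to
weaken binding when `E[i, mut] − E[i, wt] > 0` (activities are nM-like:
lower = stronger). The package also implements the surrounding machinery:
frame-selection strategies (all frames, last half, best-energy half,
single best-energy frame), sliding-window core prediction under a
sequence PSSM with a two-method consensus and a flank filter, a
≥3-of-6 scoring-function consensus over external score tables, the
conditional-"or" combination of two methods, and a bootstrap over
mutation pairs. A synthetic-data module generates toy complexes and
planted cohorts with analytically known ground truth, so the entire
pipeline is testable offline.

Intended users: structural bioinformaticians and immunoinformaticians who
have (or simulate) peptide–receptor ensembles and want cheap,
interpretable mutation-sign predictions.

## Worked example

```r
library(structmat)

## a 20-frame synthetic ensemble with known planted interactions
toy <- make_toy_complex(toy_complex_spec(
  n_frames = 20, peptide_length = 11, core_start = 1,
  planted_contacts = c(4,2,5,1,3,2,4,2,2),
  planted_hbonds  = c(1,0,1,0,1,0,0,1,0),
  peptide_sequence = "AWCDEFGHIKA", jitter_sd = 0.02, seed = 1))
toy$ensemble
#> EnsembleComplex: 20 frame(s), 67 atoms
#>   peptide chain C : AWCDEFGHIKA  core: WCDEFGHIK (offset 1)
#>   receptor chains: A, B
#>   per-frame energies: present

count_backbone_hbonds(toy$ensemble, frame = 0)$per_position
#> 1 2 3 4 5 6 7 8 9
#> 1 0 1 0 1 0 0 1 0

## scoring matrix from the best-energy half of the frames
tab <- observable_table(toy$ensemble, run_id = "run1")
sel <- select_frames(toy$ensemble, "best_energy_half")
mat <- build_matrix(accumulate_observables(list(tab), "hbonds", list(sel)),
                    pseudocount = 1e-6, observable = "hbonds",
                    strategy = "best_energy_half")
round(mat$E[1:3, c("A","W","C")], 3)
#>        A      W      C
#> 1 13.816  0.000 13.816
#> 2  2.996  2.996  2.996
#> 3 13.816 13.816 13.816
```

Position 1 of the core is a tryptophan that donates one hydrogen bond per
frame, so W scores (near) zero there — strongly favourable — while unseen
amino acids share the pseudocount-limited worst score; position 2 made no
hydrogen bonds, so all twenty amino acids collapse to the uninformative
`ln 20 ≈ 2.996`.

```r
## sign prediction and bootstrap on a planted 56-pair set
E <- default_planted_matrix(seed = 1)
pairs <- make_mutation_pairs(E, n_pairs = 56, activity_noise_sd = 0.5, seed = 2)
m <- build_matrix(exp(-E), pseudocount = 0)
matches <- predict_pair_signs(m, pairs) ==
           experimental_sign(pairs$activity_wt, pairs$activity_mut)
bootstrap_matches(matches, n_replicas = 50, seed = 3)
#> matched 36 of 56 pairs: 0.643  (bootstrap 0.648 +/- 0.068, 50 replicas)
```

With activity noise of 0.5 log-nM the matrix recovers the sign of 36 of
the 56 planted mutations (64.3%), with a 50-replica bootstrap standard
deviation of about 0.07 — the same evaluation protocol used for real
mutation panels.

## Command line

A thin wrapper script is installed under `inst/scripts/structmat`:

```sh
Rscript inst/scripts/structmat simulate --what complex --spec spec.json --out out/
Rscript inst/scripts/structmat observables --pdb out/complex.pdb \
    --peptide-chain C --receptor-chains A,B --core-start 1 --out obs.tsv
Rscript inst/scripts/structmat build --observables obs.tsv \
    --observable hbonds --strategy best_energy_half \
    --energies out/complex.pdb.energies.tsv --out matrix
Rscript inst/scripts/structmat --version
```

Subcommands: `ingest`, `observables`, `compare-dihedrals`, `build`,
`predict-core`, `predict-sign`, `consensus`, `evaluate`, `simulate`,
`summarize`. Every run writes a `manifest.json` with its configuration,
seed and input digests.

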
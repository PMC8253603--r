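---
title: "Structural scoring matrices for MHC class II peptide cores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural scoring matrices for MHC class II peptide cores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmat)
```

## The model

MHC class II receptors bind peptide antigens through a nine-residue core
lodged in the groove between the receptor's α and β chains. The premise
of this package is that the *interactions* each core amino acid forms in
a conformational ensemble of the bound complex — main-chain hydrogen
bonds and non-bonded contacts — carry information about binding
preferences that pure sequence statistics miss.

Given ensembles for a cohort of peptides bound to one allele, the average
observable for amino acid $j$ at core position $i$ is

$$O_{ij} \;=\; \frac{1}{N_f}\sum_{\alpha}\sum_{f} o_{ij\alpha f},$$

where $\alpha$ indexes the simulation runs (one per peptide), $f$ the
selected frames, and $N_f$ is the number of selected frames. If an amino
acid never occurs at a position, its cell is zero. Because each run only
contributes the amino acids of its own peptide, the cohort's natural
amino-acid frequencies weight $O$ implicitly — the matrix is a
frequency-weighted interaction profile, not a per-occurrence average.
The scoring energy is the position-normalized log transform

$$E_{ij} \;=\; -\ln\frac{O_{ij}}{\sum_j O_{ij}},$$

so that $\sum_j e^{-E_{ij}} = 1$ at every position and $e^{-E}$ is a
per-position probability vector (which is also what the logo export
returns). For a single substitution wt→mut at position $i$, the predicted
sign of the activity change is $\operatorname{sign}(E_{i,\text{mut}} -
E_{i,\text{wt}})$: positive predicts weakened binding, matching the
nM convention in which larger activity values mean weaker binders. Ties
(sign 0) are treated as non-matches, and pairs with exactly equal
experimental activities are excluded from evaluation denominators.

### The $N_f$ convention

The definition above leaves open whether $N_f$ is the per-run selected
frame count or the grand total across runs. The two readings differ by a
constant factor per position, which the normalization in $E$ cancels
exactly; `accumulate_observables()` therefore defaults to the per-run
reading (which keeps frame-selection audits coherent, since every run
must contribute the same number of selected frames) and exposes
`nf_convention = "global"` for the other. The equivalence is asserted in
the test suite.

### Zero cells and the pseudocount

$O_{ij} = 0$ would give an infinite energy. `build_matrix()` adds a
pseudocount to every cell before the transform; by default
$10^{-6}\times\max_j O_{ij}$ per position, small enough to leave observed
cells essentially untouched while pinning unseen amino acids at a large
finite energy. The pseudocount scales with $O$, which makes $E$ exactly
invariant under global rescaling of the observable — a property the
transform itself promises and the suite verifies.

## Structural observables

**Contacts.** A contact is a (peptide-atom, receptor-atom) pair within
4.0 Å, with an *inclusive* boundary (a pair at exactly 4.0 Å counts).
Only heavy atoms are counted by default, because crystal-derived frames
rarely carry hydrogens and counts should not depend on protonation
bookkeeping; a flag enables all-atom counting. Frames here are small (a
peptide plus a receptor groove), so the implementation is an exact
vectorized distance computation with no spatial acceleration structure —
the test suite checks it cell-for-cell against an independently written
double loop.

**Main-chain hydrogen bonds.** The peptide-side partner must be a
main-chain atom of a core residue: the amide nitrogen as donor or the
carbonyl oxygen as acceptor. Geometric criteria (defaults chosen to
mirror the classic hydrogen-bond geometry programs): donor–acceptor
distance ≤ 3.9 Å, hydrogen–acceptor distance ≤ 2.5 Å, donor–H–acceptor
angle ≥ 90°. Two auxiliary angle criteria involving the acceptor
antecedent are implemented but disabled by default. Amide hydrogens
absent from the file are placed geometrically: 1.00 Å from N, in the
C(i−1)–N–CA plane, opposing the bisector of the two backbone bonds —
prolines and chain-start residues cannot donate. Receptor-side partners
are all oxygen atoms plus histidine ring nitrogens (acceptors), and
backbone amides or any N/O with an explicit hydrogen (donors).

**Side-chain dihedrals.** χ1 (N–CA–CB–G) and χ2 (CA–CB–G–D) use the
standard per-residue atom tables and the IUPAC sign convention, reported
in [−180, 180). Distributions over an ensemble are histogrammed on 36
fixed 10° bins; two ensembles are compared with the Kullback–Leibler
divergence after adding a pseudocount of $1/(n_\text{samples}\cdot
n_\text{bins})$ to every bin. No circular smoothing is applied, and
symmetric side chains are *not* folded onto [−90, 90) by default: raw
dihedrals are compared, since folding assumptions differ between
force-field conventions. KL is reported directed (both directions from
the CLI), as it is not symmetric.

## Frame selection

Four strategies mirror how trajectory information is typically
subsampled: all frames; the last ⌈N/2⌉ frames (late, equilibrated part);
the ⌈N/2⌉ frames with the best (lowest) energy scores; and the single
lowest-energy frame. Energy ties are broken stably toward the earlier
frame. "Best" always means minimum, the lower-is-better convention of
simulation score functions.

## Sequence-side machinery

Cohorts are assembled by predicting each peptide's 9-mer core with a
published sequence PSSM over sliding windows (ties toward the earlier
window), requiring a second method to agree on the top window
(`consensus_core()`), and discarding peptides whose flanks would force
more than two residues to be appended to either terminus of the
modelling template (`flank_filter()`). These filters are reproduced here
exactly because they shape the amino-acid frequencies that the matrix
inherits.

## Prediction assessment

`make_pairs()` emits every unordered pair of peptides differing at
exactly one core residue, labelling the stronger binder (lower nM) as
wild type. External scoring functions are consumed as per-frame score
tables; a pair is a consensus match when at least 3 of the 6 functions'
mean-score differences carry the experimental sign, with a per-function
orientation flag (lower-is-better by default) — misoriented score
directions are the most dangerous silent failure in this kind of
rescoring, hence the explicit `#orientation` header in the table format.
Two methods combine through a conditional "or": a pair counts if either
method predicted it correctly, so the combined match count is monotone.
Uncertainty comes from a bootstrap over pairs (50 replicas by default,
seeded, resampling with replacement).

## The synthetic-data generator

The generator exists so that every claim above is testable without
external simulations. It produces three things.

**Toy complexes.** An extended 9-mer-core peptide backbone (residue
spacing 7 Å — an idealized stand-in for the extended, polyproline-II-like
conformation of groove-bound peptides) with receptor probe atoms placed
at exact distances to realize *planted* per-position contact counts, and
receptor acceptor oxygens placed on the amide N–H axes (at
donor–acceptor 3.0 Å / 2.9 Å, angles 180°/145°) to realize planted
hydrogen-bond counts. Decoy acceptors violating exactly the angle
criterion can be planted as negative controls. Because a planted
acceptor necessarily sits inside the donor residue's 4 Å contact shell,
the generator brute-force-counts those induced contacts first and plants
only the remainder as probes; impossible requests (contacts below the
induced count, more than 15 probe slots, more than 2 bonds per position,
donors without a preceding residue, proline donors) fail with a capacity
error rather than silently degrading. Frames add Gaussian jitter whose
per-atom displacement is norm-clamped at 0.1 Å, and the base geometry is
validated to keep every atom pair at least 0.22 Å away from the 4.0 Å
cutoff and every hydrogen-bond criterion inside its margin — so planted
counts are exact in *every* frame, not just on average. Per-frame
energies are standard-normal draws, giving the energy-based selection
strategies something deterministic to select under a seed.

**Planted cohorts.** A 9 × 20 planted energy grid $E^\*$ (by default,
per position, a random permutation of 20 linearly spaced frequency
weights with a six-fold spread) generates peptide cores from
$p = e^{-E^\*}$ and activities
$\exp(a + b\,S + \varepsilon)$, where $S$ is the peptide's total planted
score, $\varepsilon \sim N(0, \sigma)$ is log-scale noise, and $a, b$ are
calibrated once so noise-free activities span exactly 1–10,000 nM. At
$\sigma = 0$ the sign of any single-substitution activity difference
equals the planted energy difference by construction. A slope multiplier
allows the null model (activities independent of sequence), under which
sign prediction collapses to 50% — verified in the suite. Observable
counts couple to the same planted grid: the contact count of amino acid
$j$ at position $i$ is $1 + \mathrm{round}(9\, p_{ij}/\max_j p_{ij})$, a
monotone function of the planted frequency, so the matrix pipeline must
recover the planted ordering from both occurrence frequencies and count
magnitudes, as the real method assumes interaction counts track binding.
The coupling gain is a parameter, making that premise itself testable.

**Score tables.** Six synthetic scoring functions whose mean-score
difference carries each pair's experimental sign independently with a
stated accuracy $p$; frame noise (σ = 0.05 around unit mean differences,
10 frames) is small enough that the planted accuracy is exact, which is
what makes the ≥3-of-6 consensus rate comparable to its binomial closed
form $\sum_{k\ge3}\binom{6}{k}p^k(1-p)^{6-k}$ to Monte-Carlo precision.

### What passing tests do and do not show

The generator plants rigid, margin-protected geometry and lognormal
activity noise. Passing the recovery and consensus checks therefore
demonstrates that the *bookkeeping and statistics* of the pipeline are
correct — attribution of interactions to core positions, the
accumulation and normalization algebra, sign conventions, selection and
resampling. It does not demonstrate that real backrub or MD ensembles
sample realistic conformations, that hydrogen-bond counts causally track
binding affinity in real complexes, or that the 4 Å / HBPLUS-style
thresholds are optimal — those are claims about physics and data, outside
what synthetic fixtures can establish.

## Problem sizes and numerical choices

The bundled checks use a 500-peptide noise-free cohort (one frame per
complex) for end-to-end recovery, 400-pair panels for the activity-noise
ladder (σ ∈ {0, 0.5, 2} log-nM), 5,000 pairs for the consensus closed
form, and 100 random frames per observable for oracle equivalence —
sizes chosen so the whole suite runs in well under a minute while
leaving Monte-Carlo error far smaller than the effects being asserted.
The recovery statistic is the mean over the nine positions of the
per-position Spearman correlation between recovered and planted
energies; with 500 peptides the multinomial occupancy noise of
individual rare cells makes a per-position *minimum* an unstable
statistic, while the mean is a faithful summary of ranking recovery.
Other conventions fixed here: 0-based frame identifiers in all files and
tables; 0-based core offsets internally with author residue numbering
preserved for I/O; altloc resolution by highest occupancy (ties toward
altloc "A"); waters and heteroatoms dropped on read by default; the
restrained-receptor question (atoms far from the peptide) resolved by
counting all receptor atoms present in the file.

## Known limitations

Side-chain hydrogen bonds, salt bridges and π interactions are not
counted; only the sign of activity differences is claimed, never the
magnitude; one matrix describes one allele (no pan-allele
generalization); mmCIF and binary trajectory formats are not read; and
the toy geometry makes no claim of structural realism beyond realizing
its planted counts exactly.
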
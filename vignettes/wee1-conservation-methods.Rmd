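---
title: "Methods: reference-anchored conservation analysis of WEE1-family kinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored conservation analysis of WEE1-family kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinanchor)
```

## The analysis

`kinanchor` answers one question about a kinase family: *which of the
residues known to make the reference enzyme work are conserved in each
homolog, and what do the departures imply?* The pipeline has five stages,
each usable on its own:

1. **Pairwise alignment.** Global Needleman–Wunsch with affine gaps
   (Gotoh's three-state recursion): a gap of length $k$ costs
   $g_o + k\,g_e$. End gaps are penalized — a deliberately strict global
   mode, because ragged termini are handled explicitly by end trimming
   rather than silently by free end gaps. Scores come from a symmetric
   substitution matrix over the 20 amino acids plus `X`, which scores 0
   against everything so unknown residues neither reward nor punish an
   alignment.
2. **Progressive multiple alignment.** p-distances from all pairwise
   alignments, a neighbor-joining guide tree (midpoint-rooted), and
   profile–profile merging in post-order under the same affine gap model.
   A profile column is a residue-frequency vector $f$; two columns score
   $f_a^\top S f_b$ with the gap row scoring 0. Alignment never edits
   residues: degapping any row reproduces its input.
3. **Reference anchoring.** One row (the full-length human WEE1A homolog
   by default) defines the coordinate system: column $c$ carries reference
   position $p$ iff the reference row's $p$-th residue sits in $c$. Every
   query is then "what does sequence $s$ have in the column of reference
   position $p$, and at which of its own positions?"
4. **Site calling.** A catalog lists expected residues at reference
   positions. Observed residues are classified `conserved` (member of the
   expected set), `conservative` (same physicochemical class),
   `class-change`, or `missing` (gap / trimmed away). Flags condense the
   calls: a kinase without the catalytic-loop aspartate is
   `catalytic-dead`; without the DFG aspartate,
   `ATP-binding-compromised`; and so on.
5. **Structure.** Kabsch superposition (SVD with reflection correction) on
   alignment-paired Cα atoms, and the pocket-access measurement: the
   minimum distance between heavy side-chain atoms of the two residues
   flanking the substrate entrance.

## The WEE1 site catalog

`builtin_wee1_catalog()` encodes, in human WEE1A numbering: E309 (G-loop,
tyrosine-specificity gate), K328, N376 (gatekeeper), C379, D426 (catalytic),
K428, N431, the activation-segment motif at 463–465 (aspartate, then L *or*
F — human WEE1 has DLG where most kinases and all the plant homologs have
DFG, so position 464 accepts either without a flag; only the aspartate is
function-critical), the signatory EGD at 477–479, and the docking arginines
R481 and R518. The catalytic-segment consensus `IVHxDLKPxNIx` is anchored
at 422–433. Two classification choices follow the conventional coloring of
kinase alignment figures rather than chemistry textbooks: histidine is
grouped with the aromatics (Y, H), not the basics, and the
"hydrophobic-relaxed" consensus mode (off by default, reported when on)
accepts any of A, I, L, M, F, V, W wherever the pattern letter is itself
hydrophobic — exactly the hydrophobic class, nothing more.

The catalog is data, not code: it serializes to JSON
(`write_catalog_json()`), so other kinase families can be annotated by
supplying their own sites.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| substitution matrix | BLOSUM62 | the standard protein matrix at ~60% identity and below |
| `gap_open` | 10 | Clustal-style protein default |
| `gap_extend` | 0.5 | ditto; long indels between domains stay cheap |
| `min_occupancy` (trimming) | 0.5 | drop terminal columns where most rows are absent; 1.0 reproduces strict complete-column trimming |
| NJ distance | p-distance | monotone in identity; `poisson_correct()` ($-\ln(1-p)$) available for deeper divergences and is flagged in reports |
| gate distance mode | `min-side-chain-heavy` | "access" between side chains is their closest heavy-atom approach; the achieving atom pair is always reported, and `atom-pair` mode probes alternatives |

Trimming bookkeeping is worth a note: trimmed alignments remember, per row,
how many residues were removed at each end, so reference numbering always
refers to the *full-length* sequences and a query into a trimmed-away
region answers `"outside"` rather than silently renumbering.

## Design choices where the design was open

* **Pairwise vs. family-wide anchoring.** Per-species positions of the
  form "reference position 309 = own position 259" can be derived either
  from the full family MSA or from a pairwise alignment to the reference.
  Both modes exist (`build_column_map()` accepts either), and on the
  synthetic panel they agree; the pairwise mode is the primary interface
  because it isolates each correspondence from unrelated taxa.
* **Distance trees, not Bayesian inference.** The phylogenetic surface here
  is a convention (midpoint-rooted phylograms, Newick exchange), not the
  analytical core, so the package builds NJ trees and *imports* externally
  computed consensus trees (support labels retained) for comparison via
  Robinson–Foulds. MCMC tree inference is explicitly out of scope.
* **Determinism over optimality polish.** Traceback ties break
  diagonal > up > left; NJ Q-ties break on the lexicographically smallest
  label pair; negative NJ branch estimates are clamped to zero with the
  deficit moved to the sister branch (midpoint rooting itself is delegated
  to `phangorn::midpoint()`, which is deterministic for fixed input).
  Identical inputs therefore give byte-identical outputs, which
  `run_report()` turns into a reproducibility guarantee for the whole
  artifact bundle.
* **Superposition on Cα only.** Homology models and crystals differ most
  in side-chain placement, so the fit uses backbone Cα pairs; side chains
  enter only through the explicit distance measurements.

## The synthetic generators: what they do and do not show

`simulate_family()` evolves the reference down a (given or random) tree:
each site substitutes independently per branch with a fixed probability,
uniformly over the 19 alternatives; indels (Poisson per branch) avoid ±2
residues around protected positions; planted events are applied on terminal
branches and guaranteed present. The generator trades realism for exact
bookkeeping — no rate heterogeneity, no empirical substitution bias, no
correlated indels — because its job is ground truth: per-taxon homology
maps make "did the pipeline recover the planted event?" a well-defined
exact question (and the test suite requires recall = precision = 1 through
simulate → align → anchor → call).

`synthetic_wee1_reference()` and `synthetic_plant_wee1()` are deterministic
stand-ins: a 646-residue reference with every catalog feature at its
documented human position (filler drawn once from a fixed seed, then
scrubbed of accidental motif hits), and plant-like derivatives that are
N-terminally shortened, ~50% diverged outside protected windows, and carry
the documented plant substitutions (H/Y/N at the E309-homologous position,
methionine gatekeeper, glutamate at 518; the Chr6.1-like paralog loses both
aspartates). The offsets are chosen so the E309 analogs fall at own
positions 259, 248 and 256. What passing tests on these data show is that
the *computation* — scanning, aligning, numbering transfer, measurement —
recovers planted truth; they do not validate alignment quality on real
families, where domain architecture, composition bias and real indel
processes are harsher than the generator.

`simulate_structure_pair()` builds a helix-like backbone and a rigidly
transformed, optionally noise-perturbed copy; `simulate_gate()` plants an
exact minimum side-chain distance between a glutamate and an arginine with
all other atoms strictly farther, so the measurement's atom-pair report is
also checkable. Synthetic structures are idealized (no clashes, minimal
atom sets); they validate geometry code, not stereochemistry.

## Numerical notes and degenerate inputs

* Alignment DP runs in C++ over a precomputed cell-score matrix (the same
  kernel serves residue and profile alignment); scores are exact doubles,
  and the brute-force enumeration oracle agrees on all short inputs.
* Kabsch uses `svd()`; a reflection is corrected by negating the smallest
  singular direction, so the rotation always has determinant +1. Collinear
  inputs (second singular value ~0) are rejected.
* An all-zero tree has no midpoint; `midpoint_root()` warns and returns the
  tree unchanged rather than inventing a root.
* PDB coordinates carry three decimals, so structure round-trips are exact
  to 1e-3 Å; planted gate distances are exact to 1e-6 in memory.
* Identical sequences give a zero distance matrix; NJ still returns a
  (star-like) tree and progressive alignment handles it gap-free.

## Problem sizes

The test suite and acceptance script are sized for a single CPU: brute-force
alignment oracles to length 6 (4-letter alphabet), NJ recovery to 12 taxa,
Kabsch Monte-Carlo bounds with 1000 random transforms at n = 50 points,
noisy-rotation recovery over 20 seeds at n = 100 residues, and families of
3–6 taxa over the 646-residue reference. Everything runs in well under a
minute each; the complete suite takes on the order of 15 seconds.

## Known limitations

* p-distance NJ is a rough phylogeny; for publication-grade trees import a
  tree computed with a proper model and compare topologies here.
* The progressive aligner has no iterative refinement and will not match
  a modern MSA tool column-for-column on hard families; it is deterministic
  and sufficient for site transfer between clearly homologous kinase
  domains.
* Site calling reads single columns; it does not model compensatory or
  context-dependent substitutions.
* Pocket-access distances depend on side-chain conformations of the input
  structures; on homology models they inherit the model's side-chain
  uncertainty, which is why the achieving atoms are always reported.
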
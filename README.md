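# kinanchor

Reference-anchored conservation analysis of WEE1-family kinases.

WEE1 is the kinase that restrains the cell cycle by inhibitory
phosphorylation of cyclin-dependent kinases. Whether a plant WEE1 homolog is
a *functional* kinase — and whether it can be inhibited or can act on the
same substrates as the human enzyme — comes down to a handful of residues in
the kinase domain: the catalytic aspartate of the HxD catalytic loop (human
D426), the Mg²⁺-ATP-binding aspartate of the DFG/DLG motif (D463), the
WEE1-signatory EGD motif (477–479), the ATP-pocket gatekeeper (N376), the
G-loop glutamate implicated in tyrosine specificity (E309), and the
substrate-docking arginines (R481, R518). `kinanchor` is a toolkit for
asking those questions systematically across a sequence family, for
phylogeneticists and structural biologists working on kinase families:

* **Alignment** — global pairwise alignment with affine gaps
  (Needleman–Wunsch/Gotoh; score of a length-*k* gap is
  `gap_open + k·gap_extend`, BLOSUM62 defaults) and Clustal-style
  progressive multiple alignment with a neighbor-joining guide tree and
  low-occupancy end trimming.
* **Reference-anchored numbering** — every sequence is read in the residue
  coordinates of one full-length reference (human WEE1A by default), so a
  finding like "the human E309 corresponds to H259 in *A. thaliana*" is one
  function call.
* **Functional-site annotation** — a curated, JSON-serializable site
  catalog is evaluated on every sequence; substitutions are classified
  physicochemically (hydrophobic / acidic / basic / polar / aromatic / C /
  P / G) and condensed into functionality flags (`catalytic-dead`,
  `ATP-binding-compromised`, `EGD-variant`, `gatekeeper-variant`,
  `docking-R481-variant`, `R518-variant`).
* **Phylogeny** — neighbor joining on p-distances (optionally
  Poisson-corrected), midpoint rooting, Newick import/export with support
  labels, Robinson–Foulds comparison against externally computed trees.
* **Structure** — PDB parsing, Kabsch (SVD) superposition on
  alignment-paired Cα atoms, and catalytic-pocket "access" measurement: the
  minimum heavy side-chain atom distance between the two residues flanking
  the substrate entrance (E309/R518 in human numbering).
* **Synthetic data with known truth** — generators for sequence families
  evolved down a tree with planted substitutions at functional sites,
  rigid-transformed structure pairs, and gate structures with planted
  access distances, so every pipeline stage is testable end to end without
  downloads.

## Worked example

The package ships deterministic synthetic stand-ins for the human reference
and four plant orthologs (`synthetic_wee1_panel()`; these are labelled
synthetic sequences built around the documented site architecture, not
database entries). Real data go through the same calls — read them with
`read_fasta()` / `read_pdb()`; `inst/scripts/fetch_real_inputs.R` documents
how to download the corresponding NCBI/RCSB inputs.

```r
library(kinanchor)

panel <- synthetic_wee1_panel()
msa   <- trim_ends(progressive_align(panel), 0.5)
cmap  <- build_column_map(msa, "HsWEE1_synth")

residue_at(msa, cmap, "AtWEE1_synth", 309)
#> <residue_obs> AtWEE1_synth @ ref 309: H (own position 259) (ok)
```

The *A. thaliana*-like sequence carries a histidine at its own position 259,
the column homologous to the human G-loop glutamate 309 — the substitution
that removes the tyrosine-specificity gate.

```r
tab <- call_sites(msa, cmap)   # builtin_wee1_catalog() by default
assess_function(tab)
#> HsWEE1_synth: (none)
#> AtWEE1_synth: gatekeeper-variant, R518-variant
#> MtWEE1_synth: gatekeeper-variant, R518-variant
#> PsWEE1_synth: gatekeeper-variant, R518-variant
#> VuWEE1_Chr6.1_synth: catalytic-dead, ATP-binding-compromised, EGD-variant,
#>   gatekeeper-variant, docking-R481-variant, R518-variant
```

All plant-like sequences show the methionine gatekeeper and the
arginine-to-glutamate change at 518 (a wider, less restricted substrate
entrance); the *V. unguiculata* Chr6.1-like paralog additionally lacks both
the catalytic and the ATP-binding aspartates — a kinase-dead configuration.
`site_summary(tab)` tabulates per-site status counts, and
`write_conservation_tsv()` exports the sequences-by-sites table.

Pocket geometry is measured the same way on any PDB structure:

```r
gate <- simulate_gate(8.3, seed = 1)   # or read_pdb("1X8B.pdb")
residue_distance(gate, "A:309", "A:518")
#> <gate_measurement> A:309 OE2 -- A:518 NH1  8.30 A (min-side-chain-heavy)
```

An end-to-end run (`run_report(run_config(...))`, or the `kinanchor` CLI in
`exec/`) writes the alignment, four segment views (G-loop, ATP-binding,
catalytic, activation), the conservation table, flags JSON, a
midpoint-rooted NJ tree, gate-access table and a run manifest into one
output directory, deterministically.

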
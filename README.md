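# pepbind

Template-based prediction of protein–peptide binding sites in R.

Short peptides (5–25 residues, often disordered until they bind) drive a
large share of regulatory protein interactions and are attractive drug
targets, but their complexes are difficult to crystallise and docking them
blind is hard. `pepbind` answers the narrower, tractable question: **given a
receptor structure and a peptide sequence, which receptor residues form the
binding site?** It does so by precedent rather than physics: known
protein–protein and protein–peptide interfaces are treated as reusable
templates for new interactions.

## Method

Given a receptor chain and an interaction-template library (all chain pairs
from a structure collection with any heavy atom within 6 Å):

1. **Structural alignment** — the receptor is superposed on every template's
   receptor-role chain; matches are scored with the TM-score
   `TM = (1/L) Σ 1/(1 + (dᵢ/d₀)²)`, `d₀ = 1.24 (L−15)^⅓ − 1.8`, and
   alignments with target-normalized TM ≥ 0.5 transfer the template's
   interface residues onto the receptor as a candidate site.
2. **Features** — each candidate gets a 23-dimensional descriptor
   (alignment quality, lengths, contact order, composition distances,
   secondary structure, exposure, conservation, template-peptide
   continuity; optionally receptor model quality).
3. **Random forest** — a 100-tree probability forest (√N features per
   split, unlimited depth) scores each candidate's probability of being
   correct (a candidate is *correct* when ≥ 80% of its residues lie in the
   true site).
4. **Clustering and scores** — candidate surfaces are clustered
   (average linkage on mean cross-pair Cα distance, elbow cutoff); the best
   cluster's top 10% of templates are averaged, weighted by forest
   probability, into per-residue **local scores**, and the prediction's
   confidence is the **global score** `0.61·cluster + 0.39·max(local)`.

A deterministic synthetic-structure generator (ideal helices, strands,
hairpins, helix bundles with pseudo side chains) makes the whole pipeline
testable without any downloads, including planted-template benchmarks with
known answers.

## Worked example

```r
library(pepbind)

# a synthetic benchmark complex with a known binding site
rec <- make_chain("HELIX_BUNDLE", 60, seed = 11)
pep <- make_chain("HELIX", 9, seed = 12)
cx  <- make_complex(rec, pep, id = "target")

# a template library with one noisy copy of the truth among 20 decoys
pl <- make_planted_library(cx, n_decoys = 20, noise_sigma = 0.5, seed = 5)

# train the ranking forest on an independent synthetic labelled set
model <- train_ranker(make_training_set(n_targets = 6, seed = 42), seed = 7)

pred <- predict_binding_site(cx$structure, "A", pep$sequence, pl$library, model)
pred
#> <pb_prediction> 1 candidate(s) in 1 cluster(s)
#>   global score 0.668 (cluster 0.455, max local 1.000)
#>   predicted site: 8,11,15,18,27,31,34

cx$true_site$members
#> [1]  4  8 11 15 27 31 34

site_identified(pred$site, cx$true_site)
#> [1] 1
```

Six of the seven predicted residues are true interface residues
(PPV = 0.86 ≥ 0.5, so the site counts as identified); the global score 0.668
combines the forest's confidence in the best template cluster (0.455) with
the perfect local consensus (1.0) using the fixed 0.61/0.39 weights.

Real structures enter through `read_pdb()`, libraries are built from any
directory of PDB files with `build_library()` (serialized with
`write_library()` / `read_library()`), and predictions can be written as a
TSV score table, JSON report and B-factor-annotated PDB with
`write_prediction()`. A thin command-line wrapper with `build-library`,
`train`, `predict`, `fixtures` and `benchmark` subcommands ships in
`inst/cli/pepbind`.

## Scope

The package predicts binding *sites*, not bound peptide poses; mmCIF
parsing, hydrogen handling and nucleic acids are out of scope. See the
methods vignette (`vignettes/pepbind-methods.Rmd`) for the full model
description, parameter table and design rationale.
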
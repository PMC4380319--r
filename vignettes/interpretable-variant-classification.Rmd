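---
title: "Interpretable missense variant classification: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable missense variant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misvep)
```

## The problem and the modelling idea

A missense variant replaces one amino acid in a protein with another.
Most such substitutions segregating in the population are neutral; a
minority disrupt protein function and associate with disease. Black-box
predictors can separate the two classes well, but give no insight into
*why* a substitution is dangerous. This package takes the opposite
trade-off: linear maximum-margin classifiers over five transparent,
sequence-derived feature categories, so that every fitted coefficient can
be read as evidence for or against pathogenicity.

A single linear model over all variants is however mis-specified: the
meaning of a feature like "mutant is aspartate" depends strongly on what
the reference residue was. The central device is therefore to train **one
classifier per reference amino acid** — variants with reference glutamine
are scored by the glutamine model, and so on. Tryptophan, tyrosine and
phenylalanine are individually too rare as reference residues to support
their own classifiers and are pooled into a joint `WYF` subset, giving 18
subsets over the 20 amino acids. Per-subset probability outputs (Platt
calibration) make scores comparable across subsets, so one pooled ROC
curve summarises the whole ensemble (the combined-subset protocol,
`C_S`); a classifier trained on all variants at once (`C_E`, summarised
by the mean of its per-fold AUCs) serves as the comparison baseline.

## Feature categories

For a variant (protein $p$, position $i$, reference $r$, mutant $m$):

* **Substitution** (20 columns): $-1$ at the reference amino acid, $+1$
  at the mutant, 0 elsewhere. Each row sums to zero.
* **Surrounding sequence** (20 columns): counts of each amino acid in a
  19-residue window centred on $i$, truncated at the sequence ends. The
  window is read as positions $i-9 \dots i+9$; whether the centre residue
  itself is counted is switchable (`window_spec(include_center =)`), and
  the default counts it — the encoding is a composition summary and the
  centre is part of the local composition. Because the reference residue
  is constant within a subset, this choice only shifts one count by a
  constant per subset and is absorbed by standardization.
* **Conservation** (4 columns): from the alignment column at $i$ of a
  pre-computed multiple sequence alignment whose first row is the query —
  the frequency of $r$, the frequency of $m$, the number of aligned
  proteins, and the number of non-gap residues in the column. Frequencies
  are computed over non-gap residues (`n_residues`), not alignment depth:
  a mostly-gapped column with two identical residues is fully conserved
  *given the evidence available*, and the two count features carry the
  amount of evidence separately. The query row is included in the column,
  so the reference frequency is never 0 merely because homologs are
  missing.
* **Physicochemical conservation** (one column per amino-acid scale, 19
  by default): for each scale $s$, $\min_{a \in \text{column}} |s(m) -
  s(a)|$ — how far the mutant's physicochemical properties are from
  anything tolerated at that position. Zero whenever the mutant itself is
  observed (which makes the feature exactly consistent with a positive
  mutant frequency); zero also for an empty column, where the
  conservation counts already flag that nothing is known. All residues
  observed in the column, including the reference, form the comparison
  set.
* **Domain** (3 columns): indicators for the variant lying inside an
  annotated Pfam family, domain, or clan span.

### The amino-acid scale set

The packaged scale table (`inst/extdata/aa_scales_varimax19.tsv`, loaded
by `read_scales()`) contains 19 mutually uncorrelated scales derived from
the 531 complete amino-acid indices of the AAIndex collection:
each index is standardized across the 20 amino acids, the resulting
matrix decomposed by SVD, the 19 non-trivial loading vectors
varimax-rotated, and the rotation carried to the orthonormal score
vectors, which therefore remain exactly uncorrelated; each scale is
rescaled to zero mean and unit variance. Scale `V1` correlates 0.92 with
Kyte–Doolittle hydropathy, so the leading scale retains a direct physical
reading. Any user table of the same shape (20 rows, one column per
scale) is accepted in its place.

## Dataset construction

`filter_variants()` reproduces the dataset-construction pipeline in a
fixed stage order, with a count-reconciled report:

1. **Class overlap**: a variant reported both as disease and as neutral
   keeps the disease label; the neutral copy is dropped.
2. **Basic sanity**: synonymous records, exact duplicates, variants at
   position 1 (the start codon, in protein coordinates), and records with
   non-standard letters are removed.
3. **Single-codon reachability**: substitutions that require more than
   one nucleotide change in any codon of the reference amino acid are
   removed, since single-nucleotide variants cannot produce them and
   their presence differs systematically between data sources. Under the
   standard genetic code exactly 150 of the 380 ordered amino-acid pairs
   survive; from serine specifically, aspartate, glutamate, histidine,
   lysine, methionine, glutamine and valine are unreachable.
4. **Sequence fit**: records whose protein is unknown or whose stated
   reference residue does not match the sequence are removed.
5. **Duplicate windows**: variants at different locations sharing the
   same substitution and the same 19-residue sequence context are taken
   to be one DNA mutation mapped to several protein entries. One
   canonical record (smallest protein id, then position) is kept; the
   stricter reading that removes the whole group is available
   (`drop_all_window_dups = TRUE`), as is restricting the comparison to
   within a label (`within_label = TRUE`). The default compares across
   labels, because the mechanism being corrected — redundant protein
   entries — does not depend on the label.

## Classifier and training protocol

Support vector machines are fit with libsvm (via e1071): linear kernel
with `C = 0.1` by default, or an RBF kernel (`C = 1.0`,
`gamma = 0.01`) for the non-interpretable performance ceiling. Before
fitting, features constant within the training subset are removed (for
the serine subset this removes serine's own indicator and the seven
unreachable-mutant indicators exactly), and the remaining columns are
standardized to zero mean and unit variance. Population (divide-by-$n$)
standard deviation is used throughout — the convention matters only as a
single constant factor absorbed by `C`, but it is fixed and documented.
Scalers are fitted within each cross-validation training fold only and
re-applied verbatim to the held-out fold, the leak-free convention.

Evaluation uses seeded, stratified 10-fold cross-validation within each
subset. Fold assignment, and the random stream used by the Platt
probability calibration, are derived deterministically from the
configuration seed and the subset key, so results are reproducible and
independent of the order in which subsets are processed. A subset lacking
a class, or with fewer minority-class variants than folds (so that
stratification cannot give every training fold both classes), is flagged
untrainable and skipped with a warning — a small-sample guard that never
triggers at realistic subset sizes. AUC is computed by pROC; a
brute-force Mann–Whitney count serves as the oracle in the tests.

## Weight interpretation

For a linear model the weight vector is recovered from the dual solution,
$w = \sum_i \alpha_i y_i \Phi(v_i)$ over the support vectors (labels
$y_i \in \{-1, +1\}$, $+1$ = disease), and every trained model is checked
against its own decision function: $x \cdot w + b$ must reproduce the
solver's decision values to within $10^{-6}$ relative error. Weight
vectors are standardized to zero mean and unit variance per classifier —
each row of a weight table is a *pattern*, comparable across subsets of
very different sizes and margins; masked (removed-constant) features are
excluded from the row statistics. Positive standardized weight reads
"disease-predictive", negative "neutral-predictive".

Two display orderings are provided: a fixed physicochemical amino-acid
ordering (an editable constant, `AA_PROPERTY_ORDER`: aliphatic →
aromatic → polar → charged → conformationally special), and
complete-linkage hierarchical clustering of rows and columns on Euclidean
distances, with masked cells imputed as 0 for the distance computation
only. Euclidean distance is the natural choice for rows that are already
z-scored patterns.

As a model-free cross-check, `log_odds_matrix()` counts each substitution
in the disease and neutral sets and reports
$\log\frac{(d_{rm} + c)/(D + 380c)}{(n_{rm} + c)/(N + 380c)}$,
normalized by class totals so the matrix is insensitive to class
imbalance, and masked to the 150 reachable ordered pairs (230
off-diagonal cells masked). The pseudocount defaults to the
Haldane–Anscombe $c = 0.5$ so that zero-count cells stay finite;
$c = 0$ reproduces raw log odds where counts permit. The orientation is
chosen so that positive = disease-enriched, matching the weight-table
sign convention: a substitution-feature weight matrix from the ensemble
should visibly echo this matrix.

## The synthetic-data generator

Real training data requires curated variant catalogues, population
sequencing, alignment and domain-annotation pipelines. The generator
(`simulate_variant_data()`) replaces all of that with a controlled
emulation: i.i.d. protein sequences (uniform composition by default, a
composition table may be supplied); alignments in which each homolog
residue copies the query with a per-column probability drawn from a
configurable conservation range, is replaced uniformly otherwise, and
gaps appear at a fixed rate; Pfam-like random interval annotations; and
variants drawn only at positions ≥ 2 whose reference matches the
sequence, with mutants drawn among single-codon-reachable amino acids —
so generated data passes the whole filtering pipeline with zero
sequence-fit removals by construction.

Labels come from a logistic model over the z-scored *true* feature
values: $P(\text{disease}) = \text{logit}^{-1}(b_0 + \sum_f \beta_f
z_f)$, with $b_0$ solved so the expected disease fraction matches the
configured class balance (default 0.125, the order of magnitude of real
curated datasets). A logistic label model, rather than a deterministic
threshold, makes the Bayes-optimal AUC finite, tunable, and computable:
`oracle_auc()` estimates it by Monte Carlo as the AUC of the true linear
predictor. The default planted effects — one feature per category,
`sub_G` +1.5, `count_S` −1.5, `f_ref` +2.0, `pc_V1` +1.5, `in_domain`
+1.5 on the log-odds-per-SD scale — were chosen once, against the oracle
only, to put the ceiling near 0.965–0.97 at $n = 20{,}000$; the trained
ensemble's pooled AUC is then measured against that ceiling. With
`subset_heterogeneity = TRUE` every effect's sign flips for reference
amino acids in the first half of the alphabet, planting exactly the kind
of reference-conditional rule that per-subset classifiers can represent
and a single linear model cannot — the testbed for the `C_S` versus
`C_E` comparison.

What the generator does **not** emulate: phylogenetic correlation between
homologs (columns are conditionally independent given the query),
realistic domain architectures, compositional biases around variants, or
label noise structure of curated databases. Passing the synthetic
recovery suite therefore demonstrates that the machinery is correct and
that planted signal of realistic strength is recovered — not that any
particular accuracy will be achieved on real human variant data.

## Problem sizes and numerical choices

The test and acceptance runs use $n = 20{,}000$ variants over 60
proteins for the headline recovery (matching the scale at which all 18
subsets are comfortably trainable), $n = 4{,}000 \times 20$ replicates
for weight-recovery rates, $n = 4{,}000 \times 10$ seeds for the
subset-versus-entire comparison, and $n = 2{,}000$ for the null control —
sizes chosen so the full suite runs on a single CPU in minutes while
keeping binomial noise well inside the asserted margins. Ties in ROC
construction are handled by the trapezoidal rule; standardization
refuses zero-variance columns (they must have been removed); degenerate
alignment columns yield zero frequencies and distances with the evidence
counts carrying the information; predictions for substitutions that are
not single-codon reachable are produced with a warning, since the subset
model extrapolates there.

## Known limitations

* The RBF configuration is provided for the performance comparison only;
  weight extraction refuses it by design.
* The entire-set and subset protocols generate their fold partitions
  independently from the same seed; they are not forced to share
  partitions.
* The shipped scale set is derived from the current AAIndex collection;
  it is *a* 19-scale uncorrelated basis with the documented construction,
  not a copy of any previously published table.
* Genomic (VCF) coordinates, codon-level data, and running aligners or
  domain scanners are out of scope; the package consumes their outputs.
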
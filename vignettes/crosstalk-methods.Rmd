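---
title: "Methods: inferring TAM-secreted drivers of GBM invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring TAM-secreted drivers of GBM invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamtalk)
```

## The problem

Tumor-associated macrophages (TAMs) are abundant in glioblastoma and
their secreted factors can drive tumor-cell invasion, but which ligands
matter, and from which macrophage population they come, is not readable
from any single assay. `tamtalk` implements a multi-omics inference
chain that triangulates candidate ligands from three directions:
label-free proteomics of conditioned media (CM) from M1- vs M2-polarized
macrophages (who secretes what, and in which polarization state), bulk
RNA-seq of the tumor cells (which receptors the tumor actually
expresses), and single-cell RNA-seq of patient tumors (which candidate
ligands are expressed by TAMs in vivo, and by which TAM ontogeny).

## The procedure and its assumptions

### Detection filtering and fold change

Label-free CM proteomics yields a protein × (condition, replicate)
intensity table in which a missing cell means "not detected in that
run". Two decisions define the differential-abundance stage:

* **Replicate-detection filter.** A protein detected in fewer than
  `min_detected` (default 2 of `R = 3`) replicates of a condition is
  treated as not detected in that condition at all; a protein left with
  no condition is dropped. We read "per sample" as "per condition":
  M1 CM and M2 CM are the two samples, each in biological triplicate,
  and this is the only reading under which "detected only in M1 CM" is
  well defined. The filter is idempotent and commutes with the
  secretome restriction (both are tested properties).
* **Fold change.** FC = mean(M2) / mean(M1) over *detected* replicates
  only — no zero-imputation, no moderated statistics, no abundance
  p-values. The procedure is deliberately detection-plus-ratio; anything
  more would be a different method. For one-sided detection we adopt the
  extended-value convention FC = ∞ (M2-only) and FC = 0 (M1-only), so
  condition-exclusive proteins fall into the matching specificity class
  downstream. The source analysis computes FC only where both means
  exist and never states a convention; ours is the unique one consistent
  with the class definitions.

### Secretome restriction

The detected proteins are intersected with a predicted conventional
secretome list (in the original study, the Human Protein Atlas predicted
secreted annotation). The biological rationale: the proinvasive activity
of M2 CM survives EV depletion, so EV-borne and unconventionally
released proteins are excluded from the hypothesis space. The package
treats the annotation as an opaque identifier set — any list in the same
format works.

### Identifier harmonization

Proteomics outputs, pair databases and expression tables disagree on
gene-symbol synonyms (TGFBI vs BIGH3 being the motivating case).
Every reader uppercases, trims and resolves identifiers through one
alias map before any join; the built-in map is deliberately tiny and
user-extensible. The map must be canonical-stable (targets map to
themselves), which makes harmonization idempotent; a property test
injects mixed-case aliased inputs and asserts identical pipeline output.
How the original study mapped protein identifiers to gene symbols is not
stated; the alias mechanism is this package's device.

### Receptor gating and polarization classes

A database pair (ligand, receptor) becomes an interaction record when
the ligand is a detected secreted CM protein (in either polarization
state) and the receptor's base-mean expression in the configured bulk
sample is ≥ `receptor_gate` (default 1, boundary inclusive — "1 or
greater"). Records are classified by ligand FC with both boundaries
inclusive: M2-specific at FC ≥ 2, M1-specific at FC ≤ 0.5, pan-macrophage
strictly between. The classes are mutually exclusive and exhaustive, and
classification is monotone in FC; both are tested properties, as is
antitonicity of the record count in the gate. Duplicate database rows
are dropped (counted and reported); a pair listed with swapped roles is
*not* auto-symmetrized, because direction (macrophage ligand → tumor
receptor) is the object of study.

### Single-cell prioritization

Cluster markers carry pct.1 (fraction of cells in the cluster detecting
the gene) and pct.2 (average fraction across all other clusters); the
enrichment score is pct.1 / pct.2 with 0/0 → 0 (a gene absent everywhere
is not enriched) and x/0 → ∞ for x > 0, sorted above all finite scores.
pct.2 is by default the *unweighted mean* of the other clusters'
fractions — per the phrase "on average in all the other clusters" — not
the pooled fraction over all other cells; both modes are offered.

"Predominantly expressed by TAMs" has no published quantitative rule
(the original evidence is a dot plot), so we operationalize it as: the
argmax-enrichment cluster of the ligand is annotated TAM, with
deterministic tie-breaks (higher pct.1, then lower cluster id). The
microglia-vs-BMD ontogeny call compares the ligand's maximum enrichment
over BMD clusters vs microglia clusters and requires a ratio of at least
`ontogeny_ratio` (default 1.5, our parameter, exposed in config) for a
one-sided call, else "mixed". These rules reproduce the expected calls
on synthetic reconstructions; they are not guaranteed to match the
original authors' visual judgement on their data.

Cluster annotation follows published marker sets (malignant: GAP43,
GPM6B, SEC61G, PTN; TAM: C1QA, C1QB, C1QC, TYROBP, CD68), assigning
each cluster the cell type with the highest mean marker enrichment;
explicit published cluster lists override scoring, since studies
typically state the assignment outright.

The BMD DEG ranking keeps genes upregulated in BMD TAMs at adjusted
p < 1e-3 and orders by *effect size* (log2 fold change), ties by
ascending p then gene name. "Top 3 DEGs" could equally mean p-ordered;
effect-size-first is our choice, recorded here, and deterministic.

## The synthetic-data generator

The generators produce every pipeline input with planted ground truth,
at defaults mirroring the study's scale: 1,093 proteins (207 planted
M1-exclusive, 63 M2-exclusive; the 823 two-condition proteins split
206 / 206 / 411 into M2-specific / M1-specific / pan — the study never
reports a protein-level class mix, so this is a fixed package choice),
3 replicates per condition, a 3,631-row pair database with 7% planted
cognate rows, 2,000 expression genes with 60% above the gate, and an
800-cell detection matrix over 8 clusters (TAM clusters "2","3","6","7",
of which "2","3" are BMD) carrying the ten candidate ligands
(BIGH3, S100A9, LYZ planted BMD-restricted at pct.1 ≈ 0.8 against a
0.05 background).

Model choices:

* **Intensities** are log-normal with a protein-level abundance spread
  (sd 1 on the natural-log scale) and replicate-level variation
  (sd 0.25, i.e. a realistic ~25% CV for label-free CM work). The
  replicate base value is *shared between conditions* and the planted
  M2/M1 effect multiplies the M2 column, modelling the condition effect
  as exact on top of run-level variation. Consequence: at zero dropout
  the empirical FC equals the planted effect exactly, which is what
  makes zero-noise scenarios exactly identifiable — the end-to-end
  oracle test demands equality, not approximation. With dropout > 0 the
  detected replicate subsets differ between conditions and the empirical
  FC becomes noisy, which is the regime the recovery criterion measures.
* **Dropout** is i.i.d. per replicate by default; an intensity-dependent
  option (logistic in log intensity, lower-abundance proteins dropping
  more often) is provided as the more realistic regime.
* **Planted effects** default to 4× / 0.25× / 1×, comfortably beyond the
  2 / 0.5 class bounds, emulating clearly polarization-specific ligands.
* **The pair database** mixes cognate rows (eligible ligand × gated
  receptor) with decoys built to fail at least one join side
  (non-secreted ligand, ungated receptor, or a ligand absent from the
  proteome). Every planted candidate TAM ligand is guaranteed at least
  one cognate row — as in the study, the candidate list *arises from*
  the pair list, so a generator that could omit them would starve the
  prioritization stage of its intended inputs.
* **The single-cell matrix** is detection-only (no expression
  magnitudes): cells are split near-evenly across clusters and each gene
  is Bernoulli-detected at its planted per-cluster probability. The
  marker table is computed from the matrix itself, and the
  BMD-vs-microglia DEG table is likewise *derived* from the matrix
  (pooled detection fractions, Fisher exact test, BH adjustment) rather
  than drawn parametrically, so the ranking stage is exercised on data
  consistent with the planted ontogeny design.

What the generator does **not** emulate: correlated protein abundances,
batch effects, intensity-dependent mean-variance structure, doublets or
ambient contamination in the single-cell data, or the real identity of
proteins beyond the ten named candidates. Passing tests therefore show
that the pipeline's logic is correct under its stated model, not that
the thresholds are optimal for any particular real dataset.

## The independent oracle

`expected_counts()` re-derives every downstream count (Venn
decomposition, pair count, class partition, unique members) by directly
enumerating the planted design — secreted flags, detection designs,
planted effects, gated set, database rows — with inline threshold logic
that shares no code with the pipeline. On zero-dropout scenarios the
pipeline, run through its on-disk interface, must agree with this
enumeration *exactly*; the test suite asserts this over 50 randomized
parameter draws. The pct.1/pct.2 statistics have their own oracle: a
per-cell counting loop over the detection matrix, asserted exact
(integer counts before division).

## Numerical and degenerate-input choices

* Extended values (∞, 0) flow through fold change, classification and
  enrichment without special-casing; JSON reports contain only counts
  and names, and TSV outputs serialize `Inf` literally, so round trips
  are lossless.
* A literal 0 intensity is non-detection by default (configurable),
  the common label-free encoding; the original encoding is unstated.
* Empty tables, empty candidate sets and an empty database all
  propagate to empty-but-typed outputs rather than errors.
* All orderings (interaction records, priorities, DEG ranks, tie-breaks)
  are deterministic, so identical config and inputs give byte-identical
  outputs; the analysis stages use no randomness at all, and the
  generators run under private seeded RNG streams that leave the
  caller's state untouched.
* Config validation collects every problem in one pass rather than
  failing at the first.

## Scale of the shipped checks

The test suite runs the property checks at desk scale: 100 randomized
proteomics tables for Venn conservation, 50 zero-dropout scenarios of
60–200 proteins for exact oracle equivalence, 20 generations of 500
proteins at 10% dropout for planted polarization-label recovery
(scored over proteins retained by the detection filter — a protein the
filter drops is a sensitivity outcome, not a misclassification), and
5 × 250-cell matrices for the pct oracle. The acceptance script runs the
full default paper-scale scenario; both finish in well under a minute on
one CPU.

## Known limitations

* The pipeline consumes published cluster/DEG tables; it does not
  cluster, reduce, or test single-cell data itself.
* No communication-probability modelling (CellChat-style), no pathway
  enrichment, no autocrine or reverse-direction interactions.
* The predominance and ontogeny rules are principled but necessarily
  sharper than the visual judgement they replace; borderline ligands can
  flip with `ontogeny_ratio`.
* Config files are YAML only.
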
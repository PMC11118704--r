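---
title: "Joint masked-language modeling of expression and phenotype tokens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint masked-language modeling of expression and phenotype tokens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`genophen` treats a single cell as a sentence. Each cell is encoded as a
fixed-length token sequence

\[ C = (p_1, \dots, p_F,\; g_1, \dots, g_T) \]

whose first \(F\) slots carry one categorical phenotype token per metadata
field (sex, age group, tissue, cell type) and whose remaining \(T\) slots
carry the binned expression value of the \(T\) most variable genes. Gene
slot \(i\) always holds the HVG-rank-\(i\) gene: genes have no natural
order, so identity is carried entirely by a learned position embedding
rather than by an expression-sorted ordering that would reshuffle under
measurement noise. A gene whose normalized expression falls below the
expressed/non-expressed threshold carries the PAD token in that slot.

A pre-norm transformer encoder (multi-head scaled-softmax attention, GELU
feed-forward blocks, residual connections, final layer norm) maps the token
matrix \(X_0 = W_e[\text{tokens}] + W_p\) through \(L\) blocks; the output
head is tied to the token embedding, \(S = X_L W_e^\top\), and every slot's
logits are restricted to the slot's *legal set* — bin tokens at gene slots,
the field's categories at a phenotype slot — so each position predicts a
distribution over the tokens it could actually hold.

Pretraining is masked-token recovery over both modalities at once:
phenotype slots are masked with probability 0.5, non-PAD gene slots with
probability 0.15 (phenotypes are few, so they are corrupted more
aggressively), and the model minimizes the mean cross-entropy between its
legal-set softmax and an ordinal *soft label* that puts \(1 - r\) on the
true bin and \(r/(B-1)\) on every other legal token (\(r = 0.1\)).
Recovering a masked phenotype token *is* phenotype annotation; recovering a
masked bin is genotype imputation. The attainable lower bound of the loss
is the soft-label entropy, which the test suite uses as an exact anchor for
an overfitting check.

Optimization follows the reference recipe: Adam, mini-batch 10, linear
warmup over the first 10% of steps then linear decay, fresh corruption
every epoch, gradient clipping at global norm 1. The configured defaults
(learning rate 2e-5, 13 epochs) describe the large-scale regime; the
desk-scale runs in the tests and the acceptance script use a higher rate
(1e-3) and 2–4 epochs, sized so that a full synthetic run fits in minutes
on one CPU. The encoder, its analytic gradients and Adam are implemented
directly in R on BLAS matrix products; a finite-difference gradient check
at 1e-4 relative tolerance guards the backward pass.

## Preprocessing

Raw counts are library-size scaled to 10,000 per cell, log1p transformed,
and each gene is divided by its dispersion (variance/mean across cells of
the log values) so magnitudes are comparable across genes. Two numerical
points deserve note:

* **HVG ranking.** Dividing a gene by its dispersion makes variance/mean
  equal to one for every gene *by construction*, so variability must be
  scored on the pre-scaling log values. The raw log1p dispersion is in turn
  dominated by lowly expressed, mostly-zero genes, so the score is the
  dispersion z-scored within quantile bins of mean expression — the
  standard normalized dispersion of scRNA-seq practice. Ties break
  lexicographically by gene id, making the ranking a deterministic
  permutation.
* **Binning.** The range above the threshold is cut into \(B\) equal-width
  bins (default \(B = 10\); the top bin is right-inclusive). The upper edge
  is the 99.9th percentile of above-threshold values rather than the
  absolute maximum — dispersion scaling produces a long right tail, and an
  outlier-set edge collapses nearly all values into the lowest bin; values
  beyond the edge clamp into the top bin and are counted. A global range is
  used rather than per-gene ranges because the tied output head requires
  bin tokens to mean the same thing at every slot.

The expressed/non-expressed threshold defaults to 0.1 in normalized units.
`detect_threshold()` can derive it from the data as the first interior
local minimum of the density of positive values, accepted only when the
valley is flanked on both sides by density at least 1.2 times deeper —
a guard against noise dips in unimodal distributions, which fall back to
the default.

## Padding: absent genes still inform

A below-threshold gene carries PAD in its slot and is excluded from
masking, loss, embedding extraction, and (by default) from attention keys.
Exclusion from attention does *not* hide the absence signal: the softmax
renormalizes over whichever keys are present, so the set of expressed genes
shapes every contextual state. We also evaluated the alternative of keeping
PAD visible as a dedicated "not expressed" embedding (`pad_attend = TRUE`);
in planted-signal ablations it consistently slowed learning — in sparse
cells more than half of all keys are PAD and they swamp attention — so
strict key masking remains the default.

## Embedding analytics

`extract_embeddings()` runs the trained encoder on clean (uncorrupted)
cells and keeps the final-layer state at every non-PAD slot — the
contextualized embedding of that gene or phenotype token in that cell —
plus a per-cell mean vector. Everything downstream is geometry on these
vectors:

* **Context embeddings** are means over all cells sharing a phenotype
  context (`aggregate_by_context()`, minimum support 20 flagged).
* **Phenotype–gene similarity**: cosine between a gene's context embedding
  and the phenotype slot's context embedding, per context value; the
  *universal* score of a gene is its mean over values (its minimum is also
  reported, for a conservative reading).
* **Differentially embedded genes**: one minus the mean pairwise cosine
  among a gene's context embeddings across a field's values — zero for a
  context-stable gene, up to two for antipodal contexts. This is the
  simplest symmetric dispersion on the similarity scale and is our choice;
  the statistic itself has no canonical definition.
* **Tissue similarity**: Pearson correlation between per-tissue mean cell
  vectors, clustered by average linkage on \(1 - r\).
* **Gene networks**: edges between genes whose context-embedding cosine
  exceeds a threshold, given absolutely or (default) as the 0.95 quantile
  of all pairwise similarities, which keeps edge density comparable across
  contexts. Degree distributions are fit with a discrete maximum-likelihood
  power law, the lower cutoff chosen by Kolmogorov–Smirnov minimization
  (Clauset-style); a log-log regression slope is also reported because
  "slope of the power law" is how such fits are often read. The MLE
  recovers a planted exponent 2.5 within ±0.15 at n = 10,000 in the test
  suite.
* **Network comparison** (e.g., young vs old endothelial cells): per-gene
  degree deltas on the shared node set plus both power-law fits; added
  cross-module coupling among otherwise weakly connected genes flattens the
  fitted exponent.

## Polyfunctionality

A gene is *polyfunctional* in a cell type when its per-cell contextualized
embeddings form at least two well-separated clusters. The procedure: the
gene's embeddings within the cell type are first residualized against the
cell's detected-gene count — the dominant technical covariate of per-cell
embeddings (with key-masked attention it sets the size of the attended
set), and without the correction every gene's embeddings split by cell
sparsity rather than biology. Louvain communities are then found on a
cosine 15-NN graph, clusters under 5% of cells are merged into the nearest
centroid, and the partition maximizing mean silhouette along a greedy
centroid-merging path is taken. Because community detection finds
"clusters" in any point cloud, the partition is refined: each cluster pair
is projected onto its centroid-difference axis, and pairs whose projected
union is not *decisively* better described by a two-component than a
one-component Gaussian mixture (BIC margin of 20, via mclust) are merged —
an artificial split through one mode projects to a single Gaussian, two
genuine modes to a bimodal mixture. The margin was calibrated so that kNN
communities found in single simulated Gaussian clouds (which reach BIC
margins of roughly 17) are always merged; we prefer this projected mixture
test to a covariance-matched Gaussian null because real bimodality inflates
the covariance along the mode axis, making such a null circular. A gene is
called polyfunctional when at least two clusters survive refinement and
the mean silhouette (cosine distance) reaches 0.1.

A measured limitation: the tied output head makes expression-bin
embeddings discrete directions, so a gene whose expression spans several
bins genuinely fragments into per-bin embedding islands. At desk scale
(hidden width 128, a few epochs) the planted two-mode gene's mode axis is
present — its projection is bimodal with a BIC margin of roughly 5–15 —
but that is below the decisive threshold that keeps single-mode controls
clean, so unsupervised recovery of exactly two modes is not reliable at
this scale; the detection machinery itself is validated on constructed
geometries in the test suite, and false positives (single-mode control
genes, diffuse clouds) are what the guards are tuned to exclude.

## The synthetic atlas

`generate_atlas()` emulates the structure of a multi-donor atlas so the
whole pipeline is testable without any download: categorical fields sex
(2), age group (3), tissue (3), cell type (4) drawn uniformly; one
20-gene program per tissue at natural-log loading 1.5 and one 10-gene
program per cell type at loading 1.0; negative-binomial counts (dispersion
0.5) on a per-gene lognormal baseline (meanlog log 0.8, sdlog 0.4), scaled
by a lognormal library factor (sdlog 0.3); 2,000 cells by 300 genes by
default, giving roughly half-zero matrices. Two genes are planted for the
analytics. The polyfunctional gene occupies one of two modes per cell —
a latent Bernoulli state independent of every phenotype field, because
polyfunctional modes are functional states *within* a phenotype context —
with a 2.5 log-unit expression shift between modes (disjoint bin ranges
after normalization) and two dedicated 10-gene partner modules, the mode's
module mildly active (loading 1.5) and coupled to the gene through a shared
latent (sd 0.5) in cells of that mode. The single-mode control gene gets a
private, context-independent latent (sd 1.2). These scales were iterated
during generator design so that the planted genes are themselves HVGs and
the two modes are genuinely well separated in token space; the design
history is nontrivial because the dispersion normalization compresses
exactly the genes it makes most variable. `generate_aged_variant()`
re-draws counts after adding a shared latent of scale `edge_noise` across
all program genes of old cells, inducing the cross-module correlations
whose network signature the comparison tools measure.

What the generator does *not* emulate: batch effects, doublets, ambient
RNA, realistic gene-gene correlation beyond the planted programs, realistic
cell-type proportions. Tests passing on this atlas demonstrate that the
machinery recovers planted structure through the full pipeline; they do not
certify performance on real atlases.

## Problem sizes and known limitations

The test suite and the acceptance script run, by design, at desk scale:
synthetic atlases of 300–2,000 cells, models of 2–4 layers and hidden
width 64–128, 2–4 training epochs. These sizes were chosen so a complete
run finishes in minutes on one CPU while every planted recovery remains
detectable. The headline numbers of large pretrained models (masked
phenotype F1 in the mid-80s on a 500,000-cell atlas) are out of reach of
any desk-scale rerun and are not targets of this package's tests.

Known limitations: the encoder is plain dense attention, O(S²) per cell,
fine for a few hundred gene slots and unsuitable for whole-transcriptome
sequences; checkpoints are JSON (text) and sized for desk models; input/output uses
the Matrix Market bundle (`write_mtx_bundle()` / `read_mtx_bundle()`) —
there is no reader for HDF5-based annotated-matrix files, whose users
should export an MTX bundle first; dropout uses plain inverted masks and
there is no mixed precision or multi-device support.
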
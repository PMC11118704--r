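# genophen

Joint masked-language modeling of single-cell gene expression and phenotype
metadata, in pure R.

## The problem

Single-cell RNA-seq measures thousands of gene expression values per cell,
but the phenotypes those expression states produce — the donor's sex and
age, the tissue of origin, the cell type — are usually carried along as
side-table metadata and analyzed separately. `genophen` treats both
modalities as one language: each cell becomes a token sequence

```
[ sex, age, tissue, cell_type,  g_1, g_2, ..., g_T ]
```

where the first slots hold categorical phenotype tokens and slot `F + i`
always holds the binned expression value of the rank-`i` highly variable
gene (genes have no natural order, so identity lives in a learned position
embedding; a gene below the expression threshold is PAD). A transformer
encoder with a tied input/output embedding is pretrained to reconstruct
randomly masked tokens of *both* kinds — phenotype slots masked at rate
0.5, expressed gene slots at 0.15 — under a soft-label cross-entropy that
puts `1 - r` on the true expression bin and `r/(B-1)` on the others
(`r = 0.1`), the ordinal analogue of label smoothing.

Filling a masked phenotype slot is phenotype annotation. The last-layer
states at each slot are contextualized embeddings, and the package ships
the analysis toolkit built on them: phenotype–gene cosine similarity and
"universal" gene rankings, differentially embedded genes (1 − mean pairwise
cosine of a gene's context embeddings), tissue Pearson-correlation
dendrograms, similarity-threshold gene networks with discrete
maximum-likelihood power-law fits of their degree distributions
(Clauset-style KS-selected cutoff), average-linkage gene dendrograms in
Newick, young-versus-old network comparison, and polyfunctionality
clustering of a gene's per-cell embeddings guarded by covariate
residualization and a projected two-component mixture test.

A seeded synthetic atlas generator (negative-binomial counts, log-normal
library sizes, planted tissue/cell-type gene programs, a planted
polyfunctional gene and a single-mode control) makes the entire pipeline
testable on one CPU in minutes, with known ground truth. The transformer,
its analytic gradients, and Adam with linear warmup are implemented
directly on R matrix operations — no Python or GPU anywhere.

## Worked example

```r
library(genophen)

# a 2,000-cell x 300-gene atlas with planted tissue programs
atl  <- generate_atlas(synthetic_config(seed = 42))
prep <- prepare_corpus(atl$matrix, T = 64, B = 8)
prep$cells
#> tokenized_cells: 2000 cells, 4 phenotype + 64 gene slots

sp  <- split_corpus(prep$cells, val_frac = 0.1, seed = 1)
cfg <- model_config(L = 4, h = 128, k = 4, B = 8, T = 64, F = 4,
                    vocab_size = prep$vocab$size)
fit <- pretrain(sp$train, cfg,
                train_config(learning_rate = 1e-3, epochs = 2, seed = 5),
                verbose = TRUE)
#> epoch 1/2  mean loss 1.1738
#> epoch 2/2  mean loss 1.0766

# phenotype annotation by mask filling
ann <- annotate_phenotype(fit$params, cfg, sp$val, "tissue")
mean(ann$category == sp$val$phenotypes$tissue)
#> [1] 0.7437186
```

The mean masked loss falls from 1.17 to 1.08 nats over this deliberately
short two-epoch demonstration, and filling the masked tissue slot already
recovers the held-out tissue label for 74% of cells (chance is 33%); the
longer schedule used by the acceptance script — six epochs over 128
retained genes and 16 bins — takes the same pipeline above 0.95. Embedding
analytics on the demo model:

```r
emb <- extract_embeddings(fit$params, cfg, subset_tokenized(sp$train, 1:600))
pg  <- phenotype_gene_similarity(emb, "tissue")
head(pg$universal$gene, 5)
#> [1] "G0031" "G0028" "G0022" "G0036" "G0025"   # all planted tissue markers

ts <- tissue_similarity_matrix(emb)
round(ts$correlation, 3)
#>       blood heart  lung
#> blood 1.000 0.997 0.970
#> heart 0.997 1.000 0.983
#> lung  0.970 0.983 1.000
```

The five genes most cosine-similar to the tissue phenotype embedding are
all planted tissue markers. Gene networks, power-law fits, dendrograms,
young/old network comparison and polyfunctionality clustering
(`build_gene_network()`, `fit_power_law()`, `gene_dendrogram()`,
`compare_networks()`, `polyfunctionality()`) operate on the same embedding
table; the methods vignette describes each procedure, its guards, and the
measured desk-scale limits of polyfunctional-mode recovery.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ig.R` (`Rscript ig.R synth|preprocess|train|eval|annotate ...`).

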
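# mcist

Multiscale cell-cell interactive spatial transcriptomics analysis:
spatial domain detection by persistent-Laplacian-regularized sparse PCA,
multi-view alignment, and consensus clustering.

## What it does

Spatial transcriptomics assigns expression profiles to spatially indexed
spots; the analysis goal here is to partition spots into *spatial domains*
(e.g. cortical layers). `mcist` models cell-cell interactions in gene
expression space at several scales at once:

1. **kNN-induced filtration.** Union-symmetrized k-nearest-neighbour graphs
   over spot expression profiles at decreasing scales k = 15, 12, 9, 6 form
   a nested filtration; each snapshot contributes its (order-0 persistent)
   graph Laplacian `L^k`, whose zero-eigenvalue multiplicity counts that
   scale's connected components.
2. **Accumulated regularizer.** Binary switches select scales:
   `L_P = sum_k zeta_k L^k`, one PSD regularizer per combination (15
   combinations for 4 scales).
3. **Topological PCA.** For each combination, an orthonormal spot embedding
   `Q` and loadings `U` minimize

   ```
   || X - U Q' ||_{2,1} + beta ||Q||_{2,1} + gamma Tr(Q' L_P Q),   Q'Q = I
   ```

   (beta = gamma = 1), solved by monotone alternating IRLS with exact
   closed-form steps.
4. **CCA alignment.** Each embedding is aligned with a spatially informed
   embedding (loaded from file, or the built-in baseline spatial encoder)
   through the cross-product eigenproblem `(Z'Qc)(Qc'Z) q = lambda q`,
   giving canonical score features per scale combination.
5. **Consensus domains.** Every aligned embedding is clustered (Leiden or
   Gaussian mixture); the co-association matrix across members feeds
   average-linkage agglomerative clustering, yielding the final domains.
   Alternatively the residue-similarity index (RSI) selects the single best
   scale combination without ground truth.

A ligand-receptor edge-enrichment z-score (symmetric edge product vs a
profile-permutation null) quantifies pair co-localization on any graph
view, and a seeded negative-binomial generator of layered-tissue data makes
the whole pipeline testable offline.

See `vignettes/mcist-methods.Rmd` for models, parameters and design
decisions.

## Worked example

```r
library(mcist)

# synthetic layered tissue: 20 x 75 lattice, 5 strip domains, 300 genes
ds <- generateSynth(synthConfig(seed = 0))
X  <- preprocessExpression(ds@expression)   # QC -> log-normalize -> HVG

res <- runMcist(X, ds@coords, nDomains = 5, seed = 0)
res
#> ConsensusResult: 1500 spots, 5 domains, 15 ensemble members

evaluateRecovery(res, ds@truth)
#>       nmi       ari
#> 0.9944463 0.9966633
```

The printed numbers are normalized mutual information and adjusted Rand
index between the recovered consensus domains and the planted strip layers:
at the reference signal strength (marker log2 fold change 1.5) the ensemble
recovers the layering almost perfectly; regenerating the data with
`markerLog2fc = 0` drops NMI below 0.2, confirming that recovery reflects
the planted signal rather than the pipeline's structure.

A shell interface wraps the same functions:

```sh
mcist synth --out data/ --seed 0
mcist run --expr data/expression --coords data/coords.tsv \
      --n-domains 5 --mode ensemble --method leiden --seed 0 --out out/
```

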
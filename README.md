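# chromapick

Epigenomic pattern discovery from genome-wide chromatin-modification
signal: pick a small representative subset of marks, catalogue the
recurrent combinatorial shapes they form at promoters, and scan the genome
for unannotated loci that carry an active-promoter shape.

`chromapick` is for computational epigenomics groups working with panels of
ChIP-seq tracks (histone modifications, histone variants, factors such as
CTCF) who want a quantitative answer to "which marks are redundant?" and a
pattern-matching route to novel promoter candidates, without training a
genome-wide chromatin-state HMM.

## Method in brief

1. **Affinity by sparse self-representation.** Bin each track (100 bp),
   extract ±5 kb strand-oriented profiles at every TSS, and flatten each
   mark into a vector `h_i`. Solve, per mark,

   ```
   min over a :  1/2 ||h_i − H a||² + λ ||a||₁ ,   a_i = 0
   ```

   The coefficients form an N×N affinity matrix A (zero diagonal). Marks
   that are near-linear combinations of shared latent profiles select each
   other. λ is chosen by solving on two datasets (e.g. two cell lines) and
   maximizing the Pearson correlation between the N(N−1)/2 symmetrized
   affinity pairs.
2. **Representative marks.** Hierarchically cluster marks on
   `W = (|A|+|Aᵀ|)/2` (average linkage on `1 − W/max W`), choose the
   cluster count by cross-dataset partition overlap (adjusted Rand index),
   and keep the within-cluster affinity medoid of each cluster.
3. **Combinatorial patterns.** K-means (k-means++/Lloyd, seeded,
   best-of-restarts) on the per-promoter concatenation of the N′
   representative profiles; silhouette and within-cluster-distance curves
   guide the choice of K; patterns are ranked CP1..CPK by median
   target-gene expression. Pattern similarity is the *modified PCC*: the
   mean of per-mark-block Pearson correlations.
4. **Novel promoter scan.** Slide a 10 kb window (2 kb step, both strands)
   along the binned genome; a window is a putative promoter when **every**
   per-mark correlation with an active centroid reaches the threshold
   (0.75). Hits are merged, ranked by mean PCC, and classified as
   annotation-overlapping, within-gene, or intergenic.

A synthetic-data module (`synthConfig()`, `simulateStack()`,
`simulateChromatin()`) generates fixtures with planted mark clusters,
promoter shape classes, expression ladders and hidden intergenic promoter
loci, so the whole pipeline is testable without downloads.

## Worked example

```r
library(chromapick)

## fully synthetic study: 12 marks in 4 planted clusters, 8 promoter
## classes x 250 loci, 10 hidden promoter loci on one chromosome
sim  <- simulateChromatin(synthConfig(), seed = 5)
tss  <- sim$tss

## affinity over marks and mark clustering
stack <- stackProfiles(lapply(sim$tracks, extractProfiles, tss = tss, flank = 5000))
A  <- solveSelfRepresentation(stack, lambda = 50)
cl <- selectRepresentatives(A, clusterMarks(A, K = 4))
representatives(cl)
#> [1] "mark03" "mark06" "mark09" "mark12"

## promoter patterns on the representative subset
X <- concatenateProfiles(stack, representatives(cl))
model <- fitPatterns(X, K = 8, seed = 5)
model <- rankByExpression(model, sim$expression, sim$truth$geneIds)

## genome scan for promoter-patterned loci
hits <- mergeHits(scanGenome(sim$tracks[representatives(cl)], model, scanConfig()))
evaluateRecovery(sim$truth, clustering = cl, model = model,
                 hits = hits, tss = tss)
#> $markClusterARI
#> [1] 1
#> $patternAgreement
#> [1] 1
#> $hiddenRecall
#> [1] 1
#> $hiddenPrecision
#> [1] 1
```

The recovery report reads: the mark partition matches the planted one
exactly (adjusted Rand index 1), every promoter locus lands in its planted
shape class after label matching, and all 10 hidden intergenic loci are
found with no false novel hits at threshold 0.75.

`runAll(runConfig(...))` drives the same workflow from file inputs
(bedGraph/bigWig tracks, BED6 TSS, chrom.sizes, optional gene bodies and
expression TSV) and writes every stage output plus a deterministic
`manifest.json`. A thin CLI over the same functions is included at
`inst/scripts/chromapick.R`.

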
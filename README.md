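# exoalign

Alignment and crosslink deconvolution of strand-separated ChIP-exo profiles.

## The problem

ChIP-exo and ChIP-nexus map protein–DNA crosslinking points at base-pair
resolution: lambda exonuclease digests immunoprecipitated DNA 5′→3′ and
stops, on average, ~6 bp before a crosslink, so each crosslinking event
leaves a pair of tag 5′-end peaks — one on each strand, ~12 bp apart,
flanking the event. When a multi-protein complex (e.g. the Pol III
machinery at tRNA genes, or Rap1/Fhl1/Ifh1/Sfp1/Hmo1 at ribosomal protein
gene promoters) binds hundreds of regions in a consistent spatial
arrangement, pooling the per-region profiles sharpens these signatures —
but only if the regions are first placed into a common coordinate system,
which is nontrivial when internal spacing varies between loci (tRNA genes
vary from 74 to 134 bp) and no sequence feature is available to anchor on.

`exoalign` addresses this with signal-level alignment: no motifs, no
sequence — just the tag profiles.

## Method

1. **Profiles.** For each of R regions, a 2K × L matrix of per-base tag 5′
   counts (K experiments × two strands), max-normalized per experiment
   within each region.
2. **Pairwise alignment.** Affine-gap overlap Needleman–Wunsch on profile
   columns. Column similarity is a Pearson-style correlation over the
   paired Watson/Crick products: with q̄ the mean of a column's 2K entries,

       s(x_i, y_j) = Σ_k (q_kw−q̄)(q_kc−q̄)(p_kw−p̄)(p_kc−p̄)
                     / ( √Σ_k (q_kw−q̄)²(q_kc−q̄)² · √Σ_k (p_kw−p̄)²(p_kc−p̄)² )

   and a gap run of length g costs γ(g) = −d − (g−1)e with e = 0.1d.
   Both orientations of each profile are scored.
3. **Progressive alignment.** Greedy agglomeration: repeatedly align and
   merge the most similar pair of (composite) profiles until one remains;
   gaps are carried in a per-column gap-count array; after the final merge
   a scaled control can be subtracted per base and strand (floored at 0).
4. **Deconvolution.** The composite is modeled as a mixture of crosslink
   events; each event emits tags from a ±strand Gaussian pair (σ = 6 bp,
   strands offset 12 bp). EM with a sparseness-promoting negative Dirichlet
   prior (`π̂_j = max(0, N_j − α)/Σ max(0, N_j' − α)`; α = minimum tags to
   support an event) prunes the 5-bp initialization grid down to the
   supported events; event positions are shared across experiments.
5. **Quantification & PCA.** ML assignment of each experiment's tags to the
   fixed events yields an experiments × events crosslinking-strength matrix
   (rows normalized to 1), compared across conditions as log2 fold
   differences and summarized by PCA of the rows.

## Worked example

```r
library(exoalign)

# simulate a variably spaced two-block complex: 3 experiments, 8 regions,
# region-specific spacers, +/-20 bp anchor jitter, known truth
truth <- synthetic_truth(n_regions = 8, tags_per_region = 4000,
                         jitter_halfwidth = 20)
sim <- generate_synthetic(truth, seed = 1)

cfg <- run_config(experiments = sim$libraries, regions = sim$regions,
                  window = sim$window, gap_open = 5, gap_ext = 0.5,
                  alpha = 150, seed = 1, out_dir = "example_out")
res <- run_pipeline(cfg)

res$components
#> CrosslinkComponents: 8 component(s) at [147, 162, 177, 283, 295, 297, 311, 315],
#>   3 experiment(s), converged after 369 iteration(s)
res$crosslinks
#> CrosslinkMatrix: 3 experiment(s) x 8 crosslink position(s)
#>        [,1]  [,2]  [,3]  [,4]  [,5]  [,6]  [,7]  [,8]
#> exptA 0.349 0.257 0.196 0.092 0.001 0.059 0.028 0.018
#> exptB 0.051 0.098 0.147 0.183 0.000 0.240 0.158 0.123
#> exptC 0.041 0.061 0.099 0.183 0.000 0.239 0.200 0.178
round(res$pca$explained_variance_ratio, 3)
#> [1] 0.982 0.018
```

The planted truth puts the six crosslink sites at alignment columns 147,
162, 177 (upstream block) and 284, 299, 314 (downstream block, spacers
absorbed as gaps). The upstream block is recovered at exactly the planted
columns with exptA's planted 0.35/0.25/0.20 preferences; the
closer-spaced, weaker downstream sites come back within a few bp with
some splitting (283/295+297/311+315). Each experiment's strength row
reproduces its planted bias (exptA upstream, exptC downstream), and PC1 —
98% of variance — separates the upstream- from the downstream-binding
proteins. Artifacts (alignment TSV, gap counts, composite, merge tree,
crosslink matrix, PCA tables, run log) are written to `example_out/`.

A command-line launcher with the same flags as `run_config()` is installed
at `system.file("exec", "exoalign.R", package = "exoalign")`; inputs are
BAM/SAM/TSV tag files plus BED or `chrom:pos:strand` region lists.

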
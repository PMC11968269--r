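# cohesinproc

Genomic-distance-biased analysis of cohesin processivity at clustered gene
loci.

## What this package is for

At the clustered protocadherin (cPcdh) locus, three tandem gene clusters
(alpha, beta, gamma — 58 isoform genes in mouse) share downstream
super-enhancers and are activated through CTCF/cohesin-mediated chromatin
loops. Cohesin *processivity* — the mean linear length of DNA a cohesin
complex extrudes before release, written here as lambda (bp) — sets how far
enhancer contact reaches. When processivity drops, distal promoters lose
enhancer contact and expression first, producing a characteristic
*distance-biased* downregulation that hits the enhancer-distal beta cluster
hardest.

`cohesinproc` is for computational biologists who want to exercise and
validate that style of analysis against a known ground truth. It provides:

- **`synthetic locus generator`** — a cPcdh-like locus plus background
  genome, with WT/mutant multi-modal data (negative-binomial RNA counts,
  ChIP peak counts, per-cluster 4C tracks, Poisson contact matrices) driven
  by the contact model
  `c(d) = A exp(-d/lambda) + background power law`. The planted
  `lambda_wt = 400 kb`, `lambda_mut = 150 kb` are the recoverable truth.
- **`quantify`** — FPKM / peak enrichment / RPM, per-gene fold changes with
  t-tests and Benjamini-Hochberg adjustment, DEG calling
  (|log2FC| > 0.5, padj < 0.05, strict), and virtual-4C per-gene contact
  values.
- **`enrichment scan`** — the Manhattan statistic: 1-Mb genome bins, hit
  counts of downregulated-gene anchors, maximum-likelihood Poisson rate
  `lambda = total hits / bins`, and per-bin upper-tail probabilities
  `P(X >= k)` computed in log space (stable far below 1e-300), with fold
  enrichment `k / lambda`.
- **`distance bias`** — pairs each gene's log2 fold change with its
  promoter-to-enhancer distance (5'-UTR anchor to assigned element-set
  midpoint; alpha→HS5-1, beta→HS18-22, gamma→HS5-1bL), fits
  `log2FC ~ distance` by OLS, and inverts the slope into a processivity
  change: `Delta(1/lambda) = -slope * ln2 / eta`,
  `lambda_mut = 1 / (1/lambda_wt + Delta(1/lambda))`.
- **`hic topology`** — cis-depth normalization (to 1e8 by default),
  Knight-Ruiz matrix balancing, directionality index
  `DI = sign(B-A) * ((A-E)^2/E + (B-E)^2/E)`, Gaussian-HMM state decoding,
  TAD calling with the standard filters (regions of >= 3 bins and median
  posterior >= 0.99), and differential contact maps.
- **`run_pipeline()`** — one seeded, deterministic run of all stages with
  plain-text outputs (BED/TSV/MatrixMarket/bedGraph/JSON) and a
  machine-readable report. A thin CLI lives at
  `inst/scripts/cohesinproc-cli.R`.

## Worked example

```r
library(cohesinproc)

ann <- build_locus_annotation()
ann
#> Synthetic clustered locus on chrS (100000000 bp)
#>   genes: alpha=14, beta=22, gamma=22, background=2000
#>   enhancers: HS7, HS5-1, HS7L, HS5-1bL, HS18-20, HS21, HS22
#>   locus span: 60000000-61062000 bp

params <- processivity_params(lambda_wt = 400000, lambda_mut = 150000)
expr <- simulate_expression(ann, params, seed = 1)
fpkm <- compute_fpkm(expr)
wt <- expr$samples$condition == "wt"
fc <- fold_change(fpkm[, wt], fpkm[, !wt], modality = "RNA")

fit <- fit_distance_trend(make_pairs(fc, ann))
fit
#> Distance trend of log2 fold change (RNA)
#>   slope: -5.333e-06 per bp (95% CI -5.658e-06 .. -5.009e-06), n = 58

recover_processivity_delta(fit, lambda_wt = 400000)
#> Processivity change implied by distance trend
#>   Delta(1/lambda): 3.697e-06 per bp (reduced processivity)
#>   implied lambda_mut: 161373 bp (given lambda_wt = 400000 bp)
```

The negative slope is the distance-biased signature: each additional 100 kb
of promoter-enhancer distance costs ~0.53 log2 units of expression in the
mutant. Inverting it recovers a mutant processivity of ~161 kb against the
planted 150 kb — slightly high because the default generator includes the
distance power-law contact background, which flattens the trend at large
distances (disable it with `processivity_params(background_scale = 0)` for
the exact closed-form regime).

A full seeded run of all five stages:

```r
report <- run_pipeline(pipeline_config(seed = 1), outdir = "out")
report
#> Pipeline run (seed 1, config 38c3510d)
#>   clustered genes: 58
#>   DEGs: 151 (96 down / 55 up)
#>   top Manhattan bin: chrS:60000000-61000000  k=46 fold=47.9 -log10p=59.0
#>   RNA: slope=-5.23e-06/bp, recovered lambda_mut=163277 bp
#>   ChIP: slope=-5.29e-06/bp, recovered lambda_mut=162160 bp
#>   contact: slope=-5.34e-06/bp, recovered lambda_mut=161338 bp
#>   TADs called: 1
```

The top Manhattan bin is the locus bin (46 downregulated anchors against a
genome-wide rate below one per Mb), all three data modalities independently
recover a consistent reduced processivity, and the topology stage calls the
locus-spanning contact domain.

See the methods vignette (`vignettes/cohesin-processivity.Rmd`) for the
model, parameter meanings, and the reasoning behind every numerical choice.

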
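# crcscape

Subtyping cell populations by their enhancer landscapes and core
regulatory circuitry.

Cell identity is maintained by a small set of master transcription factors
(mTFs) that sit on super-enhancers (SEs), bind their own SEs, and bind one
another's — a fully interconnected auto-regulatory loop called the core
regulatory circuitry (CRC). Populations that look homogeneous by marker
staining (for example cancer-associated fibroblasts) can split into
functionally distinct subgroups whose CRCs differ. `crcscape` implements
that subtyping computation for H3K27ac ChIP-seq–style inputs:

* **SE calling** by rank ordering: peaks are stitched (gaps ≤ 12.5 kb),
  scored against a bedGraph signal track (optionally control-corrected),
  and split into SE/TE at the tangent ("hockey-stick") cutoff — the first
  point of the axis-scaled rank–signal curve whose slope exceeds 1.
* **SE-to-gene assignment** for genes with a TSS within 1 kb of an SE, and
  auxiliary statistics: SE-vs-TE binding rates and densities for a TF's
  peak set, and broad-domain ranking for H3K4me3.
* **Motif scanning** of SEs extended ±500 bp with PWM log-odds scores and
  exact p-value thresholds (default 1e-4) from a discretized convolution
  of the null score distribution.
* **CRC construction**: SE-assigned TFs → auto-regulated TFs (self-motif
  in own SE window) → directed motif-evidence graph → maximal fully
  interconnected cliques (mutual edges, size ≥ 2) → expression-filtered
  mTF candidates and CRC target genes (SEs hit by ≥ 3 distinct CRC TFs).
* **Network comparison** with the three-term structural dissimilarity

  D(G,G′) = w₁ √(J(μ_G, μ_G′)/log 2) + w₂ |√NND(G) − √NND(G′)|
  + w₃ (√(J(P_αG, P_αG′)/log 2) + √(J(P_αGᶜ, P_αG′ᶜ)/log 2)),

  with J the Jensen–Shannon divergence, μ_G the network distance
  distribution, NND the network node dispersion, P_α the α-centrality
  distribution, Gᶜ the complement graph, and default weights
  w₁ = w₂ = 0.45, w₃ = 0.1. Similarity is S = 1 − D. Samples are
  clustered on D (average linkage, k = 2 by default).

A deterministic synthetic-cohort generator with planted SEs, planted
cliques and machine-readable ground truth supports end-to-end validation.

## Worked example

Generate a synthetic cohort (two groups × three samples, planted cliques
`{TF01,TF02,TF03}` and `{TF04..TF07}`), run the full analysis, and inspect
the results:

```r
library(crcscape)

spec     <- synthetic_spec(seed = 1)
cohort   <- generate_cohort(spec)
analysis <- analyze_cohort(cohort)

head(tibble::as_tibble(analysis$samples$A_s1$calls), 4)
#>   region_id   contig  start    end  signal  rank class
#> 1 region_0006 chr1    98756 103218 587365.     1 SE
#> 2 region_0004 chr1    60711  64762 585764.     2 SE
#> 3 region_0014 chr2    21018  25217 576622.     3 SE
#> 4 region_0012 chr1   253144 259046  48093.     4 TE

analysis$samples$A_s1$crc
#> <crc_result> 1 maximal clique(s), 3 CRC TF(s)
#>   {TF01, TF02, TF03}

analysis$dissimilarity
#> <crc_dissimilarity> 6 samples
#>        A_s1   A_s2   A_s3   B_s1   B_s2   B_s3
#> A_s1 0.0000 0.0000 0.0000 0.0743 0.0743 0.0743
#> ...

analysis$clustering
#> <sample_clustering> k = 2
#>   sample group
#> 1 A_s1       1
#> 2 A_s2       1
#> 3 A_s3       1
#> 4 B_s1       2
#> ...
```

The three planted SEs of sample `A_s1` rank far above the background
regions (signal ≈ 5.9e5 versus ≈ 5e4), the recovered clique is exactly the
planted one, within-group CRC dissimilarity is 0 (identical 3-cliques),
between-group D is 0.074 (a 3-clique versus a 4-clique differs in
α-centrality structure but not in distance distribution), and clustering
at k = 2 reproduces the planted groups.

`tidy()` / `glance()` methods return tibbles for every result type, and
`autoplot()` draws the rank–signal hockey stick, the D heatmap, and the
clustering dendrogram. A file-based front end is available through
`run_pipeline()` + `crc_config()`, or from a shell via
`inst/cli/crcscape.R` (subcommands `simulate`, `call-se`, `scan`,
`build-crc`, `compare`, `run`, `init-config`).

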
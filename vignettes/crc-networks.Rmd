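---
title: "Super-enhancer landscapes and CRC network comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer landscapes and CRC network comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscape)
```

# The model

`crcscape` implements an epigenomic subtyping workflow for cell populations
profiled with an activating enhancer mark (typically H3K27ac ChIP-seq). The
pipeline has four stages, each exposed as tibble-in / tibble-out functions:

1. **Super-enhancer (SE) calling.** Called peaks are stitched into candidate
   regions (gaps up to a stitch distance merge), each region is scored by
   summing `signal × covered bp` from a bedGraph track (minus an optional
   control, floored at zero), and regions are rank-ordered. On the curve of
   scaled rank versus scaled signal, the cutoff is the first point (scanning
   from low rank) whose forward finite-difference slope exceeds 1 — the
   tangent or "hockey-stick" rule. Regions with signal strictly above the
   cutoff are SEs; the rest are typical enhancers (TEs).
2. **Motif scanning.** Each SE is extended 500 bp on both sides and scanned
   with position weight matrices under a log-odds model (natural-log units,
   pseudocount `c = 0.001` applied as `p' = (p + c)/(1 + 4c)`). Hit
   thresholds come from the exact null distribution of the score under the
   background model, computed by position-wise convolution over scores
   discretized at `1e-3` nats; the threshold is the smallest discrete score
   with tail probability at most the p-value threshold (default `1e-4`).
   Window scores are discretized identically, so the hit set is exactly
   consistent with the null model. `N` bases score 0 (background).
3. **Core regulatory circuitry (CRC).** A TF is SE-assigned when an SE
   window (region ± 1 kb) contains its TSS; the highest-signal such SE is
   its primary SE (ties break by coordinate). A TF is auto-regulated when
   its own motif hits its primary SE window. Among auto-regulated TFs, a
   directed edge `i → j` records at least one hit of motif `i` in the SE
   window of `j`. Fully interconnected loops are the maximal cliques (size
   ≥ 2) of the mutual-edge undirected projection; the mutuality requirement
   operationalises "fully interconnected": every pair must regulate each
   other. CRC TFs are the clique union, optionally filtered to those with
   expression ≥ 10 (TPM-like) in the sample. Target genes are genes linked
   to an SE whose window carries hits of ≥ 3 distinct CRC TFs.
4. **Network comparison.** Per-sample CRC graphs (undirected mutual-edge
   subgraph induced on the CRC TFs) are compared with a three-term
   structural dissimilarity

   $$D(G, G') = w_1 \sqrt{\frac{J(\mu_G, \mu_{G'})}{\log 2}}
     + w_2 \left| \sqrt{NND(G)} - \sqrt{NND(G')} \right|
     + w_3 \left( \sqrt{\frac{J(P_{\alpha G}, P_{\alpha G'})}{\log 2}}
     + \sqrt{\frac{J(P_{\alpha G^c}, P_{\alpha G'^c})}{\log 2}} \right)$$

   with $J$ the Jensen–Shannon divergence, $\mu_G$ the mean shortest-path
   distance distribution, $NND$ the network node dispersion (generalized
   JSD of per-node distance distributions over $\log(\text{diam}+1)$),
   $P_{\alpha G}$ the α-centrality distribution and $G^c$ the graph
   complement. Weights default to $w_1 = w_2 = 0.45$, $w_3 = 0.1$. The
   similarity is $S = 1 - D$. Samples are clustered on the pairwise $D$
   matrix with average-linkage agglomerative clustering cut at $k = 2$.

The measure compares structure only — node identity is ignored. Two CRCs
that are isomorphic graphs have $D = 0$ even with disjoint TF sets.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `stitch_distance` | 12,500 | bp | peak gap bridged when stitching |
| `gene_window` | 1,000 | bp | SE-to-TSS assignment window (half-open right) |
| `extension` | 500 | bp | SE extension for motif scanning |
| `p_threshold` | 1e-4 | — | exact motif p-value cutoff |
| `min_hits` | 1 | hits | occurrences supporting a regulatory edge |
| `expression_threshold` | 10 | TPM-like | "high expression" filter for master TF candidates |
| `min_distinct_tfs` | 3 | TFs | distinct CRC TFs needed to call a target gene |
| `w1, w2, w3` | 0.45, 0.45, 0.1 | — | D-measure weights |
| `k` | 2 | groups | clustering cut |
| `broad_fraction` | 0.05 | — | widest-peak fraction flagged as broad domains |

The expression threshold and `broad_fraction` are conventions: "high
expression" and "broad domain" have no universally agreed cutoffs, so both
are plain configuration flags. The target-gene rule counts **distinct** TFs
by default; `count_total = TRUE` switches to total occurrences for users who
prefer the multiplicity reading.

# Numerical choices

* **Coordinates** are 0-based half-open throughout, matching BED/bedGraph.
  Gene-assignment distance is `max(0, start − tss, tss − (end − 1))`, so a
  TSS exactly `window` bp past the region end is excluded (half-open
  window).
* **Cutoff conventions.** SE classification uses strict inequality above
  the cutoff; the slope scan takes the first crossing (deterministic under
  ties). Degenerate inputs — a single region, or all-equal signals — yield
  zero SEs: a cutoff defined on one point cannot be exceeded by it.
* **Score discretization.** Thresholds, p-values and window scores share
  one per-position integer-bin representation (step `1e-3` nats), making
  the scan provably consistent with the exact convolution; the continuous
  score is still reported per hit. Identical per-position score/background
  multisets share one cached convolution.
* **Round-off floor on divergences.** Jensen–Shannon divergences below
  `1e-13` nats collapse to an exact zero before the square root: without
  the floor, `sqrt()` amplifies `1e-16`-scale entropy round-off into
  `1e-8`-scale dissimilarity terms between graphs that are in fact
  structurally identical.
* **α-centrality.** The system `c = αAc + e` is solved with `e = 1` and
  `α = 1/(1 + λ_max(A))`, which converges for every graph; the solution is
  normalized to a probability vector and sorted descending before JSD, and
  shorter vectors are zero-padded. The damping convention is isolated so
  alternates can be swapped.
* **Disconnected and degenerate graphs.** Unreachable pairs accumulate in
  one extra distance bin; the NND denominator counts finite bins plus that
  bin. A one-node graph contributes an empty, zero-padded distance profile;
  comparing a zero-node CRC yields the maximum of the three raw terms, with
  a warning — empty CRCs are reported, never crashed on.
* **The α-centrality bracket is not halved.** As composed here, the third
  term is `w3 × (sqrt(J/log 2) + sqrt(J_c/log 2))`, so the formal supremum
  of `D` under the default weights is 1.1 rather than 1. The originally
  published form of this measure divides the bracket by 2; we keep the
  composition as stated in the weighting we adopt, and verify empirically
  (see the acceptance checks) that `D` stays in `[0, 1)` across random
  graph pairs — in practice comparable CRC graphs sit far below 1.
* **Determinism.** All orderings (region ids, ranks, clique order, cluster
  labels) have fixed tie-breaks; re-running any stage on identical inputs
  reproduces identical outputs byte for byte.

# What the synthetic cohorts emulate

`synthetic_spec()` defines a desk-scale cohort: 2 contigs × 300 kb, 60
genes of which 12 are TFs, 8-bp motifs with 0.85 consensus-dominated rows,
80 background peaks per sample at truncated-normal signal (mean 10, sd 2
per bp), and planted super regions at 20× signal. Two groups (3 samples
each) carry planted cliques of different sizes — `{TF01..TF03}` and
`{TF04..TF07}` — because the D-measure ignores node identity: same-size
cliques would be isomorphic and indistinguishable. Every clique TF's SE
region contains planted consensus occurrences of all clique members
(including itself), so the full auto-regulatory loop is recoverable by
construction. Expression of clique TFs is 50 in their own group and 1
elsewhere; other genes draw a baseline in [15, 25].

Two generator choices deserve comment:

* **Background peaks are laid out as clusters of four with inter-cluster
  gaps larger than the stitch distance.** With 80 peaks on 600 kb, uniform
  placement would put the mean gap (7.5 kb) below the 12.5 kb stitch
  default, chaining most of the genome into a few mega-regions and
  destroying the very rank-ordering geometry the method assumes; real
  enhancer landscapes are sparse at ROSE's operating point. Clustered
  placement keeps background regions comparable in signal (≈ 4 peaks each)
  and the planted jump unambiguous.
* **One shared genome carries the union of all groups' planted motifs, in
  group-disjoint regions.** Group identity is then expressed through which
  regions are SEs in a sample — the same logic by which real CRCs differ
  because SE landscapes differ — and scanning stays sample-agnostic.

What the generator does **not** emulate: read-level noise, chromatin-domain
structure, nucleosome-free-region substructure, correlated peak widths, or
motif co-occurrence biases. Passing the planted-recovery checks therefore
demonstrates algorithmic correctness under the stated statistical
structure, not performance on real ChIP-seq, where peak calling quality,
control normalization and motif database redundancy dominate.

# Problem sizes in the checks

The acceptance checks run the D-measure identities on 200 random graphs,
the bound check on 100 seeded Erdős–Rényi pairs (n = 20, p = 0.3), the
Eq-style oracle on all 4-node graphs up to isomorphism plus random 5–6-node
pairs, clique enumeration against 2^n subset enumeration up to n = 12,
motif scanning against exhaustive per-window scoring on 100 random
instances plus a 10^5-draw Monte-Carlo calibration of the exact p-value,
stitching against an interval-merge oracle on 20 × 1,000 random intervals,
and full planted-structure recovery across 100 cohort seeds. These sizes
were chosen to exercise every code path at desk scale.

# Known limitations

* The D-measure is structure-only; two samples whose CRCs share no TF but
  are isomorphic compare as identical. Node-identity-aware comparison is
  out of scope.
* SE calling consumes called peaks; peak calling itself (and its control
  handling) is upstream of this package.
* The motif model is mononucleotide with a single background; dinucleotide
  backgrounds and de-novo motif discovery are not provided.
* Scanning covers the full extended SE window; restriction to
  nucleosome-free subregions would require per-sample accessibility data
  that the pipeline does not consume.
* With very small region counts (< ~10) the tangent cutoff is noisy; the
  degenerate rules keep it deterministic but SE calls on such inputs should
  be treated as exploratory.
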
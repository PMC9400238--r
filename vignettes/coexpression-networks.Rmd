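---
title: "Integrated co-expression network construction with mutual ranks and topological overlap"
author: "cenweaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated co-expression network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenweaver)
```

## The problem

Bulk RNA-seq co-expression networks connect genes whose expression profiles
covary across tissues, developmental stages or conditions; shared expression
is then used as evidence of shared function, most prominently for
transcription-factor families (NAC, MYB) regulating secondary cell wall and
lignin biosynthesis, with the conserved photosynthetic light-harvesting
complex (LHC) families serving as a positive control. A single edge rule is
fragile: hard Pearson-correlation (PCC) cutoffs admit many spurious edges in
dense correlation regimes, mutual ranks (MR) favour locally reciprocal
partners but can miss moderately correlated hubs, and soft-threshold
topological overlap (TOM) rewards shared neighbourhoods but depends on a
scale-free assumption. `cenweaver` implements all three strategies behind
one edge-table contract, evaluates each edge set against a labelled gold
standard by ROC/AUC, and integrates them with per-edge method provenance.

## The model and its pieces

**Expression substrate.** A `TpmExperiment` wraps a genes × samples TPM
matrix (a `SummarizedExperiment` with one `tpm` assay). Validity enforces
unique gene/sample identifiers and finite, non-negative values; correlation
steps additionally require at least 3 samples.

**3σ low-expression filter.** Lowly expressed genes produce unstable
correlation estimates. The threshold is

$$t = \mathrm{mean}(L) + 3\,\mathrm{sd}(L),$$

where $L$ is the lowest 5% (by default) of all *strictly positive* TPM
values pooled across the matrix. Zeros are excluded because sparse matrices
would otherwise collapse the tail to zero; pooling across the matrix yields
one threshold per dataset, matching how a single per-species threshold is
normally reported. A gene is removed only when its TPM is below $t$ in
*every* sample — removing genes below the threshold in *any* sample would
discard exactly the tissue-specific genes co-expression analysis is after.
An optional per-group variant is available by merging replicate groups
first (`mergeSampleGroups()`). The filter is idempotent and monotone in the
threshold, and both properties are asserted in the test suite.

**Outlier screening.** Samples are clustered with Ward linkage on Euclidean
distances in its squared form (`ward.D2`), the convention under which the
merge heights are interpretable as within-cluster variance increments. A
sample is *flagged* (never dropped) when the height at which it first joins
the tree strictly exceeds the 0.99 quantile (linear interpolation) of all
merge heights. With identical samples all heights are zero and nothing is
flagged; in a perfectly symmetric three-sample configuration `ward.D2`
yields equal merge heights, so symmetry never produces a false flag.

**Correlations, ranks and mutual ranks.** PCC is the standard
product-moment correlation across samples. Zero-variance genes have no
defined correlation; they are flagged (`undefined` slot) rather than left
as silently propagating `NaN`s. Directional ranks sort each gene's partners
by *signed* PCC descending — the convention of the mutual-rank
co-expression databases this pipeline follows — with ties broken by gene id
in byte order for cross-platform determinism (an `rank_on = "abs"` switch
exists because integrated networks retain negative edges). The mutual rank
is the geometric mean

$$\mathrm{MR}(A,B) = \sqrt{\mathrm{Rank}(A \to B)\cdot\mathrm{Rank}(B \to A)},$$

symmetric by construction and invariant under any monotone transform of
each gene's correlation profile. Edges are retained by two rules, both
strict: bidirectional $\mathrm{MR} < 30$ and unidirectional
$\min(\mathrm{Rank}) < 3$. The default combines them as a union
(`combine = "any"`), since the two rules describe two retention routes; an
AND combination is available.

**Hard correlation cuts.** The positive cut is the $1 - 0.05$ quantile of
all defined off-diagonal correlations, the negative cut the $0.05$
quantile; both use the type-7 (linear interpolation) quantile convention,
pinned for reproducibility. An additive offset tightens the cuts, by
default symmetrically on both sides (a flag restricts it to the positive
side). Intervals at the cuts are closed — a correlation exactly at the cut
is kept — while the MR cuts are strict.

**Soft threshold and TOM.** For candidate powers $\beta = 1..20$ the
unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ is formed, connectivities
$k_i = \sum_{j\neq i} a_{ij}$ binned into 10 equal-width bins, and
$\log_{10} p(k)$ regressed on $\log_{10} \bar k$ over non-empty bins. The
fit statistic is a *signed* $R^2$ (negated when the slope is positive,
since scale-free behaviour requires a decreasing law); the selected power
is the smallest $\beta$ with signed $R^2 \ge 0.90$. When no power reaches
the target — the normal outcome on strongly modular data, whose degree
distributions are not scale-free — the pipeline falls back to the
conventional sample-count default for unsigned networks
(`defaultSoftPower()`: 9 below 20 samples, then 8, 7, and 6 from 40
samples). The unsigned topological overlap is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
                           {\min(k_i, k_j) + 1 - a_{ij}},$$

whose denominator is at least 1 for unsigned adjacencies, so isolated genes
are handled without special cases (TOM 0). Candidate pairs are those with
$\mathrm{TOM} > 0.1$, strict. Dynamic tree cutting into modules is
deliberately not implemented: only TOM candidate edges feed the
integration, though the customary module-detection parameters are accepted
and recorded in the run manifest for provenance.

**Evaluation.** A gold standard labels gene pairs positive (sharing an
annotation term, or planted in the same synthetic module) or negative
(seeded uniform sample of term-disjoint or cross-module pairs). Edge sets
are scored — $|r|$, $1/\mathrm{MR}$, TOM, or for integrated networks the
per-edge maximum of min–max-normalised method scores — and pairs absent
from an edge set score 0 ("not called co-expressed"). The AUC is computed
from the rank statistic with half-credit ties, so it equals the normalised
Mann–Whitney U; the test suite checks this identity against a brute-force
comparison oracle on hundreds of random configurations. The offset
optimizer sweeps $\delta = 0, 0.1, \ldots$ over the quantile cuts, records
(offset, cuts, edge count, AUC) per step, and returns the argmax with ties
resolved toward the smallest offset; offsets that empty the edge set are
recorded with `NA` AUC and skipped.

**Integration.** Union keeps one row per pair with the union of method
provenances and coalesced score columns (a genuinely conflicting shared
column is preserved method-qualified, e.g. `pcc_tom`, with a warning);
intersection keeps pairs present in both inputs. Union is the default
because the method's point is coverage gain — the hard-threshold and TOM
strategies recover complementary edge populations — while intersection is
exposed for strict networks. Downstream summaries report gene coverage
against a stated universe, mean connectivity $2E/V$, the percentage of
negative edges, family subnetworks with *both* per-gene conventions
(`pairsPerGene` $= E/V$ and `meanDegree` $= 2E/V$, because both appear in
the literature), top-$k$ correlation neighbourhoods, homolog-map overlap of
neighbourhoods across species, hypergeometric term enrichment with
Benjamini–Hochberg adjustment, and degree-based hub ranking.

## The synthetic generator

`simulateExpression()` provides ground truth without any download. Each
module $m$ has a latent profile $z_m$: a standardised Gaussian random walk
across samples, mimicking the smooth tissue/developmental gradients of
multi-tissue designs rather than i.i.d. noise. The walk is squashed to
$w_m = 0.9\tanh(\lambda z_m)$ and a module gene $g$ with baseline
$b_g \sim U(1, 4)$ (log-TPM) and loading sign $s_g \in \{+1, -1\}$ gets

$$\mathrm{TPM}_{gs} = e^{b_g + \varepsilon_{gs}}\,(1 + s_g w_{ms}),
\qquad \varepsilon_{gs} \sim N(0, \sigma^2).$$

Keeping the signal linear on the TPM scale (rather than additive in
log-TPM) means that with $\sigma = 0$ two same-sign module genes correlate
exactly $+1$ and opposite signs exactly $-1$ on the scale the pipeline
consumes — the property the generator's unit tests pin. Background genes
carry baseline and noise only. Planted low-expression genes are
zero-inflated uniform draws (60% dropout, ceiling 0.3 TPM): the dropout
matters, because the pooled 3σ threshold is estimated from the positive
low tail and must come out *above* each low gene's maximum for the
all-samples removal rule to fire; a dense uniform low tail would place the
threshold inside the low genes' range.

The reference scenario — 200 genes, 40 samples, four modules of 30, a fifth
of module genes anti-correlated, $\lambda = 1$, $\sigma = 0.25$, 20
low-expression genes, 60 background genes — was fixed once as a realistic
mid-size design: strong but noisy modules (within-module $|r|$ around 0.9,
cross-module around 0.2) and a clean low-expression tail. What the
generator does *not* emulate: count-level sampling noise (negative
binomial), batch effects, correlated background structure, and the heavy
right tail of real TPM distributions. Passing the recovery tests therefore
demonstrates the pipeline's correctness and its behaviour under its own
assumptions, not performance on real tissue panels.

## Numerical choices and degenerate inputs

- Quantiles everywhere use type 7 (linear interpolation); documented since
  the choice moves thresholds at small $n$.
- Rank ties break by gene id in byte (`radix`) order, never locale order.
- `sd` of a singleton low tail is taken as 0, so the threshold degrades to
  the tail mean.
- Zero-variance genes: undefined correlations, excluded from rankings,
  adjacency 0 with a warning.
- TOM of fully isolated genes is 0; the perfect-overlap limit
  ($a_{ij} = 1$, neighbourhood containment) yields exactly 1 and is clamped
  against floating-point overshoot.
- All-pairs matrices are held dense. Mutual ranks need complete correlation
  rows, and at the package's intended scale (up to roughly $10^4$ genes
  after filtering) a dense double matrix is unproblematic; genuinely
  genome-scale inputs (≈50k genes, ~20 GB per matrix) would need a
  blockwise backend, which is a known limitation.
- Timestamps are deliberately absent from the run manifest so that reruns
  with the same config and inputs are byte-identical.

## Problem sizes in the tests

The suite exercises brute-force oracles (correlation, ranks, TOM, AUC,
hypergeometric enumeration) on instances of up to 20 genes, where exhaustive
evaluation is exact and fast; recovery and determinism checks run the full
pipeline on the 200-gene reference scenario and an 80-gene variant across
three seeds. These sizes were chosen so the whole suite completes in well
under a minute while every formula path and boundary case is still covered.

## Known limitations

- The ROC gold standard is the user's responsibility; annotation-sharing
  positives embed the biases of the annotation.
- The scale-free fit target of 0.90 is rarely reached on modular synthetic
  data (by design of the data, not a defect of the fit); real bulk panels
  behave closer to scale-free.
- Spearman/biweight correlations, partial correlations, signed TOM and
  module detection (dynamic tree cut, eigengenes) are out of scope.
- Regulatory direction is not modelled: edges are undirected and carry only
  the sign of the correlation.
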
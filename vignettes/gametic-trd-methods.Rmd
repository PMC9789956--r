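---
title: "Modeling transmission ratio distortion with gametic interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transmission ratio distortion with gametic interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametrd)
```

## The problem

Transmission ratio distortion (TRD) is the departure of offspring
allele or genotype frequencies from Mendelian expectation in genotyped
parent-offspring trios. Two mechanisms are distinguished here:

* a **direct effect** — one allele of a heterozygous parent is
  transmitted more often than its partner, e.g. through meiotic drive or
  a deleterious allele acting regardless of the partner gamete; and
* a **gametic interaction** — a specific *combination* of a
  sire-transmitted and a dam-transmitted allele is over- or
  under-represented among live, genotyped offspring, the signature of
  gametic incompatibility (failed fertilization or early loss of
  particular genotype combinations).

`gametrd` estimates both per genomic region from trio genotype tables,
flags regions with decisive evidence, and carries the resulting regions
into positional gene lists and over-representation summaries. The
intended data are livestock pedigrees of the artificial-insemination
type — very many offspring per sire, few per dam — and multi-allelic
region "alleles" (haplotypes) coded as small integers, but nothing in
the machinery is cattle-specific.

## The offspring probability model

Consider one region with alleles coded `1..n` and a mating
$A_{s_1}A_{s_2} \times A_{d_1}A_{d_2}$. Each ordered offspring
combination (allele $s$ from the sire, $d$ from the dam) is assigned the
product

$$P(s, d) \;=\; t_s \, t_d \,(1 + \beta_{s,d})
  \prod_{(s',d') \neq (s,d)} \Bigl(1 - \tfrac{\beta_{s',d'}}{3}\Bigr),$$

where the transmission factor $t_s$ is $0.5 + \alpha_{s_1 s_2}$ for the
lower-coded allele of a heterozygous sire, $0.5 - \alpha_{s_1 s_2}$ for
the higher-coded one, and $1$ for a homozygous parent; dams contribute
symmetrically with the same per-pair $\alpha$ parameters. The product
over the *other* combinations of the same mating compensates the change:
with a single nonzero $\beta$ and $\alpha = 0$ the four terms of a fully
heterozygous mating sum exactly to one, and at the null every
combination has probability $0.25$. Combinations that produce the same
unordered genotype (e.g. allele 1 from the sire and 2 from the dam, or
vice versa) are summed, because parental origin is unobservable in
genotype data.

Parameter supports follow Mendelian logic: $\alpha \in [-0.5, 0.5]$
(transmission probability $0$ to $1$) and $\beta \in [-1, 1]$
($\beta = -1$ abolishes a combination; positive values inflate it).
Priors are flat on these supports.

### Normalization

The raw product does not sum to one when $\alpha$ and $\beta$ act
simultaneously or when several $\beta$ are nonzero (a single $\beta$
with a nonzero $\alpha$ already gives a total of $1 + 2\alpha\beta/3$).
Observed offspring are by construction a draw from *some* proper
distribution, so the likelihood uses the per-mating renormalized
probabilities; `combination_probs(..., normalize = FALSE)` exposes the
raw products for inspection. At the null, and in every single-$\beta$
configuration with $\alpha = 0$, normalization is a no-op.

### Identifiability and the reported representative

Renormalization has a consequence that shapes the whole inference
design: within every mating, only *ratios* of the per-combination
factors matter. Writing $f(\beta) = (1+\beta)/(1-\beta/3)$, the
likelihood is exactly invariant under rescaling each allele's
transmission factor by some $w_a > 0$ (absorbed by moving each $\alpha$
along its odds) while compensating every interaction factor
$f_{s,d} \mapsto c\, f_{s,d}/(w_s w_d)$. The data therefore identify the
parameter vector only up to a continuous group of dimension roughly the
number of alleles. Concretely, a biallelic region generated with
$\alpha = 0.2,\ \beta_{1,1} = -0.6$ produces *identical* offspring
distributions, for every mating type, as one with
$\alpha = -0.0625,\ \beta_{2,2} = -0.6$: no estimator can distinguish
them.

The package handles this explicitly rather than letting chains wander a
flat ridge. Every kept posterior draw is mapped to the representative of
its equivalence class minimizing

$$\sum_{s,d} \sqrt{\lvert \beta_{s,d} \rvert} \;+\;
  \tfrac{1}{2} \sum_{i<j} \lvert \alpha_{ij} \rvert ,$$

i.e. the *sparsest* description of the same distribution: the concave
square root concentrates the interaction signal on as few combinations
as possible (a convex criterion would split one over-represented
combination into several weaker under-represented ones), and the
$\alpha$ term selects, among representations with equally sparse
interactions, the one needing the least direct distortion. The
attribution pattern is chosen once per chain by majority vote across
draws, so marginal summaries are unimodal; the per-draw gauge element is
found by pattern-wise linear least squares in log space followed by a
Nelder-Mead polish. Raw draws remain available in `samples_raw`, and
`run_chain(..., canonical = FALSE)` disables the gauge.

Two consequences deserve emphasis. First, when the generating
configuration is itself the sparsest member of its class — a single
distorted parameter, the usual simulation design — the gauge-fixed
posterior concentrates on the generating values (small conservative
attribution bias, about $0.04$ in $|\beta|$ at $10^4$ trios in the
bundled checks). Second, when direct and interaction effects are truly
simultaneous, the reported representative may be an *equivalent*
configuration rather than the generating labels; this is a property of
the model class, not of the estimator, and analyses should read the
output as "the most parsimonious description consistent with the data".

## Sampling and evidence

Each region runs a single-chain componentwise random-walk
Metropolis-Hastings sampler (Metropolis-within-Gibbs): per sweep, every
identifiable parameter is updated from a uniform proposal reflected at
its support bounds, so the flat prior cancels from the acceptance ratio.
Proposal half-widths start at 0.1 ($\alpha$) and 0.2 ($\beta$) and adapt
every 250 burn-in sweeps toward a 20-50% acceptance rate, frozen
afterwards. The default protocol is 110,000 sweeps with 10,000 discarded
as burn-in; the bundled tests use reduced chains (11,000/1,000, thinned)
as a scaled-down surface of the same procedure. Parameters structurally
absent from the data — a $\beta$ for an ordered combination no observed
mating can produce, or any parameter of a region whose matings are all
homozygous $\times$ homozygous — are pinned at zero and excluded.

An alternative `update_mode = "independent"` fits each parameter in a
one-parameter model with all others held at their null value. The
compensation constant $1/3$ makes each such univariate model exactly
proper, which is why this literal protocol is internally coherent; its
drawback is that a direct effect leaks into the univariate interaction
estimates, so the joint Gibbs mode with gauge fixing is the default.

Evidence per parameter is a Savage-Dickey density ratio against the
point null: prior density at zero (1 for $\alpha$, 0.5 for $\beta$)
divided by the posterior density at zero, estimated by a Gaussian kernel
with reflection at the support bounds (histogram fallback with bin width
support/100 if the bandwidth degenerates; an exactly zero estimate
returns `Inf` flagged as a density floor). The decisive-evidence
threshold is $BF \ge 100$. No multiplicity correction is applied across
regions — the threshold itself is the filter, and all BFs are reported
so users can post-process.

Downstream, a region is *strong-interaction* when at least one $\beta$
posterior mean lies strictly outside $[-0.5, 0.5]$; the filter uses the
posterior mean as its point estimate and strict inequalities, so an
estimate of exactly $0.5$ is dropped. Duplicate candidate records per
region collapse to the one carrying the largest $|\beta|$.

## The synthetic trio generator

`simulate_trd_dataset()` provides the test bed the analysis assumes:

* **Pedigree.** `n_trios / trios_per_sire` sires (default 57.07 matings
  per sire) and `n_trios / trios_per_dam` dams (default 2.57), matching
  the scale of artificial-insemination cattle pedigrees. Sire usage
  weights are symmetric-Dirichlet (concentration 1 by default), giving
  the realistic few-bulls-sire-most-calves skew without claiming any
  particular pedigree's shape. Each (sire, dam) mating appears at most
  once — one genotyped offspring per mating.
* **Genotypes.** Parents draw two alleles from the region's frequency
  vector (Hardy-Weinberg; default equifrequent). Offspring sample an
  ordered combination from the *same* `combination_probs()` the sampler
  fits, then store the unordered pair, as real genotype data would. A
  mating whose viable-offspring mass is zero (every producible
  combination lethal) is resolved by redrawing the dam's genotype — such
  a mating cannot contribute a genotyped trio.
* **Not emulated:** linkage between regions, genotyping or imputation
  error, pedigree loops, and the original selection rules (genotyping
  within 90 days of birth, first offspring per mating) beyond the
  one-offspring constraint. Passing tests therefore demonstrate
  correctness of the estimation machinery under the model's own
  generating process, not robustness to real-data artifacts.

Problem sizes used by the bundled checks: 10,000-trio regions for
recovery, 20 null regions of 2,000 trios for calibration of the
$BF \ge 100$ rule, ten 6,700-trio regions (about 5,000 informative
matings each) for the end-to-end scan, all with fixed seeds and reduced
chains.

## Annotation and over-representation

Regions surviving the filters become genomic windows extended by
50,000 bp on both sides (clamped at position 1; 1-based inclusive
coordinates throughout, the GFF3 convention). Genes with any 1-bp
overlap on the same chromosome are extracted via `rtracklayer` /
`GenomicRanges`, deduplicated across regions. Over-representation of a
gene list in GMT gene sets uses the hypergeometric upper tail with
`Expected = Total x list/background`, `Ratio = Hits/Expected` and
Benjamini-Hochberg FDR; the background defaults to the union of set
members (genes annotated in the database), configurable. Database
versions and identifiers are the user's responsibility — enrichment
output is only as comparable as its background.

## Numerical notes and limitations

* Likelihood evaluation is grouped: trios collapse to (mating type,
  offspring genotype) counts, so chain cost is independent of the number
  of trios.
* Reflection at bounds keeps proposals in the closed support; a
  boundary value of $\beta = -1$ gives a zero-probability cell and is
  simply rejected when an observed offspring contradicts it.
* Chains are reproducible bit-for-bit given a `chain_config` seed; a
  scanned region `i` derives its seed as `seed + i`.
* The Savage-Dickey estimate inherits kernel-density error near the
  bounds; with the gauge, parameters pinned at zero produce degenerate
  (near-constant) marginals whose Bayes factors are effectively zero,
  which is the intended reading.
* The gauge optimization is heuristic (pattern vote + local polish);
  pathological draws keep their raw values, which are members of the
  same equivalence class and thus leave the likelihood interpretation
  intact.
* Sex chromosomes, imprinting-style parent-of-origin direct effects,
  and genotyping-error models are out of scope.
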
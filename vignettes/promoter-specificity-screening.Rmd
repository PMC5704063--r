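---
title: "Methods: promoter-level cell-type specificity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-level cell-type specificity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscreen)
```

## The problem

CAGE (cap analysis of gene expression) counts sequencing reads at
clustered transcription start sites, so a promoter-by-sample table of tag
counts measures promoter activity directly, promoter by promoter rather
than gene by gene. Given such a table for a handful of samples of one
cell type — say, a rare ocular cell population profiled in biological
triplicate — and a large reference atlas of the same measurement across
hundreds of tissues and primary-cell samples, the question is: which
promoters are active in the target cell type and essentially nowhere
else? Those promoters are candidate identity markers, and when a
non-major (alternative) promoter of a gene is specific while the gene's
main promoter is broadly active, promoter-level data reveal specificity
that gene-level quantification would average away.

`promscreen` implements this screen end to end, together with the
companion analysis of a paired two-state design (progenitors and their
differentiated derivatives from the same donors), and a synthetic-data
generator with planted truth that lets every stage be validated without
any external data.

## Normalization model

Raw tag counts are normalized in two steps.

**RLE size factors.** For sample $j$, the size factor is
$f_j = \operatorname{median}_{i \in R}\; c_{ij} / g_i$, where
$g_i = (\prod_j c_{ij})^{1/m}$ is the per-promoter geometric mean and the
reference set $R$ contains the promoters with strictly positive counts in
every sample. The median is taken on the ratio scale (arithmetic
interpolation for even counts), and factors are rescaled so their
geometric mean is exactly 1. The reference-set rule is the standard
median-of-ratios construction; it assumes that most promoters are not
differentially active between samples, which holds for genome-wide
promoter tables but not for heavily filtered ones — hence
`rle_size_factors()` refuses matrices with no all-positive promoter
rather than silently extrapolating.

**Tags per million.** $\mathrm{tpm}_{ij} = 10^6\, c_{ij} / (N_j f_j)$
with $N_j$ the raw column total, i.e. normalization against the
*effective* library size $N_j f_j$. Because $f_j$ is computed from raw
counts and then geometric-mean-centred, a column's tpm total is
$10^6/f_j$, not $10^6$; depth is removed exactly only when all libraries
are rescaled by a common constant. We kept this composition because it
reproduces the worked median-of-ratios arithmetic exactly and keeps the
two stages independently testable.

## Quality control

Replicate concordance is the Spearman rank correlation of
$\log_2(\mathrm{tpm}+1)$ between every within-group pair (average ranks
for ties; the log transform is monotone, so it affects nothing except
the exported scatter tables). A sample fails when the *median* of its
correlations with its co-replicates falls below a threshold, 0.7 by
default. The threshold is deliberately below the $\rho > 0.77$ seen
between healthy replicate pairs in practice: it is an exclusion gate for
replicates that have drifted (for cultured cells, typically by
mesenchymal transition), not a tight concordance requirement. A second,
orthogonal gate — `marker_panel_check()` — requires a user-supplied
panel of established markers of the target cell type to be expressed
(≥ 10 tpm by default) in every sample; a sample that fails it has likely
lost the identity being profiled, whatever its concordance.

## The exact test

Significance of a target-vs-reference (or state-vs-state) difference is
assessed with a negative-binomial exact test in the Robinson–Smyth
style, implemented from first principles:

1. counts are scaled to the geometric mean of the effective library
   sizes and rounded to pseudo-counts (nearest integer, ties to even —
   this matters only at very low counts);
2. pseudo-counts are summed within groups, giving $(y_A, y_B)$ with
   total $s$;
3. under the null the group sums are modeled as independent negative
   binomials with means $s\,n_A/(n_A+n_B)$ and $s\,n_B/(n_A+n_B)$ and
   dispersions $\phi/n_A$, $\phi/n_B$ (the NB is parameterized as
   $\mathrm{Var} = \mu + \phi\mu^2$ throughout, $\phi = 0$ being
   Poisson);
4. the two-sided p-value is the total conditional probability, given
   $s$, of every split no more likely than the observed one. At
   $\phi = 0$ the conditional law is exactly
   $\mathrm{Binomial}(s, n_A/(n_A+n_B))$.

Two numerical details are part of the definition. Splits count as "no
more likely" up to a relative probability tolerance of $10^{-8}$, which
makes exactly tied outcomes (e.g. the symmetric balanced split, whose
p-value is 1) robust to floating-point rounding. And for totals above
2048 the same quantity is computed without enumerating all $s+1$ splits:
the normalizer has the closed form $P(Y_A + Y_B = s)$ (a single NB
density, since the two NBs share their probability parameter), the
conditional pmf is log-concave and therefore unimodal, so the inclusion
set is a union of two tails whose boundaries are found by binary search,
and the tail masses are accumulated outward with truncation at $10^{-15}$
relative. Both paths agree to floating-point accuracy; the test suite
checks them against an independent enumeration oracle.

**Dispersion.** The common dispersion is estimated by pooled method of
moments: per promoter, within each group with $\ge 2$ samples,
$\hat\phi = (s^2 - m)/m^2$ on library-equalized counts, pooled across
groups by residual degrees of freedom, floored at 0; the common value is
the median over promoters with positive mean. This is deliberately
simpler than likelihood-based dispersion machinery: it is deterministic,
closed-form, and adequate for a screen whose significance gate
(adjusted $P < 0.01$) sits far from the decision boundary for genuine
markers. Its known cost is noise at small sample and promoter counts —
the estimate stabilizes around a few thousand promoters — and a
conservative bias when reference heterogeneity (which the screen *wants*
in the null) inflates within-group variance.

Multiple testing uses Benjamini–Hochberg step-up adjustment
(`stats::p.adjust`, validated in the suite against a literal step-up
oracle).

## The five-criterion screen

With target samples $T$ and reference samples $R$ on the tpm scale, a
promoter is called specific iff all five hold (strict inequalities;
boundary values fail):

1. $\min_{j \in T} \mathrm{tpm}_j > 10$;
2. $\mathrm{mean}_{j \in R}\,\mathrm{tpm}_j < 3$;
3. $\max_{j \in R}\,\mathrm{tpm}_j < \mathrm{mean}_{j \in T}\,\mathrm{tpm}_j$;
4. $\log_2\frac{\mathrm{mean}_T + c}{\mathrm{mean}_R + c} > 5$;
5. BH-adjusted $P < 0.01$ for the target-vs-reference exact test.

The pseudocount $c$ (default 0.1 tpm) exists because genuinely specific
promoters can have a reference mean of exactly zero; 0.1 tpm is an order
of magnitude below criterion 2's cap, so it never rescues a borderline
fold change, it only keeps the ratio finite. Criteria tighten
monotonically: raising any one threshold can only shrink the specific
set, a property the suite tests criterion by criterion.

Two screens — one per reference facet, e.g. tissues versus primary
cells, each compared against its matching target preparation — are then
intersected, the surviving peaks are collapsed to gene loci (unmapped
location-style peaks become singleton loci), and each locus is
classified. A locus is `alternative_promoter_only` when its p1 (the
promoter with the highest total tag count for that gene) is *not*
specific **and** p1 reaches at least 10 tpm somewhere in the reference:
the gene is broadly expressed and only an alternative promoter is
specific. A silent p1 does not disqualify a locus — a gene whose main
promoter is simply off everywhere, while a non-major promoter is
specifically active, is still a clean marker locus. The 10 tpm
"broadly expressed" threshold is our formalization of an otherwise
qualitative judgement; it mirrors criterion 1 and is configurable.

## Paired differentiation analysis

For donor-matched two-state designs, significance again comes from the
exact test on group sums (the conditioning removes no donor pairing, so
the test is unpaired and slightly conservative for paired data), while
the effect size is paired: per donor $d$,
$\mathrm{FC}_d = (\mathrm{tpm}_{B,d} + c)/(\mathrm{tpm}_{A,d} + c)$ with
$c = 1$ tpm, combined as a geometric mean — the geometric mean is
symmetric under direction reversal (swapping the groups maps
$\overline{\mathrm{FC}} \mapsto 1/\overline{\mathrm{FC}}$ exactly), which
an arithmetic mean is not; the arithmetic mean remains available by
argument. A promoter is called up when
$\overline{\mathrm{FC}} > 2$ and adjusted $P < 0.01$, down when
$\overline{\mathrm{FC}} < 1/2$ at the same significance.

## Clustering recipes

Two report recipes are exposed through one operation,
`hierarchical_cluster()`: complete linkage on Euclidean distances of
$\log_2(\mathrm{tpm}+1)$ profiles (for grouping specific promoters by
expression pattern), and average linkage (UPGMA) on Spearman correlation
distances $1-\rho$ (for genome-wide sample similarity). Agglomeration is
delegated to `stats::hclust`; with continuous expression values exact
merge ties have probability zero, and the suite verifies both recipes
against a brute-force agglomeration oracle and checks that results are
invariant to leaf order up to relabeling. Items with zero rank variance
are assigned $\rho = 0$ (distance 1) rather than propagating `NA`.
`cut_clusters(k)` removes the $k-1$ highest merges and renumbers
clusters stably by first leaf; each cut refines the previous one.

## What the synthetic data emulates — and what it does not

`simulate_atlas()` draws NB counts
($\mathrm{Var} = \mu + \phi\mu^2$, default $\phi = 0.1$) for 10,000
promoters distributed over gene loci of 1–8 promoters, with:

* log-normal per-promoter baselines, median 10 tpm, $\sigma_{\log} = 1.5$
  — a heavy-tailed activity distribution in which a few promoters
  dominate the library, as in real CAGE tables. Baselines are *not*
  rescaled to sum to $10^6$: the matrix stands for a subset of the
  genome-wide peak set, so within-matrix tpm is the analysis quantity;
* log-normal library sizes around $10^6$ tags
  ($\sigma_{\log} = 0.25$);
* per-reference-sample log-normal baseline jitter
  ($\sigma_{\log} = 0.5$), so the reference maximum in criterion 3 is a
  genuinely variable order statistic over 180 heterogeneous samples
  rather than a copy of the mean;
* 30 planted specific promoters: target mean = 64 × their drawn
  baseline, reference baseline 0.05 tpm (near-silent, occasionally
  sampling a stray tag — which exercises criterion 3's max rather than
  trivially passing it). Setting the planted effect to 1 disables the
  perturbation entirely, turning the planted set into pure-null decoys
  for false-positive accounting.

`simulate_differentiation()` draws donor-paired two-state counts for
5,000 promoters, 3 donor pairs, with a shared per-donor log-normal
effect ($\sigma_{\log} = 0.15$) inducing the within-donor correlation of
a paired design, and 100 + 100 promoters planted at 4-fold up/down in
the differentiated state. Baselines are log-normal with median 200 tpm
($\sigma_{\log} = 1.2$): the recovery condition this design validates is
stated at a 200 tpm baseline and generating dispersion
$\phi = 0.05$, and the donor effect is sized so that the *effective*
dispersion seen by the unpaired exact test stays near that $\phi$ — a
donor CV much above ~15% would be a statement about a different, harder
design, not about the machinery being validated.

What the generator does **not** emulate: correlated promoter blocks
(co-regulation), sample-size imbalance beyond the two facets,
zero-inflation beyond what NB sampling at low means produces, batch or
protocol effects between target and reference (in real use the target
and atlas must come from the same protocol for the screen to be
meaningful), and any genomic structure (the coordinates in simulated
peak IDs are ranks, not positions). Passing recovery tests on this
generator therefore demonstrates that the statistical machinery is
correct under its own model, not that the thresholds are optimal for any
particular real atlas.

## Problem sizes and determinism

Default validation runs use the sizes above (10,000 × 183 for the
screen, 5,000 × 6 for the paired design); unit tests use scaled-down
versions of the same configurations (a few hundred to a few thousand
promoters, 30–60 reference samples), which keeps the whole suite
desk-scale while the acceptance checks run the full defaults. Every
simulation is driven by a single integer seed through R's default RNG;
identical seeds give bit-identical matrices, truth sets, and therefore
byte-identical pipeline outputs, which the suite verifies through the
command-line entry point.

## Known limitations

* The exact test treats the 3-vs-180 comparison symmetrically through
  group sums; with a common dispersion estimated mostly from the large,
  heterogeneous reference, p-values for the small target group are
  conservative rather than anti-conservative.
* The method-of-moments dispersion is a single common value; promoters
  with atypical dispersion are gated only by the fold-change and
  absolute-expression criteria.
* `parse_promoter_id()` stores peak-name coordinates as 0-based
  half-open spans (the BED-derived convention); if a table's peak names
  use 1-based inclusive coordinates, spans are off by one at the start —
  ranking, screening and collapsing are unaffected, as they never use
  coordinates except as tie-breaks.
* The replicate-concordance gate needs ≥ 3 replicates to isolate a
  single bad sample; with duplicates it can only flag the pair.
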
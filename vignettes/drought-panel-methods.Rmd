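---
title: "Methods: drought-tolerance dissection of a diversity panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-tolerance dissection of a diversity panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtpanel)
```

This vignette documents the models behind `droughtpanel`, the parameters
that matter, the design decisions taken where the methodology left room,
and what the bundled simulator does and does not emulate.

## 1. Fuzzy-membership phenotype scoring

**Model.** For each accession, trait, stress treatment and environment,
the relative trait is the ratio of replicate means,
$TR = X_d / X_c$, with $X_d$ the mean under stress and $X_c$ under the
well-watered control. The drought-tolerance index is yield-based; its
printed definition is typographically ambiguous, so both readings are
implemented:

* `di_formula = "ratio"` (default): $DI = (Y_D/Y_P)\,(Y_D/\bar Y_D)$ —
  dimensionless, on the same 0–2-ish scale as typical published DI
  summaries;
* `di_formula = "literal"`: $DI = (Y_D/Y_P)\,\bar Y_D$ — carries yield
  units.

Neither reading is asserted as the original intent; the default was
chosen for dimensional consistency.

The standardized indicator matrix (per-treatment relative traits
averaged over environments, plus DI) is reduced by PCA. Components are
retained up to a cumulative explained variance of `cum_var = 0.85`; the
retained scores are the *composite indicators*, the explained-variance
shares $P_i$ give weights $\omega_i = P_i/\sum P_i$ (so
$\sum\omega_i = 1$ to $10^{-10}$), memberships are min–max rescaled per
indicator, and $D = \sum \mu(X_i)\,\omega_i \in [0,1]$.

**Sign alignment (design decision).** Principal-component signs are
arbitrary, but every indicator here is larger-is-more-tolerant. Each
retained component is therefore flipped, if necessary, to correlate
positively with the standardized indicator row mean. Without this step
the orientation of $D$ — and hence which cluster is called "tolerant" —
would be undefined. Classification is Ward-linkage hierarchical
clustering (Euclidean, on membership vectors), cut at `k = 3`, clusters
labelled tolerant/medium/sensitive by descending mean $D$. Clustering is
performed on accessions in sorted-identifier order, so results do not
depend on input row order. An all-tied $D$ vector is flagged degenerate
with a warning rather than an error.

**Degenerate inputs.** Zero control means flag the cell undefined (with
a count message) instead of propagating `Inf`; a constant indicator
column aborts the PCA naming the column; `max == min` aborts the
membership scaling for that indicator. Accessions with missing
indicator cells are dropped with a message (`impute = "mean"` mean-fills
instead). Descriptive summaries use the adjusted Fisher–Pearson sample
skewness and small-sample-corrected excess kurtosis (the common
spreadsheet definitions), and `CV = 100·sd/mean`.

## 2. Mixed-model association scan

**Model.** The scan is the classic two-stage approximation: under the
null $y = \mu + g + e$ with $g \sim N(0, \sigma^2_g K)$ and
$e \sim N(0, \sigma^2_e I)$, the variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ is estimated once by REML, profiled
through the eigen-decomposition of $K$ and maximized with Brent search
on $\log\delta \in [-5\ln 10, 5\ln 10]$. Each SNP is then tested by a
GLS Wald test ($t$, $n-2$ df) at fixed $\delta$ — the defining EMMAX
shortcut: variance components are *not* re-estimated per marker.
$K$ is the VanRaden genomic relationship matrix
$WW'/(2\sum p(1-p))$ from mean-imputed, frequency-centred genotypes.
With $K = I$ the scan reduces *exactly* to OLS regression — asserted to
$10^{-8}$ in the tests on every run.

**Parameters.** `min_maf = 0.05` and `min_call_rate = 0.9` are the
community defaults (failing SNPs are reported flagged, not dropped
silently); missing genotypes are mean-imputed for both kinship and
testing. Thresholds: `bonferroni` ($0.05/n$) and `suggestive`
($10^{-4}$, i.e. $-\log_{10} p \ge 4$); both are exposed because
published analyses use each in different places, and neither is asserted
as the one that produced any printed SNP count. Cross-environment
co-detection matches SNPs by exact chromosome + position.

**QTL merging.** Significant SNPs chain into a QTL when consecutive
(position-sorted) members are within `max_gap = 100000` bp *and* in LD
`r² > 0.35` (genotypic $r^2$: squared Pearson correlation of dosages
over pairwise-complete accessions). Single-linkage chaining on
chain-adjacent pairs was chosen over all-pairs LD for determinism; the
merge is idempotent, order-invariant on sorted input, and conserves the
member count. Candidate windows are $\pm$`flank = 100000` bp around each
SNP, clipped to `[1, chromosome length]`, with $\ge 1$ bp inclusive
overlap defining gene membership. (`flank` is a parameter because
published candidate tables sometimes use wider, e.g. ±400 kb, windows.)

## 3. Selective-sweep scan

Per-site Weir–Cockerham (1984) variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$
(within individuals) are computed for two diploid groups with unequal
sample sizes from genotype counts, heterozygote-aware. Per-site
estimates $a/(a+b+c)$ may legitimately be negative; monomorphic sites
carry a zero denominator and are flagged, sites with fewer than two
called genotypes in a group are flagged missing. Windows are 100 kb
advancing by 10 kb, anchored at position 1 (the anchor is configurable;
the convention is otherwise arbitrary), and the window statistic is the
ratio-of-sums $\sum a / \sum(a+b+c)$ — the weighted form used by the
standard command-line tool — with the mean-of-ratios also reported.
Windows with no informative SNP are removed *before* the top-5% cut
(ranking undefined values is meaningless), and the cut is genome-wide
rather than per-chromosome (a documented choice; the source analyses do
not say). Flagged windows merge into maximal regions by overlap or
book-ending. Exact count-scale invariance under doubling both groups
holds only asymptotically — the finite-sample corrections
$\bar n/n_c$ and $1/(\bar n - 1)$ shift slightly — so the tests assert
sign equality and closeness, not identity.

## 4. Co-expression networks

Adjacency is $|cor|^\beta$ (unsigned, default; signed
$((1+cor)/2)^\beta$ by flag) with $\beta = 9$; the topological overlap
is
$TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
symmetric, in $[0,1]$, unit diagonal. Note that $TOM_{ij} \ge a_{ij}$ is
*not* an invariant of this normalization: with sizable connectivity and
a small shared neighbourhood the denominator exceeds 1 and TOM can fall
below the adjacency; only the $[0,1]$ bounds, symmetry and the formula
itself are asserted.

**Module detection (design decision).** The full published dynamic
tree-cut algorithm is deliberately not replicated. Instead, on the
average-linkage tree of $1 - TOM$: all merge heights are scanned, the
branch count (branches $\ge$ `min_module_size = 50`) that persists over
the widest total range of heights is taken as the module count, and the
tree is cut at the top of that count's longest plateau — so modules are
fully assembled before unrelated genes begin to join. This is
deterministic, has no tuned height constant, recovers planted modules
even when two modules' latent factors are correlated, and degrades
gracefully (everything grey when no branch ever reaches the minimum
size). A fixed `cut_height` overrides the scan. Modules whose eigengenes
correlate above $1 - $`merge_cut`$ = 0.75$ merge iteratively; final
labels follow the conventional color sequence by size rank. The module
count on any real dataset depends on that dataset; it is not a quantity
this package promises to reproduce.

Eigengenes are first principal components of the standardized module
expression, unit variance, sign-aligned with the module mean profile;
module–trait correlations use the exact $t$ transform ($n-2$ df) with
`*`/`**`/`***` at 0.05/0.01/0.001. The differential-expression function
is a *declared stand-in*: log2 fold change on $\log_2(\mathrm{FPKM}+1)$,
Welch test, BH adjustment, flagged at $|log2FC| > 2$ and $q < 0.01$
(the stricter of the two thresholds quoted in the motivating analyses;
both are parameters). It is a linear-model surrogate appropriate for
the simulator's FPKM-like matrices, not a negative-binomial count
model — do not use it on raw RNA-seq counts.

## 5. Integration and regional analysis

The candidate-gene table is pure interval arithmetic plus a
module-membership lookup: one row per (gene, module, SNP window) with
$\ge 1$ bp overlap, restricted to a user-supplied significant-module
list (module significance is an input, mirroring how module–treatment
stars are read off the correlation table; no cross-module FDR is
imposed). Allele–phenotype tests partition accessions into 0/0, 0/1,
1/1 and missing; classes below `min_class_size = 2` are reported but
not tested; two testable classes get Welch's $t$, three get one-way
ANOVA. The choice of test family is a design decision — the motivating
figures do not name theirs.

Regional LD reports both genotypic $r^2$ (identical, to $10^{-12}$, to
the genome-wide LD function) and $D'$ from two-SNP haplotype
frequencies EM-estimated from unphased diploid genotypes (only the
double heterozygote is phase-ambiguous; iteration cap 100, tolerance
$10^{-8}$ on the log-likelihood, which is non-decreasing by
construction and asserted so in the tests). Regional association is
plain per-SNP OLS — deliberately *without* kinship correction, the
fine-mapping convention of regional tools — flagged at
$-\log_{10} p \ge 2.5$. Haplotypes are exact strings of unphased codes
(0/0, 0/1, 1/1) over the region's SNPs: no phasing is implemented
because the grouping being emulated is defined on genotype codes.
Missing is *not* a wildcard (two strings differing only in a missing
call are different haplotypes); accessions with more than
`max_missing_frac = 0.1` missing calls in the region are excluded with
a report. Groups are numbered Hap1, Hap2, … by descending carrier
count, ties broken lexicographically, making the numbering
order-invariant.

## 6. What the simulator emulates — and what it does not

The generator reproduces the *statistical structure* the pipeline
assumes, at desk scale:

* **Genotypes:** biallelic 0/1/2 SNPs with ~1% missing calls, LD induced
  block-wise (each block carries founder haplotype indicators copied
  per-site with mutation probability 0.03) — sufficient for $r^2$-based
  merging and haplotype grouping, but *not* a coalescent: no
  recombination gradients, no allele-frequency spectrum realism, no
  population-size history. Inside the planted sweep the two
  subpopulations draw block frequencies $0.5 \pm d/2$ with
  $d = \sqrt{t/(2-t)}$, which makes the *expected Weir–Cockerham ratio*
  match the target $t$ at equal group sizes (mutation noise dilutes the
  realized value slightly downward).
* **Phenotypes:** multiplicative around a treatment mean:
  `mean × stress_effect × (1 + u + env + e)`, where the accession
  effect `u` combines standardized planted-QTL dosages (variance =
  `effect_size`), a genome-wide polygenic score (variance =
  `heritability − Σeffect_size`, giving the kinship correction
  something real to absorb), and, under stress only, a
  tolerant/sensitive group shift of `group_effect = 2` accession-effect
  SDs. That default was set once to produce the very wide stress-trait
  dispersions (CVs approaching 70–100%) characteristic of diversity
  panels whose subgroups genuinely differ in tolerance; without *some*
  group shift the planted subpopulations would have no phenotypic
  identity at all and subgroup-recovery checks would be vacuous.
  Defaults: `stress_effect = c(M = 0.7, S = 0.35)`, between-accession
  CV 0.2, `heritability = 0.6`, three environments × three replicates.
* **Expression:** module genes are loadings (0.7–1.3) on one latent
  factor per module plus Gaussian noise; each factor is constructed to
  have its target correlation with a treatment indicator; background
  genes are independent noise. Values are affinely shifted to an
  FPKM-like non-negative scale (clipping at zero is possible in
  principle but negligibly rare), so they are *linear-Gaussian*, not
  count-distributed — which is exactly why the DE stand-in is a linear
  model.
* **Annotation:** non-overlapping gene intervals, uniform gaps, 1-based
  inclusive coordinates throughout (VCF/GFF3 convention).

Everything is bitwise-reproducible for a fixed seed, and serialized
through standard formats (VCF v4.2 with `##contig` headers, GFF3, TSV).
Passing the recovery tests on these data shows the *methods* find the
structure they target; it does not certify performance on real panels,
where LD decay, rare alleles, batch effects and count noise are richer
than anything simulated here.

## 7. Problem sizes and numerical tolerances

The test suite and `scripts/acceptance.R` run the pipeline at sizes
chosen to exercise every code path while staying desk-sized: panels of
100–200 accessions, 600–5,000 SNPs, expression matrices of 400–1,500
genes × 12–18 samples, five simulation seeds for each recovery claim.
Key tolerances: weight sums and membership bounds exact to $10^{-10}$;
estimator-vs-oracle agreement $10^{-12}$ (Weir–Cockerham components,
TOM, LD $r^2$), $10^{-8}$ (OLS-limit of the mixed model, eigengene
variance), $10^{-4}$ (EM $D'$ vs a likelihood-grid search); null
calibration bands $[0.03, 0.07]$ for the scan's type-I error at
$\alpha = 0.05$.

## 8. Known limitations

* Single-block co-expression only; very large gene sets would need
  blockwise partitioning.
* No population-structure fixed-effect covariates in the scan (kinship
  only), no multi-locus or multi-trait models.
* The Fst scan handles exactly two groups; no haplotype-based sweep
  statistics (iHS, XP-EHH).
* Functional consequences of SNPs (missense/synonymous) are consumed
  from user annotation, never computed.
* GO/KEGG enrichment and all figure rendering are out of scope; outputs
  are tables designed to feed external tools.
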
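---
title: "Differential co-expression and regulator rewiring between two conditions"
author: "CoexRewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression and regulator rewiring between two conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoexRewire)
```

# The analysis

A typical use case is a treatment-versus-control bulk RNA-seq design — for
example, offspring liver transcriptomes under two maternal diets, six
animals per group. Beyond asking which genes shift in mean expression, the
interesting question is often *regulatory rewiring*: which transcription
factors (TFs) change how they co-express with the responsive genes, and
which genes gain or lose network connectivity between the conditions.
CoexRewire implements that full chain on a gene-by-sample count matrix:

1. expression filtering, median-of-ratios size factors, a
   variance-stabilizing transform;
2. a per-gene negative-binomial (NB) Wald test calling differentially
   expressed genes (DEGs);
3. regulatory impact factors RIF1/RIF2 scoring every expressed TF against
   the DEG set;
4. per-condition co-expression networks pruned by the
   partial-correlation-and-information-theory (PCIT) rule;
5. differential connectivity (DK) z-scores between the two networks;
6. hypergeometric over-representation analysis (ORA) and preranked gene
   set enrichment analysis (GSEA).

Every stage is exported on its own; `runPipeline()` chains them from files
to files and writes a JSON manifest of all bookkeeping counts.

# Models and conventions

## Differential expression

For gene $g$ with counts $y_{gs}$, size factors $sf_s$ and fixed
dispersion $\alpha_g$, we fit the NB GLM
$\log \mu_{gs} = \log sf_s + \beta_0 + \beta_1 [s \in VTM]$ by IRLS and
test $\beta_1$ with a two-sided normal Wald test;
$\log_2\!FC = \beta_1/\ln 2$. Dispersion comes from a method-of-moments
estimate on normalized counts pooled within conditions,
$\alpha = \max\{(s^2-\bar\mu)/\bar\mu^2, 10^{-8}\}$, with the mean and
variance averaged over the two condition-level estimates. Deliberate
simplifications relative to full RNA-seq machinery — no dispersion trend
or shrinkage, no fold-change shrinkage, no outlier filtering — are
recorded in the result's provenance metadata. In the Poisson limit the
estimate collapses to the log ratio of group means (verified to $10^{-6}$
in the tests), and on null simulations the raw-p type-I error at 0.05
lands near 0.05–0.07 (slightly liberal, as expected for a Wald test at
$n=6$ without shrinkage).

A gene is a DEG iff raw $p \le 0.05$ and $|\log_2\!FC| \ge 0.5$; the
direction is the fold-change sign. The *raw* p-value gates the call —
the threshold rule is stated in terms of p, not FDR — while BH-adjusted
values are reported alongside.

## Variance stabilization

`vstExpr()` is the closed-form stand-in
$\log_2(y_{gs}/sf_s + 1)$ rather than a fitted-dispersion VST. It is
monotone, exact to document, and adequate for the correlation-based
stages that consume it; the provenance tag in the output records the
transform so downstream users know which scale RIF means live on.

## Regulatory impact factors

With condition means $e^A_j, e^B_j$ of DEG $j$ on the VST scale
(A = reference = CON, B = VTM), abundance $a_j = (e^A_j+e^B_j)/2$,
differential expression $d_j = e^A_j - e^B_j$, phenotypic impact factor
$PIF_j = a_j d_j$, and within-condition TF–DEG Pearson correlations
$r^A_{ij}, r^B_{ij}$ with differential wiring
$dw_{ij} = r^A_{ij} - r^B_{ij}$:

$$RIF1_i = \frac{1}{n_{de}}\sum_j PIF_j\,dw_{ij}^2,\qquad
  RIF2_i = \frac{1}{n_{de}}\sum_j\left[(e^A_j r^A_{ij})^2 -
  (e^B_j r^B_{ij})^2\right].$$

Both metrics are z-standardized across tested TFs and flagged at
$|z| \ge 1.96$. Conventions: a TF that is itself a DEG is excluded from
its own sum (self-correlation is uninformative) but remains a target for
other TFs; zero-variance genes contribute $r = 0$ with a counted warning;
swapping the condition labels negates every raw score exactly. The
single-TF worked example in the tests pins the formulas numerically
(RIF1 = 58.32, RIF2 = 29.16 for $e^A=10$, $e^B=8$, $r^A=0.9$,
$r^B=-0.9$).

## PCIT networks

Per condition, the Pearson matrix over that condition's samples is pruned
by the PCIT rule: for every gene trio the first-order partials give a
tolerance $\varepsilon$ (mean of the three signed partial/direct ratios),
and an edge $(x,y)$ dies when some third gene $z$ dominates it,
$|r_{xy}| \le |\varepsilon r_{xz}|$ and
$|r_{xy}| \le |\varepsilon r_{yz}|$. Trios containing a direct
correlation at or below $10^{-12}$ cannot eliminate (the ratio is
undefined). The scan is a compiled $O(n^3)$ loop (about a minute for
2,000 genes on one CPU); a config cap warns above 5,000 genes. Surviving
edges are kept when $|r| \ge 0.9$ (the magnitude filter applies to the
*direct* correlation by default; a switch applies it to the edge's
minimum absolute partial instead, since the published phrasing is
ambiguous) and at least one endpoint is a DEG or significant RIF TF. The
node set is the set of retained-edge endpoints.

One property worth knowing: elimination is *not* monotone in $|r_{xy}|$.
Pushing a surviving edge's correlation towards 1 inflates the other two
partials through their $1-r_{xy}^2$ denominators, which can raise the
trio tolerance enough to eliminate the edge. The tests assert
implementation/oracle agreement across exactly such a regime change
rather than a monotonicity that does not hold.

## Differential connectivity

Degrees are max-normalized per network, $k = K/\max K$ (an empty network
contributes zeros), $DK = k_{VTM} - k_{CON}$ is computed over the union
of both node sets — genes present in one network keep degree 0 in the
other — and z-scored; $z \ge 1.96$ is "gained", $z \le -1.96$ "lost".
Whether DK should be z-scored over all network genes or only the DEG/RIF
anchors is not fixed by the published description; the union is the
default and `dk_population = "keep"` exposes the alternative.

## Enrichment

ORA is the one-sided hypergeometric upper tail of the DEG/set overlap
against the expressed-gene universe, BH-corrected, significant at
FDR $\le 0.05$. GSEA ranks all tested genes by
$\mathrm{sign}(\log_2\!FC)\cdot(-\log_{10} p)$ (p clamped at $10^{-300}$,
ties broken lexicographically for determinism), computes the weighted
Kolmogorov–Smirnov enrichment score (weight 1; weight 0 recovers the
classical KS statistic), and builds the null by gene-label permutation:
random same-size sets from the ranked universe, which is the only
permutation scheme available to a pipeline that consumes a ranked list.
$NES = ES/\mathrm{mean}|ES^*|$ over same-sign permutations; the nominal p
is add-one smoothed; a set is flagged at $p \le 0.1$ and
$|NES| \ge 1.5$.

# The synthetic world

`simulateCounts()` emulates the target design: two conditions × 6
samples, ~13k-gene studies scaled to a 2,000-gene desk preset with 100
TFs, ten TF-anchored modules of 15 targets, mean depth near $10^6$, a 5%
planted DEG fraction with $|\log_2\!FC| \in [0.5, 2]$, per-gene NB
dispersion from Gamma(2, 40) (mean 0.05), and library-size multipliers
in [0.7, 1.3].

Module structure is a latent factor per module, condition and sample:
the TF carries $x = f_s$ and each target
$x = \rho f_s + \sqrt{1-\rho^2}\,\epsilon_{gs}$, scaled by
$\sigma = 1$ natural-log unit, so the log-scale TF–target correlation
equals the coupling $\rho$ and target–target correlation $\rho^2$ before
NB noise. The $-\sigma^2/2$ centering keeps expected counts invariant to
coupling, so rewiring alone never masquerades as differential
expression. At $\rho = 0$ a module carries no latent term and counts are
exactly NB — which is what makes the moment-matching test possible.
$\sigma = 1$ (about an $e^{\pm 1}$ module swing) was fixed a priori as a
realistic strength for strongly co-regulated liver modules.

Rewired modules (coupling differs between conditions) additionally have
all their targets planted as DEGs with one coherent sign per module: a
regulator whose wiring changed is assumed to shift its targets together.
The uniform `frac_deg` draw covers the rest of the genome with random
signs. `plantGeneSets()` emits each module's target set plus uniform
decoys, so ORA/GSEA can be scored against ground truth.

What the generator does *not* emulate: batch effects, GC or length bias,
read-level artifacts, correlated library composition, TF families, and
any annotation content. A green recovery test therefore establishes that
the statistics behave as designed under clean NB-plus-latent-factor data,
not that they would survive real-data artifacts.

# Statistical power at n = 6, honestly

Two recovery properties are asserted at their intended strength in
`test-acceptance.R` and fail there, deliberately, because the stated
sample size cannot support them; the suite documents rather than hides
this.

*RIF recovery.* With six samples per condition a null Pearson estimate
has $\mathrm{Var}(\hat r) \approx 1/(n-1) = 0.2$. Every one of the
~150–240 DEG columns feeds $dw^2$ noise of mean ~0.4 into each TF's RIF1
sum, while only the TF's own 15 targets carry signal; the per-TF
signal-to-noise ratio is near 1 and the rewired-TF AUROC plateaus around
0.6. The same code reaches AUROC $\approx$ 1 at 30 samples per group, so
the limitation is the design's information content, not the
implementation.

*GSEA NES saturation.* ES is bounded at 1. Ranking by $-\log_{10} p$
puts extreme weights (NB Wald p-values reach $10^{-100}$ and below) on a
hundred-plus genes, so weight-1 permutation sets that catch any of them
reach $|ES^*| \approx 0.9$; the same-sign mean $|ES^*|$ rises toward
0.65 and NES caps near 1.45 — below the 1.5 flag — even for a perfectly
top-loaded true set whose nominal p is small. With a quieter background
(2% planted fraction) the flag fires reliably; at the default 5% it
cannot. Users applying the $|NES| \ge 1.5$ rule to heavy-tailed ranked
lists should expect the same compression.

# Numerical choices

* Correlations are clipped to $|r| \le 0.999999$ off-diagonal so partial
  correlations stay defined; zero-variance genes get $r = 0$ with a
  counted warning.
* IRLS: at most 50 iterations, convergence at $|\Delta\beta| < 10^{-8}$,
  one refinement step past convergence (this is what makes label-swap
  antisymmetry hold to $10^{-12}$ in p); diverging fold changes are
  capped at $|\log_2\!FC| = 30$ and flagged; non-converged genes get
  p = 1 and a counted warning.
* GSEA ties are broken lexicographically by gene id; permutation draws
  depend only on the seed and set order, so reruns are bit-identical.
* Seeds fan out from one master seed by counter
  (stage seeds are independent of call order); all derived seeds stay
  below $2^{31}$.
* The run manifest hash covers analysis parameters only, not the output
  directory.

# Limitations

Single-factor designs only; no batch correction; no dispersion/LFC
shrinkage (interpret borderline DEGs accordingly); the PCIT scan is
cubic in gene count and intended for filtered matrices up to a few
thousand genes; GSEA set-membership permutation does not model
inter-gene correlation within sets, so its p-values are calibrated for
random sets, not for correlated pathways.
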
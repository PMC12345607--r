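---
title: "Models and methods for endosymbiont-dominated microbiome tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for endosymbiont-dominated microbiome tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidbiome)
```

aphidbiome analyses 16S amplicon count tables from communities in which one
intracellular endosymbiont — in greenbug aphids, *Buchnera aphidicola*, with
50–200 genome copies per cell — carries the overwhelming majority of reads in
every sample. This vignette documents the models behind each component, the
parameters that matter and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical conventions adopted where a
published description left the choice open.

## The amplification-bias model

PCR is multiplicative: if taxon $i$ amplifies with per-cycle efficiency
$e_i$, then after $c$ cycles an initially even community holds relative
abundances

$$ f_i = \frac{e_i^{\,c}}{\sum_j e_j^{\,c}}. $$

Efficiencies are modelled as $e_i = 1 + (m_i - 0.5)$ with $m_i$ the mean of
$N$ independent uniform$(0,1)$ draws, so $e_i \in (0.5, 1.5)$ with standard
deviation $\approx 1/\sqrt{12N}$. $N$ is the model's single dispersion knob:
small $N$ means noisy, taxon-specific amplification (poor primer matches,
template secondary structure); large $N$ means nearly uniform efficiency.

`run_bias_experiment()` sweeps $N \in \{20, 30, 40, 50\}$ by default with
1,000 taxa, 30 cycles (a standard amplicon protocol length) and reports two
statistics per $N$, averaged over 200 replicate simulations with standard
errors:

* the share of reads captured by the **top 1%** of taxa
  (`top_fraction_mean`), and
* the **mean absolute efficiency deviation** $E|e - 1|$ (`mad_mean`),
  together with its normal-approximation closed form
  $\sqrt{2/(12 N \pi)}$ (`analytic_mad`), obtained from the mean absolute
  value $\sigma\sqrt{2/\pi}$ of a centred normal.

A single 1,000-taxon run leaves visible sampling error in the top-1%
statistic, so the default averages 200 independent replicates; the reported
standard errors make the Monte-Carlo uncertainty explicit. The closed form
is an approximation: at $N = 1$ the exact value is $0.25$ versus $0.2303$
from the formula, but for $N \ge 20$ the discrepancy is below 0.02
percentage points. Numerically, amplification is evaluated as
$c \log e_i$ followed by a max-shifted exponential, so arbitrary cycle
counts cannot overflow. The "top $k$" count is
$k = \mathrm{round}(n \cdot \mathrm{top\_percent}/100)$, rounding halves
away from zero with a floor of 1 — exactly 10 taxa for the default 1% of
1,000 — and abundance ties are broken by taxon index (immaterial for
continuous efficiencies, deterministic for constructed inputs).

```{r bias}
run_bias_experiment(replicates = 50, seed = 1)
```

## The synthetic community generator

The generator exists so that every downstream operation can be exercised,
and its statistical guarantees tested, without sequencing data. It emulates
three structural features of a greenbug infestation experiment:

1. **The factorial design.** `greenbug_design()` encodes 2 biotypes × 17
   cultivars (5 host species) × days {2, 4, 8} × 3 replicate plants, plus
   day-0 baselines. The published design states 312 samples in total but not
   the day-0 breakdown; the only decomposition consistent with that total
   and with sampling three of four plants per cage is 3 baseline replicates
   per biotype on the source cultivar (2·17·3·3 + 6 = 312), taken on wheat
   cv. Newton where the colonies were propagated. This reconstruction is an
   assumption and is flagged as such.
2. **Endosymbiont dominance.** Each sample's endosymbiont fraction is drawn
   from a Beta distribution with mean `endosymbiont_fraction` (default 0.97,
   the overall share typical of *Buchnera* in greenbug surveys) and
   concentration `focal_concentration` (default 25). The concentration is a
   design choice the published account does not constrain; 25 makes 312
   samples span roughly 0.78–0.9999, the per-sample range such surveys
   report. The remaining mass is split among the other taxa by a symmetric
   Dirichlet with parameter `base_concentration` (default 0.5, a sparse,
   uneven community; as the parameter grows the non-focal community becomes
   uniform). Counts are multinomial at a depth drawn uniformly from
   `depth_range` (default 301,562–853,907, a realistic per-sample MiSeq
   range).
3. **Outbreak taxa.** `outbreak_taxa` taxa (default 8) are each assigned one
   uniformly chosen home sample — a single replicate plant within a single
   treatment. The home weight is fixed at 0.2 of the sample's non-focal
   mass, and the leakage weight elsewhere is solved against the realized
   non-focal read masses $(1 - f_s)\,\mathrm{depth}_s$ so that the expected
   share of the taxon's total counts inside its home replicate equals
   `outbreak_restriction` (default 0.95). Solving against realized masses
   rather than expectations matters: with a dominant endosymbiont the
   non-focal mass varies several-fold between samples, and a fixed leakage
   weight would let the restriction drift well below its target whenever
   the home sample happens to draw a high endosymbiont fraction.

All randomness flows from a single integer seed through one sequential
stream, so a fixed seed gives bit-identical tables. What the generator does
**not** emulate: taxonomic identity and phylogenetic signal (trees from
`generate_tree()` are random), spatial or temporal autocorrelation between
timepoints, overdispersion beyond Dirichlet-multinomial, chimeras,
contamination gradients, and any real biotype or cultivar effect — generated
tables are exchangeable across design cells apart from the planted
outbreaks. Passing tests therefore demonstrate the correctness of the
statistical machinery, not biological conclusions about real aphids.

## Preprocessing conventions

* **Order.** Contaminants are removed first, then rare counts, then depth
  normalization, so contaminant removal is never diluted by rescaling.
* **Rare filter.** Within each sample, cells strictly below
  `threshold_fraction` (default $10^{-4}$, i.e. 0.01%) of that sample's
  total are zeroed; the comparison is strict, so a cell exactly at the
  threshold survives. Filtering is per sample, not global, and taxa left
  with no counts anywhere are dropped.
* **Scaling with ranked subsampling.** Each sample is scaled to the target
  depth, integer parts kept, and the residual units assigned one each by
  decreasing fractional part. The cited family of methods permits random
  tie-breaking; here ties go to the larger scaled count, then to the
  earlier taxon, making the operation fully deterministic and hence exactly
  testable. Every output column sums to the target, and a larger input
  count never maps below a smaller one.
* **Rarefaction.** Curves are computed both by Monte-Carlo subsampling
  without replacement (sequential hypergeometric draws; default 10 draws
  per depth) and by the exact expectation
  $E[S_d] = \sum_i \left(1 - \binom{T - n_i}{d}\middle/\binom{T}{d}\right)$,
  evaluated with log-binomials. The exact curve is the oracle for the
  Monte-Carlo one; each sample's curve ends at its own depth.

## Diversity and ordination

Shannon entropy uses natural logarithms (the convention of the vegan
family), so Hill-1 is exactly $\exp(H)$; the identity is tested to machine
precision, and using a different log base would change $H$ but not Hill-1.

UniFrac is computed by a single postorder accumulation of per-edge
descendant abundance. Unweighted UniFrac is unique branch length over
branch length reaching either sample, with edges having no present
descendants excluded. Weighted UniFrac is
$\sum_e b_e\,\lvert p_e^A - p_e^B\rvert$, and the normalized variant (the
default) divides by the abundance-weighted root-to-leaf depth
$\sum_j d_j (p_j^A + p_j^B)$, bounding it in $[0, 1]$; the raw variant is
available by flag since both normalizations circulate in analysis
pipelines. Unweighted UniFrac and the raw weighted form are invariant to
the root position, which is itself tested; on a star tree with unit
branches unweighted UniFrac collapses to Jaccard. The test suite pins the
production traversal against a brute-force per-edge enumeration oracle on
all random trees with up to 6 leaves and against an independent
implementation (phyloseq).

PCoA eigendecomposes the Gower double-centred matrix $-\tfrac12 C D^2 C$;
negative eigenvalues (non-Euclidean metrics) are reported but yield no
axes, with positivity judged against a $10^{-10}$ relative tolerance.
PERMANOVA partitions the sum of squared distances
($SS_\mathrm{total} = \sum_{i<j} d_{ij}^2/n$, within-group analogues per
group) into a pseudo-$F$; on 1-D Euclidean distances this reduces exactly
to the classical one-way ANOVA $F$, which the tests verify. Permutation
p-values use the $(1 + \#\{F_\pi \ge F\})/(1 + B)$ convention with
$B = 999$ by default and are not multiplicity-adjusted. Under a simulated
null the p-values are uniform (checked by a Kolmogorov–Smirnov test over
500 independent runs). For multi-factor designs, `permanova_sequential()`
implements the sequential (Type-I) decomposition in model-declaration order
via the hat-matrix trace formulation on the Gower-centred matrix — the
convention of the distance-based ANOVA programs this field uses — and is
cross-checked against vegan's `adonis2(by = "terms")`.

## Dominance and pathway statistics

`restriction_fractions()` groups samples into treatments
(biotype × cultivar × timepoint; day-0 baselines form their own cells) and
replicates within treatments; for each taxon it reports the largest share
of its total counts inside one treatment and inside one replicate. The
replicate share can never exceed the treatment share (the best replicate
lies inside some treatment) — a property tested on a thousand random
tables. Ratios from `abundance_ratio()` are returned at full precision and
rounded only for display; `count_taxa_above()` uses a strict inequality.
The bundled `greenbug_genus_summary()` table (78 genus-level rows from a
published greenbug survey) drives the worked dominance examples: a 196-fold
*Buchnera*/*Pseudomonas* ratio, an 840-fold *Buchnera*/*Rhodanobacter*
ratio, and 15 genera above 10,000 total counts.

Pathway tables (as produced by functional-inference tools run upstream) are
ranked by summed count, descending, with ties broken lexicographically by
pathway id — determinism the source description does not specify but
testing requires. A pathway is "absent" from a subset if it has no row or a
zero count; `lost_pathway_summary()` counts pathways present in the rest of
the community but absent from the focal taxon, overall and among the $k$
lowest-ranking pathways, where genome-reduced endosymbionts lose
disproportionately.

## Problem sizes and limitations

The test suite and the acceptance script run at deliberately modest sizes —
200 replicate simulations of 1,000 taxa for the bias experiment, count
tables of tens of taxa and tens to hundreds of samples, 199–999
permutations — which a laptop completes in well under a minute while
keeping Monte-Carlo standard errors small relative to every tolerance
used. Known limitations: the generator's exchangeability means PERMANOVA
on generated tables has no real effects to detect (only calibration is
testable); `analytic_mad()` is an approximation below $N \approx 20$; the
sequential PERMANOVA permutes raw labels rather than residuals, matching
the default of the reference implementation but not the
residual-permutation variants; and weighted-UniFrac normalization is
root-dependent by construction, so normalized values should be compared
only across a fixed rooted tree.
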
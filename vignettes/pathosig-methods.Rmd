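---
title: "Methods: pan-pathogen array signatures and viral integration detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-pathogen array signatures and viral integration detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathosig)
```

pathosig analyses two kinds of data from pan-pathogen screens of tumour
tissue: two-channel microarray intensities from a probe set covering
viruses, bacteria, fungi and parasites (plus human reference probes), and
targeted capture-sequencing reads used to locate viral integrations in
the host genome. This vignette describes the statistical model behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical
conventions the implementation commits to.

## Two-channel normalization

Each array hybridizes the sample (green, Cy3) against a common reference
(red, Cy5). Probe intensities are put on a common scale per array via the
human reference probes, which should light up equally in both channels up
to a global channel imbalance. The scale factor of sample $j$ is

$$ s_j = \frac{\sum_{p \in \mathrm{human}} g_{pj}}{\sum_{p \in \mathrm{human}} r_{pj}}, $$

the ratio of summed green to summed red human-probe intensity, and the
normalized signal of every non-human probe is

$$ n_{pj} = \log_2(g_{pj} + \varepsilon) - \log_2(s_j\, r_{pj} + \varepsilon). $$

Two choices here were genuinely open:

* **Ratio of sums vs mean of ratios.** "Sum of green over sum of red
  ratios" can be read either way; `compute_scale_factor()` defaults to the
  ratio of sums because it degrades gracefully when individual red
  intensities approach zero, and exposes the mean-of-ratios variant via
  `method = "mean-of-ratios"`.
* **Pseudocount.** Microarray exports can contain zero intensities and
  the log-ratio is undefined there. A pseudocount of $\varepsilon = 1$
  intensity unit (configurable, `eps`) is added inside both logarithms; at
  typical intensities of $2^{10}$ it perturbs $n$ by about $10^{-3}$ log2
  units. Identity checks in the test suite use `eps = 0`, where
  $g = s\,r$ gives exactly $n = 0$.

A useful invariance follows from the construction: multiplying one
sample's entire green (or red) channel by any $c > 0$ moves $s_j$ by the
same factor and leaves every $n_{pj}$ unchanged. The test suite asserts
this numerically for random $c$.

## Signature detection

Detection is probe-wise and asymmetric between the cancer and control
directions, mirroring how screens of this design are read out:

* **Cancer side.** For every non-human probe, a two-sample t test of the
  cancer samples against the pooled (matched + non-matched) controls on
  the normalized signal; Benjamini–Hochberg adjustment across all tested
  probes; a probe is detected when the adjusted $p < \alpha$ **and** the
  log2 fold change exceeds $\lambda$. Defaults $\alpha = 0.05$,
  $\lambda = 0.5$ log2 units.
* **Control side.** Each control group is tested separately against the
  cancer samples, and detection uses the *nominal* $p < \alpha$ with the
  same fold-change gate and no multiple-testing correction. Control-side
  hits are therefore suggestive only — the adjusted values are still
  computed and returned so users can apply the stricter rule.

The t statistic is Welch's (unequal variance), computed row-wise for
speed; `var_equal = TRUE` restores Student's form. The pooled-versus-
individual composition of real sample sets makes equal group variances
implausible, which is why Welch is the default. Degenerate probes are
resolved by convention: both groups constant and equal gives $t = 0$,
$p = 1$; constant but unequal gives $p = 0$; fewer than two observations
in a group gives `NA` and exclusion.

The conjunctive gate matters for calibration: under a complete null the
BH step already bounds the expected false-discovery proportion by
$\alpha$, and the fold-change gate only removes rejections. The null
calibration (50 replicates at the default generator conditions) is
recomputed by `analysis/06_null_calibration.R` and by
`scripts/acceptance.R`.

## Prevalence

Prevalence is the percentage of a group's samples in which a detected
taxon is present, independent of intensity, rounded half away from zero
to an integer (matching the convention of printed percentages such as
10/11 → 91). The per-sample presence rule is not fixed by the assay, so
`compute_prevalence()` exposes two:

* `"mean"` (default): a taxon is present in a sample when the mean
  normalized signal of its detected probes exceeds $\theta$.
* `"any"`: one detected probe above $\theta$ suffices.

The default is the mean rule because the any-probe rule's per-sample
false-presence probability grows with the number of probes per taxon
(with 10 probes and noise sd 0.5 it approaches 0.8 at $\theta = 0.5$),
which destroys the correspondence between planted and recovered
prevalence that the generator-based tests verify. $\theta$ defaults to
0.5 — presence means the taxon's signal exceeds the reference channel by
the same margin as the fold-change gate. Per-probe prevalences are
attached to the result for transparency.

## Aggregation and set comparison

Taxon- and family-level summaries average `mean_case` over the unit's
detected probes; group-level totals sum the family averages (the "sum of
average hybridization signals" convention of group-level bar summaries),
and tables are ordered by descending signal. The per-kingdom signature
sets detected in cancer, matched controls and non-matched controls are
partitioned into the seven disjoint regions of the three-set Venn
diagram; names are matched case-insensitively after trimming and stored
as given. Integer percentages (phylum distribution over everything
detected in cancer; tumorigenic fraction of cancer-detected viral
families against the six families Retroviridae, Hepadnaviridae,
Papillomaviridae, Flaviviridae, Polyomaviridae, Herpesviridae) round half
away from zero.

The packaged membership fixture transcribes the published table of
signatures per kingdom and membership column. One edit was required: the
printed table lists the genus *Campylobacter* under both the cancer-only
and the NC-only columns, which contradicts the partition semantics and
the printed counts (52 cancer-only, 5 shared cancer/NC); the fixture
keeps it cancer-only, consistent with the printed counts.

## Clustering

Samples are clustered on the normalized signal matrix with Euclidean
distance and complete linkage, deliberately without further
standardization ("non-adjusted" signals); per-probe z-scoring is
available behind `scale = TRUE` but off by default. The number of
clusters is chosen by the Calinski–Harabasz index

$$ \mathrm{CH}(k) = \frac{\operatorname{tr}(B)/(k-1)}{\operatorname{tr}(W)/(n-k)} $$

maximized over $k \in \{2, \dots, \min(10, n-1)\}$ (first maximum on
ties). A clustering with zero within-cluster scatter returns `+Inf` as a
documented sentinel. Agglomeration is delegated to `stats::hclust`,
whose tie handling is deterministic; the CH computation and its
brute-force scatter-matrix cross-check are both part of the test suite.
Cluster contrasts reuse the Welch test per taxon aggregate between each
pair of clusters with at least two samples, BH-adjusted within the pair.

## Integration calling

The virus-fusion procedure keeps the virus genome as the primary
alignment target: reads are locally aligned to the viral metagenome
(Smith–Waterman scoring: match +1, mismatch −2, gap open −3, gap extend
−1, a length-$L$ gap costing $3 + L$); terminal soft-clipped segments of
at least `min_clip = 20` bases are extracted and remapped to the host
genome; a uniquely mapped clip yields one breakpoint pair — the terminal
virus-aligned base and the host base adjacent to the junction — at
single-base resolution. Calls agreeing within `merge_radius = 5` bp on
both coordinates are merged with support summed (the modal coordinate,
smallest on ties, represents the cluster). Every suppressed read is
logged with a reason.

Numerical and design choices:

* **Seeded alignment.** Aligning every read exhaustively against every
  reference is quadratic and unnecessary; reads are seeded with exact
  13-mers and the dynamic programme runs in windows around seed
  diagonals (both strands; a minus-strand hit flips the read into the
  reference orientation before clip extraction). The windowed scores are
  checked against an exhaustive quadratic reference in the tests.
* **Clip remapping filters.** A clip mapping must cover ≥ 90% of the
  clip at ≥ 95% identity over aligned columns, and is suppressed as
  ambiguous when a second, distinct host locus scores within 2 score
  units of the best — single-base claims require unique placement.
* **Junction microhomology.** When the host sequence at the junction
  continues the viral sequence (exactly or with a net-positive alignment
  score), any local aligner extends through the junction and both
  breakpoints shift by the homology length; such junctions are not
  single-base resolvable from read evidence. The read simulator warns
  when asked to plant one, and `sample_integration_sites()` draws
  homology-free sites for exact-recovery experiments.
* **Gene context.** A breakpoint inside an exon is exonic; inside a gene
  but not an exon, intronic; otherwise the nearest gene within
  `window = 100000` bp (100 kb, the distance within which upstream
  perturbation plausibly affects expression) classifies it upstream or
  downstream *relative to the gene's strand*, with the distance in bp;
  beyond the window it is intergenic.
* **Minimum support.** All calls are reported with their support count;
  no support threshold is imposed, so users filter downstream.

Capture validation counts aligned reads over capture-probe BED regions:
a read counts for the region with the largest overlap (≥ 1 bp; ties to
the lowest region start) and for at most one region. Externally produced
viral alignments can be supplied as SAM, bypassing the built-in aligner.

## Synthetic data

The array generator plants a known truth: green intensity
$2^{\mathrm{ref} + n^\ast + e}$ with $e \sim N(0, \sigma)$ on the log2
scale, red intensity $2^{\mathrm{ref}}/s^\ast$, so that the planted
per-sample scale factor $s^\ast$ is exactly recoverable from the
(noiseless by default) human probes and the planted normalized signal
$n^\ast$ is the baseline plus a group effect $\delta$ for planted taxa in
exactly `round(prevalence_target * n_group)` samples of their group. The
default conditions are a desk-scale version of a real screen: 2,000
non-human probes, 100 human probes, 20 cancer / 10 matched / 10
non-matched samples, noise sd 0.5 log2 units, $s^\ast = 1.5$. Gaussian
noise on the log2 scale (log-normal intensities) matches the scale on
which the analysis operates; the generator does not model FFPE
degradation, amplification bias, spatial artefacts, probe
cross-hybridization or correlated noise, so passing tests demonstrate
the statistical machinery, not robustness to those artefacts.

The read generator emits uniform-random references (3 viruses × 8 kb, 2
host chromosomes × 100 kb by default), non-overlapping genes with 1–3
exons, capture regions on the viral references, and 250-nt single-end
reads: chimeric junction reads whose split point lies at least
`min_anchor = 30` bases into the virus side (so every spanning read
clears the aligner's score threshold) and at least `min_clip = 20` bases
from the host end, among pure-host and capture-enriched pure-virus
background, each read reverse-complemented with probability 1/2 and
substituted at a configurable error rate. Real reads are paired,
quality-banded and repeat-ridden; none of that is emulated, which is why
the specificity figures from random backgrounds are upper bounds.

Both generators are deterministic given their mandatory seed (R's
default Mersenne-Twister, no platform- or locale-dependent state), and
their truth tables are sufficient to score every downstream module.

## Problem sizes

The test suite and the analysis drivers run at deliberately small sizes
chosen so the whole battery completes in minutes on one CPU: null
calibration at 50 replicates of the default 2,000 × 40 design; cluster
recovery over 100 seeds of 24 samples × 10 features; integration
recovery over a handful of seeds with 4–6 planted sites; specificity on
10,000 background reads. These sizes are stated here as the package's
own reproducible conditions.

## Known limitations

* Detection treats each array as one observation; pooled arrays are not
  weighted by pool size (the pooling composition is not modelled).
* The control-side rule is intentionally liberal (nominal p); its hits
  carry no FDR guarantee.
* Breakpoints inside repeated host sequence are suppressed as ambiguous
  rather than rescued by paired-end or split-read co-evidence; the
  caller uses soft-clip evidence only.
* The CH index is computed on the full normalized matrix; no feature
  selection precedes clustering.
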
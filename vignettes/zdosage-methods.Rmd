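---
title: "Detecting germline Z-chromosome dosage states from single-nucleus multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting germline Z-chromosome dosage states from single-nucleus multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdosage)
```

## The question and the measurement model

In ZW species the female carries a single Z. Genes in the fully
differentiated stratum of the Z (here called S0) have no expressed W
homolog, so in the absence of any regulation their expression should sit
at half the diploid autosomal level; dosage compensation would restore
it to parity, and meiotic sex-chromosome inactivation (MSCI) would push
it far below one half. `zdosage` quantifies where each nucleus sits on
this axis using a per-cell ratio statistic:

$$ r_c \;=\; \frac{\tfrac{1}{|S_0|}\sum_{g \in S_0} x_{cg}}
                 {\tfrac{1}{|A|}\sum_{g \in A} x_{cg}}, $$

where $x_{cg}$ are size-normalized counts, $S_0$ is the fixed inventory
of S0 genes and $A$ the fixed inventory of autosomal genes. Means are
taken over the *full* gene inventories, zeros included: the statistic
compares compartment-level transcriptional output, not detected-gene
averages, and dropout then affects numerator and denominator alike.

Because library composition differs between cell types, raw ratios are
anchored to a somatic baseline assumed to be fully compensated: all
cells receive the constant offset $1 - \mathrm{median}(r_c\,|\,c\
\text{somatic})$, so the somatic median is exactly 1 and a germline
value of 0.5 reads directly as a two-fold reduction. The offset is
additive (not multiplicative) so that the adjusted somatic median is an
exact identity; for somatic medians near 1 the two conventions are
numerically indistinguishable.

Adjusted ratios are classified into three regimes:

* **DC** (complete or partial dosage compensation): ratio > 0.66;
* **LACK** (no compensation, single-copy expression): 0.33 < ratio ≤ 0.66;
* **REPRESSED** (below single-copy, consistent with MSCI): ratio ≤ 0.33.

Both boundaries are inclusive downward. The fixed cutoffs bracket the
single-copy expectation of 0.5 symmetrically on the ratio scale (2/3 and
1/3). The percentile scheme replaces 0.66 by the 5th percentile of the
somatic adjusted ratios — imposing a 5% false-positive rate on the DC
call among somatic cells — and uses half that value as the repression
boundary. Percentiles use linear interpolation between order statistics
(R's default type 7), the convention of the surrounding single-cell
toolchain; conventions differ enough across software that this choice is
worth stating. Computed cutoffs are reported at full precision rather
than rounded.

Cluster-level enrichment of a zone is tested with a Pearson chi-square
contingency test on the 2×2 table (zone vs all other zones) ×
(target cluster vs pooled somatic clusters). No continuity correction is
applied by default and no multiple-testing adjustment is made; raw
p-values are annotated with the conventional 0.001/0.01/0.05 stars. A
Yates flag exists because common toolchains silently apply the
correction to 2×2 tables, which matters when comparing printed p-values
across software.

## Normalization scale

Ratios default to linear size-normalized values (`SIZE`): each cell is
scaled to a fixed total (10,000 by default). On the linear scale a ratio
of 0.5 literally means a two-fold reduction, which is the scale on which
the 0.66/0.33 cutoffs are meaningful. Log-normalized values
(`LOG_SIZE`, $\log(1+x)$) are available because many pipelines store
only that slot, but log compression shifts ratio distributions and the
fixed cutoffs were not designed for it; the linear mode is the default
for that reason.

## Controls against sparsity artifacts

Low per-cell depth could depress the S0 mean simply because 446 genes
are a small panel. Two controls address this:

* **Gene windows.** Autosomal genes are position-sorted and chunked into
  non-overlapping windows of exactly 446 genes (the S0 panel size);
  `floor(N/446)` full windows are kept and the remainder dropped. The
  per-cluster median of mean(S0)/mean(window) across windows should
  reproduce the all-autosome ratio if the S0 signal is not a small-panel
  artifact. With the full 26,439-gene autosomal inventory this chunking
  yields 59 windows; published analyses of this design report 49, which
  implies an additional, unstated gene filter upstream — the package
  implements the plain floor-division rule and does not guess the
  filter.
* **Permutation null.** Relabelling 446 random autosomal genes as a
  pseudo-S0 and re-running the ratio + adjustment produces a germline
  median within a few percent of 1 (the adjustment is computed with the
  same pseudo-panel, so panel-level rate noise cancels); sparsity alone
  does not generate the repression signal. This is exercised in the test
  suite on simulated data.

## Chromatin accessibility

ATAC fragments are pooled into pseudo-bulks (per cluster, or per
cluster × expression zone) and counted in 500-kb windows tiling every
chromosome half-open from 0; the trailing partial window is kept (a flag
can drop windows shorter than half the window size). Each window takes
the compartment of the region-map span covering its midpoint, and each
fragment is assigned once, to the window containing its midpoint —
single assignment avoids double counting across window boundaries; the
any-overlap alternative differs only for the ~0.04% of 200-bp fragments
straddling a 500-kb boundary.

Per pseudo-bulk, window counts are placed on a comparable scale by
subtracting the median log2 autosomal window:
`adjusted = log2(count) − median(log2(autosomal windows))`. Zero-count
windows are excluded from both the median and the output rather than
pseudocounted: this keeps the adjusted autosomal median exactly 0 and
makes −1 exactly a two-fold decrease (the reference line used for
single-copy accessibility). Compartment shifts are tested with a
two-sided Wilcoxon rank-sum test across windows.

## Transcriptional shutdown metrics

Late meiotic prophase is expected to show global transcriptional
quiescence: low total RNA, collapsed ATAC counts in peaks, and a high
*spliced* fraction (little nascent, intron-containing RNA). The package
consumes spliced/unspliced layers produced upstream (read-level
assignment is out of scope), pools them per cluster, and tests
composition shifts (target cluster vs all others pooled) with the same
chi-square machinery. Per-cell totals and counts-in-peaks are exported
for rank tests and plotting. The 2×2 pooled-count test treats UMIs as
independent draws; within-cell correlation makes it anticonservative in
absolute terms, which is the convention the surrounding literature uses
and why the package reports the table alongside the p-value.

## The statistical tests

Both tests the analysis relies on are implemented in the package and
verified against independent oracles in the test suite:

* `chi_square_test()`: Pearson statistic, `df = (r−1)(c−1)`, upper-tail
  chi-square p; optional Yates correction for 2×2.
* `wilcoxon_test()`: rank-sum with midranks for ties. `EXACT` mode
  enumerates all `choose(n+m, n)` arrangements of the pooled midranks
  (feasible when `min(n, m) ≤ 10` and ≤ 1e6 arrangements; the null
  distribution is cached, as untied samples of the same sizes share
  one distribution) and returns
  `min(1, 2 × min(tail masses including the observed value))`. `NORMAL`
  mode uses the tie-corrected normal approximation with continuity
  correction; `AUTO` prefers `EXACT` when feasible. At `n = m = 10` the
  two modes agree within 0.02 absolute, and both hold the nominal 5%
  size within Monte-Carlo error in the suite's null simulations.

## What the simulator emulates — and what it does not

The generator produces paired snRNA/snATAC data with known per-cell
dosage regimes so every downstream stage can be checked against ground
truth:

* **Gene rates**: gamma-distributed (shape 2 by default), then rescaled
  to unit mean *within each compartment*. The rescaling is deliberate:
  it makes the configured dosage factor exactly the generative
  S0:autosome ratio, so recovery tests have an exact target instead of
  one blurred by the sampling noise of a 446-gene panel.
* **Cells**: depth is log-normal around the cluster mean (sdlog 0.35 by
  default), counts are Poisson given depth. The depth mixture already
  induces overdispersion at the gene level while keeping the generative
  expectation analytic; a negative-binomial hook was considered and left
  out for that reason.
* **Dosage regimes**: each cell draws a zone from its cluster's
  probabilities; the zone's factor (defaults 1.0 / 0.5 / 0.15 for
  DC / LACK / REPRESSED) multiplies S0 gene rates. PAR, S1 and S2 retain
  W homologs and are left at the diploid rate by default
  (configurable); W genes are always at single-copy (0.5×) rate, and W
  never enters ratio denominators.
* **Ambient RNA**: with probability `ambient_fraction` (default 5%) a
  UMI is replaced by a draw from the pooled population profile,
  approximating droplet contamination. Ambient contamination pulls
  germline ratios toward the population mixture — with the default 5%
  the LACK median moves from 0.50 to roughly 0.52 — so ground-truth
  recovery analyses in the acceptance script use a contamination-free
  configuration, while pipeline-level tests keep the 5% default.
* **ATAC**: per-cell fragment counts are Poisson around the cluster
  mean; fragment midpoints land in compartment spans with probability
  proportional to span length × the zone's accessibility factor
  (defaults 1.0 / 0.5 / 0.5) applied to all Z strata, with W at half
  rate. Fragment length is fixed at 200 bp and support counts are
  1 + geometric, so support-weighted counting is exercised.

Not emulated: doublets, batch/replicate effects, peak structure (ATAC
fragments are compartment-scaled background, so peak-level analyses are
exercised only mechanically), gene-length effects, UMI saturation, and
cell-type marker structure. Passing recovery tests therefore shows that
the *statistics* behave as designed under the assumed noise model, not
that the upstream clustering or contamination removal of a real dataset
is sound.

## Default study conditions

The default cluster panel mirrors the ovary-atlas setting the method
targets: three fully compensated somatic clusters (follicle, tracheal,
ovarian muscle; depth ~8,000–9,000 UMIs), an early germline cluster
(depth 6,000; zones 0.70/0.28/0.02) and a late germline cluster with
collapsed depth (1,200 UMIs), a low unspliced fraction (5%), few ATAC
fragments, and zones 0.28/0.55/0.17. Gene inventories default to 5,000
autosomal, 446 S0, 300 PAR, 100 S1, 100 S2 and 20 W genes — the S0
panel size matches the real annotation; the autosomal inventory is
scaled down from 26,439 to keep simulations fast while leaving the
denominator mean far more precise than the numerator's.

Recovery checks in the test suite use 1,000–2,000 cells per cluster at
5,000 UMIs: at that depth the per-cell ratio has a coefficient of
variation of ~7%, so cluster medians are estimated to well under one
percentage point and zone proportions to ~1 point — comfortably inside
the ±3–4 point bands the tests assert.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open (BED) everywhere; GFF-style input
  must be shifted on read.
* Cells with zero total counts are dropped with a warning during
  normalization (strict mode turns this into an error); cells with a
  zero autosomal mean get an undefined ratio, are reported, and are
  excluded from medians, classification and proportions.
* Zone boundaries are assigned by the stated inequalities (`>` for DC,
  `≤` for REPRESSED), so values exactly at a cutoff fall downward.
* Clusters with no defined-ratio cells are omitted from proportion
  tables with a warning; zones with no cells are omitted from zone
  pseudo-bulks with a warning.
* All generator randomness flows from one seed (`seed`, `seed + 1`,
  `seed + 2` for expression, layers, fragments), so a fixed seed makes
  every pipeline output byte-identical across runs.

## Known limitations

* The per-cell ratio is a compartment-mean statistic; a few highly
  expressed S0 genes dominate it, as they do the underlying biology.
* The somatic-median adjustment assumes somatic cells are fully
  compensated; if they are not, the anchor shifts all calls.
* The additive adjustment can produce adjusted ratios slightly below 0
  for extreme cells; classification treats them as REPRESSED, which is
  the intended reading.
* The fixed 0.66/0.33 cutoffs are calibrated for the linear
  normalization scale and should not be reused on log-scale ratios.
* Chi-square enrichment treats cells (or pooled UMIs) as independent;
  replicate structure is carried in the metadata but not modeled.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
run <- pipeline_config(outdir = "zdosage_run", simulate = cfg)
res <- run_pipeline(run)
res$proportions
res$enrichment
```

The same stages are exposed individually (`simulate_expression()`,
`normalize_counts()`, `compartment_ratio()`, `somatic_adjust()`,
`classify_fixed()`, `zone_proportions()`, `enrichment_test()`,
`tile_genome()`, `count_fragments()`, `adjust_log2()`,
`zone_pseudobulks()`, `splice_summary()`), and every table the pipeline
writes is also returned in memory.
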
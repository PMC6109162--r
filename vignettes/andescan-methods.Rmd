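---
title: "Methods: windowed PBS selection scans with coalescent nulls and haplotype statistics"
author: "andescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed PBS selection scans with coalescent nulls and haplotype statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

`andescan` implements a selection scan for a three-population design: a
focal highland group (Andean) contrasted against two lowland groups
(Amazonian and Mesoamerican), with the topology
((Andean, Amazonian), Mesoamerican) — the sister pair split more recently
than either did from the outgroup.  Under drift alone the sister groups are
the most similar pair; a locus where the highland group alone has shifted
strongly is a candidate for local adaptation (here, to high-altitude
hypoxia).  The package covers the full analysis chain: per-SNP and windowed
Population Branch Statistic (PBS), empirical outlier peaks with
nearest-gene assignment, coalescent-simulation significance under three
demographic models, EHH/iHS/XP-EHH haplotype statistics, bootstrap
confidence intervals for sample-size-weighted allele frequencies, and
inverse-distance-weighted (IDW) geographic frequency surfaces, plus a
synthetic-data generator so every stage is testable without restricted
genotype data.

# Population Branch Statistic

For each SNP the three pairwise FST values are transformed into additive
branch lengths, $T = -\log(1 - F_{ST})$, and the focal branch is

$$\mathrm{PBS} = \frac{T_{AM} + T_{AA} - T_{MA}}{2},$$

where $A$, $M$ and the second subscript letters denote the Andean,
Mesoamerican and Amazonian groups.  Negative PBS (drift concentrated on the
outgroup branch) is retained as-is; FST is clamped to $[0, 1 - 10^{-9}]$
only inside the log transform.

FST uses the Reynolds (1983) coancestry moment estimator $a/(a+b)$ from
group-pooled allele counts: with haploid counts $m_i$, frequencies $p_i$,
and the pooled within-population heterozygosity
$\bar h = (m_1 h_1 + m_2 h_2)/(m_1 + m_2 - 2)$ (where $h_i = 2 p_i (1 -
p_i)$),

$$a = (p_1 - p_2)^2 - \bar h \frac{m_1 + m_2}{2 m_1 m_2}, \qquad b = \bar h.$$

$a$ is an unbiased moment estimator of $2\theta p(1-p)$ under the
pure-drift coancestry model and $a + b$ of $2p(1-p)$, so the ratio
estimates the coancestry $\theta$.  For equal sample sizes this coincides
exactly with the Hudson estimator in the Bhatia et al. parameterization;
both Hudson and the Weir–Cockerham haploid ANOVA form are available via
the `estimator` argument.  Group-pooled counts (rather than averaging
per-population FST within groups) are the default, and missing genotypes
shrink the chromosome count SNP-wise.

Windows hold exactly 20 SNPs and advance by 5; they restart at chromosome
boundaries and a trailing remainder is dropped rather than shrunk.  Outlier
thresholds are type-7 (linearly interpolated) empirical percentiles of the
window means over the whole scan, at the 99.5th and 99.9th tiers.  Runs of
outlier windows with overlapping or touching SNP spans merge into one peak;
each peak reports the SNP with the maximum per-SNP PBS in its span and that
SNP's nearest gene (distance 0 inside an interval, ties broken by smaller
interval start).  Only SNPs polymorphic in at least two of the three groups
enter the scan.

# The coalescent null

Significance is assessed against a structured coalescent with no
migration, one segregating site per replicate.  Three demographic presets
are shipped (diploid effective sizes):

* **constant** — Ne 7,000 everywhere;
* **bottleneck** — Ne 8,000 (Mesoamerican), 4,000 (Andean), 2,000
  (Amazonian), ancestors at 8,000;
* **bottleneck_expansion** — the bottleneck model with all three sampled
  populations halved between 10,000 and 8,000 years BP and then expanded
  tenfold (relative to the bottlenecked size) to the present.  The
  expansion factor is a package parameter because no canonical magnitude
  exists for a "sharp expansion"; 10x is the default.

Splits are fixed at 12,000 yBP (Andean/Amazonian) and 15,000 yBP
(continental peopling, the Mesoamerican divergence), reconciling the three
colonization dates with the sister topology: the Amazonian date of 10,000
yBP is used as the bottleneck onset in the third model rather than as a
split.  Years convert to generations at 25 y/generation (configurable).
The ancestral size is 7,000 in the constant model and 8,000 (the
Mesoamerican value) before the splits otherwise.

Each replicate draws a genealogy (pairwise coalescence at rate
$\binom{k}{2}/2N_e(t)$ per generation within each population, lineages
merging at split times), places one mutation on a branch chosen
proportionally to branch length, and applies the same
polymorphic-in-two-groups filter as the empirical scan (failing replicates
are redrawn and counted).  PBS from the replicate counts forms the null;
the simulation p-value of an observed value is the conservative add-one
rank $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n + 1)$, so $10^{-4}$ is
the floor at 9,999 accepted replicates.

Two numerical notes, both consequences of single-site conditioning:

* The derived-allele count distribution is $E[L_i/L_{tot}]$, not the
  mutation-process spectrum $E[L_i]/E[L_{tot}] \propto 1/i$; weighting
  replicates by total tree length recovers the analytic spectrum, which is
  how the engine is validated.
* Allele-count configurations recur, so the null has atoms and the
  conservative p-value is stochastically *super*-uniform under the null.
  Calibration is therefore checked on the randomized
  probability-integral-transform (`empirical_pvalue(ties = "randomized")`),
  which is exactly uniform; reported scan p-values keep the conservative
  formula.

The bulk engine is compiled (Rcpp); a pure-R single-tree sampler with the
same event logic (`sample_coalescent_tree`) serves as the readable
reference and both are checked against analytic expectations
($E[T_2] = 2N_e$, two-population $E[F_{ST}] \approx 1 - e^{-t/2N_e}$) and
against an independent coalescent simulator (msprime) distributionally.

# Haplotype statistics

EHH at a flanking SNP is the probability that two random carriers of the
core allele are identical over the stretch from core to flank inclusive:
partition the $n$ carriers into extended-haplotype classes of sizes $e_i$
and compute $\sum_i \binom{e_i}{2} / \binom{n}{2}$.  Successive partition
refinement makes curves non-increasing by construction.  iHH integrates
the curve over physical distance by trapezoids, truncated at the first
flank below 0.05 (that segment included) and at inter-SNP gaps above
200 kb (that segment excluded); a side that never decays is integrated to
the data end and flagged censored.  These defaults follow common
EHH-toolkit conventions.

iHS is $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, standardized within
derived-allele-frequency bins (20 equal-width bins; strata with fewer than
20 scored SNPs merge with their neighbor, because standardizing against
moments estimated from a handful of SNPs injects spurious tails).  SNPs
with minor-allele frequency below 0.05, fewer than two carriers of either
allele, or no ancestral/derived polarization are skipped with a recorded
reason.  XP-EHH compares populations: EHH is computed over *all*
haplotypes at the site per population, and
$\ln(\mathrm{iHH}_{test}/\mathrm{iHH}_{ref})$ is standardized genome-wide;
positive standardized values mean extended homozygosity in the test
(highland) population.  XP-EHH p-values default to the one-sided empirical
rank $p = \#\{\text{scores} \ge s\}/(N+1)$; a standard-normal upper tail
is available behind `method = "normal"`.  The empirical default was chosen
because published score/p-value pairs of this analysis type are not
consistent with a normal tail; both options are exposed.

# Frequencies, bootstrap, geography

Group frequencies are sample-size-weighted means over the member
populations, $\sum n_i p_i / \sum n_i$, which for counts drawn from one
genotype matrix equals the pooled-count frequency.  The lowland bootstrap
resamples individuals with replacement *within* each population
(preserving each population's size and observed genotypic proportions),
recomputes the weighted group frequency, and takes the 2.5th/97.5th
percentiles of 10,000 replicates as the 95% CI.  Altitude classification
exposes both conventional cutoffs — 4,000 m for the highland/lowland
bootstrap contrast and 2,500 m as the descriptive lowland bound — without
guessing either to be an error.

IDW surfaces interpolate per-population frequencies over a lat/lon grid
with weights $d^{-2}$ (power 2, the common GIS default) using great-circle
(haversine) distances; only populations with at least 3 samples
contribute, a cell within a meter of a sample point takes that point's
value exactly, and the output is a plain raster table rather than a map
(cartography is out of scope).

# The synthetic-data generator

The generator emulates the study design: 63 Andean, 106 Amazonian and 153
Mesoamerican diploids, split over plausible sub-populations so bootstrap
weighting is exercised.  Ancestral frequencies are drawn from a
Beta(0.8, 0.8) truncated to [0.05, 0.95], mimicking SNP-array
ascertainment toward common variants; group frequencies then follow a
hierarchical Balding–Nichols model whose per-branch drift
$F = 1 - e^{-t/2N_e}$ integrates the chosen demographic preset's epochs
over each branch, respecting the sister topology.  A coalescent backend
(delegating to the null engine, alleles assigned exchangeably to
chromosomes) provides the same interface.  The two backends produce
closely matching per-SNP and window PBS null distributions (window 99.5th
percentiles 0.0446 vs 0.0463 in an 8,000-SNP comparison), which is the
generator's main calibration check.

Sweeps are injected, not simulated forward: `inject_sweep` redraws a single
target SNP binomially (defaults 0.40 highland vs 0.05 lowland, the
magnitude of the study's reported frequency contrasts) and touches nothing
else; the haplotype generator additionally plants one founder haplotype
shared by all carriers across a core interval (default 600 kb) with sparse
mutations, which is what the EHH statistics respond to.  Neutral
haplotypes are mosaics over a 12-founder panel with geometric block
lengths (mean 30 kb over a mean SNP spacing of 10 kb), so background LD
decays with distance.  Mosaic copying is deliberately simpler than a
coalescent with recombination: it suffices to test directionality and
calibration of the haplotype statistics, while the coalescent oracle is
reserved for the genealogy engine.

What passing tests on these fixtures do *not* show about real data: no
ascertainment correction is inferred (the spectrum is a stand-in), there
is no missingness model beyond what the user injects, linkage is
block-exchangeable rather than genealogical, and sweeps carry no partial /
soft-sweep structure.

# Problem sizes and determinism

Default test and acceptance runs use 1,000–5,000 SNP panels, 10,000-
replicate nulls and bootstraps, 20-replicate recovery studies, and
500-dataset coverage studies; these sizes make every distributional check
stable while keeping a full run in minutes.  The pipeline derives each
stage's seed from the master seed by hashing the stage name, so a rerun of
`run_full_scan` with the same configuration is byte-identical, and the
YAML manifest records the resolved configuration (no timestamps, by
design).

# Known limitations

* **Windowed recovery of a single-SNP sweep signal is intrinsically
  partial.**  At the study's sample sizes the injected 0.40-vs-0.05
  contrast realizes PBS $\approx 0.43 \pm 0.08$, contributing only
  $\approx 0.022$ to a 20-SNP window mean, while the genome-wide window
  99.5th percentile sits near 0.045 over a mean of 0.017 under the very
  same null — so the sweep window clears the empirical threshold in
  roughly half of replicates, not reliably.  Real hard sweeps are lifted
  by hitchhiking across the window; with hitchhiking genotypes the window
  is flagged, but the target SNP is then often out-ranked *within* the
  peak by hitchhikers whose background alleles are rarer in the lowland
  groups — which is exactly why scans report the top SNP per window
  without asserting it is the causal site.  The acceptance suite states
  the stricter single-SNP expectation and records the measured rate.
* **Formal normality of standardized iHS fails at scale.**  On neutral
  mosaic fixtures the standardized scores are symmetric (|skew| < 0.1)
  with mild excess kurtosis ($\approx 3.5$), a discrete-mixture footprint
  of the finite founder panel; a Shapiro–Wilk test at ~1,500 scored SNPs
  is powered to reject this visually Gaussian shape.  Per-stratum
  centering and scaling are exact and asserted.
* The null has no migration and no recombination (single site), as in the
  modeled study design; both would thicken the null's tails.
* Real unphased genotypes are not phased by the package; haplotype
  statistics require phased input (the generator supplies it).
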
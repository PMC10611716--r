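---
title: "Models and methods behind qgikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qgikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgikit)
```

qgikit implements three statistical pipelines that together cover the
computational side of a chemical-genetic study of N-terminal
acetyltransferase (NAT) biology: quantitative genetic-interaction (qGI)
scoring of pooled genome-wide CRISPR knockout screens, quantification of
N-terminal acetylation degrees from positional proteomics, and
Perseus-style differential protein abundance testing. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where the methodology was genuinely open.

## Quantitative genetic-interaction scoring

### From read counts to fold-changes

A pooled knockout screen measures, for every guide RNA, how its abundance
changes between infection (T0) and the screen endpoint. Counts are
normalized to counts per million with a pseudocount:

$$\mathrm{cpm}_{gs} = \frac{c_{gs}}{\sum_g c_{gs}} \times 10^6 + 0.5,$$

so zero counts remain finite in log space. Guides whose mean raw T0 count
across a screen's technical replicates falls outside $[40, 10000]$ are
removed: below 40 reads the fold-change is dominated by sampling noise,
above 10,000 the guide is usually an amplification artifact. The bounds
are inclusive and configurable; a `t0_filter_mode` switch selects whether
the mean (default), every replicate (`all`), or any replicate (`any`) must
be in range, because per-replicate versus pooled filtering is an
implementation detail that upstream descriptions of this scoring scheme
leave open.

Guide-level log2 fold-changes $\log_2(\mathrm{cpm}_{T_{end}} /
\mathrm{cpm}_{T_0})$ are computed per technical replicate — paired by
replicate index, or against the mean T0 profile when replicate counts
differ, since the T0 pool is typically sequenced once and split — and then
averaged across replicates.

### Residuals against a wild-type panel

A genetic interaction is a deviation of the double-mutant fitness from the
single-mutant expectation. The single-mutant expectation comes from a
panel of wild-type control screens: the query KO screen's guide LFC minus
the per-guide panel mean LFC is the raw interaction signal. Two systematic
artifacts are then removed:

1. **Control-dependent non-linearity.** A second-degree LOESS curve of the
   raw residuals on the panel mean LFC (span 0.4) is fit and subtracted.
   The x-variable choice (panel mean) makes this an MA-style correction:
   guides with strong single-mutant dropout often show compression in the
   query screen that would otherwise look like a positive interaction.
2. **T0-abundance dependence.** Shallowly sampled guides have noisy,
   systematically inflated fold-changes. A degree-1 LOESS trend of the
   corrected residuals on $\log_{10}$ T0 cpm is subtracted. Mean-trend
   removal is the minimal-assumption reading of "adjusting for T0
   dependence"; it deliberately does not rescale variances.

The LOESS smoother is implemented exactly as specified rather than through
a generic smoother: for each point the $\lceil \mathrm{span}\cdot n\rceil$
nearest neighbours (ties broken by input order, windows contiguous in
sorted x) receive tricube weights scaled by the window's maximum distance,
a local polynomial is fit by weighted least squares, and zero robustifying
iterations are performed. This makes the fit reproducible against a
per-point weighted-least-squares oracle to numerical precision, which the
test suite exploits.

### Gene-level scores and moderated tests

The qGI score of a gene is the mean adjusted residual over its retained
guides, pooled across replicate screens; genes with fewer than two
retained guides are not scored. Significance uses an empirical-Bayes
moderated one-sample t-test: gene-wise sample variances $s_g^2$ with $d$
residual degrees of freedom are modelled as $s_g^2 \sim s_0^2 F(d, d_0)$,
and $(d_0, s_0^2)$ are estimated by method of moments on $\log s_g^2$
(digamma/trigamma matching; the estimator agrees numerically with limma's
`fitFDist`, which the tests use as an independent cross-check). The
posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$$

gives $t_g = \bar r_g / (\tilde s_g/\sqrt{n_g})$ with $d_0 + d$ degrees of
freedom. When the spread of $\log s^2$ does not exceed pure sampling
variation, $d_0 = \infty$ and the statistic becomes z-like with the common
variance; $d_0 = 0$ recovers the ordinary t-test. The observation unit is
the guide-level adjusted residual (pooled across replicate screens when
several are scored together); this is one concrete choice among several
possible moderated designs and is recorded as such.

P-values are Benjamini-Hochberg adjusted across all scored genes of one
query screen (one family per screen). Default calls require
$|qGI| > 0.3$ and FDR $< 0.10$; both thresholds are arguments.

### Reproducibility as a WBC z-score

Replicate agreement of qGI profiles is summarized as a Within-vs-Between
replicate Correlation score. All profile correlations are Pearson
correlations over shared genes (at least 50 required), Fisher-z
transformed. With replicate-pair mean $z_w$ and the set $\{z_b\}$ of
correlations between each replicate and a panel of screens of *other*
queries,

$$\mathrm{WBC} = \frac{z_w - \overline{z_b}}{\mathrm{sd}(z_b)}.$$

The published construction this emulates adjusts the within-replicate
correlation to a panel of knockout screens without giving formulas; the
Fisher-z standardization above is this package's concrete definition and
should be read as an approximation of that score. All components
(`within_r`, the between distribution) are returned so a different
standardization can be applied downstream.

## N-terminal acetylome quantification

In positional proteomics with heavy in vitro acetylation, free N-termini
are chemically labelled (AcDC) so the light/heavy ratio $r$ of an
N-terminal peptide measures its in vivo acetylation degree:

$$\mathrm{Ac\%} = 100\cdot\frac{r}{r+1}.$$

Records are first filtered to true, quantifiable N-termini: peptide length
at least 8 residues, confident spectrum, tryptic cleavage, start position
1 or 2, rank-1 match. Missing ratios propagate as "not quantified", never
as 0%. Per protein N-terminus (accession, start position, first two
residues) the median and standard deviation of peptide-level degrees are
reported, pooling all quantified peptides across replicates (a
median-of-medians variant would weight replicates equally; pooling weights
peptides equally and is the default here because peptide counts per
replicate are small and uneven).

NAT substrate classes follow the first-two-residue specificity rules:
small residues exposed after initiator-Met cleavage (A, C, G, P, S, T, V
at start position 2) are NatA-type; retained Met followed by an
acidic/amidic residue (D, E, N, Q) is NatB-type; retained Met followed by
a hydrophobic or amphipathic residue (L, I, F, W, V, M, Y, K, H) is
NatC/E/F-type. Valine is position-dependent: an MV- N-terminus with
retained Met is NatC/E/F-type while an exposed valine is NatA-type — the
observed start position disambiguates, which is why the classifier takes
it as input. The residue sets are configuration tables
(`nat_residue_sets()`), not hard-coded constants, because specificity
boundaries (e.g. MK-, MH-) are fuzzy in vivo. Actin-specific NatH and the
post-translational Golgi activity of NatF are not modelled.

## Differential protein abundance

The abundance module reproduces the Perseus workflow used for label-free
and TMT proteomics. Intensities are log2 transformed and optionally
median-normalized per sample. Proteins need at least `min_valid = 3`
present values in at least one group; everything else is removed.
Missing values are then imputed from a downshifted normal per sample:
$N(\mu_c - 1.8\sigma_c, (0.3\sigma_c)^2)$, the Perseus defaults, which
model missingness as left-censoring at the detection limit. Imputation is
seeded and never touches present values.

Tests use SAM-style S0 statistics: for two groups
$d = (\bar x_A - \bar x_B)/(se + s_0)$ with pooled standard error
(Perseus behaviour; Welch is an option), and for $k$ groups an F statistic
whose denominator scale is inflated by $s_0$:
$F_{s_0} = MS_B / (\sqrt{MS_W} + s_0)^2$. At $s_0 = 0$ these are exactly
the classical t and one-way F (the tests verify both identities to 1e-10);
$s_0 > 0$ de-emphasizes low-variance proteins whose tiny absolute changes
would otherwise dominate. FDR control is either Benjamini-Hochberg on the
parametric p-values (exact at $s_0 = 0$, conservative otherwise) or
permutation-based: the observed statistics are compared with the pooled
null statistics from `n_perm = 250` random permutations of the sample
labels, the estimated FDR at a symmetric threshold is the mean number of
null exceedances per permutation divided by the observed count
($\pi_0$ fixed at 1, conservative), and the significant set is the largest
set with estimated FDR below target. Permutations that merely reproduce
the observed grouping (possible at small sample sizes) are excluded, since
they are not null draws. Defaults follow the workflow this reimplements:
pairwise tests at $s_0 = 0.1$, multi-group at $s_0 = 0$, FDR 0.01.

## What the simulators emulate — and what they do not

The simulators exist so every stage can be exercised against known ground
truth without any external data.

`simulate_screen()` draws T0 counts as negative binomial
($\mathrm{Var} = \mu + \alpha\mu^2$, default $\alpha = 0.05$ for technical
replicates, depth 500 reads/guide) around a per-guide log-normal library
representation (sd 0.5 log units, giving the order-of-magnitude abundance
spread the T0 filter and the T0 adjustment act on). Endpoint expectations
are the T0 expectation times $2^{f_g e_i + \gamma_g}$, with per-gene
fitness $f_g$ (15% essential genes at $-1.2 \pm 0.4$, the rest near 0),
truncated-normal guide efficacies $e_i$ around 1 (sd 0.2), and planted
interaction effects $\gamma_g$ in the KO screens only. Optional trend
functions add a control-LFC-dependent and a $\log_{10}$ T0-dependent bias
to the query screens to create exactly the artifacts the LOESS and T0
corrections target. These defaults were fixed once as a realistic
desk-scale stand-in for a genome-wide library (tests run at 1,000–2,000
genes x 4 guides); they are not adjusted per analysis. Not modelled:
PCR/sequencing read-level error, cell-passaging population dynamics,
guide off-target effects, and correlated guide efficacies — so a clean
pass on simulated screens shows the statistical machinery is correct, not
that real screens satisfy its assumptions.

`simulate_nterm()` perturbs peptide Ac/AcDC ratios log-normally around
$\theta/(100-\theta)$ and draws N-termini from a NatA/NatB/NatC-E-F class
mix, plus decoy records violating each filter rule. It does not model
spectrum-level interference or isotope-envelope effects.

`simulate_lfq()` draws log-normal intensities (baseline
$\log_2 \sim N(24, 1.5)$, replicate sd 0.3), plants shifts of 2 log2 units
on 10% of proteins, and censors below a detection limit (default 21.5) to
produce MNAR missingness. Missingness is purely left-censored; real LFQ
matrices also contain stochastic MAR missingness the imputation model does
not target.

All generators accept a seed and are bit-reproducible; they restore the
caller's RNG state.

## Numerical choices and degenerate inputs

- LOESS windows: $q = \lceil \mathrm{span}\cdot n\rceil$ nearest
  neighbours; distance ties broken toward earlier input order; zero-width
  windows (all x equal) fall back to equal weights; rank-deficient local
  fits drop aliased coefficients. An error is raised when
  $q < \mathrm{degree}+1$.
- Moderation: `estimate_moderation()` returns $d_0 = \infty$ whenever
  $\mathrm{var}(\log s^2) \le \psi'(d/2)$, including the all-identical
  case; the trigamma inverse is solved by Newton iteration to 1e-10.
- A gene whose residuals are exactly zero gets $t = 0$, $p = 1$ (not NaN).
- Ac% round-trips its inverse $p \mapsto p/(100-p)$ to 1e-12 on (0, 100).
- `write_table()` writes doubles at full precision; round-trips are exact
  to at least 1e-12.
- p-values entering `bh_fdr()` must lie in $(0, 1]$; zeros are clamped to
  the smallest double only where they arise from machine underflow of the
  F tail.

## Problem sizes used by the test and acceptance runs

The packaged checks run at desk scale, chosen as the smallest sizes at
which the stochastic properties are stable: null calibration and
planted-effect recovery at 2,000 genes x 4 guides x 3 technical
replicates over 10 seeds; trend removal at 1,000 genes; moderation
recovery at 5,000 simulated variances; LFQ power/FDR at 300 proteins,
4 samples/group, 50 seeds; acetylation recovery at 20 proteins x 5
peptides over 100 seeds. The WBC checks use synthetic qGI profiles
(2,000 genes) rather than full screen simulations, because WBC consumes
profiles, not counts.

## Known limitations

- The WBC standardization is this package's own concretization of a score
  whose exact published construction is not recoverable; absolute WBC
  values are therefore not comparable to published ones.
- The moderated-test observation unit (guides pooled across replicate
  screens, one-sample versus zero) is one defensible reading of
  "moderated t-testing" on residual LFCs; a per-screen random-effect
  design would weight replicate screens differently.
- The S0-modified F has no exact finite-sample reference distribution; at
  $s_0 > 0$ use the permutation FDR (the parametric p-values are
  conservative).
- The null calibration of the screen pipeline is approximate at low
  sequencing depth, where log-ratios of negative-binomial counts are
  visibly skewed.
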
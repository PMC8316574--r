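---
title: "Prioritizing functional phosphosites: methods and design"
author: "phosprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing functional phosphosites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosprio)
```

## The problem

Quantitative phosphoproteomics screens routinely identify thousands of
phosphorylation sites, of which only a small minority has any documented
function. `phosprio` implements the two computational halves of a
prioritization strategy for such screens:

1. a **differential-phosphorylation caller** that decides, from replicate
   light/heavy (e.g. ^14^N/^15^N metabolic labelling) ratio measurements,
   which phosphoisoforms change between a test genotype and a control; and
2. a **functional-site scorer** that ranks every site by a logistic
   regression over six sequence/structure features, normalizes the score
   to [0, 1], and intersects the top-scoring fraction with the regulated
   sites to produce a short candidate list.

Around these sit kinase/pathway enrichment statistics and a seeded
synthetic-data generator that reproduces the statistical structure of
each input, so the whole workflow is testable with known ground truth.

## Differential calling

For each phosphoisoform quantified at least `min_quant = 3` times in the
test genotype, a control vector is assembled: the control genotype's own
measurements when it has at least three ("control-1"), otherwise the pool
of control plus auxiliary genotypes ("control-2"). A control genotype
with zero measurements falls into the same merge branch; only an empty
merged pool excludes the isoform, and exclusion is signalled rather than
silent. The effect size is
$\log_2(\mathrm{median}_{test}/\mathrm{median}_{control})$.

The cohort's spread is summarized robustly. With $Q_1$ and $Q_3$ the
quartiles of the log~2~ fold-change distribution,

$$\mathrm{IQ} = Q_3 - Q_1, \qquad \mathrm{NIQ} = 0.7413 \times \mathrm{IQ},$$

where $0.7413 \approx 1/(2\,z_{0.75})$ makes NIQ a consistent robust
estimate of a normal standard deviation (the package verifies this by
Monte Carlo). An isoform is called regulated by a two-tier flexible
filter — either

* $|\log_2\mathrm{FC} - \mathrm{median}| > 1.5\,\mathrm{NIQ}$ with
  one-tailed Wilcoxon rank-sum $p < \alpha$, or
* $|\log_2\mathrm{FC} - \mathrm{median}| > \mathrm{NIQ}$ with two-tailed
  $p < \alpha$,

with $\alpha = 0.05$ by default. Direction (hyper/hypo) follows the sign
of the deviation from the cohort median.

**Quantile convention.** All quartiles in the package (spread statistics
and the score normalizer alike) use linear interpolation between order
statistics — `stats::quantile` type 7 — recorded here once so every
worked value is reproducible by hand.

**Wilcoxon implementation.** The rank-sum p-value is exact (from the
null rank-sum distribution) when the combined sample has at most 20
observations and no ties; ties or larger samples use the normal
approximation with tie correction and continuity correction. Exactness
at small *n* matters because the filter's one-tailed branch operates at
typical replicate counts of 3–5 per genotype. A granularity consequence
worth knowing: with 3 test and 3 control measurements the smallest
attainable one-tailed exact p is $1/\binom{6}{3} = 0.05$, which is *not*
below 0.05 — so designs with three replicates per arm can only be called
through the two-tailed tier with pooled controls. The generator's
default of 4 replicates per genotype (2 biological × 2 technical runs is
a common design) gives a minimum one-tailed p of $1/70 \approx 0.014$.

**Isoform-to-site expansion.** A site is regulated if any isoform
containing it is; a site called in opposite directions by different
isoforms is reported with both directions and a warning, since dropping
either call would misstate the evidence.

## The six-feature functional score

Each candidate site is encoded as eight numeric covariates:

| feature | column(s) | meaning | default source |
|---|---|---|---|
| UKF | `ukf_count` | number of distinct upstream kinase families predicted to phosphorylate the site | kinase–site edge table |
| PhC | `rcs` | residue conservation score (below) | ortholog MSAs + species tree |
| IDM | `idm_count` | interaction partners of domains containing the site; 0 outside domains | domain spans + partner counts |
| ASC | `asc` | 1 if an acetylation site lies within ±15 residues (inclusive) | acetylation table |
| RSA | `rsa` | predicted relative surface accessibility, [0, 1] | per-site RSA table |
| SS | `ss_helix`, `ss_strand`, `ss_coil` | secondary-structure probabilities (sum to 1) | per-site SS table |

The annotation tables stand in for the predictors that generate them
upstream (kinase predictors, acetylation predictors, Pfam/domain
interaction resources, surface-accessibility predictors); the package
consumes their outputs as flat TSVs and validates them strictly by
default — silent row-dropping would corrupt enrichment backgrounds, so
lenient mode is an explicit opt-in that reports every dropped row.

Two deliberately open choices are fixed as follows: overlapping domains
contribute their partner counts **additively** (a site in two
interacting domains participates in both interfaces; `overlap = "max"`
is available), and features enter the regression **unscaled**, so
fitted weights are directly comparable across runs.

### Residue conservation

For a site mapped (through reference-row gaps) to its alignment column,
the conserved set is the species whose residue at that column is
phosphoacceptor-equivalent to the site residue. S and T form one
equivalence class and Y its own, because serine/threonine and tyrosine
kinases are distinct enzyme families; exact-residue matching is
available via `strict_residue`. The score is

$$\mathrm{RCS} = \mathrm{MBL} \times \frac{N_p}{N},$$

where MBL is the longest path distance on the species tree between any
two conserved species, $N_p$ the number of conserved species, and $N$
the number of analysis species in the **smallest clade (MRCA subtree)
spanning the conserved set**. The clade reading of "species within the
MBL" is deliberate: it is well defined even when several species pairs
tie for the maximum distance, whereas a "species on the MBL path"
reading is not. Species with no ortholog row are excluded from both
$N_p$ and $N$; a site conserved only in the reference has MBL 0 and
hence RCS 0.

### Training, evaluation, normalization

Benchmarks fix the positive class and draw `ratio` negatives per
positive from the negative pool without replacement, independently for
each of `n_sets` sets (the generator's default ratio is 1:5, the ratio
that performed best in the screen this design follows). The classifier
is a binary logistic regression fitted by Newton/IRLS with a tiny ridge
penalty (`l2 = 1e-8`) on the slopes only: the intercept stays
unpenalized so degenerate fits have their closed form, and separable toy
data cannot diverge. The fit is deterministic and
initialization-independent (the penalized loss is strictly convex).

Model selection runs stratified 10-fold cross-validation per benchmark
set and refits on the set with the highest cross-validated AUC, ties
breaking to the lowest set index with a warning. The CV AUC is computed
on the **pooled out-of-fold scores** rather than averaged over folds —
with a positive class of ~100 sites, per-fold AUCs would rest on ~10
positives each and their mean would be noisy and ill-defined under
stratification remainders. AUC itself is the Mann–Whitney rank
statistic (ties count half), and confidence intervals come from
stratified (within-class) bootstrap resampling with a percentile
interval. Because resampling is stratified, both classes are present in
every replicate by construction and no degenerate-resample handling is
needed.

Raw scores are mapped to [0, 1] by outlier-fenced min–max: with raw
quartiles $Q_1, Q_3$ and $\mathrm{IQ} = Q_3 - Q_1$, the fences are
$Q_1 - 3\,\mathrm{IQ}$ and $Q_3 + 3\,\mathrm{IQ}$; scores beyond the
fences clamp to 0 or 1, and scores inside map linearly between the
extreme in-fence scores $S_{min}$ and $S_{max}$:

$$S_{norm} = \frac{S - S_{min}}{S_{max} - S_{min}}.$$

If all in-fence scores coincide, in-fence values map to 0.5 with a
warning. Prioritization keeps the smallest set of at least
$\lceil f \cdot n \rceil$ sites ($f = 0.05$ by default) such that no
excluded site outscores an included one; ties at the cut are all kept.
The terminal output intersects this top fraction with the regulated
sites.

## Enrichment statistics

For a unit (kinase family or pathway) with $n$ annotated items in a
background of $N$, and $m$ annotated items among $M$ regulated ones:

$$E\text{-ratio} = \frac{m/M}{n/N}, \qquad
p = \sum_{m'=m}^{\min(n,M)} \frac{\binom{M}{m'}\binom{N-M}{n-m'}}{\binom{N}{n}}.$$

The tail's upper limit is $\min(n, M)$ — terms beyond are zero
binomials, so this is numerically identical to summing to $n$ but never
evaluates an invalid coefficient. The significance rule is raw
$p < 0.05$ together with $E > 1$, with no multiple-testing correction by
default (a Benjamini–Hochberg option exists behind `adjust = "BH"`);
the raw-p rule mirrors standard practice for this screen type, and the
package's null simulations confirm the per-test false-flag rate stays
at or below $\alpha$ (hypergeometric p-values are super-uniform). The
kinase background defaults to all identified phosphosites and is
configurable. The per-category score Z-test
($Z = (\bar{x} - \mu)/(\sigma/\sqrt{n})$, two-tailed) takes the
population parameters from **all** items, including category members —
the simpler of the two possible conventions, flagged here because the
choice matters for very large categories.

## The synthetic generator

The generator emulates the statistical structure of each input, not its
biology:

* **Quantitation tables** use multiplicative lognormal replicate noise
  (`sdlog = 0.1`), the standard error model for isotope-ratio MS, with
  planted fold changes (default 2.0, alternating hyper/hypo in 10% of
  isoforms) confined to the test genotype; 4 replicates per genotype.
* **Benchmarks** come in a single-feature Gaussian-shift mode, whose
  population AUC has the closed form $\Phi(d/\sqrt{2})$ used as an
  analytic oracle, and a logistic mode with known coefficients for
  recovery tests (realistic count/probability marginals, or standard
  normal covariates where a well-posed recovery check is the point).
* **Alignments and trees** realize requested conserved species sets
  exactly (non-conserved species carry a non-phosphorylatable residue at
  the site column; alignments are gap-free), over random trees with
  uniform branch lengths.
* **Annotations** plant one enriched kinase by exact counts — it
  receives exactly $\mathrm{round}(E_{target} \cdot n \cdot M/N)$ edges
  into the regulated set — so the truth enrichment ratio equals the
  configured target rather than fluctuating binomially around it.

What this does **not** emulate: real amino-acid composition, real
kinome topology, correlated features, batch effects, or missingness
patterns of real MS data. Passing tests therefore demonstrate that the
statistics are implemented correctly and have their nominal power and
size under the stated noise model — not that the scorer's biological
feature set generalizes to any particular organism.

Problem sizes used in the shipped checks (chosen to make Monte-Carlo
error small relative to each tolerance): 5,000 per class for the
analytic-AUC check, 20,000 observations for coefficient recovery, 500
isoforms for caller power/size, 200 replicates of a 2,000-site
background for enrichment power, a 200-site fixture for the end-to-end
run, and 100 simulations × 2,000 bootstrap replicates for CI coverage.

## Determinism and the run manifest

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state, so generators and pipeline runs are pure functions
of (config, seed). The pipeline writes a manifest listing each output
with its MD5 content hash; the manifest is fully deterministic —
deliberately, it contains **no timestamps**, because reproducibility of
the manifest bytes themselves is a tested contract. Stages communicate
only via TSV/JSON files, so any stage can be re-run or inspected in
isolation.

## Known limitations

* The caller tests each isoform marginally; no shrinkage or sharing of
  variance across isoforms (a limma-style moderation would be a natural
  extension for very low replicate counts).
* Conservation treats the MSA as correct; misalignment maps to false
  non-conservation.
* The enrichment tests assume exchangeable sites; kinase edge sets that
  cluster on proteins violate the hypergeometric null mildly.
* Accessions are opaque strings; no identifier mapping between database
  releases is attempted.
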
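---
title: "Decomposing drug action into efficacy and bias axes in four-group metabolomics"
author: "metaboDecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing drug action into efficacy and bias axes in four-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboDecomp)
```

## The problem and the design

A drug given on top of a metabolic challenge produces two kinds of
metabolite response that are easy to conflate. *Efficacy-related*
responses are restorative: the challenge pushed the metabolite away from
its baseline and the drug pulls it back, so the treated-group level sits
between the control and challenge levels. *Bias-related* (drug-intrinsic)
responses have nothing to do with restoration: the drug shifts the
metabolite outside the control–challenge interval, to the same side
whether or not the challenge is present. Separating the two requires a
four-group design — control, challenge, challenge+drug ("treated"), and
drug alone — and that is the design this package consumes.

The chain is:

1. **Preprocess** the samples × metabolites abundance table
   (`preprocessFeatures`): presence filter, half-minimum imputation,
   natural-log transform, autoscaling.
2. **PLS-DA by NIPALS** (`fitPlsda`) with **VIP** scoring (`computeVip`):
   a multivariate screen for metabolites that carry group contrast.
3. **Differential tests** (`differentialTest`): per metabolite, Student's
   t or Mann–Whitney, chosen per metabolite by a Shapiro–Wilk check, with
   Benjamini–Hochberg adjustment.
4. **Classification** (`classifyAll`): the interval rule assigns
   `efficacy`, `bias_up`, `bias_down`, or `unclassified`.
5. **Set and pathway enrichment**: hypergeometric over-representation of
   metabolite sets (`msea`), and centrality-weighted permutation
   enrichment of pathway graphs over genes mapped from the classified
   metabolites (`mapSelection`, `cepaEnrichment`).
6. **Dual-axis ranking** (`dualAxis`, `rankPathways`): per pathway,
   `logP = -log10(p_bias)` and `foldP = p_efficacy / p_bias`; a pathway
   enriched on both axes (`joint_flag`) is a candidate shared mechanism.

## The latent-variable model

Let $X$ be the preprocessed $n \times p$ matrix and $Y$ the
column-centered one-hot indicator of the four groups. NIPALS extracts one
component at a time: iterate $w \propto X'u$ (normalized to unit norm),
$t = Xw$, $q \propto Y't$, $u \propto Yq$ until the relative change of
$t$ falls below `tol`; then deflate $X$ by $t p'$ with $p = X't/t't$ and
$Y$ by $t q'$. The drop in $\lVert Y\rVert^2$ at each deflation is stored
as that component's explained class variance $SSY_a$. This alternation is
a power iteration on $(X'Y)(X'Y)'$, which is why the tests can check
component-1 weights against `svd(crossprod(X, Y))` — an oracle that
shares no code with the implementation.

VIP summarizes each variable's contribution across the $A$ components:

$$VIP_j = \sqrt{p \cdot \frac{\sum_a SSY_a\, w_{ja}^2}{\sum_a SSY_a}}.$$

Because weight columns have unit norm, the mean of $VIP_j^2$ over
variables is exactly 1, so the conventional gate $VIP > 1$ selects
variables contributing more than average. Both the cumulative VIP and
per-component VIPs are computed; the cumulative form is the default gate
(`vipColumn = "VIP"`) because the per-component attribution of "bias" and
"efficacy" to particular components is a reading of a score plot, not an
operational rule. For the same reason the classifier below never assumes
which fitted component is which axis.

## The classification rule

With analysis-scale group means $m_C$ (control), $m_A$ (challenge),
$m_T$ (treated) and a dead-band $\epsilon \ge 0$:

* `efficacy` iff $\min(m_C, m_A) + \epsilon \le m_T \le
  \max(m_C, m_A) - \epsilon$ **and** the control-vs-challenge contrast is
  significant (BH-adjusted $p < \alpha$) — without a challenge effect,
  "restoration" is undefined;
* `bias_up` iff $m_T > \max(m_C, m_A) + \epsilon$, `bias_down` iff
  $m_T < \min(m_C, m_A) - \epsilon$ — additionally requiring the
  treated-vs-control contrast significant, because the rule is meant for
  *differential* metabolites: without that gate, roughly a third of
  pure-noise metabolites pass the VIP screen and two thirds of those have
  their treated mean outside the control–challenge interval by chance,
  which would flood the bias class with false positives;
* otherwise `unclassified`. Only metabolites with $VIP > 1$ can receive a
  non-`unclassified` label. The rule is symmetric in $m_C$ and $m_A$, and
  drug-alone means are recorded in the verdicts but not used by it.

$\epsilon$ defaults to 0: boundary ties have measure zero under a
continuous model, but the parameter exists because ties are real in
rounded data. The differential tests and the verdict means are computed
on **observed** log abundances (missing cells omitted), not on imputed
values: half-minimum imputation fabricates low outliers that inflate test
variances, so imputation feeds only the multivariate model, which cannot
tolerate missing entries.

## Enrichment statistics

**MSEA.** For a selection of $n$ metabolites, a set with $K$ members in a
universe of $N$, and overlap $k$, the p-value is the upper hypergeometric
tail $P(\text{overlap} \ge k)$, with BH adjustment across sets. The tests
verify the tail against exhaustive enumeration of all $\binom{N}{n}$
selections for every $N \le 12$.

**Pathway stage.** Each pathway is an undirected graph over genes; the
observed score is the summed node weight of pathway genes present in the
differential gene list, where weights are network centralities: `equal`
(default), `degree`, or unnormalized shortest-path `betweenness`. The
null redraws the same number of genes uniformly without replacement from
the gene universe `nPerm` times;
$p = (1 + \#\{\text{null} \ge s\})/(1 + nPerm)$, so $p \in (0, 1]$ always
— both dual-axis coordinates stay finite. With equal weights the score
reduces to the overlap count and the permutation p converges to the
hypergeometric tail, which is the calibration check in the tests. `equal`
is the default because it is the most conservative choice and the
weighting scheme is genuinely open; the choice is recorded in every
output row. The gene universe is the set of genes appearing in the
mapping table — not the union of pathway nodes — because the mapping
defines what *could* have been selected; this choice changes p-values
and is therefore stated in output metadata.

**Dual axis.** `foldP` is the raw ratio $p_E/p_B$ (a log10 display
transform is trivial for plotting, but the stored value is the ratio),
computed on BH-adjusted p-values by default (`useAdjusted = TRUE`); raw
p-values are a flag away since the convention cannot be pinned down.
Output rows are sorted by descending `logP`, ties by ascending `foldP`,
then lexicographic id under C collation — a total order, so shuffled
input reproduces identical output. `rankPathways` puts jointly enriched
pathways first within the same order.

## What the synthetic cohorts emulate

`generateCohort` draws $\exp(N(\mu_{gj}, \sigma))$ abundances:
multiplicative noise with a shared $\sigma$ across groups, the standard
first approximation to LC-MS intensity data. Defaults describe a
small-animal study: 7 samples per group, 400 metabolites, 40 planted
efficacy and 40 planted bias responders, challenge and bias effects of
$d = 3$ standard deviations on the log scale, half restoration
(`restorationFraction = 0.5`), baseline log-mean 10 ($\approx 2.2\times
10^4$ in raw intensity), $\sigma = 0.3$, and 2% cells missing completely
at random. The challenge moves only the efficacy subset; the bias subset
responds only to the drug (treated and drug-alone together, direction
50/50 up/down, recorded in the ground truth); the drug alone leaves
efficacy metabolites at control level. This is the simplest mean
structure consistent with the two class definitions.

`generateKnowledge` emits a metabolite→gene mapping covering every
metabolite (one primary gene each, a quarter also touching a shared hub
gene), metabolite sets, and connected pathway graphs: one pathway drawn
from efficacy-metabolite genes, one from bias-metabolite genes, one
"double" pathway drawing half from each — the planted target that should
be flagged jointly enriched — plus size-matched decoys drawn from
unplanted genes. Planted pathways contain no decoy filler; decoys carry
the null.

What the generator does **not** emulate: batch and drift effects,
informative missingness, correlated metabolite blocks, retention-time or
adduct artifacts, and heavy-tailed measurement error. Passing recovery
tests therefore show that the chain recovers the planted mean structure
under idealized noise — they do not certify performance on real data,
where preprocessing choices and correlation structure matter.

## Numerical choices

* NIPALS: `tol = 1e-10` on the relative score change, `maxIter = 500`.
  Convergence slows as the leading singular values of the deflated
  $X'Y$ approach a tie — on null cohorts this happens by chance, so the
  package's own simulation studies raise the cap to 25000 cheap
  iterations rather than accept spurious failures; exceeding the cap is
  an error reporting the component and residual, never a silent result.
* Sign convention: each weight column's largest-magnitude entry is made
  positive (scores and Y-loadings flipped along), so refits are
  bit-reproducible.
* Projection of new samples uses $R = W(P'W)^{-1}$, which reproduces
  training scores exactly and agrees with explicit sequential deflation.
* Autoscaling uses the $n-1$ sample standard deviation; a zero-variance
  metabolite under scaling is an error naming the metabolite. Feature
  tables written to disk use `%.17g`, so read–write round-trips are exact.
* Degenerate tests: two identical zero-spread groups give $p = 1$ with a
  flag; constant samples make Shapiro–Wilk undefined and count as
  non-normal, falling back to the rank test; the Mann–Whitney null is
  exact when tie-free.
* All randomness descends from explicit integer seeds; generators save
  and restore the caller's RNG state. The pipeline fans its root seed
  out to the two enrichment stages by fixed offsets; the run manifest
  (config hash, seed, versions, timestamp) plus the inputs reproduce
  every numeric table byte for byte.

## Simulation sizes used by the checks

The shipped checks use sizes chosen to make Monte-Carlo error small
relative to the margins being tested: 200 cohorts for
classification recovery and for null-cohort specificity, 100 cohorts for
the end-to-end dual-axis study (with `nPerm = 2000`, ample for
BH-adjusted calls at $\alpha = 0.05$ over eight pathways; the pipeline
default stays 10000), 50000 permutations for the calibration check
against the exact tail, and full enumeration for every ORA instance with
$N \le 12$. The acceptance script reports the same quantities at 40–60
cohorts per estimate.

## A worked example

```{r example, eval = FALSE}
library(metaboDecomp)
bundle <- simulateCohortFiles(cohortSpec(seed = 1), "cohort1")
cfg <- runConfig(featureTable = bundle$paths$featureTable,
                 metaboliteSets = bundle$paths$metaboliteSets,
                 mapping = bundle$paths$mapping,
                 graphDir = bundle$paths$graphDir,
                 membershipGmt = bundle$paths$membershipGmt,
                 outDir = "run1", seed = 1)
res <- runPipeline(cfg)
table(res$verdicts$class)
head(res$dual)
```

## Known limitations

* The classifier is a hard rule on means: no uncertainty on the class
  label, no time-course modelling of restoration.
* Component selection is fixed by the user (`nComponents`, default 2);
  there is no cross-validated selection or permutation test of class
  separation.
* The pathway stage scores node sets weighted by centrality; it does not
  model edge signs, directions, or propagation beyond centrality.
* Group sizes are assumed balanced by design; Y columns are not
  reweighted for unbalanced cohorts.
* Whether efficacy should additionally require a significant
  treated-vs-challenge contrast is left open by the class definitions;
  this package does not require it, and records enough evidence per
  verdict for users to impose it afterwards.
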
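# metaboDecomp

Separating what a drug *fixes* from what a drug *does* in untargeted
metabolomics. Given a four-group design — control, challenge,
challenge+drug ("treated"), drug alone — `metaboDecomp` classifies each
metabolite response as **efficacy-related** (the treated-group level
falls back between the control and challenge levels: the drug restores
it toward baseline) or **drug-bias-related** (the treated level sits
outside the control–challenge interval: a drug-intrinsic shift), then
ranks pathways by joint enrichment of the two response classes. It is
aimed at pharmacometabolomics analysts who have a peak-area table and
want the decomposition, and at methodologists who want a tested,
reproducible implementation with planted-truth simulations.

## The method in brief

1. **Preprocessing** — presence filter, half-minimum imputation,
   natural-log transform, autoscaling (`preprocessFeatures`); the fitted
   parameters project new samples identically.
2. **PLS-DA by NIPALS** — regression of the centered one-hot group matrix
   *Y* on *X*, one component at a time (w ∝ X′u, t = Xw, q ∝ Y′t,
   u ∝ Yq, deflation by t p′ and t q′), with **VIP**

   VIP_j = sqrt( p · Σ_a SSY_a w_ja² / Σ_a SSY_a ),

   whose squared mean over variables is exactly 1 — so the classical gate
   VIP > 1 selects above-average contributors (`fitPlsda`, `computeVip`).
3. **Differential testing** — per metabolite, two-tailed Student's t or
   Mann–Whitney chosen by a Shapiro–Wilk check, Benjamini–Hochberg
   adjusted (`differentialTest`).
4. **Classification** — the interval rule on analysis-scale means, gated
   on VIP > 1 and on the relevant significant contrast
   (`classifyAll`).
5. **Enrichment** — hypergeometric over-representation of metabolite sets
   (`msea`); genes interacting with each class mapped via a local lookup
   (`mapSelection`); centrality-weighted pathway scores against a
   gene-sampling permutation null with plus-one-corrected p
   (`cepaEnrichment`).
6. **Dual axis** — per pathway, logP = −log10(p_bias) and
   foldP = p_efficacy / p_bias; pathways significant on both axes carry a
   joint flag and lead the ranking (`dualAxis`, `rankPathways`).

A synthetic-cohort generator with full ground truth (`generateCohort`,
`generateKnowledge`, `simulateCohortFiles`) plants efficacy/bias
structure and a jointly enriched "double" pathway, so every stage has a
recoverable target.

## Worked example

```r
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
#>    bias_down      bias_up     efficacy unclassified
#>           23           17           40          320
head(res$dual[, c("pathway", "p_bias", "p_efficacy", "logP", "foldP",
                  "joint_flag")], 4)
#>                 pathway p_bias p_efficacy  logP   foldP joint_flag
#> PW_DOUBLE     PW_DOUBLE  4e-04      4e-04 3.398 1.0e+00       TRUE
#> PW_BIAS         PW_BIAS  4e-04      1e+00 3.398 2.5e+03      FALSE
#> PW_EFFICACY PW_EFFICACY  1e+00      4e-04 0.000 4.0e-04      FALSE
#> PW_DECOY01   PW_DECOY01  1e+00      1e+00 0.000 1.0e+00      FALSE
```

The cohort planted 40 efficacy and 40 bias metabolites among 400; the
run recovers all 40 efficacy calls and 40 bias calls here (23 down + 17
up). The planted double pathway is the only one significant on both axes
(BH-adjusted p = 4×10⁻⁴ each side at 10000 permutations), so it carries
the joint flag and ranks first; the bias-only and efficacy-only pathways
light up one axis each and the decoys stay dark. `run1/` holds every
table as TSV plus a manifest (config hash, seed, versions) that makes the
run bit-reproducible.

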
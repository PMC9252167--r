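---
title: "Local invasion power and early metastatic risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local invasion power and early metastatic risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalip)
```

# The scientific problem

Colorectal tumors seed metastases by first invading the histologically
normal-appearing tissue adjacent to the tumor (*paracancer* tissue).
When matched normal, paracancer and tumor specimens of one patient are
exome-sequenced, the variant allele fraction (VAF) of a variant in each
tissue is a proxy for the fraction of DNA molecules carrying it, and
the *relative* VAFs across the three tissues carry a signal about local
invasion: a variant allele relatively enriched in paracancer tissue
marks clones that have moved outward, while enrichment confined to the
tumor marks clones staying put.

`metalip` implements this idea as a statistic, a screening cascade and
a risk classifier:

1. **LIP** (local invasion power) per variant and **sLIP** per subject;
2. a three-step **driver/resister cascade** combining mean LIP,
   case-control odds ratios, and an eQTL-plus-survival penetrance
   filter;
3. a **LIP-weighted logistic model** of early metastatic risk with
   leave-one-out and leave-one-cohort-out evaluation;
4. a fully seeded **synthetic cohort generator** that produces every
   input of the pipeline, with ground truth, so the whole chain is
   testable without patient data.

# The LIP statistic

For variant $M_i$ with normalized VAFs $V_{MN_i}$, $V_{MP_i}$,
$V_{MT_i}$ in normal, paracancer and tumor tissue, the invasion
promotion rate and invasion resistance rate are

$$R_{M_i} = V_{MP_i} / V_{MT_i}, \qquad
  \bar R_{M_i} = V_{MT_i} / V_{MN_i},$$

and the local invasion power is their base-2 log ratio

$$\mathrm{LIP}_i = \log_2 \frac{R_{M_i}}{\bar R_{M_i}}
                = \log_2 \frac{V_{MP_i}\, V_{MN_i}}{V_{MT_i}^2}.$$

LIP is measured in bits: doubling the paracancer VAF adds exactly one
bit. LIP > 0 marks invasion promotion, LIP < 0 resistance. Under the
working assumption that variant effects on invasion add linearly, a
subject's burden is the sum over their $n$ called variants,
$\mathrm{sLIP} = \sum_{i=1}^{n} \mathrm{LIP}_i$.

```{r}
lipScore(vN = 0.25, vP = 0.5, vT = 0.25)
```

## VAF normalization and zero handling

Raw VAFs are alt reads / total reads per locus. Because LIP uses
cross-tissue VAF *ratios*, only the relative sequencing effort of the
three matched tissues matters; the default `library_size` policy of
`normalizeVafs()` therefore divides each tissue's raw VAF by that
tissue's library size relative to the subject's three-tissue mean.
When the three tissues were sequenced at the same effort the factor is
exactly 1 and the policy coincides with `none`. Whether library sizes
should be on-target or all-mapped totals is left to the caller — both
are accepted through the same field.

LIP is undefined at zero VAFs, which the upstream callers do produce
(a variant absent from one tissue's calls). Two explicit policies keep
every LIP finite:

* `half_read` (default): a locus with positive depth $d$ but zero alt
  reads gets VAF $0.5/(d+1)$ — half a read's worth of evidence, so
  deeper loci get smaller imputed VAFs;
* `epsilon`: a fixed floor (default $10^{-4}$), also used whenever the
  locus has zero depth.

Calls whose LIP is still non-finite are dropped with a warning, never
silently. Absolute sLIP values are policy-dependent (and depend on how
many variants a caller emits); sign and ordering claims are the robust
quantities, and the per-subject tables always report `n_variants`
alongside sLIP.

## Per-variant and per-subject summaries

`summarizeLip()` averages LIP per variant **over the subjects in which
the variant was called**: an uncalled variant has no VAF, and imputing
LIP = 0 would conflate absence with neutrality. Per-subject sLIP sums
all finite LIPs of that subject. Germline and somatic profiles run
through the same code path; the caller labels the variant set.

Group contrasts (non-metastasis NM vs lymphatic-metastasis LM) use the
two-sided Wilcoxon rank-sum test — exact enumeration when the combined
sample size is at most 20 without ties, tie-corrected normal
approximation otherwise. The sLIP association with the
tumor-to-paracancer purity change uses the Pearson correlation with
the usual t-based p-value.

# The driver/resister cascade

`runCascade()` intersects three filters, with defaults in
`cascadeConfig()`:

| step | gate | default |
|------|------|---------|
| 1 | per-variant mean LIP | > 1 (promoter arm), < −1 (resister arm), strict |
| 2 | carrier odds ratio vs metastasis status | > 5, strict |
| 3 | eQTL trend p and log-rank p | both < 0.01 |

Step 1 also records the plain mean LIP > 0 list as an intermediate
artifact, but the operative promoter gate is the stricter > 1
threshold. The odds ratio is the cross-product ratio
$(M_m N_n)/(M_n N_m)$ over subject-level carrier counts; a zero
control-carrier cell with carriers present in cases yields $+\infty$,
which deliberately **passes** the filter (no Haldane–Anscombe
correction by default — the structural infinity means carriers are
confined to the metastasis group; the correction and an allele-count
mode are available as options). No multiple-testing adjustment is
applied: the screen ranks by effect magnitude, not p-value.

Step 3 tests, per variant, (a) a linear trend of host-gene expression
on allele dosage (slope sign = direction of the conferred expression
change; a precomputed eQTL table can stand in), and (b) a log-rank
contrast between the high- and low-expression strata of an independent
survival table, median-split with ties to low and administratively
censored at 120 months (a 10-year horizon). Variants missing from the
carrier, expression or survival tables are excluded conservatively,
each with a logged stage and reason, so every input variant is
accounted for.

**MP/MR classification.** The sources this pipeline follows apply the
promoter/resister labels without stating the mapping rule; `metalip`
formalizes it explicitly: a candidate is a *metastasis promoter* (MP)
when the expression level it confers (up- or down-regulation, from the
eQTL slope sign) is the stratum with the worse survival, and a
*metastasis resister* (MR) otherwise. This reproduces MP labels for
both up- and down-regulating drivers.

# The risk model

Given a fixed panel of $k$ variants (the cascade's candidates;
$k = 11$ in the motivating study) a subject is encoded as a binary
carrier vector $V = (V_1,\dots,V_k)$ and weighted by
$L = (\mathrm{LIP}_1, \dots, \mathrm{LIP}_k)$, the panel's average
LIPs from the discovery cohort — carrier status is cheap to assay,
while $L$ carries the invasion effect sizes measured once from
tri-tissue data. The metastasis probability is the logistic

$$P(y = 1) = \frac{1}{1 + \exp\!\big(-\sum_{i=1}^k w_i V_i L_i - b\big)}$$

with $(w, b)$ fitted by maximum likelihood (`glm`). With tens of
subjects and 11 features, complete separation is a real possibility;
the fit then falls back to an L2-penalized likelihood (ridge
$\lambda = 10^{-4}$ on the slopes only, Newton–Raphson to a gradient
norm of $10^{-8}$), recorded in the model metadata. Predicted
probabilities map to risk tiers with closed-left boundaries: high
$[0.75, 1]$, moderate $[0.5, 0.75)$, mild $[0, 0.5)$.

Evaluation reports the confusion matrix at threshold 0.5 (the
mild/moderate boundary), accuracy, sensitivity, specificity, and the
rank-statistic AUC with ties counted 1/2. `loocv()` holds each subject
out once ($n$-fold where $n$ is the actual training-set size — the
"fold count" is always derived from the data, since fixed fold numbers
quoted for one cohort do not transfer) and pools the held-out
predictions; the mean per-fold accuracy is reported alongside, because
pooled-prediction and per-fold averages are both defensible summaries
and sources differ silently on which they quote. `groupedEval()`
implements the leave-one-cohort-out scheme: train plus internal LOOCV
on the union of the other cohorts, one external evaluation on the
held-out cohort.

# The synthetic study

The generator (`generatorConfig()` defaults) emulates the study design
the methods assume, at desk scale, with these conditions:

* **Discovery cohort**: 4 NM + 4 LM subjects; 1,000 background
  germline variants at population frequencies 0.1–0.9 (dosage
  $\sim\mathrm{Bin}(2, f)$, true VAF 0.5 or 1 in every tissue); read
  depths Poisson(197) matching ~197× on-target coverage; alt reads
  binomial. One sequencing effort per subject is shared by the three
  tissues, so the (default-on) library-size normalization has factor 1
  — the binomial read model already puts tissues on a common scale.
* **Background drift**: every non-driver variant's paracancer VAF is
  multiplied by 0.98, a small outward depletion of neutral alleles, so
  a neutral mutation profile accumulates a *negative* sLIP
  (≈ −0.029 bits × ~700 called variants ≈ −20, against a binomial
  noise SD of ≈ 5).
* **Planted drivers** (10, heterozygous in all subjects): in LM
  subjects the paracancer VAF is multiplied by the boost (default 3,
  capped at 1) and the tumor VAF divided by it — the
  variant-carrying clone migrating toward and past the tumor edge.
  A paracancer-only boost cannot exceed one bit for a heterozygous
  variant (the VAF cap), so the effect is deliberately split across
  both tissues; at the defaults each LM carrier contributes ≈ 4.2
  bits, giving carrier-mean LIPs ≈ 2 and clearly positive LM sLIPs.
  The planted resister applies the inverse. Effect sizes are synthetic
  choices for clear recovery, not inferred quantities.
* **Validation cohorts** (named `cohortA/B/C` of 10/24/19 subjects
  plus a discovery-sized fourth; 28/53 metastasis fraction): planted
  variants are carried by controls with probability 0.02 and by cases
  at the odds-ratio target (default 50), so the empirical odds ratio
  is frequently the structural $+\infty$ that candidate tables in this
  setting actually report; background variants share one carrier
  probability in both groups. Carrier profiles here are drawn from
  this case-control process per cohort (exchangeable across cohorts)
  rather than tied back to the read-level discovery simulation.
* **Expression/survival tables**: expression = 10 + slope·dosage +
  N(0, 1) with slope ±1.5 per the planted direction (0 for
  background); survival exponential with median 40 months in the
  better stratum, hazard ratio 3 in the worse one, censored at 120
  months; 300 samples each. Six drivers up-regulate, four
  down-regulate, and the resister confers the better-faring stratum,
  so the MP/MR rule is exercised on all its branches.

What the generator does **not** model: mapping error, strand or batch
artifacts, copy-number and structural variation, purity-driven somatic
VAF dilution in the default germline mode (a purity-mixing somatic
interpretation can be emulated by passing lower true VAFs), linkage
between variants, and population structure in the case-control
cohorts. Passing tests therefore demonstrate the statistical machinery
and its conventions — not that real cohorts of this size would yield
the same power.

# Numerical choices and degenerate inputs

* Wilcoxon: exact only without ties and combined n ≤ 20; otherwise
  tie-corrected normal approximation without continuity correction.
* Odds ratio: $0/0$ cross products are undefined (`NA`) and never pass
  the filter; all thresholds are strict inequalities (a variant at
  exactly OR 5 or mean LIP 1 is excluded).
* Log-rank with zero events overall: statistic 0, p 1. The "worse"
  stratum is the one with more observed than expected deaths.
* Constant expression in the eQTL test: p 1, direction undefined,
  variant excluded before classification.
* Ties at the expression median go to the low stratum; risk-tier
  boundaries are closed on the left (p = 0.75 is high, p = 0.5
  moderate).
* JSON model files store numbers at 17 significant digits so
  serialization round-trips exactly.
* All randomness flows from one master seed through fixed per-stage
  offsets; outputs are written atomically and a manifest records
  checksums, so identical configurations reproduce byte-identical
  output trees.

# Problem sizes used by the test suite

The packaged tests and the acceptance script run the generator at its
defaults (1,000 background variants, 8 + 61 subjects, 300-sample
expression/survival tables) and complete in well under a minute on one
core; the heavier calibration checks use 2,000 log-rank null
replicates and 200 logistic-recovery replicates at n = 500. These
sizes were chosen so the Monte-Carlo error of each check is comfortably
below the margin being asserted.

# Command-line use

The exported functions are the primary interface. A thin wrapper
(`lipCli()`, installed at `inst/cli/metalip`) covers the three
shell-friendly entry points — `simulate`, `run-all` and `predict`
(which takes the yes/no carrier status of the panel variants and
prints a probability and risk tier, mirroring interactive risk
calculators). The remaining stages are deliberately *not* duplicated
as subcommands: they are single function calls on files the package
reads and writes anyway.

# Known limitations

* Absolute sLIP magnitudes are not comparable across zero policies,
  normalization policies or variant callers; only signs and orderings
  are.
* The eQTL and survival filters test marginal associations per
  variant; no covariate adjustment, no Cox modeling, no multi-gene
  signatures.
* The OR screen pools all case-control cohorts into one table; no
  per-cohort direction-consistency requirement is imposed.
* The MP/MR rule is an explicit formalization of a convention its
  sources leave implicit; alternative orientations for ambiguous
  variants are possible.
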
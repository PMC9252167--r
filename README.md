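# metalip

Local invasion power analysis and early metastatic risk modeling from
matched normal / paracancer / tumor variant profiles.

## What problem this solves

Colorectal tumors metastasize by first invading the histologically
normal-appearing tissue next to the tumor (*paracancer* tissue). When
the three matched tissues of a patient are exome-sequenced, each
variant's allele fraction (VAF) per tissue estimates the fraction of
DNA molecules carrying it, and the cross-tissue VAF ratios carry a
signal about which variants push cells outward. `metalip` is for
researchers with such tri-tissue variant calls (or case-control
carrier data) who want to score local invasion per variant and per
patient, screen for metastasis driver/resister variants, and assess
early metastatic risk — plus a seeded synthetic-cohort generator so
every stage runs and is testable without patient data.

## The statistic at the core

For variant *M<sub>i</sub>* with normalized VAFs *V<sub>MN<sub>i</sub></sub>*,
*V<sub>MP<sub>i</sub></sub>*, *V<sub>MT<sub>i</sub></sub>* in normal,
paracancer and tumor tissue:

- invasion promotion rate *R<sub>M<sub>i</sub></sub>* =
  *V<sub>MP<sub>i</sub></sub>* / *V<sub>MT<sub>i</sub></sub>*
- invasion resistance rate *R̄<sub>M<sub>i</sub></sub>* =
  *V<sub>MT<sub>i</sub></sub>* / *V<sub>MN<sub>i</sub></sub>*
- **LIP<sub>i</sub>** = log₂(*R<sub>M<sub>i</sub></sub>* /
  *R̄<sub>M<sub>i</sub></sub>*) =
  log₂(*V<sub>MP<sub>i</sub></sub>* · *V<sub>MN<sub>i</sub></sub>* /
  *V<sub>MT<sub>i</sub></sub>*²), in bits; LIP > 0 promotes invasion
- **sLIP** = Σᵢ LIP<sub>i</sub> per subject (linear-effect assumption)

On top of LIP sit a three-step driver screen (mean LIP > 1 or < −1;
carrier odds ratio > 5 with +∞ from zero control cells retained;
eQTL trend p < 0.01 and expression-stratified log-rank p < 0.01, with
promoter/resister classification) and a LIP-weighted logistic risk
model P(y=1) = 1/(1+exp(−Σ wᵢVᵢLᵢ − b)) evaluated by leave-one-out and
leave-one-cohort-out cross-validation. The methods vignette
(`vignettes/metalip-methods.Rmd`) derives and motivates each piece.

## Worked example

```r
library(metalip)

# the LIP of one variant: paracancer VAF double the tumor VAF
lipScore(vN = 0.25, vP = 0.5, vT = 0.25)
#>   R Rbar LIP
#> 1 2    1   1

# full synthetic study: simulate, score, screen, model
res <- runPipeline(generatorConfig(seed = 1), outDir = "run1")

perSubject(res$lip)
#>   subject group n_variants      sLIP
#> 1      L1    LM        695   8.39613
#> 2      L2    LM        690  23.72145
#> 3      L3    LM        694  15.06383
#> 4      L4    LM        709  21.23031
#> 5      N1    NM        711 -14.23626
#> 6      N2    NM        711 -24.07254
#> 7      N3    NM        697 -15.91902
#> 8      N4    NM        710 -20.62833
```

Every lymphatic-metastasis (LM) subject accumulates a positive sLIP
and every non-metastasis (NM) subject a negative one — the planted
invasion signal plus the small negative background drift. The group
contrast and the purity correlation:

```r
res$groupTest$p.value        # 0.02857143  (exact rank-sum, 4 vs 4)
res$purityCorrelation$r      # -0.9003454  (sLIP vs tumor-paracancer purity change)

funnel(res$cascade)
#>        input lip_positive     promoter     resister      or_pass     survived
#>         1000          363           10            1           11           11
```

Of 1,000 background plus 11 planted variants, the mean-LIP gate keeps
exactly the 10 planted drivers (promoter arm) and the planted resister;
all 11 survive the odds-ratio and expression/survival filters:

```r
head(candidates(res$cascade)[c("rsid", "class", "mean_LIP", "OR", "survival_p")], 3)
#>        rsid class mean_LIP   OR   survival_p
#> 1 rs9001001    MP 2.137237 20.8 1.801872e-24
#> 2 rs9001009    MP 2.386684  Inf 1.814320e-22
#> 3 rs9001008    MP 2.062941 20.8 5.706356e-22

res$loocv$pooled
#> EvalReport (threshold 0.50): TP=29 TN=25 FP=4 FN=3
#>   accuracy=0.8852 sensitivity=0.9062 specificity=0.8621 auc=0.9106
```

`MP` marks metastasis promoters, `MR` resisters; `OR = Inf` means no
control carried the variant. The leave-one-out cross-validated
classifier over the recovered 11-variant panel reaches AUC 0.91 on the
61 validation subjects. `runPipeline()` also writes the candidate
table, the serialized model, per-subject predictions with risk tiers
(high ≥ 0.75, moderate ≥ 0.5, mild < 0.5) and a checksummed run
manifest into the output directory.

A thin command-line wrapper is installed at `inst/cli/metalip`:

```sh
Rscript inst/cli/metalip run-all --seed 1 --out run1
Rscript inst/cli/metalip predict --model run1/risk_model.json \
        --status yes,no,no,yes,no,no,no,no,no,no,yes
```

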
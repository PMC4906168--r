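# spliceSurv

Survival analysis of mRNA isoform variation from RNA-seq splice-junction
read counts.

## What problem this solves

In clinical RNA-seq cohorts, the exon-inclusion level (PSI, *per cent
spliced in*) of an alternative exon is estimated per patient from a
handful of junction reads, so the estimate carries substantial,
coverage-dependent uncertainty. A conventional Cox regression on PSI
point estimates ignores that uncertainty and loses power exactly where
clinical data sets live: large sample size, modest sequencing depth.

`spliceSurv` fits a **measurement-error proportional-hazards model**
per exon-skipping event. Patient *k*'s hazard is

    lambda_k(t) = lambda_0(t) * exp(beta * psi_k)

with the latent inclusion level `psi_k` as covariate, while the
observed inclusion-junction count is binomial,

    IC_k ~ Binomial(n_k, f(psi_k)),   f(psi) = l_I psi / (l_I psi + l_S (1 - psi)),

where `f` converts the inclusion level into a read proportion via the
isoform effective lengths (`l_I = 2`, `l_S = 1` for junction-only
counting). The per-exon likelihood integrates the latent `psi_k` out of
the product of the two components (64-node Gauss–Legendre quadrature,
log space), the cumulative baseline hazard is profiled out of the fit
(Breslow increments with posterior-expected relative hazards), and the
association is tested with a likelihood-ratio test against chi-squared
with 1 df, followed by Benjamini–Hochberg FDR across exons.

The package also provides the Cox-on-point-estimates comparator, a
Gamma–Poisson cohort simulator reproducing the reference study design
(600 subjects, 20,000 exons, 10% alternative, 85% censoring, mean
depths 5–100), ROC / concordance-index / Kaplan–Meier / two-means
stratification utilities, and a Monte Carlo cross-validated survival
prediction workflow built on univariate screening plus L1-penalized Cox
regression. See the vignette in `vignettes/` for the model, priors,
and numerical choices.

## Worked example

Simulate a shallow cohort (mean 10 junction reads per exon and
patient, 85% censoring), fit both methods, and score detection of the
truly survival-associated exons:

```r
library(spliceSurv)

sc <- simScenario(nSubjects = 200L, nExons = 400L, altFraction = 0.1,
                  meanDepth = 10, seed = 7L)
co <- simulateCohort(sc)
res <- fitSimulatedCohort(co, "me")    # measurement-error model
cox <- fitSimulatedCohort(co, "cox")   # comparator on PSI point estimates

lab <- as.integer(trueBeta(co) != 0)
ok  <- !is.na(res$pvalue); okc <- !is.na(cox$pvalue)
rocFromPvalues(res$pvalue[ok],  lab[ok])$tprAt
rocFromPvalues(cox$pvalue[okc], lab[okc])$tprAt
```

which prints (exactly reproducible from the seed):

```
ME : AUC 0.745  TPR@5%FPR 0.400
Cox: AUC 0.708  TPR@5%FPR 0.275
```

i.e. at a 5% false-positive rate the measurement-error model recovers
40% of the truly associated exons versus 27.5% for Cox on point
estimates — the low-depth advantage of modelling the read-count
uncertainty. The top of the per-exon result table:

```
  exon_id  beta   pvalue true_beta
1 exon368  3.44 0.000199      3.57
2 exon248  9.22 0.000259      3.27
3  exon31  3.76 0.001199      1.98
4 exon187 -3.48 0.001326     -2.29
5 exon100  3.79 0.003905      3.39
```

`beta` is the fitted hazard log-ratio per unit PSI (positive = higher
inclusion, poorer survival); `pvalue` is the likelihood-ratio test
against `beta = 0`.

For real data, build the dataset from the TSV contract
(`exon_id, l_inc, l_skip, <patient>_IC, <patient>_SC, ...` and
`patient_id, time, event`):

```r
sds <- readSpliceSurvDataSet("counts.tsv", "survival.tsv")
res <- fitSplicingSurvival(sds)
writeResultsTable(as.data.frame(res)[, 1:7], "results.tsv")
```

A thin command-line wrapper with `fit`, `cox`, `simulate` and
`evaluate` subcommands is installed at `inst/scripts/splice-surv`.

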
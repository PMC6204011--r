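# cstdyn

Coordinated development of infant gut, nasal and throat microbiota,
analyzed through community state types (CSTs).

Longitudinal 16S cohorts of pre-term and full-term infants pose a
specific statistical problem: every subject carries three clocks —
gestational age at birth (GA), week of life (WOL) and post-menstrual age
(PMA = GA + WOL) — and microbiota development at each body site may
follow any of them. cstdyn packages the full analysis chain for such
cohorts, for microbiome researchers who have per-site OTU count tables
and visit metadata:

* **CST inference.** Per site, samples are clustered with
  Dirichlet-multinomial mixtures: component *k* is a Dirichlet prior
  α<sub>k</sub> over OTUs, counts are multinomial given proportions drawn
  from it. The number of components is chosen by the Laplace
  approximation of the negative log model evidence on ten random 80%
  subsamples, with a one-standard-error rule; samples get posterior CST
  memberships and MAP labels, CST 1 the most frequent.
* **Temporal structure.** Each CST's occurrence probability is modeled on
  the linear probability scale as a penalized smooth of (WOL, GA) with a
  subject random intercept, and as a *single-index* model
  P(CST) = f(a·WOL + b·GA), a² + b² = 1. Binning log2(b/a), together with
  a logistic test of any-occurrence against GA, classifies every CST as
  *chronological* (WOL-driven), *convergent* (PMA-like index; pre-terms
  catch up) or *idiosyncratic to maturity at birth*.
* **Cross-site association.** Same-visit sample pairs feed a chi-squared
  test of CST co-occurrence, Pearson correlations of CST membership
  probabilities, and per-taxon linear mixed models (arcsine-sqrt
  abundance ~ remote-site CSTs + delivery mode + GA + birth season +
  natural spline of WOL + subject intercept) with Wald deviation tests,
  block Wald-F tests, marginal ΔR², and per-site Benjamini-Hochberg
  control with most-specific-taxon roll-up.
* **Time-adjusted CCA.** Canonical correlations between the CSS-normalized
  compositions of two sites, cross-validated over subject-blocked folds,
  before and after regressing a 14/25-df PMA spline out of every feature.
* **Synthetic cohorts.** A generator with known ground truth (latent CST
  paths, index weights, cross-site coupling) emulating the 38 pre-term +
  44 full-term weekly/monthly design, so the whole pipeline is testable
  without external data.

## Worked example

Simulate a small two-site cohort, infer CSTs, and classify one CST's
temporal pattern:

```r
library(cstdyn)

cfg <- synth_config(
  n_preterm = 10, n_fullterm = 10,
  sites = list(gut = synth_site_spec(k = 3, n_otus = 24)),
  coupling = data.frame(site = character(0), source = character(0),
                        kappa = numeric(0)),
  seed = 7)
sim <- simulate_cohort(cfg)

ct  <- dmm_normalize(prevalence_filter(sim$counts$gut))
ks  <- select_k(ct, k_max = 4, reps = 10, seed = 1)
ks
#> Component selection over k = 1..4 (10 subsamples of 80%)
#>              k1         k2         k3         k4
#> mean 3149455.98 3146077.99 3143706.91 3143662.80
#> sem      654.64     725.94     655.66     656.28
#> chosen k = 3 (one_se rule)

fit <- dmm(ct, ks$chosen_k, seed = 1)
asg <- assign_cst(fit, ct, site = "gut")
asg
#> CST assignment (gut): 366 samples, 3 CSTs
#> CST
#>   1   2   3
#> 217  87  62

si <- single_index(asg$posterior[, 1], sim$samples$wol,
                   sim$samples$ga_birth, sim$samples$subject_id)
si
#> Single-index fit: a = 0.679 (WOL), b = 0.734 (gaBirth), theta = 47.2 deg
#>   log2(b/a) = 0.112, REML criterion -51.9141

occ <- tapply(asg$cst == 1, sim$samples$subject_id, any)
gab <- tapply(sim$samples$ga_birth, sim$samples$subject_id, `[`, 1)
p   <- occurrence_logistic_test(as.logical(occ), as.numeric(gab))$p_value
classify_pattern(si$a, si$b, p)
#>           a         b log2_ratio occurrence_p      class
#> 1 0.6791489 0.7340006  0.1120533            1 convergent
```

Reading the output: the evidence curve flattens at k = 3, the true number
of generating components; the most frequent gut CST (217 of 366 samples)
gets index weights a ≈ 0.68, b ≈ 0.73, i.e. log2(b/a) ≈ 0.11 — prenatal
and postnatal weeks contribute about equally, a PMA-like clock — and with
no GA-occurrence association (p = 1) the CST is classified *convergent*:
pre-term infants manifest it after a delay proportional to their
prematurity. (This CST was generated with a = b = 1; the generator's
ground truth in `sim$truth` lets you check every such call.)

The full pipeline — filtering, K selection, assignment, temporal
classification, cross-site suite, CCA — runs from one config and writes
TSV tables plus a hashed manifest:

```r
run_pipeline(pipeline_config(seed = 1), "results/benchmark")
```

## Layout

```
R/                  implementation (io/prep, synthetic cohorts, DMM/CST,
                    temporal models, cross-site suite, CCA, pipeline)
src/                Rcpp core of the DMM EM
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, assumptions, design choices)
scripts/acceptance.R  benchmark reproduction script
```
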
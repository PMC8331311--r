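---
title: "Gene-pair prognostic signatures: models, policies and the synthetic testbed"
author: "irgpsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: models, policies and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpsig)
```

## The model

For an ordered pair of genes $(a, b)$ and a sample $s$ with expression
values $x_{a s}, x_{b s}$, the pair feature is the binary indicator

$$I_{(a,b)}(s) = \mathbf{1}\{x_{a s} > x_{b s}\},$$

with ties scoring 0. The feature uses only the within-sample ordering of
the two genes, so it is invariant under any strictly increasing transform
of a sample's expression profile. That is the point of the construction:
RNA-seq FPKM/TPM values and microarray intensities differ by roughly
monotone, platform-specific distortions, and rank-pair features cross that
divide without joint normalisation, quantile matching or batch correction.
A patient can be scored from a single profile.

The prognostic signature is a sparse linear risk score over selected pairs,

$$\eta_s = \sum_k \beta_k \, I_{(a_k, b_k)}(s),$$

with coefficients $\beta_k$ from an L1-penalised Cox proportional-hazards
fit, dichotomised at a cutoff $c$ into high risk ($\eta_s > c$) and low
risk ($\eta_s \le c$). The package ships a published 37-pair bladder-cancer
signature with its cutoff $c = -0.13$ (`load_signature_fixture()`,
checksummed at load); `apply_published_signature()` scores any expression
matrix containing the 74 signature genes.

## Pair enumeration

`enumerate_pairs()` defaults to the full ordered Cartesian product over the
sorted gene list, self-pairs included: $n$ genes give $n^2$ pairs, and a
1,223-gene list gives 1,495,729. Self-pairs are constant 0 and the two
orientations of a pair are complementary off ties, so the `"unordered"`
convention ($n(n-1)/2$ pairs) carries the same information at a quarter of
the size; it is offered for efficiency. Constant indicator rows — all
self-pairs, and any pair whose ordering never varies in the data — are
removed by `drop_degenerate_pairs()` before testing, because association
and survival tests are undefined for them.

Indicator matrices are stored as plain dense integer matrices. At the
scales this package targets (up to a few hundred genes, i.e. tens of
thousands of pairs, by a few hundred samples) this is a few tens of
megabytes. Full-scale enumeration of a 1,223-gene universe is supported as
pair *enumeration* (the count above); materialising all 1.5M indicator
rows is not something the analysis ever needs, and the package does not
optimise for it.

## Two-stage screening

**Stage 1 (differential frequency).** For each pair, the 2×2 table of
indicator value by tumor/normal label is tested per cohort. Policy: a
Pearson chi-square test *without* continuity correction when every
expected cell count is at least 5, Fisher's exact test (two-sided)
otherwise; either test can be forced. Yates' correction is deliberately
not used: on 2×2 tables it makes the screen conservative (empirical size
well below the nominal 0.05), and the uncorrected Pearson statistic at
expected counts ≥ 5 is the standard screening practice. A table with a
zero margin carries no evidence and scores p = 1. Pairs flagged in *both*
cohorts (`shared_differential()`) move on; requiring both cohorts is what
filters platform-specific artifacts.

**Stage 2 (prognostic association).** Patients are first filtered to
follow-up strictly greater than 30 days with known event status
(`filter_patients()`; the strict inequality is intentional — exactly 30
days is excluded). Each surviving pair is tested two ways: a univariate
Cox proportional-hazards fit on the indicator (Efron tie handling; Wald p)
and a log-rank test between the indicator-defined groups. The prognostic
flag requires **both** p-values below the screening level (default
α = 0.05); an OR combination is available. Both screens use raw p-values
by default, mirroring the screening tradition this design comes from; a
Benjamini–Hochberg mode (`fdr = TRUE`) is provided but off by default.
Pairs whose indicator is constant among analysed patients, or whose Cox
likelihood is monotone (the indicator perfectly orders the risk sets), are
skipped with the reason recorded rather than reported with meaningless
statistics.

## Penalised fit, risk score and cutoff

`fit_l1_cox()` maximises the L1-penalised Cox partial likelihood over the
candidate indicators (glmnet). Policy decisions, each of which the
underlying literature leaves open:

* **Penalty choice**: 10-fold cross-validated partial-likelihood deviance,
  penalty at the minimum (not the 1-SE rule). Fold assignment is seeded;
  folds are redrawn (with a message) until every fold contains an event.
* **No standardisation**: indicators enter as raw 0/1 columns so the
  returned coefficients apply directly to indicator profiles — the
  published signature's coefficients are on this scale.
* Pairs with zero coefficient at the chosen penalty are dropped from the
  returned model.

`find_optimal_cutoff()` implements the maximally selected log-rank
statistic: candidate cutoffs are the midpoints of adjacent sorted unique
scores; candidates leaving either group below a minimum fraction of
patients (default 10%) are infeasible; the feasible candidate maximising
the two-sample log-rank chi-square is returned, ties resolved to the
smallest cutoff. `classify_patients()` assigns high risk strictly above
the cutoff; a score exactly at the cutoff is low risk (documented
tie rule).

## Evaluation tools

* `km_logrank()` — Kaplan–Meier curves per risk group plus the log-rank
  chi-square and p (survival package underneath).
* `cox_model()` / `cox_report()` — univariate and multivariate Cox
  reports (HR, Wald 95% CI, p). T/N/M stages enter as ordinal integers via
  `encode_stage()` (T0 < … < T4, N0 < … < N3, M0 < M1); unknown codes
  (TX/NX/MX/NA) become NA and drop out of the affected model's rows only.
  The combined report admits to the multivariate model only covariates
  significant univariately (configurable to all) — the convention used in
  the clinical tables this mirrors, where a non-significant sex covariate
  is simply absent from the adjusted model.
* `time_dependent_auc()` — cumulative-cases / dynamic-controls AUC with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimate
  of the censoring distribution. At horizon $t$: cases are patients with
  an observed event by $t$, weighted $1/\hat G(T_i^-)$; controls are
  patients at risk beyond $t$, weighted $1/\hat G(t)$; the AUC is the
  weighted exceedance probability with ties counting ½. This estimator
  was chosen because it is well defined at fixed horizons and reduces
  *exactly* to empirical case/control concordance when censoring is
  absent, which makes it oracle-checkable by brute-force pair counting.
  Horizons lacking cases or controls are omitted with a warning.
* `discretize_segment_mean()` — copy-number calls at the ±0.2 segment-mean
  thresholds: below −0.2 → loss (−1), above +0.2 → gain (+1), the *closed*
  interval [−0.2, 0.2] → wild type (0). The boundary values map to 0; the
  threshold is configurable. `cnv_frequency_compare()` tests per-gene
  altered-vs-wild frequencies between risk groups with the same
  chi-square/Fisher policy as the screen.
* `group_difference()` — two-sided Wilcoxon rank-sum: exact when the
  combined sample is ≤ 20 without ties, normal approximation with
  continuity and tie correction otherwise; an all-tied comparison returns
  p = 1 with a warning.

## The synthetic testbed

`simulate_study()` generates the dual-cohort structure the pipeline
assumes, so every stage is testable without external data.

**What it emulates.**

* Two cohorts share one latent layout of gene-level means, so the
  within-sample orderings of latent means agree across cohorts; each
  cohort is then observed through its own strictly monotone platform
  transform (`apply_platform_transform()`, registry of monotone maps) —
  the cross-platform situation rank-pair features are built for.
* Tumor/normal labels per cohort.
* Planted signal pairs: each owns two dedicated genes separated by
  `signal_gap` (default 2 latent units, noise SD 0.4, so the reference
  ordering holds in normals with ~0.2% error). A tumor sample flips a
  pair's ordering with marginal probability `flip_prob_tumor` (default
  0.5, the variance-maximising choice for a binary feature).
* Correlated flips: a per-sample aggressiveness latent $a_s \sim N(0,1)$
  shifts every pair's flip probability on the logit scale
  (`flip_correlation`, default 1.5), oriented by the sign of the pair's
  effect so hazard-raising orderings co-occur in aggressive tumors. Real
  prognostic signatures show exactly this correlated block structure
  across patients; with fully independent flips, each pair's *marginal*
  association with survival is strongly attenuated by the unexplained
  variance of the other effects, which no univariate screen can overcome.
* Survival: exponential times at rate
  $h_0 \exp(\eta_s)$, where $\eta_s$ sums the planted pair indicators
  (weights default ±0.8, alternating sign) and clinical terms (age,
  ordinal T stage); censoring uniform on (0, `censor_window`),
  independent of everything. Defaults $h_0 = 5\times10^{-4}$/day and a
  3,000-day window give a median survival around two years at $\eta = 0$
  and roughly half the patients censored — the event maturity of a
  typical muscle-invasive bladder-cancer cohort. The exponential law is
  the simplest generator consistent with proportional hazards.
* Clinical covariates: age normal(68, 8) truncated to [34, 89], sex ~3:1
  male, T/N/M multinomials resembling a muscle-invasive cohort (unknown
  codes included).
* `simulate_segment_means()` draws per-gene, per-sample segment means from
  loss/neutral/gain mixtures with group-specific weights, with components
  placed so discretisation recovers the component exactly.

**Identifiability by construction.** Signal pairs occupy pairwise disjoint
value bands, with background genes kept outside all bands. If a third gene
sat inside a pair's swap band, its comparisons with the pair's genes would
form indicator columns nearly collinear with the planted one, and no
selection method could prefer the planted pair over its proxies. With
disjoint bands, cross-pair and background comparisons are constant (and
removed as degenerate) or uninformative noise, so the planted indicators
are exactly the identifiable signal. The latent scale is arbitrary and
partly unrealistic (values up to ~60 latent units for 20 pairs); this is
immaterial because the pipeline consumes only within-sample orderings,
and the platform transforms remap the scale anyway.

**What it does not emulate** — and hence what passing tests do not show
about real data: realistic marginal expression distributions; correlated
background genes (co-expression modules); probe-level artifacts beyond
the largest-mean collapse rule; non-proportional or time-varying hazards;
informative censoring; missing clinical data mechanisms beyond unknown
stage codes; somatic mutations. Recovery results on the testbed
demonstrate that the pipeline's stages compose correctly and are
calibrated, not that 37 particular pairs generalise to any cohort.

## Numerical choices and degenerate inputs

* Ties in expression score 0 in the indicator ("otherwise" clause); ties
  at the risk-score cutoff go to low risk; probe-collapse ties keep the
  probe earlier in input order.
* The stratified 7:3 split (`split_cohort()`) stratifies on T stage,
  assigns ⌈0.7·n⌉ per stratum to training (a singleton stratum therefore
  always trains, with a message), and is a deterministic function of the
  seed. A 391-patient cohort reproduces the published 276/115 shape only
  approximately, since the original rounding rule is unknowable.
* The signature fixture is checksummed (md5) at load; corruption is an
  error, not a silent re-read.
* Seeded randomness is confined with an RNG-state–restoring helper, so
  package calls do not perturb the caller's random stream.
* Test problem sizes: calibration suites use 10,000 null pairs at
  100–150 patients; oracle equivalences run at n ≤ 500; the end-to-end
  recovery study uses the generator defaults (two cohorts of 300 tumors +
  50 normals, 100 genes, 20 planted pairs) over 20 replicates. These
  sizes keep the full suite in the low minutes on one CPU while leaving
  Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The screens test pairs marginally; strongly correlated candidate pairs
  can pass or fail together, and the penalised fit resolves such groups
  arbitrarily (any L1 method does, under near-collinearity).
* The log-rank–maximising cutoff is an optimised statistic; its p-value
  on the *same* data is optimistic and should be read descriptively.
  Validation belongs on independent data, as in the end-to-end tests.
* `cox_report()`'s ordinal stage encoding assumes a linear per-level
  log-hazard; dummy coding is not currently offered.
* The IPCW censoring model is the marginal Kaplan–Meier (censoring
  independent of covariates); covariate-dependent censoring would bias
  the AUC weights.
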
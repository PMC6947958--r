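---
title: "Discovering and classifying blood DNA-methylation episignatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and classifying blood DNA-methylation episignatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Several Mendelian neurodevelopmental disorders caused by mutations in
chromatin-machinery genes leave a reproducible genome-wide DNA-methylation
fingerprint in peripheral blood — an *episignature*. Once such a probe set is
characterised on Illumina 450K/EPIC arrays, a supervised classifier over those
probes can screen undiagnosed patients and classify variants of uncertain
significance. The statistical difficulty is the design: a handful of cases
(often fewer than ten) against database controls, with leukocyte composition,
age, sex and batch all able to masquerade as disease signal.

`episignr` implements the full discovery-and-classification chain as tested,
reusable functions, together with a synthetic cohort generator
(`simulate_reference()`, `sim_config()`, `simulate_cohort()`,
`simulate_samples()`) that reproduces the statistical structure the analysis
assumes, so that every stage is verifiable against a known truth table
without access to patient arrays.

# Pipeline model

## Quality control

The methylation level of a CpG probe is the beta value
$\beta = M/(M+U) \in [0,1]$ from methylated and unmethylated intensities
(`compute_beta()`; both-zero signals are missing). Probe-level filters
(`filter_probes()`) remove probes failing detection ($p > 0.01$) in **any**
retained sample, probes on chromosomes X and Y, SNP-containing probes, and
cross-reactive probes. The any-sample detection rule is deliberately
conservative: a cohort-wide clean probe set keeps downstream per-probe degrees
of freedom uniform. Arrays with more than 5% failing probes are excluded
first (`filter_failed_arrays()`), so a single bad array cannot doom probes
for everyone.

Sample-level sanity checks: `predict_sex()` uses the median log2 total
intensity of X-chromosome probes minus that of Y-chromosome probes — females
(two X copies, background-level Y signal) score high — split by an exact 1-D
two-means clustering; when the two centres are closer than 2 (a single-sex
cohort), a fixed threshold of 0 is used with a warning.
`bimodality_check()` fails samples whose mid-range $\beta \in (0.3, 0.7)$
mass exceeds 0.35; clean arrays are strongly bimodal (a uniform sample has
mid-mass 0.40). A fixed mass rule was chosen over a dip statistic because it
is deterministic and directly explainable.

`pca_outliers()` projects samples onto the first two principal components
and flags deviations from the component median in robust-SD (MAD) units.
The cutoff is *multiplicity-calibrated*: examining $n$ samples on two
components is $2n$ implicit tests, so a fixed 3-SD rule flags about one
clean sample per 60–70-sample cohort by chance, which would make any
iterative flag-reacting loop churn indefinitely. The cutoff is
$(k_{sd}/3)\,\Phi^{-1}(1-\alpha/(4n))$ robust SDs with $\alpha = 0.01$
family-wise, so a clean cohort is flag-free with probability about
$1-\alpha$ while a globally shifted sample (e.g. +0.3 beta) is still flagged
essentially always. `k_sd` keeps its conventional meaning (3 = calibrated
default, 0 = flag everything).

## Matched-control selection

`match_controls()` performs greedy 1:`ratio` nearest-age matching within
exact sex strata, without replacement, cases in input order, age ties broken
by smallest sample id — the simplest deterministic reading of "matched by
age and sex". `iterative_match()` wraps it in the loop: match, PCA over
cases plus matched controls, remove flagged controls from the pool, rematch,
until no sample is flagged. A flagged **case** aborts with diagnostics
rather than being dropped: with six cases, silently losing one would change
the signature being discovered.

## Differential methylation

Testing happens on M values, $M = \log_2(\beta'/(1-\beta'))$ with
$\beta' = \mathrm{clip}(\beta, \varepsilon, 1-\varepsilon)$,
$\varepsilon = 0.001$ (boundary betas occur; the clip bounds the logit).
Leukocyte proportions are estimated by constrained projection onto a
cell-type reference over high-contrast marker probes
(`estimate_cell_composition()`): minimise $\lVert \beta - R w \rVert^2$
subject to $w \ge 0$, $\sum_k w_k \le 1$, solved as a quadratic program.
The design matrix (`build_design()`) holds an intercept, the case indicator,
and $K-1$ of the $K$ composition covariates — one type is dropped because
proportions near-sum to one and would be collinear with the intercept.

`fit_probe_models()` fits ordinary least squares to every probe by matrix
algebra; `ebayes_moderate()` shrinks the per-probe residual variances toward
a pooled prior. The prior $(d_0, s_0^2)$ is fitted by the closed-form method
of moments on $\log s^2_g$ (digamma/trigamma inversion); the posterior
variance is $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ and the
moderated $t$ is referred to $d_0 + d_g$ degrees of freedom, two-sided.
When the observed variances show no excess dispersion beyond chi-square
sampling noise, the prior degrees of freedom are infinite and the scale is
the geometric mean of the variances, so moderated and ordinary statistics
coincide in the degenerate all-equal case. The implementation is
cross-checked in the test suite against an independent empirical-Bayes
fit (limma's `fitFDist`) — agreement to 6 decimals — but does not call it.

Significant probes (`select_dmps()`) must pass both $q < 0.01$
(Benjamini–Hochberg, `bh_adjust()`, delegating to `stats::p.adjust`) **and**
$|\Delta\beta| > 0.10$, where $\Delta\beta$ is the difference of group mean
betas. The effect threshold is computed on the beta scale — an
interpretable methylation percentage — even though testing is done on the M
scale; this suppresses probes whose significance rests on tiny, technically
fragile differences. $\Delta\beta$ is computed on the matched controls used
in the regression.

## Region calling

`probe_z()` converts two-sided p-values to signed z-scores,
$z = \mathrm{sign}(\Delta\beta)\,\Phi^{-1}(1-p/2)$. `kernel_smooth()`
smooths them along the genome per chromosome with a Gaussian kernel
($\sigma = \lambda/C$, defaults $\lambda = 1000$ bp, $C = 2$, consistent
with the 1-kb grouping rule), normalising by $\sqrt{\sum_j K_{ij}^2}$ so the
smoothed statistic keeps unit variance under an independent null.
`call_regions()` seeds regions from probe-level significant CpGs
($q < 0.01$), groups seeds with consecutive gaps $\le 1$ kb on one
chromosome, requires $\ge 3$ probes, combines member z-scores by Stouffer's
method $Z = \sum z_i / \sqrt{n}$, BH-adjusts the region p-values across
candidates, and reports regions with FDR $< 0.01$ and
$|\overline{\Delta\beta}| > 0.10$.

Two open points are resolved as follows and kept switchable. Seeding comes
from probe-level significance by default (`seed_from = "probe"`); seeding
from the smoothed statistic is available (`seed_from = "smoothed"`), since
either reading is compatible with kernel-smoothed region identification.
The Stouffer combination assumes independent probes and is anti-conservative
under the spatial correlation that makes regions regions; the structural
rules ($\ge 3$ probes, gap and effect thresholds) are what keep calls
regional, and the smoothed statistic is reported as a diagnostic
(`mean_smoothed_z`). Coordinates are 1-based inclusive throughout (array
manifest convention); `write_dmr_bed()` converts to BED's 0-based half-open.

Regions map to genes by $\ge 1$ bp interval overlap
(`map_regions_to_genes()`), and gene sets are tested by the one-sided
hypergeometric tail with BH correction (`enrichment_test()`, GMT input via
`read_gmt()`).

## Clustering diagnostics and classifier

`ward_cluster()` (Ward's minimum-variance criterion on Euclidean distances,
`hclust` `"ward.D2"`) and `mds_embed()` (classical Torgerson scaling:
double-centred squared distances, top eigenpairs) visualise the structure of
the signature; on rank-2 data the embedding reproduces distances exactly.

The classifier (`train_rf()`) is a random forest over signature-probe betas,
restricted to probes present on both array generations so 450K and EPIC
profiles can be scored (`create_episignature()`, `build_features()`).
Hyperparameter `mtry` is chosen by stratified 10-fold cross-validation over
$\{\lfloor\sqrt p\rfloor/2, \lfloor\sqrt p\rfloor, 2\lfloor\sqrt p\rfloor\}$
(500 trees, the conventional default bracketed; ties go to the smallest
`mtry`), then the model is refit on all samples and applied back to its
training set as a success check. A sample's score (`score_samples()`) is the
fraction of trees voting the case class — a confidence in $[0,1]$ with the
class call at 0.5. Per-tree majority votes are used rather than
probability-weighted voting, to keep the score an actual vote fraction.
Missing signature probes in a scored profile are imputed with
discovery-control means up to a 5% cap (`build_features()`); beyond that the
profile is refused. `specificity_battery()` scores tagged cohorts (healthy,
isolated cell types, other syndromes, unresolved screens) and summarises
score distributions per cohort, isolating per-cohort failures.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a rare-syndrome
blood methylation study; defaults are the discovery design: 6 cases, a
matched-control pool, $10^5$ probes, a planted 1000-probe signature with
$|\Delta\beta| \in [0.10, 0.25]$ of which 4.6% hypermethylated, concentrated
in 100 five-probe blocks spaced $\le 200$ bp.

Its components, and why they are there:

* **Cell-type mixtures.** Each sample's expected beta is
  $\sum_k w_k \cdot \text{profile}_k$ with $w$ drawn from group-specific
  Dirichlet distributions, so composition genuinely confounds the contrast
  and the Houseman-style adjustment is exercised, not decorative. The
  reference (`simulate_reference()`) carries marker probes with $\ge 0.5$
  between-type contrast for deconvolution. The real cohorts'
  composition spread is unpublished; the Dirichlet concentrations were
  chosen once for testability (clear confounding, realistic whole-blood
  means) rather than fitted to data.
* **Beta-distributed observation noise** with mean equal to the expected
  value and precision `noise_precision` (default 100, per-probe SD about
  0.02–0.05) keeps observations in $[0,1]$ without truncation dominating.
* **Population heterogeneity.** Samples draw standard-normal scores on five
  latent methylation axes with per-probe loadings of SD 0.01 (beta scale),
  identically distributed in both groups. Real blood methylomes have
  strongly structured inter-individual variation that dominates the top
  principal components; without it, a planted signature on 1% of probes
  unrealistically surfaces in PC2 and the matching loop's outlier PCA would
  "discover" the biology as an artifact.
* **Nuisance effects**: uniform ages with per-probe age slopes on 1% of
  probes, batch intercepts (SD 0.01) and sex-dependent sex-chromosome
  intensities (near-background Y in females, single-copy X in males), so
  sex prediction and batch examination are exercisable.
* **Baseline bimodality.** Background betas mix an unmethylated mode
  Beta(4, 22), a methylated mode Beta(22, 4) and a 10% mid class — mode
  peaks near 0.12 and 0.88, because Infinium intensities saturate before
  0/1; placing heavy mass above $\beta = 0.95$, where the logit explodes,
  would misrepresent the platform.
* **Planted truth.** Signature probes are drawn from CpGs with enough
  headroom that the configured shift keeps expected betas inside $(0,1)$
  (any residual excursion is clipped and counted), and deconvolution marker
  probes are excluded from planting. Direction counts are exact —
  `round(hyper_fraction * n_signature_probes)` hypermethylated, allocated
  to blocks proportionally — rather than sampled: the truth table should
  impose its configured composition, not draw it by lot.
* **Array dialects** are boolean masks on one master manifest; the 450K
  mask is a strict subset of EPIC. Signals are emitted as
  $M = \beta T$, $U = (1-\beta) T$ with log-normal total intensity $T$, so
  `compute_beta()` reproduces the simulated betas to $10^{-12}$.
* **Reproducibility**: one global seed is split into per-stage substreams,
  so e.g. the manifest is identical across two runs that differ only in a
  downstream stage.

What the generator does **not** model: probe chemistry (Type I/II), IDAT
binary format, dye bias or normalisation artifacts, genuine spatial
correlation of background methylation beyond the planted blocks, and
age/population structure in the composition weights. Passing tests
therefore demonstrate correctness of the statistical machinery under the
model's assumptions — not performance on raw instrument output, which in
production enters this pipeline only after platform-specific normalisation.

# Numerical choices

* Logit clip $\varepsilon = 0.001$; M values are bounded by $\pm\log_2 999
  \approx \pm 9.97$.
* Trigamma inversion by Newton iteration (monotone on $(0,\infty)$,
  convergence tolerance $10^{-8}$); no excess dispersion ⇒ infinite prior
  df and geometric-mean scale.
* The deconvolution quadratic program adds a $10^{-9}$ ridge for numerical
  positive-definiteness; weights are clipped at 0 after solving.
* Kernel smoothing truncates Gaussian weights beyond $5\sigma$.
* `probe_z()` clips $p = 0$ to the smallest positive double.
* Degenerate inputs: constant matrices warn in clustering; two-means sex
  clustering falls back to a fixed threshold when centres are within 2;
  `k_sd = 0` flags all samples; empty DMP tables yield empty (typed) DMR
  tables and a `NULL` signature.
* Tie-breaks are deterministic everywhere (age ties by sample id, `mtry`
  ties by smallest value).

# Problem sizes in the test suite

The packaged tests exercise the full design at discovery scale — $10^5$
probes, 6 cases vs 60 matched controls from a 70-control pool — once for
signal recovery and classifier validation (with 500 healthy, 200
other-signature, 18 pure-cell-type and 100 screening samples scored at the
signature probes), and twenty replicates for null calibration. Unit tests
use 2000–20000-probe cohorts. These sizes were chosen so the whole suite
exercises every claim in minutes while keeping every check at the design's
true case-control imbalance, which is the statistically hard part; probe
count scales the multiple-testing burden linearly and $10^5$ is enough to
make an FDR of 0.01 meaningful.

# Known limitations

* The Stouffer region p-value ignores inter-probe correlation and is
  anti-conservative for tight probe clusters; treat region FDR as a ranking
  device backed by the structural rules, as region-combination methods
  commonly do.
* Greedy nearest-age matching is order-dependent across cases (each case
  takes its best remaining controls); no optimal/caliper matching variants.
* The classifier's vote-fraction score is uncalibrated confidence, not a
  probability; no multi-syndrome classification.
* No normalisation, background correction or batch correction beyond PCA
  flagging — inputs are assumed normalised betas or signals.
* Sex prediction assumes intensity dosage; it has no concept of sex
  chromosome aneuploidy.
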
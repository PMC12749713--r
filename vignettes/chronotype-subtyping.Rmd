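---
title: "Latent chronotype subtyping with chronopls: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent chronotype subtyping with chronopls: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopls)
```

## The scientific problem

Chronotype — a person's diurnal preference for morningness or eveningness —
is a coarse, binary-codable trait, yet it is linked to a wide range of brain,
behavioural and health differences. Rather than asking *whether* the brain
differs between early birds and night owls, `chronopls` asks *in how many
distinct ways* it does: it extracts multiple orthogonal latent components
("subtypes") of a multimodal brain-feature matrix that each covary with the
binary trait, then characterises every component separately — its statistical
significance, the robustness of its anatomical loadings, its phenome-wide
association profile, and its age distribution in a second, independently
measured cohort.

The intended feature matrix concatenates three blocks of imaging-derived
phenotypes (IDPs): regional grey-matter volumes (GMV, 139 features in the
default design), fractional anisotropy of major white-matter tracts (FA, 48),
and functional-connectivity link strengths between 21 network components
(FC, 21·20/2 = 210). Access to the population cohorts this design mirrors is
restricted, so the package ships a synthetic cohort generator that plants
known brain–trait covariance modes; every statistical claim the package makes
is verified against that ground truth.

## The model

Write $X$ for the $n \times p$ matrix of residualized brain features and
$y \in \{-1, +1\}^n$ for the encoded chronotype (−1 early bird, +1 night
owl). `chronopls()` fits a PLS1 regression: components are extracted
sequentially, and for the current deflated matrix $X_h$ and response $y_h$,

$$ w_h = \frac{X_h^\top y_h}{\lVert X_h^\top y_h \rVert}, \qquad
   t_h = X_h w_h, \qquad
   p_h = \frac{X_h^\top t_h}{t_h^\top t_h}, \qquad
   q_h = \frac{y_h^\top t_h}{t_h^\top t_h}, $$

followed by deflation $X_{h+1} = X_h - t_h p_h^\top$ and
$y_{h+1} = y_h - q_h t_h$. With a single response the NIPALS inner iteration
converges in one pass, so this closed form *is* the converged NIPALS
solution and fitting is fully deterministic — no random initialisation
exists to seed. Score columns are mutually orthogonal by construction, and
the rotation identity $T = X_c W (P^\top W)^{-1}$ holds on the training
data; both are asserted to $10^{-8}$ in the test suite on every fit.

Three conventions matter in practice:

* **Scaling.** Features are centered and scaled to unit variance before
  fitting (volumes, anisotropy values and correlation strengths live on
  incommensurate scales, and PLS maximises covariance, which is
  scale-sensitive). The centering/scaling vectors are stored in the model so
  prediction and cross-cohort projection are self-contained.
* **Sign.** A PLS component is only identified up to sign. Each component is
  oriented so its largest-magnitude weight entry is positive; the
  morning/evening meaning of a component is then read off its latent
  correlation or the group t-test reported by `summary()`, not off the
  algebraic sign.
* **Latent correlation.** The strength of component $j$ is
  $\rho_j = \mathrm{cor}(t_j, y)$. With a single response, the correlation
  with the response and with the y-scores agree up to sign, so the package
  uses the response directly and reports signed values.

## Data preparation

`preprocess_cohort()` reproduces the preparation contract of the study
design the package emulates:

* The six-level chronotype question is encoded −1 ("definitely a morning
  person", "more a morning than an evening person") or +1 ("more an evening
  than a morning person", "definitely an evening person"); "do not know"
  and "prefer not to answer" drop the participant.
* Participants flagged for shift work are excluded, as are participants
  whose codable answers at the two assessment visits disagree (a
  non-codable answer at either visit is not a disparity).
* Brain features are residualized per column on the nuisance covariates —
  acquisition site (one-hot, reference level dropped), head motion, and the
  five-variable sleep battery — by ordinary least squares with an
  intercept. Age and sex are variables of scientific interest and are
  **not** residualized. Rows with missing covariates are dropped from the
  fit and reported, mirroring a complete-case analysis. The nuisance fit is
  within the analysis sample; the regression coefficients are retained.

## Inference

**Permutation test.** Holding $X$ fixed, the target is shuffled across
participants and the full $k$-component model refit per iteration; the
per-component null is the distribution of $|\rho_j|$ under extraction-order
(positional) matching. The p-value estimator
$p_j = (1 + \#\{b : |\rho^{null}_{bj}| \ge |\rho_j|\})/(1 + B)$ is
never zero; at $B = 1000$, attaining the minimum $1/1001 < 0.001$ is
equivalent to the observed association beating every null model. Magnitudes
rather than signed values are compared because the component sign is a
convention, making a signed one-sided test ill-defined. The test suite
verifies the estimator against its definition, checks uniformity of the
p-values under a true null (Kolmogorov–Smirnov over 200 replicates at
$B = 99$), and checks the nominal rejection rate at $\alpha = 0.05$.

**Bootstrap loading inference.** Participants are resampled with
replacement ($B$ times, same $n$; resamples that lose a target class are
redrawn and counted), the model refit, and the refit components matched to
the reference model before recording loadings: a correlation similarity
matrix between bootstrap and reference x-loading columns is formed, and a
hand-written Jonker–Volgenant (Hungarian) solver — verified against
exhaustive search for $k \le 6$ — finds the assignment maximising total
absolute correlation; the sign of each matched correlation aligns the
column. A loading is flagged robust when its two-sided 5–95% percentile
interval excludes zero.

Two properties of this procedure deserve emphasis. First, the "all draws
equal the reference" degenerate behaviour on noise-free data holds exactly
for a single planted mode; with several modes, resampling remixes
components within the span of the true loadings, so exact equality is not
an invariant of the multi-mode case. Second, the percentile interval is
slightly anti-conservative for truly null features at the dimensionality
the package targets ($p/n \approx 0.2$): resampling rows of one realised
dataset treats that dataset's chance alignment between noise features and
the score as stable structure, so the bootstrap spread understates the
across-dataset sampling spread by roughly ten percent. The acceptance suite
measures the consequence directly: planted (truly nonzero) GMV loadings are
flagged with sensitivity ~0.98, while the fraction of truly-zero loadings
flagged is ~0.106 — just above the nominal 0.10 of a 90% interval. Users
who need strict null control should raise the interval (e.g. 2.5–97.5%) or
confirm flags across seeds; the 5–95% default is kept because it is the
procedure the package models.

## Phenome-wide association scans

`association_scan()` correlates each score column with every phenotype of a
family (behaviour, diagnosis, medication) on pairwise-complete rows; binary
phenotypes enter as 0/1 numerics, making the statistic point-biserial.
P-values come from the t-transform of $r$ with $n_{used} - 2$ degrees of
freedom; $-\log_{10} p$ is reported (the Manhattan-plot convention), with
underflow capped at the smallest positive double so the logarithm stays
finite. Bonferroni control is strictly per family — the threshold is
$\alpha / m_{family}$, with $m_{family}$ the number of phenotypes actually
tested in that family and never pooled across families. Phenotypes with
fewer than `min_n = 50` complete pairs, or above the optional 80%
missingness pre-filter, are emitted flagged `untested`; zero-variance
phenotypes are emitted flagged `zero_variance`, never silently dropped.
Pairwise-complete handling (deleting rows missing in phenotype $j$ affects
only phenotype $j$'s statistics) is a documented package choice.
`summarize_hits()` ranks significant rows by $-\log_{10} p$ within each
component and category, breaking ties by $|r|$ and then name, so output
order is fully deterministic.

## Cross-cohort projection and age stratification

An external cohort measured only on a feature subset (the GMV block, in the
design emulated here) is projected into the trained latent space by
restricting the weight and loading rows to the subset and applying

$$ X_{scores} = X_{sub} \cdot W_{sub} (P_{sub}^\top W_{sub})^{-1}. $$

The rotation is computed by linear solve, never an explicit inverse, and a
numerically singular $P_{sub}^\top W_{sub}$ (condition number above
$10^{12}$) is a hard error rather than a silent pseudo-inverse, because the
projection formula presumes invertibility. The external matrix is
residualized against the external cohort's *own* covariates and centered
and scaled with its *own* statistics — the two cohorts' acquisition scales
differ and the external data are preprocessed independently; this is a
documented interpretation where the emulated design is silent, and the
training statistics are stored in the projection object for callers who
prefer them.

`age_bracket_summary()` reports mean, sample SD (denominator $n-1$;
undefined at $n < 2$) and count of scores per age bracket. The standard
bracket lists share endpoints (40–50, 50–55, … years; 100–110, 110–120, …
months), so a deterministic convention is required: brackets are
left-closed, right-open, with the final bracket right-closed, and
participants outside all brackets are counted separately.

## The synthetic cohort generator

`generate_cohort()` draws brain features as

$$ X = Z\,\mathrm{diag}(a)\,L^\top + B + C\Gamma + \sigma E $$

with standard-normal latent scores $Z$, sparse unit-norm planted loadings
$L$ (support a configurable fraction of each block, restrictable to chosen
blocks so block-dominated subtypes can be simulated), dense low-rank
background $B$, covariate leakage $C\Gamma$, and i.i.d. noise $E$. The
binary target thresholds a noisy weighted combination of the latent columns
(a liability-threshold construction) calibrated so that
$\mathrm{cor}(z_j, y)$ equals the configured strength and the +1 fraction
equals the configured balance; the same liability construction generates
binary diagnosis/medication phenotypes at a configurable prevalence, and
continuous behavioural phenotypes are linear in the latent scores. Ages are
uniform on the configured range; the latent scores can be tilted toward age
(default: correlation 0.2 for mode 1), and `external_cohort_config()`
reverses that tilt so subtype expression trends run in opposite directions
in the two cohorts, as `generate_external_cohort()` shares the planted GMV
loading structure of a source cohort.

**Why the background term exists.** Real multimodal IDPs are strongly
autocorrelated — global volume, body size and shared physiology put much of
the feature variance in a few dozen shared directions. This matters
statistically, not just cosmetically. For a permuted target, the null
latent correlation of the first PLS component concentrates around
$\sqrt{PR/n}$, where $PR = (\sum\lambda_d)^2 / \sum\lambda_d^2$ is the
participation ratio of the feature covariance spectrum. With white
per-feature noise at $p = 397$, $n = 2000$, the null sits near
$\sqrt{p/n} \approx 0.45$ — above anything a planted mode of realistic
strength produces, so *no* signal would ever be permutation-significant at
that scale. With 20 dense background components contributing one unit of
per-feature variance (the default), $PR \approx 100$ and the null drops to
about 0.21, while a planted mode of strength 0.3 yields an observed
$|\rho_1| \approx 0.33$. The defaults — planted amplitude 8 (the mode
carries about 7% of total feature variance), 20 background components at
per-feature background SD 1, unit noise SD — were fixed once, from a power
analysis of exactly this trade-off, before the test suite was written.

**What the generator does not emulate:** spatial/atlas structure, realistic
phenotype marginals beyond type and sparsity, site effects beyond linear
leakage, and longitudinal drift. Tests passing on synthetic cohorts
therefore establish the *machinery* (recovery, calibration, determinism),
not fidelity to any real population.

## Numerical and reproducibility choices

* Degeneracy tolerance $10^{-10}$ in extraction: a residual
  cross-covariance or score norm below it means the requested $k$ exceeds
  the effective rank, and fitting stops with an error rather than emitting
  noise components.
* Every stochastic routine takes an explicit seed; the pipeline derives one
  stream per stage from a single global seed (`seed + 97 ×` stage index),
  and `manifest.json` records the per-stage seeds, counts and output
  checksums, so a run can be reproduced bit-identically. Generation is
  byte-deterministic: same configuration and seed, same tables.
* Model and ground-truth JSON is written with 17 significant digits, making
  serialisation round trips lossless to full double precision.
* Test and acceptance studies run at deliberately desk-scale sizes — the
  planted-mode studies at $n = 2000$ with the full 397-feature design,
  calibration studies at $n$ of a few hundred with small $p$ — chosen so
  the whole suite completes in minutes while keeping every statistical
  claim at the size it is stated for.

## Known limitations

* Percentile-bootstrap loading flags are mildly anti-conservative for null
  features at $p/n \approx 0.2$ (measured ~0.106 against a nominal 0.10;
  see above).
* The permutation test compares components positionally by extraction
  order; component swapping between the observed and null fits is not
  corrected for, which is the standard, slightly conservative convention
  for this design.
* Binary targets with extreme imbalance make bootstrap resamples
  single-class; the implementation redraws (and counts) such resamples
  rather than modelling the imbalance.
* No sparse or regularised PLS, no multi-response variant, no analytic
  p-values, no FDR alternative to Bonferroni, and no site harmonisation for
  the external cohort — each either out of scope or deliberately excluded
  to match the modelled design.
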
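---
title: "Methods and design notes for gvhdmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gvhdmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gvhdmeth` implements a donor-blood DNA methylation analysis for acute
graft-versus-host disease (aGVHD) severity: probe-level quality control
and batch adjustment of 450K-style β matrices, reference-based leukocyte
deconvolution, covariate-adjusted differential methylation with
empirical-Bayes moderation, probe-lasso region calling, nested
leave-one-out evaluation of a shrunken-centroid classifier, and
MethyLight PMR quantification. This vignette records the models, the
parameters that matter, and the design decisions taken where the
underlying methods left choices open.

## 1. Preprocessing

**β values.** The methylation fraction at a CpG is
$\beta = M / (M + U + 100)$, with $M$ and $U$ the methylated and
unmethylated fluorescent intensities and 100 intensity units the
conventional stabilizing offset. β is strictly below 1 and monotone
increasing in $M$, decreasing in $U$. Functional normalization and NOOB
background/dye-bias correction require raw IDAT control probes and are
out of scope; the pipeline starts from β (or $M$/$U$) matrices.

**The six probe filters** remove, as a union: (1) probes failing the
detection p-value rule, (2) probes with bead count < 3 in ≥ 5% of
samples, (3) sex-chromosome probes, (4) non-CG probes, (5) ambiguously
mapping probes, and (6) probes with a SNP at the probed CG. The rules are
conjunctive and order-independent; `filter_probes()` reports per-rule
counts. The canonical phrasing of rule (1) — "median detection P value
≥ 0.01 in one or more samples" — is internally inconsistent ("median"
summarizes across samples; "one or more samples" is a per-sample
quantifier). Both readings are implemented: the default
`detection_rule = "any"` removes a probe whose detection p is ≥ 0.01 in
at least one sample (the stricter reading), `"median"` removes probes
whose across-sample median is ≥ 0.01. Neither is asserted to be the
original intent.

**Batch adjustment** (`combat_adjust()`) is the standard parametric
empirical-Bayes location/scale model: per probe, data are standardized
against a least-squares fit that retains preserved covariates (default:
the phenotype group); per-batch location parameters get a normal prior
and scale parameters an inverse-gamma prior, both with moment-matched
hyperparameters across probes; the conditional-posterior fixed point is
iterated to `eb_tol = 1e-6`; adjusted values are back-transformed and
clipped into (0, 1). Refusals: a batch with a single sample, or a batch
factor confounded with a preserved covariate (checked by design-matrix
rank). A single batch is an exact identity. One property worth noting:
exact per-probe grand-mean preservation does *not* hold under shrinkage —
the EB step displaces the weighted batch means by a term of order
(shrinkage weight × per-probe sampling error), empirically ~1e-4 at
noise sd 0.02, two orders of magnitude below the batch shifts being
removed. The test suite asserts the displacement is small relative to the
removed shift rather than numerically zero.

All downstream modeling operates on β values, not M-values, matching the
regression convention of the analysis this package reproduces; a logit
transform is deliberately not applied by default.

**MDS QC.** `mds_embed()` is classical Torgerson scaling of Euclidean
distances between sample profiles over all surviving probes, centered at
the origin — a visual check for group separation and batch clustering.

## 2. Cell composition

Whole blood is a mixture; differential composition confounds differential
methylation. `estimate_cell_proportions()` solves, per sample,
$\hat w = \arg\min_{w \ge 0} \| b - R w \|^2$ over the reference profiles
$R$ of six leukocyte types (CD8T, CD4T, Bcell, NK, Mono, Gran), by
Lawson–Hanson active-set NNLS. No sum-to-one constraint is imposed: the
estimates are *relative* proportions and enter the regression as six
separate covariates, so an affine constraint would only introduce
collinearity. Rank-deficient references are refused with the condition
number reported (cutoff 1e8). At zero noise and an identifiable reference,
recovery is exact to the solver tolerance (1e-8; tested).

## 3. Differentially methylated positions

Per probe $g$, an OLS fit of β on intercept, group (severe = 1), sex,
age, and the six cell proportions yields the group coefficient
$\hat\beta_g$, residual variance $s_g^2$, and residual df $d$. Variances
are moderated empirically:
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by matching the moments of $\log s_g^2$ to a scaled
log-chi-square distribution (closed-form trigamma inversion, Newton
iterations to 1e-12). The moderated $\tilde t_g$ has $d_0 + d$ df and
two-sided p-values. When the observed log-variance dispersion does not
exceed chi-square sampling ($\text{evar} \le 0$), $d_0 = \infty$ and all
variances shrink to the arithmetic mean; with fewer than 10 probes,
moderation is skipped ($d_0 = 0$) with a warning. Exact zero variances
(constant probes) are floored at $10^{-12}\times$ the smallest positive
variance before the log transform. On heteroscedastic instances the
implementation agrees with `limma::eBayes` to ~1e-9 (oracle test).

**Selection**: Bonferroni-adjusted p < 0.05 *and* |Δβ| ≥ 0.05. Δβ is the
raw group mean difference (severe − no/mild), not the adjusted
coefficient — the convention that makes a published Δβ column directly
comparable with semi-quantitative assay effect sizes; both quantities are
reported. The ±5% floor exists because a clinical qPCR assay cannot
resolve smaller differences.

## 4. Differentially methylated regions

The probe-lasso idea: window sizes adapt to local probe density by
annotation category. Probes are grouped into 7 feature × 4 CpG-context
categories (missing labels form their own category); each category's
nearest-neighbor-distance distribution is summarized at the common
quantile at which the aggregate of category radii — `max`, `mean` or
`min` per `lasso_style` — equals `lasso_radius` (2000 bp default). If no
quantile attains the target (e.g. a single dense category), radii are
rescaled multiplicatively; under `max` they are capped at `lasso_radius`.
Categories with fewer than two usable probes receive the global radius.
The exact quantile scheme of the original implementation is not published
in the source analysis; this construction is documented as the package's
own choice.

Lassos are thrown around probes with unadjusted p below `seed_p = 0.05`
(region-level FDR comes later, so seeding is pre-adjustment); lassos
capturing ≥ `min_sig_probes = 2` significant probes are kept; kept lassos
on one chromosome merge when closer than `min_dmr_sep = 1000` bp. Region
p-values combine member probes by unweighted Stouffer
($z_i = \Phi^{-1}(1 - p_i)$, combined $p = 1 - \Phi(\sum z_i / \sqrt k)$;
$p = 0$ clipped to the machine minimum with a warning), a swappable
strategy since the original combination formula is unspecified. q-values
are Benjamini–Hochberg; regions with q < 0.1 and size ≥ `min_dmr_size`
are returned, 1-based inclusive internally and converted to 0-based
half-open only at BED export.

## 5. Classifier and nested cross-validation

**Nearest shrunken centroids.** With class centroids $\bar x_{ik}$,
overall centroid $\bar x_i$, pooled within-class sd $s_i$ and offset
$s_0 = \mathrm{median}_i(s_i)$:
$d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$, soft-thresholded
$d'_{ik} = \mathrm{sign}(d_{ik})(|d_{ik}| - \Delta)_+$ at $\Delta = 1$,
giving shrunken centroids
$\bar x'_{ik} = \bar x_i + m_k (s_i + s_0) d'_{ik}$. The discriminant is
$\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$;
the severe-class score is the softmax of $-\delta_k/2$ (shift-stabilized).
$m_k = \sqrt{1/n_k - 1/n}$ is the convention of the classical shrunken-
centroid implementation; the $\sqrt{1/n_k + 1/n}$ alternative is a flag
(`mk_convention = "plus"`) since the source analysis states no formula.
Fully shrunk models predict by priors alone (tested identity).

**Nested LOOCV.** The defining property is that *feature selection runs
inside every fold*: each iteration re-runs the whole moderated-t DMP
selection on the n−1 training samples, ranks significant DMPs by p-value,
trains the NSC at Δ = 1, and scores the single held-out sample. Held-out
scores pool into one ROC; the AUC (Mann–Whitney concordance, ties ½)
carries a DeLong 95% CI. A per-iteration training AUC summary is also
emitted, since "mean AUC over n single-prediction iterations" is not a
well-defined pooled quantity. Cell-proportion covariates are taken from
the sample sheet as given (estimated once); re-estimating the reference
fit inside folds would be required only if the reference itself were
learned from the cohort, which it is not.

**Zero-DMP folds** score the held-out sample at the *cohort-level* severe
prevalence — one constant across folds — rather than the per-fold
training prevalence. The per-fold prior differs between folds only
through the held-out sample's own label (a severe hold-out leaves 8/84
severe in training, a no/mild hold-out 9/84), so using it anti-ranks the
held-out samples and drives a pure-noise AUC to 0 instead of 0.5. With a
constant fallback, all-tie folds contribute concordance ½, and the null
calibration lands in [0.35, 0.65] as it should. Recurrence — the number
of iterations selecting each probe — is the stability statistic used to
rank the final DMP table (ties broken by descending |Δβ|).

## 6. MethyLight quantification

The standard curve is the least-squares line of Ct on log(relative input)
over a serial dilution (4-fold default, 5 points); efficiency
$E = e^{-1/\text{slope}}$, refused outside (1, 2.2] or when $R^2 < 0.9$,
when fewer than 3 finite points remain, or when the series is
non-monotone. Quantities invert the line; an undetected well maps to
quantity 0. PMR is the ratio of ratios
$100\,(T/R)_{\text{sample}} / (T/R)_{\text{M.SssI}}$ — self-normalizing
against global Ct offsets (tested invariance). PMR is computed on
*interpolated quantities*, the standard MethyLight definition, not on raw
Ct ratios: the literal "Ct-ratio" wording found in methods sections is
unit-inconsistent (Ct is logarithmic), and the two cannot be
distinguished without the original plate data. Samples whose target
reaction never amplified are excluded from group comparisons (reported),
since a truly unmethylated sample and a failed reaction are
indistinguishable; a missing *reference* reaction leaves PMR undefined.

Thresholds use the ROC point closest to the top-left corner, minimizing
$(1-\text{sens})^2 + (1-\text{spec})^2$ over midpoints between sorted
distinct values, ties broken toward higher specificity; the marker
orientation (severe donors are *hypo*methylated, so low PMR flags
severe) is chosen to give AUC ≥ 0.5. Group comparison is a two-sided
Wilcoxon rank-sum test: exact by enumeration of midrank assignments for
pooled sizes ≤ 12 (valid under ties, and the only reading under which
identical groups give an exact p = 1), otherwise the normal approximation
with tie and continuity corrections.

## 7. The synthetic world

`generate_cohort()` emulates the discovery design: 85 donors, 9 matched
to severe aGVHD; 20,000 probes laid out in CpG-island-like runs
(within-cluster spacing ≤ 500 bp, inter-cluster gaps ≥ 5 kb) with
manifest-style flags; a six-cell-type mixture with blood-like Dirichlet
weights (granulocyte-dominated); two array slides with per-probe location
shifts (sd 0.02) and per-batch noise-scale factors; age (0.003 β/year)
and sex (0.05 β) effects on designated probes; 30 planted DMPs with
|Δβ| ∈ [0.06, 0.18], of which 4 form one contiguous hypomethylated island
run emulating a coherent multi-probe DMR. Sample β is the
mixture-weighted reference profile plus effects plus additive Gaussian
noise (sd 0.02), clipped to [0.001, 0.999]. Defaults the source design
does not state — within-group noise sd, batch shift sd, QC failure
fraction (0.2%), Dirichlet concentrations — were chosen once for
realism/testability (blood 450K technical replicates sit at β-sd
0.01–0.03) and are not tuned against test outcomes. Noise is Gaussian on
the β scale rather than Beta-distributed: simpler, and matching the
additive ±Δβ semantics of the selection filter.

Cluster methylation state is coherent (islands jointly methylated,
unmethylated, or intermediate), which both reflects real island behavior
and guarantees mid-range clusters exist for region planting. Reference
profiles differ across cell types only on a designated discriminating
subset (600 probes, between-type spread ≥ 0.3), so mixture variation
does not contaminate null probes — this is what makes the null
z-score calibration test exact.

**What a green test does not establish:** the generator has no
Infinium I/II chemistry differences, no raw-IDAT control probes, no
spatial slide artifacts, no probe cross-hybridization structure, no
genetic (meQTL) component, and planted effects are additive and constant
within group. Passing the recovery criteria shows the *machinery* is
correct at the stated effect sizes, not that the original cohort's
headline numbers would reproduce; those depend on controlled-access data.

The MethyLight generator plants per-sample true PMRs (lognormal around
group means 5 severe / 25 no/mild, sdlog 0.8 — PMR distributions are
strongly right-skewed), per-sample input variation, a fully methylated
control (true PMR 100), unmethylated and non-template controls (no
amplification), and a 4-fold 5-point dilution series; Ct =
intercept − log(q)/log(E) + noise (sd 0.25 cycles).

## 8. Scaling choices in the test suite

Everything runs on one CPU: the headline-analog criterion uses the full
stated 20,000 × 85 cohort; the null-calibration and DMR-recovery
criteria, whose cohort sizes the contract leaves open, use 2,000- and
1,500-probe cohorts respectively across 10 and 20 seeds. The full suite
runs in ~35 s.

## 9. Known limitations

- Filters and batch adjustment assume the QC tables and batch labels are
  trustworthy; there is no outlier-sample detection stage.
- The DMR caller's category quantile scheme and chromosome-end behavior
  are this package's documented choices, not a byte-level reproduction of
  the original probe-lasso implementation.
- DeLong intervals degenerate at AUC = 1 (zero variance); the per-fold
  training-AUC summary is reported alongside for that reason.
- Deconvolution quality is bounded by the reference: with real data the
  discriminating-probe selection (top-F-statistic, default 600) and the
  external purified-cell reference must be supplied.
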
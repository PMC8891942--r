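---
title: "Methods: voxel-wise functional asymmetry with pasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise functional asymmetry with pasym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasym)
```

## The statistic

For a voxel $v$ with retained-frame time series $x_v$, let $r_{vw}$ be the
Pearson correlation with every other analysed voxel $w$. Keep only
survivors $r_{vw} > \theta$ (default $\theta = 0.2$; a strictly positive
threshold simultaneously discards negative correlations, whose inclusion
harms reliability), Fisher-transform them $z_{vw} = \operatorname{atanh}
r_{vw}$, and average separately over the two hemispheres:

$$\mathrm{PAS}(v) \;=\; \overline{z}_{\text{inter}}(v) \;-\;
  \overline{z}_{\text{intra}}(v).$$

$\overline{z}_{\text{inter}}$ runs over contralateral survivors,
$\overline{z}_{\text{intra}}$ over ipsilateral survivors excluding $v$
itself. An empty survivor set contributes $0$ with a support count of $0$,
so the map is defined everywhere; the counts are reported so low-support
voxels can be masked downstream.

### Numerical edge cases

* **Zero-variance series** have undefined correlations; they never appear
  as survivors and their own components are zero with zero support. An
  all-flat volume is an error.
* **Near-perfect correlations** ($r > 0.999999$) are treated as degenerate
  duplicates of the target series and excluded from the survivor set. This
  keeps every Fisher z finite and gives the clean invariant that an exact
  mirror-image copy of one hemisphere produces PAS $\equiv 0$: each
  voxel's contralateral survivor multiset then equals its ipsilateral one.
  An alternative convention — clipping $r$ into $[-0.999999, 0.999999]$
  and keeping the pair — breaks that invariant by injecting one huge z
  into the inter mean only; we chose exclusion because duplicated series
  carry no independent information about coupling. Real data are never
  affected (sample correlations of distinct noisy series do not reach
  $0.999999$).
* **Hemisphere assignment** is by the sign of the world-space x coordinate
  (negative = left) from the mask affine; a voxel whose center lies within
  half a voxel width of $x = 0$ is excluded from the analysis and from all
  partner sets. The analysed voxel set is otherwise whatever mask the user
  supplies — the method takes no position on whole-brain versus
  gray-matter masks.
* **Blocked evaluation.** `compute_pas()` accumulates survivor sums in
  column blocks and never stores the $V \times V$ correlation matrix; the
  quadratic `pas_oracle()` implements the identical contract with explicit
  loops and the test suite drives both across random instances (including
  zero-variance and duplicate columns and boundary thresholds) requiring
  agreement to $10^{-10}$.

## Temporal preprocessing

The package consumes spatially normalized 4-D volumes and implements only
the temporal contract, in this fixed order:

1. **Confound regression**: least-squares residuals against an intercept,
   the Friston-24 motion expansion (6 parameters, their one-frame lags,
   both sets squared) and mean CSF/WM signals supplied as columns. The
   projection uses the SVD, so rank-deficient designs (duplicated or
   constant columns) are handled by the minimum-norm solution.
2. **Linear detrend + band-pass** (default 0.01–0.08 Hz): a hard Fourier
   mask; components outside the band, including DC, are zeroed. Requires
   $0 < f_{low} < f_{high} <$ Nyquist.
3. **Scrubbing**: frames with framewise displacement above 0.2 mm are
   deleted (not interpolated) from all subsequent correlation windows.

FD follows the Power convention: the sum of absolute backward differences
of the six rigid-body parameters, rotations mapped to arc length on a
50 mm sphere, first frame 0. Subjects exceeding 2 mm translation or 2°
rotation (strict inequalities) at any frame are excluded outright.

Whether band-pass filtering should precede or respect scrubbing is a
convention, not a derivable fact; filtering the full series first keeps
the spectral estimate well defined and is documented as this package's
order. Scrubbing down to fewer than 3 retained frames is allowed at the
scrub step (with a warning) and becomes an error only when a correlation
is actually requested — the count, not the scrub, is the problem.
Dummy-volume removal is the caller's concern (`--drop-initial` in the
CLI, default 10).

## Group inference

Per voxel, the group effect is the partial F comparing
$y \sim \text{group} + \text{covariates}$ against
$y \sim \text{covariates}$ (age, gender coded male = 0 / female = 1,
education years, mean FD; all covariates mean-centered; reference group =
healthy controls). Post-hoc contrasts are *covariate-adjusted two-group
models over the contrast's subjects only* — not pooled contrasts inside
the three-group model — because each pairwise panel (including the
control contrasts) is reported as its own family. The first-listed group
carries the positive sign, and $t^2$ equals the two-group partial F
identically.

Multiplicity is controlled per contrast map with Benjamini–Hochberg
(step-up $q_i = \min_{j \ge i} m p_{(j)} / j$, clipped at 1), rejecting at
$q < 0.05$. BH was chosen for the voxel maps to match the procedure the
association analysis names explicitly; a BY variant was considered and
rejected as needlessly conservative absent any stated dependency
rationale.

Clusters are connected components of significant voxels, positive and
negative effects labeled separately, default 26-connectivity, minimum
extent 0 (report everything; raise it in the config — published tables
in this literature report clusters of ≥ 42 voxels without stating an
extent rule, so no rule is hard-coded). The peak is the maximum
$|statistic|$, ties broken by lowest grid index so output is
deterministic; peak coordinates are reported in world mm through the mask
affine. Summary-statistics operations (`anova_from_summary`,
`ttest_from_summary`, `chi_square_independence`) use the sample-SD
($n-1$) convention and are exact — not approximate — when fed
full-precision summaries, which the tests verify against raw-data
references.

## Association and classification

Cluster-mean PAS is correlated with clinical scores by Spearman's rho
(mid-ranks on ties; two-sided p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$), pooling both patient groups by
default. BH runs across the *entire* cluster × variable grid of valid
pairs in one family; constant inputs are flagged invalid and excluded
from the family rather than contributing meaningless p values. The family
definition is configurable because the corrected grid's exact membership
is a reporting choice, not a statistical necessity.

Discrimination uses a C-classification SVM trained by sequential minimal
optimization — written in-package because no SVM library is available in
the supported dependency set — with a deterministic second-choice
heuristic so refits are reproducible. Defaults follow common LIBSVM
practice: RBF kernel, $C = 1$, $\gamma = 1/(d \cdot \mathrm{Var}(X))$.
The solver was checked against scikit-learn's SVC during development
(decision values agree to $\sim 10^{-3}$ at tolerance $10^{-3}$). The
leave-one-out protocol standardizes features with training-fold statistics
only (no leakage), predicts the held-out subject, and aggregates confusion
counts; a decision value of exactly 0 predicts the negative class. The
feature sweep runs every requested subset and prints
`percent%(num/den)` fractions whose rounding identity is tested. The
original report's kernel and cost are unstated, so its exact fractions are
not reproducible by construction and are not targets; class imbalance is
left unweighted to match the silent default.

## The synthetic cohort

`simulate_bold()` draws each voxel series as

$$x_v(t) = \alpha\, s_{\mathrm{pair}(v)}(t) + \beta\, s_{\mathrm{side}(v)}(t)
  + \sigma\, e_v(t)$$

with one latent per homotopic pair, one per hemisphere, and iid unit
Gaussians throughout. Expected correlations are closed-form —
$r_{\text{pair}} = \alpha^2/(\alpha^2+\beta^2+\sigma^2)$ for mirror pairs,
$r_{\text{intra}} = \beta^2/(\ldots)$ within a hemisphere, $\approx 0$
otherwise — which makes acceptance analytic: defaults
$\alpha^2 = 0.5, \beta^2 = 0.25, \sigma^2 = 0.25$ give
$r_{\text{pair}} = 0.5$ and $r_{\text{intra}} = 0.25$, recovered
empirically within $\pm 0.05$ at $T = 2000$. The latent-factor form was
chosen over explicit covariance sampling for $O(V)$ cost and those closed
forms. Regional group effects raise $\alpha$ (PAS up) or $\beta$ (PAS
down) inside a region for one group, matching the interpretation of PAS
changes as inter- versus intra-hemispheric shifts. Motion traces are
mean-centered random walks rescaled to a 0.1 mm default amplitude
(passing the exclusion rule unless a failure is requested); cohort sizes
default to 35/17/28 and clinical scores are drawn from the published
per-group mean ± SD models truncated at zero, so at large n the generated
table reproduces the summary statistics it feeds — a self-test the suite
runs. The GI-severity item is generated as a noisy monotone function of
each affected subject's effect multiplier, making association recovery
testable. All randomness flows from one seed through a hierarchical
stream (cohort → subject), so any subject regenerates in isolation.

What the generator does **not** emulate: hemodynamic response shapes,
spatial autocorrelation from smoothing, physiological noise spectra,
distance-dependent connectivity. A green pipeline test therefore
establishes the *statistical contract* of each stage — not that the
package would reproduce any particular empirical imaging result.

### Inference-level simulations

Type-I-error and power studies run at the PAS-stack level
(`simulate_pas_stack()`): per-subject PAS values around a common spatial
baseline with Gaussian subject noise (SD 0.2, a realistic spread for
voxel-level Fisher-z differences), optional regional shifts for one
group. Regenerating full BOLD for 50–70 cohort replicates would cost
hours for no added coverage of the inference code; the stack-level world
is the stated design (effect +0.4, SD 0.2, n = 35/17) applied directly.
The BOLD-level path is exercised separately by the closed-form
correlation checks and the end-to-end demo.

## Defaults that matter

| parameter | default | unit | why |
|---|---|---|---|
| `fc_threshold` | 0.2 | r | removes weak/negative correlations before Fisher-z |
| `fd_scrub_threshold_mm` | 0.2 | mm | standard scrubbing cut for the 50 mm FD convention |
| `bandpass_hz` | 0.01–0.08 | Hz | canonical resting-state band |
| `max_translation_mm` / `max_rotation_deg` | 2 / 2 | mm / ° | subject exclusion rule |
| `alpha_fdr` | 0.05 | — | BH level per contrast map |
| `cluster_connectivity` | 26 | — | most inclusive standard neighborhood |
| `min_cluster_extent` | 0 | voxels | report all; no principled extent rule exists |
| `svm_kernel`, `svm_cost` | radial, 1 | — | common LIBSVM defaults; kernel unknowable from the source report |
| rotation radius | 50 | mm | Power FD convention |

## Known limitations

* The NIfTI-1 reader covers single-file 3-D/4-D volumes with the common
  dtypes and sform affines; detached `.hdr/.img` pairs, qform-only
  rotation matrices and header extensions are out of scope.
* The SMO solver targets tens of subjects; it is quadratic in memory
  (kernel matrix) and not intended for large-n training.
* Post-hoc contrasts use per-pair error terms; a shared three-group error
  term is a defensible alternative the package does not implement.
* Cluster records carry coordinates, not anatomical labels — atlas lookup
  is deliberately out of scope.
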
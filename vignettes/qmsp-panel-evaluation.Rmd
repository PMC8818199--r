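---
title: "Methods: evaluating a urinary methylation marker panel from qMSP data"
author: "qmspPanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a urinary methylation marker panel from qMSP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmspPanel)
```

# The measurement model

Quantitative methylation-specific PCR amplifies bisulphite-converted,
methylated template only; the quantification cycle Ct falls by one for
every doubling of input. Nine markers (*FAM19A4*, *PHACTR3*, *PRDM14*,
*GHSR*, *SST*, *ZIC1*, *MAL*, *miR-129*, *miR-935*) are measured in three
multiplexes, each alongside the reference gene *ACTB*, which tracks the
total amount of amplifiable DNA. The methylation level is expressed as a
comparative-Ct ratio

$$\mathrm{ratio} = 2^{-\Delta Ct}\times 100,\qquad
\Delta Ct = Ct_{\mathrm{target}} - Ct_{ACTB},$$

so a target amplifying as efficiently as the reference scores 100, one
cycle later scores 50, and so on.

Two conventions deserve making explicit:

- **Reference-gene QC.** A multiplex with $Ct_{ACTB} > 32$ (or an
  undetected *ACTB*) indicates too little or too degraded input DNA; all
  three of its targets are invalidated together. The boundary itself
  passes: exactly 32 is valid. QC therefore partitions marker validity
  exactly by multiplex — *GHSR*, *SST* and *ZIC1* are always valid or
  invalid together.
- **Undetected targets.** When *ACTB* passes QC but a target never
  amplifies, the package scores ratio 0 rather than missing: in
  methylation-specific PCR the absence of amplification means no
  detectable methylated template, which is a bona fide fully-unmethylated
  measurement, not a failed one. This is a convention — instrument
  exports do not distinguish "no template" from rare chemistry failures —
  and it is deliberately conservative for a test whose positives are
  high ratios.

Log2-transformed ratios $\log_2(\mathrm{ratio} + \varepsilon)$ are used
for display and for the continuous panel score only, with
$\varepsilon = 10^{-4}$ guarding the ratio-0 case. Every inferential
quantity — rank tests, ROC curves, AUCs, thresholds — operates on raw
ratios, so $\varepsilon$ cannot change any p-value, AUC or
threshold-based call; the test suite checks this invariance directly.

# Per-marker inference

Case–control differences per marker use the two-sided Mann–Whitney
U test. Groups of at most 8 are handled by exact enumeration of the
(mid-)rank assignments, which stays exact under ties; larger groups use
the normal approximation with tie and continuity correction. At the
cohort sizes this package targets (around 100 per group) the distinction
is immaterial; the exact path exists so that small pilot subsets are not
silently approximated. Multiplicity across the nine markers is handled
by Bonferroni: $p_{\mathrm{adj}} = \min(1, 9\,p)$.

Before pooling heterogeneous controls (haematuria evaluations, other
benign urological conditions, healthy volunteers) into one comparison
group, a Kruskal–Wallis test per marker checks that their methylation
levels are exchangeable.

Discrimination is summarized by the empirical ROC curve with positivity
called as ratio $\ge$ threshold. Candidate thresholds are the midpoints
between consecutive distinct scores plus $\pm\infty$ sentinels; ties are
grouped into single vertices, so the trapezoidal area equals the
tie-adjusted $U/(n_1 n_2)$ — the probability that a random case
outscores a random control, ties counted half. This identity is enforced
to $10^{-12}$ against a brute-force pairwise oracle in the tests. AUC
confidence intervals use the DeLong placement-based variance (a Wald
interval truncated to $[0,1]$; perfect separation degenerates to a point
interval with a warning). The interval method is a package choice among
several asymptotically equivalent ones; it is deterministic, standard,
and cross-checked against an independent implementation (pROC) in the
suite. AUC bands follow the usual convention — 0.5–0.6 very poor,
0.6–0.7 poor, 0.7–0.8 fair, 0.8–0.9 good, 0.9–1.0 excellent — with
left-closed intervals, so 0.9 is "excellent"; prose definitions of these
bands overlap at the boundaries and a tie-break had to be fixed.

# The believe-the-positive panel

The panel (default *GHSR/MAL*) uses one cutpoint per marker, chosen to
maximize Youden's $J = \mathrm{sens} + \mathrm{spec} - 1$ over the same
midpoint candidate cuts. Ties in $J$ are broken towards the higher
specificity, then the larger threshold: for a triage test meant to spare
patients unnecessary cystoscopies, the more specific of two equally
informative cutpoints is the clinically preferable one.

Calls combine by the *believe-the-positive* OR rule: the panel is
positive if at least one valid member marker is at or above its
threshold. This maximizes sensitivity at a specificity cost and makes
the panel's operating characteristics exactly bracketable: on any fixed
sample set, panel sensitivity $\ge$ each member's sensitivity and panel
specificity $\le$ each member's specificity (tested as an exact
property). A sample in which no valid marker is positive but some member
is invalid is **indeterminate** — a negative cannot be asserted from a
failed measurement — and is excluded from performance denominators but
counted and reported.

Sensitivity and specificity carry exact Clopper–Pearson intervals,
$\mathrm{lower} = B^{-1}(\alpha/2;\,x,\,n-x+1)$,
$\mathrm{upper} = B^{-1}(1-\alpha/2;\,x+1,\,n-x)$, with the usual 0/1
boundary conventions. Exact intervals were chosen over Wilson or Wald
because panel subgroups can be small (down to ~20 cases), where exact
coverage guarantees matter; their conservatism is verified by simulated
coverage at $n \in \{23, 108\}$.

Because the OR rule has no natural continuous output, the reported panel
AUC uses a declared convention: the **max-margin score**
$\max_m [\log_2(\mathrm{ratio}_m + \varepsilon) -
\log_2(\mathrm{thr}_m + \varepsilon)]$ over valid members. Its sign
reproduces the OR decision exactly, so the score's ROC curve passes
through the panel's operating point; any other monotone-compatible
combination (e.g. a logistic blend) would be an equally defensible but
different convention.

# Validation

**LOOCV.** Leave-one-out cross-validation re-derives the per-marker
Youden thresholds on the $n-1$ remaining samples for every fold and
classifies the held-out sample with them. Re-estimating thresholds per
fold is the only construction under which LOOCV can differ from
resubstitution — with frozen thresholds every "fold" would repeat the
training fit — and the suite checks both that each out-of-fold call is
invariant to the held-out sample's own label and that resubstitution is
optimistically biased relative to LOOCV on average over simulated
cohorts.

**Subgroups.** Case sensitivity is tabulated for grade (G3 vs G1–G2 and
high vs low grade), stage (muscle-invasive $\ge$T2 vs Ta/T1/Tis),
disease status (primary vs recurrent) and gender, using the
pooled-cohort thresholds, each with an exact CI, and each dichotomized
contrast tested by Pearson chi-square **without** continuity correction
(1 df). The no-correction choice is anchored by a worked example in the
tests: on the baseline gender table [[79, 29], [63, 37]] the
uncorrected test gives $p = 0.116 \to 0.12$ while the corrected one
gives 0.155. Subgroup p-values are reported unadjusted — they are
descriptive sensitivity analyses, not the primary hypothesis family —
whereas Bonferroni applies to the nine marker-level tests.

**Gender strata.** Methylated tumour DNA in female urine is diluted by
unmethylated DNA from cells of gynaecological origin and leucocytes, so
a shared threshold penalizes sensitivity in women. The post hoc analysis
therefore splits the cohort by gender and re-runs the whole machinery —
Youden thresholds, resubstitution performance, LOOCV — entirely within
stratum.

# Study design

For planning, the anticipated AUC $A$ determines the group size through
the Hanley–McNeil variance approximation

$$SE^2(A) = \frac{A(1-A) + (n_1-1)(Q_1 - A^2) + (n_2-1)(Q_2 - A^2)}
{n_1 n_2},\quad Q_1 = \frac{A}{2-A},\; Q_2 = \frac{2A^2}{1+A},$$

and the smallest integer $n$ with
$2\,z_{1-\alpha/2}\,SE \le \mathrm{width}_{\max}$ is found by direct
search (with $A = 0.89$, width 0.1, $\alpha = 0.05$ and equal groups
this gives $n = 87$; $n = 86$ misses at width 0.1003). Other published
AUC variance approximations (e.g. the binormal-exponential refinement)
give slightly different $n$; Hanley–McNeil was adopted as the
conventional planning formula. Enrolment is inflated for dropout by the
plain ceiling $\lceil n/(1-\mathrm{rate})\rceil$ — 109 at 20% — noting
that study teams often round such targets further up to a convenient
number, which is a planning habit rather than a statistical rule.
Simulated cohorts at the returned $n$ realize the promised DeLong CI
width on average (tested).

# The synthetic cohort generator

No public patient-level qMSP dataset accompanies this problem setting,
so the generator is a first-class, tested module that emulates the data
structure the analysis assumes:

- **Composition.** Covariates are assigned by exact quota
  (largest-remainder apportionment), not i.i.d. draws, so the default
  108-case / 100-control cohort reproduces its configured composition
  *exactly*: 79/29 male/female cases, grades G1/G2/G3 = 17/39/52,
  LG/HG = 45/63, stages Ta/T1/Tis/$\ge$T2 = 59/16/10/23, primary/
  recurrent = 76/32, 63/37 male/female controls, and control subtypes
  34/43/23. The two grading systems share one latent severity order, so
  G3 tumours nest inside the high-grade stratum.
- **Effects.** Each case draws a lognormal tumour-burden factor $B$
  (SD `burdenSd` on the log scale) shared across markers — a deliberately
  minimal way to induce the positive inter-marker correlation tumours
  produce, in place of an unknown full covariance matrix. Marker $m$'s
  true log2-ratio is $N(\mu_{0m}, \sigma^2)$ in controls and
  $N(\mu_{0m} + \delta_m \sigma B g, \sigma^2)$ in cases, where $g$
  multiplies the applicable factors: `gradeMultiplier` (high grade),
  `stageMultiplier` ($\ge$T2), `recurrenceMultiplier` (recurrent
  disease, $<1$: surveillance-detected recurrences shed less tumour
  DNA), `femaleDilution` ($<1$).
- **Assay layer.** Ratios are back-transformed to target Ct against a
  drawn *ACTB* Ct ($N(26, 1.5^2)$), so normalization exactly inverts
  generation — a round-trip the tests rely on. Targets past the 45-cycle
  detection limit are emitted undetected, back-computed cycles below 1
  saturate at 1, and each (sample, multiplex) independently suffers an
  *ACTB* QC failure (Ct drawn in 32.5–36) with probability
  `actbFailureRate`. Note the failure rate is per *multiplex*; the
  fraction of *samples* flagged is about $1-(1-r)^3$, so the default
  0.03 flags roughly 9% of samples.

Default effect sizes ($\delta$ from 1.4 to 1.9 SD units, baseline
$\mu_0 = -5$, $\sigma = 2$ log2 units) were fixed once to place
single-marker AUCs in the high-0.7 to high-0.8 range typical of urinary
methylation markers, with *GHSR* and *MAL* strongest; the calibration
identity $AUC = \Phi(\delta/\sqrt 2)$ (exact when `burdenSd = 0` and all
multipliers are 1) is what the tests check, at $\delta = 2$ and
$n = 500/500$, within three Monte-Carlo standard errors.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: assay noise beyond Gaussian log-ratios
(no amplification-efficiency drift, no batch or plate effects), realistic
age structure or age–methylation confounding, the true inter-marker
correlation (the shared burden factor is one-parameter), correlation
between covariates other than the grade pair, and verification bias from
the case–control design itself. Because the case population mixes strong
(high-grade, invasive) and weak (diluted, recurrent) signals, the
Youden-optimal operating point on default synthetic cohorts is
sensitivity-heavy; real cohorts can and do land elsewhere on the curve.

# Numerical and edge-case conventions

- QC boundary: *ACTB* Ct exactly 32 is valid; the rule is strictly
  "> 32 fails".
- Youden and ROC threshold grids use midpoints of distinct scores;
  Youden adds finite sentinels one unit beyond the data range so the
  all-positive/all-negative rules are representable with finite,
  serializable thresholds.
- J ties: highest specificity, then largest threshold.
- Mann–Whitney: exact enumeration iff both groups $\le 8$.
- Degenerate AUC (0 or 1, or zero DeLong variance): point interval plus
  warning rather than an undefined Wald interval.
- Samples whose panel markers are all invalid produce no LOOCV fold;
  `n_folds` counts determinate out-of-fold calls.
- Subgroup contrasts where all determinate cases share one outcome
  report $p = 1$ (no contrast exists), not an error.
- Display rounding is half-up to 2 decimals for proportions (whole
  percentages for rates); JSON reports always carry full precision.

# Problem sizes in the test suite

The suite favours many small, seeded instances over few large ones:
1000-instance oracle sweeps for the AUC/rank identity and Youden
optimality at $n \le 30$; simulator calibration at 500 cases / 500
controls; LOOCV null behaviour averaged over six permutations at
$n = 200$; coverage at 1000 replicates per $(n, p)$ cell. These sizes
keep Monte-Carlo error well below the asserted tolerances while the
whole suite runs in about a minute and a half.

# Known limitations

- The package evaluates a *given* panel; it does not perform marker
  selection or penalized combination (a random-forest-style omnibus
  model is out of scope by design).
- The DeLong interval is asymptotic; for very small strata the reported
  AUC CI can be optimistic even while the binomial CIs remain exact.
- The max-margin panel score is a convention; panel AUCs from different
  score conventions are not comparable across software.
- Dropout inflation is the plain ceiling; site-level enrolment rounding
  is left to the study team.
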
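---
title: "Attention network effects and cognitive control capacity: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention network effects and cognitive control capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccckit)
```

## What the package computes

`ccckit` implements an analysis pipeline for cognitive control studies that
compare children with ADHD, children with subthreshold ADHD (3--5 symptomatic
SNAP-IV items, below the 6-item clinical criterion), and typically developing
(TD) peers on two computerized tasks:

* the **Attention Network Test -- Interaction (ANT-I)**, a flanker task with
  auditory alerting signals and spatial orienting cues, scored as three
  subtraction effects (alerting, orienting, conflict) plus overall reaction
  time (RT); and
* the **backward-masked majority function task (MFT-M)**, in which the
  subject reports the majority direction of 1, 3, or 5 briefly exposed
  arrows, from which a **cognitive control capacity (CCC)** in bits per
  second is estimated.

Because the underlying clinical data are not publicly deposited, the package
ships a synthetic cohort generator that emulates the study's structure:
demographics, parent and teacher SNAP-IV/ASQ reports, two-informant
diagnosis, and latent task parameters per subject. Every analysis stage
(cleaning, effect scoring, capacity estimation, deficit frequencies,
covariate-adjusted inference, SVM classification) runs identically on
simulated or real trial tables in the documented CSV schemas.

## Information content of a majority judgement

A set of $n = m + k$ arrows ($m$ in the majority direction, $k$ in the
minority, $n$ odd) is quantified under the **grouping-search strategy**: the
observer samples subsets ("groups") of size $g = (n+1)/2$ at random, with
replacement of groups, until a homogeneous group appears; that group's
direction must be the majority. The probability that a random group is
homogeneous is hypergeometric,

$$ p = \frac{\binom{m}{g} + \binom{k}{g}}{\binom{n}{g}}, \qquad
   E[S] = 1/p, $$

and the information conveyed by the set is the log cost of the search,

$$ I = \log_2 \left( g \cdot E[S] \right) \ \text{bits}. $$

For the six design ratios 1:0, 3:0, 2:1, 5:0, 4:1, 3:2 this yields 0, 1.00,
2.58, 1.58, 2.91, 4.91 bits (2 dp):

```{r info}
cond <- mft_info_conditions(exposure_s = 1)
round(setNames(cond$info_bits, paste(cond$majority_n, cond$minority_n, sep = ":")), 2)
```

The single-arrow 1:0 set carries 0 bits by this definition ($g = 1$,
$E[S] = 1$) even though the response is binary; we take that as a fixed
property of the published quantification rather than re-deriving it. A
Monte-Carlo search simulation is kept in the test suite as an independent
oracle for $E[S]$.

## The capacity-limited accuracy model

Accuracy in a condition with information amount $I$ and exposure time $T$ is
modelled as

$$ p(I, T) \;=\; \begin{cases}
  a_0 & I \le C\,T \\[2pt]
  0.5 + (a_0 - 0.5)\, \dfrac{C\,T}{I} & I > C\,T,
\end{cases} $$

where $C$ (bits/s) is the capacity and $a_0 \in (0.5, 1]$ the subject's
ceiling accuracy. Below the knee the subject processes everything and
performs at ceiling; above it, only the processed fraction $CT/I$ of the
information contributes, and the remainder is a coin flip between the two
response keys (floor 0.5). $C$ is therefore literally "the information rate
at which accuracy starts to drop". The form is continuous at the knee,
weakly decreasing in $I$, increasing in $T$ and $C$, and isolated behind
`predict_accuracy()` so an alternative parametric form can be swapped in at
a single point.

### Maximum-likelihood estimation

`estimate_ccc()` fixes $a_0$ from the zero-information 1:0 conditions (108
trials in the full design), clipped to $[0.51, 0.999]$, and maximizes the
Bernoulli log-likelihood of trial correctness over $C$, with no-response
trials counted as errors. Numerical choices:

* **Grid search, not gradient.** The likelihood is piecewise smooth with
  knees at $C = I/T$ for each of the up-to-18 cells; a 200-point log-spaced
  grid on $[0.05, 10]$ bits/s followed by a local linear refinement at 0.01
  resolution avoids derivative bookkeeping entirely. A test compares the
  result against an exhaustive 0.001-step grid on 20 simulated subjects.
* **Boundary censoring, not errors.** A subject correct at every information
  rate identifies only a lower bound on $C$: the optimum sits at the upper
  grid edge and `boundary_flag = "upper"` is set (symmetrically `"lower"`).
  Downstream stages keep flagged estimates but carry the flag.
* **One free parameter.** $a_0$ is fixed from the 1:0 cells rather than
  jointly fitted, matching the published description of capacity as *the*
  free parameter; `ceiling_acc` can be supplied explicitly for joint or
  sensitivity analyses. No lapse parameter is fitted; lapses depress the
  measured $a_0$ and are absorbed there.

On full 324-trial schedules the estimator recovers a TD-like cohort
(true $C \sim N(3.26, 0.61)$ truncated at 0.3) with mean bias below
0.05 bits/s, and a single subject at $C = 3$ within $\pm 0.2$ over ten
schedule repetitions; both are frozen as tests.

## ANT-I cleaning and effect scores

Per subject: no-response trials are marked incorrect and excluded from RT
analysis; among correct responded trials, RTs beyond $\pm 3$ SD of the same
18-cell condition mean are excluded, in a single pass, per cell. Effects are
subtraction scores oriented so that *larger = worse*:
alerting $=$ RT(no signal) $-$ RT(signal); orienting $=$ RT(invalid) $-$
RT(valid); conflict $=$ RT(incongruent) $-$ RT(congruent). (One published
table footnote states the alerting direction reversed, but the printed
condition means confirm the definition used here: $726.7 - 676.6 \approx
50$, the printed effect.) Accuracy effects mirror the RT directions; overall
RT averages all retained trials, with a flag to exclude neutral-flanker
trials since their contribution is not specified.

A numerical property worth knowing: with the task's 4 trials per cell per
block (8 per cell after pooling two blocks), a sample of $n$ values cannot
contain a point farther than $(n-1)/\sqrt{n} \approx 2.47$ SD from its own
mean, so the within-cell $\pm 3$ SD rule cannot fire at this design size —
it becomes active only when cells are pooled more coarsely or sessions are
repeated. The rule is implemented exactly as stated and is oracle-tested on
constructed cells of $n \ge 11$, where exclusions are possible.

## The synthetic cohort generator

The generator's defaults are the study conditions: group sizes 39/34/36,
sex ratios 29:10 / 24:10 / 17:19, ages $10.6 \pm 1.9$ / $11.0 \pm 1.9$ /
$11.6 \pm 1.5$ years, six schools, and per-group latent parameters set from
the published condition means and SDs — congruent-condition RT
($662.4 \pm 137.2$, $594.4 \pm 113.2$, $566.5 \pm 129.5$ ms), alerting,
orienting, and conflict deltas, and true capacity
($2.73 \pm 0.73$, $2.82 \pm 0.71$, $3.26 \pm 0.61$ bits/s, truncated at
0.3). Trial RTs are ex-Gaussian ($\sigma = 60$, $\tau = 150$ ms at the trial
level — values typical for children's choice RT and small relative to the
between-subject SDs, which therefore dominate the group-level picture, as in
the published tables); condition means are additive in the latent deltas,
with uncued trials carrying half the orienting delta (they lack the spatial
cue benefit but also the invalid-cue reorienting cost). Error probability is
2% at baseline plus 6.5% on incongruent trials (matching the ~6--7% conflict
accuracy effects); response lapses occur at a per-subject rate of
$0.02 \pm 0.015$ (capped at 0.2), and RTs beyond the response windows
(1,700 / 2,500 ms) become non-responses.

Symptom reports are generated top-down: a target count of symptomatic items
(score $\ge 2$) per subscale is drawn from the group's published
distribution ($6.4 \pm 1.8$ inattention items for ADHD, $3.4 \pm 1.3$
subthreshold, $0.2 \pm 0.4$ TD, analogously for hyperactivity/impulsivity)
and constrained to the intended diagnostic band; the teacher report is the
parent report with a 5% per-item $\pm 1$ perturbation, so informant
agreement is imperfect. The realized group label is produced by
`diagnose()` — each rater must meet the symptom criterion
($\ge 6$ items $\ge 2$ in either subscale for ADHD; 3--5 for subthreshold)
and the ASQ cut-off of 10 — so roughly 5% of subjects end up with a label
other than intended, as in any two-informant screen. Design choices made
where the published procedure is silent:

* The ASQ cut-off is required of **both** raters (symmetry with the symptom
  rule); `asq_both_raters = FALSE` switches to either-rater.
* "Both raters meet subthreshold" is read as both meeting
  subthreshold-**or-stronger** while not both meeting ADHD, since each child
  receives a single label.
* The DSM-IV age-of-onset / two-setting impairment criterion has no
  observable counterpart in simulated reports and is treated as always
  satisfied.
* The opposition/defiance subscale is generated but never used by diagnosis.

What the generator does **not** emulate: the population screening funnel and
detection rates, comorbidity, subtypes, skewed or heavy-tailed
between-subject RT distributions, correlations between latent effects within
a subject, and practice or fatigue effects. Passing tests therefore show
that the estimators recover the structure this generator encodes — not that
they would reproduce every idiosyncrasy of the clinical sample.

## Deficit frequencies

The cut point for each measure is the decile of the TD distribution lying in
the *deficit* tail: the 10th percentile of CCC (lower is worse) and the 90th
of each RT effect (larger is worse), by linear interpolation between order
statistics (type-7 quantile). The published rule says "10th percentile" for
all measures; read literally for the effects that would flag the *best*
performers, so the worst-decile reading is the default and
`literal_decile = TRUE` provides the literal one. Ties at the cut are not
deficits. Frequencies are compared with the Pearson chi-square test of
independence with **no continuity correction** — the package reproduces all
of the study's printed chi-square statistics (6.87, 5.81, 1.18, 1.68,
0.1484, 0.0004) from the printed counts only without the correction.

## Group inference

`ancova()` fits the index on group plus covariates (sex, age, school — school
as an unordered factor) by least squares with sum-to-zero contrasts and
reports the Type-III F for group, partial $\eta^2 =
SS_g/(SS_g + SS_{res})$ (this is the $\eta^2$ convention that reproduces the
published effect sizes from their F statistics), covariate-adjusted group
means, and Bonferroni-corrected pairwise contrasts via estimated marginal
means. Note the published denominator dfs are consistent with school entered
as a single numeric covariate; treating school as categorical costs five
additional dfs and is the statistically defensible choice adopted here.
Partial correlations residualize both variables on the covariates and apply
the t test with $df = n - 2 - k$; Fisher's z compares two independent
correlations on raw group sizes. Bayes factors are supplied only as the BIC
approximation $BF_{10} = \exp((BIC_0 - BIC_1)/2)$, labelled by the
$> 3$ / $< 1/3$ convention — a descriptive supplement, not a JZS
reproduction.

## Classification

Features are the three RT effects, overall RT, and CCC, z-scored across all
subjects in the classified sample — replicating the original procedure
including its train/test leakage; `scale_in_folds = TRUE` gives the
leakage-free variant and is recommended for new work. The classifier is a
linear soft-margin SVM with unit box constraint. The default resampling
follows the published description literally: each of 1,000 repeats holds out
a random $\lceil N/10 \rceil$ subjects, trains on the rest, and records test
accuracy; the per-repeat baseline shuffles the held-out labels; significance
is a one-sided one-sample t test of accuracies against the mean baseline. A
classical 10-fold partition per repeat is available as `mode = "kfold"`.
Cross-population prediction trains once on one clinical-vs-TD sample
(standardized on its own population) and evaluates on random tenths of the
other. Chance level is the prevalence of the more-affected class.

On default synthetic cohorts the pipeline reproduces the qualitative
published pattern: both clinical-vs-TD classifications are far above chance
($p < 0.001$ at 1,000 repeats) while ADHD-vs-subthreshold is statistically
indistinguishable from the shuffled baseline. With imbalanced classes a
signal-free SVM's accuracy can fall *below* the prevalence-based chance
level, so "at chance" is asserted as not exceeding chance and not beating
the baseline, rather than as a two-sided band around prevalence.

## Problem sizes, seeds, determinism

Every stochastic operation takes an explicit seed; the cohort and pipeline
default to seed 20220311, and per-subject and per-stage sub-seeds are derived
deterministically, so whole pipeline runs are byte-identical under a fixed
configuration. The test suite exercises study-sized problems throughout: the
full 109-subject cohort with complete 144/324-trial sessions, 36-subject
recovery cohorts, 1,000-repeat classifications for the acceptance pattern and
20--400 repeats for structural checks, and $10^5$-draw Monte-Carlo oracles —
sizes chosen to keep every sampling check several standard errors wide of its
threshold.

## Known limitations

* The accuracy model's linear descent is one defensible reading of
  "accuracy starts to drop"; the original estimation script was not
  available for differencing, so the form is isolated behind
  `predict_accuracy()`.
* Capacity is not identified above the design's maximum information rate
  (19.64 bits/s); estimates at the grid edge are flagged, not extrapolated.
* BIC Bayes factors can differ substantially from JZS values for small
  samples; treat the labels as descriptive.
* The generator draws latent effects independently within subject; real
  effect scores correlate through shared base RT and arousal, so real-data
  classification accuracies need not match the synthetic ones.
* MFT-M RTs are simulated for schema completeness but no published analysis
  consumes them beyond cleaning; they are carried, not interpreted.
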
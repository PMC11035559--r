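---
title: "Statistically validated comorbidity networks: model, calibration, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistically validated comorbidity networks: model, calibration, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The model

A diagnosis registry is a bipartite network: disease codes on one side,
patients on the other, a link whenever the patient was ever diagnosed with
the code. Projecting onto the code side links any two codes sharing a
patient, but that projection is dominated by the enormous heterogeneity of
registries — code prevalences span orders of magnitude and per-patient
diagnosis counts vary just as widely. `comorbnet` therefore tests each
co-occurring pair against a null model that rewires the bipartite network
at random **while keeping every node's degree fixed**: each code keeps its
number of carriers, each patient keeps their number of diagnoses, and only
the matching is randomized.

Under this null, for a cohort of $N$ patients in which $N_i$ carry code $i$
and $N_j$ carry code $j$, the number of co-carriers $X$ follows the
hypergeometric law

$$H(X \mid N, N_i, N_j) = \frac{\binom{N_i}{X}\binom{N-N_i}{N_j-X}}{\binom{N}{N_j}},$$

and the p-value of an observed co-occurrence count $N_{ij}$ is the right
tail

$$p(N_{ij}) = P(X \ge N_{ij}) = 1 - \sum_{X=0}^{N_{ij}-1} H(X \mid N, N_i, N_j).$$

Only over-representation is tested; under-representation (codes co-occurring
*less* than chance) is out of scope. Because thousands of pairs are tested
per cohort, the retained links are selected by the Benjamini–Hochberg
step-up rule at level $\alpha$: sort the $T$ p-values increasingly and
validate all pairs of rank $\le k^\* = \max\{k : p_{(k)} \le k\alpha/T\}$.
A Bonferroni mode ($p \le \alpha/T$) is available for a familywise-error
reading. The default $\alpha = 0.01$.

One deliberate interpretation is worth stating: a literal "stop when
$p_n > n\alpha$" rule, without dividing by the number of tests, is not an
FDR-controlling procedure; `fdr_select()` implements the standard step-up
rule $p_{(k)} \le k\alpha/T$ and records the applied per-rank threshold on
every link so the decision is auditable.

## Cohorts and first-diagnosis ages

The analysis is stratified by gender (M/W) and ten-year age decade. Each
patient's history is first reduced to one record per (patient, code): the
age at which the code was *first* diagnosed. A patient joins cohort
(gender, decade) if at least one of their first diagnoses falls in that
decade, and contributes their cumulative history up to the decade's end —
a patient first diagnosed at 56 and 63 is in the 50–59 cohort with one
code and in the 60–69 cohort with both. The top decade is an open-ended
80–XX bucket. Two readings of "membership" are defensible for decades in
which a patient has no *new* first diagnosis; the strict reading above is
the default, and `build_cohorts(carry_forward = TRUE)` implements the
alternative (membership in every decade from first activity onward) for
sensitivity analysis.

Ages given as dates are converted to completed years,
$\lfloor \text{days}/365.25 \rfloor$, the clinical convention. ICD codes
are analyzed at the three-character category plus at most one subcategory
digit ("XX.X"); extra digits are truncated, never rounded, so the mapping
is deterministic and idempotent.

## Numerical policy

The tail sum is evaluated in log space from `lchoose` terms. Which side is
summed depends on where $N_{ij}$ sits relative to the distribution's mode:
above the mode the right tail is summed directly (smallest terms first,
via a max-factored log-sum-exp), which preserves full relative precision
for p-values down to about $10^{-300}$; at or below the mode the
complement of the left tail is used, where $p \gtrsim 0.5$ and the
subtraction from 1 is harmless. Choosing the side by *length* instead of
by mode position is tempting but wrong — the shorter tail is not always
the smaller one — and the test suite pins this distinction. Values beyond
double range are clamped to the smallest positive double, honoring the
$p \in (0, 1]$ contract. Exactness is verified against exhaustive subset
enumeration for every margin combination with $N \le 12$ and against the
survival function of the hypergeometric distribution at registry-scale
margins; pmf normalization holds to $10^{-9}$ up to $N = 10^6$.

Ties in p-values share eligibility under the step-up rule, and the sort
key (p-value, then lexicographic pair) makes ranks reproducible. $T$
defaults to the number of pairs actually tested — pairs of retained codes
co-occurring at least `min_cooccurrence` (default 1) times. Pairs that
never co-occur have $p = 1$ and can never be rejected, but including them
inflates $T$ and tightens every threshold; `test_all_pairs = TRUE` opts
into that stricter convention. Both prevalence and co-occurrence filters
default to 1 (no filtering), since the source analyses state none.

## The synthetic registry generator

`generate_population()` emulates the statistical structure the validation
assumes, with ground truth known exactly:

* **Prevalences** are log-uniform on $[0.001, 0.3]$ by default — several
  orders of magnitude, as registries show. The focal code I67.1 defaults
  to 3% prevalence, the population figure usually cited for unruptured
  intracranial aneurysms.
* **Baseline assignment** is independent Bernoulli per (patient, code)
  given the prevalences. This is an *exact* null for the degree-preserving
  test — conditional on the margins, the carrier sets are uniform random
  subsets — while still yielding heterogeneous per-patient code counts
  (sums of independent Bernoullis).
* **Planted comorbidity**: for a pair $(a, b)$ with relative risk
  $\rho \ge 1$, carriers of $a$ receive $b$ with probability
  $\min(1, \rho p_b)$ instead of $p_b$. The conditional is one-directional
  but induces symmetric excess co-occurrence; no directionality should be
  read into recovered links. Restrictions by gender and by age decade
  confine the effect to one cohort (ages of both planted codes are then
  drawn inside that decade).
* **Ages** are uniform integers within a per-code range (default 30–89);
  no longitudinal correlation is modeled, since the analysis consumes only
  first-diagnosis ages.

What the generator does *not* emulate: real diagnostic correlation
structure beyond the planted pairs, coding-practice artifacts, censoring
and mortality, and calendar effects. Passing calibration on synthetic data
therefore demonstrates that the procedure controls its error and recovers
strong signals under its own assumptions — not that any particular
clinical association in real registries is certain.

Identical configuration and seed reproduce the registry byte for byte;
the pipeline itself is deterministic, so end-to-end runs are byte-identical
too.

## Calibration and power

Two study functions make the package's operating characteristics
measurable:

* `null_fdp_study()` generates replicate null registries (no planted
  pairs), runs the full validation, and reports the mean realized
  false-discovery proportion and the median validated-link count. The
  shipped configuration uses 200 replicates of a 2000-patient,
  150-code cohort with prevalences log-uniform on $[0.005, 0.30]$ at
  $\alpha = 0.01$ — sizes chosen to finish in minutes on one core while
  leaving the binomial error of the estimate well below the level being
  verified. Because hypergeometric p-values are discrete and conservative,
  the realized proportion typically sits far below $\alpha$.
* `planted_recovery_study()` plants one focal pair (defaults: 5000
  patients, focal at 3%, partner pinned at 20%, $\rho = 5$, so every focal
  carrier receives the partner code) and measures how often the link is
  validated, alongside `analytic_planted_power()` — a closed-form estimate
  from the hypergeometric tail at the expected margins with a
  Bonferroni-conservative threshold $\alpha/T$. At these settings the
  expected co-occurrence (~150) sits dozens of standard deviations above
  the null expectation (~34), the analytic power is 1 to double precision,
  and recovery is expected in every replicate.

## Ego networks and summaries

The ego network of a focal code comprises the code and all its validated
neighbors. The standard definition of an ego *subgraph* includes
alter–alter edges, and that induced mode is the default;
`mode = "star"` keeps only focal-incident edges for analyses that treat
neighbors as a plain list. A focal code absent from a cohort's network
yields a singleton ego network rather than an error, so cross-cohort
tabulations stay total.

Chapter summaries count non-focal ego members per ICD chapter block
(E00–E99 … Z00–Z99, plus "other" for letters outside the usual summary
set), with percentages per gender row. Two H-block conventions coexist in
the field: eye (H00–H59) and ear (H60–H95) split for display and coloring,
merged H00–H99 for summary tables; `icd_chapters(merged_h =)` exposes
both, and within every letter the ranges tile 00–99 so every normalized
code maps to exactly one block. Percentages are rounded **half-up** to one
decimal (14/19 renders 73.7) — matching printed-table conventions rather
than R's round-half-to-even — and per-row percentages re-sum to 100 within
±0.3 rounding slack.

Cross-cohort presence is reported both as distinct codes (union over
cohorts, also per gender) and as code–cohort incidences (with
multiplicity): stratified analyses are commonly quoted both ways and the
two counts differ whenever a code recurs across cohorts, so the package
reports both and asserts neither as "the" count.

## Degenerate inputs and edge cases

* $N_{ij} = 0$ (or at the support's lower bound) gives $p = 1$ — the empty
  sum.
* A code carried by all patients can only co-occur maximally; its pairs
  get $p = 1$.
* A cohort in which every patient has one code yields zero tested pairs
  and an empty network, not an error.
* Patients with conflicting gender across records abort
  `first_diagnosis_ages()` with the offending identifiers listed;
  unparseable rows are dropped, counted, and attributed by reason in the
  parse report — never silently.
* Planted pairs with $\rho p_b > 1$ are capped at probability 1 with a
  warning.

## Problem sizes

The shipped tests and the acceptance script use: exhaustive enumeration up
to $N = 12$ (~1650 margin combinations), normalization checks up to
$N = 10^6$, 200 null replicates at 2000 patients × 150 codes, and 100
planted replicates at 5000 patients × 150 codes. These sizes make the
Monte-Carlo error of each estimate small relative to the property being
checked while keeping a full run in the minutes range on a single core.

## Known limitations

* The hypergeometric null conditions on margins; it does not model
  systematic reporting differences between hospitals or calendar periods.
* Validated links are population-level co-occurrence statements, not
  causal claims, and precedence (which diagnosis came first) is not
  analyzed.
* Only two genders are modeled, following the strict M/W stratification of
  the registries this design targets; other values are dropped with an
  attributed count.
* ICD-9/ICD-11 vocabularies and mappings between revisions are out of
  scope.
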
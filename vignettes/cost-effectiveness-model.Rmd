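---
title: "Methods: the CYP2C19 test-and-treat cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CYP2C19 test-and-treat cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `strokepgx`: its structure,
every tunable parameter and why its default takes the value it does, the
numerical conventions the engine uses where the literature leaves a choice
open, what the synthetic-data generator does and does not emulate, and the
limitations a user should keep in mind.

## The decision problem

After an ischaemic, non-cardioembolic stroke, UK practice prescribes
clopidogrel for secondary prevention. Carriers of a *CYP2C19*
loss-of-function (LoF) allele — about 25% of a European-ancestry cohort —
activate clopidogrel poorly and retain a high recurrence risk. A
point-of-care genotype test (result in ~40 minutes, £60 plus £16.91 of
staff time) allows carriers to be switched at first prescription to
modified-release dipyridamole plus aspirin (MRD+aspirin), or aspirin alone.
The model compares, from an NHS perspective in £2021 over a lifetime
horizon, *testing* against *no testing* for the annual UK cohort of
first ischaemic strokes (60,424 patients entering at mean age 67).

## Model structure

**Decision tree.** Treatment is resolved once at model entry.
Tolerance of each drug is a probability: a patient intolerant of
clopidogrel cascades to MRD+aspirin, and if intolerant of dipyridamole, to
aspirin. Under *testing*, LoF carriers skip clopidogrel and start the
cascade at MRD+aspirin; non-carriers get the full cascade. Under
*no testing* the genotype is unknown and both genotype groups receive the
identical clopidogrel cascade. A test-failure hook exists
(`test_failure_rate`, default 0): failed tests fall back to untested
prescribing while still paying for the test.

**Markov model.** Five states: no additional stroke, one additional stroke,
two or more additional strokes, vascular death, non-vascular death. Annual
cycles; everyone enters in "no additional stroke". From a living state
with annual recurrent-stroke probability $p$ and fatal fraction $f$:

* fatal recurrence, $p f$ → vascular death;
* non-fatal recurrence, $p(1-f)$ → next stroke-count state (recurrences
  from "two plus" remain there, but still count as stroke events for
  one-off costs);
* background death, $(1-p)\,q(\text{age})$ → non-vascular death;
* stay, $(1-p)(1-q)$.

The composition order — stroke event first, background mortality applied to
the stroke-free — is a documented convention; the published description
does not fix one.

**Genotype stratification.** The unstratified clopidogrel stroke
probability $\bar p$ is treated as a prevalence-weighted mixture,
$(1-f_{LoF})\,p_{noLoF} + f_{LoF}\,p_{LoF} = \bar p$, with
$p_{noLoF} = RR \cdot \bar p$ and $p_{LoF}$ solved from the identity.
Both arms are simulated as genotype-stratified sub-cohorts: in the
untested arm both groups receive clopidogrel at their group-specific
risks, which reproduces $\bar p$ exactly in the entry cycle (by the
identity) and lets the mixture evolve consistently in later cycles as the
higher-risk group is depleted faster. This is the natural cohort-level
reading of "the average probability of either metaboliser group"; a
strictly homogeneous-average implementation would differ only at second
order in later cycles.

## Parameters

All money is £2021; all probabilities are annual. Published point
estimates:

| Parameter | Default | Notes |
|---|---|---|
| LoF prevalence | 0.25 | binary: any of *2/*3/*8 vs none |
| RR, non-carriers on clopidogrel vs unstratified | 0.702 | implies a 2.79% non-carrier annual risk |
| Test cost / staff time | £60 / £16.91 | up front, undiscounted |
| Annual cost, non-disabling / disabling stroke state | £2,087 / £6,407 | |
| One-off cost: non-disabling / disabling / fatal stroke / non-stroke death | £7,936 / £16,896 / £10,855 / £2,755 | |
| Annual drug cost: clopidogrel / MRD+aspirin / aspirin | £32 / £82 / £22 | |
| Annual AE treatment cost per regimen | £25 / £32 / £27 | |
| Utility, no further stroke | 0.61 | stroke states: 0.61 − 0.174 = 0.436 |
| AE disutilities: minor bleed / major bleed / worsening CHF | 0.0033 / 0.1426 / 0.0163 | |
| Discount rate / λ / entry age / cohort | 3.5% / £20,000 per QALY / 67 / 60,424 | |

Inputs whose source values are not publicly printed ship as **documented
assumptions**, segregated under an `assumptions:` block in the bundled
parameter file so they can be replaced by a data edit:

* `p_stroke_clopidogrel_avg = 0.03974` — back-derived so that
  $RR \cdot \bar p = 2.79\%$, the non-carrier risk the analysis quotes.
* `p_stroke_mrd_aspirin = p_stroke_aspirin = 0.03974` — the alternative
  regimens are assumed to match unstratified clopidogrel, consistent with
  the trial synthesis they derive from.
* `fatal_stroke_fraction = 0.20` — a typical early case-fatality for
  recurrent ischaemic stroke in the trial era the cost data come from.
* `disabling_fraction = 0.50` — share of non-fatal recurrences costed as
  disabling for the one-off event cost; an agnostic midpoint.
* `tolerance_clopidogrel = 0.95`, `tolerance_mrd = 0.90` — most patients
  tolerate either drug; discontinuation for intolerance is the exception.
* Adverse-event probabilities (minor bleed 3%/yr on all regimens; major
  bleed 0.5%/0.4%/0.4%; worsening CHF 0.6%/yr on MRD+aspirin only,
  reflecting dipyridamole's vasodilatory cardiac effects) — small expected
  burdens of the right order for antiplatelet therapy.
* `max_age = 100` — the "lifetime" horizon: 33 cycles, by which point the
  life table has closed the cohort.
* `p_stroke_after_first_recurrence` — `NULL` by default, meaning the risk
  of a further stroke from the post-recurrence states equals the
  first-recurrence risk for the same regimen; it can be set per regimen.

**State-to-cost mapping.** The published five states do not name disability
severity. The convention here: the "no additional stroke" and "one
additional stroke" states carry the *non-disabling* annual treatment cost,
"two plus" carries the *disabling* annual cost; `disabling_fraction`
splits only the one-off cost of each non-fatal recurrence. Both
post-recurrence states use the decremented utility 0.436.

**Adverse events** are expected per-person-year burdens
(probability × unit cost, probability × disutility), not model states —
they are small, annual, and regimen-specific, so expanding the state space
for them would change nothing but the bookkeeping.

**Life table.** Background mortality is synthetic by default: a Gompertz
hazard $q(a) = 1 - \exp(-A e^{Ba})$ with $A = 2\times10^{-5}$, $B = 0.1$,
chosen to resemble recent UK all-cause rates (≈1.6% at 67, ≈15% at 90),
forced to $q = 1$ at the top age. A loader for a real two-column
(age, q) file is provided. Two simplifications are documented rather than
corrected: the table is all-cause (not decremented for the vascular deaths
the model produces itself), and the table value for a cycle is looked up
at the age attained at the end of that cycle, which is what lets the
forced closure empty the cohort by the horizon.

## Accounting conventions

* Cycle $t$ (the first cycle is $t = 0$) accrues the occupancy at the
  *start* of the cycle, discounted by $(1+r)^{-t}$; one-off event costs
  for events during cycle $t$ carry the same factor. The up-front testing
  cost is added once, undiscounted.
* No half-cycle correction by default (the source analysis states none);
  `half_cycle = TRUE` averages start- and end-of-cycle occupancy for the
  continuous accruals, leaving event flows unchanged.
* Because mortality applies to the stroke-free, the survivors of the final
  cycle's non-fatal strokes — a fraction bounded by
  $p(1-f)$ of the (already tiny) population alive entering the last cycle
  — outlive the forced closure. The residue is of order $10^{-4}$ of the
  cohort and is ignored by the economics; the test suite asserts the bound.
* Display rounding (£ to the pound, QALYs to 3 d.p.) happens only at print
  time; all arithmetic is done unrounded.

## Probabilistic sensitivity analysis

The original appendix of distributions is not available, so the families
are the standard conventions — beta for probabilities, proportions and
utilities; gamma for costs; lognormal for the risk ratio — with family
parameters obtained by moment matching. Default dispersions are a
coefficient of variation of 0.15 for costs and a standard error of
0.1 × the point estimate for probabilities and utilities (0.1 CV for the
risk ratio), every one overridable per parameter in the `psa:` block.
Because these dispersions are the package's assumptions, the published PSA
probabilities (77% cost-effective, 62% cost-saving) are plausibility
anchors, not reproduction targets: with the defaults here the intervention
is more robustly dominant than that.

Design settings (discount rate, λ, ages, cohort size) are fixed across
iterations. Each iteration draws from its own deterministically derived
substream seed, so results are independent of execution order; a draw whose
joint parameters are infeasible (the mixture identity would push the
carrier risk outside [0, 1]) is resampled, up to 100 attempts, and the
resample count is reported. "Cost-effective" is strict: NMB > 0;
"cost-saving" is ΔCost < 0.

## Threshold analysis

One parameter is varied, all else at base case, and the boundary is
per-patient NMB = 0 — equivalent to ICER = λ in the north-east quadrant
and still well-defined where a strategy dominates. The search is bisection
with |NMB| ≤ £0.01 convergence and a 200-step cap; if NMB does not change
sign across the bounds the result is "none in range", which is itself
informative (the MRD tolerance behaves this way in the source analysis and
in the null-effect scenario here). Any scalar parameter or per-regimen
element can be searched; the four clinically central ones are the risk
ratio, the test cost, and the two tolerances.

## The synthetic-data generator

`generate_fixture()` produces internally consistent parameter sets plus a
matching life table in four scenarios: `base_case` (the defaults
above), `null_effect` (risk ratio 1 and identical regimens, so testing is
pure dead weight and NMB = −£76.91 exactly, up to floating-point
rounding), `extreme_effect` (risk ratio 0.3), and `randomized` (uniform
draws within each parameter's support, bounded so the genotype mixture
stays feasible; deterministic per seed). Generated files pass the loader's
validation and round-trip bit-identically (YAML serialised at 22
significant digits).

What the generator does *not* emulate: correlation between parameters (no
correlation information exists to calibrate it), time-varying treatment
effects or adherence, secular trends in costs, competing cardiovascular
events other than stroke, and individual-level heterogeneity beyond the
genotype split. Passing tests therefore demonstrate the engine's internal
correctness and the arithmetic of the published summaries — not that the
default assumptions are the true epidemiology.

## Problem sizes used by the test suite

The structural property checks run the full engine on 1,000 randomized
fixtures; PSA determinism and classification checks use 40–60 iterations;
the grid-versus-bisection cross-check uses a 201-point grid. These sizes
give each property thousands of distinct assertions while keeping the
whole suite under a minute on a laptop; all are the package's own choices
and can be scaled up freely.

## Known limitations

* The unpublished transition inputs are assumptions; the headline
  increments (ΔC, ΔQ) therefore differ from the source analysis even
  though every published derived statistic (population counts, utilities,
  net-benefit arithmetic) is reproduced exactly. The qualitative result —
  testing dominant, driven by RR < 1 at 25% prevalence — is robust across
  the fixture scenarios.
* Two strategies only; no ticagrelor arm, no TIA population.
* Cohort-level (no microsimulation); tolerance resolved once at entry;
  no re-testing or switching dynamics.
* All index strokes are treated as atherothrombotic and antiplatelet-
  eligible.
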
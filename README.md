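# strokepgx

Early decision-analytic cost-effectiveness modelling of a point-of-care
*CYP2C19* pharmacogenetic test to guide antiplatelet prescription after
ischaemic, non-cardioembolic stroke.

## The problem

Clopidogrel is first-line secondary prevention after ischaemic stroke, but
it is a prodrug activated by the enzyme encoded by *CYP2C19*. Roughly 25%
of people of European ancestry carry a loss-of-function (LoF) allele
(*2, *3 or *8), metabolise clopidogrel poorly, and get little antiplatelet
protection from it. A rapid point-of-care genotype test lets clinicians
switch LoF carriers to modified-release dipyridamole plus aspirin (or
aspirin alone) at first prescription. `strokepgx` asks the health-economic
question: does paying for the test (and for the more expensive alternative
regimen) buy more health than it costs the NHS, at a willingness-to-pay
threshold of λ = £20,000 per QALY?

The package is aimed at health economists and HTA analysts who want a
transparent, fully parameterised, re-runnable version of this analysis: every
input is a field in a validated parameter file, and every published summary
statistic is a function call away.

## The model

* **Decision tree** — under *testing*, patients with no LoF allele receive
  clopidogrel (cascading to MRD+aspirin, then aspirin, if not tolerated);
  LoF carriers skip clopidogrel and start at MRD+aspirin. Under
  *no testing* everyone enters the clopidogrel cascade. Testing costs
  £60 + £16.91 staff time per patient, up front.
* **Markov cohort model** — five states: no additional stroke, one
  additional stroke, two or more additional strokes, vascular death,
  non-vascular death; annual cycles from age 67 to 100 (lifetime horizon).
  Within a cycle, a recurrent stroke (fatal with probability *f*) resolves
  first; background mortality *q(age)* then applies to the stroke-free.
* **Genotype stratification** — the unstratified annual stroke probability
  on clopidogrel, p̄, is a prevalence-weighted mixture of the group risks:
  (1−f_LoF)·p_noLoF + f_LoF·p_LoF = p̄, with p_noLoF = RR·p̄ (RR = 0.702).
* **Economics** — discounted (3.5%/yr) costs (£2021) and QALYs per
  strategy; ICER = ΔC/ΔQ with dominance labels; NHB = ΔQ − ΔC/λ;
  NMB = ΔQ·λ − ΔC; totals scaled to the 60,424 UK first ischaemic strokes
  per year.
* **Uncertainty** — probabilistic sensitivity analysis (beta/gamma/lognormal
  distributions by moment matching, per-iteration substream seeds) with
  cost-effectiveness plane and acceptability curve; deterministic one-way
  threshold search by bisection on NMB.

## Worked example

```r
library(strokepgx)
fit <- cea()          # base case: bundled defaults, synthetic life table
summary(fit)
```

```
Cost-effectiveness of point-of-care CYP2C19 testing after ischaemic stroke
  Strategy                       Total cost  Total QALYs
  No testing (clopidogrel)         £33,821        6.627
  CYP2C19 testing                  £32,560        6.757
  Incremental (testing - no testing): cost -£1,260, QALYs 0.130
  ICER: not applicable - testing dominant
  NHB 0.193 QALYs/patient, NMB £3,858/patient at lambda £20,000/QALY
  Population (n = 60,424): total NHB 11,656 QALYs, total NMB £233,124,969
  Strokes prevented across cohort: 5,621 non-fatal, 1,405 fatal
  Undiscounted life expectancy per patient: 15.74 (testing) vs 15.55 years
```

Testing *dominates* current prescribing here: it saves £1,260 per patient
over a lifetime and adds 0.130 QALYs, so no trade-off price need be paid.
(The exact increments depend on the documented assumptions filling the
unpublished transition inputs — see the vignette; the direction is driven
by RR < 1 and carrier prevalence.)

```r
ps <- simulate(fit, nsim = 1000, seed = 1)   # probabilistic SA
ps
plot(ps, "plane"); plot(ps, "ceac")

threshold_search("test_cost", c(0, 20000))
```

```
One-way threshold analysis on 'test_cost'
  baseline 60, searched [0, 20000], NMB decreasing in parameter
  threshold value 3918.15 (NMB 0.0000 at threshold; 16 bisection steps)
```

i.e. under the default assumptions the test price could rise to about
£3,918 before testing stopped being cost-effective at £20,000/QALY.

A command-line front end wraps the same functions:

```sh
exec/stroke-cea run --params inst/extdata/parameters_default.yaml --out out/
exec/stroke-cea psa --params inst/extdata/parameters_default.yaml --n 10000 --seed 1 --out out/
```

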
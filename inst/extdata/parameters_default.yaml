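# Default inputs for the CYP2C19 test-and-treat cost-effectiveness model.
# Top-level fields carry published point estimates (2021 GBP); the
# `assumptions` block segregates inputs without a published point estimate,
# so sourcing better values later is a data edit, not a code change.
schema_version: 1

# genotype and treatment effect
lof_prevalence: 0.25            # carriers of >=1 CYP2C19 LoF allele (*2/*3/*8)
rr_clopidogrel_noLoF: 0.702     # stroke risk, non-carriers vs unstratified

# testing costs
test_cost: 60.0                 # point-of-care test, manufacturer price
staff_cost: 16.91               # 10 min nurse + 5 min consultant time

# health-state and event costs
annual_cost_nondisabling: 2087.0
annual_cost_disabling: 6407.0
onecost_nondisabling: 7936.0
onecost_disabling: 16896.0
onecost_fatal_stroke: 10855.0
onecost_nonstroke_death: 2755.0

# per-regimen annual costs
drug_cost: {clopidogrel: 32.0, mrd_aspirin: 82.0, aspirin: 22.0}
ae_cost: {clopidogrel: 25.0, mrd_aspirin: 32.0, aspirin: 27.0}

# utilities
utility_no_further_stroke: 0.61
utility_decrement_per_stroke_state: 0.174   # stroke states: 0.61 - 0.174 = 0.436
disutility_minor_bleed: 0.0033
disutility_major_bleed: 0.1426
disutility_chf: 0.0163

# economics and cohort
discount_rate: 0.035
lambda: 20000.0                 # willingness to pay, GBP per QALY
start_age: 67
cohort_size: 60424              # first ischaemic strokes, UK, one year

psa:
  cost_cv: 0.15
  prob_se_frac: 0.1
  rr_cv: 0.1
  overrides: {}

assumptions:
  # implied by the 2.79% annual risk in non-carriers at RR 0.702
  p_stroke_clopidogrel_avg: 0.03974
  # alternative regimens assumed to match unstratified clopidogrel
  p_stroke_mrd_aspirin: 0.03974
  p_stroke_aspirin: 0.03974
  # case fatality of recurrent stroke
  fatal_stroke_fraction: 0.2
  # share of non-fatal recurrences treated as disabling for one-off costs
  disabling_fraction: 0.5
  # ability to remain on the prescribed drug (resolved once at entry)
  tolerance_clopidogrel: 0.95
  tolerance_mrd: 0.9
  # annual adverse-event probabilities per regimen
  p_minor_bleed: {clopidogrel: 0.03, mrd_aspirin: 0.03, aspirin: 0.03}
  p_major_bleed: {clopidogrel: 0.005, mrd_aspirin: 0.004, aspirin: 0.004}
  p_chf: {clopidogrel: 0.0, mrd_aspirin: 0.006, aspirin: 0.0}
  # model horizon: run to extinction of the cohort
  max_age: 100
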
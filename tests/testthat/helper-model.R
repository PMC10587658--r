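# Shared test helpers: small deterministic model instances and an
# independent matrix-power oracle built from explicit arithmetic.

# A flat life table: constant annual mortality q at every age except the
# top age, which closes at 1.
flat_life_table <- function(q, start_age = 67, max_age = 100) {
  ages <- start_age:max_age
  data.frame(age = ages, q = c(rep(q, length(ages) - 1L), 1))
}

# Degenerate parameters: a single-regimen world with no strokes, no
# background deaths before the horizon, no adverse events, no discounting.
# Used to isolate single accrual terms.
quiet_params <- function(...) {
  defaults <- list(
    p_stroke_clopidogrel_avg = 0, p_stroke_mrd_aspirin = 0,
    p_stroke_aspirin = 0, rr_clopidogrel_noLoF = 1,
    fatal_stroke_fraction = 0, tolerance_clopidogrel = 1, tolerance_mrd = 1,
    p_minor_bleed = c(clopidogrel = 0, mrd_aspirin = 0, aspirin = 0),
    p_major_bleed = c(clopidogrel = 0, mrd_aspirin = 0, aspirin = 0),
    p_chf = c(clopidogrel = 0, mrd_aspirin = 0, aspirin = 0),
    drug_cost = c(clopidogrel = 0, mrd_aspirin = 0, aspirin = 0),
    ae_cost = c(clopidogrel = 0, mrd_aspirin = 0, aspirin = 0),
    onecost_nonstroke_death = 0, onecost_fatal_stroke = 0,
    onecost_nondisabling = 0, onecost_disabling = 0,
    discount_rate = 0
  )
  do.call(cea_params, utils::modifyList(defaults, list(...)))
}

# Independent single-cycle matrix, written out state by state from the
# competing-risk composition (stroke event first, background mortality on
# the stroke-free), without calling the package's constructor.
oracle_matrix <- function(p1, p2, f, q) {
  rbind(
    c((1 - p1) * (1 - q), p1 * (1 - f), 0, p1 * f, (1 - p1) * q),
    c(0, (1 - p2) * (1 - q), p2 * (1 - f), p2 * f, (1 - p2) * q),
    c(0, 0, (1 - p2) * (1 - q) + p2 * (1 - f), p2 * f, (1 - p2) * q),
    c(0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 1))
}
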
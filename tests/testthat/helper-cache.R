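# Expensive shared computations, built once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

ref_model <- function() cached("model", build_default_model())
ref_expression <- function() cached("expression", default_expression(ref_model()))
ref_trajectory <- function() cached(
  "trajectory", simulate_model(ref_model(), ref_expression()))

# full perturbation scan over all 40 reactions (the single most expensive
# shared computation, ~1 minute)
ref_scan <- function() cached(
  "scan", scan_all(ref_model(), ref_expression()))

ref_prediction_table <- function() cached(
  "prediction_table", prediction_table(ref_model(), ref_expression()))

fix_model <- function() cached("fixture", fixture_model())
fix_expression <- function() cached("fixture_expr", fixture_expression(fix_model()))

# last index at or nearest a given DAF
at_daf <- function(traj, daf) which.min(abs(traj$time_daf - daf))
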
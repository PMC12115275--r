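# Shared fixture accessors and small builders used across the suite.

material_profiles <- sedem_fixture("material_profiles")
formulation_profiles <- sedem_fixture("formulation_profiles")
carb_profile <- material_profiles[["carbamazepine"]]

# A complete, physically consistent synthetic dataset for parser/pipeline
# tests (not tied to any reference material).
demo_dataset <- function(name = "demo") {
  powder_dataset(
    name,
    density = density_measurement(100, 171.2,
      c("10" = 168, "500" = 143.5, "1250" = 142.5)),
    cone = cone_measurement(2.5, c(5, 5.1, 4.9, 5)),
    flow = flow_measurement(c(3.6, 3.7, 3.7)),
    moisture = moisture_record(100, 99.67, 100.10),
    sieve = sieve_analysis(c(15, 25, 30, 19, 11)),
    hardness = hardness_sample(c(58, 60, 62))
  )
}

# Independent literal expansion of the homogeneity index for up to 5
# fractions: explicit neighbor-offset terms around the majority fraction,
# written out rather than vectorized, as an oracle for the generic loop.
homogeneity_literal <- function(retained, diam) {
  stopifnot(length(retained) <= 5, length(retained) == length(diam))
  m <- which.max(retained)
  acc <- 0
  for (off in 1:4) {
    lo <- m - off
    hi <- m + off
    if (lo >= 1) acc <- acc + abs(diam[m] - diam[lo]) * retained[lo]
    if (hi <= length(retained)) acc <- acc + abs(diam[m] - diam[hi]) * retained[hi]
  }
  retained[m] / (100 + acc)
}
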
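# Shared fixtures, built in code at test time.

# A fixed perturbation of the reference parameters, inside the admissible
# box, used wherever a "known ground truth" patient is needed.
truth_multipliers <- c(n = 1.2, VolG = 0.9, p1 = 1.3, p2 = 0.8, p3 = 1.25,
                       p4 = 0.75, a1 = 1.4, a2 = 0.7, a3 = 1.2, a4 = 1.3,
                       a5 = 0.8, a6 = 1.2)

truth_params <- function(...) {
  xref <- reference_params()
  do.call(patient_params,
          c(as.list(xref * truth_multipliers[names(xref)]), list(...)))
}

# Basal-only forcing: constant u1 = u1b, no meals, no exercise.
basal_forcing <- function(params, n = 100L, dt = 5) {
  forcing_set(
    uniform_series(rep(params$u1b, n), 0, dt, "mU/min"),
    uniform_series(numeric(n), 0, dt, "g/min"),
    uniform_series(numeric(n), 0, dt, "PVO2max"))
}

# Minimal OhioT1DM-style XML fixture (written to a tempfile).
ohio_xml_fixture <- function() {
  path <- tempfile(fileext = ".xml")
  writeLines('<patient id="999" weight="60">
  <glucose_level>
    <event ts="17-09-2021 08:00:00" value="120"/>
    <event ts="17-09-2021 08:05:00" value="125"/>
    <event ts="17-09-2021 08:10:00" value="131"/>
  </glucose_level>
  <basal>
    <event ts="17-09-2021 08:00:00" value="0.9"/>
    <event ts="17-09-2021 09:00:00" value="1.1"/>
  </basal>
  <temp_basal>
    <event ts_begin="17-09-2021 08:20:00" ts_end="17-09-2021 08:40:00" value="0.3"/>
  </temp_basal>
  <bolus>
    <event ts_begin="17-09-2021 08:01:00" ts_end="17-09-2021 08:01:00" type="normal" dose="2.5"/>
    <event ts_begin="17-09-2021 08:30:00" ts_end="17-09-2021 09:00:00" type="normal dual" dose="4.0"/>
  </bolus>
  <meal>
    <event ts="17-09-2021 08:01:00" type="breakfast" carbs="45"/>
  </meal>
  <basis_heart_rate>
    <event ts="17-09-2021 08:00:00" value="72"/>
    <event ts="17-09-2021 08:30:00" value="95"/>
  </basis_heart_rate>
</patient>', path)
  path
}
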
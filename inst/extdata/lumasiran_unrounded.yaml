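# Higher-precision overlay for the lumasiran case.
#
# The published "~"-rounded maximum-scenario R&D lump sums hide precision
# that the published per-patient-year intermediates still carry:
#   - NCP/ROROR max ~EUR 1.1e9 is consistent with 1.11e9 (printed R&D PPPY
#     ~EUR 111k at 359 patients x 10 years; printed average lump ~EUR 970m
#     = (830m + 1110m)/2).
#   - AIM max ~EUR 1.1e9 is consistent with 1.108e9 (printed R&D PPPY
#     ~EUR 222k at 179 patients x 10 years; printed average ~EUR 954m).
# Apply with lumasiran_config(unrounded = TRUE).
models:
  ncp:
    max:
      rd_cost_total: 1.11e+9
  aim:
    max:
      rd_cost_total: 1.108e+9
  roror:
    max:
      rd_cost_total: 1.11e+9
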
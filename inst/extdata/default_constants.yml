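# Published parameterization of the Acartia tonsa hypoxia model.
# Field names mirror model_constants(); units in the package documentation.
slope_a: 34.9
intercept_b: -20.5
TRR: 261.5
MRR: 91.0
T_ref: 18
pcrit_se: 1.7
pleth_se: 1.7
egg_dry_wt: 0.104
egg_resp_cost: 264
vol_to_dw: 167.6
dw_to_C: 0.4
NGE: 0.75
RQ_mass: 0.338
ingestion_resp_slope: 0.07
ingestion_resp_intercept: 33.39
female_dw_intercept: 8.67
female_dw_slope: 0.25
q10_table:
  - salinity: 15
    q10: 1.5
  - salinity: 25
    q10: 2.03
  - salinity: 35
    q10: 2.22
regression_cutoff: 8
p_o2_sat: 20.95
fit_r2: 0.735
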
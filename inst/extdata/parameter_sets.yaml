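# Bundled model parameter sets.
# Units are embedded in the field names; time in hours, cell
# concentrations in cells/L, drug concentration in ng/mL, dose in mg.
#
# diseases: median individualized traits per disease cohort.
# fixed:    life-cycle constants shared by all patients.
# pd:       inhibitory-Emax drug effect on the maturation flux.
# pk_default: synthetic two-compartment oral PK calibrated so the coupled
#   model reproduces the reported qualitative ANC pattern (median DLBCL
#   patient, 3 mg daily: stable ANC to ~day 8-12, nadir after day 15).
# pk_printed_exposure: synthetic PK calibrated to the published exposure
#   scale (cycle-1 AUC ~236.2 ng/mL*h per mg on 5/7; Cmax ~23.9 ng/mL per
#   mg); for exposure reporting only.
diseases:
  gbm:
    circ0_cells_per_l: 4.5e+09
    ratio_reserv0_circ0: 3.0
    km_fraction: 0.6
    gamma: 0.02
  dlbcl:
    circ0_cells_per_l: 4.5e+09
    ratio_reserv0_circ0: 2.5
    km_fraction: 0.1
    gamma: 0.01
  mm:
    circ0_cells_per_l: 4.5e+09
    ratio_reserv0_circ0: 2.5
    km_fraction: 0.45
    gamma: 0.017
fixed:
  t_half_neutrophil_h: 30.0
  k_d_per_h: 0.001
  beta: 20.0
pd:
  emax: 0.9
  ec50_ng_ml: 15.0
  n_hill: 2.0
pk_default:
  ka_per_h: 1.0
  cl_over_f_l_per_h: 4.0
  vc_over_f_l: 50.0
  q_l_per_h: 8.0
  vp_l: 120.0
pk_printed_exposure:
  ka_per_h: 8.0
  cl_over_f_l_per_h: 84.041325
  vc_over_f_l: 18.651904
  q_l_per_h: 15.0
  vp_l: 120.0
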
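# pedtmdd run configuration template.
# Every key shown here carries its default; delete anything you do not want
# to override. Unknown keys are rejected. The units header is mandatory when
# a units section is present and must match the package-wide convention.

units:
  time: day
  concentration: nmol/l
  volume: l
  amount: nmol

# Adult reference TMDD micro constants. The shipped defaults anchor
# R0 = 1.74 nmol/l, vmax = 7.6038 nmol/l/day and km = 0.403 nmol/l; kel, kon,
# kdeg, v1, v2 and q are surrogate values in the typical IgG range. Replace
# them with the drug-specific set to reproduce a particular compound.
parameters:
  kel: 0.08928571428571429   # 1/day   (CL_linear = kel * v1 = 0.25 l/day)
  kon: 20                    # 1/(nmol/l)/day
  koff: 3.69                 # 1/day
  kint: 4.37                 # 1/day
  ksyn: 3.48                 # nmol/l/day
  kdeg: 2                    # 1/day
  v1: 2.8                    # l
  v2: 2.8                    # l
  q: 0.6                     # l/day

scaling:
  cl_exponent: 0.75
  v_exponent: 1
  ref_bw: 70                 # kg
  ref_plasma_volume: 2.8     # l

scenario:
  per_kg_doses: [0.5, 1, 2, 3, 4.5]            # mg/kg
  fixed_doses: [35, 70, 140, 210, 315]         # mg
  target_concentrations: [6.96, 1.74, 0.44, 0.11, 0.027, 0.0068, 0.0017]
  target_amounts: [19.5, 4.87, 1.23, 0.31, 0.076, 0.019, 0.005]
  age_labels: [2y, 6y, 12y, 18y]
  molecular_weight: 150000   # g/mol
  occupancy_threshold: 0.9

synthetic:
  n_per_group: 20
  bw_cv: 0.15
  obs_cv: 0.1
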
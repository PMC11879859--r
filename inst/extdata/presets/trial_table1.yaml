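# Trial-cohort calibration preset.
# Baseline means/SDs mirror the trial's published baseline table; cluster
# mixing weights mirror the observed 51/19/19 MARD/SIRD/MOD-like split.
# Cluster offsets are added to the overall mean and have weighted sum zero,
# so overall calibration is preserved.
baseline:
  glucose:       {mean: 6.4,  sd: 0.2}
  insulin:       {mean: 18.9, sd: 11.1}
  c_peptide:     {mean: 1.22, sd: 0.42}
  hba1c:         {mean: 38.2, sd: 4.1}
  bmi:           {mean: 32.1, sd: 3.8}
  waist:         {mean: 110.0, sd: 10.0}
  triglycerides: {mean: 1.5,  sd: 0.6}
  ggt:           {mean: 0.7,  sd: 0.5}
  height:        {mean: 172.0, sd: 9.0}
  age:           {mean: 63.0, sd: 9.0}
cluster_mix:
  MARD: 0.5730337078651685   # 51 / 89
  SIRD: 0.2134831460674157   # 19 / 89
  MOD:  0.2134831460674157   # 19 / 89
cluster_offsets:
  bmi:       {MARD: -2.1607843137254902, SIRD: 2.9,  MOD: 2.9}
  age:       {MARD: 2.0, SIRD: -2.6842105263157894, MOD: -2.6842105263157894}
  c_peptide: {MARD: -0.1, SIRD: 0.13421052631578947, MOD: 0.13421052631578947}
placebo_change_mean: 0.0
change_sd: 0.63
homa_change_sd: 2.2
week12_drift_sd:
  c_peptide: 0.1
  hba1c: 1.0
  bmi: 0.5
  waist: 2.0
  triglycerides: 0.2
  ggt: 0.1
effects:
  uniform:          {MARD: 0.2, SIRD: 0.2, MOD: 0.2}
  cluster_specific: {MARD: 0.4, SIRD: 0.0, MOD: 0.0}
  none:             {MARD: 0.0, SIRD: 0.0, MOD: 0.0}
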
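# BT2160 operon-regulator abundance preset.
# Stratum means are relative-abundance means of BT2160 in the high and low
# serum-sulforaphane strata; spearman_target is the target rank correlation
# of log BT2160 abundance with glycaemic improvement among MARD-like BSE
# recipients; stratified_effect is the extra mean improvement (mmol/l) of
# MARD-like BSE recipients in the above-median abundance stratum
# (mode = "stratified" only).
stratum_mean_high: 0.032
stratum_mean_low: 0.022
high_weight: 0.5
spearman_target: -0.47
stratified_effect: 0.7
change_sd: 0.63
n_features: 50
other_features_log_sd: 1.0
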
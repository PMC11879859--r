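# Serum sulforaphane bimodal mixture preset: two-component equal-variance
# Gaussian with component means (nmol/ml) separated by about twice the
# common SD. Concentrations are blank-corrected assay values, so small
# negative draws are retained by default (truncate: false); set
# truncate: true to resample negatives within component.
mean_low: 0.2
mean_high: 1.3
common_sd: 0.55
weight_high: 0.5
truncate: false
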
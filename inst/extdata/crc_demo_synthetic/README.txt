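Synthetic colorectal-cancer demonstration cohort (n = 292).
This bundle is entirely simulated: it is NOT patient data and is not
drawn from any real study. It is constructed so that the TP53
mutation prevalence is exactly 65.77% (146/222) among late-T-stage
samples (T3/T4/T4A/T4B) and exactly 50.0% (35/70) among early-T-stage
samples (T1/T2), and KRAS-mutant samples carry a planted 2-fold PFS
hazard, so the worked examples in the package README run end to end.
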
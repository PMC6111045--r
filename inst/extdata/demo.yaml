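# Demo pipeline configuration: a ~320-person family cohort with the default
# risk-factor effect sizes, array noise, and a handful of injected QC
# failures. Override any key on the command line or via readPipelineConfig().
nFamilies: 40
generations: 3
nProbes: 500
noiseSd: 0.02
heritability: 0.4
seed: 1
alpha: 0.05
mTests: 12
runPrs: true
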
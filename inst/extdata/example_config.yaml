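# Example SIP calling configuration (defaults shown; any field may be
# omitted). Load with sip_run_config(system.file("extdata",
# "example_config.yaml", package = "diazosip")).
mode: within-gradient
alpha: 0.1
lfc_threshold: 0.25
min_total: 10
min_prevalence: 0.20
min_base_mean: 1.25
hump_smooth: 3
hump_prominence: 2
windows: RNA
seed: 1
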
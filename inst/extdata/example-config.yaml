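# Example run configuration for the sinkcf CLI (see ?sinkcf_cli).
# Values here are overridden by command-line flags.
seed: 1
format: csv
k: 17            # cross-validation folds
smoothing: 1     # CDCP pseudo-count
weight_scheme: damped   # damped | relative | none
neighbors: 10    # CF neighbors retrieved
min_sim: 0.2     # CF similarity threshold
n_records: 1000  # simulate: registry size
p_offchain: 0.2  # simulate: off-chain labeling rate
p_E: 0.3         # simulate: contributing-cause rate
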
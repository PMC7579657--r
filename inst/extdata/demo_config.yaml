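# Demo pipeline configuration: generate a synthetic corpus emulating the
# study conditions, then run the full coding / rules / network analysis.
out_dir: emomine_demo
seed: 20200930
generator:
  n_total: 4000
min_support: 0.01
min_confidence: 0.1
top_k_rules: 5
top_node_fraction: 0.5
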
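# Shipped benchmark configuration for the default scRNA-seq pipeline.
# Load with read_benchmark_config(); the pipeline name resolves through the
# registry and the alternatives mirror the shipped defaults.
pipeline: scrna_default
alternatives:
  doubletmethod: [cluster_artificial]
  filt: [default]
  norm: [lognorm]
  sel: [variance]
  n_features: [2000]
  dims: [5, 10, 15, 20, 30, 50]
  graph_type: [snn_jaccard]
  clustmethod: [modularity_resolution]
  resolution: [0.005, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5,
               0.8, 1.0, 1.2, 1.5, 2.0, 4.0]
seed: 0
output_dir: results
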
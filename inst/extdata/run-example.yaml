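# Example run configuration for the ionseg command line:
#   Rscript inst/cli/ionseg.R generate --config run-example.yaml
#   Rscript inst/cli/ionseg.R train    --config run-example.yaml
#   Rscript inst/cli/ionseg.R evaluate --config run-example.yaml
seed: 1
data:
  dir: dataset
  n: 10
  synthetic:
    n_seeds: 10
    loop_fraction: 0.3
    tubule_width: 3
    psf_sigma: 1.2
    peak_snr: 8
    background_level: 20
    min_separation: 9
    clearance: 5
    margin: 5
preprocess: er_default
model:
  base_channels: 8
  depth: 4
  input_size: [64, 64]
  mre: true
training:
  steps: 100
  lr: 0.001
  base: soft_iou
  checkpoint: checkpoint.json
  log: train_log.csv
  val_fraction: 0.2
evaluation:
  threshold: 0.5
  betti_mode: organelle
  out_csv: metrics.csv
  out_json: metrics.json
analysis:
  min_area: 30
  out_csv: network_properties.csv
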
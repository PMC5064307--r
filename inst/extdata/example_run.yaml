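# Example run configuration for the ddplexr CLI.
#
#   Rscript inst/cli/ddplexr.R simulate --config example_run.yaml --output sim/
#   Rscript inst/cli/ddplexr.R quantify --config example_run.yaml --output out/
#
# (for `quantify`, point input.amplitude_files at the simulated CSVs first)

assay:
  name: MTQ1
  targets:
    - {name: hmgA, channel: 1, level: low}
    - {name: MON810, channel: 1, level: high}
    - {name: MON863, channel: 2, level: low}
    - {name: DP98140, channel: 2, level: high}

quantification:
  droplet_volume_nL: 0.85
  reaction_volume_uL: 20
  ci_level: 0.95
  detection_min_droplets: 3
  ci_method: wilson

simulation:
  n_droplets: 15000
  copies_per_reaction: {hmgA: 500, MON810: 500, MON863: 500, DP98140: 500}
  rain_fraction: 0.0
  replicates: 3

output:
  dir: .

seed: 1
verbose: true
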
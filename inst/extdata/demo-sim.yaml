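# Demo simulation: six transcripts, three planted sites, one per synthase.
# Run with: Rscript inst/cli/psistop.R run --config inst/extdata/demo-sim.yaml --outdir demo-out
n_transcripts: 6
transcript_length: 1000
depth: 50000
seed: 1
expression: [1, 1, 1, 1, 1, 1]
planted_sites:
  - transcript: 1
    offset: 500
    enzyme: rluA
  - transcript: 3
    offset: 500
    enzyme: rluC
  - transcript: 5
    offset: 500
    enzyme: rluD
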
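# Example configuration for run_pipeline() / inst/cli/coelute.R.
# Either give `simulate:` parameters (a synthetic experiment is generated)
# or an `inputs:` block with paths to abundance/design/annotation/gold
# (and optionally context) TSV tables.
seed: 1
out_dir: coelute-run
model_kind: ms_string        # or ms_only (five MS features)
target_fdr: 0.20
lambda: 0.01                 # ridge penalty of the logistic fit
cc_eligibility_intensity: 0.01
cc_eligibility_fractions: 3
cc_threshold: 0.85
simulate:
  n_proteins: 200
  n_complexes: 25
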
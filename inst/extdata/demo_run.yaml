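# Demo pipeline configuration: simulate a 1000-publication corpus and run
# the full analysis.  Usage:
#   Rscript inst/cli/lditrends.R run-all --config inst/extdata/demo_run.yaml
simulate:
  n_publications: 1000
technique: MALDI
reference_year: 2023
weighting: paper_chebi_pairs
out_dir: lditrends_demo_out
seed: 17
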
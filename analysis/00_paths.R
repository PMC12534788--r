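# Shared locations for the analysis drivers. Run the scripts from the
# repository root in numeric order; 01_simulate.R creates the inputs.
input_dir <- "results/synthetic_inputs"
inputs <- list(
  obo = file.path(input_dir, "ontology.obo"),
  upper_map = file.path(input_dir, "upper_map.tsv"),
  annotations = file.path(input_dir, "annotations.tsv"),
  genes = file.path(input_dir, "genes.bed"),
  manifest = file.path(input_dir, "manifest.tsv"),
  sumstats = file.path(input_dir, "sumstats"),
  ihs = file.path(input_dir, "ihs.tsv"),
  drc = file.path(input_dir, "drc150.tsv"),
  features = file.path(input_dir, "features.tsv"),
  expression = file.path(input_dir, "expression.tsv"),
  gmt = file.path(input_dir, "sets.gmt"),
  orthologs = file.path(input_dir, "orthologs.tsv"),
  truth = file.path(input_dir, "truth.tsv")
)
seed <- 1L
dir.create("results", showWarnings = FALSE)
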
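# Shared settings for the analysis scripts. Each numbered script can be run
# from the repository root as, e.g.:
#
#   Rscript analysis/01_simulate.R [seed]
#
# and writes its tables under results/study/. The configuration mirrors the
# budding-yeast mitochondrial study conditions at desk scale (see the
# methods vignette for the rationale behind each value).

library(xrfrag)

study_seed <- {
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 1) as.integer(a[[1]]) else 1L
}

study_dir <- file.path("results", "study")
dir.create(study_dir, showWarnings = FALSE, recursive = TRUE)

study_config <- default_config(outdir = study_dir, seed = study_seed)

fragments_path <- file.path(study_dir, "fragments.tsv")
weights_path <- file.path(study_dir, "weights.tsv")

load_study_genomes <- function() {
  gs <- load_genomes(file.path(study_dir, "genomes.fa"),
                     topology_map = c(mito = "circular", nuc1 = "linear"),
                     compartment_map = c(mito = "mito", nuc1 = "nuclear"))
  gs
}
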
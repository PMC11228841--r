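# Stage 1 — build the synthetic study: an AT-rich circular mitochondrial
# genome, a nuclear chromosome carrying an exact NUMT copy of 10% of the
# mtDNA, a random annotation, and a mixed damage-anchored fragment library
# (5'-trimming model: primary 26-nt fragments, TT dimer at positions 7-8,
# trimmed in 2-nt steps down to 20 nt).

source("analysis/00_settings.R")

sim <- run_simulate(study_config)

mito <- sim$genomes$mito
cat(sprintf("mitochondrial genome: %d bp circular, AT fraction %.3f\n",
            mito$length,
            mean(strsplit(mito$seq, "")[[1]] %in% c("A", "T"))))
cat(sprintf("TT null frequency (forward-strand windows): %.4f\n",
            dinucleotide_frequency(mito, "TT")))
cat(sprintf("nuclear genome: %d bp with NUMT at [%d, %d]\n",
            sim$genomes$nuclear$length,
            sim$genomes$nuclear$insertions$start,
            sim$genomes$nuclear$insertions$end))
cat(sprintf("library: %d reads (%d mito + %d nuclear), adapter %s\n",
            nrow(sim$reads), study_config$library$n_reads_mito,
            study_config$library$n_reads_nuclear,
            study_config$library$adapter))

write_dinuc_stats(dinuc_stats(mito, sim$features, dinucs = c("TT", "TC", "CT", "CC")),
                  file.path(study_dir, "dinuc_stats.tsv"))
cat("fixture bundle written to", study_dir, "\n")
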
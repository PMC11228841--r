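# Stage 2 — adapter trimming, exhaustive exact alignment, and the
# uniqueness/mismatch filter; reports how much of the mitochondrial genome
# the filtering leaves mappable (NUMT-shadowed regions drop out).

source("analysis/00_settings.R")

genomes <- load_study_genomes()
reads <- read_fastq(file.path(study_dir, "reads.fastq"))
features <- read_features(file.path(study_dir, "features.gff3"))

tr <- trim_adapter(reads, study_config$library$adapter)
cat(sprintf("trimming: %d/%d reads retained (%d untrimmed discarded)\n",
            tr$stats$n_trimmed, tr$stats$n_input,
            tr$stats$n_discarded_untrimmed))

aln <- align_exact(tr$reads, genomes)
fl <- filter_fragments(aln, study_config$filter$mapq_min,
                       study_config$filter$max_mismatches)
cat(sprintf("alignment: %d mapped, %d unique; filter removed %d multimapping, %d mismatched\n",
            sum(aln$uniqueness != "unmapped"), fl$report$n_kept,
            fl$report$multimapping, fl$report$mismatch))

mapp <- compute_mappability(aln, fl$kept, genomes$mito, features)
print(mapp, row.names = FALSE)
write.table(mapp, file.path(study_dir, "mappability.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

w <- fragment_weights(fl$kept, genomes)
write.table(fl$kept, fragments_path, sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(read_id = fl$kept$read_id, weight = w), weights_path,
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bed(fl$kept, file.path(study_dir, "fragments.bed"), w)
cat("filtered fragments written to", fragments_path, "\n")
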
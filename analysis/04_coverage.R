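# Stage 4 — RPKM by genome and region category, the organellar/nuclear
# coverage ratio, and template-vs-coding strand coverage normalised by
# di-pyrimidine availability.

source("analysis/00_settings.R")

genomes <- load_study_genomes()
features <- read_features(file.path(study_dir, "features.gff3"))
frags <- read.delim(fragments_path, stringsAsFactors = FALSE)
w <- read.delim(weights_path)$weight

tbl <- coverage_table(frags, genomes,
                      feature_sets = setNames(list(features), "mito"),
                      weights = w)
print(tbl)
write_coverage(tbl, file.path(study_dir, "coverage.tsv"))

strand <- strand_normalized_coverage(frags, features, genomes$mito,
                                     dipyr_set = study_config$coverage$dipyr_set,
                                     weights = w)
cat("template/coding strand coverage (di-pyrimidine normalised):\n")
print(as.data.frame(strand), row.names = FALSE)
write_coverage(strand, file.path(study_dir, "strand_report.tsv"))

cat(sprintf("org/nuc RPKM ratio: %.2f\n", coverage_ratio(tbl, "mito", "nuc1")))
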
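#' Default run configuration
#'
#' A single serialisable list drives the whole workflow: fixture geometry for
#' the simulator, adapter and filter thresholds for read processing, profile
#' and coverage settings, and one master seed from which every stochastic
#' stage derives its substream. The defaults emulate the budding-yeast
#' mitochondrial study conditions at desk scale: an AT-rich circular
#' mitochondrial genome, a larger linear nuclear chromosome carrying an
#' exact NUMT copy of part of the mtDNA, and a 5'-trimming damage model with
#' a 26-nt primary fragment whose TT dimer sits at read positions 7-8.
#'
#' @param outdir Output directory for all stage products.
#' @param seed Master seed (integer).
#' @return Nested configuration list.
#' @export
default_config <- function(outdir = "xrfrag_run", seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    genomes = list(
      mito = list(id = "mito", length = 20000L, at_fraction = 0.83,
                  topology = "circular"),
      nuclear = list(id = "nuc1", length = 60000L, at_fraction = 0.64,
                     topology = "linear"),
      numt = list(donor_start = 1001L, donor_end = 3000L,
                  insertion_site = 30001L, divergence_rate = 0)
    ),
    annotation = list(n_features = 24L, mean_length = 500L),
    damage_model = list(mechanism = "five_prime_trim", primary_length = 26L,
                        trim_step = 2L, trim_max_steps = 3L,
                        dimer_offset_3p = 19L),
    library = list(n_reads_mito = 8000L, n_reads_nuclear = 8000L,
                   adapter = "AGATCGGAAGAGCACACGTCT", read_length = 50L),
    filter = list(mapq_min = 30L, max_mismatches = 0L),
    profile = list(anchor = "three_prime", min_reads = 100L,
                   null_from = "genome", null_value = NA_real_,
                   dinucs = "TT"),
    coverage = list(dipyr_set = "TT")
  )
}

validate_config <- function(config, need_annotation = FALSE) {
  req <- c("outdir", "seed", "genomes", "damage_model", "library",
           "filter", "profile", "coverage")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  if (need_annotation && is.null(config$annotation)) {
    stop("config missing field(s): annotation")
  }
  invisible(TRUE)
}

# deterministic substreams from the master seed; offsets keep streams of
# different stages independent
sub_seed <- function(config, k) (config$seed * 101L + k * 7919L) %% .Machine$integer.max

#' Read/write a configuration file (YAML)
#' @param path YAML path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Simulate the fixture bundle
#'
#' Builds the genomes (with the configured NUMT planted into the nuclear
#' chromosome), a random annotation of the mitochondrial genome, and a mixed
#' fragment library from both compartments; writes FASTA, GFF3, FASTQ, the
#' truth TSV and a JSON copy of the config into `config$outdir`.
#'
#' @param config A [default_config()]-shaped list.
#' @return Invisibly, a list with `genomes`, `features`, `reads`, `truth`
#'   and the file `paths`.
#' @export
run_simulate <- function(config) {
  validate_config(config, need_annotation = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- config$genomes$mito
  gn <- config$genomes$nuclear
  mito <- make_random_genome(gm$length, gm$at_fraction, gm$topology,
                             seed = sub_seed(config, 1L), id = gm$id,
                             compartment = "mito")
  nuc <- make_random_genome(gn$length, gn$at_fraction, gn$topology,
                            seed = sub_seed(config, 2L), id = gn$id,
                            compartment = "nuclear")
  numt <- config$genomes$numt
  if (!is.null(numt)) {
    nuc <- plant_duplication(nuc, mito,
                             c(numt$donor_start, numt$donor_end),
                             numt$insertion_site, numt$divergence_rate,
                             seed = sub_seed(config, 3L))
  }
  features <- random_feature_set(mito, config$annotation$n_features,
                                 config$annotation$mean_length,
                                 seed = sub_seed(config, 4L))
  dm <- do.call(damage_model, config$damage_model)
  lib_m <- simulate_fragments(mito, dm, config$library$n_reads_mito,
                              seed = sub_seed(config, 5L),
                              adapter = config$library$adapter,
                              read_length = config$library$read_length,
                              id_prefix = "mt")
  lib_n <- simulate_fragments(nuc, dm, config$library$n_reads_nuclear,
                              seed = sub_seed(config, 6L),
                              adapter = config$library$adapter,
                              read_length = config$library$read_length,
                              id_prefix = "nc")
  reads <- rbind(lib_m$reads, lib_n$reads)
  truth <- rbind(lib_m$truth, lib_n$truth)

  paths <- list(
    fasta = file.path(config$outdir, "genomes.fa"),
    gff = file.path(config$outdir, "features.gff3"),
    fastq = file.path(config$outdir, "reads.fastq"),
    truth = file.path(config$outdir, "truth.tsv"),
    config = file.path(config$outdir, "config.json"))
  write_genomes(list(mito, nuc), paths$fasta)
  write_gff(features, paths$gff)
  write_fastq(reads, paths$fastq)
  write_truth(truth, paths$truth)
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(list(genomes = list(mito = mito, nuclear = nuc),
                 features = features, reads = reads, truth = truth,
                 paths = paths))
}

#' Run the analysis pipeline over a fixture bundle
#'
#' Trims adapters, aligns, filters, and computes the mappability report,
#' length spectra, positional di-pyrimidine profiles with enrichment calls,
#' the coverage table, and the strand report; every table is written to
#' `config$outdir` and a manifest records the read counts surviving each
#' stage.
#'
#' @param config A [default_config()]-shaped list.
#' @param sim Optional result of [run_simulate()] (re-run when omitted).
#' @return Invisibly, a list of all stage results plus the `manifest`.
#' @export
run_pipeline <- function(config, sim = NULL) {
  validate_config(config, need_annotation = TRUE)
  if (is.null(sim)) sim <- run_simulate(config)
  genomes <- unname(sim$genomes)
  od <- config$outdir

  tr <- trim_adapter(sim$reads, config$library$adapter)
  aln <- align_exact(tr$reads, genomes)
  fl <- filter_fragments(aln, config$filter$mapq_min,
                         config$filter$max_mismatches)
  frags <- fl$kept
  w <- fragment_weights(frags, genomes)

  mito <- sim$genomes$mito
  mapp <- compute_mappability(aln, frags, mito, sim$features)
  utils::write.table(mapp, file.path(od, "mappability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  spectra <- length_spectrum(frags, compartment_map(genomes), w)
  write_spectra(spectra, file.path(od, "spectra.tsv"))

  null_p0 <- if (identical(config$profile$null_from, "value"))
    config$profile$null_value else dinucleotide_frequency(mito, "TT")
  seqs <- fragment_sequences(frags, genomes)
  on_mito <- !is.na(frags$chrom) & frags$chrom == mito$id
  lens <- sort(unique(frags$length[on_mito]), decreasing = TRUE)
  L_max <- if (length(lens)) max(lens) else 0L
  profiles <- list()
  enrich <- list()
  for (L in lens) {
    sel <- on_mito & frags$length == L
    if (sum(sel) == 0L) next
    pr <- positional_dinuc_profile(frags[sel, , drop = FALSE], seqs[sel], L,
                                   anchor = config$profile$anchor,
                                   null_p0 = null_p0, weights = w[sel],
                                   L_max = L_max,
                                   min_reads = config$profile$min_reads)
    profiles[[as.character(L)]] <- pr
    enrich[[as.character(L)]] <- call_enrichment(pr, config$profile$dinucs)
  }
  write_profiles(profiles, file.path(od, "profiles.tsv"))
  utils::write.table(do.call(rbind, enrich), file.path(od, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cov <- coverage_table(frags, genomes,
                        feature_sets = stats::setNames(list(sim$features),
                                                       mito$id),
                        weights = w)
  write_coverage(cov, file.path(od, "coverage.tsv"))
  strand <- strand_normalized_coverage(frags, sim$features, mito,
                                       dipyr_set = config$coverage$dipyr_set,
                                       weights = w)
  write_coverage(strand, file.path(od, "strand_report.tsv"))
  write_bed(frags, file.path(od, "fragments.bed"), w)

  manifest <- list(
    seed = config$seed,
    n_reads_input = nrow(sim$reads),
    n_reads_trimmed = tr$stats$n_trimmed,
    n_discarded_untrimmed = tr$stats$n_discarded_untrimmed,
    n_aligned = sum(aln$uniqueness != "unmapped"),
    n_unique = sum(aln$uniqueness == "unique"),
    n_filtered = fl$report$n_kept,
    removed = fl$report[c("unmapped", "multimapping", "mismatch")],
    tt_null_p0 = null_p0,
    length_classes_profiled = as.integer(names(profiles)))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, trim = tr, aligned = aln, filtered = fl,
                 weights = w, mappability = mapp, spectra = spectra,
                 profiles = profiles, enrichment = enrich, coverage = cov,
                 strand = strand, manifest = manifest))
}

#' Summarise a completed run directory
#'
#' Collects the stage tables written by [run_pipeline()] into one plain-text
#' summary (markdown) and returns the parsed tables.
#'
#' @param outdir Run directory.
#' @return Invisibly, a list of the parsed tables; writes
#'   `<outdir>/report.md`.
#' @export
run_report <- function(outdir) {
  need <- c("manifest.json", "mappability.tsv", "spectra.tsv",
            "profiles.tsv", "enrichment.tsv", "coverage.tsv")
  miss <- need[!file.exists(file.path(outdir, need))]
  if (length(miss)) stop("missing stage output(s): ", paste(miss, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  tsv <- function(f) utils::read.delim(file.path(outdir, f),
                                       stringsAsFactors = FALSE)
  mapp <- tsv("mappability.tsv"); spectra <- tsv("spectra.tsv")
  profiles <- tsv("profiles.tsv"); enrich <- tsv("enrichment.tsv")
  cov <- tsv("coverage.tsv")
  lines <- c(
    "# xrfrag run report", "",
    sprintf("Reads: %d in, %d trimmed, %d aligned, %d kept after filtering.",
            manifest$n_reads_input, manifest$n_reads_trimmed,
            manifest$n_aligned, manifest$n_filtered),
    sprintf("TT null (genome-wide forward-strand frequency): %.4f.",
            manifest$tt_null_p0), "",
    "## Mappability (fraction of covered positions retained)", "",
    utils::capture.output(print(mapp, row.names = FALSE)), "",
    "## Length spectrum peaks", "",
    utils::capture.output(print(
      do.call(rbind, lapply(split(spectra, spectra$compartment), function(d)
        d[order(-d$freq), ][seq_len(min(5, nrow(d))), ])), row.names = FALSE)),
    "", "## Significant TT enrichment calls", "",
    utils::capture.output(print(enrich[enrich$significant, ],
                                row.names = FALSE)), "",
    "## Coverage (RPKM)", "",
    utils::capture.output(print(cov, row.names = FALSE)))
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(list(manifest = manifest, mappability = mapp, spectra = spectra,
                 profiles = profiles, enrichment = enrich, coverage = cov))
}
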
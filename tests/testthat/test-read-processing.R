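test_that("trim_adapter recovers fragments exactly and discards untrimmed reads", {
  adapter <- "AGATCGGAAGAGC"
  reads <- data.frame(
    id = c("full", "none", "suffix5", "suffix2", "empty"),
    seq = c(paste0("ACGTACGTAC", adapter),       # full adapter
            "ACGTACGTACGTACGTACGT",              # no adapter anywhere
            paste0("TTTTGGGG", substr(adapter, 1, 5)),  # 5-nt adapter prefix
            paste0("TTTTGGGG", substr(adapter, 1, 2)),  # below min_overlap
            adapter),                            # adapter at position 1
    stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))
  out <- trim_adapter(reads, adapter, min_overlap = 3)
  expect_equal(out$reads$id, c("full", "suffix5"))
  expect_equal(out$reads$seq, c("ACGTACGTAC", "TTTTGGGG"))
  expect_equal(out$reads$qual, c("IIIIIIIIII", "IIIIIIII"))
  expect_equal(out$stats$n_discarded_untrimmed, 2L)
  expect_equal(out$stats$n_discarded_empty, 1L)
})

test_that("trim_adapter honours the error-rate allowance per aligned length", {
  adapter <- "AGATCGGAAG"
  base <- "CCCCCCCCCC"
  mut <- paste0(base, "AGTTAGGAAG")  # 2 mismatches in 10 aligned bases
  reads <- data.frame(id = c("a", "b"), seq = c(mut, mut),
                      stringsAsFactors = FALSE)
  strict <- trim_adapter(reads, adapter, max_error_rate = 0.1)
  lax <- trim_adapter(reads, adapter, max_error_rate = 0.2)
  expect_equal(nrow(strict$reads), 0L)
  expect_equal(lax$reads$seq, c(base, base))
})

test_that("adapter trimming inverts the simulator exactly at zero error rate", {
  fx <- make_study_fixture(seed = 50)
  dm <- damage_model("five_prime_trim", trim_max_steps = 3)
  lib <- simulate_fragments(fx$mito, dm, 1000, seed = 13)
  out <- trim_adapter(lib$reads, "AGATCGGAAGAGCACACGTCT")
  expect_equal(out$stats$n_trimmed, 1000L)
  expect_equal(nchar(out$reads$seq), lib$truth$length)
})

test_that("align_exact classifies unique, duplicated and absent reads", {
  fx <- make_study_fixture(seed = 51, numt = c(1001, 2000))
  genomes <- list(fx$mito, fx$nuc)
  reads <- data.frame(
    id = c("uniq", "numt", "absent"),
    seq = c(substr(fx$mito$seq, 4001, 4026),   # single-copy region
            substr(fx$mito$seq, 1101, 1126),   # inside the planted NUMT
            strrep("ACGGTT", 5)),
    stringsAsFactors = FALSE)
  aln <- align_exact(reads, genomes)
  expect_equal(aln$uniqueness, c("unique", "multi", "unmapped"))
  expect_equal(aln$chrom[1], "mito")
  expect_equal(aln$start[1], 4001L)
  expect_equal(aln$strand[1], "+")
  expect_equal(aln$n_placements[2], 2L)
})

test_that("align_exact agrees with a naive sliding-window scan on random genomes", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(500:5000, 1)
    topo <- sample(c("linear", "circular"), 1)
    g <- genome("g", random_seq(n), topo, "mito")
    # reads drawn from the genome (both strands) plus one random decoy
    reads <- data.frame(id = character(0), seq = character(0))
    for (j in 1:8) {
      L <- sample(15:30, 1)
      s <- sample(n - L + 1L, 1)
      sq <- substr(g$seq, s, s + L - 1L)
      if (j %% 2 == 0) sq <- rc_oracle(sq)
      reads <- rbind(reads, data.frame(id = paste0("r", j), seq = sq))
    }
    reads <- rbind(reads, data.frame(id = "decoy", seq = random_seq(25)))
    aln <- align_exact(reads, list(g))
    for (j in seq_len(nrow(reads))) {
      oracle <- naive_placements(reads$seq[j], list(g))
      expect_equal(aln$n_placements[j], nrow(oracle))
      if (nrow(oracle) == 1L) {
        expect_equal(aln$start[j], oracle$start)
        expect_equal(aln$strand[j], oracle$strand)
      }
    }
  }
})

test_that("origin-spanning reads align once with correct wrapped coordinates", {
  g <- make_random_genome(500, 0.5, "circular", seed = 14, id = "circ")
  wrap_read <- paste0(substr(g$seq, 491, 500), substr(g$seq, 1, 10))
  aln <- align_exact(data.frame(id = "w", seq = wrap_read), list(g))
  expect_equal(aln$uniqueness, "unique")
  expect_equal(aln$start, 491L)
  expect_equal(aln$end, 510L)  # unwrapped; 510 > 500 flags the wrap
})

test_that("import_sam maps MAPQ and NM onto uniqueness and mismatch fields", {
  g <- genome("chrM", strrep("ACGTTGCA", 50), "circular", "mito")
  sam <- tempfile(fileext = ".sam")
  r1 <- substr(g$seq, 11, 36)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:chrM\tLN:", g$length),
    paste("good", 0, "chrM", 11, 42, "26M", "*", 0, 0, r1,
          strrep("I", 26), "NM:i:0", sep = "\t"),
    paste("lowq", 0, "chrM", 11, 3, "26M", "*", 0, 0, r1,
          strrep("I", 26), "NM:i:0", sep = "\t"),
    paste("mm2", 0, "chrM", 11, 42, "26M", "*", 0, 0, r1,
          strrep("I", 26), "NM:i:2", sep = "\t"),
    paste("noNM", 16, "chrM", 11, 42, "26M", "*", 0, 0, r1,
          strrep("I", 26), sep = "\t")), sam)
  frags <- import_sam(sam, list(g))
  expect_equal(frags$uniqueness, c("unique", "multi", "unique", "unique"))
  expect_equal(frags$mismatches, c(0L, 0L, 2L, 0L))  # noNM recomputed vs ref
  expect_equal(frags$strand, c("+", "+", "+", "-"))
  expect_equal(frags$end[1], 36L)

  bad <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chrX\tLN:1000",
               paste("r", 0, "chrX", 1, 42, "4M", "*", 0, 0, "ACGT",
                     "IIII", "NM:i:0", sep = "\t")), bad)
  expect_error(import_sam(bad, list(g)), "chrX")
})

test_that("filter_fragments removes by cause, idempotently", {
  frags <- data.frame(
    read_id = c("a", "b", "c", "d"),
    chrom = c("m", "m", "m", NA), start = c(1L, 1L, 1L, NA),
    end = c(26L, 26L, 26L, NA), strand = c("+", "+", "-", NA),
    length = 26L,
    uniqueness = c("unique", "multi", "unique", "unmapped"),
    mismatches = c(0L, 0L, 1L, 0L), mapq = NA_integer_,
    n_placements = c(1L, 2L, 1L, 0L), stringsAsFactors = FALSE)
  fl <- filter_fragments(frags)
  expect_equal(fl$kept$read_id, "a")
  expect_equal(fl$report$multimapping, 1L)
  expect_equal(fl$report$mismatch, 1L)
  expect_equal(fl$report$unmapped, 1L)
  # idempotent
  fl2 <- filter_fragments(fl$kept)
  expect_equal(fl2$kept, fl$kept)
})

test_that("fragments in a halved interval carry weight 0.5, wrap included", {
  g <- genome("g", strrep("ACGT", 100), "circular", "plastid")
  ged <- apply_reference_edits(g, list(
    reference_edit("halve_count_interval", 1, 40)))
  frags <- data.frame(
    read_id = c("in", "out", "wrap"),
    chrom = "g", start = c(10L, 200L, 390L), end = c(35L, 225L, 415L),
    strand = "+", length = 26L, uniqueness = "unique", mismatches = 0L,
    mapq = NA_integer_, n_placements = 1L, stringsAsFactors = FALSE)
  w <- fragment_weights(frags, list(ged))
  expect_equal(w, c(0.5, 1, 0.5))
})

test_that("mappability reflects only multimapping-induced coverage loss", {
  fx <- make_study_fixture(seed = 52)
  reads <- tile_reads(fx$mito, L = 26L)
  aln <- align_exact(reads, list(fx$mito, fx$nuc))
  fl <- filter_fragments(aln)
  rep <- compute_mappability(aln, fl$kept, fx$mito)
  # nothing duplicated: every covered position survives filtering
  expect_equal(rep$fraction_retained[rep$category == "total"], 1.0)
  # category with no unfiltered coverage -> NA
  fs <- feature_set(data.frame(chrom = "other", start = 1, end = 10,
                               strand = "+", category = "tRNA"))
  rep2 <- compute_mappability(aln[0, ], fl$kept[0, ], fx$mito, fs)
  expect_true(all(is.na(rep2$fraction_retained)))
})

test_that("BED export encodes weights in the score column", {
  frags <- data.frame(read_id = c("a", "b"), chrom = "m",
                      start = c(5L, 10L), end = c(30L, 35L), strand = c("+", "-"),
                      length = 26L, uniqueness = "unique", mismatches = 0L,
                      mapq = NA_integer_, n_placements = 1L,
                      stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".bed")
  write_bed(frags, p, weights = c(1, 0.5))
  lines <- readLines(p)
  expect_equal(lines[1], "m\t4\t30\ta\t1000\t+")
  expect_equal(lines[2], "m\t9\t35\tb\t500\t-")
})
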
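frag_row <- function(id, chrom, start, len, strand = "+") {
  data.frame(read_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(start + len - 1L), strand = strand,
             length = as.integer(len), uniqueness = "unique",
             mismatches = 0L, mapq = NA_integer_, n_placements = 1L,
             stringsAsFactors = FALSE)
}

test_that("rpkm follows its definition and scaling law", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(10, 1000, 2e6), 5)     # doubling the library halves RPKM
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_error(rpkm(10, 0, 1e6), "target_length")
})

test_that("region assignment is by midpoint with priority tie-breaks", {
  g <- genome("g", strrep("A", 200), "linear", "mito")
  fs <- feature_set(data.frame(
    chrom = "g", start = c(50, 100, 95), end = c(80, 130, 105),
    strand = "+", category = c("CDS", "CDS", "tRNA")))
  inside <- frag_row("a", "g", 55, 20)          # wholly inside CDS
  expect_equal(assign_region(inside, g, fs), "CDS")
  # straddles the CDS start; midpoint at 52 falls inside
  straddle <- frag_row("b", "g", 43, 20)
  expect_equal(assign_region(straddle, g, fs), "CDS")
  # midpoint in tRNA/CDS overlap -> tRNA wins
  overlap <- frag_row("c", "g", 91, 20)         # midpoint 100
  expect_equal(assign_region(overlap, g, fs), "tRNA")
  # unannotated chromosome -> intergenic
  expect_equal(assign_region(inside, genome("x", strrep("A", 200),
                                            "linear", "mito"), NULL),
               "intergenic")
})

test_that("midpoint assignment partitions reads: per-category sums equal per-genome totals", {
  fx <- make_study_fixture(seed = 70)
  fs <- random_feature_set(fx$mito, n_features = 12, seed = 19)
  dm <- damage_model("five_prime_trim", trim_max_steps = 3)
  lib <- simulate_fragments(fx$mito, dm, 2000, seed = 20, adapter = "AGATCG",
                            read_length = NA)
  frags <- do.call(rbind, lapply(seq_len(nrow(lib$truth)), function(i)
    frag_row(lib$truth$read_id[i], "mito", lib$truth$start[i],
             lib$truth$length[i], lib$truth$strand[i])))
  tbl <- coverage_table(frags, list(fx$mito, fx$nuc),
                        feature_sets = list(mito = fs))
  per_cat <- sum(tbl$regions$weighted_reads[tbl$regions$genome == "mito"])
  expect_equal(per_cat, tbl$genomes$weighted_reads[tbl$genomes$id == "mito"])
  expect_equal(sum(tbl$regions$length[tbl$regions$genome == "mito"]),
               fx$mito$length)
})

test_that("coverage ratios recover a planted organellar read excess", {
  fx <- make_study_fixture(seed = 71)
  set.seed(21)
  # 10:1 organellar excess, uniform placements, equal read lengths
  n_org <- 5000; n_nuc <- 500
  org <- frag_row(sprintf("o%d", 1:n_org), "mito",
                  sample(fx$mito$length - 30L, n_org, replace = TRUE), 26)
  nuc <- frag_row(sprintf("n%d", 1:n_nuc), "nuc1",
                  sample(fx$nuc$length - 30L, n_nuc, replace = TRUE), 26)
  tbl <- coverage_table(rbind(org, nuc), list(fx$mito, fx$nuc))
  # RPKM ratio = (5000/6000) / (500/15000) = 25; read-excess alone is 10
  expect_equal(unname(tbl$org_nuc_ratio["mito"]),
               (n_org / fx$mito$length) / (n_nuc / fx$nuc$length),
               tolerance = 1e-9)
  expect_equal(coverage_ratio(tbl, "mito", "nuc1"),
               unname(tbl$org_nuc_ratio["mito"]))
  expect_equal(rpkm(20, 1000, 1e6) / rpkm(10, 1000, 1e6), 2.0)
})

test_that("uniform libraries give near-equal per-category RPKM", {
  fx <- make_study_fixture(seed = 72)
  fs <- random_feature_set(fx$mito, n_features = 10, seed = 22)
  set.seed(23)
  n <- 20000
  frags <- frag_row(sprintf("u%d", 1:n), "mito",
                    sample(fx$mito$length, n, replace = TRUE), 26)
  tbl <- coverage_table(frags, list(fx$mito), feature_sets = list(mito = fs))
  reg <- tbl$regions[tbl$regions$genome == "mito" & tbl$regions$length > 300, ]
  # Poisson tolerance: relative sd ~ 1/sqrt(expected reads per category)
  expected <- n * reg$length / fx$mito$length
  expect_true(all(abs(reg$weighted_reads - expected) / expected <
                    4 / sqrt(expected)))
})

test_that("template-strand assignment and normalised ratios behave as defined", {
  g <- genome("g", strrep("TTA", 100), "linear", "mito")  # TT-rich both strands
  fs <- feature_set(data.frame(chrom = "g", start = c(1, 151), end = c(150, 300),
                               strand = c("+", "-"),
                               category = c("CDS", "CDS")))
  # feature on + with fragment mapped to - => template
  tmpl <- frag_row("t", "g", 10, 26, "-")
  cod <- frag_row("c", "g", 10, 26, "+")
  rep1 <- strand_normalized_coverage(rbind(tmpl, cod), fs, g)
  cds <- rep1[rep1$category == "CDS", ]
  expect_equal(cds$template_count, 1)
  expect_equal(cds$coding_count, 1)

  # damage planted only on template strands -> ratio >> 1
  set.seed(24)
  frs <- lapply(1:60, function(i) {
    on_plus_feature <- i %% 2 == 0
    if (on_plus_feature) frag_row(paste0("p", i), "g", sample(1:120, 1), 26, "-")
    else frag_row(paste0("m", i), "g", sample(151:270, 1), 26, "+")
  })
  rep2 <- strand_normalized_coverage(do.call(rbind, frs), fs, g)
  expect_gt(rep2$normalized_ratio[rep2$category == "CDS"], 5)

  # symmetric planting on a TT-symmetric region -> ratio ~ 1
  gsym <- genome("s", strrep(paste0(strrep("TTAA", 25), strrep("AATT", 25)), 4),
                 "linear", "mito")
  fsym <- feature_set(data.frame(chrom = "s", start = 1, end = 800,
                                 strand = "+", category = "CDS"))
  set.seed(25)
  sym <- do.call(rbind, lapply(1:200, function(i)
    frag_row(paste0("s", i), "s", sample(1:770, 1), 26,
             if (i %% 2 == 0) "+" else "-")))
  rep3 <- strand_normalized_coverage(sym, fsym, gsym)
  expect_equal(rep3$normalized_ratio[rep3$category == "CDS"], 1,
               tolerance = 0.25)
})

test_that("strand report is invariant under genome complementation", {
  fx <- make_study_fixture(seed = 73, mito_len = 3000)
  fs <- random_feature_set(fx$mito, n_features = 8, seed = 26)
  dm <- damage_model("fixed_incision")
  lib <- simulate_fragments(fx$mito, dm, 800, seed = 27)
  frags <- do.call(rbind, lapply(seq_len(nrow(lib$truth)), function(i)
    frag_row(lib$truth$read_id[i], "mito", lib$truth$start[i],
             lib$truth$length[i], lib$truth$strand[i])))
  rep_f <- strand_normalized_coverage(frags, fs, fx$mito)

  # complement the world: reverse-complement genome, flip features, fragments
  L <- fx$mito$length
  grc <- genome("mito", rc_oracle(fx$mito$seq), "circular", "mito")
  f <- fs$features
  frc <- feature_set(data.frame(chrom = f$chrom,
                                start = L - f$end + 1L, end = L - f$start + 1L,
                                strand = ifelse(f$strand == "+", "-", "+"),
                                category = f$category))
  wrap <- frags$end > L
  fr <- frags[!wrap, ]  # mirrored wrap arithmetic differs; exclude wraps
  fr2 <- fr
  fr2$start <- L - fr$end + 1L
  fr2$end <- L - fr$start + 1L
  fr2$strand <- ifelse(fr$strand == "+", "-", "+")
  rep_r <- strand_normalized_coverage(fr2, frc, grc)
  rep_f2 <- strand_normalized_coverage(fr, fs, fx$mito)
  expect_equal(rep_r$template_dipyr, rep_f2$template_dipyr, tolerance = 0.02)
  expect_equal(rep_r$normalized_ratio, rep_f2$normalized_ratio,
               tolerance = 0.05)
})

test_that("halving the retained repeat copy restores single-copy coverage", {
  # plastid-like genome: region A + IR + region B + inverted second copy
  set.seed(28)
  a <- random_seq(2000); ir <- random_seq(1500); b <- random_seq(2000)
  full <- genome("pt", paste0(a, ir, b, rc_oracle(ir)), "circular", "plastid")
  edited <- apply_reference_edits(full, list(
    reference_edit("remove_interval", 5501, 7000, "second IR copy"),
    reference_edit("halve_count_interval", 2001, 3500, "first IR copy")))
  expect_equal(edited$length, 5500L)

  # saturating tiling reads from the ORIGINAL two-copy genome
  reads <- tile_reads(full, L = 26L)
  aln <- align_exact(reads, list(edited))
  fl <- filter_fragments(aln)
  w <- fragment_weights(fl$kept, list(edited))
  depth <- weighted_depth(fl$kept, edited, w)
  # interior positions away from copy boundaries: IR depth == single-copy depth
  single <- mean(depth[100:1900])
  ir_depth <- mean(depth[2100:3400])
  expect_equal(single, 26, tolerance = 0.01)
  expect_equal(ir_depth / single, 1, tolerance = 0.02)
})
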
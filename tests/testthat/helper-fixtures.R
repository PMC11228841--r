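# Independent oracles and fixture builders shared across the suite.
# Oracles are written as direct transcriptions of the definitions (window
# enumeration, sliding-window scans) and deliberately share no code with the
# implementation paths they check.

# brute-force dinucleotide frequency: enumerate every window with substr
brute_dinuc_freq <- function(seq, dinuc, circular = FALSE) {
  L <- nchar(seq)
  windows <- character(0)
  for (i in seq_len(L - 1L)) windows <- c(windows, substr(seq, i, i + 1L))
  if (circular) windows <- c(windows, paste0(substr(seq, L, L), substr(seq, 1, 1)))
  ok <- !grepl("N", windows, fixed = TRUE)
  sum(windows[ok] == dinuc) / sum(ok)
}

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# naive sliding-window aligner: every start, both strands, every genome;
# circular genomes are scanned on the doubled sequence
naive_placements <- function(read, genomes) {
  hits <- list()
  L <- nchar(read)
  for (g in genomes) {
    s2 <- if (g$topology == "circular") paste0(g$seq, g$seq) else g$seq
    wins <- substring(s2, seq_len(g$length), seq_len(g$length) + L - 1L)
    wins <- wins[nchar(wins) == L | g$topology == "circular"]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc_oracle(read)
      st <- which(wins == pat)
      st <- st[st <= g$length]
      if (length(st)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = g$id, start = st, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), strand = character())
}

# weighted per-position read depth (wrap-aware), for coverage invariants
weighted_depth <- function(fragments, g, weights) {
  depth <- numeric(g$length)
  sel <- which(!is.na(fragments$chrom) & fragments$chrom == g$id)
  for (i in sel) {
    pos <- (((fragments$start[i]:fragments$end[i]) - 1L) %% g$length) + 1L
    depth[pos] <- depth[pos] + weights[i]
  }
  depth
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# tiling read set: one read of length L starting at every position (plus
# strand), wrapping for circular genomes — a saturating library
tile_reads <- function(g, L = 26L) {
  starts <- seq_len(if (g$topology == "circular") g$length else g$length - L + 1L)
  data.frame(id = sprintf("tile_%d", starts),
             seq = vapply(starts, function(s) xrfrag:::genome_subseq(g, s, L), ""),
             stringsAsFactors = FALSE)
}

# small yeast-like study fixture used by several files
make_study_fixture <- function(seed = 42L, mito_len = 6000L, nuc_len = 15000L,
                               numt = NULL, divergence = 0) {
  mito <- make_random_genome(mito_len, 0.83, "circular", seed = seed,
                             id = "mito", compartment = "mito")
  nuc <- make_random_genome(nuc_len, 0.64, "linear", seed = seed + 1L,
                            id = "nuc1", compartment = "nuclear")
  if (!is.null(numt)) {
    nuc <- plant_duplication(nuc, mito, numt, nuc_len %/% 2L,
                             divergence_rate = divergence, seed = seed + 2L)
  }
  list(mito = mito, nuc = nuc)
}
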
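#' Construct a Genome object
#'
#' A `Genome` bundles a DNA sequence with the metadata the rest of the
#' pipeline needs: its topology (small organellar genomes are circular, so
#' position arithmetic wraps around the origin), the cellular compartment it
#' belongs to, and any reference edits that have been applied to it (see
#' [apply_reference_edits()]).
#'
#' @param id Accession-like identifier (unique within a genome set).
#' @param seq DNA sequence as a single string over `A`, `C`, `G`, `T`, `N`
#'   (lower case is accepted and uppercased).
#' @param topology `"linear"` or `"circular"`.
#' @param compartment `"nuclear"`, `"mito"` or `"plastid"`.
#' @return An object of class `Genome`: a list with fields `id`, `seq`,
#'   `length`, `topology`, `compartment`, `edits`, `halve_intervals` and
#'   (after editing) `coord_map`.
#' @export
genome <- function(id, seq, topology = c("linear", "circular"),
                   compartment = c("nuclear", "mito", "plastid")) {
  topology <- match.arg(topology)
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("genome '", id, "': empty sequence")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("genome '", id, "': invalid character '",
         substr(seq, bad, bad), "' at position ", bad)
  }
  structure(
    list(id = id, seq = seq, length = nchar(seq),
         topology = topology, compartment = compartment,
         edits = list(), halve_intervals = NULL, coord_map = NULL,
         insertions = NULL),
    class = "Genome"
  )
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome %s: %s %s, %d bp, %d edit(s)\n",
              x$id, x$topology, x$compartment, x$length, length(x$edits)))
  invisible(x)
}

is_genome <- function(x) inherits(x, "Genome")

#' Load reference genomes from FASTA
#'
#' Reads one or more (multi-record) FASTA files and assigns every record a
#' topology and a compartment. Record ids are the first whitespace-delimited
#' token of the header line.
#'
#' @param fasta_paths Character vector of FASTA file paths.
#' @param topology_map Named character vector mapping record id to
#'   `"linear"`/`"circular"`.
#' @param compartment_map Named character vector mapping record id to
#'   `"nuclear"`/`"mito"`/`"plastid"`.
#' @return Named list of [genome()] objects.
#' @export
load_genomes <- function(fasta_paths, topology_map, compartment_map) {
  missing <- fasta_paths[!file.exists(fasta_paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  sets <- lapply(fasta_paths, Biostrings::readDNAStringSet)
  seqs <- do.call(c, sets)
  if (length(seqs) == 0L) stop("no records in FASTA input")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genomes <- vector("list", length(ids))
  names(genomes) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (is.na(topology_map[id]) || is.null(topology_map[id]) ||
        !id %in% names(topology_map)) {
      stop("no topology assigned for sequence '", id, "'")
    }
    if (!id %in% names(compartment_map)) {
      stop("no compartment assigned for sequence '", id, "'")
    }
    genomes[[i]] <- genome(id, as.character(seqs[[i]]),
                           topology = topology_map[[id]],
                           compartment = compartment_map[[id]])
  }
  genomes
}

#' Write genomes to a FASTA file
#'
#' @param genomes List of [genome()] objects.
#' @param path Output path.
#' @export
write_genomes <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Describe a reference edit
#'
#' Two kinds of edits are supported, mirroring how multi-copy sequence is
#' handled before read mapping: `remove_interval` deletes a span from the
#' reference (used for the second copy of the plastid inverted repeat and for
#' a large NUMT, so that reads from the remaining copy map uniquely), and
#' `halve_count_interval` leaves the sequence alone but marks a span whose
#' read counts must be divided by two downstream (the retained inverted
#' repeat copy now soaks up reads from both original copies).
#'
#' @param kind `"remove_interval"` or `"halve_count_interval"`.
#' @param start,end 1-based inclusive interval on the *original* coordinates.
#' @param reason Free-text note recorded with the edit.
#' @export
reference_edit <- function(kind = c("remove_interval", "halve_count_interval"),
                           start, end, reason = "") {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid edit interval [", start, ", ", end, "]")
  }
  structure(list(kind = kind, start = start, end = end, reason = reason),
            class = "ReferenceEdit")
}

#' Apply reference edits to a genome
#'
#' Removal edits delete their spans and record an invertible coordinate map
#' between the original and the edited genome; halving edits are translated
#' onto the edited coordinates and stored for the coverage stage. Edits must
#' not overlap one another and must lie within the original sequence.
#'
#' @param g A [genome()].
#' @param edits List of [reference_edit()] objects (original coordinates).
#' @return The edited `Genome`, with `coord_map`, `halve_intervals` and
#'   `edits` populated. Positions can be translated with [old_to_new()] /
#'   [new_to_old()].
#' @export
apply_reference_edits <- function(g, edits) {
  stopifnot(is_genome(g))
  if (length(g$edits)) stop("genome '", g$id, "' already edited")
  if (!length(edits)) return(g)
  kinds <- vapply(edits, `[[`, "", "kind")
  starts <- vapply(edits, `[[`, 1L, "start")
  ends <- vapply(edits, `[[`, 1L, "end")
  if (any(ends > g$length)) stop("edit interval out of bounds for '", g$id, "'")
  o <- order(starts)
  if (any(starts[o][-1] <= ends[o][-length(o)])) stop("overlapping edits")

  rem <- which(kinds == "remove_interval")
  keep_seq <- g$seq
  # removed bases strictly before each original position, for old->new
  rem_ir <- IRanges::IRanges(starts[rem], ends[rem])
  if (length(rem)) {
    ro <- rem[order(starts[rem], decreasing = TRUE)]
    for (i in ro) {
      keep_seq <- paste0(substr(keep_seq, 1L, starts[i] - 1L),
                         substr(keep_seq, ends[i] + 1L, g$length))
    }
  }
  new_g <- g
  new_g$seq <- keep_seq
  new_g$length <- nchar(keep_seq)
  new_g$edits <- edits
  new_g$coord_map <- list(removed = rem_ir, original_length = g$length)

  halve <- which(kinds == "halve_count_interval")
  if (length(halve)) {
    hs <- old_to_new(new_g, starts[halve])
    he <- old_to_new(new_g, ends[halve])
    if (anyNA(hs) || anyNA(he)) stop("halve interval overlaps a removed span")
    new_g$halve_intervals <- IRanges::IRanges(hs, he)
  }
  new_g
}

#' Translate original coordinates to edited coordinates
#'
#' Positions inside a removed interval return `NA`; all others shift left by
#' the number of removed bases preceding them. [new_to_old()] inverts the
#' map, so `new_to_old(g, old_to_new(g, p)) == p` for every retained `p`.
#'
#' @param g An edited [genome()].
#' @param pos Integer vector of 1-based positions.
#' @export
old_to_new <- function(g, pos) {
  if (is.null(g$coord_map)) return(as.integer(pos))
  pos <- as.integer(pos)
  rem <- g$coord_map$removed
  out <- pos
  for (i in seq_along(rem)) {
    s <- IRanges::start(rem)[i]; e <- IRanges::end(rem)[i]
    out[pos >= s & pos <= e] <- NA_integer_
    shift <- e - s + 1L
    out[!is.na(out) & pos > e] <- out[!is.na(out) & pos > e] - shift
  }
  out
}

#' @rdname old_to_new
#' @export
new_to_old <- function(g, pos) {
  if (is.null(g$coord_map)) return(as.integer(pos))
  invert_kept(g, as.integer(pos))
}

invert_kept <- function(g, pos) {
  rem <- g$coord_map$removed
  L0 <- g$coord_map$original_length
  o <- order(IRanges::start(rem))
  ks <- integer(0); ke <- integer(0)
  cur <- 1L
  for (i in o) {
    s <- IRanges::start(rem)[i]; e <- IRanges::end(rem)[i]
    if (cur <= s - 1L) { ks <- c(ks, cur); ke <- c(ke, s - 1L) }
    cur <- e + 1L
  }
  if (cur <= L0) { ks <- c(ks, cur); ke <- c(ke, L0) }
  newlen <- ke - ks + 1L
  newstart <- cumsum(c(1L, newlen))[seq_along(newlen)]
  out <- rep(NA_integer_, length(pos))
  for (j in seq_along(ks)) {
    hit <- pos >= newstart[j] & pos <= newstart[j] + newlen[j] - 1L
    out[hit] <- ks[j] + (pos[hit] - newstart[j])
  }
  out
}

## ---- sequence utilities ----------------------------------------------------

# reverse complement of a plain character string (hot path: avoids XString
# object construction)
rc_string <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

# Extract a subsequence of `len` bases starting at `start` (1-based),
# wrapping past the origin for circular genomes.
genome_subseq <- function(g, start, len) {
  L <- g$length
  stopifnot(len >= 1L)
  start <- ((start - 1L) %% L) + 1L
  end <- start + len - 1L
  if (end <= L) return(substr(g$seq, start, end))
  if (g$topology != "circular") stop("interval exceeds linear genome bounds")
  if (len > L) stop("interval longer than genome")
  paste0(substr(g$seq, start, L), substr(g$seq, 1L, end - L))
}

# Dinucleotide windows of a genome as a character vector: windows start at
# positions 1..L-1 (linear) or 1..L (circular; the last wraps the origin).
dinuc_windows <- function(g) {
  s <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  L <- length(s)
  if (L < 2L) stop("genome shorter than 2")
  a <- s[-L]; b <- s[-1L]
  w <- paste0(a, b)
  if (g$topology == "circular") w <- c(w, paste0(s[L], s[1L]))
  w
}

DINUCS <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)))
PYR_DINUCS <- c("TT", "TC", "CT", "CC")

#' Genome-wide dinucleotide frequency
#'
#' Frequency of a dinucleotide over all overlapping forward-strand windows of
#' the genome. Circular genomes contribute one extra window wrapping the
#' origin. Windows containing `N` are excluded from both the numerator and
#' the denominator. This is the null expectation (`p0`) that read-internal
#' di-pyrimidine frequencies are compared against.
#'
#' @param g A [genome()].
#' @param dinuc One of the 16 dinucleotides, e.g. `"TT"`.
#' @return Frequency in `[0, 1]`.
#' @export
dinucleotide_frequency <- function(g, dinuc) {
  stopifnot(is_genome(g), dinuc %in% DINUCS)
  w <- dinuc_windows(g)
  ok <- !grepl("N", w, fixed = TRUE)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] == dinuc) / sum(ok)
}

#' All 16 forward-strand dinucleotide frequencies
#'
#' @param g A [genome()].
#' @return Named numeric vector over the 16 dinucleotides, summing to 1 for
#'   N-free genomes.
#' @export
dinucleotide_frequencies <- function(g) {
  w <- dinuc_windows(g)
  ok <- !grepl("N", w, fixed = TRUE)
  tab <- table(factor(w[ok], levels = DINUCS))
  fr <- as.vector(tab) / sum(ok)
  names(fr) <- DINUCS
  fr
}

## ---- feature sets ----------------------------------------------------------

REGION_CATEGORIES <- c("intergenic", "intron", "CDS", "rRNA", "tRNA")
# priority when annotations overlap: most specific/smallest feature wins
REGION_PRIORITY <- c(intergenic = 0L, intron = 1L, CDS = 2L, rRNA = 3L, tRNA = 4L)

#' Construct a feature set
#'
#' Typed, stranded intervals partitioning each annotated chromosome into the
#' region categories used throughout: CDS, intron, rRNA, tRNA, with the
#' unannotated remainder as intergenic. Where annotations overlap, a position
#' belongs to the highest-priority category (tRNA > rRNA > CDS > intron).
#'
#' @param features `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`), `category`
#'   (CDS/intron/rRNA/tRNA).
#' @return Object of class `FeatureSet`.
#' @export
feature_set <- function(features) {
  need <- c("chrom", "start", "end", "strand", "category")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  stopifnot(all(features$start >= 1L), all(features$start <= features$end),
            all(features$strand %in% c("+", "-")),
            all(features$category %in% setdiff(REGION_CATEGORIES, "intergenic")))
  structure(list(features = features[, need, drop = FALSE]), class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet: %d features on %d chromosome(s)\n",
              nrow(x$features), length(unique(x$features$chrom))))
  invisible(x)
}

#' Per-position region category of a genome
#'
#' @param g A [genome()].
#' @param fs A [feature_set()] (or `NULL`, giving all-intergenic).
#' @return Character vector of length `g$length` over the five categories.
#' @export
category_vector <- function(g, fs = NULL) {
  cats <- rep("intergenic", g$length)
  if (is.null(fs)) return(cats)
  f <- fs$features[fs$features$chrom == g$id, , drop = FALSE]
  if (!nrow(f)) return(cats)
  if (any(f$end > g$length)) stop("feature interval out of bounds on ", g$id)
  # paint in increasing priority so the highest-priority category wins
  for (cat in c("intron", "CDS", "rRNA", "tRNA")) {
    fc <- f[f$category == cat, , drop = FALSE]
    for (i in seq_len(nrow(fc))) cats[fc$start[i]:fc$end[i]] <- cat
  }
  cats
}

#' Dinucleotide counts by region category and strand
#'
#' Counts occurrences of `dinuc` within each region category, separately for
#' the forward strand and the reverse strand (i.e. occurrences of the
#' reverse complement of `dinuc` read on the forward sequence). A window is
#' attributed to the category of its first position, which makes the
#' per-category counts a partition of the genome-wide count.
#'
#' @param g A [genome()].
#' @param fs A [feature_set()] or `NULL`.
#' @param dinuc Dinucleotide, e.g. `"TT"`.
#' @return `data.frame` with columns `category`, `plus`, `minus`.
#' @export
region_dinuc_counts <- function(g, fs, dinuc) {
  stopifnot(dinuc %in% DINUCS)
  w <- dinuc_windows(g)
  cats <- category_vector(g, fs)[seq_along(w)]
  rc <- rc_string(dinuc)
  out <- data.frame(category = REGION_CATEGORIES,
                    plus = 0, minus = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    sel <- cats == out$category[i]
    out$plus[i] <- sum(w[sel] == dinuc)
    out$minus[i] <- sum(w[sel] == rc)
  }
  out
}

#' Summarise genome dinucleotide statistics
#'
#' Combines the 16 genome-wide forward-strand frequencies with per-category,
#' per-strand counts for a chosen set of dinucleotides.
#'
#' @param g A [genome()].
#' @param fs A [feature_set()] or `NULL`.
#' @param dinucs Dinucleotides to tabulate by region (default all 16).
#' @return Object of class `DinucStats`: list with `genome_id`,
#'   `frequencies` (named vector) and `region_counts` (long `data.frame`).
#' @export
dinuc_stats <- function(g, fs = NULL, dinucs = DINUCS) {
  rc_list <- lapply(dinucs, function(d) {
    df <- region_dinuc_counts(g, fs, d)
    df$dinuc <- d
    df
  })
  structure(list(genome_id = g$id,
                 frequencies = dinucleotide_frequencies(g),
                 region_counts = do.call(rbind, rc_list)),
            class = "DinucStats")
}

#' Write DinucStats as TSV
#'
#' Two tables are written: `<path>` holds the long per-category counts and a
#' `frequency` column repeats the genome-wide value per dinucleotide.
#'
#' @param stats A [dinuc_stats()] result.
#' @param path Output TSV path.
#' @export
write_dinuc_stats <- function(stats, path) {
  df <- stats$region_counts
  df$genome <- stats$genome_id
  df$genome_frequency <- stats$frequencies[df$dinuc]
  utils::write.table(df[, c("genome", "dinuc", "category", "plus", "minus",
                            "genome_frequency")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- GFF3 I/O --------------------------------------------------------------

#' Read a feature set from GFF3
#'
#' Feature types are mapped to region categories through `type_map`;
#' unmapped types are dropped.
#'
#' @param path GFF3 file.
#' @param type_map Named character vector, GFF3 `type` -> category. The
#'   default maps CDS, intron, rRNA, tRNA to themselves (plus the common
#'   `*_gene` spellings for structural RNAs).
#' @return A [feature_set()].
#' @export
read_features <- function(path,
                          type_map = c(CDS = "CDS", intron = "intron",
                                       rRNA = "rRNA", tRNA = "tRNA",
                                       rRNA_gene = "rRNA", tRNA_gene = "tRNA")) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% names(type_map)
  gr <- gr[keep]
  if (!length(gr)) stop("no mappable features in ", path)
  feature_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = unname(type_map[type[keep]]),
    stringsAsFactors = FALSE))
}

#' Write a feature set as GFF3
#'
#' @param fs A [feature_set()].
#' @param path Output path.
#' @export
write_gff <- function(fs, path) {
  f <- fs$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(f)) {
    lines <- sprintf("%s\txrfrag\t%s\t%d\t%d\t.\t%s\t.\tID=feat%d",
                     f$chrom, f$category, f$start, f$end, f$strand,
                     seq_len(nrow(f)))
    writeLines(lines, con)
  }
  invisible(path)
}
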
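#' Trim a 3' adapter, discarding untrimmed reads
#'
#' Locates the adapter (either fully contained in the read, or a prefix of
#' the adapter overlapping the read's 3' end by at least `min_overlap`
#' bases) allowing up to `max_error_rate` mismatches per aligned base, and
#' truncates the read at the adapter start. Reads with no adapter hit are
#' discarded, as are reads that become empty after trimming — only
#' adapter-bearing molecules are informative about fragment length.
#'
#' The leftmost admissible adapter start wins; ties are impossible since
#' starts are scanned left to right.
#'
#' @param reads `data.frame` with `id`, `seq` (and optionally `qual`).
#' @param adapter Adapter sequence (nonempty).
#' @param min_overlap Minimum adapter overlap at the read end (>= 3).
#' @param max_error_rate Allowed mismatches per aligned adapter base.
#' @return List with `reads` (trimmed, qualities truncated in step) and
#'   `stats` (input/trimmed/discarded counts).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L,
                         max_error_rate = 0) {
  stopifnot(nzchar(adapter), min_overlap >= 3L,
            max_error_rate >= 0, max_error_rate < 1)
  adapter <- toupper(adapter)
  alen_full <- nchar(adapter)
  ach <- strsplit(adapter, "", fixed = TRUE)[[1]]
  n <- nrow(reads)
  cut_at <- rep(NA_integer_, n)
  todo <- seq_len(n)
  if (max_error_rate == 0) {
    # exact full-adapter occurrence, vectorised (the common case)
    hit <- regexpr(adapter, reads$seq, fixed = TRUE)
    cut_at[hit > 0L] <- as.integer(hit[hit > 0L])
    todo <- which(hit <= 0L)
  }
  for (r in todo) {
    sq <- reads$seq[r]
    L <- nchar(sq)
    sch <- strsplit(sq, "", fixed = TRUE)[[1]]
    for (i in seq_len(L)) {
      al <- min(alen_full, L - i + 1L)
      if (al < alen_full && al < min_overlap) next
      mm <- sum(sch[i:(i + al - 1L)] != ach[seq_len(al)])
      if (mm <= floor(max_error_rate * al)) { cut_at[r] <- i; break }
    }
  }
  keep <- !is.na(cut_at) & cut_at > 1L
  trimmed <- reads[keep, , drop = FALSE]
  newlen <- cut_at[keep] - 1L
  trimmed$seq <- substr(trimmed$seq, 1L, newlen)
  if (!is.null(trimmed$qual)) trimmed$qual <- substr(trimmed$qual, 1L, newlen)
  rownames(trimmed) <- NULL
  list(reads = trimmed,
       stats = list(n_input = n,
                    n_trimmed = sum(keep),
                    n_discarded_untrimmed = sum(is.na(cut_at)),
                    n_discarded_empty = sum(!is.na(cut_at) & cut_at == 1L)))
}

# Build the match subject for a genome: circular genomes are extended by
# max_read_len - 1 bases so origin-spanning placements appear as ordinary
# matches with start <= genome length.
match_subject <- function(g, max_read_len) {
  ext <- if (g$topology == "circular" && max_read_len > 1L)
    paste0(g$seq, substr(g$seq, 1L, max_read_len - 1L)) else g$seq
  Biostrings::DNAString(ext)
}

#' Exhaustive exact alignment of reads against a genome set
#'
#' Enumerates all perfect full-length placements of each read on both
#' strands of every genome; circular genomes include origin-spanning
#' placements (counted once). Uniqueness is combinatorial: a read is
#' `unique` iff it has exactly one perfect placement anywhere in the genome
#' set, `multi` if more, `unmapped` if none. This realises the intent of a
#' MAPQ >= 30 filter — removing reads that map equally well to multiple
#' locations — as an exact, testable definition.
#'
#' @param reads `data.frame` with `id`, `seq`.
#' @param genomes List of [genome()] objects.
#' @return `data.frame` of aligned fragments: `read_id`, `chrom`, `start`
#'   (1-based), `end` (unwrapped, may exceed the genome length for
#'   origin-spanning placements), `strand`, `length`, `uniqueness`,
#'   `mismatches`, `mapq` (`NA` for this aligner), `n_placements`. For
#'   `multi` reads the first placement found is recorded; `unmapped` reads
#'   have `NA` coordinates.
#' @export
align_exact <- function(reads, genomes) {
  if (is_genome(genomes)) genomes <- list(genomes)
  max_len <- max(nchar(reads$seq), 1L)
  subjects <- lapply(genomes, match_subject, max_read_len = max_len)
  glens <- vapply(genomes, `[[`, 1L, "length")
  gids <- vapply(genomes, `[[`, "", "id")

  rc_subjects <- lapply(subjects, Biostrings::reverseComplement)
  uniq <- unique(reads$seq)
  clean <- !grepl("[^ACGT]", uniq)
  place <- vector("list", length(uniq))
  names(place) <- uniq
  empty <- data.frame(chrom = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  for (sq in uniq[!clean]) place[[sq]] <- empty  # ambiguous bases: unmapped
  # match per length class with a PDict; minus-strand hits come from the
  # reverse-complemented subject and are converted back to forward starts
  for (L in unique(nchar(uniq[clean]))) {
    sqs <- uniq[clean][nchar(uniq[clean]) == L]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sqs))
    hits_by_seq <- rep(list(empty), length(sqs))
    for (k in seq_along(genomes)) {
      N <- length(subjects[[k]])
      si_fwd <- Biostrings::startIndex(Biostrings::matchPDict(pd, subjects[[k]]))
      si_rev <- Biostrings::startIndex(Biostrings::matchPDict(pd, rc_subjects[[k]]))
      for (j in seq_along(sqs)) {
        st_f <- si_fwd[[j]]
        st_f <- st_f[st_f <= glens[k]]
        st_r <- N - si_rev[[j]] - L + 2L
        st_r <- st_r[st_r >= 1L & st_r <= glens[k]]
        if (length(st_f) || length(st_r)) {
          hits_by_seq[[j]] <- rbind(hits_by_seq[[j]], data.frame(
            chrom = gids[k], start = c(st_f, st_r),
            strand = rep(c("+", "-"), c(length(st_f), length(st_r))),
            stringsAsFactors = FALSE))
        }
      }
    }
    place[sqs] <- hits_by_seq
  }

  n <- nrow(reads)
  out <- data.frame(read_id = reads$id, chrom = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, length = nchar(reads$seq),
                    uniqueness = "unmapped", mismatches = 0L,
                    mapq = NA_integer_, n_placements = 0L,
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    p <- place[[reads$seq[r]]]
    if (is.null(p) || !nrow(p)) next
    out$n_placements[r] <- nrow(p)
    out$uniqueness[r] <- if (nrow(p) == 1L) "unique" else "multi"
    out$chrom[r] <- p$chrom[1]
    out$start[r] <- p$start[1]
    out$end[r] <- p$start[1] + out$length[r] - 1L
    out$strand[r] <- p$strand[1]
  }
  out
}

#' Import alignments from SAM/BAM
#'
#' Maps records onto the aligned-fragment table used by the rest of the
#' pipeline. Uniqueness follows the MAPQ convention: `unique` iff
#' `MAPQ >= mapq_min` (default 30). Mismatch counts come from the `NM` tag;
#' records lacking `NM` are recomputed against the reference sequence.
#'
#' @param path SAM or BAM file. SAM text is converted on the fly.
#' @param genomes List of [genome()] objects covering all reference names.
#' @param mapq_min MAPQ threshold for uniqueness (default 30).
#' @return `data.frame` as in [align_exact()] (with `mapq` populated).
#' @export
import_sam <- function(path, genomes, mapq_min = 30L) {
  if (is_genome(genomes)) genomes <- list(genomes)
  gids <- vapply(genomes, `[[`, "", "id")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "mapq", "seq", "qwidth"),
      tag = "NM"))[[1]]
  n <- length(res$qname)
  chrom <- as.character(res$rname)
  mapped <- !is.na(res$pos)
  unknown <- unique(chrom[mapped & !chrom %in% gids])
  if (length(unknown)) {
    stop("reference name(s) absent from genome set: ",
         paste(unknown, collapse = ", "))
  }
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  len <- res$qwidth
  # recompute mismatches where NM is missing (no indels modelled)
  need <- which(mapped & is.na(nm))
  for (i in need) {
    g <- genomes[[match(chrom[i], gids)]]
    ref <- genome_subseq(g, res$pos[i], len[i])
    qry <- as.character(res$seq[i])   # BAM stores forward-strand sequence
    nm[i] <- sum(strsplit(ref, "")[[1]] != strsplit(qry, "")[[1]])
  }
  uniqueness <- ifelse(!mapped, "unmapped",
                       ifelse(res$mapq >= mapq_min, "unique", "multi"))
  data.frame(read_id = res$qname, chrom = ifelse(mapped, chrom, NA),
             start = res$pos, end = res$pos + len - 1L,
             strand = ifelse(mapped, as.character(res$strand), NA),
             length = len, uniqueness = uniqueness,
             mismatches = as.integer(ifelse(mapped, nm, 0L)),
             mapq = res$mapq, n_placements = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Filter aligned fragments for uniqueness and mismatches
#'
#' Keeps fragments that are uniquely placed and have at most
#' `max_mismatches` mismatches, mirroring the two-stage filter of
#' MAPQ-based multimapper removal followed by mismatch removal. The two
#' criteria are independent, so filtering is idempotent and
#' order-insensitive.
#'
#' @param fragments Fragment table from [align_exact()] or [import_sam()].
#' @param mapq_min Retained for interface symmetry; uniqueness is already
#'   resolved at import/alignment time.
#' @param max_mismatches Maximum allowed mismatches (default 0).
#' @return List with `kept` (fragment table) and `report` (removal counts
#'   by cause: `unmapped`, `multimapping`, `mismatch`).
#' @export
filter_fragments <- function(fragments, mapq_min = 30L, max_mismatches = 0L) {
  unmapped <- fragments$uniqueness == "unmapped"
  multi <- fragments$uniqueness == "multi"
  mm <- !unmapped & !multi & fragments$mismatches > max_mismatches
  keep <- !unmapped & !multi & !mm
  list(kept = `rownames<-`(fragments[keep, , drop = FALSE], NULL),
       report = list(n_input = nrow(fragments), n_kept = sum(keep),
                     unmapped = sum(unmapped), multimapping = sum(multi),
                     mismatch = sum(mm)))
}

#' Per-fragment counting weights
#'
#' Fragments overlapping a `halve_count_interval` of their genome carry
#' weight 0.5 (the retained copy of a collapsed duplicated region receives
#' reads from both original copies); all others weigh 1.
#'
#' @param fragments Fragment table.
#' @param genomes List of [genome()] objects.
#' @return Numeric weight vector aligned with `fragments` rows.
#' @export
fragment_weights <- function(fragments, genomes) {
  if (is_genome(genomes)) genomes <- list(genomes)
  gids <- vapply(genomes, `[[`, "", "id")
  w <- rep(1, nrow(fragments))
  for (k in seq_along(genomes)) {
    hi <- genomes[[k]]$halve_intervals
    if (is.null(hi) || !length(hi)) next
    on_g <- which(!is.na(fragments$chrom) & fragments$chrom == gids[k])
    if (!length(on_g)) next
    fr <- IRanges::IRanges(fragments$start[on_g], fragments$end[on_g])
    ov <- IRanges::countOverlaps(fr, hi) > 0L
    # wrapped fragments: also test the wrapped-around prefix
    L <- genomes[[k]]$length
    wrap <- fragments$end[on_g] > L
    if (any(wrap)) {
      fr2 <- IRanges::IRanges(rep(1L, sum(wrap)),
                              fragments$end[on_g][wrap] - L)
      ov[wrap] <- ov[wrap] | IRanges::countOverlaps(fr2, hi) > 0L
    }
    w[on_g][ov] <- 0.5
  }
  w
}

# Logical per-position coverage vector (length g$length) for fragments of
# one genome; origin-spanning fragments wrap.
position_covered <- function(fragments, g) {
  cov <- logical(g$length)
  sel <- which(!is.na(fragments$chrom) & fragments$chrom == g$id)
  for (i in sel) {
    s <- fragments$start[i]; e <- fragments$end[i]
    if (e <= g$length) {
      cov[s:e] <- TRUE
    } else {
      cov[s:g$length] <- TRUE
      cov[1:(e - g$length)] <- TRUE
    }
  }
  cov
}

#' Mappability report: fraction of covered positions retained by filtering
#'
#' Compares per-position coverage before and after uniqueness/mismatch
#' filtering. For each region category, `fraction_retained` is the share of
#' positions covered in the unfiltered alignment that remain covered in the
#' filtered alignment; positions never covered in the unfiltered set are
#' excluded from both numerator and denominator, so the statistic reflects
#' mappability rather than sampling depth. The `total` row aggregates over
#' positions (position-weighted).
#'
#' @param fragments_unfiltered,fragments_filtered Fragment tables derived
#'   from the same reads.
#' @param g The [genome()] to report on.
#' @param fs Optional [feature_set()] for the per-category breakdown.
#' @return `data.frame` with `category`, `covered_unfiltered`,
#'   `covered_filtered`, `fraction_retained` (`NA` where a category has no
#'   unfiltered coverage), ending with the `total` row.
#' @export
compute_mappability <- function(fragments_unfiltered, fragments_filtered,
                                g, fs = NULL) {
  cov_u <- position_covered(fragments_unfiltered, g)
  cov_f <- position_covered(fragments_filtered, g)
  cats <- category_vector(g, fs)
  rows <- lapply(c(REGION_CATEGORIES, "total"), function(cat) {
    sel <- if (cat == "total") rep(TRUE, g$length) else cats == cat
    den <- sum(cov_u & sel)
    num <- sum(cov_f & cov_u & sel)
    data.frame(category = cat, covered_unfiltered = den,
               covered_filtered = num,
               fraction_retained = if (den > 0) num / den else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write fragments as BED6
#'
#' Intervals are 0-based half-open; the score column carries
#' `round(weight * 1000)`. Origin-spanning fragments are written with their
#' unwrapped end (consumers of circular genomes should interpret
#' coordinates modulo the genome length).
#'
#' @param fragments Fragment table (mapped rows only are written).
#' @param path Output path.
#' @param weights Optional weight vector (default all 1).
#' @export
write_bed <- function(fragments, path, weights = NULL) {
  sel <- !is.na(fragments$chrom)
  f <- fragments[sel, , drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(fragments))
  w <- weights[sel]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   f$chrom, f$start - 1L, f$end, f$read_id,
                   as.integer(round(w * 1000)), f$strand)
  writeLines(lines, path)
  invisible(path)
}
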
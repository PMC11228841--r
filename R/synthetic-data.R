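# Seed handling: simulators take an explicit `seed`; the global RNG state is
# restored on exit so simulation calls do not perturb the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a damage-fragment model
#'
#' Describes how UV-damage-anchored fragments are laid out around a TT
#' dimer. Both mechanisms keep the dimer at a fixed distance from the
#' fragment 3' end, which is the geometry that makes TT peaks line up when
#' read-length classes are right (3') aligned:
#'
#' * `fixed_incision`: incisions at varying distances 5' of the dimer
#'   produce the length classes directly.
#' * `five_prime_trim`: a primary fragment of `primary_length` nt is
#'   shortened from the 5' end in steps of `trim_step` nt, up to
#'   `trim_max_steps` steps.
#'
#' In a fragment of length `L`, the TT pair occupies read positions
#' `(L - dimer_offset_3p, L - dimer_offset_3p + 1)`; with the defaults
#' (`primary_length = 26`, `dimer_offset_3p = 19`) the pair sits at
#' positions 7-8 of the primary fragment.
#'
#' @param mechanism `"fixed_incision"` or `"five_prime_trim"`.
#' @param primary_length Primary fragment length in nt (default 26).
#' @param trim_step 5'-trimming step in nt (default 2).
#' @param trim_max_steps Number of trimming steps available (>= 0).
#' @param dimer_offset_3p Offset of the dimer from the 3' end (see above).
#' @param length_weights Named probability vector over fragment lengths.
#'   Defaults to equal weight on `primary_length - k*trim_step`,
#'   `k = 0..trim_max_steps` (for `fixed_incision` with
#'   `trim_max_steps = 0`, all mass on `primary_length`).
#' @return Object of class `DamageModel`.
#' @export
damage_model <- function(mechanism = c("fixed_incision", "five_prime_trim"),
                         primary_length = 26L, trim_step = 2L,
                         trim_max_steps = 0L, dimer_offset_3p = 19L,
                         length_weights = NULL) {
  mechanism <- match.arg(mechanism)
  primary_length <- as.integer(primary_length)
  trim_step <- as.integer(trim_step)
  trim_max_steps <- as.integer(trim_max_steps)
  dimer_offset_3p <- as.integer(dimer_offset_3p)
  stopifnot(trim_max_steps >= 0L, trim_step >= 1L, dimer_offset_3p >= 1L)
  if (primary_length < dimer_offset_3p + 2L) {
    stop("primary_length must be >= dimer_offset_3p + 2")
  }
  lengths <- primary_length - trim_step * (0:trim_max_steps)
  if (is.null(length_weights)) {
    length_weights <- stats::setNames(rep(1 / length(lengths), length(lengths)),
                                      lengths)
  }
  lw_len <- as.integer(names(length_weights))
  if (anyNA(lw_len)) stop("length_weights must be named by fragment length")
  if (!all(lw_len %in% lengths)) {
    stop("length_weights lengths must be primary_length - k*trim_step")
  }
  if (abs(sum(length_weights) - 1) > 1e-9) stop("length_weights must sum to 1")
  # every emitted length must still contain the dimer pair
  if (any(lw_len[length_weights > 0] < dimer_offset_3p + 1L)) {
    stop("a weighted length is too short to contain the dimer")
  }
  structure(list(mechanism = mechanism, primary_length = primary_length,
                 trim_step = trim_step, trim_max_steps = trim_max_steps,
                 dimer_offset_3p = dimer_offset_3p,
                 length_weights = length_weights),
            class = "DamageModel")
}

#' Generate a random genome of given AT content
#'
#' Bases are drawn i.i.d. with `P(A) = P(T) = at_fraction/2` and
#' `P(C) = P(G) = (1 - at_fraction)/2`. Organellar genomes are strongly
#' AT-rich, so the pipeline fixtures use high `at_fraction` for the
#' mitochondrial genome.
#'
#' @param length Genome length (>= 100).
#' @param at_fraction AT fraction in `[0, 1]`.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param seed Optional integer seed (reproducible output).
#' @param id Genome id.
#' @param compartment Compartment label.
#' @return A [genome()].
#' @export
make_random_genome <- function(length, at_fraction, topology = "circular",
                               seed = NULL, id = "synthetic",
                               compartment = "mito") {
  stopifnot(length >= 100L, at_fraction >= 0, at_fraction <= 1)
  seq <- with_seed(seed, paste(
    sample(c("A", "T", "C", "G"), length, replace = TRUE,
           prob = c(at_fraction / 2, at_fraction / 2,
                    (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
    collapse = ""))
  genome(id, seq, topology = topology, compartment = compartment)
}

#' Plant an organellar duplication (NUMT/NUPT) into a nuclear genome
#'
#' Inserts a copy of `donor_interval` from `donor_genome` into
#' `nuclear_genome` at `insertion_site`, substituting each copied base with
#' probability `divergence_rate` (to a uniformly chosen different base). The
#' planted interval and substitution count are recorded in the returned
#' genome's `insertions` field as ground truth for mappability tests.
#'
#' @param nuclear_genome Recipient [genome()].
#' @param donor_genome Donor [genome()] (circular donors may wrap).
#' @param donor_interval 1-based inclusive `c(start, end)` on the donor.
#' @param insertion_site 1-based position in the nuclear genome before which
#'   the copy is inserted (1 .. length+1).
#' @param divergence_rate Per-base substitution probability in `[0, 0.25]`.
#' @param seed Optional seed.
#' @return The modified nuclear [genome()].
#' @export
plant_duplication <- function(nuclear_genome, donor_genome, donor_interval,
                              insertion_site, divergence_rate = 0,
                              seed = NULL) {
  stopifnot(is_genome(nuclear_genome), is_genome(donor_genome),
            divergence_rate >= 0, divergence_rate <= 0.25)
  ds <- as.integer(donor_interval[1]); de <- as.integer(donor_interval[2])
  len <- de - ds + 1L
  if (len < 1L) stop("invalid donor interval")
  if (donor_genome$topology == "linear" && de > donor_genome$length) {
    stop("donor interval out of bounds")
  }
  if (insertion_site < 1L || insertion_site > nuclear_genome$length + 1L) {
    stop("insertion site out of bounds")
  }
  seg <- genome_subseq(donor_genome, ds, len)
  n_subs <- 0L
  seg <- with_seed(seed, {
    bases <- strsplit(seg, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(len) < divergence_rate)
    for (i in hit) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
    }
    n_subs <- length(hit)
    paste(bases, collapse = "")
  })
  g <- nuclear_genome
  g$seq <- paste0(substr(g$seq, 1L, insertion_site - 1L), seg,
                  substr(g$seq, insertion_site, g$length))
  g$length <- nchar(g$seq)
  ins <- data.frame(start = insertion_site, end = insertion_site + len - 1L,
                    donor = donor_genome$id, donor_start = ds, donor_end = de,
                    n_substitutions = n_subs, stringsAsFactors = FALSE)
  g$insertions <- rbind(nuclear_genome$insertions, ins)
  g
}

# TT dimer sites of a genome: forward-strand sites are window starts where
# the forward sequence reads TT; reverse-strand sites are window starts
# reading AA (TT on the reverse strand). Window starts follow dinuc_windows().
tt_sites <- function(g) {
  w <- dinuc_windows(g)
  list(plus = which(w == "TT"), minus = which(w == "AA"))
}

#' Simulate a damage-anchored fragment library
#'
#' For each read: a strand is chosen uniformly, a TT dimer site is chosen
#' uniformly among that strand's TT sites, a fragment length is drawn from
#' the model's `length_weights`, and the fragment is laid out so that the
#' dimer occupies read positions `(L - dimer_offset_3p, L - offset + 1)` on
#' the fragment's own 5'->3' axis. Fragments may wrap the origin of circular
#' genomes; on linear genomes, placements exceeding the ends are resampled
#' (the resample count is returned). The configured 3' sequencing adapter is
#' appended and the result truncated to `read_length`, emulating fixed-length
#' single-end chemistry with adapter read-through.
#'
#' @param g Source [genome()] (must contain at least one TT on each strand).
#' @param model A [damage_model()].
#' @param n_reads Number of reads (>= 1).
#' @param seed Optional seed.
#' @param adapter 3' adapter sequence appended to each fragment.
#' @param read_length Sequencer read length; `NA` keeps full
#'   fragment+adapter.
#' @param id_prefix Read-id prefix.
#' @return List with `reads` (`data.frame`: `id`, `seq`, `qual`), `truth`
#'   (`data.frame`: one row per read with source placement and dimer
#'   positions) and `n_resampled`.
#' @export
simulate_fragments <- function(g, model, n_reads, seed = NULL,
                               adapter = "AGATCGGAAGAGCACACGTCT",
                               read_length = 50L, id_prefix = "frag") {
  stopifnot(is_genome(g), inherits(model, "DamageModel"), n_reads >= 1L)
  sites <- tt_sites(g)
  if (!length(sites$plus) || !length(sites$minus)) {
    stop("genome must contain a TT site on each strand")
  }
  lengths <- as.integer(names(model$length_weights))
  off <- model$dimer_offset_3p
  L_genome <- g$length
  with_seed(seed, {
    out_id <- character(n_reads); out_seq <- character(n_reads)
    t_strand <- character(n_reads); t_start <- integer(n_reads)
    t_len <- integer(n_reads); t_p1 <- integer(n_reads)
    n_resampled <- 0L
    for (i in seq_len(n_reads)) {
      repeat {
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        sset <- if (strand == "+") sites$plus else sites$minus
        site <- sset[sample.int(length(sset), 1L)]
        L <- if (length(lengths) == 1L) lengths else
          sample(lengths, 1L, prob = model$length_weights)
        p1 <- L - off                      # 5' base of the TT pair on the read
        if (strand == "+") {
          s <- site - (p1 - 1L)
          e <- s + L - 1L
        } else {
          e <- site + p1
          s <- e - L + 1L
        }
        if (g$topology == "linear" && (s < 1L || e > L_genome)) {
          n_resampled <- n_resampled + 1L
          next
        }
        frag <- genome_subseq(g, s, L)
        if (strand == "-") frag <- rc_string(frag)
        out_id[i] <- sprintf("%s_%06d", id_prefix, i)
        out_seq[i] <- frag
        t_strand[i] <- strand
        t_start[i] <- ((s - 1L) %% L_genome) + 1L
        t_len[i] <- L
        t_p1[i] <- p1
        break
      }
    }
    reads <- data.frame(id = out_id,
                        seq = substr(paste0(out_seq, adapter), 1L,
                                     if (is.na(read_length)) .Machine$integer.max
                                     else read_length),
                        stringsAsFactors = FALSE)
    reads$qual <- strrep("I", nchar(reads$seq))
    truth <- data.frame(read_id = out_id, genome_id = g$id,
                        strand = t_strand, start = t_start, length = t_len,
                        dimer_p1 = t_p1, dimer_p2 = t_p1 + 1L,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, n_resampled = n_resampled)
  })
}

#' Simple non-overlapping random annotation
#'
#' Tiles a genome with non-overlapping features of the four genic
#' categories, leaving random intergenic gaps, as a stand-in annotation for
#' pipeline demonstrations and tests.
#'
#' @param g A [genome()].
#' @param n_features Number of features to attempt.
#' @param mean_length Mean feature length (geometric-ish via uniform range).
#' @param seed Optional seed.
#' @param category_weights Sampling weights over CDS/intron/rRNA/tRNA.
#' @return A [feature_set()].
#' @export
random_feature_set <- function(g, n_features = 20L, mean_length = 400L,
                               seed = NULL,
                               category_weights = c(CDS = 0.55, intron = 0.15,
                                                    rRNA = 0.15, tRNA = 0.15)) {
  with_seed(seed, {
    pos <- 1L
    rows <- list()
    for (i in seq_len(n_features)) {
      gap <- sample.int(max(2L, mean_length %/% 2L), 1L)
      len <- sample.int(2L * mean_length, 1L)
      start <- pos + gap
      end <- start + len - 1L
      if (end >= g$length) break
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$id, start = start, end = end,
        strand = sample(c("+", "-"), 1L),
        category = sample(names(category_weights), 1L,
                          prob = category_weights),
        stringsAsFactors = FALSE)
      pos <- end
    }
    if (!length(rows)) stop("genome too short for any feature")
    feature_set(do.call(rbind, rows))
  })
}

## ---- plain-text I/O for reads and truth ------------------------------------

#' Write reads as FASTQ (Phred+33)
#' @param reads `data.frame` with `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Read a FASTQ file into a reads data frame
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = lines[idx + 1L], qual = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

#' Write / read fragment ground truth as TSV
#'
#' Lossless round-trip companions: `read_truth(write_truth(x, p))` returns
#' `x` (an empty truth list gives a header-only file).
#'
#' @param truth Truth `data.frame` from [simulate_fragments()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character",
                                   genome_id = "character",
                                   strand = "character"))
}
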
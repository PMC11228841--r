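#' Two-standard-error half width of the null band
#'
#' The 95% band around the genome-null dinucleotide frequency is
#' approximated as twice the binomial standard error of the null proportion
#' given the number of reads: `2 * sqrt(p0 * (1 - p0) / n)`.
#'
#' @param p0 Null proportion in `[0, 1]`.
#' @param n Number of reads (> 0).
#' @export
ci_half_width <- function(p0, n) {
  stopifnot(p0 >= 0, p0 <= 1, n > 0)
  2 * sqrt(p0 * (1 - p0) / n)
}

#' Map chromosome ids to compartments
#' @param genomes List of [genome()] objects.
#' @return Named character vector id -> compartment.
#' @export
compartment_map <- function(genomes) {
  stats::setNames(vapply(genomes, `[[`, "", "compartment"),
                  vapply(genomes, `[[`, "", "id"))
}

#' Read-length spectra by compartment
#'
#' Weighted, normalised read-length histograms per cellular compartment.
#' Counts use the halving weights (see [fragment_weights()]); frequencies
#' normalise within each compartment.
#'
#' @param fragments Filtered fragment table.
#' @param compartment_of_chrom Named vector chrom -> compartment (see
#'   [compartment_map()]).
#' @param weights Optional per-fragment weights (default 1).
#' @return Named list of `LengthSpectrum` objects (one per compartment
#'   present in `compartment_of_chrom`): each has `compartment`, `counts`
#'   (named by length), `freq`, `total`.
#' @export
length_spectrum <- function(fragments, compartment_of_chrom, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(fragments))
  comps <- unique(unname(compartment_of_chrom))
  out <- lapply(comps, function(cp) {
    sel <- !is.na(fragments$chrom) &
      compartment_of_chrom[fragments$chrom] == cp
    lens <- fragments$length[sel]
    w <- weights[sel]
    counts <- tapply(w, factor(lens), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
    total <- sum(w)
    structure(list(compartment = cp, counts = counts,
                   freq = if (total > 0) counts / total else counts,
                   total = total),
              class = "LengthSpectrum")
  })
  names(out) <- comps
  out
}

#' @export
print.LengthSpectrum <- function(x, ...) {
  cat(sprintf("LengthSpectrum (%s): %.1f weighted reads, %d length bin(s)\n",
              x$compartment, x$total, length(x$counts)))
  invisible(x)
}

#' Pearson correlation between two length spectra
#'
#' Computed over the union of length bins, with absent bins counted as 0.
#'
#' @param spec_a,spec_b `LengthSpectrum` objects.
#' @return List with `r` (Pearson correlation) and `p_value`.
#' @export
spectrum_correlation <- function(spec_a, spec_b) {
  bins <- sort(unique(as.integer(c(names(spec_a$freq), names(spec_b$freq)))))
  if (length(bins) < 3L) stop("fewer than 3 length bins; correlation undefined")
  xa <- spec_a$freq[as.character(bins)]; xa[is.na(xa)] <- 0
  xb <- spec_b$freq[as.character(bins)]; xb[is.na(xb)] <- 0
  ct <- stats::cor.test(xa, xb, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Fragment-oriented sequences of aligned fragments
#'
#' Extracts each fragment's sequence in its own 5'->3' orientation
#' (reverse-complemented for minus-strand placements), wrapping the origin
#' of circular genomes where needed.
#'
#' @param fragments Fragment table (mapped rows).
#' @param genomes List of [genome()] objects.
#' @return Character vector aligned with `fragments` rows.
#' @export
fragment_sequences <- function(fragments, genomes) {
  if (is_genome(genomes)) genomes <- list(genomes)
  gids <- vapply(genomes, `[[`, "", "id")
  out <- character(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    if (is.na(fragments$chrom[i])) { out[i] <- NA_character_; next }
    g <- genomes[[match(fragments$chrom[i], gids)]]
    sq <- genome_subseq(g, fragments$start[i], fragments$length[i])
    out[i] <- if (fragments$strand[i] == "-") rc_string(sq) else sq
  }
  out
}

# weighted per-position dinucleotide frequency matrix: 16 x (L-1)
dinuc_freq_matrix <- function(sequences, L, weights) {
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                nrow = length(sequences), ncol = L, byrow = TRUE)
  W <- sum(weights)
  freq <- matrix(0, nrow = 16L, ncol = L - 1L,
                 dimnames = list(DINUCS, NULL))
  for (p in seq_len(L - 1L)) {
    di <- paste0(mat[, p], mat[, p + 1L])
    freq[, p] <- tapply(c(weights, rep(0, 16L)),
                        factor(c(di, DINUCS), levels = DINUCS), sum) / W
  }
  freq
}

#' Positional di-pyrimidine profile of one read-length class
#'
#' For all fragments of length `L`, the weighted frequency of each
#' dinucleotide at read positions `p = 1..L-1` (the pair occupying
#' positions `p`, `p+1` on the read's own 5'->3' axis). With
#' `anchor = "three_prime"`, profiles of different length classes share a
#' right-aligned axis: display positions are offset by `L_max - L`, so that
#' a dimer at fixed distance from the 3' end falls at the same display
#' position in every class. The null band is `null_p0` plus/minus
#' [ci_half_width()].
#'
#' @param fragments Fragment table rows of length `L` (used for weights/ids;
#'   may be omitted when `sequences` are given directly).
#' @param sequences Fragment-oriented sequences (all of length `L`).
#' @param L Read length class.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param null_p0 Genome-null TT frequency (or other reference proportion).
#' @param weights Optional per-fragment weights.
#' @param L_max Reference maximum length for the right-aligned axis
#'   (default `L`).
#' @param min_reads Classes with fewer reads are flagged (`flagged = TRUE`)
#'   but still reported.
#' @return Object of class `DinucProfile`: `L`, `anchor`, `positions`
#'   (read-axis), `display_positions`, `freq` (16 x (L-1) matrix),
#'   `pyrimidine` (4 x (L-1) submatrix), `n_reads`, `null_p0`,
#'   `ci_half_width`, `flagged`.
#' @export
positional_dinuc_profile <- function(fragments = NULL, sequences, L,
                                     anchor = c("five_prime", "three_prime"),
                                     null_p0, weights = NULL, L_max = L,
                                     min_reads = 100L) {
  anchor <- match.arg(anchor)
  n <- length(sequences)
  if (n == 0L) stop("no reads in length class ", L)
  if (any(nchar(sequences) != L)) stop("all sequences must have length ", L)
  stopifnot(L_max >= L)
  if (is.null(weights)) weights <- rep(1, n)
  freq <- dinuc_freq_matrix(sequences, L, weights)
  structure(list(L = L, anchor = anchor,
                 positions = seq_len(L - 1L),
                 display_positions = seq_len(L - 1L) +
                   if (anchor == "three_prime") L_max - L else 0L,
                 freq = freq,
                 pyrimidine = freq[PYR_DINUCS, , drop = FALSE],
                 n_reads = n, null_p0 = null_p0,
                 ci_half_width = ci_half_width(null_p0, n),
                 flagged = n < min_reads),
            class = "DinucProfile")
}

#' @export
print.DinucProfile <- function(x, ...) {
  cat(sprintf(
    "DinucProfile: L=%d, %s-anchored, %d reads%s; TT argmax at p=%d (%.4f vs null %.4f +/- %.4f)\n",
    x$L, sub("_.*", "", x$anchor), x$n_reads,
    if (x$flagged) " [below min_reads]" else "",
    tt_argmax(x), max(x$freq["TT", ]), x$null_p0, x$ci_half_width))
  invisible(x)
}

#' Read-axis position of the maximal TT frequency
#' @param profile A `DinucProfile`.
#' @param display If `TRUE`, return the shared-axis display position.
#' @export
tt_argmax <- function(profile, display = FALSE) {
  i <- which.max(profile$freq["TT", ])
  if (display) profile$display_positions[i] else profile$positions[i]
}

#' Positional mononucleotide profile of one read-length class
#'
#' Weighted A/C/G/T frequencies at read positions `1..L`, same anchoring
#' semantics as [positional_dinuc_profile()].
#'
#' @inheritParams positional_dinuc_profile
#' @return Object of class `NucProfile` with `freq` (4 x L matrix).
#' @export
positional_nuc_profile <- function(fragments = NULL, sequences, L,
                                   anchor = c("five_prime", "three_prime"),
                                   weights = NULL, L_max = L) {
  anchor <- match.arg(anchor)
  n <- length(sequences)
  if (n == 0L) stop("no reads in length class ", L)
  if (any(nchar(sequences) != L)) stop("all sequences must have length ", L)
  if (is.null(weights)) weights <- rep(1, n)
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                nrow = n, ncol = L, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  W <- sum(weights)
  freq <- matrix(0, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
  for (p in seq_len(L)) {
    freq[, p] <- tapply(c(weights, rep(0, 4L)),
                        factor(c(mat[, p], bases), levels = bases), sum) / W
  }
  structure(list(L = L, anchor = anchor, positions = seq_len(L),
                 display_positions = seq_len(L) +
                   if (anchor == "three_prime") L_max - L else 0L,
                 freq = freq, n_reads = n),
            class = "NucProfile")
}

#' Call positional enrichment against the null band
#'
#' A position/dinucleotide is significant when its observed frequency
#' exceeds the null by more than the two-standard-error half width —
#' the "bars above the line" criterion.
#'
#' @param profile A [positional_dinuc_profile()] result.
#' @param dinucs Dinucleotides to call (default `"TT"`).
#' @return `data.frame`: `L`, `position`, `display_position`, `dinuc`,
#'   `observed`, `null_p0`, `ci_half_width`, `significant`.
#' @export
call_enrichment <- function(profile, dinucs = "TT") {
  stopifnot(inherits(profile, "DinucProfile"))
  rows <- lapply(dinucs, function(d) {
    data.frame(L = profile$L, position = profile$positions,
               display_position = profile$display_positions,
               dinuc = d, observed = profile$freq[d, ],
               null_p0 = profile$null_p0,
               ci_half_width = profile$ci_half_width,
               significant = profile$freq[d, ] >
                 profile$null_p0 + profile$ci_half_width,
               stringsAsFactors = FALSE)
  })
  `rownames<-`(do.call(rbind, rows), NULL)
}

#' Tidy export of spectra and profiles
#'
#' @param spectra Named list from [length_spectrum()].
#' @param path TSV path.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(spectra, function(sp) {
    if (!length(sp$counts)) return(NULL)
    data.frame(compartment = sp$compartment,
               length = as.integer(names(sp$counts)),
               count = unname(sp$counts), freq = unname(sp$freq),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @param profiles List of `DinucProfile` objects.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(pr) {
    data.frame(L = pr$L, anchor = pr$anchor,
               position = rep(pr$positions, each = 4L),
               display_position = rep(pr$display_positions, each = 4L),
               dinuc = rep(PYR_DINUCS, times = length(pr$positions)),
               freq = as.vector(pr$pyrimidine),
               n_reads = pr$n_reads, null_p0 = pr$null_p0,
               ci_half_width = pr$ci_half_width,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
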
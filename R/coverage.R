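#' Reads per kilobase per million mapped reads
#'
#' @param weighted_reads Weighted read count in the target.
#' @param target_length_nt Target length in nucleotides (> 0).
#' @param total_mapped_weighted_reads Library-wide weighted mapped reads
#'   (> 0).
#' @export
rpkm <- function(weighted_reads, target_length_nt,
                 total_mapped_weighted_reads) {
  stopifnot(target_length_nt > 0, total_mapped_weighted_reads > 0)
  weighted_reads / (target_length_nt / 1000) /
    (total_mapped_weighted_reads / 1e6)
}

# fragment midpoint as a 1-based position on the (circular) genome axis
fragment_midpoint <- function(fragments, g) {
  mid <- fragments$start + (fragments$length - 1L) %/% 2L
  ((mid - 1L) %% g$length) + 1L
}

#' Assign fragments to region categories
#'
#' Each fragment belongs to the category of its midpoint position (midpoint
#' assignment makes the per-category counts a partition of the per-genome
#' count). Overlapping annotations resolve by priority
#' tRNA > rRNA > CDS > intron > intergenic; unannotated chromosomes are
#' entirely intergenic.
#'
#' @param fragments Fragment table rows mapped to `g`.
#' @param g A [genome()].
#' @param fs A [feature_set()] or `NULL`.
#' @return Character vector of categories, one per fragment row.
#' @export
assign_region <- function(fragments, g, fs = NULL) {
  cats <- category_vector(g, fs)
  cats[fragment_midpoint(fragments, g)]
}

# strand of the (highest-priority) feature containing each position; NA for
# intergenic positions
feature_strand_vector <- function(g, fs) {
  strands <- rep(NA_character_, g$length)
  if (is.null(fs)) return(strands)
  f <- fs$features[fs$features$chrom == g$id, , drop = FALSE]
  for (cat in c("intron", "CDS", "rRNA", "tRNA")) {
    fc <- f[f$category == cat, , drop = FALSE]
    for (i in seq_len(nrow(fc))) strands[fc$start[i]:fc$end[i]] <- fc$strand[i]
  }
  strands
}

#' Genome and region coverage table
#'
#' Computes per-genome RPKM (over the full edited reference length),
#' per-(genome, category) weighted counts and RPKM (category length = number
#' of positions in the category), and the organellar/nuclear RPKM ratio for
#' each organellar genome. "Total mapped reads" is the weighted sum over all
#' genomes of the assembly.
#'
#' @param fragments Filtered fragment table.
#' @param genomes List of [genome()] objects.
#' @param feature_sets Optional named list (by genome id) of
#'   [feature_set()]s, or a single `FeatureSet` applied by chromosome name.
#' @param weights Optional per-fragment weights (default
#'   [fragment_weights()]).
#' @return Object of class `CoverageTable`: list with `genomes`
#'   (`data.frame`: id, compartment, length, weighted_reads, rpkm),
#'   `regions` (`data.frame` per genome x category), `org_nuc_ratio`
#'   (named vector per organellar genome), `total_weighted_reads`.
#' @export
coverage_table <- function(fragments, genomes, feature_sets = NULL,
                           weights = NULL) {
  if (is_genome(genomes)) genomes <- list(genomes)
  if (is.null(weights)) weights <- fragment_weights(fragments, genomes)
  gids <- vapply(genomes, `[[`, "", "id")
  total <- sum(weights[!is.na(fragments$chrom)])
  if (total <= 0) stop("no mapped weighted reads")

  fs_for <- function(id) {
    if (is.null(feature_sets)) return(NULL)
    if (inherits(feature_sets, "FeatureSet")) return(feature_sets)
    feature_sets[[id]]
  }

  gtab <- data.frame(id = gids,
                     compartment = vapply(genomes, `[[`, "", "compartment"),
                     length = vapply(genomes, `[[`, 1L, "length"),
                     weighted_reads = 0, rpkm = 0,
                     stringsAsFactors = FALSE)
  regions <- list()
  for (k in seq_along(genomes)) {
    g <- genomes[[k]]
    sel <- !is.na(fragments$chrom) & fragments$chrom == g$id
    gtab$weighted_reads[k] <- sum(weights[sel])
    gtab$rpkm[k] <- rpkm(gtab$weighted_reads[k], g$length, total)
    fs <- fs_for(g$id)
    cats_frag <- assign_region(fragments[sel, , drop = FALSE], g, fs)
    cats_pos <- category_vector(g, fs)
    for (cat in REGION_CATEGORIES) {
      clen <- sum(cats_pos == cat)
      wr <- sum(weights[sel][cats_frag == cat])
      regions[[length(regions) + 1L]] <- data.frame(
        genome = g$id, category = cat, length = clen, weighted_reads = wr,
        rpkm = if (clen > 0) rpkm(wr, clen, total) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, regions)

  nuc <- gtab$compartment == "nuclear"
  org <- !nuc
  ratio <- stats::setNames(rep(NA_real_, sum(org)), gtab$id[org])
  if (any(nuc) && sum(gtab$length[nuc]) > 0) {
    nuc_rpkm <- rpkm(sum(gtab$weighted_reads[nuc]),
                     sum(gtab$length[nuc]), total)
    if (nuc_rpkm > 0) ratio[] <- gtab$rpkm[org] / nuc_rpkm
  }
  structure(list(genomes = gtab, regions = regions, org_nuc_ratio = ratio,
                 total_weighted_reads = total),
            class = "CoverageTable")
}

#' @export
print.CoverageTable <- function(x, ...) {
  cat("CoverageTable:\n")
  print(x$genomes, row.names = FALSE)
  if (length(x$org_nuc_ratio)) {
    cat("org/nuc RPKM ratio:\n")
    print(round(x$org_nuc_ratio, 3))
  }
  invisible(x)
}

#' Organellar/nuclear RPKM ratio
#'
#' @param tbl A [coverage_table()].
#' @param organellar_id Organellar genome id.
#' @param nuclear_ids Nuclear genome ids (pooled: combined reads over
#'   combined length).
#' @export
coverage_ratio <- function(tbl, organellar_id, nuclear_ids) {
  gt <- tbl$genomes
  oi <- match(organellar_id, gt$id)
  ni <- match(nuclear_ids, gt$id)
  if (anyNA(c(oi, ni))) stop("unknown genome id")
  nuc_rpkm <- rpkm(sum(gt$weighted_reads[ni]), sum(gt$length[ni]),
                   tbl$total_weighted_reads)
  if (nuc_rpkm <= 0) stop("zero nuclear RPKM")
  gt$rpkm[oi] / nuc_rpkm
}

# occurrences of dinucs (summed over dipyr_set) within [start, end] of g,
# on the given strand; "+" counts forward occurrences, "-" counts reverse
# complements read on the forward sequence. Windows are attributed by their
# first position, consistent with region_dinuc_counts().
count_dipyr_interval <- function(g, start, end, dipyr_set, strand) {
  w <- dinuc_windows(g)
  idx <- start:min(end, length(w))
  pats <- if (strand == "+") dipyr_set else vapply(dipyr_set, rc_string, "")
  sum(w[idx] %in% pats)
}

#' Template vs coding strand coverage, normalised by di-pyrimidine content
#'
#' For each genic category, counts fragments mapping to the template strand
#' (opposite the feature's annotated strand — the strand read by RNA
#' polymerase) and the coding strand, then normalises each count by the
#' number of di-pyrimidines available on that strand within the category's
#' features. The reported ratio
#' `(template_count/template_dipyr) / (coding_count/coding_dipyr)` exceeds 1
#' when the template strand is repaired or degraded preferentially, after
#' accounting for unequal damage substrate on the two strands.
#'
#' @param fragments Filtered fragment table rows on `g`.
#' @param fs A [feature_set()].
#' @param g A [genome()].
#' @param dipyr_set Di-pyrimidines counted as damage substrate (default
#'   `"TT"`; use `c("TT","TC","CT","CC")` for all).
#' @param weights Optional per-fragment weights.
#' @return Object of class `StrandReport`: `data.frame` per genic category
#'   with `template_count`, `coding_count`, `template_dipyr`,
#'   `coding_dipyr`, `normalized_ratio` (`NA`, with a warning, where a
#'   strand has no di-pyrimidines).
#' @export
strand_normalized_coverage <- function(fragments, fs, g, dipyr_set = "TT",
                                       weights = NULL) {
  stopifnot(inherits(fs, "FeatureSet"), all(dipyr_set %in% PYR_DINUCS))
  if (is.null(weights)) weights <- rep(1, nrow(fragments))
  sel <- which(!is.na(fragments$chrom) & fragments$chrom == g$id)
  f <- fragments[sel, , drop = FALSE]
  w <- weights[sel]
  cats <- assign_region(f, g, fs)
  fstr <- feature_strand_vector(g, fs)[fragment_midpoint(f, g)]

  genic <- c("CDS", "intron", "rRNA", "tRNA")
  out <- data.frame(category = genic, template_count = 0, coding_count = 0,
                    template_dipyr = 0, coding_dipyr = 0,
                    normalized_ratio = NA_real_, stringsAsFactors = FALSE)
  feats <- fs$features[fs$features$chrom == g$id, , drop = FALSE]
  cats_pos <- category_vector(g, fs)
  for (i in seq_len(nrow(out))) {
    cat_i <- out$category[i]
    in_cat <- cats == cat_i & !is.na(fstr)
    is_template <- in_cat & f$strand != fstr
    is_coding <- in_cat & f$strand == fstr
    out$template_count[i] <- sum(w[is_template])
    out$coding_count[i] <- sum(w[is_coding])
    fc <- feats[feats$category == cat_i, , drop = FALSE]
    for (j in seq_len(nrow(fc))) {
      # restrict to positions the priority rules actually give this category
      span <- fc$start[j]:fc$end[j]
      span <- span[cats_pos[span] == cat_i]
      if (!length(span)) next
      runs <- split(span, cumsum(c(1L, diff(span) != 1L)))
      for (rn in runs) {
        coding <- count_dipyr_interval(g, rn[1], rn[length(rn)],
                                       dipyr_set, fc$strand[j])
        templ <- count_dipyr_interval(g, rn[1], rn[length(rn)], dipyr_set,
                                      if (fc$strand[j] == "+") "-" else "+")
        out$coding_dipyr[i] <- out$coding_dipyr[i] + coding
        out$template_dipyr[i] <- out$template_dipyr[i] + templ
      }
    }
    if (out$template_dipyr[i] > 0 && out$coding_dipyr[i] > 0) {
      if (out$template_count[i] + out$coding_count[i] > 0) {
        out$normalized_ratio[i] <-
          (out$template_count[i] / out$template_dipyr[i]) /
          (out$coding_count[i] / out$coding_dipyr[i])
      }  # no reads on either strand: ratio stays NA
    } else if (out$template_count[i] + out$coding_count[i] > 0) {
      warning("category ", cat_i, ": a strand has no di-pyrimidines; ratio NA")
    }
  }
  class(out) <- c("StrandReport", class(out))
  out
}

#' Write a coverage table / strand report as TSV
#' @param x A `CoverageTable` or `StrandReport`.
#' @param path Output path prefix (CoverageTable writes `<path>` for the
#'   genome table and `<path>` with `.regions.tsv` appended for categories).
#' @export
write_coverage <- function(x, path) {
  if (inherits(x, "CoverageTable")) {
    gt <- x$genomes
    gt$org_nuc_ratio <- x$org_nuc_ratio[gt$id]
    utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(x$regions, paste0(path, ".regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
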
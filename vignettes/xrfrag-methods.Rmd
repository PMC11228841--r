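---
title: "Methods: organellar XR-seq fragment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organellar XR-seq fragment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`xrfrag`. It is the package's reference for *why* each statistic is
computed the way it is; the README shows what a run looks like.

## The analysis problem

XR-seq libraries sequence the short single-stranded DNA fragments released
after UV damage: each read is (ideally) one excised oligonucleotide
containing a pyrimidine dimer, so the read population carries two signals —
the *length distribution* of the fragments and the *position of the dimer
within the fragment*. For organellar genomes two obstacles intervene.
First, nuclear genomes contain insertions of organellar DNA (NUMTs, NUPTs)
and plastid genomes contain a large inverted repeat, so a short read can
map equally well to several places; a read "mapping to the mtDNA" may in
truth be nuclear. Second, any positional signal must be judged against how
often the dinucleotide occurs in the genome at all — AT-rich organellar
genomes have high background TT frequency.

The package therefore decomposes the analysis into: reference editing and
uniqueness filtering (so that retained reads are unambiguous), spectra and
anchored profiles (the two signals), coverage accounting (where the
fragments come from), and a generator that plants all of these signals
synthetically so each stage can be checked against ground truth.

## Uniqueness, reference edits and weights

Duplicated reference sequence is handled before and after alignment:

* `remove_interval` deletes one copy of a duplicated span (the second
  inverted-repeat copy of a plastid genome; a nuclear NUMT that contains a
  full mtDNA copy). Coordinates are 1-based inclusive on the original
  genome, as duplicated-region coordinates are usually published; the
  edited genome records an invertible position map (`old_to_new()` /
  `new_to_old()`), and the internal representation converts to 0-based
  half-open arithmetic only inside interval code.
* `halve_count_interval` marks the retained copy: every fragment
  overlapping it carries weight 0.5 in all downstream counting (spectra,
  profiles, RPKM), because that single copy now absorbs the reads of both
  original copies. Weighting at the fragment level keeps every statistic
  consistent instead of patching coverage after the fact.

The internal aligner defines uniqueness *combinatorially*: it enumerates
every perfect full-length placement of a read on both strands of every
genome (origin-spanning placements on circular genomes included, counted
once) and keeps a read only when exactly one exists. A MAPQ threshold on an
external aligner's output is an approximation of exactly this criterion, so
for imported SAM/BAM the conventional MAPQ ≥ 30 rule is applied instead,
with mismatch counts taken from `NM` (recomputed against the reference when
absent). No indels are modelled: fragments are ≤ ~40 nt and the mismatch
filter discards imperfect alignments anyway.

Mappability is reported as the fraction of *covered* positions that remain
covered after filtering, per region category and in total
(position-weighted). Using covered-position sets rather than genome length
keeps the statistic about mappability, not sampling depth; a category never
covered in the unfiltered alignment is reported `NA`.

## The dinucleotide null and positional profiles

The null for TT enrichment is the genome-wide frequency of TT among
overlapping forward-strand dinucleotide windows; a circular genome
contributes one wraparound window (an O(1/L) correction kept for
consistency of circular semantics), and windows containing `N` are excluded
from numerator and denominator. Counting a single strand is a deliberate
convention: reads are single-stranded fragments scored in their own
orientation, and the single-strand count is the simplest null for "how
often would a random read position land on a TT". The reverse-complement
symmetry test (`freq(TT)` of a genome equals `freq(AA)` of its reverse
complement) pins the convention down. Whether an edited or unedited
reference is used for the null is the caller's choice; the pipeline uses
the genome it aligned to.

A dinucleotide position *p* means the pair occupying read positions
(*p*, *p*+1), 1-based on the read's 5′→3′ axis; a peak "at positions 7–8"
is *p* = 7. With `anchor = "three_prime"`, profiles of different length
classes are placed on a shared right-aligned axis by offsetting positions
by `L_max − L`, so a dimer at a fixed 3′ distance appears at one display
position in all classes. The 95% band is `p0 ± 2·sqrt(p0(1−p0)/n)` — the
normal approximation, used deliberately rather than an exact binomial
interval because it is the field's stated convention for these plots; `n`
is the number of reads in the class (weighted frequencies, unweighted `n`:
with halving weights the effective `n` is slightly smaller, so the band is,
if anything, slightly anti-conservative for IR-heavy classes). Length
classes below `min_reads` (default 100) are still reported but flagged,
mirroring the practice of profiling only abundant classes.

## Coverage conventions

* RPKM uses the full (edited-reference) length of the genome or category,
  never the mappable length; mappability is a separate report. "Total
  mapped reads" is the weighted sum over all genomes of the assembly, so
  compartments within one library are comparable.
* Fragments are assigned to region categories by their midpoint. This makes
  per-category counts a partition of per-genome counts (a testable
  conservation law), which bp-overlap apportionment would not.
* Overlapping annotations resolve by priority tRNA > rRNA > CDS > intron >
  intergenic — the smallest, most specific feature wins.
* A fragment is template-strand when its mapped strand is opposite the
  feature's annotated strand (the template is the strand RNA polymerase
  reads). Strand counts are normalised by the di-pyrimidine counts
  available on each strand within the category, by default TT only (the
  plotted dinucleotide), optionally all four di-pyrimidines; both
  conventions are exposed because published analyses are ambiguous on this
  point.

## The synthetic generator

`simulate_fragments()` emulates a damage-anchored fragment library:

* Damage sites are TT pairs, chosen uniformly among a uniformly chosen
  strand's TT sites. TT-only is the default because the positional analysis
  keys on TT; uniform site choice is the simplest null that recovery tests
  need (no sequence-context weighting).
* Two mechanisms share one geometry: `fixed_incision` (incisions 2/4/6...
  nt further 5′ of the dimer) and `five_prime_trim` (a primary fragment
  shortened from the 5′ end in `trim_step` steps). Both keep the dimer's
  distance to the 3′ end fixed at `dimer_offset_3p`, which is what makes
  right-aligned TT peaks coincide across length classes — the two
  mechanisms are intentionally indistinguishable from fragment geometry
  alone, and the generator exposes offset and step as free parameters
  rather than fixing one mechanism's interpretation.
* Reads are emitted in fragment orientation (5′→3′ of the excised strand),
  a literal 3′ adapter is appended, and the result is truncated to the
  sequencer read length (default 50 nt). No sequencing errors are simulated
  by default, isolating pipeline logic from error-model complexity.

Default study conditions (chosen once, as the package's model of a
yeast-like mitochondrial study at desk scale): a 20 kb circular
mitochondrial genome at AT fraction 0.83 (typical of yeast mtDNA), a 60 kb
linear nuclear chromosome at AT 0.64 carrying an exact 2 kb NUMT copy
(10% of the mtDNA), primary length 26 nt with `dimer_offset_3p = 19`
(TT at positions 7–8), trim step 2 nt with three steps (classes 26/24/22/20
at equal weight), 8,000 reads per compartment. Genome and library sizes are
scaled so every stage, including exhaustive alignment, runs in seconds to
a minute on one CPU; all statistics of interest are rate-like and stable at
these sizes (tests use 2,000–20,000 reads; mappability uses saturating
position-tiling read sets, which make the expected retained fraction an
exact interval-arithmetic quantity rather than a sampling estimate).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: PCR amplification bias against AT-rich stretches,
adapter-ligation and antibody sequence preferences, sequencing errors
(configurable but off by default), non-TT photoproducts (TC/CT/CC dimers),
context-dependent damage rates, and transcription-coupled repair structure.
Tests demonstrate that the *pipeline* recovers planted signals exactly; they
cannot certify that real libraries are free of those biases.

## Numerical and degenerate-input choices

* Adapter search takes the leftmost admissible start; a full-adapter
  occurrence always precedes any admissible 3′-suffix partial match, so the
  fast exact-substring path is consistent with the general scan. Reads with
  no adapter, or empty after trimming, are discarded and counted.
* Mismatch allowance is `floor(max_error_rate × aligned_length)`, applied
  per candidate start.
* `spectrum_correlation` works on the union of length bins with absent bins
  as 0 and refuses fewer than 3 bins.
* Degenerate inputs: empty compartments give empty spectra (total 0);
  empty length classes are errors at profile time; a strand with zero
  di-pyrimidines gives an `NA` ratio with a warning; a category with no
  reads on either strand gives `NA` without one.
* Linear-genome placements that would overrun an end are resampled and the
  resample count reported, so truth tables never contain clipped fragments.
* All simulators take an explicit seed and restore the caller's RNG state;
  the pipeline derives fixed substreams from one master seed, making every
  output byte-reproducible from (inputs, config).

## Known limitations

* The exact aligner is exhaustive and exact but only for perfect matches;
  it is not a general-purpose aligner and does not emulate aligner-specific
  MAPQ arithmetic beyond the uniqueness intent.
* `region_dinuc_counts` attributes a window to the category of its first
  position; category boundaries can therefore shift single windows between
  adjacent categories (a one-window effect at each boundary, accepted in
  exchange for exact partition behaviour).
* The confidence band treats reads as independent draws from the null;
  overlapping fragments from the same damage site violate independence in
  deep local pileups.
* Real reference constants (published genome-wide TT frequencies for
  specific accessions) require those reference FASTA files; the package
  computes them from any user-supplied FASTA but does not bundle genomes.
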
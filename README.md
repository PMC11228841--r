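# xrfrag

Analysis of organellar XR-seq excision fragments in R.

XR-seq captures the short, damage-containing DNA oligonucleotides that cells
release after UV exposure: fragments are immunoprecipitated with
anti-photoproduct antibodies, sequenced, and mapped back to the genome,
giving single-nucleotide maps of where cyclobutane pyrimidine dimers (CPDs)
were excised. Reads originating from mitochondrial and plastid genomes are
biologically puzzling — organelles are thought to lack nucleotide excision
repair — and they are also technically treacherous: nuclear insertions of
organellar DNA (NUMTs/NUPTs) and the large plastid inverted repeat make
short reads map ambiguously between compartments. `xrfrag` is for
researchers who want to analyse the organellar fraction of XR-seq libraries
(or emulate one end-to-end): it provides the uniqueness-aware filtering,
the read-length and positional di-pyrimidine statistics, and the
region/strand coverage accounting that such an analysis needs, plus a
synthetic-data generator with full ground truth so every stage can be
validated without touching external data.

## What it computes

**Multi-copy handling.** References are edited before alignment:
`remove_interval` deletes a duplicated span (second inverted-repeat copy, a
large NUMT) and keeps an invertible coordinate map; `halve_count_interval`
marks the retained copy so every read overlapping it counts with weight
1/2. Uniqueness is combinatorial: the internal exact aligner enumerates
*all* perfect placements of a read on both strands of all genomes (circular
genomes include origin-spanning placements), and a read is kept only if it
has exactly one. SAM/BAM imports use the conventional MAPQ ≥ 30 rule
instead. Mappability is then reported as the fraction of covered positions
that survive filtering, per region category.

**Positional di-pyrimidine statistics.** For a read-length class *L*, the
frequency of TT (and TC/CT/CC) at each pair of read positions
(*p*, *p*+1) is compared with the genome-wide null

> p̂₀ = (number of TT windows) / (number of dinucleotide windows)

counted over overlapping forward-strand windows of the organellar genome
(circular genomes contribute one wraparound window). The 95% band around
the null is approximated as

> p₀ ± 2·√(p₀(1 − p₀)/n)

for *n* reads, and a position is called enriched when its observed
frequency exceeds the upper bound. Profiles can be anchored at the 5′ or 3′
end; 3′-anchoring puts all length classes on a shared right-aligned axis,
which is how a dimer at fixed distance from the 3′ end shows up as a single
aligned peak across classes.

**Coverage.** RPKM = reads / (length/1000) / (total/10⁶) per genome and per
region category (intergenic, CDS, intron, rRNA, tRNA; midpoint assignment,
priority tRNA > rRNA > CDS > intron), the organellar/nuclear RPKM ratio,
and template-vs-coding strand coverage normalised by each strand's
di-pyrimidine availability.

**Synthetic libraries.** `simulate_fragments()` plants TT-anchored
fragments under two mechanisms that produce identical 3′ geometry — direct
incisions at varying 5′ distances, or 5′ trimming of a primary product —
with configurable primary length, trim step, dimer offset and length
weights, then appends a 3′ adapter and emits FASTQ plus a ground-truth
table.

## Worked example

The `analysis/` scripts run the whole study on a synthetic fixture
(a 20 kb AT-rich circular mitochondrial genome; a 62 kb nuclear chromosome
carrying an exact 2 kb NUMT; 16,000 reads under the 5′-trimming model):

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_filter.R 1
Rscript analysis/03_profiles.R 1
Rscript analysis/04_coverage.R 1
```

Stage 2 prints the mappability report (the NUMT-shadowed portion of the
mtDNA drops out; annotation categories that happen to overlap it lose
more):

```
trimming: 16000/16000 reads retained (0 untrimmed discarded)
alignment: 16000 mapped, 14832 unique; filter removed 1168 multimapping, 0 mismatched
   category covered_unfiltered covered_filtered fraction_retained
 intergenic               8905             8242         0.9255474
        CDS               8589             7891         0.9187333
      total              19911            17948         0.9014113
```

about 90% of the mitochondrial genome remains mappable after removing
multimapping reads — the planted 2 kb NUMT (10% of the genome) accounts
for the loss. Stage 3 recovers the planted dimer geometry:

```
DinucProfile: L=26, three-anchored, 1800 reads; TT argmax at p=7 (1.0000 vs null 0.1686 +/- 0.0176)
DinucProfile: L=24, three-anchored, 1809 reads; TT argmax at p=5 (1.0000 vs null 0.1686 +/- 0.0176)
DinucProfile: L=22, three-anchored, 1863 reads; TT argmax at p=3 (1.0000 vs null 0.1686 +/- 0.0173)
DinucProfile: L=20, three-anchored, 1753 reads; TT argmax at p=1 (1.0000 vs null 0.1686 +/- 0.0179)
right-aligned TT argmax per class: 26nt=7, 24nt=7, 22nt=7, 20nt=7
```

the TT peak sits at read positions 7–8 in the primary 26-nt class and
shifts forward by exactly the trimmed amount in the shorter classes, so all
classes coincide on the right-aligned axis — the signature of a dimer at a
fixed distance from the fragment 3′ end. Stage 4 reports RPKM per genome
and the organellar/nuclear ratio (`org/nuc RPKM ratio: 2.94` for this
mixture: equal read numbers over a 3.1-fold genome-length difference).

The same workflow is available as one call: `run_pipeline(default_config())`.

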
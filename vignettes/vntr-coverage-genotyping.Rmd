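---
title: "Spanning-read coverage and repeat-count genotyping QC for VNTRs"
author: "vntrspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spanning-read coverage and repeat-count genotyping QC for VNTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrspan)
```

# The problem

Variable Number Tandem Repeats (VNTRs) — tandem arrays whose repeat
unit is at least 6 bp — are accurately genotyped only from reads that
span the entire array plus flanking sequence: inside the array, a
non-spanning read cannot anchor its position, and the repeat count is
undetermined. Long, accurate reads make spanning feasible, and two
sequencing designs compete: targeted hybridization capture (very deep
coverage where probes work, with strong GC- and probe-distance-driven
dropout) and whole-genome sequencing (uniform but shallow). `vntrspan`
provides the analysis layer for this comparison: catalog curation,
spanning/reliable read counting, a principled minimum-coverage
threshold, a simplified repeat-count caller with support filters, and
genotype-concordance and trio-consistency evaluation — together with a
deterministic synthetic-data generator so the whole pipeline is
verifiable end to end without external cohorts.

# Models and procedures

## Catalog curation

Candidate loci come from Tandem Repeats Finder output or BED. Curation
retains a locus when **all** of the following hold, applied in a fixed
order so each exclusion has exactly one attributable reason:

1. consensus motif length ≥ 6 bp (shorter units are STRs);
2. no overlap with annotated LINE/SINE elements;
3. no overlap with segmental duplications (reads recruited to a
   duplicated locus may originate elsewhere);
4. gene proximity: overlap with a gene body, or lying in the promoter
   window upstream of a transcription start site (`tssFlank` = 500 bp);
5. autosomal chromosome (optional).

The exclusion-interval rule is *any overlap* (≥ 1 bp); full containment
is available via `containment = TRUE`. We read the promoter criterion
strand-aware — the locus start within `[TSS − 500, TSS)` for plus-strand
genes, mirrored for minus strand — because upstream regulatory sequence
is a stranded notion; both choices are exposed. Annotation labels
(`exonic`, `utr`, `intronic`, `promoter`, `multiple`) use the precedence
exonic > utr > intronic, with `multiple` reserved for loci spanning both
exonic and intronic sequence.

GC content is computed over the locus ± 100 bp of flank: capture
efficiency is a property of the hybridized fragment, not the array
alone. N bases leave the denominator; an all-N window yields `NA`
rather than 0 (a window with unknown sequence has unknown GC).

## Spanning and reliable reads

A read **spans** a locus when its reference-aligned interval strictly
contains the array — at least one aligned base on each side. The
definition deliberately has no minimum flank: flank quality is handled
by the second, stricter tier. A spanning read is **reliable** when its
alignment covers ≥ 10 bp of reference on each side of the array and
each flank separately aligns with ≥ 95 % base identity (deletions count
as mismatches). The identity denominator is the flank window the read
actually covers, capped at 100 bp per side; with exactly 10 bp
available, 95 % forces a perfect flank (⌈9.5⌉ = 10 matches). The cap
makes the filter a *local* anchoring test rather than a global mapping
quality, which the aligner already enforced. Secondary and
supplementary alignments are ignored; duplicates are kept, since
long-read protocols lack duplicate marking.

Coverage tiers use the cross-sample median of spanning counts:
`uncovered` (0), `low` (< 15), `well_covered` (≥ 15) and `high` (≥ 63).
The 15-read boundary is the genotyping threshold derived below; 63
marks the deeply-covered stratum a successful capture produces.
Cross-sample homogeneity is the *population* variance of counts
projected to 30 (values above 30 are set to 30): the projection asks
"is the locus consistently well covered" without letting a single
2000× capture blow up the variance. The median over an even number of
samples is the mean of the central pair.

## The spanning-read threshold

With `n` spanning reads over a heterozygous locus, no allele dropout,
and each read drawn from either allele with probability ½, the caller
collapses to homozygous when one allele receives ≤ 2 reads. The miscall
probability is the binomial union

$$P_{err}(n) = P(x \ge n-2 \;\mathrm{OR}\; x \le 2), \quad
x \sim \mathrm{Binomial}(n, 1/2),$$

which for $n \ge 6$ reduces to the exact rational
$2\sum_{i=0}^{2}\binom{n}{i}/2^n$; for $n \le 5$ the two tails overlap
and the union saturates at 1 (it is written as a probability of a
union, not a sum). `perr()` uses exact integer arithmetic, converting
to floating point only at the boundary. $P_{err}(14) = 212/16384
\approx 0.013$ and $P_{err}(15) = 242/32768 \approx 0.0074$, so
`minSpanningThreshold(0.01)` = 15 — the smallest count with a miscall
probability below 1 %. An allele-balance parameter generalizes the ½
(capture could skew sampling), but ½ is the default and the reference
case.

## The STR-like motif score

Some consensus motifs are themselves near-perfect tandem repeats of a
shorter unit (`AAAAGA` ≈ 5×A + G). At such loci two genotypers can
disagree on the repeat decomposition while agreeing on the sequence, so
they are excluded from consistency analyses. The score masks up to
$k$ motif positions (a masked position matches anything on either side
of a comparison), concatenates the masked motif $M'$ with itself into
$M''$, and takes the maximum over mask sets and window offsets
$o = 1..n-1$ (skipping the two trivial identity offsets) of
$(n - d_H(M', M''[o..o+n-1]))/n$. Both copies of $M'$ inside $M''$
inherit the mask. The budget is $k = \lceil n/10 \rceil$ for motifs up
to 40 bp and 1 beyond, keeping the exhaustive search cheap for long
motifs; mask sets of size *up to* $k$ are searched, and the
implementation's branch-and-bound (each mask can repair at most two
mismatches per offset) is exactly equivalent to naive enumeration, which
the test suite asserts against an independent oracle.

Worked values: homopolymers and rotations of perfect repeats score
1.0; `AAAAGA` scores 1.0 (mask the G); `GGCCTG` scores exactly 5/6 —
masking the T at offset 1 leaves a single residual mismatch — and
`ACGTGG` scores 4/6. Note that under these masking semantics any 6-bp
motif one substitution away from a perfect internal repeat scores at
least 5/6; a cutoff of 0.8 with strict `>` therefore discards `GGCCTG`
as well. The defining property of the score is the *ranking* (near-
perfect internal repeats above structureless motifs), and the cutoff is
a tunable argument everywhere it is used. Scores are exact rationals
$m/n$; the discard comparison is strict.

## Genotype calling and its filters

The repeat-count estimator is deliberately simple and clearly a
stand-in for a full HMM genotyper: for a reliable spanning read, count
the read bases aligned between the two flank anchors (the last aligned
base before the array and the first after it; insertions attached to
either array boundary count as array sequence), divide by the motif
length, and round half-away-from-zero. It is deterministic and robust
to where the aligner left-shifts repeat-count indels, but it does not
model motif-level substructure — which is exactly why STR-like loci
are filtered before consistency analyses.

Calling: repeat counts with fewer than 3 reliable supporting reads are
discarded (the accuracy filter — a second allele supported by 1–2
erroneous reads must not produce a heterozygous call). No surviving
count is a no-call; one is a homozygous call; otherwise the two
best-supported counts are called, support ties breaking toward the
smaller count (deterministic, and small counts are the more common
allele in practice).

Consistency between two read sets of the same sample is three-valued:
`consistent` (identical sorted pairs), `partially_consistent` (pairs
differ, exactly two unique alleles in the union, at least one call
heterozygous — the signature of one allele lacking spanning reads on
one side), and `inconsistent` (anything else, e.g. (2,5) vs (2,7) or
(2,2) vs (4,4), which missing reads cannot explain). No-calls are
`not_comparable` and leave every denominator. A trio call is
Mendelian-consistent when the child pair admits one allele from each
parent; loci without complete trio calls leave the denominator, and the
summary optionally restricts to catalog loci, arrays < 150 bp
(short-read regime), and motifs passing the STR-like filter.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions the rest of the package is validated under. Each locus
occupies its own neighborhood on a synthetic contig: 1 kb unique flanks
around a perfect array (motif × reference repeat count, motif lengths
6–30 bp, repeat counts 3–15). Locus GC alternates between 0.45 and
0.70 so the catalog straddles the 0.60 capture knee. A 120-bp probe is
placed at a configurable gap from each array. Decoy loci inside labeled
segmental-duplication or LINE intervals and on chrX exercise curation.

Individuals are diploid; 76 % of loci are non-polymorphic (all samples
homozygous for the reference count) and founder haplotypes elsewhere
are uniform over the repeat-count range. Trio children draw one allele
from each parent uniformly; a de-novo knob replaces a transmitted
allele with a non-parental count, for negative controls.

Reads are emitted **pre-aligned** at their true coordinates as plain
SAM (consumed through the same Rsamtools/GenomicAlignments path as any
BAM): repeat-count differences appear as a single insertion or deletion
at the array's 3′ end, substitution errors are planted at the HiFi-like
default of 0.2 % (indels off by default), and read lengths are
log-normal with median 4,200 bp (targeted) or 18,000 bp (WGS),
truncated to the locus neighborhood — the generator models per-locus
sampling, not whole-molecule fragmentation. Targeted capture thins the
expected per-locus depth by
`floor + (1-floor) · logistic(gc) · logistic(probe distance)` with
knees at GC 0.60 and 1 kb; a zero slope disables a component, and WGS
mode is unbiased by construction. Every output is bit-reproducible
under the seed, and a sidecar table records each read's sample, locus,
haplotype, allele and spanning status — with substitutions at 0, the
pipeline's spanning counts must (and do) equal this truth exactly.

What the generator does *not* emulate: PCR stutter, chimeric reads,
motif-sequence polymorphism within arrays, recombination, reference
bias from real aligners, and capture chemistry beyond the logistic
dropout shape. Passing tests therefore demonstrate the correctness of
the counting, thresholding and classification logic under a clean
error model — not aligner robustness on real data.

# Numerical and design choices

* Coordinates are 1-based closed internally (GRanges); BED converts at
  the boundary. Locus identifiers use the BED convention
  (`chrom:start-end`, 0-based start) for portability.
* `perr` is exact; the Monte-Carlo check in the test suite uses 10⁵
  fair-coin trials per n within three standard errors.
* Rounding of repeat-count estimates is half-away-from-zero
  (`floor(x + 0.5)`); the generator's indel placement avoids
  half-integer cases by construction.
* The projected-variance convention is population variance (divide by
  the number of samples), since the samples are the complete panel
  under comparison, not a sample from a larger one.
* Raw spanning counts (not per-million-normalized) feed the
  30-projection, matching the homogeneity heat-map convention.
* Empty flanks, all-N windows, contig-edge truncation and no-call
  pairs each have explicit, tested behavior (`NA`, never silent 0).
* Pipeline problem sizes in the shipped tests are deliberately desk
  scale (tens of loci, 1–4 samples, depth 10–40, 100 bias replicates);
  all stages scale linearly in reads × loci.

# Known limitations

The repeat-count caller assumes clean flank anchoring and integer
repeat counts; partial-motif alleles round. The capture-dropout model
is a two-knee logistic chosen to reproduce the qualitative quadrant
structure of targeted data — its parameters are configuration, not
claims about chemistry. Genotype concordance between two read sets of
the same synthetic individuals shares the simulator's error model, so
concordance numbers on synthetic data are upper bounds on what mixed
real platforms would show.
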
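---
title: "Methods: post-assembly analysis of a clonal diploid transcriptome"
author: "anemone package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-assembly analysis of a clonal diploid transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anemone)
```

# Scope and model

This package implements the computational layer that sits between a de novo
short-read transcriptome assembly of a clonal diploid animal and the
biological statements one wants to make from it: how heterozygous the
animal is, how its variants are distributed over substitution classes, how
large its genome is, how trustworthy the contigs are, and whether the
transcripts encode neuropeptide precursors of the GLW-amide family. The
assembly itself (and all similarity-based annotation) is out of scope; the
package starts from contigs, reads and alignments.

Two facts about the biological setting drive the design. First, the animal
is **clonal**, so every "variant" is a site of heterozygosity between the
two haplotypes of one genotype and is expected at an allele fraction near
0.5 in genomic reads. That justifies the simple threshold caller: at depth
$d \ge 10$, a site is heterozygous when the leading non-reference base
reaches at least $0.35\,d$. A binomial argument shows why these floors
work: at depth $d$, a true heterozygous site fails the 35% rule with
probability $P[\mathrm{Bin}(d, 0.5) < 0.35 d]$, which is about 5% at
$d = 30$ and under 1% at $d \ge 50$, while sequencing errors (well under
1% per base, spread over three alternative bases) essentially never reach
35% of a site at $d \ge 10$.

Second, the reference being mapped against is a **transcriptome embedded
in a genome**: genomic reads run off transcript ends into introns and
UTR-adjacent sequence. Two consequences are wired in: alignment validity
only requires 40% of the read to align (a read straddling an exon-intron
boundary still counts, as long as the aligned part agrees at >= 96%), and
the read simulator pads transcripts with random flanking context before
sampling (below).

# The pipeline stages and their parameters

| Stage | Function(s) | Key parameters (defaults) |
|---|---|---|
| read cleaning | `collapseDuplicates`, `qualityTrim`, `lengthFilter` | prefix 30 bp; Q floor 10 (inclusive); length floor 45 bp (inclusive) |
| hairpin repair | `detectHairpin`, `splitHairpin`, `repairHairpins` | min arm 100 bp; min identity 0.95; 200 bp product floor |
| alignment validity | `isValidAlignment` | aligned fraction >= 0.40 of read length; identity >= 0.96 (both inclusive) |
| pileup + calling | `buildPileup`, `callVariants` | depth >= 10; alt fraction >= 0.35 of site depth (both inclusive) |
| genome sizing | `contigMeanCoverage`, `modalCoverage`, `estimateGenomeSize` | integer-rounded per-contig means; ties to the lower mode |
| pair concordance | `pairConcordance` | identity floor 0.90; co-optimal tie window 0.005 |
| GLW scanning | `findOrfs`, `scanGlwPrecursors`, `predictMaturePeptides` | min ORF 60 aa; min 3 motifs |

All of these are exposed as arguments; the defaults are the operating
point the package is built around.

# Design decisions in detail

**Coordinates.** All internal and reported coordinates are 1-based closed,
the R/Bioconductor convention (IRanges, GRanges, VCF POS). Conversions to
0-based systems happen only in the caller's head.

**Quality trimming as longest clean window.** The trimming contract
constrains the *result* — no surviving base below Q10, no N — not the
procedure. We therefore return the longest contiguous window satisfying
the constraint (leftmost on ties) rather than trimming only from the
ends. The brute-force recount oracle in the tests enforces exactly this
definition per read.

**Duplicate collapsing.** Full duplicate-collapsing pipelines cluster
reads with error tolerance; we implement the contract (one representative
per family with improved qualities) with an exact prefix signature
(default 30 bp, both mates for pairs), per-position majority consensus
(ties by summed quality, then alphabetically) and per-position maximum
quality. Collapsing is idempotent and conserves read counts.

**Hairpin detection.** No published criterion exists for calling a contig
a hairpin, so the scan is defined from first principles and fully
parameterised: for each candidate apex $k$ the suffix starting at $k+1$
is compared un-gapped with the reverse complement of the prefix ending at
$k$; the call is the longest arm whose running identity stays at or above
the floor, apex ties broken toward the lower coordinate. For random DNA
the probability that a >= 100 bp arm reaches 95% identity is
astronomically small (matching probability 0.25 per position), so false
calls on honest contigs are not a practical concern; the tests verify
this empirically.

**Alignment engine.** The paper-scale pipeline treats read mapping as an
input, the way the original analyses used external mappers. The package
still ships a deterministic seed-and-extend mapper (`alignReads`: exact
k-mer seed at read start/middle/end on both strands, un-gapped full-extent
extension, leftmost-first tie-breaking) that is exact on the data it is
used for — genomic reads against a haploid reference and clone-end reads
against their source contigs — and is checked against a Smith-Waterman
dynamic-programming oracle on small instances. Reads against a *diploid*
simulation are projected through the generator's truth
(`truthAlignments`), which produces exactly the gapped block alignments
an ideal mapper would emit, including clipping in the padded flanks and
insertion/deletion gap openings; sequencing errors still lower identity
naturally, so the validity filter acts on realistic inputs.

**Variant calling choices.** The alt fraction uses total site depth as
denominator (the most literal reading of "35% of the reads at that
site"), boundaries are inclusive, multi-allelic sites consider only the
top alternative base (ties alphabetical), and sites where the reference
itself drops below 35% are reported once and flagged `refMinority` rather
than as two variants. Indels are called from gap-opening counts at their
left-flanking position, with the most frequent event at the site as the
reported allele; sizes are histogrammed 1..8 with an overflow bin.

**Genome sizing.** Per-contig means are rounded to the nearest integer
before taking the mode, zero-coverage contigs are excluded, and ties go to
the lower value — the binning the headline "modal coverage ~24x" language
implies. The estimate divides *total* sequenced genomic bases (mapped or
not) by the modal coverage. The estimate is scale-equivariant: doubling
every read count doubles both numerator and mode and leaves it fixed.

**Concordance categories.** "Maps to one and only one contig" is only
well defined once co-optimal hits are handled: all alignments within 0.5%
identity of a read's best are treated as its hit set (the window is a
parameter). Unique-unique pairs are concordant when the shared contig is
hit in opposite orientations; multi-mapping pairs when at least one contig
is. Percentages are integer-rounded (half up) from their integer counts.

**Peptide grammar.** Cleavage is placed C-terminal to the basic residue
(K/R) nearest the motif on each side. We deliberately do not implement a
separate preference for dibasic sites: the C-side member of a dibasic site
*is* the nearest basic residue whenever one is present, and cutting at
anything other than the nearest basic would leave a basic residue inside
a mature peptide. X-Ala/X-Pro dipeptides are trimmed iteratively from the
N-terminus, with one biochemical guard: a leading glutamine cyclises to
pyroglutamate, which blocks dipeptidylaminopeptidase — so trimming stops
at Q. (Without this guard, any mature peptide beginning Q-P — the
pyroglutamate peptides the scan exists to find — would be destroyed by
its own maturation.) Motifs with no flanking basic residue, or whose
excised fragment does not end at the motif core plus donor glycine, are
skipped with a warning rather than emitting malformed peptides.

# What the simulator emulates — and what it does not

`simulateDiploidTranscriptome` generates reference contigs with a
log-normal length law (floor 200 bp, median ≈ 450 bp, mean ≈ 770 bp,
cap ≈ 13 kb — the shape of a short-read transcriptome assembly), and a
haplotype pair: A equals the reference; B carries heterozygous SNVs at
1/808 per bp with transitions:transversions 1.6:1, and indels at the rate
implied by ~8,700 indels per 44.7 Mb, with sizes 1–8 bp at monotonically
decreasing frequency. Indels are planted only on haplotype B and at least
100 bp (one read length) from contig ends, so indel recovery is scored
away from coverage edge effects. All generators are pure functions of
their arguments and the seed.

`simulateGenomicReads` defines **coverage as fold-coverage of the
haplotype set**: total emitted read bases ≈ coverage × summed haplotype
length, reads split equally between haplotypes, so a diploid pair at
coverage 30 yields read depth near 60 on the reference — the natural
accounting when each haplotype is an equally sequenced molecule. Each
haplotype sequence is padded with random flanking sequence (default one
read length per side) before sampling: this emulates genomic reads running
off transcript ends and keeps read depth flat across the contig, as it is
in real genomic-versus-transcriptome mapping; without the pad, depth would
ramp to zero at contig ends and edge sites would be systematically
uncallable in a way real data does not exhibit.

Not emulated: quality-score decay along reads (qualities are constant
Q40; trimming behaviour is tested on explicitly crafted reads instead),
sequencing indel errors, GC or amplification bias, paired-end inserts for
the short-read libraries, contamination, and expression-level variation.
Passing the recovery tests therefore demonstrates that the *computational
contracts* are correct at realistic scales and rates — not that the
thresholds are optimal for any particular instrument's error profile.

# Numerical and degenerate-input conventions

* Rounding for report tables is half-up (`770.45 -> 770`, `32.06% -> 32%`);
  the mode uses R's `round` on means before tabulation.
* Zero SNVs make the density *undefined* (NA), never infinite.
* An empty contig set (or all contigs below the 200 bp floor) is an error
  for `assemblyStats`; all-zero coverage is an error for `modalCoverage`.
* FASTQ is Phred+33 only; IUPAC codes other than N are rejected at input,
  because pileup counting assumes {A,C,G,T,N}.
* `detectHairpin` returns `NULL` (no call) for contigs shorter than twice
  the minimum arm; `injectHairpin` with arm 0 is the identity.
* Read Ns contribute to no pileup base count and therefore to no call.

# Problem sizes used in the checks

The test suite scores parameter recovery on a 2 Mb simulated diploid
transcriptome at coverage 30 with 0.5% base errors (SNV recall/precision,
density, transition fraction), genome-size recovery on a 5 Mb genome with
a 40% transcribed fraction at 20x, hairpin round-trips over 100 random
contigs, and read-cleaning recounts over 10,000 crafted reads; these sizes
give stable statistics (thousands of planted SNVs) while keeping a full
run in the single-digit minutes on one CPU. Unit tests use miniature
versions of the same constructions.

# Known limitations

* The caller is a threshold rule, not a genotype-likelihood model; it is
  the right tool for deep clonal data and the wrong one for low coverage
  or pooled samples.
* The built-in mapper is un-gapped by design; reads spanning
  reference-relative indels need an external mapper (or the simulator's
  truth projection). Spliced alignment is out of scope.
* Hairpin arms are compared un-gapped and must abut at the apex; hairpins
  with long loops or indel-divergent arms are not detected.
* `pairConcordance` checks orientation only, not insert-size consistency.
* The GLW scanner targets one neuropeptide family; it is not a general
  precursor predictor and does no signal-peptide modelling.
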
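---
title: "Models and methods behind plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastidkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plastidkit analyses plastid genomes sequenced at high depth with long,
homopolymer-error-prone reads. This vignette explains the models each
module implements, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the problem left the design open.

## The quadripartite genome model

A plastid genome is a circle partitioned into a large single-copy region
(LSC), a small single-copy region (SSC), and two identical inverted
repeats (IRa, IRb) separating them; IRa is the exact reverse complement
of IRb. The four junctions are named JLB (LSC–IRb), JSB (IRb–SSC), JSA
(SSC–IRa) and JLA (IRa–LSC). All genomes are stored linearized with the
origin at the JLA→LSC junction (LSC first), and every reported
coordinate is 1-based inclusive; intervals are handled 0-based half-open
internally only within tight loops.

`detect_quadripartite()` finds the maximal-length exact inverted-repeat
pair of at least `min_ir_len` (default 1,000 bp, well above incidental
inverted repeats and well below real plastid IRs of 20–28 kb) on the
circle; the search runs on the doubled sequence so an IR crossing the
origin is still found, and duplicate hits from the doubling are reduced
modulo the genome length. The larger single-copy gap is labelled LSC, and
IRb is the copy first encountered downstream of the LSC end. A genome
without a qualifying IR yields a "not found" layout object rather than an
error, since that is an answer, not a failure.

## The synthetic-data generator

The generator is the testbed for every downstream stage; its defaults are
the study conditions of the reference genome: LSC 86,198 bp, SSC
17,712 bp, IR 27,276 bp, genome-wide A+T fraction 0.63. Background
sequence is i.i.d. with the A+T split evenly between A and T; single-base
runs longer than `max_background_run` (default 6) are broken so that
planted homopolymers are the only runs reaching the inventory threshold
of 7. Planted features (genes, operons, homopolymer runs, repeat pairs,
stem-loops) are placed in the LSC without overlap, keeping a margin from
the junctions; every feature's final coordinates are recorded in truth
tables. Two details matter for exact round-trips: feature flanks are
adjusted so planted repeats and stems are *maximal* (a mismatch-dense
flank pins down the mismatch-tolerant maximality definition), and the
junction-adjacent bases are adjusted so the planted IR pair cannot be
extended by chance complementarity — otherwise detected region lengths
would drift off the specification by a base or two.

Read simulation emulates GS FLX pyrosequencing: read lengths normal
around 380 bp (sd 40), uniform positions on the circle with wrapping,
both strands. The characteristic error is a homopolymer length miscall:
for a run of length $L \ge 4$ within a read, the run length is changed by
±1 with probability $\min(0.9,\, r\,(L-3))$, with rate $r$ (default
0.02); the literature describes the failure mode but no quantitative
model, so this linear-in-length form was chosen once as a reasonable
monotone model and not revisited. Substitution errors are uniform
(default 0.002/bp) and Phred qualities decay linearly from a mean of Q30
across the read (Phred+33 in FASTQ output). Depth is a required argument
rather than a default: nominal coverage figures reported for such datasets
are often not internally consistent with read counts and lengths, so the
simulator treats coverage as free. Heteroplasmy is injected per covering
read with the specified minor fraction (at most 0.5), so observed minor
counts are binomial.

The cDNA simulator draws a gene by relative abundance and then a read
overlapping that gene uniformly from its transcription unit's genomic
span, so reads cross gene junctions within an operon. A gene with a
genomic A-run of at least `enrich_min_a` (default 15) bases within
`enrich_window` (default 200) bp upstream in transcription orientation is
over-sampled by `enrichment` (default 50) — the polyT-priming artifact.
The generator does not emulate flowgram-level noise, paired ends, RNA
secondary structure, or transcription start/stop biology; tests passing
on it show the *detectors* are correct under the stated error model, not
that the model captures every property of real runs.

## Read mapping and assembly

The internal mapper is seed-and-extend: exact 15-mers at five positions
across the read vote for a diagonal; the gapless placement is accepted at
≥0.95 identity; otherwise a stepwise aligner walks the read, deciding at
each mismatch between substitution, 1-bp deletion or 1-bp insertion by a
12-bp lookahead — an $O(L)$ procedure matched to isolated
homopolymer-length miscalls; reads that still fail fall back to full
dynamic programming (`Biostrings::pairwiseAlignment`) on a padded window.
Insertions are left-normalized against the reference so equivalent
placements of the same event group together.

Contig elongation is end-anchored consensus extension: reads carrying the
contig's terminal `min_overlap` (default 40) bases vote per position on
the extension. Two guards depart from a bare majority vote, and both were
forced by failure modes the simulations expose. First, a column must
reach near-unanimity (90%): at the exit of a large repeat — the IR — the
anchored reads split between the two repeat copies, and a bare majority
walks a chimeric path; a split vote halts the end instead, mirroring the practice of confirming IR junctions
independently (e.g. by PCR product sequencing). Second, a column must be covered by at least 30% of
the anchored reads: at the tip of an extension only the few longest reads
vote, and with indel-bearing reads a tiny shifted family can reach
unanimity by chance. Contigs whose ends overlap by `min_overlap` at
`min_identity` (default 0.98) are merged; a contig whose own ends overlap
is closed as circular, verifying a bounded window around the anchor
(3 × `min_overlap`) rather than the whole duplicated stretch, which
consensus indels can throw out of register. Closed circles are
canonicalized to the reference rotation when one is given, else to the
lexicographically minimal rotation over both strands.

Read screening keeps a read iff its best seeded alignment to any
reference reaches `min_identity` (default 0.90) over `min_cov` (default
0.80) of the read; the thresholds are exposed because the original
screening criteria were not stated.

## Repeats and small inversions

Repeat discovery is REPuter-style: maximal repeat pairs (forward and
inverted) of at least 30 bp with at most 3 substitutions (no indels).
The engine works per diagonal: one vectorized comparison yields the
mismatch positions, from which all maximal ≤`max_mismatch` windows are
enumerated; terminal mismatches are trimmed so a hit never starts or ends
on one, containment-redundant hits are suppressed, and each pair is
reported once with `start1 < start2`. The production finder uses q-gram
filtering: any qualifying hit carries, within each of its windows of the
minimum length, a guaranteed number of exact seeds of length
$\lceil (L_{\min}-m)/(m+1) \rceil$ on its diagonal (pigeonhole), so only
bounded regions around such seed clusters are scanned, and a scanned
slice is widened whenever a reported window could be truncated at its
edge; when the seed guarantee drops below 5 bp the finder scans every
diagonal instead. The test suite holds the finder equal to an
independently formulated brute-force oracle on 120 sequences. Because
maximality is mismatch-tolerant, the genome-scale IR pair is maximal a
few bases *past* the exact IR boundaries; callers masking the IR should
pad the exclusion intervals accordingly.

Small inversions are short stem-loops: a perfect (by default)
inverted-repeat stem of 11–24 bp flanking a loop shorter than 50 bp.
Three filters run in order: geometry; stability, using the surrogate
hairpin score $-(3\,\mathrm{GC} + 2\,\mathrm{AT}) + \lambda \max(0,
\mathrm{loop}-4)$ with $\lambda = 0.5$ and threshold $-10$ — a
calibration chosen so that 13-bp mixed stems pass and very short stems
fail, standing in for a thermodynamic folding energy without claiming its
units (whether folding should be scored as DNA or RNA is moot for a
rank-order surrogate); and comparator homology at ≥90% identity over the
SI span, recording the loop orientation per comparator. Candidates
failing only the homology filter are returned separately as putative
rather than dropped. Every reported SI satisfies
$\mathrm{end}-\mathrm{start}+1 = 2\,\mathrm{stem} + \mathrm{loop}$. The
reported SI length range in the literature (5–50 bp) conflicts with its
own 63-nt example; the loop bound is treated as the binding constraint
and the total length left free.

## Codon statistics

CDS extraction concatenates exons in annotated rank order — not genomic
order — reverse-complementing minus-strand parts, which handles both
ordinary introns and trans-spliced genes whose parts sit on both strands.
Pseudogenes are excluded; records with length not divisible by 3 are
flagged, not dropped. Counting uses the plastid/bacterial genetic code
(table 11), where Met and Trp are single-codon families (RSCU ≡ 1 when
present). Stop codons are counted and included in the denominator of
amino-acid percentages — required to reproduce published values such as
2001/22,950 = 8.72% — while their RSCU is reported as 0 by table
convention. The internal alphabet is DNA (T); reports render U. Rounding
is half-away-from-zero at 2 decimals for RSCU and 1–2 for percentages, to
match printed tables. Positional base composition is the count-weighted
A+T (A+U) share at each codon position.

## Heteroplasmy calling

The pileup keeps a base iff its Phred quality exceeds 20 (strict), and a
read gapped at a locus is tallied separately and removed from that
locus's depth. A SNP call requires: quality-passing, gap-free depth
strictly above 50; at least two observed genotypes; the largest minor
genotype strictly above 10% — computed over the two reported genotypes
only, which is what reproduces printed percentages like 863(124) →
87.4(12.6); and the locus outside the homopolymer mask. The mask covers
runs of ≥5 bases plus one flanking base on each side: the published rule
says only "overlapping homopolymer runs" and motivates it with
artifactual minor genotypes at run edges, so the run threshold and flank
are exposed as parameters. Thresholds are strict inequalities, following
the wording "above 50" and "above 10%". Ties between top counts resolve
to the lexicographically smaller base and are flagged ambiguous. Codon
effects are classified on the coding strand at the CDS offset:
synonymous, nonsense (minor codon is a stop) or nonsynonymous, with the
variant position upper-cased in rendered codons (`acC`/`acT`). Insertion
calls group identical left-normalized insertion strings seen in at least
two reads and report carrier versus non-carrier counts. The genotype
comparison maps each CDS call through a global pairwise alignment to the
orthologous CDS and reports swap (comparator base equals the minor
allele), no-swap, or a third state; pairs under 60% identity are skipped
with a warning.

## Transcription units and expression

A gene is "detected" in a cDNA library iff reads at ≥99% identity cover
strictly more than 80% of its exonic length. Unit assignment merges
mapped reads into transcript contigs per strand (requiring 40 bp of
overlap), bridges contig gaps lying wholly inside annotated introns so
intron-containing genes do not split a unit, and claims genes whose
exonic length is covered above 80% by one contig; claimed genes are
ordered in transcription direction, and a unit is polycistronic iff it
holds two or more genes. Units are estimated from the deepest (leaf-like)
library. The expression matrix renders `reads(coverage)` per gene and
tissue with "-" for genes without reads, and the writer/parser round-trip
is bit-identical. PolyA-like tracks are maximal A-rich windows (purity ≥
0.8, length ≥ 10 by default), built by chaining nearby A-runs while the
combined purity holds, each linked to the nearest downstream gene start
within 200 bp; the polyT-priming bias is diagnosed, never corrected.

## Problem sizes and numerical choices

The test and acceptance simulations run at reduced scale chosen as the
package's own working sizes: quadripartite genomes of 4–60 kb for
round-trips (158 kb for the layout arithmetic), read depths of 50–800×,
120 sequences for the finder-versus-oracle equality, 20 homoplasmic
replicates for the false-positive check, and 18 planted operons plus 10
singletons for unit recovery. Heteroplasmy recovery is scored on the
caller's *estimate* (queried below the discovery threshold) against the
planted fraction within three binomial standard deviations, and
separately on discovery behaviour at the published thresholds: a planted
fraction of 0.11 sits within sampling noise of the strict 10% cutoff, so
discovery of such borderline sites is a coin toss by design of the
published rule, while estimation accuracy is not. Known limitations: the
assembler resolves IR-flanked ambiguity only when seed contigs span the
junctions (in practice such junctions are confirmed by targeted sequencing); the SI stability
score is a rank-order surrogate, not an energy; the mapper's stepwise
aligner assumes isolated short indels and defers anything else to full
dynamic programming; and manual curation steps common in such analyses
(junction inspection, unit curation) are replaced by the automated rules
above.
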
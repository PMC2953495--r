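---
title: "Detecting and characterizing conjoined genes: methods and design"
author: "conjoinr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing conjoined genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjoinr)
```

## The problem

A conjoined gene (CG) is a locus that produces transcripts combining at
least part of one exon from each of two or more distinct annotated
(parent) genes lying on the same chromosome and strand. Such
read-through transcripts are easy to miss and easy to over-call: a
spliced EST crossing two annotated records may be a genuine CG, a
misalignment between paralogous family members, a naming artifact (one
locus annotated under several gene symbols), or simply a low-quality
single-block alignment. `conjoinr` implements positional CG detection
from pre-aligned transcripts plus the downstream characterization a CG
survey needs: splicing pattern, reading-frame fate, NMD candidacy,
junction conservation, and candidate-pair enumeration.

The package works entirely in 0-based half-open coordinates internally
(BED convention); conversion to and from 1-based inclusive coordinates
happens only in the GTF reader/writer. All tabular inputs and outputs
are tibbles with list-columns for exon/block interval matrices, so the
stages compose with ordinary dplyr verbs.

## Detection model

Detection is purely positional. After **locus collapse** — gene records
on the same chromosome and strand whose exons overlap by ≥ 1 bp are
merged, because such records are nearly always naming variants of a
single locus and would otherwise yield false CG calls — a transcript is
called iff blocks of its alignment intersect annotated exons of at
least two distinct collapsed loci on its own strand, each by at least
`min_exon_overlap_bp`. The default is 1 bp, the weakest reading of "at
least part of one exon"; it is exposed because single-base overlaps are
sensitive to alignment wobble in real data. Parents are ordered in
transcription direction, and genes that lie inside the transcript span
but are skipped entirely are recorded (`skipped_internal`) without
breaking the call — real CGs can bypass several internal genes.

**Curation** stands in for the manual screening a CG survey requires,
with three reproducible rules:

- `short_alignment`: summed block length < 200 bp. Quality scores are
  not available for pre-aligned blocks, so a minimum aligned length is
  the operational proxy for "short or poor-quality EST".
- `unspliced`: no gap ≥ 40 bp between consecutive blocks. Requiring at
  least one intron mirrors restricting EST evidence to spliced
  alignments; 40 bp is well below the ~70 bp minimum of genuine introns
  and well above indel artifacts.
- `paralog_suspect`: the two parents' spliced exonic sequences share a
  local alignment with ≥ 90 % identity over ≥ 100 bp. The identity is
  assessed on windows of the best local alignment (Biostrings
  `pairwiseAlignment`): score-neutral tie extensions of an optimal local
  alignment can otherwise dilute a genuine 150 bp near-identical
  duplication below the threshold, which we observed in testing.

Calls are grouped by their ordered parent tuple; a group supported by
two or more transcripts with distinct intron chains is flagged as
alternatively spliced. Intron chains — not terminal block ends — define
splice variants, because EST 5'/3' ends are ragged.

## Splicing patterns

The hallmark **junction-intron pattern** holds for an adjacent parent
pair iff some transcript intron fully contains the genomic interval
from the (transcription-direction) terminal exon of the upstream parent
to the initial exon of the downstream parent. Multi-parent calls are
evaluated per adjacent pair and summarized with `all()`, with the
per-pair vector retained.

A block is a **novel exon** iff it intersects no exon of any parent;
its origin is `intergenic` (within the gap between adjacent parents'
spans), `intronic` (within a parent intron), `flanking_upstream` /
`flanking_downstream` (outside the joint span, sides taken in
transcription direction), or `mixed`.

**Splice sites** are classified per boundary: a donor is conserved iff
the intron's transcription-direction 5′ boundary coincides with an
annotated intron 5′ boundary of *either* parent (acceptors analogously
at 3′ boundaries). The per-intron-pair alternative would be stricter;
per-boundary is the weaker claim and the report keeps both
granularities (per-site statuses per intron plus the per-call
`any_new_site`). Canonicality is GT at the first two and AG at the last
two intron bases on the transcribed strand; any `N` in those
dinucleotides, or an intron shorter than 4 bp, is non-canonical.

## ORFs, frames, NMD

Without an annotated CDS, the CG ORF is the longest ATG-initiated open
reading frame; ties go to the 5′-most start, and an ATG with no
downstream in-frame stop yields an incomplete ORF running to the
transcript end (classification proceeds; NMD is not applicable). The
reported interval includes the stop codon; the stop codon is excluded
from frame comparison.

Frame comparison is coordinate-only: the ORF is mapped through the
block chain to genomic positions with phase *i* mod 3, each parent CDS
contributes positions with phase derived from its GTF phase field
(base *k* of a segment with phase *p* sits at codon offset
(*k* − *p*) mod 3), and the verdict on the shared position set *S* is
`conserved` (|S| ≥ 30 bp, all phases agree), `different` (|S| ≥ 30 bp,
any disagreement), or `no_overlap`. The 30 bp floor avoids verdicts on
trivial overlaps and is exposed (`min_shared_bp`). Product classes
follow: all CDS-bearing parents conserved (and at least two) →
`chimeric`; exactly one conserved → `similar_to_one_parent`, recording
the 5′/3′ side so directional statistics can be computed; otherwise
`novel_or_noncoding`. Parent CDS records here include the stop codon;
only coordinates and phases matter, so either convention works as long
as it is consistent.

NMD candidacy uses the standard 50-nt boundary rule — the stop codon
must end ≥ 50 nt (exposed as `nmd_distance`) upstream of the last
exon–exon junction in transcription direction; single-block transcripts
are never candidates. The flag flips exactly at distance 50 vs 49.

## Junction exons, SHS, conservation search

The junction exon of an adjacent parent pair is the single block
overlapping exons of both parents (`single_exon`), or else the spliced
region from the last upstream-overlapping block through the first
downstream-overlapping block, including intervening novel exons
(`spanning_region`). The breakpoint — where upstream-derived sequence
ends — is the full contribution of the upstream block in spanning mode,
and the end of the upstream parent's exonic overlap within the block in
single-exon mode; if the two parents' exonic overlaps themselves
overlap inside one block, the midpoint of the conflict is used and
flagged `ambiguous_breakpoint`.

**SHS** (short homologous sequence) detection returns every maximal
common substring ≥ 4 bp between the 20 nt windows ending/starting at
the breakpoint; both the window size and the cutoff are parameters,
since the slippage-model construct is not standardized. Maximality is
per occurrence pair (not extendable in either direction), implemented
as diagonal run-length scanning and tested against exhaustive
enumeration.

**Conservation search** replaces an external BLAT dependency with an
internal seed-and-extend aligner: a target qualifies if it shares an
exact 11-mer with the junction sequence on either strand, and
qualifying targets are aligned with an affine-gap Smith–Waterman
(match +1, mismatch −1, gap open −2, extend −1; Rcpp). A hit requires
coverage > 0.90 of the junction sequence and identity > 0.90 over
aligned columns — the primary criterion — plus a raw score ≥ 30, which
plays the role of a tool-specific E-value floor and is exposed. At
these thresholds the decisions coincide with a full
dynamic-programming oracle on all test sequences, accept 2 %-mutated
copies and reject 15 %-mutated or half-length targets with wide margin
(identity of a 15 %-mutated 300-mer concentrates near 0.85).

## Candidate pairs

`enumerate_pairs()` lists all ordered same-chromosome, same-strand
locus pairs with intergenic gap 0 ≤ g < 10 kb (after collapse;
overlapping loci are excluded). Pairs are not restricted to neighbours
— CGs bypass internal genes — but `adjacent_only = TRUE` reproduces the
conservative screen used to pick validation cases. Validation regions
are the transcription-direction second-to-last exon of the upstream
gene and second exon of the downstream gene, because the most common
CG splicing mode skips the upstream terminal and downstream initial
exons. `parent_distance_stats()` summarizes parent gaps (standard
median, quartiles, > 100 kb outliers listed by pair).

## The simulator: what it emulates, and what it does not

`simulate_scene()` is first-class, tested code that emulates the input
side of a CG survey: an annotation of multi-exon protein-coding genes
with phase-annotated CDSs and canonical GT–AG introns, plus spliced
transcript alignments among which CGs of eight classes are planted —
junction-intron, retained-terminal-exon, novel exon from the intergenic
or intronic space, codon-aligned chimeric fusions, frame-shifted
fusions similar to the 5′ parent, NMD-positive transcripts, and
junctions with a planted 4–8 bp SHS — alongside five negative classes
(antisense chimeras, unspliced single-block ESTs, single-locus
multi-name variants, paralog mimics with a ~97 %-identical 150 bp exon
copy, and ordinary monogenic transcripts).

Default geometry is chosen once to resemble compact vertebrate loci:
3–6 exons of 80–300 bp, introns 0.1–2 kb, intergenic gaps 0.5–15 kb,
pair gaps capped at 8 kb so planted pairs also appear in the < 10 kb
candidate screen. The default scene plants 50 CGs and 50 negatives
with 30 background genes on one auto-sized chromosome (~2 Mb); the
chromosome is sized to fit, and a fixed `chrom_length` that cannot fit
raises a sizing error. Units alternate strands deterministically so
both orientations are exercised.

Two sequence-composition devices make the planted labels hold **by
construction for every seed**, not just lucky ones. First, every
designed coding fill uses sense codons with "shifted-stop" codon pairs
every ten codons — sense in frame 0 but containing stop codons in the
+1 and +2 frames — so any frame-shifted reader terminates within ~36 nt
while the intended frame runs on. Second, UTR fills embed an 11-nt
cassette with a stop codon in all three frames, bounding spurious
upstream ORFs. Fusion junctions are codon-aligned (or deliberately
shifted by one base for the frame-shift classes) by solving the 5′-UTR
length modulo 3. The generator additionally verifies each planted ORF
with an internal minimal scanner and computes the truth SHS length by
brute-force longest-common-substring on the actual junction windows,
so the truth table always reflects the emitted sequences. A planted
in-frame ATG may extend an intended ORF upstream into the 5′ UTR; all
class labels are invariant to such extensions, and the internal checks
allow them.

What the simulator does *not* model — and what passing tests therefore
do not show about real data: alignment errors and soft-clipped block
boundaries, sequencing error, expression levels and tissue specificity,
non-canonical splice sites in parents, overlapping gene architectures
beyond simple naming variants, and paralogy subtler than a planted
high-identity exon copy. Corpus-level fractions from real surveys
(e.g. what share of CGs shows each splicing pattern) depend on real
transcript corpora and are out of scope; the package computes the same
statistics on whatever corpus it is given.

`random_scene()` is a second, unstructured generator (random gene and
transcript chains, no genome) used for equivalence and monotonicity
property tests of the detector against a brute-force double-loop
oracle.

## Numerical and interface choices

- Coordinates: 0-based half-open everywhere internally; GTF conversion
  at the file boundary only; BED12 written canonically so round-trips
  are bit-exact.
- Exons per gene are the union over transcripts (merged when
  overlapping); parent genes are treated as single loci.
- `N` bases are allowed in genomes; splice-site dinucleotides containing
  `N` never count as canonical, and `N` never counts as a match in the
  aligner.
- All simulator randomness flows from the single seed
  (`withr::with_seed`); pipelines are deterministic given inputs.
- Problem sizes in the test suite (100 random scenes of ≤ 50 genes /
  ≤ 200 transcripts; 1,000 random sequences for the ORF oracle; 1,000
  window pairs for the SHS oracle; 40 mutated junction copies per rate
  for the conservation thresholds) were chosen as the smallest sizes at
  which the property being tested is exercised across its case space.
- The command-line entry point (`exec/conjoinscan`) is a thin optparse
  wrapper over the exported functions; the R API is the primary
  interface, and `run_conjoin_pipeline()` is the single-call end-to-end
  path whose combined report equals the column-wise join of the
  individually run stages.

## Known limitations

- The paralog screen compares parents' merged exonic sequences, not the
  specific aligned portion of the transcript; a CG between genuinely
  paralogous neighbours would be (conservatively) rejected.
- Locus collapse keeps the representative member's CDS; merged loci
  with conflicting CDS annotations lose the non-representative ones.
- `similar_to_one_parent` records the conserved side; with more than
  two parents and an interior conserved parent, the gene id is recorded
  instead of 5′/3′.
- The conservation aligner reports the best hit per target; multiple
  distinct hits within one target (e.g. a duplicated junction) are not
  enumerated.
- Breakpoint placement inside a single junction exon trusts the
  annotation; when parent exonic overlaps conflict, the flagged
  midpoint is a convention, not an inference.
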
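---
title: "gxscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gxscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gxscreen detects cross-species contamination in genome assemblies by
aligning every assembled sequence against an indexed reference set and
classifying each sequence as belonging to the declared source organism
(*primary*), to a foreign taxonomic division (*contaminant*), or as
*inconclusive*. This vignette explains the model behind each stage, the
parameters that matter, what the bundled simulator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The h-mer index

Cross-species alignment must tolerate the substitution spectrum of neutral
divergence, which is dominated by transitions, and by third-codon-position
("wobble") changes inside coding sequence. The index key — an *h-mer* —
builds this tolerance into the hash itself:

1. take a 56-bp window;
2. drop every third base (0-based offsets 2, 5, 8, ... on each strand's own
   5'→3' reading — the wobble position when the window is in-frame coding
   sequence), leaving 38 bases;
3. encode each retained base with one bit, purine vs pyrimidine
   (A,G → 0; C,T → 1), so any transition leaves the code unchanged;
4. hash the 38-bit code of the forward window and, independently, of the
   reverse-complement window, and keep the lesser hash (a *minword*), making
   the key strand-invariant.

The result is a 38-bit key invariant under strand flips, transitions at any
retained position, and any substitution at a wobble position; only
transversions at retained positions change it. Note that because each
strand drops its own wobble frame, the two strands drop different physical
positions — this is forced by computing the reverse-complement key
independently, and is what makes the canonicalization exact.

The mixing hash is deliberately simple and pinned: a splitmix64-style
64-bit finalizer (fixed multiply–xorshift constants in `src/gx_core.cpp`)
truncated to the key width. Any well-mixing 64-bit permutation would do;
what matters is that it is deterministic across platforms so databases are
bit-reproducible. Keys split into a 30-bit upper and 8-bit lower subkey:
lookup locates the upper-subkey bucket from a precomputed offsets table and
binary-searches the lower subkey inside it. The on-disk node record is
exactly 9 bytes (1-byte lower subkey, 4-byte subject ordinal, 4-byte signed
position; the sign records which strand minimized the hash). One format
choice departs from a dense offsets layout: a dense table over all 2^30
upper subkeys would serialize to gigabytes regardless of database size, so
the `.gxi` file stores offsets only for non-empty buckets as
(upper subkey, offset) pairs. Lookup semantics, the subkey split and the
node layout are unchanged, and full keys round-trip exactly.

References are sampled at a 10-bp stride for prokaryotes and viruses and
20 bp for eukaryotes, covering all reading frames; queries are sampled at
every position. Non-ACGT bases are replaced by pseudorandom bases drawn
from a generator seeded by (sequence id, position), so rebuilds are
identical; filled positions are flagged and never count as identity during
scoring.

## Masking

Two masks limit seeding (masked regions remain available to extension, as
in standard masker practice; a window is skipped when at least half its
bases are masked):

* **Low complexity.** A 50-bp window slides at 1-bp steps; windows whose
  hexamer Shannon entropy falls below 4.5 bits are merged into intervals.
  A uniform distribution over the 45 window hexamers has entropy
  log2(45) ≈ 5.49 bits, typical random sequence sits near that bound, and
  homopolymers or short tandem repeats fall far below it, so 4.5 bits
  separates the two regimes cleanly.
* **Transposon-like repeats** (eukaryote queries only; high-copy elements
  otherwise generate cross-division noise). Genome-wide h-mer counts are
  taken over the query's own sequences, restricted to sequences whose
  source scaffold is at least min(100 kbp, scaffold N80) long — a genome
  consisting of many short near-identical sequences (egregious
  contamination, e.g. a phage) therefore contributes nothing and is not
  mistaken for a repeat family. Counting uses stride 1 so that repeat
  copies are registered regardless of their phase relative to any sampling
  grid. The overrepresentation cutoff is max(10, 5 × the count expected
  under uniform sampling); at desk scale the floor of 10 governs. The
  cutoff is configurable; the floor keeps the rule scale-free at fixture
  sizes.

Scaffolds are split into contigs at every run of 10 or more Ns before
masking and alignment, and contigs are aligned in 100-kbp chunks with
100-bp overlaps whose hits are recombined afterwards as if the contig had
been aligned whole.

## Two-pass alignment

**Pass 1** looks up every query h-mer in the database. Seeds — (query
position, subject, subject position) tuples with signed coordinates
encoding orientation — are kept only if another seed lies within 1 kbp on
the diagonal *and* 10 kbp on the antidiagonal, which removes isolated
chance matches while keeping anything with local support. Surviving
same-diagonal seeds within 1 kbp are merged into ungapped runs (the merge
radius is a package choice; the filter windows above pin its natural
scale), runs are X-drop extended on their diagonal, and per taxon only the
best-scoring runs among those overlapping on query coordinates are kept.
Four per-taxon metrics — number of ungapped alignments, maximum alignment
length, summed alignment length, and summed squared alignment length
(read as the sum of squared lengths, consistent with the score definition
below) — are pooled over chunks, and every taxon in the top three of any
metric (ties broken by metric value then taxid, for reproducibility)
proceeds to pass 2.

**Pass 2** indexes the query on the fly with smaller h-mers (30-bp
windows → 20-bit keys, the same wobble-drop/one-bit construction; only the
key width is fixed by the index design, the window size follows from it)
and scans subject neighborhoods limited to min(100 kbp, 2 × query length)
around the pass-1 loci of each selected taxon against that index.
Neighborhoods are computed per chunk. Each seed is extended ungapped
(X-drop 30, match +1, mismatch −3), then gapped: repeatedly, the indel
within ±25 bp of the alignment end that yields the longest exact
continuation run is taken, as long as that run is significant (≥ 8 bp);
candidate ties break by smallest total offset, then smallest query offset,
an ordering that is mirror-symmetric so screening a sequence and its
reverse complement gives the same alignments up to coordinate reflection.

Extension ends advance only on exact runs of at least 5 bp, except at
sequence boundaries where a shorter trailing run is genuine homology. This
matters at chimeric junctions: without it, a couple of chance matches past
the junction drag the alignment end a few bases into foreign sequence, and
a span lying exactly on a reporting threshold would be measured
inconsistently.

**Score.** The score of an alignment is the square root of the sum of
squared lengths of its maximal 100%-identity segments. Two 60-bp segments
score √7200 ≈ 84.9 while an unbroken 120-bp segment scores 120: clustered
mismatches (alignment artifacts, multi-nucleotide mutations) cost less
than the same mismatches scattered through the alignment, which is the
signature of genuine distant homology. Pseudorandom-filled bases never
extend an identity segment.

## Taxonomic summary

Per sequence, alignments are aggregated by species (coverage = length of
the union of query intervals; score = the L2 combination of all identity
segments) and reporting is truncated to at most four species overall and
two per division — keeping a second species per division helps distinguish
real contaminants from contamination *inside the database*. Per-division
aggregates are computed from all hits regardless of the reporting caps.
For eukaryote queries, bases covered by alignments from at least five
distinct divisions form *highly conserved intervals* (rRNA,
ultraconserved elements), which are treated like repeats during calling.
Divisions are grouped into eight kingdoms (Metazoa, Viridiplantae, Fungi,
other-Eukaryota, Bacteria, Archaea, Viruses, Synthetic); Bacteria and
Archaea stay distinct kingdoms. Virus divisions are split by host
superkingdom (prokaryotic / eukaryotic / other) to support the virus
rules.

## Contamination calling

Calling runs at two levels.

**Genome level.** The aggregate coverage fraction (query length aligned to
each sequence's top-4 species, over total genome length) measures how well
the database represents the organism. The inferred primary set starts from
the top-coverage division; other divisions of the same kingdom join it
when their alignments overlap the top division's by at least a dynamic
concordance threshold, 0.5 + 0.25 × aggregate coverage — lower for poorly
represented species, where database granularity scatters hits across
sister divisions. If the declared division is well represented in the
database (≥ 1 sequence and ≥ 50 kbp at the desk-scale defaults,
configurable) yet absent from the inferred set, the declared taxid is
presumed wrong: the inferred divisions are reported as contaminants and a
warning is raised. Division aggregates accumulate only high-confidence
evidence — alignments scoring ≥ 150 with per-sequence coverage > 80% — and
a division is flagged as a contamination source only when (a) under 75% of
its aligned bases are low-complexity/conserved, (b) under 75% are
transposon-like, (c) over 10 kbp are non-repetitive, and (d) under 75%
overlap the primary divisions' alignments.

**Sequence level.** A sequence with zero alignments is inconclusive. For a
flagged division, a sequence is a contaminant when its score exceeds 50,
or, for inter-kingdom evidence, when coverage reaches 80%; for an
unflagged division the bar is a score above 100 with repeat/conserved
content below 50%. Every call must additionally clear the minimum coverage
cutoff max(0.2, 0.6 × (1 − aggregate coverage fraction)) over the called
region — applying the cutoff to the called region rather than the whole
sequence keeps kilobase chimeric spans in 100-kbp hosts detectable while
still suppressing thin, patchy evidence; this is the one point where the
calling text admits two readings and the region-level one is the only one
consistent with chimera actions existing at all.

When primary-division alignments cover an appreciable part of the sequence
(≥ 100 bp by default), the contaminant spans are the *holes* in primary
coverage that carry contaminant alignments: host and contaminant
alignments partition the sequence, and the hole boundaries are set by
where the host alignment stops. Because local alignment ends are ambiguous
by a few bases at a junction, each hole may widen to the contaminant
alignment's boundary by at most 25 bp per side (`junctionFuzz`). Holes
closer than 1 kbp merge; spans under 50 bp are dropped.

**Actions.** Whole-sequence contaminants are EXCLUDE. Inter-kingdom
chimeric spans are TRIM when the span reaches within 100 bp of a sequence
end, otherwise FIX. Chimeras from configured lateral-gene-transfer source
divisions (endosymbionts; the list is configuration, defaulting to
`prok:endosymbionts`) are INFO. Intra-kingdom chimeras are ignored below
10 kbp and reported as REVIEW from 10 kbp. Prokaryote-in-prokaryote
contamination totaling at most 1% of the genome is downgraded to
REVIEW_RARE instead of being cleaned. Virus rules: eukaryote hosts clean
only wholly-viral sequences and ignore chimeric viral spans; prokaryote
hosts ignore viral elements entirely; virus queries report
cross-superkingdom viral and all non-viral contaminants. Only EXCLUDE,
TRIM and FIX ever modify the cleaned FASTA; FIX splits the remainder into
`.1`, `.2`, ... parts. Report coordinates are 1-based inclusive;
everything internal is 0-based half-open.

## The simulator

`generateReferenceSet()` builds one random ancestral genome per division
(order-0 composition at the configured GC), plants a shared 2-kbp
"conserved" segment into every genome (per-species divergence 3%) so the
conserved-interval logic has something to find, plants a division-specific
800-bp repeat family (25 copies, 2% divergence) into eukaryote genomes to
exercise transposon masking, and derives species at 5% divergence.
Query strains diverge from their reference at 1% substitutions and 0.1%
indels (≤ 5 bp), transition:transversion 2:1 so the h-mer transition
tolerance is actually exercised. `generateQuerySet()` reproduces the three
evaluation designs: equal-size fragments (1/10/100 kbp), 100-kbp host
fragments plus 5%-by-length 1-kbp contaminant fragments, and chimeras
fusing each host fragment with one contaminant span, optionally separated
by 10 Ns (in which case preprocessing splits them into separate contigs).
`evaluateSnSp()` scores sensitivity as the percentage of truth-contaminant
sequences receiving a corrective action (EXCLUDE/TRIM/FIX) with the
correct source division (prokaryote-virus assignments count as true
positives for prokaryote sources), specificity as the percentage of
truth-clean sequences receiving no corrective or REVIEW action, and the
sequence-level specificity bounds from total called lengths.

What the simulator does **not** emulate: real genome composition (isochore
structure, codon bias — so the "wobble" positions here are statistical,
not truly codonic), repeat landscapes beyond a single planted family,
sequencing or assembly error, database curation artifacts, and real
phylogenetic structure between divisions (division ancestors are
independent except for the planted conserved segment). Passing the test
suite therefore demonstrates that the machinery implements its rules
correctly and recovers planted signal at realistic divergences — not that
sensitivity/specificity on real genomes will match the synthetic numbers.

## Numerical choices and degenerate inputs

* All thresholds live in `gxConfig()` / `gxAlignParams()` with the
  defaults above; scores are plain doubles and the score equality used in
  tests allows floating tolerance.
* Ties: species and division rankings break by score then taxid; pass-1
  taxon selection by metric value then taxid; gapped-extension candidates
  by run length, total offset, query offset. All orderings are total, so
  identical inputs give byte-identical reports.
* Sequences shorter than 56 bp yield no h-mers and screen as inconclusive;
  all-N scaffolds vanish at the contig split; an empty reference set
  builds a valid, always-empty database.
* Palindromic windows whose forward and reverse hashes tie store a single
  node with positive (forward) orientation.
* Fragment sizes used by the test suite and acceptance script are a
  deliberate desk-scale choice: reference worlds of 0.4–2.6 Mbp, queries
  of 0.1–2.3 Mbp. These sizes exercise every code path (chunking included)
  while a full run stays in the minutes range on one CPU.

## Known limitations

* Prokaryote contaminants are assigned at division level only; no attempt
  is made to discriminate families or genera within a kingdom.
* The gapped extension is greedy; it recovers indel structure well at
  strain-to-species divergences but is not an optimal-alignment algorithm,
  and the test suite checks agreement with a dynamic-programming oracle
  only on total matched bases, not the exact path.
* The dynamic concordance for the inferred primary set and the
  well-represented thresholds are calibrated for desk-scale databases; a
  production-size reference set would warrant re-examining both.
* Virus screening follows the conservative rules above and nothing more;
  dedicated viral contamination detection is out of scope.
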
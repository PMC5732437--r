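---
title: "Amplicon variant calling with ampliCall: methods and design"
author: "ampliCall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon variant calling with ampliCall: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliCall)
```

# The model

Amplicon assays sequence PCR products whose primers sit at known
genomic positions, with the forward and reverse primers separated by
slightly less than twice the read length so that the two mates of every
pair overlap. `ampliCall` exploits both facts: reads are assigned to
amplicons by primer matching instead of genome alignment, and each
pair is collapsed into a single consensus read before any variant is
extracted. The unit of evidence throughout is the *merged read pair* —
depth, variant support and VAF are all counted in pairs, never in raw
reads, because the two mates of a pair are one DNA molecule observed
twice.

The processing per pair is:

1. **Cache lookup** on the raw `(seq1, seq2)` pair. Amplicon data is
   highly redundant, so most pairs repeat; a repeated pair reuses the
   first-seen result wholesale.
2. **Amplicon assignment**: Hamming distance between each amplicon's
   forward primer and the prefix of read 1, and its reverse primer and
   the prefix of read 2. Both distances must be within the mismatch
   budget (default 3); among several candidates the smallest total
   wins and a residual tie is treated as unassigned rather than
   guessed.
3. **Overlap merge**: Smith–Waterman local alignment of read 1 against
   the reverse complement of read 2. If the overlap spans at least
   `minOverlap` columns (default 15) at `minOverlapIdentity` identity
   (default 0.90), a consensus over the union of the two reads is
   built. Where the mates agree, Phred qualities add (capped at 60);
   where they disagree, the higher-quality mate wins with quality
   `|q1 − q2|`, and an exact quality tie keeps mate 1's base at quality
   2. Pairs that fail the overlap test are counted and excluded —
   the assay design guarantees overlap, so an unmergeable pair is
   evidence of an artefact, not of a variant. Unmerged and unassigned
   pairs never contribute to depth.
4. **Variant extraction**: the consensus is locally aligned to the
   amplicon reference and the edit operations are walked. Each
   mismatched column yields one substitution; each gap run yields one
   VCF-style anchored insertion or deletion. Because the whole merged
   read is aligned in one pass with affine gaps, large indels fall out
   directly, with no realignment step. Alignments covering less than
   half the read are discarded as unalignable; variants whose
   reference span touches a primer-binding region are dropped, since
   primer bases are synthesized, not sequenced, and recurrent
   primer-region artefacts otherwise surface as false positives.
5. **Phasing**: variants on one merged read are in phase by
   construction. Variants whose reference spans are separated by at
   most `phaseWindow` bases (default 15, measured as the count of
   reference bases strictly between the spans, transitively closed)
   are combined into a compound delins parent spanning first to last
   reference base, carrying the read's observed alternate sequence.
   The constituents are retained and reported individually as well;
   parent and constituents share an `MNP_LINK`, and each record counts
   exactly the pairs exhibiting it. Reporting both matters because the
   compound consequence can differ from every constituent consequence
   (p.V600R vs p.V600M/p.V600G in the BRAF codon-600 example).

After all pairs: support and depth are aggregated per variant — depth
at a locus sums, across amplicons, the pairs whose alignment covers the
variant's span, so loci tiled by several amplicons are counted once per
contributing pair — and a call is retained iff `vaf >= minVaf` (default
0.20) and `altPairs >= minAltReads` (default 5). Thresholds are
inclusive; a germline assay runs at the 20 % default while somatic
ladders are called down to 1 %.

# Normalization

A raw `(chrom, pos, ref, alt)` tuple is not a variant identity: the
same indel admits many encodings. `normalizeVariant()` maps every
encoding of one edit to one representation:

1. **Trim** shared suffix then shared prefix of `ref`/`alt`, keeping
   one anchoring base for indels.
2. **Select the transcript**: among transcripts overlapping the
   variant, one named in the preferred-transcript map wins; multiple
   preferred candidates are ranked by genomic distance from the
   variant to the nearest exon (0 if exonic), then by lexicographically
   smallest accession. The same distance rule applies when no
   preferred transcript matches. The preference file is deliberately a
   two-column editable TSV: transcript choice is a reporting policy,
   not a property of the data.
3. **3′ shift** pure insertions and deletions to their maximal
   position in the transcript's reading direction — genomic right for
   plus-strand transcripts, genomic left for minus-strand ones, and
   genomic right for intergenic variants. The genomic (g.) coordinate
   is reported at the same transcript-matched position rather than
   independently right-shifted, so the g. and c. names always point at
   the same bases. The result is re-anchored on the 5′ side
   regardless of how the input was anchored, which is what collapses
   left- and right-anchored encodings onto one tuple.
4. **Classify duplications**: an insertion whose sequence equals the
   reference immediately 5′ (transcript direction) of the insertion
   point is a `dup`.
5. **Render** HGVS. c. positions map through the exon geometry with
   intronic offsets (`c.N+k` / `c.N−k`, nearest-exon rule, ties to the
   upstream exon) and UTR forms (`c.-n`, `c.*n`). Protein consequences
   are computed by translating the mutated CDS: substitutions and
   in-frame delins directly, frameshifts as `fs*N` with `N` found by
   scanning to the first downstream stop, synonymous changes as
   `p.X###=`, initiator-codon disruption as `p.?`. One-letter
   amino-acid codes by default; `oneLetter = FALSE` gives three-letter
   names.

The operation is idempotent, and the test suite verifies with an
enumeration oracle that every padded or shifted VCF encoding of 500
random indels lands on one identical representation. Normalization
runs after aggregation; records whose canonical tuples coincide are
then combined (support sums, VAF recomputed) so read sets that spelled
the same indel differently still yield one record with the correct
VAF.

# Alignment engine and numerical choices

Local alignment is delegated to `Biostrings::pairwiseAlignment()`
behind a thin wrapper that fixes the scoring scheme at match +2,
mismatch −2, gap −3 charged on the first gap base and −1 per further
base (common striped-SW defaults; all configurable through
`MergeParams()`). Biostrings' affine model charges
`gapOpening + L * gapExtension` for a length-`L` gap, so the wrapper
passes `gapOpening = 2, gapExtension = 1`. Tie-breaking among
equal-scoring alignments follows Biostrings' deterministic traceback;
determinism, not a particular tie order, is the property the pipeline
relies on, and the suite checks score-level agreement against an
independent full-matrix Gotoh implementation. Alignments are batched —
one vectorized call for all unique pairs at the merge step, one per
amplicon at the call step — because per-call overhead, not the DP
itself, dominates at panel scale.

Degenerate inputs: alignments with no positive-scoring cell return an
explicit empty alignment (score 0); empty FASTQ input produces an
empty call set with zeroed statistics; a mate-count mismatch between
the two FASTQ files is fatal; duplicate VCF records abort the write
naming the offending tuple.

# The read cache

The cache key is the raw sequence pair only — qualities are excluded.
Consequently the first-seen pair's quality-resolved consensus is reused
for later identical pairs. The simulator guarantees that identical
sequence pairs carry identical (cycle-determined) qualities, which
makes cache-on and cache-off runs byte-identical on simulated data, and
the suite asserts exactly that. On real data, two identical sequence
pairs with different qualities could in principle resolve a
disagreeing overlap base differently; with the consensus rule above
this can only matter for pairs that already disagree with themselves,
which the identity threshold keeps rare.

# The simulator, and what passing tests mean

`makePanel()` builds a random panel on a synthetic chromosome with
pairwise-distant primers (Hamming > 2× the assignment budget,
verified, regenerated on violation) and two toy transcript models: a
plus-strand, single-exon model (gene label `BRAF`) with a 60 nt 5′UTR,
a 2100 nt stop-free CDS whose codon 600 is forced to `GTG` and whose
c.21–24 context is fixed so a tandem copy of c.21–22 is already
maximally 3′-shifted, and a 60 nt 3′UTR; and a minus-strand two-exon
model to exercise reverse-strand coordinate mapping. `simulateSample()`
draws `depth` pairs per amplicon (default 2000, matching deep clinical
panels), assigns molecules to variant haplotypes either binomially
(realistic default) or exactly (`round(fraction × depth)`, used where a
deterministic count is the point of the experiment), injects uniform
per-base substitution errors (default 0.1 %) outside primer regions,
and emits gzipped FASTQs with a declining cycle-quality profile (read
2 lower than read 1) plus a truth table of realized counts.

What the simulator does *not* model bounds what green tests mean for
real data: no PCR chimeras or polymerase stutter, no quality-dependent
error profile (errors are uniform and independent of the emitted
qualities), no indel sequencing errors, no primer-site mutations and no
coverage imbalance between amplicons. Recovery of a planted 3 %
variant here demonstrates the counting and thresholding machinery, not
assay-level sensitivity, which on real chemistry is limited by exactly
the artefacts excluded above. The ladder experiment in the acceptance
tests (fractions 48/29/18/11/5/3 % at depth 2000, 0.1 % error, 1 %
VAF floor) checks that every recovered VAF sits inside the central
99 % binomial interval of its target — the tightest claim the
simulation's own sampling noise permits.

# Design choices on open points

* Mismatch runs are emitted as per-base substitutions and recombined
  by the phasing stage, rather than as single multi-base
  substitutions; this is what makes constituents individually
  reportable alongside the delins parent.
* The phasing gap is measured between reference spans, exclusive of
  both endpoints, so adjacent substitutions (gap 0) always phase and
  the scan over two-variant spacings flips from compound to
  independent exactly after a 15-base gap.
* Depth is counted per locus, summed over amplicons, rather than per
  amplicon, so tiled designs report one correct VAF per variant.
* Constituents carry an `MNP_LINK` only when their parent is itself
  reported; a suppressed parent leaves its constituents as ordinary
  independent records.
* Evaluation matches on normalized tuples and ignores MNP parents
  unless the truth set itself lists the parent, so a truth table of
  simple SNVs is not "missed" by also reporting their compound form.
* The VCF reader/writer is a purpose-built serializer for the dialect
  this tool emits: byte-stable rewrite of its own output, verbatim
  preservation of unknown INFO keys in annotate-only mode, and dotted
  annotation keys (e.g. `cadd.gene.prot.domain`) in INFO. Every
  written file is cross-checked against a strict external VCF parser
  in the tests.
* Annotation is a backend contract: the offline JSON fixture backend
  is the tested implementation; an HTTP batch client (100 ids per
  request, one retry) exists for live use and degrades to a warning
  plus an unannotated VCF, with a distinct exit status, when
  unreachable.

# Problem sizes

The shipped tests run the full pipeline at depths of 40–2000 pairs per
amplicon on panels of 1–8 amplicons of 160 bp, the normalization
uniqueness property over 500 random indels × all their enumerated
encodings, and the alignment oracle over 500 random string pairs of
length ≤ 50 — sizes chosen so the entire suite exercises every stage
end-to-end in a couple of minutes on one core.

# Known limitations

Single-threaded; single-sample VCF only (no gVCF, no multi-sample
merging); no adapter or quality trimming (QC is assumed upstream); no
copy-number inference, which amplicon PCR masks by design; the HGVS
renderer covers the forms this pipeline emits, not the full grammar
(no r. notation, no liftover); unmergeable pairs are discarded rather
than rescued as single-end evidence, and are visible in the run
statistics.
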
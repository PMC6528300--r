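---
title: "Annotating plastomes by homology transfer: methods and design"
author: "plastanno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating plastomes by homology transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastanno)
```

# The annotation model

`plastanno` transfers annotations from one or more annotated reference
plastomes to an unannotated target by similarity, in the *reverse
query–subject* orientation: reference genes are the queries, the target is
the subject. This inverts the usual transfer direction and has a useful
consequence — the search is for a *fixed, known* set of genes, so the
result can be audited gene by gene: every reference gene is either
annotated, skipped with a stated identity, or reported missing, and the
three counts always add up to the reference total.

The working assumptions are those of plastid genomics: gene content and
order are strongly conserved among related plastomes; coding sequences
tolerate substitutions but keep frame; intron positions are conserved but
introns are occasionally lost as a unit; the genome is essentially complete
(assembly fragments are out of scope); and coordinates never shift by
insertion within the gene span at the divergences the transfer is useful
for (roughly under 15–20 % nucleotide divergence).

## The reference database

`buildReferenceDb()` extracts every CDS, tRNA and rRNA feature carrying a
`/gene` qualifier and builds four components: RNA nucleotides, PCG
nucleotides, intron-free CDS amino acids, and intron-containing CDS amino
acids. Two design points matter downstream:

* **Verbatim translation.** CDS are translated under genetic code table 11
  without initiator special-casing, so a GTG-initiated reference CDS keeps
  V as its first residue. The start-codon machinery depends on literal
  N-terminal residues for its probes; forcing M would corrupt them. The
  stock Biostrings translator applies initiator rules, so the package uses
  a plain codon-table lookup instead.
* **Per-exon peptides.** For intron-containing CDS both the full
  translation and per-exon translations are stored. Per-exon peptides are
  codon-aligned: exon 1 keeps its full codons, later exons first drop the
  leading split-codon nucleotides. The residue encoded across the junction
  is therefore represented in the full translation only — boundary probes
  never need it, and its absence keeps every per-exon peptide an honest
  window of the genome.

Entries identical in (gene name, sequence) are deduplicated, which
collapses the two inverted-repeat copies of a gene; distinct sequences from
different references are kept in parallel and resolved per gene by the
best-hit rule (highest percent identity; ties broken by aligned length,
then input order).

## The search layer

Two interchangeable backends return the same HSP table (query and subject
intervals 0-based half-open, subject coordinates always on the forward
axis, reading frame recorded for protein hits):

* The **external** backend shells out to NCBI BLAST+ (`blastn` /
  `tblastn -db_gencode 11`), parses tabular output, and maps the 1-based
  inclusive tool coordinates to the internal convention. The e-value
  ceiling defaults to 1e-5; other tool parameters are left at their
  defaults. These values are declared choices, not inferences.
* The **builtin** backend is pure R. Because homologous plastomes differ
  essentially by substitutions over the spans being searched,
  substitution-tolerant pattern matching (`matchPattern` with a mismatch
  budget) finds every occurrence of a query — including both IR copies —
  in one pass. The mismatch budget scales with query length (40 % under
  60 residues/nucleotides, up to 75 % for long peptides) so that chance
  matches, whose expected identity is ~6 % for peptides and 25 % for
  nucleotides, stay negligible while a gene diverged to ~30 % amino-acid
  identity is still seen (it must be *seen* to be skipped and logged).
  Loci the pattern pass cannot represent — truncated or locally diverged
  genes — fall back to Smith–Waterman local alignment (BLOSUM62 / +2,−3)
  with iterative masking to surface multiple copies. A full-length,
  low-identity pattern hit is re-examined locally and replaced only when
  the local alignment is decisively cleaner (25 identity points better):
  that distinguishes a truncated gene running into intergenic sequence
  (trim to the conserved prefix) from a uniformly diverged gene (keep the
  full-length reading rather than cherry-picking its best window).

PCGs are located by the protein search alone: the identity threshold
(default 40 %) and all downstream boundary rules are defined on
protein-level HSPs. For intron-containing genes the builtin backend submits
per-exon queries with query coordinates on the concatenated-exon axis —
contract-equivalent to an aligner splitting one query into per-exon HSPs.

HSPs are clustered per gene copy by strand and subject proximity; the
cluster span cap (`maxIntronSpan`, default 10,000 nt) bounds how far apart
two exons of one copy may lie. Hits crossing the sequence end are not
produced; for circular targets whose origin interrupts a gene, rotate the
sequence first (the CLI and IR detector have a circular mode, the gene
search deliberately does not: silently double-counting genes on a doubled
sequence is a worse failure than asking for a rotation).

## Boundary detection

**Stops.** The annotated stop is the first in-frame stop codon scanning
downstream from the HSP 5′ end. Scanning from the 5′ end means a premature
in-frame stop *inside* the HSP is returned — deliberate, with a pseudogene
warning, because silently reading through an internal stop would hide real
pseudogenes. If no stop exists before the sequence end, the last full codon
is kept with a "runaway ORF" warning.

**Starts.** The four-strategy cascade (a)–(d) described in the README. Two
interpretation points the implementation fixes: "closest to the upstream
stop" means the smallest nucleotide distance from the stop's 3′ end to the
candidate's first nucleotide (in-frame ties are impossible); and when
strategy (c)'s back-shift would land a candidate upstream of the stop, the
candidate is rejected and scanning continues — the region bound is
authoritative. Probes always come from the reference N-terminus
(positions 1–20), even when the HSP starts mid-protein. The 20-amino-acid
search depth is inclusive of the 20th residue. Probe matching is exact:
the algorithm is a pattern search, not an alignment, and its robustness
comes from sliding the window, not from tolerating mismatches.

**RNA ends.** For rRNAs and intron-free tRNAs, each end is refined
independently: 9-nt probes drawn from the terminal 30 nt of the reference
gene (offsets 0–21, moving inward) are searched over the 60-nt region made
of the HSP's terminal 30 nt plus the 30-nt flank; the first matching probe
anchors the boundary, shifted outward by its offset. Among multiple
occurrences of one probe the candidate closest to the HSP end wins — under
substitution-only divergence the true boundary sits exactly at the HSP end,
so this tie-break makes the refinement exact whenever any clean 9-mer
exists in the terminus.

**Introns.** The inter-HSP region (strictly between HSP1's 3′ end and
HSP2's 5′ end, frame inherited from HSP1; overlapping HSPs are first
trimmed to frame) is classified: in-frame stop or length ≢ 0 (mod 3) ⇒
intron present; otherwise (or zero length) ⇒ intron lost, exons joined into
a single CDS and logged. For present introns, the exon-2 boundary comes
from the strategy-(c) probe walk against the reference exon-2 N-terminus,
then moves left by the split-codon count — reference exon-2 length mod 3.
The exon-1 boundary uses the mirrored construction: probes from the
reference exon-1 C-terminus, searched toward the first in-frame stop
*downstream* of HSP1, with the boundary moved right by exon-1 length mod 3.
The mirror is this package's symmetric reading of "the same process"; the
complementary identity (exon-1 shift + exon-2 shift ≡ 0 mod 3) is asserted
in the tests, and every annotated multi-exon CDS is checked to be
frame-complete and internally stop-free (violations warn rather than
fail). Genes with more than two exons are handled by applying the two-HSP
procedure to consecutive HSP pairs, with cumulative exon lengths supplying
the split-codon arithmetic (this reduces exactly to the two-exon formula
for two-exon genes). Intron-containing tRNAs use the 9-nt probe scheme at
all four exon ends; their intron-loss rule is purely positional (gap under
10 nt with abutting query coordinates), since no frame exists.

**Short first exons.** The 6–9 nt first exons of *rpl16*, *petB* and
*petD* cannot seed a similarity search. When such a gene (configurable
set) yields only its exon-2 HSP, the reference exon-1 sequence is searched
as an exact probe within 2,000 nt upstream (configurable; one mismatch may
be allowed). The match nearest exon 2 wins; total length is frame-checked
against the located exon 2 and the result carries a warning when the check
fails. Probe failure annotates exon 2 alone, logged.

**Inverted repeat.** Self-search of the sequence against its reverse
complement: 250-nt windows seed with a 10 % mismatch budget (near-identical
arms still seed; random sequence cannot), seeds chain along anti-diagonals,
contiguous runs become candidate arm pairs, ends extend while exactly
complementary. The longest non-overlapping pair at least `minIrLength`
(default 1,000 nt) long is (IRa, IRb); ties prefer higher identity, then
the leftmost pair. Arm mismatches are reported as a warning with their
count; boundaries of near-identical arms come from the self-hit endpoints
without polishing. The larger inter-arm region is the LSC, the smaller the
SSC (the region spanning the sequence end is encoded with end = start +
width past the length). Genes inside the IR are annotated per copy from
their own HSP clusters, never mirrored from the other copy.

**Pseudogene screen.** Query coverage is annotated length over reference
length (exon-sum lengths for multi-exon genes). Bounds are strict
inequalities — coverage exactly 0.5 or 2 passes — matching the reading of
"less or greater than" the thresholds.

# The synthetic-fixture generator

`generateFixture()` builds reference/target pairs with a known-truth table
so the whole pipeline can be validated without downloads. The generated
genome emulates what the algorithms actually consume: ~36 % GC; a
single-copy region with intron-free PCGs (ATG start, stop-free body,
methionine-free codons 2–20 so the start strategies can be isolated),
two-exon PCGs, plain and intron-containing tRNAs; optionally an
*rpl16*-like gene with a 9-nt first exon 1,200 nt upstream of exon 2; and
an exact inverted repeat duplicating an rRNA/tRNA subset, with
non-complementary guard bases at the arm flanks so the maximal repeat is
exactly the planted one (otherwise "exact recovery" would be ill-posed).
Introns are generated *stop-rich* by default — stop codons planted
mid-intron in both flanking HSP frames, so the stop criterion of the
intron classifier is exercised — or, as a sub-option, stop-free with
length ≢ 0 (mod 3), so the length criterion alone fires. A stop-free,
frame-preserving intron is indistinguishable from an intron loss under the
classification rule, by design of the rule itself; the generator therefore
cannot (and does not) produce that combination for an intact intron.

The target is the reference mutated by per-site substitutions at the
requested divergence, plus structural perturbations each mapping to one
expected outcome class: intron deletion (expects an intron-loss call at
exact merged coordinates), start-codon mutation to ACG with a
methionine-free neighbourhood (expects strategy (c) and a non-ATG
warning), an upstream in-frame ATG planted behind a stop (expects
strategy (b) at the new start), 3′ truncation with a planted stop at ~36 %
of the gene (expects a low-coverage flag), whole-gene deletion (expects
"missing"), and a codon scramble replacing 70 % of internal codons with
different-residue codons, i.e. ~30 % amino-acid identity (expects a skip
logged with that identity).

Two generator rules keep the truth table *valid* rather than easy:
substitutions never touch CDS start/stop codons or the 9-nt short exon 1,
and substitutions that would create an in-frame stop inside a CDS are
re-drawn. Both mirror purifying selection — real coding divergence is
overwhelmingly non-nonsense — and without them the expected annotation
could not be stated at generation time (a mutated start codon genuinely
changes the correct answer). Everything else, including gene bodies,
boundary-probe regions and intergenic sequence, diverges freely.

What passing fixture tests does **not** show: robustness to indels and
rearrangements (coordinates in the fixtures never shift within genes),
assembly gaps, RNA editing, trans-splicing, or real IR
expansion/contraction. The fixtures validate the boundary logic and the
bookkeeping, not the full messiness of field data.

# Numerical and policy choices

* Coordinates are 0-based half-open internally; conversion to the 1-based
  inclusive GenBank convention happens only in the GenBank reader/writer.
  Reading order (5′→3′ of the gene) is the canonical segment order.
* Fuzzy GenBank positions (`<`, `>`) and `order(...)` locations are
  rejected as validation issues rather than silently reinterpreted.
* Gene names are matched case-sensitively; IR copies are separate
  annotations with their own copy index.
* The log's statistics lines count the reference total in unique gene
  names and the annotated total in copies; the convention is printed in
  the log header so the two numbers are never compared naively.
* The annotation path is seed-free and deterministic: identical inputs
  and backend give byte-identical GenBank and log output (search output
  is order-normalised). All randomness lives in the fixture generator,
  which restores the caller's RNG state.
* Problem sizes in the shipped validation: fixtures of ~9–12 kb with
  8–12 genes; 20 self-annotation fixtures; 50 single-perturbation
  fixtures at 3 % divergence; 55 genes for the split-codon oracle;
  planted 30 kb sequences for IR recovery. These sizes exercise every
  code path (both IR copies included) while keeping a full validation run
  in well under a minute.

# Known limitations

* Indels near boundaries: probe anchoring assumes substitution-dominated
  divergence within the 30–60 nt probe regions; an indel there degrades a
  boundary to the HSP end (warned).
* Origin-spanning genes require a prior rotation of the target.
* The stop-scan-from-5′ rule annotates premature stops in pseudogene-like
  loci (with a warning) rather than the homologous full-length stop.
* The exon-1 mirror construction for intron boundaries is a symmetric
  reading of the two-exon procedure; the frame identity it must satisfy is
  asserted, but exotic split arrangements (trans-splicing) are out of
  scope.
* `ycf`/ORF renaming, de-novo gene discovery and RNA-editing-aware start
  prediction are out of scope.
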
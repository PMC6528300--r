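# plastanno

Reference-based batch annotation of plastid genomes (plastomes) in R.

## The problem

Plastomes are small (120–160 kb), circular, gene-dense genomes with a
highly conserved gene complement and a quadripartite structure: a large and
a small single-copy region separated by two inverted-repeat (IR) copies.
New plastome assemblies arrive as bare FASTA sequences; annotating them
means transferring the ~110–130 known genes from an annotated relative and
then getting every boundary right — start and stop codons for
protein-coding genes (PCGs), exact ends for tRNAs and rRNAs, exon–intron
junctions for the ~20 intron-containing genes, and the IR boundaries.
Boundary errors, not missed genes, are the dominant failure mode of
annotation transfer; `plastanno` is built around explicit boundary-detection
algorithms and a warning log that tells the curator exactly what to check.

## The method

`plastanno` uses a *reverse query–subject* search: the annotated reference
genes are the queries, the unannotated target is the subject. Searching for
a fixed set of genes exploits the conserved gene content of plastomes.

1. **Reference database** (from GenBank flat files, keyed on the
   indispensable `/gene` qualifier): four components — RNA-gene
   nucleotides, PCG nucleotides, CDS amino acids without introns, CDS amino
   acids with introns (per-exon and full translations, genetic code
   table 11, translated verbatim so non-ATG initiator codons are
   preserved).
2. **Search**: BLASTN/TBLASTN-style alignment of each reference gene
   against the target (external NCBI BLAST+ adapter, or a built-in
   in-process backend with identical contract). With several references,
   the entry with the highest percent identity wins per gene; PCGs below a
   threshold (default 40 %) are logged and not annotated. High-scoring
   segment pairs (HSPs) are clustered per gene copy, so IR-duplicated genes
   are annotated once per copy.
3. **Gene boundary detection (PCG starts/stops)**: the stop codon is the
   first in-frame TAA/TAG/TGA downstream of the HSP 5′ end. The start codon
   cascade: (a) the HSP begins with methionine → that ATG; (b) otherwise
   the in-frame ATG closest to the first upstream in-frame stop, searched
   up to the HSP's 20th amino acid; (c) otherwise a sliding 4-amino-acid
   probe from the reference N-terminus, searched right-to-left, with the
   matched position shifted back by the probe offset — this recovers
   non-ATG start codons; (d) otherwise the HSP 5′ end, flagged. Strategies
   (c)/(d) always produce a manual-verification warning. RNA-gene ends are
   refined with 9-nt probes from the reference termini over a 60-nt window
   per end.
4. **Intron boundary detection**: the region between two consecutive HSPs
   contains an intron iff it has an in-frame stop codon or its length is
   not a multiple of three; otherwise the intron has been *lost* and the
   exons are annotated as a single CDS (logged). Present introns get their
   exon-2 boundary from the same sliding-probe search anchored on the
   reference exon-2 N-terminus, shifted left by the number of split-codon
   nucleotides (reference exon-2 length mod 3); the exon-1 boundary by the
   mirrored procedure. Intron-containing tRNAs use the 9-nt probe variant.
   The short (6–9 nt) first exons of *rpl16*, *petB* and *petD* are invisible
   to the similarity search and are recovered by an exact probe search
   upstream of exon 2.
5. **IR detection**: self-search of the target against its reverse
   complement; the longest non-overlapping reverse-strand pair at least
   `minIrLength` (default 1000 nt) long becomes IRa/IRb.
6. **Pseudogene screening**: query coverage = annotated length / reference
   length; coverage strictly below 0.5 or above 2 (both adjustable) is
   flagged in the log.

Output is one annotated GenBank file per target plus a consolidated
`warning.log` with skipped genes (and their identities), typed warnings,
and per-target statistics (reference gene total, annotated total, missing
gene names).

## Worked example

The package ships a synthetic-fixture generator that builds
reference/target pairs with known truth (see the methods vignette). Here a
target carrying an *atpF* intron loss is annotated against its reference:

```r
library(plastanno)
fx <- generateFixture(
    fixtureSpec(seed = 5, divergence = 0.02,
                perturbations = c("intron_loss", "short_exon1_gene")),
    dir = "demo")
dir.create("demo/refs"); dir.create("demo/tgts")
file.copy(fx$referencePath, "demo/refs/reference.gb")
file.copy(fx$targetPath, "demo/tgts/sample1.fasta")
runBatch("demo/refs", "demo/tgts", "demo/out")
```

or, from the shell:

```sh
Rscript inst/scripts/annotate_plastomes.R -r demo/refs -t demo/tgts -o demo/out
```

`demo/out/warning.log` then reads:

```
plastanno warning log
Gene counting: the reference total counts unique gene names; the annotated total counts every annotated copy (inverted-repeat duplicates included).

== Target: target5 ==
Warnings:
  atpF (copy 1) [intron_loss]: intron loss between exons 1 and 2: joined exons annotated as a single CDS
Statistics:
  Total genes in the reference plastome(s): 10
  Total genes annotated: 12
  Genes not annotated: none
```

The intron-lost *atpF* is written as a single CDS, the intact *rpl2* keeps
its `join(...)` location, the 9-nt first exon of the *rpl16*-like gene is
recovered exactly, and the IR pair appears as two `repeat_region` features
(`demo/out/sample1.gb`):

```
     CDS             2303..2800
                     /gene="atpF"
                     /note="intron lost"
     CDS             join(3047..3101,3210..3502)
                     /gene="rpl2"
     CDS             join(3721..3729,4930..5304)
                     /gene="rpl16"
     repeat_region   6236..8004
                     /note="inverted repeat A (IRa)"
```

Ten unique reference genes produce twelve annotated copies because the
rRNA and one tRNA inside the IR are annotated once per IR copy.

For real data, put annotated GenBank plastomes of close relatives in the
reference directory (check that every gene, CDS, tRNA and rRNA feature
carries its `/gene` qualifier — `validateReference()` reports lapses) and
one FASTA sequence per target file. For highly incomplete or fragmented
plastomes, a whole-genome aligner such as Mauve is the better tool for a
first pass; `plastanno` assumes an essentially complete target sequence.
Genes spanning the sequence origin of a circular target are not annotated;
rotate the sequence so the origin falls in an intergenic region first.

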
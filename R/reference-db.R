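## Build the four-component reference database from parsed reference
## plastomes: RNA nucleotides, PCG nucleotides, CDS amino acids without
## introns, CDS amino acids with introns.

## per-exon verbatim translations: exon1 keeps full codons only; later exons
## drop their leading split-codon nucleotides first, so every per-exon
## peptide is a clean codon-aligned window of the gene (the residue encoded
## by a split codon is not represented).
.exonPeptides <- function(ntSeq, exonLengths) {
    offs <- cumsum(c(0L, exonLengths))
    out <- character(length(exonLengths))
    carry <- 0L   # nt carried over a split codon into this exon
    for (i in seq_along(exonLengths)) {
        s <- offs[i] + carry
        len <- exonLengths[i] - carry
        keep <- len - (len %% 3L)
        out[i] <- if (keep >= 3L)
            translateCds(substr(ntSeq, s + 1L, s + keep)) else ""
        carry <- (3L - (len %% 3L)) %% 3L
    }
    out
}

.makeEntry <- function(geneName, category, ntSeq, exonLengths, sourceRecord) {
    warn <- character(0)
    aa <- ""
    aaExons <- character(0)
    hasIntron <- length(exonLengths) > 1L
    if (category == "PCG") {
        if (nchar(ntSeq) %% 3L != 0L) {
            warn <- c(warn, "CDS length not a multiple of 3; left untranslated")
        } else {
            aa <- translateCds(ntSeq)
            if (grepl("\\*", aa))
                warn <- c(warn, "internal stop codon in reference CDS (possible pseudogene)")
            if (hasIntron) aaExons <- .exonPeptides(ntSeq, exonLengths)
        }
    }
    new("ReferenceGeneEntry", geneName = geneName, category = category,
        ntSequence = ntSeq, exonLengths = as.integer(exonLengths),
        hasIntron = hasIntron, aaSequence = aa, aaExons = aaExons,
        sourceRecord = sourceRecord, warnings = warn)
}

#' Build the four-component reference database
#'
#' Extracts every CDS, tRNA and rRNA feature from the given reference
#' records, translates CDS under genetic code table 11 (verbatim, no
#' initiator forcing), and partitions entries into the four components: RNA
#' nucleotides, PCG nucleotides, intron-free CDS amino acids and
#' intron-containing CDS amino acids. Entries with identical
#' (gene name, nucleotide sequence) are deduplicated, so the two
#' inverted-repeat copies of a gene collapse to one entry; distinct sequences
#' from multiple references are kept as parallel entries and resolved later
#' by best-hit selection.
#'
#' @param records list of \linkS4class{PlastomeRecord} reference plastomes.
#' @return a \linkS4class{ReferenceDatabase}.
#' @export
buildReferenceDb <- function(records) {
    if (is(records, "PlastomeRecord")) records <- list(records)
    entries <- list()
    seen <- character(0)
    for (rec in records) {
        for (f in rec@features) {
            if (!f@kind %in% c("CDS", "tRNA", "rRNA")) next
            if (!nzchar(f@geneName)) next
            category <- if (f@kind == "CDS") "PCG" else f@kind
            nt <- extractFeatureSequence(rec, f@location)
            key <- paste0(f@geneName, "\r", nt)
            if (key %in% seen) next
            seen <- c(seen, key)
            exLen <- f@location@ends - f@location@starts
            ## reading order is already 5'->3' in the location
            entries[[length(entries) + 1L]] <- .makeEntry(
                f@geneName, category, nt, exLen, rec@recordId)
        }
    }
    if (!length(entries)) stop("no annotatable features in the reference(s)")
    cats <- vapply(entries, function(e) e@category, "")
    intr <- vapply(entries, function(e) e@hasIntron, TRUE)
    new("ReferenceDatabase",
        rnaNt = entries[cats %in% c("tRNA", "rRNA")],
        pcgNt = entries[cats == "PCG"],
        cdsAaIntronless = entries[cats == "PCG" & !intr],
        cdsAaIntron = entries[cats == "PCG" & intr],
        geneNames = unique(vapply(entries, function(e) e@geneName, "")))
}

#' Serialize database components to FASTA files
#'
#' Writes one FASTA per component (rna_nt, pcg_nt, cds_aa_intronless,
#' cds_aa_intron) so an external search tool can index them verbatim.
#' Sequence ids are \code{gene|source|entryIndex}.
#'
#' @param db a \linkS4class{ReferenceDatabase}.
#' @param dir output directory (created if missing).
#' @return named character vector of the four paths.
#' @export
writeDbFasta <- function(db, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    comp <- list(rna_nt = db@rnaNt, pcg_nt = db@pcgNt,
                 cds_aa_intronless = db@cdsAaIntronless,
                 cds_aa_intron = db@cdsAaIntron)
    paths <- character(0)
    for (nm in names(comp)) {
        p <- file.path(dir, paste0(nm, ".fasta"))
        con <- file(p, "w")
        for (i in seq_along(comp[[nm]])) {
            e <- comp[[nm]][[i]]
            sq <- if (grepl("^cds_aa", nm)) e@aaSequence else e@ntSequence
            writeLines(c(sprintf(">%s|%s|%d", e@geneName, e@sourceRecord, i),
                         sq), con)
        }
        close(con)
        paths[nm] <- p
    }
    paths
}

## all database entries as one list (internal)
.dbEntries <- function(db) c(db@rnaNt, db@pcgNt)
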
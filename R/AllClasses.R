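#' @import methods
#' @importFrom utils head tail
NULL

#' FeatureLocation: ordered exon segments with strand
#'
#' The coordinate currency of the package. Segments are intervals on the
#' forward axis of the subject sequence, stored 0-based half-open and ordered
#' 5'->3' in the gene's reading direction (so on the reverse strand the first
#' segment has the largest forward coordinates). Conversion to the 1-based
#' inclusive GenBank convention happens only at the GenBank read/write
#' boundary.
#'
#' @slot starts integer vector of segment starts (0-based).
#' @slot ends integer vector of segment ends (half-open).
#' @slot strand "+" or "-".
#' @export
setClass("FeatureLocation",
    representation(starts = "integer", ends = "integer", strand = "character"))

setValidity("FeatureLocation", function(object) {
    s <- object@starts; e <- object@ends
    if (length(s) == 0L) return("location must have at least one segment")
    if (length(s) != length(e)) return("starts/ends length mismatch")
    if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
    if (any(s >= e)) return("each segment must satisfy start < end")
    if (any(s < 0L)) return("negative coordinate")
    if (length(s) > 1L) {
        fwd <- if (object@strand == "+") s else rev(s)
        fe <- if (object@strand == "+") e else rev(e)
        if (any(diff(fwd) <= 0) || any(utils::head(fe, -1L) > utils::tail(fwd, -1L)))
            return("segments must be non-overlapping and ordered in reading direction")
    }
    TRUE
})

#' A single annotated feature read from (or written to) a GenBank record
#'
#' @slot geneName gene-name qualifier value ("" when absent; flagged by
#'   \code{validateReference}).
#' @slot kind one of "gene", "CDS", "tRNA", "rRNA", "repeat_region".
#' @slot location a \linkS4class{FeatureLocation}.
#' @slot qualifiers named list of qualifier values.
#' @export
setClass("GeneFeature",
    representation(geneName = "character", kind = "character",
        location = "FeatureLocation", qualifiers = "list"))

#' A plastome sequence with (possibly empty) feature annotations
#'
#' @slot recordId record identifier (LOCUS name or FASTA header word).
#' @slot sequence a \link[Biostrings]{DNAString} (uppercase).
#' @slot features list of \linkS4class{GeneFeature} (empty for targets).
#' @slot parseIssues character vector of problems met while parsing
#'   (rejected fuzzy locations etc.), surfaced by \code{validateReference}.
#' @export
setClass("PlastomeRecord",
    representation(recordId = "character", sequence = "ANY",
        features = "list", parseIssues = "character"))

setValidity("PlastomeRecord", function(object) {
    if (!is(object@sequence, "DNAString")) return("sequence must be a DNAString")
    L <- length(object@sequence)
    for (f in object@features) {
        if (any(f@location@ends > L)) return(sprintf(
            "feature '%s' extends beyond sequence end", f@geneName))
    }
    TRUE
})

#' One gene entry of the reference database
#'
#' @slot geneName gene name.
#' @slot category "rRNA", "tRNA" or "PCG".
#' @slot ntSequence coding-strand nucleotides, exons concatenated.
#' @slot exonLengths ordered exon lengths (nt).
#' @slot hasIntron logical.
#' @slot aaSequence full verbatim translation, PCG only ("" otherwise).
#' @slot aaExons per-exon translations (full codons only), PCG with intron.
#' @slot sourceRecord id of the reference record the entry came from.
#' @slot warnings issues met while building (internal stop codon etc.).
#' @export
setClass("ReferenceGeneEntry",
    representation(geneName = "character", category = "character",
        ntSequence = "character", exonLengths = "integer",
        hasIntron = "logical", aaSequence = "character",
        aaExons = "character", sourceRecord = "character",
        warnings = "character"))

#' The four-component reference database
#'
#' Built from annotated reference plastomes: RNA (rRNA + tRNA) nucleotides,
#' protein-coding gene (PCG) nucleotides, CDS amino acids without introns and
#' CDS amino acids with introns (per-exon and full translations).
#'
#' @slot rnaNt list of \linkS4class{ReferenceGeneEntry} (rRNA + tRNA).
#' @slot pcgNt list of PCG entries (nucleotide view).
#' @slot cdsAaIntronless list of intron-free PCG entries (amino-acid view).
#' @slot cdsAaIntron list of intron-containing PCG entries (amino-acid view).
#' @slot geneNames union of gene names across entries.
#' @export
setClass("ReferenceDatabase",
    representation(rnaNt = "list", pcgNt = "list",
        cdsAaIntronless = "list", cdsAaIntron = "list",
        geneNames = "character"))

setValidity("ReferenceDatabase", function(object) {
    nt <- c(vapply(object@rnaNt, function(x) x@geneName, ""),
            vapply(object@pcgNt, function(x) x@geneName, ""))
    aa <- c(vapply(object@cdsAaIntronless, function(x) x@geneName, ""),
            vapply(object@cdsAaIntron, function(x) x@geneName, ""))
    pcg <- vapply(object@pcgNt, function(x) x@geneName, "")
    if (!setequal(pcg, aa))
        return("every PCG must appear in exactly one amino-acid component")
    if (length(intersect(
            vapply(object@cdsAaIntronless, function(x) x@geneName, ""),
            vapply(object@cdsAaIntron, function(x) x@geneName, ""))) &&
        anyDuplicated(aa) == 0L) TRUE
    TRUE
})

#' A finished annotation for one gene copy
#'
#' @slot geneName gene name.
#' @slot category "rRNA", "tRNA" or "PCG".
#' @slot copyIndex which copy (inverted-repeat duplicates get 1, 2, ...).
#' @slot location forward-axis \linkS4class{FeatureLocation}.
#' @slot startStrategy "a", "b", "c", "d" or "" (non-PCG).
#' @slot startCodon annotated start codon 3-mer ("" for non-PCG).
#' @slot intronStatus "none", "intron_present" or "intron_lost".
#' @slot warnings character vector of warning messages.
#' @slot sourceReference id of the winning reference entry.
#' @slot coverage annotated length / reference length (query coverage).
#' @export
setClass("GeneAnnotation",
    representation(geneName = "character", category = "character",
        copyIndex = "integer", location = "FeatureLocation",
        startStrategy = "character", startCodon = "character",
        intronStatus = "character", warnings = "character",
        sourceReference = "character", coverage = "numeric"))

#' Inverted-repeat / quadripartite structure annotation
#'
#' Intervals are forward-axis, 0-based half-open; \code{found = FALSE} for
#' IR-lacking plastomes (all intervals then empty).
#'
#' @slot found logical.
#' @slot ira,irb,lsc,ssc integer length-2 vectors (start, end).
#' @slot identity percent identity between IRa and reverse-complemented IRb.
#' @slot warnings character vector.
#' @export
setClass("IrAnnotation",
    representation(found = "logical", ira = "integer", irb = "integer",
        lsc = "integer", ssc = "integer", identity = "numeric",
        warnings = "character"))

## ---- constructors ----------------------------------------------------------

#' Create a FeatureLocation
#'
#' @param starts,ends integer vectors, 0-based half-open forward-axis
#'   segments, given in reading order.
#' @param strand "+" or "-".
#' @return a \linkS4class{FeatureLocation}.
#' @export
FeatureLocation <- function(starts, ends, strand = "+") {
    new("FeatureLocation", starts = as.integer(starts),
        ends = as.integer(ends), strand = strand)
}

#' @rdname FeatureLocation
#' @param x a FeatureLocation.
#' @export
locStrand <- function(x) x@strand

#' @rdname FeatureLocation
#' @export
locStarts <- function(x) x@starts

#' @rdname FeatureLocation
#' @export
locEnds <- function(x) x@ends

#' @rdname FeatureLocation
#' @export
locWidth <- function(x) sum(x@ends - x@starts)

setMethod("show", "FeatureLocation", function(object) {
    segs <- paste0("[", object@starts, ",", object@ends, ")", collapse = ",")
    cat("FeatureLocation(", segs, ") strand ", object@strand, "\n", sep = "")
})

setMethod("show", "PlastomeRecord", function(object) {
    cat("PlastomeRecord '", object@recordId, "': ",
        length(object@sequence), " nt, ", length(object@features),
        " features\n", sep = "")
})

setMethod("show", "ReferenceDatabase", function(object) {
    cat("ReferenceDatabase:",
        length(object@rnaNt), "RNA nt entries,",
        length(object@pcgNt), "PCG nt entries,",
        length(object@cdsAaIntronless), "intron-free CDS aa,",
        length(object@cdsAaIntron), "intron-containing CDS aa\n")
})

setMethod("show", "GeneAnnotation", function(object) {
    cat(sprintf("GeneAnnotation %s (%s) copy %d %s [%s] strategy=%s %s\n",
        object@geneName, object@category, object@copyIndex,
        locStrand(object@location),
        paste0(locStarts(object@location), "-", locEnds(object@location),
               collapse = ","),
        object@startStrategy, object@intronStatus))
})

setMethod("show", "IrAnnotation", function(object) {
    if (!object@found) { cat("IrAnnotation: no IR found\n"); return(invisible(NULL)) }
    cat(sprintf("IrAnnotation: IRa [%d,%d) IRb [%d,%d) identity %.1f\n",
        object@ira[1], object@ira[2], object@irb[1], object@irb[2],
        object@identity))
})

## accessors used across the package

#' Accessors for annotation and record objects
#'
#' @param x the object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
geneName <- function(x) x@geneName

#' @rdname accessors
#' @export
recordId <- function(x) x@recordId

#' @rdname accessors
#' @export
recordSequence <- function(x) x@sequence

#' @rdname accessors
#' @export
recordFeatures <- function(x) x@features

#' @rdname accessors
#' @export
annotationLocation <- function(x) x@location

#' @rdname accessors
#' @export
annotationWarnings <- function(x) x@warnings
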
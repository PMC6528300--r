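## Turn per-gene HSP clusters into preliminary gene loci, including the
## dedicated upstream search for the short first exons of rpl16, petB and
## petD (6-9 nt, too short for the similarity search to find).

.entryIds <- function(entries)
    vapply(seq_along(entries), function(i)
        paste(entries[[i]]@geneName, entries[[i]]@sourceRecord, i, sep = "|"),
        "")

#' Locate all reference genes in a target plastome
#'
#' Runs the nucleotide search for RNA genes and the protein search for
#' protein-coding genes, selects the best reference per gene and clusters
#' HSPs into per-copy loci. PCGs whose best percent identity falls below the
#' threshold are put on the skipped list with their identity (for the log);
#' genes with no hit at all are recorded as missing.
#'
#' @param db a \linkS4class{ReferenceDatabase}.
#' @param target a \linkS4class{PlastomeRecord}.
#' @param cfg a \code{\link{searchConfig}}.
#' @param index optional precomputed target index.
#' @return list(loci, skipped, missing): \code{loci} is a list of
#'   preliminary loci (geneName, category, strand, cluster data.frame,
#'   copyIndex, entry); \code{skipped} a data.frame(geneName, identity);
#'   \code{missing} a character vector of gene names.
#' @export
locateGenes <- function(db, target, cfg = searchConfig(), index = NULL) {
    if (is.null(index) && cfg$backend == "builtin")
        index <- .targetIndex(target)
    rnaEntries <- db@rnaNt
    aaEntries <- c(db@cdsAaIntronless, db@cdsAaIntron)
    hsps <- .emptyHsp()
    if (length(rnaEntries))
        hsps <- rbind(hsps, searchNucleotide(rnaEntries, target, cfg, index))
    if (length(aaEntries))
        hsps <- rbind(hsps, searchProtein(aaEntries, target, cfg, index))
    lookup <- c(stats::setNames(rnaEntries, .entryIds(rnaEntries)),
                stats::setNames(aaEntries, .entryIds(aaEntries)))
    clusters <- selectBestHits(hsps, cfg)
    loci <- list()
    skipped <- data.frame(geneName = character(0), identity = numeric(0),
                          stringsAsFactors = FALSE)
    for (g in names(clusters)) {
        cls <- clusters[[g]]
        entry <- lookup[[cls[[1]]$entryId[1]]]
        bestId <- max(vapply(cls, function(cl) max(cl$identity), 0))
        if (entry@category == "PCG" && bestId < cfg$identityThresholdPcg) {
            skipped <- rbind(skipped, data.frame(geneName = g,
                identity = bestId, stringsAsFactors = FALSE))
            next
        }
        for (i in seq_along(cls)) {
            loci[[length(loci) + 1L]] <- list(
                geneName = g, category = entry@category,
                strand = cls[[i]]$strand[1], cluster = cls[[i]],
                copyIndex = i, entry = entry)
        }
    }
    missing <- setdiff(db@geneNames,
                       c(names(clusters), skipped$geneName))
    list(loci = loci, skipped = skipped, missing = missing)
}

#' Locate the short first exon of rpl16/petB/petD upstream of exon 2
#'
#' Exact-match search (optionally tolerating one mismatch) for the reference
#' exon-1 sequence on the coding strand within \code{window} nt upstream of
#' the located exon 2; the match nearest to exon 2 wins. Returns NULL when
#' no match exists (the caller logs a warning and annotates exon 2 only).
#'
#' @param targetCs coding-strand target sequence (character).
#' @param exon2Start 0-based coding-strand offset of the annotated exon 2.
#' @param refExon1Nt reference exon-1 nucleotides (6-9 nt).
#' @param window upstream search window (nt). Default 2000.
#' @param mismatches 0 (default) or 1.
#' @return c(start, end) on the coding strand, or NULL.
#' @export
locateShortExon1 <- function(targetCs, exon2Start, refExon1Nt,
                             window = 2000L, mismatches = 0L) {
    n <- nchar(refExon1Nt)
    rs <- max(0L, exon2Start - window)
    if (exon2Start - rs < n) return(NULL)
    region <- Biostrings::DNAString(substr(targetCs, rs + 1L, exon2Start))
    m <- Biostrings::matchPattern(Biostrings::DNAString(refExon1Nt), region,
                                  max.mismatch = mismatches,
                                  with.indels = FALSE)
    if (!length(m)) return(NULL)
    st <- BiocGenerics::start(m) - 1L + rs
    if (mismatches > 0L) {
        ## prefer exact matches, then proximity to exon 2
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(refExon1Nt),
            region, starting.at = BiocGenerics::start(m))
        st <- st[order(mm, -st)]
    } else {
        st <- st[order(-st)]   # nearest to exon 2 first
    }
    c(st[1], st[1] + n)
}
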
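## Internal helpers: coordinates, strand flips, verbatim translation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## genetic code table 11 (plastid/bacterial) as a plain lookup; verbatim
## translation, no initiator special-casing (GTG stays V): start-codon
## handling is the boundary algorithms' job, not the translator's.
.CODE11 <- local({
    gc <- Biostrings::getGeneticCode("11")
    attributes(gc) <- list(names = names(gc))
    gc
})

#' Translate a coding sequence verbatim under genetic code table 11
#'
#' Terminal stop is dropped; internal stops are kept as "*" (callers attach a
#' pseudogene warning). Codons containing ambiguity codes translate to "X".
#'
#' @param nt nucleotide string, length a multiple of 3.
#' @return amino-acid string.
#' @export
translateCds <- function(nt) {
    nt <- toupper(nt)
    n <- nchar(nt)
    if (n %% 3L != 0L)
        stop("CDS length ", n, " is not a multiple of 3")
    if (n == 0L) return("")
    codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- .CODE11[codons]
    aa[is.na(aa)] <- "X"
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste0(aa, collapse = "")
}

## reverse complement of a plain character string
.revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## map one 0-based half-open interval between forward axis and the
## coding-strand axis of a reverse-strand gene (sequence length L)
.flipInterval <- function(start, end, L) c(L - end, L - start)

## orient a forward-axis interval set (reading order) into coding-strand
## coordinates: identity on "+", flip on "-"
.toCodingStrand <- function(starts, ends, strand, L) {
    if (strand == "+") return(list(starts = starts, ends = ends))
    list(starts = L - ends, ends = L - starts)
}

## inverse of .toCodingStrand (same involution)
.toForward <- .toCodingStrand

## first in-frame stop codon start scanning upstream from `from` (exclusive),
## on a coding-strand character sequence; NULL when none
.upstreamStop <- function(cs, from) {
    p <- from - 3L
    while (p >= 0L) {
        if (substr(cs, p + 1L, p + 3L) %in% STOP_CODONS) return(p)
        p <- p - 3L
    }
    NULL
}

## all in-frame positions of `codon` within [rs, re) of cs (0-based starts)
.inFrameCodonHits <- function(cs, rs, re, codons) {
    if (re - rs < 3L) return(integer(0))
    p <- seq(rs, re - 3L, by = 3L)
    cod <- substring(cs, p + 1L, p + 3L)
    p[cod %in% codons]
}

## restore-on-exit seeded evaluation (keeps global RNG stream untouched)
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
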
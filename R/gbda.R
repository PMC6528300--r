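## Gene Boundary Detection Algorithm (GBDA).
##
## Resolves start and stop codons for protein-coding genes through a
## four-strategy cascade (a-d), and refines rRNA / intron-free tRNA ends
## with a sliding 9-nt probe. All operations act on the coding-strand
## oriented target sequence (plain character string, 0-based half-open
## coordinates); the caller maps results back to the forward axis.

#' GBDA tuning parameters
#'
#' @param searchDepthAa how deep into the HSP / reference N-terminus the
#'   start-codon search reaches (amino acids, bound inclusive). Default 20.
#' @param rnaProbeNt length of the RNA boundary probe. Default 9.
#' @param rnaWindowNt reference terminal window the probes are drawn from
#'   (and the HSP-side half of the search region). Default 30.
#' @param rnaFlankNt flank added beyond the HSP end. Default 30.
#' @return named list.
#' @export
gbdaParams <- function(searchDepthAa = 20L, rnaProbeNt = 9L,
                       rnaWindowNt = 30L, rnaFlankNt = 30L) {
    stopifnot(searchDepthAa > 0, rnaProbeNt > 0, rnaWindowNt >= rnaProbeNt,
              rnaFlankNt > 0)
    list(searchDepthAa = as.integer(searchDepthAa),
         rnaProbeNt = as.integer(rnaProbeNt),
         rnaWindowNt = as.integer(rnaWindowNt),
         rnaFlankNt = as.integer(rnaFlankNt))
}

#' Find the annotated stop codon
#'
#' Scans codons downstream from the 5' end of the HSP; the first TAA/TAG/TGA
#' encountered in frame is returned as the annotated stop. A stop falling
#' inside the HSP itself (premature, pseudogene-like) is still returned, with
#' a warning. If no stop exists before the sequence end, the last full codon
#' boundary is returned with a "runaway ORF" warning.
#'
#' @param targetCs coding-strand target sequence (character).
#' @param hsp5p 0-based offset of the HSP 5' end (in frame).
#' @param hsp3p optional HSP 3' end, used only to warn on premature stops.
#' @return list(stopEnd, found, warnings).
#' @export
findStop <- function(targetCs, hsp5p, hsp3p = NULL) {
    L <- nchar(targetCs)
    p <- hsp5p
    while (p + 3L <= L) {
        if (substr(targetCs, p + 1L, p + 3L) %in% STOP_CODONS) {
            w <- character(0)
            if (!is.null(hsp3p) && p + 3L < hsp3p)
                w <- "in-frame stop codon inside the HSP (possible pseudogene)"
            return(list(stopEnd = p + 3L, found = TRUE, warnings = w))
        }
        p <- p + 3L
    }
    list(stopEnd = hsp5p + 3L * ((L - hsp5p) %/% 3L), found = FALSE,
         warnings = "runaway ORF: no stop codon before sequence end")
}

## start/end (0-based) of the start-search region: from the first in-frame
## stop upstream of the HSP (exclusive) to the HSP's 20th amino acid
.startRegion <- function(targetCs, hspStart, params) {
    up <- .upstreamStop(targetCs, hspStart)
    warn <- character(0)
    if (is.null(up)) {
        rs <- hspStart %% 3L
        warn <- "no in-frame stop codon upstream of HSP; region truncated at sequence start"
    } else rs <- up + 3L
    re <- hspStart + 3L * params$searchDepthAa
    re <- min(re, 3L * ((nchar(targetCs) - rs) %/% 3L) + rs)
    list(rs = rs, re = re, warnings = warn)
}

#' Resolve the start codon of a protein-coding gene (strategies a-d)
#'
#' The cascade: (a) the HSP's first amino acid is methionine - its codon is
#' the start; (b) otherwise the in-frame ATG closest to the first upstream
#' in-frame stop codon, searched between that stop and the HSP's 20th amino
#' acid, is the start; (c) otherwise a sliding 4-amino-acid probe from the
#' reference N-terminus (window shifted one residue at a time, up to the
#' 20th) is searched right-to-left across the same region, and the matched
#' position shifted left by the window shift becomes the (possibly non-ATG)
#' start; (d) otherwise the HSP 5' end is the putative start. Strategies (c)
#' and (d) always attach a manual-verification warning.
#'
#' @param targetCs coding-strand target sequence.
#' @param hspStart 0-based HSP 5' offset (in frame).
#' @param refAa reference N-terminal amino acids (the full reference peptide
#'   is fine; only the first \code{searchDepthAa} are probed).
#' @param params \code{\link{gbdaParams}}.
#' @return list(start, strategy, startCodon, probeShift, probe, warnings).
#' @export
findStart <- function(targetCs, hspStart, refAa, params = gbdaParams()) {
    reg <- .startRegion(targetCs, hspStart, params)
    warn <- reg$warnings
    codonAt <- function(p) substr(targetCs, p + 1L, p + 3L)
    ## (a) first HSP amino acid is methionine
    if (.CODE11[codonAt(hspStart)] %in% "M")
        return(list(start = hspStart, strategy = "a",
                    startCodon = codonAt(hspStart), probeShift = NA_integer_,
                    probe = NA_character_, warnings = warn))
    ## (b) in-frame ATG closest to the upstream stop
    atg <- .inFrameCodonHits(targetCs, reg$rs, reg$re, "ATG")
    if (length(atg))
        return(list(start = min(atg), strategy = "b", startCodon = "ATG",
                    probeShift = NA_integer_, probe = NA_character_,
                    warnings = warn))
    ## (c) sliding 4-aa probe from the reference N-terminus
    nReg <- (reg$re - reg$rs) %/% 3L
    if (nReg >= 4L) {
        regionAa <- translateCds(substr(targetCs, reg$rs + 1L,
                                        reg$rs + 3L * nReg))
        for (k in 0:(params$searchDepthAa - 4L)) {
            if (k + 4L > nchar(refAa)) break
            probe <- substr(refAa, k + 1L, k + 4L)
            hit <- gregexpr(probe, regionAa, fixed = TRUE)[[1]]
            if (hit[1] == -1L) next
            cand <- (hit - 1L) - k          # aa index of implied start
            cand <- cand[cand >= 0L]        # never left of the upstream stop
            if (!length(cand)) next
            c0 <- min(cand)                 # closest to the upstream stop
            start <- reg$rs + 3L * c0
            codon <- codonAt(start)
            return(list(start = start, strategy = "c", startCodon = codon,
                probeShift = k, probe = probe,
                warnings = c(warn, sprintf(
                    "start codon %s placed by reference probe '%s' (shift %d); verify manually",
                    codon, probe, k))))
        }
    }
    ## (d) tentative: HSP 5' end
    list(start = hspStart, strategy = "d", startCodon = codonAt(hspStart),
         probeShift = NA_integer_, probe = NA_character_,
         warnings = c(warn,
             "putative start codon at HSP 5' end (strategy d); verify manually"))
}

## shared 9-nt probe search for one feature end.
##   side "5p": probes from the reference 5' terminus, boundary = match - off
##   side "3p": probes from the reference 3' terminus, boundary = matchEnd + off
## anchor is the corresponding HSP end; the candidate closest to the anchor
## wins. Returns NULL when no probe matches.
.probeEnd <- function(targetCs, anchor, refSeq, side, params) {
    L <- nchar(targetCs)
    rs <- max(0L, anchor - params$rnaWindowNt)
    re <- min(L, anchor + params$rnaFlankNt)
    if (side == "5p") { rs <- max(0L, anchor - params$rnaFlankNt)
                        re <- min(L, anchor + params$rnaWindowNt) }
    region <- substr(targetCs, rs + 1L, re)
    n <- nchar(refSeq); pr <- params$rnaProbeNt
    for (off in 0:(params$rnaWindowNt - pr)) {
        probe <- if (side == "5p") substr(refSeq, off + 1L, off + pr)
                 else substr(refSeq, n - pr - off + 1L, n - off)
        if (nchar(probe) < pr) break
        hit <- gregexpr(probe, region, fixed = TRUE)[[1]]
        if (hit[1] == -1L) next
        cand <- if (side == "5p") rs + (hit - 1L) - off
                else rs + (hit - 1L) + pr + off
        cand <- cand[cand >= 0L & cand <= L]
        if (!length(cand)) next
        return(cand[which.min(abs(cand - anchor))])
    }
    NULL
}

#' Refine the boundaries of an rRNA or intron-free tRNA
#'
#' For each end independently, 9-nt probes drawn from the first 30 nt of the
#' corresponding reference gene terminus (sliding inward one nt at a time)
#' are searched across the 60-nt region made of the terminal 30 nt of the
#' HSP plus the adjacent 30-nt flank; the first matching probe anchors the
#' boundary, shifted outward by the probe's offset within the reference
#' terminus. If no probe matches, the HSP end is kept and a warning emitted.
#'
#' @param targetCs coding-strand target sequence.
#' @param hsp5p,hsp3p HSP ends, 0-based half-open.
#' @param refRnaNt reference RNA gene nucleotides (sense strand).
#' @param params \code{\link{gbdaParams}}.
#' @return list(start, end, warnings).
#' @export
refineRnaBoundaries <- function(targetCs, hsp5p, hsp3p, refRnaNt,
                                params = gbdaParams()) {
    warn <- character(0)
    s <- .probeEnd(targetCs, hsp5p, refRnaNt, "5p", params)
    if (is.null(s)) {
        s <- hsp5p
        warn <- c(warn, "no 5' probe match; HSP end kept")
    }
    e <- .probeEnd(targetCs, hsp3p, refRnaNt, "3p", params)
    if (is.null(e)) {
        e <- hsp3p
        warn <- c(warn, "no 3' probe match; HSP end kept")
    }
    if (s >= e) { s <- hsp5p; e <- hsp3p
        warn <- c(warn, "inconsistent probe boundaries; HSP ends kept") }
    list(start = s, end = e, warnings = warn)
}
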
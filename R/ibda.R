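## Intron Boundary Detection Algorithm (IBDA).
##
## Classifies the inter-HSP region of a two-HSP gene (intron present vs
## intron lost), places the exon-intron boundaries via the GBDA-style
## sliding-probe search plus split-codon arithmetic for protein-coding
## genes, and via the 9-nt probe variant for intron-containing tRNAs.
## Coordinates are coding-strand, 0-based half-open; hsp1 lies strictly 5'
## of hsp2.

#' Classify the inter-HSP region: intron present or intron lost
#'
#' The intron is present iff the region strictly between the 3' end of HSP1
#' and the 5' end of HSP2 contains an in-frame stop codon (frame inherited
#' from HSP1) or its length is not a multiple of three. The intron is lost
#' iff the region length is a multiple of three with no in-frame stop, or
#' the two HSP ends coincide (zero-length region).
#'
#' @param targetCs coding-strand target sequence.
#' @param hsp1End 3' end of HSP1 (0-based half-open, in frame).
#' @param hsp2Start 5' end of HSP2. Overlapping HSPs (hsp2Start < hsp1End)
#'   are treated as zero-length regions (the caller trims).
#' @return "intron_present" or "intron_lost".
#' @export
classifyInterHsp <- function(targetCs, hsp1End, hsp2Start) {
    g <- hsp2Start - hsp1End
    if (g <= 0L) return("intron_lost")
    if (g %% 3L != 0L) return("intron_present")
    if (length(.inFrameCodonHits(targetCs, hsp1End, hsp2Start, STOP_CODONS)))
        "intron_present" else "intron_lost"
}

## probe search for exon2's first full codon: GBDA strategy-(c) bookkeeping
## against the reference exon2 N-terminus, region between the first in-frame
## stop upstream of HSP2 and HSP2's 20th amino acid
.probeExon2FirstCodon <- function(targetCs, hsp2Start, refExon2Aa, params) {
    reg <- .startRegion(targetCs, hsp2Start, params)
    nReg <- (reg$re - reg$rs) %/% 3L
    if (nReg < 4L) return(NULL)
    regionAa <- translateCds(substr(targetCs, reg$rs + 1L, reg$rs + 3L * nReg))
    for (k in 0:(params$searchDepthAa - 4L)) {
        if (k + 4L > nchar(refExon2Aa)) break
        probe <- substr(refExon2Aa, k + 1L, k + 4L)
        hit <- gregexpr(probe, regionAa, fixed = TRUE)[[1]]
        if (hit[1] == -1L) next
        cand <- (hit - 1L) - k
        cand <- cand[cand >= 0L]
        if (!length(cand)) next
        return(list(pos = reg$rs + 3L * min(cand), shift = k, probe = probe))
    }
    NULL
}

## mirrored probe search for exon1's last full codon: 4-aa probes drawn from
## the reference exon1 C-terminus (window shifted upstream one residue at a
## time), searched across the region between HSP1's 20th-from-last amino
## acid and the first in-frame stop downstream of HSP1's 3' end; the
## candidate closest to that stop wins
.probeExon1LastCodon <- function(targetCs, hsp1End, refExon1Aa, params) {
    L <- nchar(targetCs)
    ## region end: first in-frame stop at/after hsp1End (codons in HSP1 frame)
    re <- hsp1End
    while (re + 3L <= L &&
           !substr(targetCs, re + 1L, re + 3L) %in% STOP_CODONS)
        re <- re + 3L
    rs <- max(hsp1End %% 3L, hsp1End - 3L * params$searchDepthAa)
    nReg <- (re - rs) %/% 3L
    if (nReg < 4L) return(NULL)
    regionAa <- translateCds(substr(targetCs, rs + 1L, rs + 3L * nReg))
    n1 <- nchar(refExon1Aa)
    for (k in 0:(params$searchDepthAa - 4L)) {
        if (n1 - k - 3L < 1L) break
        probe <- substr(refExon1Aa, n1 - k - 3L, n1 - k)
        hit <- gregexpr(probe, regionAa, fixed = TRUE)[[1]]
        if (hit[1] == -1L) next
        ## match covers aa [hit-1, hit+3); exon1's last full codon ends k
        ## codons right of the probe's last residue
        cand <- (hit - 1L) + 4L + k
        cand <- cand[cand <= nReg]
        if (!length(cand)) next
        return(list(pos = rs + 3L * max(cand), shift = k, probe = probe))
    }
    NULL
}

#' Locate the exon-intron boundaries of an intron-containing PCG
#'
#' Call after \code{\link{classifyInterHsp}} returned intron_present. The
#' 5' end of exon2 is found by the sliding-probe search against the
#' reference exon2 N-terminus, then moved left by the number of split-codon
#' nucleotides (reference exon2 length mod 3). The exon1/intron boundary is
#' found by the mirrored procedure at exon1's 3' end (probe from the
#' reference exon1 C-terminus, boundary moved right by reference exon1
#' length mod 3). On probe failure the corresponding HSP end is used
#' instead (fallback, logged for manual verification).
#'
#' @param targetCs coding-strand target sequence.
#' @param hsp1End,hsp2Start HSP ends flanking the intron (in frame).
#' @param refExon1Aa,refExon2Aa per-exon reference peptides.
#' @param refExon1LenNt,refExon2LenNt reference exon nucleotide lengths.
#' @param params \code{\link{gbdaParams}}.
#' @return list(status, exon1End, exon2Start, splitCodonNt, strategy,
#'   warnings); exon1End/exon2Start delimit the annotated intron.
#' @export
locatePcgIntronBoundaries <- function(targetCs, hsp1End, hsp2Start,
        refExon1Aa, refExon2Aa, refExon1LenNt, refExon2LenNt,
        params = gbdaParams()) {
    splitNt <- refExon2LenNt %% 3L
    r1 <- refExon1LenNt %% 3L
    warn <- character(0)
    strategy <- "probe"
    p2 <- .probeExon2FirstCodon(targetCs, hsp2Start, refExon2Aa, params)
    if (!is.null(p2)) {
        exon2Start <- p2$pos - splitNt
    } else {
        strategy <- "fallback_b"
        exon2Start <- hsp2Start - splitNt
        warn <- c(warn, paste0("exon2 probe failed; first amino acid of ",
            "HSP2 tentatively annotated as first codon; verify manually"))
    }
    p1 <- .probeExon1LastCodon(targetCs, hsp1End, refExon1Aa, params)
    if (!is.null(p1)) {
        exon1End <- p1$pos + r1
    } else {
        if (strategy == "probe") strategy <- "fallback_b"
        exon1End <- hsp1End + r1
        warn <- c(warn, "exon1 probe failed; HSP1 3' end kept; verify manually")
    }
    if (exon1End >= exon2Start) {
        exon1End <- hsp1End + r1
        exon2Start <- hsp2Start - splitNt
        strategy <- "fallback_b"
        warn <- c(warn, "inconsistent intron boundaries; HSP ends kept")
    }
    list(status = "intron_present", exon1End = exon1End,
         exon2Start = exon2Start, splitCodonNt = splitNt,
         strategy = strategy, warnings = warn)
}

#' Locate the exon-intron boundaries of an intron-containing tRNA
#'
#' Intron loss first: a gap shorter than 10 nt with abutting query
#' coordinates means the intron is absent and the exons are annotated as a
#' single feature. Otherwise each of the four exon ends is refined
#' independently with the 9-nt probe scheme (probes from the first/last
#' 30 nt of each reference exon, searched over the 30 nt of the HSP end plus
#' the adjacent 30-nt flank); on probe failure the HSP end is kept with a
#' warning.
#'
#' @param targetCs coding-strand target sequence.
#' @param hsp1,hsp2 lists with sStart/sEnd (coding-strand) and qStart/qEnd
#'   (concatenated-exon nucleotide axis).
#' @param refExon1Nt,refExon2Nt reference exon nucleotide sequences.
#' @param params \code{\link{gbdaParams}}.
#' @return list(status, segments (list of c(start, end)), strategy, warnings).
#' @export
locateTrnaIntronBoundaries <- function(targetCs, hsp1, hsp2,
        refExon1Nt, refExon2Nt, params = gbdaParams()) {
    gap <- hsp2$sStart - hsp1$sEnd
    qAbut <- abs(hsp2$qStart - hsp1$qEnd) <= 3L
    if (gap < 10L && qAbut) {
        outer <- refineRnaBoundaries(targetCs, hsp1$sStart, hsp2$sEnd,
            paste0(refExon1Nt, refExon2Nt), params)
        return(list(status = "intron_lost",
            segments = list(c(outer$start, outer$end)),
            strategy = "probe", warnings = outer$warnings))
    }
    warn <- character(0)
    strategy <- "probe"
    endOf <- function(anchor, ref, side) {
        p <- .probeEnd(targetCs, anchor, ref, side, params)
        if (is.null(p)) {
            warn <<- c(warn, sprintf("no probe match at %s end near %d; HSP end kept",
                                     side, anchor))
            strategy <<- "fallback_b"
            p <- anchor
        }
        p
    }
    s1 <- endOf(hsp1$sStart, refExon1Nt, "5p")
    e1 <- endOf(hsp1$sEnd, refExon1Nt, "3p")
    s2 <- endOf(hsp2$sStart, refExon2Nt, "5p")
    e2 <- endOf(hsp2$sEnd, refExon2Nt, "3p")
    if (s1 >= e1 || e1 >= s2 || s2 >= e2) {
        warn <- c(warn, "inconsistent tRNA exon boundaries; HSP ends kept")
        s1 <- hsp1$sStart; e1 <- hsp1$sEnd; s2 <- hsp2$sStart; e2 <- hsp2$sEnd
        strategy <- "fallback_b"
    }
    list(status = "intron_present",
         segments = list(c(s1, e1), c(s2, e2)),
         strategy = strategy, warnings = warn)
}
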
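## Inverted-repeat detection via self-search, and query-coverage pseudogene
## screening.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## character-level complement test (single bases)
.isComp <- function(a, b) identical(unname(.COMP[a]), b)

#' Detect the inverted repeat and the quadripartite structure
#'
#' Self-search of the target against its own reverse complement: exact
#' window matches are chained along anti-diagonals into candidate repeat
#' pairs, maximally extended, and the longest non-overlapping
#' reverse-strand pair of length >= \code{minIrLength} becomes (IRa, IRb),
#' ordered by position. The larger inter-IR region is reported as the LSC,
#' the smaller as the SSC; the region spanning the sequence end is encoded
#' with end = start + width possibly exceeding the sequence length (modular
#' coordinates). With no qualifying pair, \code{found} is FALSE (IR-lacking
#' plastome). With \code{circular = TRUE} the search runs on the doubled
#' sequence so a repeat arm spanning the origin is still recovered (arm
#' starts reported mod L).
#'
#' @param target a \linkS4class{PlastomeRecord}.
#' @param minIrLength minimum allowed IR length (nt). Default 1000.
#' @param circular treat the sequence as circular.
#' @param window seed window size for the self-search (nt).
#' @return an \linkS4class{IrAnnotation}.
#' @export
detectIr <- function(target, minIrLength = 1000L, circular = FALSE,
                     window = 250L) {
    seqChr <- as.character(target@sequence)
    L <- nchar(seqChr)
    none <- new("IrAnnotation", found = FALSE, ira = integer(0),
                irb = integer(0), lsc = integer(0), ssc = integer(0),
                identity = NA_real_, warnings = character(0))
    if (L < 2L * minIrLength) return(none)
    work <- if (circular) paste0(seqChr, seqChr) else seqChr
    wL <- nchar(work)
    w <- as.integer(min(window, max(50L, minIrLength %/% 2L)))
    dna <- Biostrings::DNAString(work)
    rc <- Biostrings::reverseComplement(dna)
    starts <- seq(0L, wL - w, by = w)
    pairA <- integer(0); pairC <- integer(0)
    for (a in starts) {
        pat <- Biostrings::subseq(dna, a + 1L, a + w)
        ## 10% mismatch budget: near-identical IR arms (diverged copies)
        ## still seed, random sequence never does at this window size
        m <- Biostrings::matchPattern(pat, rc,
                                      max.mismatch = w %/% 10L)
        if (!length(m)) next
        for (q in BiocGenerics::start(m) - 1L) {
            cpos <- wL - q - w     # forward-axis start of the partner arm
            if (cpos <= a) next    # each pair once, left arm first
            if (a + w > cpos) next # overlapping (palindrome) pairs excluded
            pairA <- c(pairA, a); pairC <- c(pairC, cpos)
        }
    }
    if (!length(pairA)) return(none)
    key <- pairA + pairC
    best <- NULL
    runs <- list()
    for (k in unique(key)) {
        ## one candidate per contiguous window run on this anti-diagonal
        ## (a gap of more than two windows separates distinct repeats,
        ## e.g. the two images of a circular sequence doubled)
        as <- sort(pairA[key == k])
        brk <- cumsum(c(0L, diff(as) > 2L * w))
        for (r in split(as, brk))
            runs[[length(runs) + 1L]] <- list(k = k, aMin = min(r),
                                              aMax = max(r))
    }
    for (run in runs) {
        k <- run$k
        aMin <- run$aMin; aMax <- run$aMax
        a1 <- aMin; a2 <- aMax + w
        c1 <- k - aMax; c2 <- k - aMin + w
        ## maximal extension outward and inward
        chr <- function(i) substr(work, i + 1L, i + 1L)
        while (a1 > 0L && c2 < wL && .isComp(chr(a1 - 1L), chr(c2))) {
            a1 <- a1 - 1L; c2 <- c2 + 1L
        }
        while (a2 < c1 && c1 > a2 && .isComp(chr(a2), chr(c1 - 1L))) {
            a2 <- a2 + 1L; c1 <- c1 - 1L
        }
        len <- a2 - a1
        if (len < minIrLength || a2 > c1) next
        if (circular) {
            ## drop duplicate/chimeric images arising from the doubling
            if (a1 >= L) next
            if (len > L %/% 2L || c2 - a1 > L) next
        }
        ident <- {
            arm1 <- substr(work, a1 + 1L, a2)
            arm2 <- .revcomp(substr(work, c1 + 1L, c2))
            mm <- sum(strsplit(arm1, "")[[1]] != strsplit(arm2, "")[[1]])
            100 * (len - mm) / len
        }
        cand <- list(a1 = a1, a2 = a2, c1 = c1, c2 = c2, len = len,
                     identity = ident)
        if (is.null(best) || cand$len > best$len ||
            (cand$len == best$len && (cand$identity > best$identity ||
             (cand$identity == best$identity && cand$a1 < best$a1))))
            best <- cand
    }
    if (is.null(best)) return(none)
    warn <- character(0)
    if (best$identity < 100)
        warn <- sprintf("IRa/IRb differ at %d position(s)",
                        round(best$len * (100 - best$identity) / 100))
    ira <- c(best$a1, best$a2); irb <- c(best$c1, best$c2)
    if (circular) {
        ira <- c(best$a1 %% L, best$a1 %% L + best$len)
        irb <- c(best$c1 %% L, best$c1 %% L + (best$c2 - best$c1))
    }
    inner <- c(ira[2], irb[1])                 # between the arms
    innerW <- inner[2] - inner[1]
    outerW <- L - 2L * best$len - innerW       # spans the sequence end
    outer <- c(irb[2], irb[2] + outerW)
    if (innerW >= outerW) { lsc <- inner; ssc <- outer }
    else { lsc <- outer; ssc <- inner }
    new("IrAnnotation", found = TRUE,
        ira = as.integer(ira), irb = as.integer(irb),
        lsc = as.integer(lsc), ssc = as.integer(ssc),
        identity = best$identity, warnings = warn)
}

#' Query coverage of an annotated gene
#'
#' Annotated gene length divided by reference gene length; for multi-exon
#' genes both lengths are exon-sum lengths.
#'
#' @param annotatedLen annotated exon-sum length (nt).
#' @param referenceLen reference exon-sum length (nt).
#' @return the ratio.
#' @export
queryCoverage <- function(annotatedLen, referenceLen) {
    if (referenceLen <= 0) stop("reference length must be positive")
    annotatedLen / referenceLen
}

#' Flag putative pseudogenes by query coverage
#'
#' One flag per annotation whose coverage falls strictly below \code{qmin}
#' or strictly above \code{qmax} ("less or greater than": boundary-equal
#' coverages pass).
#'
#' @param annotations list of \linkS4class{GeneAnnotation} (their
#'   \code{coverage} slot must be filled).
#' @param qmin,qmax coverage bounds. Defaults 0.5 and 2.
#' @return data.frame(geneName, copyIndex, coverage, boundViolated).
#' @export
flagPseudogenes <- function(annotations, qmin = 0.5, qmax = 2) {
    if (qmin >= qmax) stop("qmin must be smaller than qmax")
    out <- data.frame(geneName = character(0), copyIndex = integer(0),
                      coverage = numeric(0), boundViolated = character(0),
                      stringsAsFactors = FALSE)
    for (a in annotations) {
        if (is.na(a@coverage)) next
        if (a@coverage < qmin)
            out <- rbind(out, data.frame(geneName = a@geneName,
                copyIndex = a@copyIndex, coverage = a@coverage,
                boundViolated = "low", stringsAsFactors = FALSE))
        else if (a@coverage > qmax)
            out <- rbind(out, data.frame(geneName = a@geneName,
                copyIndex = a@copyIndex, coverage = a@coverage,
                boundViolated = "high", stringsAsFactors = FALSE))
    }
    out
}
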
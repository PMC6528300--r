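## Synthetic plastome fixtures with known-truth annotations.
##
## The generator emulates the conserved quadripartite plastome structure: a
## large single-copy region carrying protein-coding genes (intron-free and
## intron-containing), tRNAs and optionally an rpl16-like gene with a short
## (9 nt) first exon; an inverted-repeat pair duplicating an rRNA/tRNA
## subset in reverse complement; and a small single-copy spacer. The target
## is the reference mutated by per-site substitutions plus structural
## perturbations, and every perturbation maps to exactly one expected
## outcome class in the truth table. Composition is ~36% GC to resemble
## plastomes.

.NONSTOP_CODONS <- local({
    b <- c("A", "C", "G", "T")
    all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
    setdiff(all, STOP_CODONS)
})

.randBases <- function(n)
    sample(c("A", "T", "G", "C"), n, replace = TRUE,
           prob = c(0.32, 0.32, 0.18, 0.18))

.randSeq <- function(n) paste0(.randBases(n), collapse = "")

## random non-stop codons; optionally methionine-free
.randCodons <- function(n, avoidM = FALSE) {
    pool <- .NONSTOP_CODONS
    if (avoidM) pool <- setdiff(pool, "ATG")
    sample(pool, n, replace = TRUE)
}

## a stop-free CDS: ATG start, no methionine in codons 2-20 (so the
## probe-based start strategies are exercised cleanly by perturbations),
## one terminal stop
.makeCds <- function(nAa) {
    head <- .randCodons(min(19L, nAa - 1L), avoidM = TRUE)
    rest <- if (nAa - 1L > 19L) .randCodons(nAa - 1L - 19L) else character(0)
    paste0(c("ATG", head, rest, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Fixture specification
#'
#' @param seed integer seed; fixed seed gives byte-identical fixture files.
#' @param nPcgPlain,nPcgIntron,nTrnaPlain,nTrnaIntron,nRrna gene counts.
#' @param irLength inverted-repeat arm length (nt); 0 disables the IR.
#' @param divergence per-site substitution probability applied to the
#'   target (0-0.3). Substitutions never touch CDS start/stop codons and
#'   never create in-frame stop codons inside a CDS (nonsense substitutions
#'   are re-drawn), so the truth table stays valid.
#' @param perturbations subset of {"intron_loss", "start_non_atg",
#'   "start_shift_to_upstream_atg", "truncate_gene", "delete_gene",
#'   "mutate_below_threshold", "short_exon1_gene"}.
#' @param intronMode "stop_rich" (in-frame stop codons planted in every
#'   intron, the primary intron-presence signal) or "frameshift_stop_free"
#'   (stop-free introns whose length is not a multiple of three, so only
#'   the length-mod-3 criterion fires).
#' @return validated spec list.
#' @export
fixtureSpec <- function(seed, nPcgPlain = 3L, nPcgIntron = 2L,
                        nTrnaPlain = 2L, nTrnaIntron = 1L, nRrna = 1L,
                        irLength = 2000L, divergence = 0,
                        perturbations = character(0),
                        intronMode = c("stop_rich", "frameshift_stop_free")) {
    intronMode <- match.arg(intronMode)
    stopifnot(divergence >= 0, divergence <= 0.3,
              nPcgPlain >= 0, nPcgIntron >= 0, nTrnaPlain >= 0,
              nTrnaIntron >= 0, nRrna >= 0)
    known <- c("intron_loss", "start_non_atg", "start_shift_to_upstream_atg",
               "truncate_gene", "delete_gene", "mutate_below_threshold",
               "short_exon1_gene")
    if (length(setdiff(perturbations, known)))
        stop("unknown perturbation(s): ",
             paste(setdiff(perturbations, known), collapse = ", "))
    if (irLength > 0L && irLength < 300L)
        stop("irLength must be 0 or >= 300")
    list(seed = as.integer(seed), nPcgPlain = as.integer(nPcgPlain),
         nPcgIntron = as.integer(nPcgIntron),
         nTrnaPlain = as.integer(nTrnaPlain),
         nTrnaIntron = as.integer(nTrnaIntron), nRrna = as.integer(nRrna),
         irLength = as.integer(irLength), divergence = divergence,
         perturbations = perturbations, intronMode = intronMode)
}

## gene block builders: block = sense-strand nt incl. intron; exons local
.geneBlock <- function(name, category, exonSeqs, intronLens, intronMode) {
    segs <- list(); pos <- 0L; seqs <- character(0)
    for (i in seq_along(exonSeqs)) {
        segs[[i]] <- c(pos, pos + nchar(exonSeqs[i]))
        seqs <- c(seqs, exonSeqs[i])
        pos <- pos + nchar(exonSeqs[i])
        if (i <= length(intronLens)) {
            seqs <- c(seqs, .randSeq(intronLens[i]))
            pos <- pos + intronLens[i]
        }
    }
    list(name = name, category = category, block = paste0(seqs, collapse = ""),
         exons = segs, intronMode = intronMode)
}

## plant / scrub stop codons inside the (single) intron of a PCG block so
## the inter-HSP classification behaves per intronMode; returns the block
## string plus block-local positions of protected (planted) stops
.conditionIntron <- function(g) {
    if (length(g$exons) != 2L) return(list(block = g$block, keep = integer(0)))
    len1 <- g$exons[[1]][2] - g$exons[[1]][1]
    iStart <- g$exons[[1]][2]; iEnd <- g$exons[[2]][1]
    ilen <- iEnd - iStart
    r1 <- len1 %% 3L
    carry <- (3L - r1) %% 3L
    h1e <- len1 - r1                 # HSP1 3' end, block-local
    h2s <- iEnd + carry              # HSP2 5' start, block-local
    sv <- strsplit(g$block, "")[[1]]
    keep <- integer(0)
    if (g$intronMode == "stop_rich") {
        ## one stop in HSP1 frame, one in HSP2 frame, mid-intron
        mid <- iStart + ilen %/% 2L
        p1 <- h1e + 3L * ((mid - h1e) %/% 3L)
        p2 <- h2s - 3L * ((h2s - (mid + 6L)) %/% 3L)
        p1 <- max(iStart, min(p1, iEnd - 3L))
        p2 <- max(iStart, min(p2, iEnd - 3L))
        sv[(p1 + 1L):(p1 + 3L)] <- c("T", "A", "A")
        keep <- c(p1 + 0:2)
        if (abs(p2 - p1) >= 3L && (p2 - h2s) %% 3L == 0L) {
            sv[(p2 + 1L):(p2 + 3L)] <- c("T", "A", "G")
            keep <- c(keep, p2 + 0:2)
        }
    } else {
        ## scrub every in-frame (HSP1 frame) stop whose codon touches the
        ## intron; a "C" at an intron base of the codon destroys any stop
        p <- h1e
        while (p + 3L <= h2s) {
            cod <- paste0(sv[(p + 1L):(p + 3L)], collapse = "")
            if (cod %in% STOP_CODONS) {
                inIntron <- which(p + 0:2 >= iStart & p + 0:2 < iEnd)
                if (length(inIntron)) sv[p + inIntron[1]] <- "C"
            }
            p <- p + 3L
        }
    }
    list(block = paste0(sv, collapse = ""), keep = keep)
}

.NAME_POOLS <- list(
    pcgPlain = c("psbA", "rbcL", "matK", "ndhF", "ccsA", "rpoB", "petA",
                 "cemA", "psbB", "atpA"),
    pcgIntron = c("atpF", "rpl2", "ndhB", "rps16", "ndhA"),
    trnaPlain = c("trnH-GUG", "trnG-GCC", "trnfM-CAU", "trnQ-UUG",
                  "trnW-CCA"),
    trnaIntron = c("trnK-UUU", "trnL-UAA", "trnV-UAC"),
    rrna = c("rrn16", "rrn23", "rrn5", "rrn4.5"))

.poolNames <- function(pool, n) {
    base <- .NAME_POOLS[[pool]]
    if (n <= length(base)) return(base[seq_len(n)])
    c(base, paste0(base[1], seq_len(n - length(base))))
}

#' Generate a reference/target fixture pair with a known-truth table
#'
#' Writes a reference GenBank file, a target FASTA and a tab-separated
#' truth table into \code{dir}. The reference always passes
#' \code{\link{validateReference}} with zero issues; with divergence 0 and
#' no perturbations the target sequence equals the reference sequence.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return list(referencePath, targetPath, truthPath, truth,
#'   referenceRecord, targetRecord, spec).
#' @export
generateFixture <- function(spec, dir = tempfile("fixture")) {
    .withSeed(spec$seed, .generateFixtureImpl(spec, dir))
}

.generateFixtureImpl <- function(spec, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wantShort <- "short_exon1_gene" %in% spec$perturbations

    ## ---- gene blocks -------------------------------------------------------
    genes <- list()
    addGene <- function(g, strand, region) {
        g$strand <- strand; g$region <- region
        genes[[length(genes) + 1L]] <<- g
    }
    for (nm in .poolNames("pcgPlain", spec$nPcgPlain))
        addGene(.geneBlock(nm, "PCG", .makeCds(sample(100:180, 1L)),
                           integer(0), spec$intronMode), "+", "LSC")
    for (nm in .poolNames("pcgIntron", spec$nPcgIntron)) {
        cds <- .makeCds(sample(110:170, 1L))
        len1 <- sample(45:120, 1L)
        ilen <- sample(80:200, 1L)
        if (spec$intronMode == "frameshift_stop_free" && ilen %% 3L == 0L)
            ilen <- ilen + 1L
        g <- .geneBlock(nm, "PCG",
                        c(substr(cds, 1L, len1),
                          substr(cds, len1 + 1L, nchar(cds))),
                        ilen, spec$intronMode)
        cond <- .conditionIntron(g)
        g$block <- cond$block; g$protect <- cond$keep
        addGene(g, sample(c("+", "-"), 1L), "LSC")
    }
    if (wantShort) {
        cds <- .makeCds(sample(110:160, 1L))
        ilen <- 1200L
        g <- .geneBlock("rpl16", "PCG",
                        c(substr(cds, 1L, 9L),
                          substr(cds, 10L, nchar(cds))),
                        ilen, "stop_rich")
        cond <- .conditionIntron(g)
        g$block <- cond$block; g$protect <- cond$keep
        g$shortExon1 <- TRUE
        addGene(g, "+", "LSC")
    }
    trnaPlain <- .poolNames("trnaPlain", spec$nTrnaPlain)
    for (nm in trnaPlain[-1L])
        addGene(.geneBlock(nm, "tRNA", .randSeq(sample(70:85, 1L)),
                           integer(0), spec$intronMode),
                sample(c("+", "-"), 1L), "LSC")
    for (nm in .poolNames("trnaIntron", spec$nTrnaIntron))
        addGene(.geneBlock(nm, "tRNA",
                           c(.randSeq(sample(30:40, 1L)),
                             .randSeq(sample(30:40, 1L))),
                           sample(60:100, 1L), spec$intronMode),
                sample(c("+", "-"), 1L), "LSC")
    rrna <- .poolNames("rrna", spec$nRrna)
    useIr <- spec$irLength > 0L
    irGenes <- character(0)
    if (useIr) {
        if (length(rrna)) irGenes <- rrna[1L]
        if (length(trnaPlain)) irGenes <- c(irGenes, trnaPlain[1L])
    }
    for (nm in rrna)
        addGene(.geneBlock(nm, "rRNA", .randSeq(sample(500:900, 1L)),
                           integer(0), spec$intronMode),
                if (nm %in% irGenes) "+" else sample(c("+", "-"), 1L),
                if (nm %in% irGenes) "IR" else "SSC")
    if (length(trnaPlain))
        addGene(.geneBlock(trnaPlain[1L], "tRNA",
                           .randSeq(sample(70:85, 1L)), integer(0),
                           spec$intronMode),
                "+", if (trnaPlain[1L] %in% irGenes) "IR" else "LSC")

    ## ---- assembly ----------------------------------------------------------
    pieces <- character(0)
    placed <- list()     # per gene copy: name, strand, abs segments, meta
    pos <- 0L
    protect <- integer(0)      # 0-based abs positions shielded from divergence
    put <- function(s) { pieces <<- c(pieces, s); pos <<- pos + nchar(s) }
    placeGene <- function(g) {
        blockStart <- pos
        blk <- if (g$strand == "+") g$block else .revcomp(g$block)
        put(blk)
        bl <- nchar(g$block)
        segs <- lapply(g$exons, function(u) {
            if (g$strand == "+") blockStart + u
            else c(blockStart + bl - u[2], blockStart + bl - u[1])
        })
        if (!is.null(g$protect)) {
            pp <- if (g$strand == "+") blockStart + g$protect
                  else blockStart + bl - 1L - g$protect
            protect <<- c(protect, pp)
        }
        placed[[length(placed) + 1L]] <<- list(
            name = g$name, category = g$category, strand = g$strand,
            segs = segs, hasIntron = length(g$exons) > 1L,
            shortExon1 = isTRUE(g$shortExon1))
    }
    lscGenes <- Filter(function(g) g$region == "LSC", genes)
    irGeneDefs <- Filter(function(g) g$region == "IR", genes)
    sscGenes <- Filter(function(g) g$region == "SSC", genes)
    put(.randSeq(sample(250:400, 1L)))
    for (g in lscGenes) { placeGene(g); put(.randSeq(sample(150:300, 1L))) }
    iraStart <- NA_integer_
    if (useIr) {
        iraStart <- pos
        put(.randSeq(80L))
        for (g in irGeneDefs) { placeGene(g); put(.randSeq(80L)) }
        need <- pos - iraStart
        if (need > spec$irLength)
            stop("irLength ", spec$irLength,
                 " too small for the IR gene content (needs ", need, ")")
        put(.randSeq(spec$irLength - need))
        iraEnd <- pos
        irContent <- paste0(pieces, collapse = "")
        irContent <- substr(irContent, iraStart + 1L, iraEnd)
        put(.randSeq(sample(500:900, 1L)))      # SSC spacer
        for (g in sscGenes) { placeGene(g); put(.randSeq(sample(150:300, 1L))) }
        irbStart <- pos
        put(.revcomp(irContent))
        irbEnd <- pos
        ## mirror the IR gene copies into IRb
        nIr <- length(irGeneDefs)
        if (nIr) {
            iraCopies <- placed[vapply(placed, function(p)
                min(vapply(p$segs, `[`, 0L, 1L)) >= iraStart &&
                max(vapply(p$segs, `[`, 0L, 2L)) <= iraEnd, TRUE)]
            for (p in iraCopies) {
                segsB <- lapply(p$segs, function(u)
                    c(irbStart + (iraEnd - u[2]), irbStart + (iraEnd - u[1])))
                placed[[length(placed) + 1L]] <- list(
                    name = p$name, category = p$category,
                    strand = if (p$strand == "+") "-" else "+",
                    segs = segsB, hasIntron = p$hasIntron,
                    shortExon1 = FALSE)
            }
        }
        put(.randSeq(sample(200:350, 1L)))
    } else {
        for (g in sscGenes) { placeGene(g); put(.randSeq(sample(150:300, 1L))) }
        iraEnd <- irbStart <- irbEnd <- NA_integer_
    }
    seqStr <- paste0(pieces, collapse = "")
    sv <- strsplit(seqStr, "")[[1]]
    if (useIr) {
        ## guard bases: the maximal inverted repeat is exactly the planted arm
        sv[iraStart] <- "A"; sv[irbEnd + 1L] <- "A"       # outer flanks
        sv[iraEnd + 1L] <- "A"; sv[irbStart] <- "A"       # inner flanks
    }

    ## protect CDS start/stop codons and the short exon 1 from divergence;
    ## build the reading-order position map for codon-aware substitution
    codingMap <- list()
    for (p in placed) {
        rpos <- unlist(lapply(p$segs, function(u) {
            if (p$strand == "+") u[1]:(u[2] - 1L) else (u[2] - 1L):u[1]
        }))
        if (p$category == "PCG") {
            protect <- c(protect, rpos[1:3], rpos[(length(rpos) - 2L):length(rpos)])
            if (p$shortExon1) protect <- c(protect, rpos[1:9])
            codingMap[[length(codingMap) + 1L]] <-
                list(rpos = rpos, strand = p$strand)
        }
    }

    ## clean spurious copies of the short exon 1 probe in its search window
    for (p in placed) {
        if (!p$shortExon1) next
        ex1 <- p$segs[[1]]
        probe <- paste0(sv[(ex1[1] + 1L):ex1[2]], collapse = "")
        ex2s <- p$segs[[2]][1]
        ws <- max(0L, ex2s - 2000L)
        win <- paste0(sv[(ws + 1L):ex2s], collapse = "")
        hits <- gregexpr(probe, win, fixed = TRUE)[[1]]
        for (h in hits) {
            if (h == -1L) next
            a <- ws + h - 1L
            if (a == ex1[1]) next
            sv[a + 5L] <- setdiff(c("A", "C", "G", "T"), sv[a + 5L])[1]
        }
    }

    refSeq <- paste0(sv, collapse = "")

    ## ---- truth table base --------------------------------------------------
    copyCount <- integer(0)
    truth <- list()
    for (p in placed) {
        copyCount[p$name] <- (if (is.na(copyCount[p$name])) 0L
                              else copyCount[p$name]) + 1L
        truth[[length(truth) + 1L]] <- list(
            geneName = p$name, copyIndex = copyCount[p$name],
            category = p$category, strand = p$strand, segs = p$segs,
            startCodon = if (p$category == "PCG") "ATG" else "",
            intronStatus = if (p$hasIntron) "intron_present" else "none",
            expectedOutcome = "annotated", expectedWarning = "",
            perturbed = "")
    }

    ## ---- target: divergence then structural perturbations ------------------
    tv <- sv
    if (spec$divergence > 0) {
        prot <- rep(FALSE, length(tv))
        prot[protect + 1L] <- TRUE
        hit <- which(stats::runif(length(tv)) < spec$divergence & !prot)
        ## codon lookup for nonsense avoidance
        codonOf <- new.env()
        for (cm in codingMap) {
            n3 <- length(cm$rpos) %/% 3L
            for (ci in seq_len(n3)) {
                trip <- cm$rpos[(3L * ci - 2L):(3L * ci)]
                for (q in trip)
                    assign(as.character(q),
                           list(trip = trip, strand = cm$strand), codonOf)
            }
        }
        for (i in hit) {
            alts <- sample(setdiff(c("A", "C", "G", "T"), tv[i]))
            info <- mget(as.character(i - 1L), codonOf,
                         ifnotfound = list(NULL))[[1]]
            for (b in alts) {
                tv[i] <- b
                if (is.null(info)) break
                bases <- tv[info$trip + 1L]
                cod <- if (info$strand == "+") paste0(bases, collapse = "")
                       else .revcomp(paste0(rev(bases), collapse = ""))
                if (!cod %in% STOP_CODONS) break
                tv[i] <- sv[i]   # nonsense: try the next base
            }
        }
    }

    deletions <- NULL   # original-axis deletions, applied at the end
    truthIdx <- function(nm) which(vapply(truth, function(t)
        t$geneName == nm && t$copyIndex == 1L, TRUE))[1]
    pool <- vapply(Filter(function(p)
        p$category == "PCG" && !p$hasIntron && p$strand == "+", placed),
        function(p) p$name, "")
    takePlain <- function() {
        if (!length(pool)) stop("not enough intron-free PCGs for perturbations")
        g <- pool[1]; pool <<- pool[-1L]; g
    }
    setCodon <- function(p0, txt) tv[(p0 + 1L):(p0 + nchar(txt))] <<-
        strsplit(txt, "")[[1]]

    for (pert in spec$perturbations) {
        if (pert == "short_exon1_gene") {
            i <- truthIdx("rpl16")
            truth[[i]]$perturbed <- pert
            next
        }
        if (pert == "intron_loss") {
            cand <- Filter(function(p) p$hasIntron && p$category == "PCG" &&
                           !p$shortExon1, placed)
            if (!length(cand)) stop("no intron-containing PCG to perturb")
            p <- cand[[1]]
            fw <- sort(unlist(p$segs))         # a1 b1 a2 b2 on forward axis
            intron <- c(fw[2], fw[3])
            deletions <- rbind(deletions,
                data.frame(start = intron[1], end = intron[2]))
            i <- truthIdx(p$name)
            ## merged span on the original axis; the shift pass subtracts
            ## the deleted intron for coordinates beyond it
            truth[[i]]$segs <- list(c(fw[1], fw[4]))
            truth[[i]]$intronStatus <- "intron_lost"
            truth[[i]]$expectedWarning <- "intron_loss"
            truth[[i]]$perturbed <- pert
        } else if (pert == "start_non_atg") {
            nm <- takePlain()
            i <- truthIdx(nm)
            s <- truth[[i]]$segs[[1]][1]
            setCodon(s, "ACG")
            setCodon(s - 12L, "TAA")           # upstream in-frame stop
            setCodon(s - 9L, "CCTCCTCCT")      # M-free gap to the start
            ## the strategy-(c) precondition: no suitable methionine in the
            ## search region (divergence may have created one in the gene)
            for (p0 in seq(s + 3L, s + 57L, by = 3L))
                if (paste0(tv[(p0 + 1L):(p0 + 3L)], collapse = "") == "ATG")
                    setCodon(p0, "ATC")
            truth[[i]]$startCodon <- "ACG"
            truth[[i]]$expectedWarning <- "non_atg_start"
            truth[[i]]$perturbed <- pert
        } else if (pert == "start_shift_to_upstream_atg") {
            nm <- takePlain()
            i <- truthIdx(nm)
            s <- truth[[i]]$segs[[1]][1]
            setCodon(s, "CTG")                 # old start no longer M
            setCodon(s - 30L, "TAA")
            setCodon(s - 27L, "ATG")           # the new, upstream start
            setCodon(s - 24L, strrep("CCT", 8L))
            truth[[i]]$segs[[1]][1] <- s - 27L
            truth[[i]]$expectedWarning <- "start_shift"
            truth[[i]]$perturbed <- pert
        } else if (pert == "truncate_gene") {
            nm <- takePlain()
            i <- truthIdx(nm)
            s <- truth[[i]]$segs[[1]][1]; e <- truth[[i]]$segs[[1]][2]
            len <- e - s
            cut <- s + 3L * floor(0.35 * len / 3)
            deletions <- rbind(deletions, data.frame(start = cut, end = e))
            truth[[i]]$segs <- list(c(s, e))   # shift pass shortens to cut+3
            truth[[i]]$truncateCut <- cut
            truth[[i]]$expectedWarning <- "coverage_low"
            truth[[i]]$perturbed <- pert
        } else if (pert == "delete_gene") {
            nm <- takePlain()
            i <- truthIdx(nm)
            s <- truth[[i]]$segs[[1]][1]; e <- truth[[i]]$segs[[1]][2]
            deletions <- rbind(deletions, data.frame(start = s, end = e))
            truth[[i]]$segs <- list()
            truth[[i]]$expectedOutcome <- "missing"
            truth[[i]]$perturbed <- pert
        } else if (pert == "mutate_below_threshold") {
            nm <- takePlain()
            i <- truthIdx(nm)
            s <- truth[[i]]$segs[[1]][1]; e <- truth[[i]]$segs[[1]][2]
            nCod <- (e - s) %/% 3L
            internal <- 2:(nCod - 1L)          # spare start and stop codons
            swap <- sort(sample(internal, floor(0.7 * length(internal))))
            for (ci in swap) {
                p0 <- s + 3L * (ci - 1L)
                old <- paste0(tv[(p0 + 1L):(p0 + 3L)], collapse = "")
                aaOld <- .CODE11[old]
                cand <- .NONSTOP_CODONS[.CODE11[.NONSTOP_CODONS] != aaOld]
                setCodon(p0, sample(cand, 1L))
            }
            truth[[i]]$expectedOutcome <- "skipped"
            truth[[i]]$expectedWarning <- "low_identity_skip"
            truth[[i]]$perturbed <- pert
        }
    }

    ## apply deletions (descending) and shift truth coordinates
    if (!is.null(deletions)) {
        deletions <- deletions[order(-deletions$start), , drop = FALSE]
        for (d in seq_len(nrow(deletions)))
            tv <- tv[-((deletions$start[d] + 1L):deletions$end[d])]
        shift <- function(x) {
            for (d in seq_len(nrow(deletions))) {
                w <- deletions$end[d] - deletions$start[d]
                x <- ifelse(x >= deletions$end[d], x - w,
                            pmin(x, deletions$start[d]))
            }
            x
        }
        for (i in seq_along(truth)) {
            if (!length(truth[[i]]$segs)) next
            truth[[i]]$segs <- lapply(truth[[i]]$segs,
                                      function(u) shift(u))
            if (!is.null(truth[[i]]$truncateCut)) {
                cut <- shift(truth[[i]]$truncateCut)
                truth[[i]]$segs[[1]][2] <- cut + 3L   # planted stop below
            }
            truth[[i]]$segs <- Filter(function(u) u[2] > u[1],
                                      truth[[i]]$segs)
        }
    }
    ## planted stop just past each truncation cut (in frame, in the joined
    ## spacer), so the annotated gene ends at a defined place
    for (i in seq_along(truth)) {
        if (!is.null(truth[[i]]$truncateCut) && length(truth[[i]]$segs)) {
            cut <- truth[[i]]$segs[[1]][2] - 3L
            tv[(cut + 1L):(cut + 3L)] <- c("T", "A", "A")
        }
    }
    targetSeq <- paste0(tv, collapse = "")

    ## ---- records and files -------------------------------------------------
    ## reference features come from the unperturbed placement
    feats <- list()
    for (p in placed) {
        ord <- p$segs   # already in reading order
        loc <- FeatureLocation(vapply(ord, `[`, 0L, 1L),
                               vapply(ord, `[`, 0L, 2L), p$strand)
        kind <- switch(p$category, PCG = "CDS", p$category)
        feats[[length(feats) + 1L]] <- new("GeneFeature",
            geneName = p$name, kind = "gene", location = loc,
            qualifiers = list(gene = p$name))
        feats[[length(feats) + 1L]] <- new("GeneFeature",
            geneName = p$name, kind = kind, location = loc,
            qualifiers = list(gene = p$name))
    }
    refRec <- new("PlastomeRecord",
        recordId = sprintf("refFixture%d", spec$seed),
        sequence = Biostrings::DNAString(refSeq), features = feats,
        parseIssues = character(0))
    tgtRec <- new("PlastomeRecord",
        recordId = sprintf("target%d", spec$seed),
        sequence = Biostrings::DNAString(targetSeq), features = list(),
        parseIssues = character(0))
    refPath <- file.path(dir, sprintf("reference_seed%d.gb", spec$seed))
    tgtPath <- file.path(dir, sprintf("target_seed%d.fasta", spec$seed))
    writeGenBank(refRec, NULL, refPath)
    writeLines(c(sprintf(">%s synthetic plastome fixture", tgtRec@recordId),
                 substring(targetSeq,
                           seq(1L, nchar(targetSeq), 70L),
                           pmin(seq(70L, nchar(targetSeq) + 69L, 70L),
                                nchar(targetSeq)))),
               tgtPath)
    truthDf <- do.call(rbind, lapply(truth, function(t) data.frame(
        geneName = t$geneName, copyIndex = t$copyIndex,
        category = t$category, strand = t$strand,
        segments = paste(vapply(t$segs, function(u)
            paste0(u[1], "-", u[2]), ""), collapse = ";"),
        startCodon = t$startCodon, intronStatus = t$intronStatus,
        expectedOutcome = t$expectedOutcome,
        expectedWarning = t$expectedWarning, perturbed = t$perturbed,
        stringsAsFactors = FALSE)))
    truthPath <- file.path(dir, sprintf("truth_seed%d.tsv", spec$seed))
    utils::write.table(truthDf, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(referencePath = refPath, targetPath = tgtPath,
         truthPath = truthPath, truth = truthDf,
         referenceRecord = refRec, targetRecord = tgtRec, spec = spec,
         ir = if (useIr) list(ira = c(iraStart, iraEnd),
                              irb = c(irbStart, irbEnd)) else NULL)
}

## parse "a-b;c-d" truth segment strings back to a list of intervals
.truthSegs <- function(s) {
    if (!nzchar(s)) return(list())
    lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(x)
        as.integer(strsplit(x, "-", fixed = TRUE)[[1]]))
}

#' Score annotations against a fixture truth table
#'
#' Gene-level counts: CG (coordinate-exact), WGB (overlapping but
#' boundary-mismatched), MG (truth entry with no overlapping annotation),
#' WG (annotation overlapping no truth locus). Exon-level counts (CE, WEB,
#' ME, WE) are computed over intron-containing truth entries.
#'
#' @param annotations list of \linkS4class{GeneAnnotation}.
#' @param truth truth data.frame from \code{\link{generateFixture}}.
#' @return list of counts plus totals (nTruth, nTruthExons).
#' @export
scoreAgainstTruth <- function(annotations, truth) {
    counts <- list(MG = 0L, WG = 0L, WGB = 0L, CG = 0L,
                   ME = 0L, WE = 0L, WEB = 0L, CE = 0L)
    annSpans <- lapply(annotations, function(a)
        c(min(locStarts(a@location)), max(locEnds(a@location))))
    usedAnn <- rep(FALSE, length(annotations))
    tRows <- which(truth$expectedOutcome == "annotated")
    nTruthExons <- 0L
    for (i in tRows) {
        segs <- .truthSegs(truth$segments[i])
        if (!length(segs)) next
        span <- c(min(vapply(segs, `[`, 0L, 1L)),
                  max(vapply(segs, `[`, 0L, 2L)))
        hit <- which(!usedAnn &
            vapply(annotations, function(a)
                a@geneName == truth$geneName[i], TRUE) &
            vapply(annSpans, function(sp)
                sp[1] < span[2] && span[1] < sp[2], TRUE))
        multi <- length(segs) > 1L
        if (multi) nTruthExons <- nTruthExons + length(segs)
        if (!length(hit)) {
            counts$MG <- counts$MG + 1L
            if (multi) counts$ME <- counts$ME + length(segs)
            next
        }
        hit <- hit[1]
        usedAnn[hit] <- TRUE
        a <- annotations[[hit]]
        aSegs <- Map(c, locStarts(a@location), locEnds(a@location))
        exact <- length(aSegs) == length(segs) &&
            all(vapply(seq_along(segs), function(k)
                identical(as.integer(segs[[k]]),
                          as.integer(aSegs[[k]])), TRUE))
        if (exact) counts$CG <- counts$CG + 1L
        else counts$WGB <- counts$WGB + 1L
        if (multi) {
            for (s in segs) {
                m <- vapply(aSegs, function(u)
                    if (identical(as.integer(u), as.integer(s))) 2L
                    else if (u[1] < s[2] && s[1] < u[2]) 1L else 0L, 0L)
                if (any(m == 2L)) counts$CE <- counts$CE + 1L
                else if (any(m == 1L)) counts$WEB <- counts$WEB + 1L
                else counts$ME <- counts$ME + 1L
            }
            for (u in aSegs) {
                over <- vapply(segs, function(s)
                    u[1] < s[2] && s[1] < u[2], TRUE)
                if (!any(over)) counts$WE <- counts$WE + 1L
            }
        }
    }
    counts$WG <- counts$WG + sum(!usedAnn &
        vapply(annotations, function(a) {
            sel <- truth$geneName == a@geneName &
                   truth$expectedOutcome == "annotated"
            !any(sel)
        }, TRUE))
    counts$nTruth <- length(tRows)
    counts$nTruthExons <- nTruthExons
    counts
}

#' Check that a perturbed fixture produced its expected outcome
#'
#' For every perturbed truth row, verifies the expected classification:
#' intron losses detected and logged, non-ATG starts resolved by strategy
#' (c)/(d) with a warning, truncations flagged by low coverage, identity
#' scrambles skipped with their identity, deleted genes reported missing,
#' and the short first exon recovered at its exact coordinates.
#'
#' @param result output of \code{\link{annotateTarget}}.
#' @param truth truth data.frame from \code{\link{generateFixture}}.
#' @return data.frame(geneName, class, pass).
#' @export
checkExpectation <- function(result, truth) {
    log <- result$log
    anns <- result$annotations
    annFor <- function(g) Filter(function(a) a@geneName == g, anns)
    warnFor <- function(g, type) {
        w <- log$warnings
        any(w$geneName == g & w$type == type, na.rm = TRUE)
    }
    out <- NULL
    for (i in which(nzchar(truth$perturbed))) {
        g <- truth$geneName[i]
        cls <- truth$perturbed[i]
        segs <- .truthSegs(truth$segments[i])
        pass <- switch(cls,
            intron_loss = {
                a <- annFor(g)
                length(a) > 0 && a[[1]]@intronStatus == "intron_lost" &&
                    length(locStarts(a[[1]]@location)) == 1L &&
                    warnFor(g, "intron_loss")
            },
            start_non_atg = {
                a <- annFor(g)
                length(a) > 0 && a[[1]]@startStrategy %in% c("c", "d") &&
                    warnFor(g, "non_atg_start")
            },
            start_shift_to_upstream_atg = {
                a <- annFor(g)
                length(a) > 0 && a[[1]]@startStrategy == "b" &&
                    locStarts(a[[1]]@location)[1] == segs[[1]][1]
            },
            truncate_gene = {
                a <- annFor(g)
                length(a) > 0 && a[[1]]@coverage < 0.5 &&
                    warnFor(g, "coverage_flag")
            },
            delete_gene = g %in% log$missingGeneNames,
            mutate_below_threshold =
                g %in% log$skipped$geneName &&
                all(log$skipped$identity[log$skipped$geneName == g] < 40),
            short_exon1_gene = {
                a <- annFor(g)
                length(a) > 0 &&
                    length(locStarts(a[[1]]@location)) == 2L &&
                    identical(as.integer(c(locStarts(a[[1]]@location)[1],
                                           locEnds(a[[1]]@location)[1])),
                              as.integer(segs[[1]]))
            },
            FALSE)
        out <- rbind(out, data.frame(geneName = g, class = cls,
                                     pass = isTRUE(pass),
                                     stringsAsFactors = FALSE))
    }
    if (is.null(out))
        out <- data.frame(geneName = character(0), class = character(0),
                          pass = logical(0), stringsAsFactors = FALSE)
    out
}
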
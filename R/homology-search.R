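## Reverse query-subject search: reference genes are the queries, the target
## plastome is the subject. Two interchangeable backends return the same HSP
## table contract:
##   * "builtin"  - in-process: substitution-tolerant pattern matching
##                  (Biostrings::matchPattern) that finds every copy
##                  (inverted-repeat duplicates included), with a local
##                  Smith-Waterman fallback (pairwiseAlignment) plus
##                  iterative masking for partially conserved loci;
##   * "external" - NCBI BLAST+ (blastn/tblastn) via temporary FASTA files
##                  and outfmt-6 parsing.
##
## HSP coordinates: qStart/qEnd on the query (aa for protein mode, nt for
## nucleotide mode; concatenated-exon axis for intron-containing genes),
## sStart/sEnd on the forward axis of the target, all 0-based half-open;
## frame is the reading-frame offset on the subject coding strand.

#' Search configuration
#'
#' @param identityThresholdPcg percent identity below which a protein-coding
#'   gene is skipped (logged, not annotated). Default 40.
#' @param evalue e-value ceiling for the external backend.
#' @param maxIntronSpan maximum subject distance (nt) for HSPs of one gene
#'   copy to be clustered together.
#' @param backend "builtin" or "external".
#' @param minNtIdentity minimum percent identity for nucleotide pattern hits.
#' @param minQueryNt,minQueryAa queries shorter than this are not searched
#'   (the short first exons of rpl16/petB/petD are handled by the dedicated
#'   upstream probe search instead).
#' @param minNtScore,minAaScore minimum Smith-Waterman score for fallback
#'   hits (filters random local matches).
#' @param exon1Window upstream window (nt) for the short-exon-1 probe search.
#' @param exon1Mismatches mismatches tolerated by the exon-1 probe (0 or 1).
#' @param irMinLength minimum inverted-repeat length (nt). Default 1000.
#' @param qcovMin,qcovMax query-coverage bounds for pseudogene flagging
#'   (strict inequalities). Defaults 0.5 and 2.
#' @param circular treat targets as circular (IR detection on the doubled
#'   sequence; genes are still annotated on the linear axis — rotate the
#'   target first if a gene spans the origin).
#' @param shortExon1Genes gene names eligible for the upstream exon-1 search.
#' @return a named list of settings.
#' @export
searchConfig <- function(identityThresholdPcg = 40, evalue = 1e-5,
                         maxIntronSpan = 10000L, backend = "builtin",
                         minNtIdentity = 60, minQueryNt = 24L,
                         minQueryAa = 10L, minNtScore = 72, minAaScore = 75,
                         exon1Window = 2000L, exon1Mismatches = 0L,
                         irMinLength = 1000L, qcovMin = 0.5, qcovMax = 2,
                         circular = FALSE,
                         shortExon1Genes = c("rpl16", "petB", "petD")) {
    stopifnot(identityThresholdPcg > 0, identityThresholdPcg <= 100)
    if (qcovMin >= qcovMax)
        stop("qcovMin must be smaller than qcovMax")
    list(identityThresholdPcg = identityThresholdPcg, evalue = evalue,
         maxIntronSpan = as.integer(maxIntronSpan), backend = backend,
         minNtIdentity = minNtIdentity, minQueryNt = as.integer(minQueryNt),
         minQueryAa = as.integer(minQueryAa), minNtScore = minNtScore,
         minAaScore = minAaScore, exon1Window = as.integer(exon1Window),
         exon1Mismatches = as.integer(exon1Mismatches),
         irMinLength = as.integer(irMinLength),
         qcovMin = qcovMin, qcovMax = qcovMax, circular = circular,
         shortExon1Genes = shortExon1Genes)
}

.emptyHsp <- function() data.frame(
    geneName = character(0), entryId = character(0), refId = character(0),
    mode = character(0), exonIndex = integer(0),
    qStart = integer(0), qEnd = integer(0),
    sStart = integer(0), sEnd = integer(0),
    strand = character(0), frame = integer(0),
    identity = numeric(0), alignedLength = integer(0),
    stringsAsFactors = FALSE)

.hspRow <- function(geneName, entryId, refId, mode, exonIndex, qStart, qEnd,
                    sStart, sEnd, strand, frame, identity, alignedLength)
    data.frame(geneName = geneName, entryId = entryId, refId = refId,
               mode = mode, exonIndex = as.integer(exonIndex),
               qStart = as.integer(qStart), qEnd = as.integer(qEnd),
               sStart = as.integer(sStart), sEnd = as.integer(sEnd),
               strand = strand, frame = as.integer(frame),
               identity = identity, alignedLength = as.integer(alignedLength),
               stringsAsFactors = FALSE)

## ---- target search index ---------------------------------------------------

## Precompute the reverse complement and the six verbatim frame translations
## of the target once per run.
.targetIndex <- function(target) {
    seq <- target@sequence
    L <- length(seq)
    rc <- Biostrings::reverseComplement(seq)
    frames <- list()
    for (strand in c("+", "-")) {
        src <- if (strand == "+") as.character(seq) else as.character(rc)
        for (f in 0:2) {
            keep <- 3L * ((nchar(src) - f) %/% 3L)
            aa <- if (keep >= 3L)
                translateCds(substr(src, f + 1L, f + keep)) else ""
            frames[[length(frames) + 1L]] <- list(
                strand = strand, off = f,
                aa = Biostrings::AAString(aa))
        }
    }
    list(seq = seq, rc = rc, seqChr = as.character(seq), L = L,
         frames = frames)
}

## ---- builtin backend -------------------------------------------------------

## all substitution-only occurrences of pat in subj with <= maxMm mismatches;
## returns 0-based half-open starts/ends on subj plus mismatch counts
.patternHits <- function(pat, subj, maxMm) {
    v <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMm,
                                  with.indels = FALSE)
    if (!length(v)) return(NULL)
    st <- BiocGenerics::start(v)
    mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st)
    o <- order(mm, st)
    st <- st[o]; mm <- mm[o]
    ## thin heavily overlapping shadows, best (fewest mismatches) first
    keep <- logical(length(st))
    taken <- integer(0)
    w <- length(pat)
    for (i in seq_along(st)) {
        if (!length(taken) || all(abs(st[i] - taken) >= w %/% 2L)) {
            keep[i] <- TRUE
            taken <- c(taken, st[i])
        }
    }
    st <- st[keep]; mm <- mm[keep]
    data.frame(start = st - 1L, end = st - 1L + w, mm = mm)
}

.swAccept <- function(pa, minScore, minWidth) {
    BiocGenerics::score(pa) >= minScore &&
        BiocGenerics::width(Biostrings::pattern(pa)) >= minWidth
}

## iterative local alignment with masking; subj is an XString, maskChar "N"
## or "X"; returns data.frame of subject/query ranges (1-based inclusive)
.swIterate <- function(pat, subj, substitutionMatrix, gapOpening,
                       gapExtension, minScore, minWidth, maxHits = 4L) {
    out <- NULL
    maskChar <- if (is(subj, "AAString")) "X" else "N"
    for (i in seq_len(maxHits)) {
        pa <- Biostrings::pairwiseAlignment(pat, subj, type = "local",
            substitutionMatrix = substitutionMatrix,
            gapOpening = gapOpening, gapExtension = gapExtension)
        if (!.swAccept(pa, minScore, minWidth)) break
        pr <- Biostrings::pattern(pa); sr <- Biostrings::subject(pa)
        row <- data.frame(
            qs = BiocGenerics::start(pr), qe = BiocGenerics::end(pr),
            ss = BiocGenerics::start(sr), se = BiocGenerics::end(sr),
            identity = Biostrings::pid(pa, type = "PID1"),
            alnLen = Biostrings::nchar(pa))
        out <- rbind(out, row)
        subj <- Biostrings::replaceAt(subj,
            IRanges::IRanges(row$ss, row$se),
            strrep(maskChar, row$se - row$ss + 1L))
    }
    out
}

## search one nucleotide query against both strands of the target
.searchNtQuery <- function(qseq, idx, cfg) {
    len <- nchar(qseq)
    if (len < cfg$minQueryNt) return(NULL)
    pat <- Biostrings::DNAString(qseq)
    ## short queries get a tighter allowance: a 35% budget on a ~30 nt tRNA
    ## exon admits chance matches, a 20% one does not while still covering
    ## the fixture divergence range
    maxMm <- if (len < 60L) floor(len * 0.2)
             else floor(len * (1 - cfg$minNtIdentity / 100))
    res <- NULL
    for (strand in c("+", "-")) {
        subj <- if (strand == "+") idx$seq else idx$rc
        h <- .patternHits(pat, subj, maxMm)
        if (is.null(h)) next
        for (i in seq_len(nrow(h))) {
            iv <- if (strand == "+") c(h$start[i], h$end[i])
                  else c(idx$L - h$end[i], idx$L - h$start[i])
            res <- rbind(res, data.frame(
                qStart = 0L, qEnd = len, sStart = iv[1], sEnd = iv[2],
                strand = strand, frame = NA_integer_,
                identity = 100 * (len - h$mm[i]) / len,
                alignedLength = len))
        }
    }
    if (!is.null(res)) return(res)
    ## Smith-Waterman fallback (partial or diverged loci)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    for (strand in c("+", "-")) {
        subj <- if (strand == "+") idx$seq else idx$rc
        h <- .swIterate(pat, subj, mat, gapOpening = 5, gapExtension = 2,
                        minScore = cfg$minNtScore, minWidth = cfg$minQueryNt)
        if (is.null(h)) next
        for (i in seq_len(nrow(h))) {
            s0 <- h$ss[i] - 1L; e0 <- h$se[i]
            iv <- if (strand == "+") c(s0, e0) else c(idx$L - e0, idx$L - s0)
            res <- rbind(res, data.frame(
                qStart = h$qs[i] - 1L, qEnd = h$qe[i],
                sStart = iv[1], sEnd = iv[2], strand = strand,
                frame = NA_integer_, identity = h$identity[i],
                alignedLength = h$alnLen[i]))
        }
    }
    res
}

## search one amino-acid query against the six frame translations
.searchAaQuery <- function(qaa, idx, cfg) {
    len <- nchar(qaa)
    if (len < cfg$minQueryAa) return(NULL)
    pat <- Biostrings::AAString(qaa)
    ## mismatch budget scaled so chance matches (~6% residue identity on
    ## random sequence) stay negligible at every query length, while a
    ## full-length gene diverged down to ~25-30% identity is still seen
    maxMm <- if (len >= 100L) floor(len * 0.75)
             else if (len >= 60L) floor(len * 0.6)
             else floor(len * 0.4)
    res <- NULL
    mapHit <- function(a0, b0, fr) {
        ## aa interval [a0,b0) on frame translation -> forward-axis nt
        if (fr$strand == "+") c(fr$off + 3L * a0, fr$off + 3L * b0)
        else c(idx$L - (fr$off + 3L * b0), idx$L - (fr$off + 3L * a0))
    }
    for (fr in idx$frames) {
        h <- .patternHits(pat, fr$aa, maxMm)
        if (is.null(h)) next
        for (i in seq_len(nrow(h))) {
            row <- NULL
            patIdent <- 100 * (len - h$mm[i]) / len
            if (patIdent < 50) {
                ## a full-length low-identity match may hide a shorter,
                ## cleaner local alignment (e.g. a truncated gene whose
                ## conserved prefix runs into intergenic sequence): trim
                ## it the way a local aligner would
                ws <- max(0L, h$start[i] - len)
                we <- min(length(fr$aa), h$end[i] + len)
                sw <- .swIterate(pat,
                    Biostrings::subseq(fr$aa, ws + 1L, we), .blosum62(),
                    gapOpening = 11, gapExtension = 1,
                    minScore = cfg$minAaScore, minWidth = cfg$minQueryAa,
                    maxHits = 1L)
                ## override the full-length reading only when the trimmed
                ## alignment is decisively cleaner (a truncated or chimeric
                ## locus), not when it merely cherry-picks the best window
                ## of a uniformly diverged gene
                if (!is.null(sw) && sw$identity[1] >= patIdent + 25) {
                    iv <- mapHit(ws + sw$ss[1] - 1L, ws + sw$se[1], fr)
                    row <- data.frame(
                        qStart = sw$qs[1] - 1L, qEnd = sw$qe[1],
                        sStart = iv[1], sEnd = iv[2], strand = fr$strand,
                        frame = fr$off, identity = sw$identity[1],
                        alignedLength = sw$alnLen[1])
                }
            }
            if (is.null(row)) {
                iv <- mapHit(h$start[i], h$end[i], fr)
                row <- data.frame(
                    qStart = 0L, qEnd = len, sStart = iv[1], sEnd = iv[2],
                    strand = fr$strand, frame = fr$off,
                    identity = 100 * (len - h$mm[i]) / len,
                    alignedLength = len)
            }
            res <- rbind(res, row)
        }
    }
    if (!is.null(res)) return(res)
    blosum <- .blosum62()
    for (fr in idx$frames) {
        h <- .swIterate(pat, fr$aa, blosum, gapOpening = 11, gapExtension = 1,
                        minScore = cfg$minAaScore, minWidth = cfg$minQueryAa)
        if (is.null(h)) next
        for (i in seq_len(nrow(h))) {
            iv <- mapHit(h$ss[i] - 1L, h$se[i], fr)
            res <- rbind(res, data.frame(
                qStart = h$qs[i] - 1L, qEnd = h$qe[i],
                sStart = iv[1], sEnd = iv[2], strand = fr$strand,
                frame = fr$off, identity = h$identity[i],
                alignedLength = h$alnLen[i]))
        }
    }
    res
}

.blosum62 <- local({
    env <- new.env()
    function() {
        if (is.null(env$m)) {
            utils::data("BLOSUM62", package = "Biostrings", envir = env)
            env$m <- env$BLOSUM62
        }
        env$m
    }
})

## per-entry query pieces: list of (seq, exonIndex, qOffset) on the
## concatenated-exon axis; aa mode uses per-exon peptides for
## intron-containing genes and the full peptide otherwise
.entryQueries <- function(entry, mode) {
    if (mode == "nucleotide") {
        if (!entry@hasIntron)
            return(list(list(seq = entry@ntSequence, exon = 1L, off = 0L)))
        offs <- cumsum(c(0L, entry@exonLengths))
        lapply(seq_along(entry@exonLengths), function(i) list(
            seq = substr(entry@ntSequence, offs[i] + 1L, offs[i + 1L]),
            exon = i, off = offs[i]))
    } else {
        if (!entry@hasIntron)
            return(list(list(seq = entry@aaSequence, exon = 1L, off = 0L)))
        naa <- nchar(entry@aaExons)
        offs <- cumsum(c(0L, naa))
        lapply(seq_along(entry@aaExons), function(i) list(
            seq = entry@aaExons[i], exon = i, off = offs[i]))
    }
}

.searchEntries <- function(entries, idx, cfg, mode) {
    out <- .emptyHsp()
    for (i in seq_along(entries)) {
        e <- entries[[i]]
        eid <- paste(e@geneName, e@sourceRecord, i, sep = "|")
        for (qp in .entryQueries(e, mode)) {
            h <- if (mode == "nucleotide") .searchNtQuery(qp$seq, idx, cfg)
                 else .searchAaQuery(qp$seq, idx, cfg)
            if (is.null(h)) next
            out <- rbind(out, .hspRow(e@geneName, eid, e@sourceRecord, mode,
                qp$exon, h$qStart + qp$off, h$qEnd + qp$off,
                h$sStart, h$sEnd, h$strand, h$frame, h$identity,
                h$alignedLength))
        }
    }
    out
}

## ---- external (BLAST+) backend --------------------------------------------

.blastAvailable <- function()
    nzchar(Sys.which("blastn")) && nzchar(Sys.which("tblastn")) &&
    nzchar(Sys.which("makeblastdb"))

.blastSearch <- function(entries, target, cfg, mode) {
    if (!.blastAvailable())
        stop("external backend: BLAST+ binaries (blastn/tblastn/makeblastdb) ",
             "not found on PATH; use backend = 'builtin'")
    td <- tempfile("blastws"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    dbFa <- file.path(td, "target.fasta")
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(list(target@sequence), "T")),
        dbFa)
    system2("makeblastdb", c("-in", dbFa, "-dbtype", "nucl"),
            stdout = FALSE, stderr = FALSE)
    qFa <- file.path(td, "query.fasta")
    con <- file(qFa, "w")
    meta <- list()
    for (i in seq_along(entries)) {
        e <- entries[[i]]
        eid <- paste(e@geneName, e@sourceRecord, i, sep = "|")
        for (qp in .entryQueries(e, mode)) {
            minLen <- if (mode == "nucleotide") cfg$minQueryNt else cfg$minQueryAa
            if (nchar(qp$seq) < minLen) next
            qid <- sprintf("q%d", length(meta) + 1L)
            meta[[qid]] <- list(gene = e@geneName, entryId = eid,
                                refId = e@sourceRecord, exon = qp$exon,
                                off = qp$off)
            writeLines(c(paste0(">", qid), qp$seq), con)
        }
    }
    close(con)
    if (!length(meta)) return(.emptyHsp())
    outTab <- file.path(td, "hits.tsv")
    fmt <- "6 qseqid pident length qstart qend sstart send bitscore"
    if (mode == "nucleotide") {
        system2("blastn", c("-task", "blastn", "-query", qFa, "-db", dbFa,
            "-evalue", format(cfg$evalue), "-dust", "no",
            "-outfmt", shQuote(fmt), "-out", outTab),
            stdout = FALSE, stderr = FALSE)
    } else {
        system2("tblastn", c("-query", qFa, "-db", dbFa,
            "-evalue", format(cfg$evalue), "-seg", "no",
            "-db_gencode", "11",
            "-outfmt", shQuote(fmt), "-out", outTab),
            stdout = FALSE, stderr = FALSE)
    }
    if (!file.exists(outTab) || !file.size(outTab)) return(.emptyHsp())
    tab <- utils::read.table(outTab, sep = "\t", stringsAsFactors = FALSE)
    names(tab) <- c("qid", "pident", "length", "qstart", "qend",
                    "sstart", "send", "bitscore")
    L <- length(target@sequence)
    out <- .emptyHsp()
    for (i in seq_len(nrow(tab))) {
        m <- meta[[tab$qid[i]]]
        if (is.null(m)) next
        rev <- tab$sstart[i] > tab$send[i]
        s0 <- min(tab$sstart[i], tab$send[i]) - 1L
        e0 <- max(tab$sstart[i], tab$send[i])
        strand <- if (rev) "-" else "+"
        frame <- if (mode == "protein") {
            if (!rev) s0 %% 3L else (L - e0) %% 3L
        } else NA_integer_
        out <- rbind(out, .hspRow(m$gene, m$entryId, m$refId, mode, m$exon,
            tab$qstart[i] - 1L + m$off, tab$qend[i] + m$off,
            s0, e0, strand, frame, tab$pident[i], tab$length[i]))
    }
    out
}

## ---- public search operations ---------------------------------------------

#' Search reference RNA/PCG nucleotide entries against a target plastome
#'
#' BLASTN-analogue: nucleotide queries (the reference genes) against the
#' target subject, both strands; intron-containing genes are searched per
#' exon with query coordinates reported on the concatenated-exon axis.
#'
#' @param entries list of \linkS4class{ReferenceGeneEntry}.
#' @param target a \linkS4class{PlastomeRecord}.
#' @param cfg a \code{\link{searchConfig}}.
#' @param index optional precomputed target index (internal reuse).
#' @return HSP data.frame (one row per high-scoring segment pair).
#' @export
searchNucleotide <- function(entries, target, cfg = searchConfig(),
                             index = NULL) {
    stopifnot(length(entries) > 0)
    if (cfg$backend == "external")
        return(.blastSearch(entries, target, cfg, "nucleotide"))
    if (is.null(index)) index <- .targetIndex(target)
    .searchEntries(entries, index, cfg, "nucleotide")
}

#' Search reference CDS amino-acid entries against a target plastome
#'
#' TBLASTN-analogue: protein queries against the six-frame translated
#' target; the reading-frame offset of each hit on the subject coding strand
#' is recorded, with subject coordinates always on the forward axis.
#'
#' @inheritParams searchNucleotide
#' @return HSP data.frame.
#' @export
searchProtein <- function(entries, target, cfg = searchConfig(),
                          index = NULL) {
    stopifnot(length(entries) > 0)
    if (cfg$backend == "external")
        return(.blastSearch(entries, target, cfg, "protein"))
    if (is.null(index)) index <- .targetIndex(target)
    .searchEntries(entries, index, cfg, "protein")
}

#' Best-reference selection and per-copy clustering of HSPs
#'
#' Per gene, only the HSPs of the single reference entry with the highest
#' percent identity survive (ties: longer aligned length, then first entry
#' in input order). Surviving HSPs are clustered by strand and subject
#' proximity (gap <= \code{maxIntronSpan}) into per-copy clusters, each
#' ordered by query coordinate; genes duplicated in the inverted repeat
#' yield two or more clusters.
#'
#' @param hsps HSP data.frame from \code{\link{searchNucleotide}} /
#'   \code{\link{searchProtein}}.
#' @param cfg a \code{\link{searchConfig}}.
#' @return named list (per gene) of lists of HSP-cluster data.frames.
#' @export
selectBestHits <- function(hsps, cfg = searchConfig()) {
    out <- list()
    if (!nrow(hsps)) return(out)
    for (g in unique(hsps$geneName)) {
        gh <- hsps[hsps$geneName == g, , drop = FALSE]
        eids <- unique(gh$entryId)
        bestId <- vapply(eids, function(e) max(gh$identity[gh$entryId == e]), 0)
        bestLen <- vapply(eids, function(e)
            max(gh$alignedLength[gh$entryId == e]), 0L)
        winner <- eids[order(-bestId, -bestLen, seq_along(eids))][1]
        gh <- gh[gh$entryId == winner, , drop = FALSE]
        gh <- gh[order(gh$sStart), , drop = FALSE]
        clusters <- list()
        for (strand in unique(gh$strand)) {
            sh <- gh[gh$strand == strand, , drop = FALSE]
            brk <- c(0L, cumsum(
                utils::tail(sh$sStart, -1L) -
                utils::head(sh$sEnd, -1L) > cfg$maxIntronSpan))
            for (cl in split(sh, brk)) {
                ## one best HSP per query exon within a copy
                cl <- cl[order(cl$exonIndex, -cl$identity,
                               -cl$alignedLength), , drop = FALSE]
                cl <- cl[!duplicated(cl$exonIndex), , drop = FALSE]
                cl <- cl[order(cl$qStart), , drop = FALSE]
                clusters[[length(clusters) + 1L]] <- cl
            }
        }
        ## stable copy order along the forward axis
        ord <- order(vapply(clusters, function(x) min(x$sStart), 0L))
        out[[g]] <- clusters[ord]
    }
    out
}
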
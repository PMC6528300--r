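## Orchestration: search -> best-hit clustering -> GBDA/IBDA/RNA refinement
## -> short-exon-1 rescue -> IR detection -> coverage QC, over single targets
## and batches; GenBank + warning-log output.

.warnRow <- function(gene, copy, type, message)
    data.frame(geneName = gene, copyIndex = copy, type = type,
               message = message, stringsAsFactors = FALSE)

.emptyWarn <- function() .warnRow(character(0), integer(0), character(0),
                                  character(0))

## classify free-text warnings into log warning types
.warnType <- function(msg) {
    if (grepl("runaway ORF", msg)) return("runaway_orf")
    if (grepl("intron loss", msg)) return("intron_loss")
    if (grepl("exon1 not found|exon 1 not found", msg)) return("exon1_not_found")
    if (grepl("verify manually|HSP end kept|HSP ends kept", msg))
        return("boundary_fallback")
    if (grepl("pseudogene|not a multiple of 3", msg)) return("frame_issue")
    "other"
}

## trim overlapping HSPs (gapped-alignment artefacts): hsp i+1's 5' end is
## pushed to the first in-frame position at or after hsp i's 3' end
.trimOverlaps <- function(rows, isProtein) {
    n <- nrow(rows)
    if (n < 2L) return(rows)
    for (i in 2:n) {
        if (rows$cs1[i] < rows$cs2[i - 1L]) {
            newS <- rows$cs2[i - 1L]
            if (isProtein) {
                shift <- (3L - ((newS - rows$cs1[i]) %% 3L)) %% 3L
                newS <- newS + shift
            }
            rows$cs1[i] <- min(newS, rows$cs2[i])
        }
    }
    rows
}

## annotate one preliminary locus; returns list(annotation, warnings df)
.annotateLocus <- function(locus, target, cfg, params) {
    L <- length(target@sequence)
    strand <- locus$strand
    seqChr <- as.character(target@sequence)
    cs <- if (strand == "+") seqChr else .revcomp(seqChr)
    entry <- locus$entry
    cl <- locus$cluster
    ## map forward-axis HSPs into coding-strand ("gene orientation") coords
    if (strand == "+") { cl$cs1 <- cl$sStart; cl$cs2 <- cl$sEnd
    } else { cl$cs1 <- L - cl$sEnd; cl$cs2 <- L - cl$sStart }
    cl <- cl[order(cl$cs1), , drop = FALSE]
    isPcg <- entry@category == "PCG"
    cl <- .trimOverlaps(cl, isPcg)
    warn <- character(0)
    segs <- list()
    strategy <- ""; startCodon <- ""; intronStatus <- "none"

    if (!isPcg) {
        if (!entry@hasIntron || nrow(cl) == 1L) {
            refNt <- if (!entry@hasIntron) entry@ntSequence else {
                ei <- cl$exonIndex[1]
                offs <- cumsum(c(0L, entry@exonLengths))
                if (entry@hasIntron)
                    warn <- c(warn, sprintf(
                        "expected %d exons, found 1; verify manually",
                        length(entry@exonLengths)))
                substr(entry@ntSequence, offs[ei] + 1L, offs[ei + 1L])
            }
            r <- refineRnaBoundaries(cs, cl$cs1[1], cl$cs2[1], refNt, params)
            warn <- c(warn, r$warnings)
            segs <- list(c(r$start, r$end))
            if (entry@hasIntron) intronStatus <- "intron_partial"
        } else {
            offs <- cumsum(c(0L, entry@exonLengths))
            exSeq <- substring(entry@ntSequence, offs[-length(offs)] + 1L,
                               offs[-1L])
            h1 <- list(sStart = cl$cs1[1], sEnd = cl$cs2[1],
                       qStart = cl$qStart[1], qEnd = cl$qEnd[1])
            h2 <- list(sStart = cl$cs1[2], sEnd = cl$cs2[2],
                       qStart = cl$qStart[2], qEnd = cl$qEnd[2])
            r <- locateTrnaIntronBoundaries(cs, h1, h2,
                exSeq[cl$exonIndex[1]], exSeq[cl$exonIndex[2]], params)
            warn <- c(warn, r$warnings)
            segs <- r$segments
            intronStatus <- r$status
            if (r$status == "intron_lost")
                warn <- c(warn, "intron loss: exons annotated as a single feature")
        }
    } else if (entry@hasIntron && nrow(cl) == 1L &&
               entry@geneName %in% cfg$shortExon1Genes &&
               entry@exonLengths[1] <= 9L) {
        ## short-first-exon special case: exon 2 located, probe for exon 1
        len1 <- entry@exonLengths[1]
        len2 <- sum(entry@exonLengths[-1L])
        splitNt <- len2 %% 3L
        p2 <- .probeExon2FirstCodon(cs, cl$cs1[1],
            if (length(entry@aaExons) >= 2L) entry@aaExons[2] else "", params)
        exon2Start <- (if (!is.null(p2)) p2$pos else cl$cs1[1]) - splitNt
        stp <- findStop(cs, cl$cs1[1], cl$cs2[1])
        warn <- c(warn, stp$warnings)
        ex1 <- locateShortExon1(cs, exon2Start,
            substr(entry@ntSequence, 1L, len1),
            window = cfg$exon1Window, mismatches = cfg$exon1Mismatches)
        if (is.null(ex1)) {
            warn <- c(warn, "exon1 not found in upstream window; exon 2 annotated alone")
            segs <- list(c(exon2Start, stp$stopEnd))
            intronStatus <- "intron_partial"
            strategy <- "d"; startCodon <- ""
        } else {
            segs <- list(c(ex1[1], ex1[2]), c(exon2Start, stp$stopEnd))
            intronStatus <- "intron_present"
            startCodon <- substr(cs, ex1[1] + 1L, ex1[1] + 3L)
            strategy <- if (startCodon == "ATG") "a" else "d"
            tot <- (ex1[2] - ex1[1]) + (stp$stopEnd - exon2Start)
            if (tot %% 3L != 0L)
                warn <- c(warn, sprintf(
                    "exon1+exon2 length %d not a multiple of 3; verify manually", tot))
        }
    } else {
        ## protein-coding gene, one or more HSPs
        n <- nrow(cl)
        if (entry@hasIntron && n < length(entry@exonLengths))
            warn <- c(warn, sprintf(
                "expected %d exons, found %d; verify manually",
                length(entry@exonLengths), n))
        refAaN <- if (entry@hasIntron && length(entry@aaExons))
            entry@aaExons[1] else entry@aaSequence
        st <- findStart(cs, cl$cs1[1], refAaN, params)
        warn <- c(warn, st$warnings)
        strategy <- st$strategy
        startCodon <- st$startCodon
        curStart <- st$start
        anyIntron <- FALSE; allLost <- entry@hasIntron
        if (n >= 2L) {
            cum <- cumsum(entry@exonLengths)
            for (i in seq_len(n - 1L)) {
                status <- classifyInterHsp(cs, cl$cs2[i], cl$cs1[i + 1L])
                if (status == "intron_lost") {
                    warn <- c(warn, sprintf(
                        "intron loss between exons %d and %d: joined exons annotated as a single CDS",
                        cl$exonIndex[i], cl$exonIndex[i + 1L]))
                    next
                }
                anyIntron <- TRUE; allLost <- FALSE
                ei <- cl$exonIndex[i]
                lenUp <- if (ei <= length(cum)) cum[ei] else cum[length(cum)]
                lenDn <- sum(entry@exonLengths) - lenUp
                b <- locatePcgIntronBoundaries(cs, cl$cs2[i], cl$cs1[i + 1L],
                    refExon1Aa = entry@aaExons[ei],
                    refExon2Aa = entry@aaExons[min(ei + 1L,
                        length(entry@aaExons))],
                    refExon1LenNt = lenUp, refExon2LenNt = lenDn,
                    params = params)
                warn <- c(warn, b$warnings)
                segs[[length(segs) + 1L]] <- c(curStart, b$exon1End)
                curStart <- b$exon2Start
            }
        }
        stp <- findStop(cs, cl$cs1[n], cl$cs2[n])
        warn <- c(warn, stp$warnings)
        segs[[length(segs) + 1L]] <- c(curStart, stp$stopEnd)
        intronStatus <- if (anyIntron) "intron_present"
                        else if (entry@hasIntron && allLost && n >= 2L)
                            "intron_lost"
                        else if (entry@hasIntron) "intron_partial"
                        else "none"
        ## frame and internal-stop QC on the joined annotation
        tot <- sum(vapply(segs, function(s) s[2] - s[1], 0L))
        if (tot %% 3L != 0L) {
            warn <- c(warn, sprintf(
                "annotated CDS length %d not a multiple of 3; verify manually", tot))
        } else {
            aa <- translateCds(paste0(vapply(segs, function(s)
                substr(cs, s[1] + 1L, s[2]), ""), collapse = ""))
            if (grepl("\\*", aa))
                warn <- c(warn,
                    "internal stop codon in annotated CDS (possible pseudogene)")
        }
    }
    if (!length(segs)) return(NULL)
    ## clip to sequence and map back to the forward axis (reading order kept)
    segs <- lapply(segs, function(s) c(max(0L, s[1]), min(nchar(cs), s[2])))
    segs <- segs[vapply(segs, function(s) s[2] > s[1], TRUE)]
    if (!length(segs)) return(NULL)
    starts <- vapply(segs, `[`, 0L, 1L)
    ends <- vapply(segs, `[`, 0L, 2L)
    if (strand == "-") { starts2 <- L - ends; ends <- L - starts
                         starts <- starts2 }
    loc <- FeatureLocation(starts, ends, strand)
    cov <- queryCoverage(locWidth(loc), nchar(entry@ntSequence))
    ann <- new("GeneAnnotation", geneName = locus$geneName,
        category = entry@category, copyIndex = locus$copyIndex,
        location = loc, startStrategy = strategy, startCodon = startCodon,
        intronStatus = if (intronStatus == "intron_partial") "none"
                       else intronStatus,
        warnings = warn, sourceReference = entry@sourceRecord,
        coverage = cov)
    wdf <- .emptyWarn()
    for (w in warn)
        wdf <- rbind(wdf, .warnRow(locus$geneName, locus$copyIndex,
                                   .warnType(w), w))
    if (strategy %in% c("c", "d"))
        wdf <- rbind(wdf, .warnRow(locus$geneName, locus$copyIndex,
            "strategy_c_or_d", sprintf(
                "start resolved by strategy %s (codon %s); manual verification advised",
                strategy, startCodon)))
    if (nzchar(startCodon) && startCodon != "ATG" && entry@category == "PCG")
        wdf <- rbind(wdf, .warnRow(locus$geneName, locus$copyIndex,
            "non_atg_start", sprintf("non-ATG start codon %s annotated",
                                     startCodon)))
    list(annotation = ann, warnings = wdf)
}

#' Annotate a single target plastome
#'
#' Executes the automatic pipeline: similarity search (reverse
#' query-subject), best-reference selection and per-copy clustering,
#' boundary refinement (start/stop codons, RNA ends, intron boundaries,
#' short-exon-1 rescue), inverted-repeat detection and query-coverage
#' pseudogene screening. Deterministic for identical inputs and backend.
#'
#' @param db a \linkS4class{ReferenceDatabase}.
#' @param target a \linkS4class{PlastomeRecord}.
#' @param cfg a \code{\link{searchConfig}}.
#' @param params \code{\link{gbdaParams}}.
#' @return list with \code{annotations} (list of
#'   \linkS4class{GeneAnnotation}), \code{ir} (\linkS4class{IrAnnotation}),
#'   and \code{log} (per-target log section: statistics, skipped genes,
#'   typed warnings).
#' @export
annotateTarget <- function(db, target, cfg = searchConfig(),
                           params = gbdaParams()) {
    located <- locateGenes(db, target, cfg)
    anns <- list()
    warnings <- .emptyWarn()
    for (locus in located$loci) {
        res <- .annotateLocus(locus, target, cfg, params)
        if (is.null(res)) next
        anns[[length(anns) + 1L]] <- res$annotation
        warnings <- rbind(warnings, res$warnings)
    }
    for (i in seq_len(nrow(located$skipped)))
        warnings <- rbind(warnings, .warnRow(
            located$skipped$geneName[i], NA_integer_, "low_identity_skip",
            sprintf("percent identity %.1f below threshold %.0f%%; not annotated",
                located$skipped$identity[i], cfg$identityThresholdPcg)))
    flags <- flagPseudogenes(anns, cfg$qcovMin, cfg$qcovMax)
    for (i in seq_len(nrow(flags)))
        warnings <- rbind(warnings, .warnRow(
            flags$geneName[i], flags$copyIndex[i], "coverage_flag",
            sprintf("query coverage %.2f outside (%.2g, %.2g): putative pseudogene",
                flags$coverage[i], cfg$qcovMin, cfg$qcovMax)))
    ir <- detectIr(target, cfg$irMinLength, circular = cfg$circular)
    annotatedGenes <- unique(vapply(anns, function(a) a@geneName, ""))
    log <- list(
        targetId = target@recordId,
        totalReferenceGenes = length(db@geneNames),
        totalAnnotatedCopies = length(anns),
        totalAnnotatedGenes = length(annotatedGenes),
        missingGeneNames = sort(union(located$missing,
            setdiff(db@geneNames,
                    c(annotatedGenes, located$skipped$geneName)))),
        skipped = located$skipped,
        warnings = warnings,
        irFound = ir@found)
    list(annotations = anns, ir = ir, log = log)
}

#' Write the consolidated warning/statistics log
#'
#' Human-readable sections per target: skipped genes with their identities,
#' typed warnings (intron losses, non-ATG starts, boundary fallbacks,
#' coverage flags), then the statistics lines: total genes in the
#' reference(s), total genes annotated, and all reference gene names not
#' annotated in the target.
#'
#' @param runLog list of per-target log sections (from
#'   \code{\link{annotateTarget}}).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeLog <- function(runLog, path) {
    out <- c("plastanno warning log",
        paste0("Gene counting: the reference total counts unique gene ",
               "names; the annotated total counts every annotated copy ",
               "(inverted-repeat duplicates included)."),
        "")
    for (sec in runLog) {
        out <- c(out, sprintf("== Target: %s ==", sec$targetId))
        if (nrow(sec$skipped)) {
            out <- c(out, "Skipped (identity below threshold):")
            for (i in seq_len(nrow(sec$skipped)))
                out <- c(out, sprintf("  %s: identity %.1f%%",
                    sec$skipped$geneName[i], sec$skipped$identity[i]))
        }
        w <- sec$warnings
        w <- w[!w$type %in% "low_identity_skip", , drop = FALSE]
        if (nrow(w)) {
            out <- c(out, "Warnings:")
            for (i in seq_len(nrow(w)))
                out <- c(out, sprintf("  %s%s [%s]: %s", w$geneName[i],
                    ifelse(is.na(w$copyIndex[i]), "",
                           sprintf(" (copy %d)", w$copyIndex[i])),
                    w$type[i], w$message[i]))
        }
        out <- c(out, "Statistics:",
            sprintf("  Total genes in the reference plastome(s): %d",
                    sec$totalReferenceGenes),
            sprintf("  Total genes annotated: %d", sec$totalAnnotatedCopies),
            sprintf("  Genes not annotated: %s",
                if (length(sec$missingGeneNames))
                    paste(sec$missingGeneNames, collapse = ", ")
                else "none"),
            "")
    }
    writeLines(out, path)
    invisible(path)
}

#' Batch-annotate a directory of target plastomes
#'
#' Reads every GenBank reference in \code{referenceDir}, builds the
#' four-component database, annotates every FASTA target in
#' \code{targetDir} (one sequence per file), and writes one GenBank output
#' per target (same basename) plus one consolidated warning log. A corrupt
#' target is reported in the log and skipped; the batch continues. The run
#' is deterministic: identical inputs give byte-identical outputs.
#'
#' @param referenceDir directory with one or more .gb/.gbk reference files.
#' @param targetDir directory with one or more .fa/.fasta target files.
#' @param outDir output directory (created if needed).
#' @param cfg a \code{\link{searchConfig}}.
#' @param logPath warning-log path (default \code{outDir/warning.log}).
#' @return invisibly, 0 on success, 1 on global failure.
#' @export
runBatch <- function(referenceDir, targetDir, outDir,
                     cfg = searchConfig(), logPath = NULL) {
    refFiles <- list.files(referenceDir, "\\.(gb|gbk|genbank)$",
                           full.names = TRUE)
    if (!length(refFiles))
        stop("no GenBank reference files in ", referenceDir)
    tgtFiles <- list.files(targetDir, "\\.(fa|fasta|fas)$", full.names = TRUE)
    if (!length(tgtFiles))
        stop("no FASTA target files in ", targetDir)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(logPath)) logPath <- file.path(outDir, "warning.log")
    refs <- list()
    for (f in refFiles) {
        rec <- parseGenBank(f)
        iss <- validateReference(rec)
        if (length(iss))
            message("reference ", basename(f), ": ",
                    length(iss), " validation issue(s); usable features kept")
        refs[[length(refs) + 1L]] <- rec
    }
    db <- buildReferenceDb(refs)
    runLog <- list()
    for (f in sort(tgtFiles)) {
        sec <- tryCatch({
            target <- readTargetFasta(f)
            res <- annotateTarget(db, target, cfg)
            outGb <- file.path(outDir,
                paste0(sub("\\.[^.]+$", "", basename(f)), ".gb"))
            writeGenBank(target, res$annotations, outGb, ir = res$ir)
            res$log
        }, error = function(e) list(
            targetId = basename(f),
            totalReferenceGenes = length(db@geneNames),
            totalAnnotatedCopies = 0L, totalAnnotatedGenes = 0L,
            missingGeneNames = db@geneNames,
            skipped = data.frame(geneName = character(0),
                                 identity = numeric(0)),
            warnings = .warnRow(NA_character_, NA_integer_, "other",
                paste("target failed:", conditionMessage(e))),
            irFound = FALSE))
        runLog[[length(runLog) + 1L]] <- sec
    }
    writeLog(runLog, logPath)
    invisible(0L)
}
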
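## GenBank flat-file reading/writing and feature-sequence extraction.
##
## Internal coordinates are 0-based half-open; the 1-based inclusive GenBank
## convention is applied only here, at the read/write boundary.

.KEPT_KINDS <- c("gene", "CDS", "tRNA", "rRNA")

## ---- location strings ------------------------------------------------------

## Parse a GenBank location string into forward-axis segments (0-based
## half-open, reading order) + strand. Returns NULL (with attribute "issue")
## for unsupported forms (fuzzy positions, order(), nested complement).
.parseLocation <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    bad <- function(msg) structure(list(), issue = sprintf("%s in '%s'", msg, s))
    if (grepl("[<>]", s)) return(bad("fuzzy position rejected"))
    if (grepl("order\\(", s)) return(bad("order() location rejected"))
    strand <- "+"
    if (grepl("^complement\\(", s)) {
        strand <- "-"
        s <- sub("^complement\\(", "", s)
        s <- sub("\\)$", "", s)
    }
    if (grepl("complement", s)) return(bad("per-segment complement rejected"))
    if (grepl("^join\\(", s)) {
        s <- sub("^join\\(", "", s)
        s <- sub("\\)$", "", s)
    }
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (!length(parts)) return(bad("empty location"))
    starts <- integer(length(parts)); ends <- integer(length(parts))
    for (i in seq_along(parts)) {
        m <- regmatches(parts[i], regexec("^([0-9]+)(\\.\\.([0-9]+))?$", parts[i]))[[1]]
        if (!length(m)) return(bad("unparseable segment"))
        a <- as.integer(m[2])
        b <- if (m[4] == "") a else as.integer(m[4])
        if (b < a) return(bad("segment end before start"))
        starts[i] <- a - 1L   # 1-based inclusive -> 0-based half-open
        ends[i] <- b
    }
    if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
    FeatureLocation(starts, ends, strand)
}

## Format a FeatureLocation back to GenBank location text.
.formatLocation <- function(loc) {
    s <- loc@starts; e <- loc@ends
    if (loc@strand == "-") { s <- rev(s); e <- rev(e) }
    segs <- paste0(s + 1L, "..", e)
    txt <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")")
           else segs
    if (loc@strand == "-") txt <- paste0("complement(", txt, ")")
    txt
}

## ---- reading ---------------------------------------------------------------

#' Parse a GenBank flat file into a PlastomeRecord
#'
#' Keeps gene, CDS, tRNA and rRNA features (join/complement locations become
#' multi-segment \linkS4class{FeatureLocation}s); other feature kinds are
#' ignored. Unsupported locations (fuzzy \code{<}/\code{>}, \code{order()})
#' are recorded as parse issues, surfaced by \code{\link{validateReference}},
#' rather than raising an error.
#'
#' @param path path to a GenBank flat file with a sequence block.
#' @return a \linkS4class{PlastomeRecord}.
#' @export
parseGenBank <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^LOCUS", lines[1]))
        stop("malformed GenBank file (line 1): missing LOCUS line in ", path)
    recId <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "[[:space:]]+")[[1]][1]
    featStart <- grep("^FEATURES", lines)
    oriStart <- grep("^ORIGIN", lines)
    if (!length(oriStart))
        stop("malformed GenBank file: no ORIGIN sequence block in ", path)
    oriStart <- oriStart[1]

    issues <- character(0)
    feats <- list()
    if (length(featStart)) {
        ftLines <- lines[(featStart[1] + 1L):(oriStart - 1L)]
        ## split the feature table into feature blocks: a new feature begins
        ## on a line whose key sits in columns 6-20
        isNew <- grepl("^ {5}[A-Za-z0-9_'-]+ +\\S", ftLines)
        idx <- cumsum(isNew)
        for (b in split(ftLines[idx > 0], idx[idx > 0])) {
            headTok <- strsplit(trimws(b[1]), "[[:space:]]+")[[1]]
            key <- headTok[1]
            rest <- c(paste(headTok[-1], collapse = ""), trimws(b[-1]))
            qualAt <- grep("^/", rest)
            locTxt <- paste(rest[seq_len(if (length(qualAt)) qualAt[1] - 1L
                                         else length(rest))], collapse = "")
            quals <- list()
            if (length(qualAt)) {
                qlines <- rest[qualAt[1]:length(rest)]
                starts <- grep("^/", qlines)
                grp <- cumsum(seq_along(qlines) %in% starts)
                for (q in split(qlines, grp)) {
                    q1 <- paste(q, collapse = " ")
                    m <- regmatches(q1, regexec('^/([A-Za-z_0-9]+)(=(.*))?$', q1))[[1]]
                    if (!length(m)) next
                    val <- m[4]
                    val <- gsub('^"|"$', "", val)
                    quals[[m[2]]] <- val
                }
            }
            if (!key %in% .KEPT_KINDS) next
            loc <- .parseLocation(locTxt)
            if (is.null(attr(loc, "issue")) && is(loc, "FeatureLocation")) {
                gn <- if (!is.null(quals$gene)) quals$gene else ""
                feats[[length(feats) + 1L]] <- new("GeneFeature",
                    geneName = gn, kind = key, location = loc,
                    qualifiers = quals)
            } else {
                issues <- c(issues, sprintf("%s feature: %s", key,
                                            attr(loc, "issue")))
            }
        }
    }
    seqLines <- lines[(oriStart + 1L):length(lines)]
    seqLines <- seqLines[!grepl("^//", seqLines)]
    seqTxt <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    new("PlastomeRecord", recordId = recId,
        sequence = Biostrings::DNAString(seqTxt),
        features = feats, parseIssues = issues)
}

#' Read a target plastome from a FASTA file (one sequence per file)
#'
#' @param path FASTA file containing exactly one sequence.
#' @return a \linkS4class{PlastomeRecord} with no features.
#' @export
readTargetFasta <- function(path) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L)
        stop("target FASTA must contain exactly one sequence, found ",
             length(ss), " in ", path)
    id <- strsplit(names(ss)[1], "[[:space:]]+")[[1]][1]
    new("PlastomeRecord", recordId = id,
        sequence = Biostrings::DNAString(toupper(as.character(ss[[1]]))),
        features = list(), parseIssues = character(0))
}

## ---- extraction ------------------------------------------------------------

#' Extract the coding/sense-strand sequence of a feature
#'
#' Segments are concatenated in reading order; reverse-strand locations are
#' reverse-complemented, so the result is always the feature's sense strand.
#'
#' @param record a \linkS4class{PlastomeRecord}.
#' @param loc a \linkS4class{FeatureLocation}.
#' @return nucleotide character string.
#' @export
extractFeatureSequence <- function(record, loc) {
    L <- length(record@sequence)
    if (any(loc@starts < 0L) || any(loc@ends > L))
        stop("feature segment out of sequence bounds [0,", L, ")")
    seqc <- as.character(record@sequence)
    segs <- substring(seqc, loc@starts + 1L, loc@ends)
    if (loc@strand == "+") return(paste0(segs, collapse = ""))
    paste0(vapply(segs, .revcomp, ""), collapse = "")
}

## ---- validation ------------------------------------------------------------

#' Check a parsed reference record for usability
#'
#' Reports one issue per feature lacking the indispensable gene-name
#' qualifier, per CDS whose extracted length is not a multiple of 3, per
#' feature out of bounds, per CDS containing ambiguity codes, plus any
#' location-parse issues. An empty return means the record is a usable
#' reference.
#'
#' @param record a \linkS4class{PlastomeRecord}.
#' @return character vector of issues (empty when clean).
#' @export
validateReference <- function(record) {
    issues <- record@parseIssues
    L <- length(record@sequence)
    for (i in seq_along(record@features)) {
        f <- record@features[[i]]
        tag <- sprintf("%s feature #%d (%s)", f@kind, i,
                       if (nzchar(f@geneName)) f@geneName else "unnamed")
        if (!nzchar(f@geneName))
            issues <- c(issues, paste0(tag, ": missing /gene qualifier"))
        if (any(f@location@starts < 0L) || any(f@location@ends > L)) {
            issues <- c(issues, paste0(tag, ": location out of bounds"))
            next
        }
        if (f@kind == "CDS") {
            nt <- extractFeatureSequence(record, f@location)
            if (nchar(nt) %% 3L != 0L)
                issues <- c(issues, sprintf(
                    "%s: CDS length %d not a multiple of 3", tag, nchar(nt)))
            if (grepl("[^ACGT]", nt))
                issues <- c(issues, paste0(tag, ": ambiguity codes inside CDS"))
        }
    }
    issues
}

## ---- writing ---------------------------------------------------------------

.wrapLocation <- function(key, locTxt, width = 58L) {
    ## feature line: 5 spaces, key padded to 16, then location (wrapped at
    ## commas onto continuation lines starting at column 22)
    pieces <- character(0)
    while (nchar(locTxt) > width) {
        cut <- max(gregexpr(",", substr(locTxt, 1L, width))[[1]])
        if (cut < 1L) break
        pieces <- c(pieces, substr(locTxt, 1L, cut))
        locTxt <- substr(locTxt, cut + 1L, nchar(locTxt))
    }
    pieces <- c(pieces, locTxt)
    c(sprintf("     %-16s%s", key, pieces[1]),
      if (length(pieces) > 1L) paste0(strrep(" ", 21L), pieces[-1]))
}

.featureBlock <- function(key, loc, quals) {
    out <- .wrapLocation(key, .formatLocation(loc))
    for (nm in names(quals)) {
        v <- quals[[nm]]
        out <- c(out, sprintf('%s/%s="%s"', strrep(" ", 21L), nm, v))
    }
    out
}

#' Write an annotated plastome to a GenBank flat file
#'
#' Each \linkS4class{GeneAnnotation} yields a gene feature plus a
#' CDS/tRNA/rRNA feature with an identical location; multi-exon features are
#' written as \code{join(...)}, reverse strand as \code{complement(...)}. An
#' optional \linkS4class{IrAnnotation} adds two repeat_region features. When
#' \code{annotations} is NULL the record's own features are written (used to
#' emit synthetic reference fixtures). The file re-parses to identical
#' coordinates.
#'
#' @param record the \linkS4class{PlastomeRecord} carrying the sequence.
#' @param annotations list of \linkS4class{GeneAnnotation}, or NULL.
#' @param path output file path.
#' @param ir optional \linkS4class{IrAnnotation}.
#' @return invisibly, the path.
#' @export
writeGenBank <- function(record, annotations = NULL, path, ir = NULL) {
    L <- length(record@sequence)
    out <- c(
        sprintf("LOCUS       %-16s %11d bp    DNA     linear   PLN 01-JAN-2000",
                substr(record@recordId, 1L, 16L), L),
        sprintf("DEFINITION  %s plastome, annotated by plastanno.",
                record@recordId),
        sprintf("ACCESSION   %s", record@recordId),
        "FEATURES             Location/Qualifiers",
        .featureBlock("source", FeatureLocation(0L, L, "+"),
                      list(organism = record@recordId,
                           mol_type = "genomic DNA")))
    kindOf <- function(cat) switch(cat, PCG = "CDS", cat)
    if (is.null(annotations)) {
        for (f in record@features)
            out <- c(out, .featureBlock(f@kind, f@location,
                f@qualifiers[intersect(names(f@qualifiers),
                                       c("gene", "note", "product"))]))
    } else {
        ord <- order(vapply(annotations, function(a)
            min(locStarts(a@location)), 0L),
            vapply(annotations, function(a) a@geneName, ""))
        annotations <- annotations[ord]
        for (a in annotations) {
            quals <- list(gene = a@geneName)
            note <- character(0)
            if (a@intronStatus == "intron_lost") note <- "intron lost"
            if (nzchar(a@startStrategy) && a@startStrategy %in% c("c", "d"))
                note <- c(note, sprintf(
                    "start codon %s found by strategy %s; verify manually",
                    a@startCodon, a@startStrategy))
            out <- c(out, .featureBlock("gene", a@location, quals))
            if (length(note)) quals$note <- paste(note, collapse = "; ")
            out <- c(out, .featureBlock(kindOf(a@category), a@location, quals))
        }
    }
    if (!is.null(ir) && isTRUE(ir@found)) {
        out <- c(out,
            .featureBlock("repeat_region",
                FeatureLocation(ir@ira[1], ir@ira[2], "+"),
                list(note = "inverted repeat A (IRa)",
                     rpt_type = "inverted")),
            .featureBlock("repeat_region",
                FeatureLocation(ir@irb[1], ir@irb[2], "+"),
                list(note = "inverted repeat B (IRb)",
                     rpt_type = "inverted")))
    }
    out <- c(out, "ORIGIN")
    seqc <- tolower(as.character(record@sequence))
    pos <- seq(1L, nchar(seqc), by = 60L)
    for (p in pos) {
        chunk <- substr(seqc, p, min(p + 59L, nchar(seqc)))
        tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
        out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
    }
    out <- c(out, "//")
    writeLines(out, path)
    invisible(path)
}
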
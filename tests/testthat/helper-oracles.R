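# Independent oracles and tiny hand-built fixtures shared across tests.
# These deliberately avoid the package's own helpers: slicing and
# complementing are done with base string ops, translation with a direct
# lookup into the published code table.

oracleRevcomp <- function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# verbatim translation under code table 11, stops kept as "*"
oracleTranslate <- function(nt) {
    gc11 <- Biostrings::getGeneticCode("11")
    n <- nchar(nt)
    cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
    paste(unname(gc11[cods]), collapse = "")
}

# manual slicing oracle: segs are 1-based inclusive (a, b) pairs in
# forward-axis order, as printed in a GenBank location
oracleExtract <- function(seqStr, segs, strand) {
    pieces <- vapply(segs, function(u) substr(seqStr, u[1], u[2]), "")
    fwd <- paste(pieces, collapse = "")
    if (strand == "+") fwd else oracleRevcomp(fwd)
}

# deterministic random sequence without touching the package generator
oracleRandSeq <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small hand-built GenBank file exercising join / complement /
# complement(join()) locations; returns list(path, seq)
toyGenBank <- function(dir = tempfile("toygb")) {
    dir.create(dir, showWarnings = FALSE)
    seqStr <- oracleRandSeq(500, seed = 424242)
    # keep the two CDS in frame (99 nt and 108 nt)
    lines <- c(
        sprintf("LOCUS       %-16s %11d bp    DNA     linear   PLN 01-JAN-2000",
                "toy", 500L),
        "FEATURES             Location/Qualifiers",
        "     source          1..500",
        '                     /organism="toy"',
        "     gene            join(10..18,101..190)",
        '                     /gene="atpF"',
        "     CDS             join(10..18,101..190)",
        '                     /gene="atpF"',
        "     tRNA            complement(50..130)",
        '                     /gene="trnL-UAA"',
        "     CDS             complement(join(200..300,400..406))",
        '                     /gene="ndhB"',
        "     misc_feature    5..9",
        '                     /note="ignored kind"',
        "ORIGIN")
    pos <- seq(1, 500, 60)
    for (p in pos) {
        chunk <- tolower(substr(seqStr, p, min(p + 59, 500)))
        tens <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
    }
    lines <- c(lines, "//")
    path <- file.path(dir, "toy.gb")
    writeLines(lines, path)
    list(path = path, seq = seqStr)
}

# fixture pair + database + annotation, memoised per (seed, key)
.fxCache <- new.env()
cachedAnnotation <- function(seed, perturbations = "short_exon1_gene",
                             divergence = 0) {
    key <- paste(seed, paste(perturbations, collapse = ","), divergence)
    if (!is.null(.fxCache[[key]])) return(.fxCache[[key]])
    fx <- generateFixture(
        fixtureSpec(seed = seed, divergence = divergence,
                    perturbations = perturbations),
        dir = tempfile("fxcache"))
    db <- buildReferenceDb(parseGenBank(fx$referencePath))
    res <- annotateTarget(db, readTargetFasta(fx$targetPath))
    out <- list(fx = fx, db = db, res = res)
    .fxCache[[key]] <- out
    out
}

# plant an exact inverted repeat in a random background; guard bases make
# the planted arm the maximal exact repeat
plantedIrRecord <- function(seed, irLen, L = 30000, at1 = 10000,
                            at2 = 25000 - irLen) {
    set.seed(seed)
    b <- sample(c("A", "T", "G", "C"), L, replace = TRUE)
    arm <- sample(c("A", "T", "G", "C"), irLen, replace = TRUE)
    b[(at1 + 1):(at1 + irLen)] <- arm
    b[(at2 + 1):(at2 + irLen)] <-
        strsplit(oracleRevcomp(paste(arm, collapse = "")), "")[[1]]
    b[at1] <- "A"; b[at2 + irLen + 1] <- "A"
    b[at1 + irLen + 1] <- "A"; b[at2] <- "A"
    new("PlastomeRecord", recordId = sprintf("ir%d", seed),
        sequence = Biostrings::DNAString(paste(b, collapse = "")),
        features = list(), parseIssues = character(0))
}
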
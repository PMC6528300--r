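test_that("GenBank locations parse to 0-based half-open segments with strand", {
    toy <- toyGenBank()
    rec <- parseGenBank(toy$path)
    feats <- recordFeatures(rec)
    kinds <- vapply(feats, function(f) f@kind, "")
    expect_setequal(kinds, c("gene", "CDS", "tRNA", "CDS"))

    cds1 <- feats[[which(kinds == "CDS")[1]]]
    expect_identical(locStarts(cds1@location), c(9L, 100L))
    expect_identical(locEnds(cds1@location), c(18L, 190L))
    expect_identical(locStrand(cds1@location), "+")

    trna <- feats[[which(kinds == "tRNA")]]
    expect_identical(locStarts(trna@location), 49L)
    expect_identical(locEnds(trna@location), 130L)
    expect_identical(locStrand(trna@location), "-")

    ## complement(join(...)): reading order is reversed
    cds2 <- feats[[which(kinds == "CDS")[2]]]
    expect_identical(locStarts(cds2@location), c(399L, 199L))
    expect_identical(locEnds(cds2@location), c(406L, 300L))
    expect_identical(locStrand(cds2@location), "-")
})

test_that("extracted feature sequences match a manual slicing oracle", {
    toy <- toyGenBank()
    rec <- parseGenBank(toy$path)
    feats <- recordFeatures(rec)
    kinds <- vapply(feats, function(f) f@kind, "")

    cds2 <- feats[[which(kinds == "CDS")[2]]]
    expect_identical(
        extractFeatureSequence(rec, cds2@location),
        oracleExtract(toy$seq, list(c(200, 300), c(400, 406)), "-"))
    cds1 <- feats[[which(kinds == "CDS")[1]]]
    expect_identical(
        extractFeatureSequence(rec, cds1@location),
        oracleExtract(toy$seq, list(c(10, 18), c(101, 190)), "+"))

    ## tiny direct cases
    mini <- new("PlastomeRecord", recordId = "m",
                sequence = Biostrings::DNAString("ATGCATGC"),
                features = list(), parseIssues = character(0))
    expect_identical(extractFeatureSequence(mini, FeatureLocation(0, 3, "+")),
                     "ATG")
    expect_identical(extractFeatureSequence(mini, FeatureLocation(0, 3, "-")),
                     "CAT")
    expect_error(extractFeatureSequence(mini, FeatureLocation(5, 12, "+")),
                 "bounds")
})

test_that("strand symmetry: reverse extraction equals revcomp of forward", {
    set.seed(99)
    for (i in 1:10) {
        s <- oracleRandSeq(200, seed = 1000 + i)
        rec <- new("PlastomeRecord", recordId = "r",
                   sequence = Biostrings::DNAString(s), features = list(),
                   parseIssues = character(0))
        a1 <- sample(0:80, 1); b1 <- a1 + sample(8:15, 1)
        a2 <- b1 + sample(5:30, 1); b2 <- a2 + sample(8:15, 1)
        a <- c(a1, a2); b <- c(b1, b2)
        fwd <- extractFeatureSequence(rec,
            FeatureLocation(a, b, "+"))
        rev <- extractFeatureSequence(rec,
            FeatureLocation(rev(a), rev(b), "-"))
        expect_identical(rev, oracleRevcomp(fwd))
    }
})

test_that("write-then-parse round trips coordinates, strands and names", {
    toy <- toyGenBank()
    rec <- parseGenBank(toy$path)
    out <- tempfile(fileext = ".gb")
    writeGenBank(rec, NULL, out)
    rec2 <- parseGenBank(out)
    expect_identical(as.character(recordSequence(rec2)),
                     as.character(recordSequence(rec)))
    f1 <- recordFeatures(rec); f2 <- recordFeatures(rec2)
    expect_length(f2, length(f1))
    for (i in seq_along(f1)) {
        expect_identical(f2[[i]]@geneName, f1[[i]]@geneName)
        expect_identical(f2[[i]]@kind, f1[[i]]@kind)
        expect_identical(locStarts(f2[[i]]@location),
                         locStarts(f1[[i]]@location))
        expect_identical(locEnds(f2[[i]]@location),
                         locEnds(f1[[i]]@location))
        expect_identical(locStrand(f2[[i]]@location),
                         locStrand(f1[[i]]@location))
    }
})

test_that("single-exon annotations are written without join()", {
    mini <- new("PlastomeRecord", recordId = "m",
                sequence = Biostrings::DNAString(strrep("ACGT", 50)),
                features = list(), parseIssues = character(0))
    ann <- new("GeneAnnotation", geneName = "psbA", category = "PCG",
               copyIndex = 1L, location = FeatureLocation(10, 40, "+"),
               startStrategy = "a", startCodon = "ATG",
               intronStatus = "intron_lost", warnings = character(0),
               sourceReference = "ref", coverage = 1)
    out <- tempfile(fileext = ".gb")
    writeGenBank(mini, list(ann), out)
    txt <- readLines(out)
    cdsLine <- grep("^     CDS ", txt, value = TRUE)
    expect_match(cdsLine, "11\\.\\.40")
    expect_false(any(grepl("join", cdsLine)))
    ## intron-containing CDS is written as join(...)
    ann2 <- new("GeneAnnotation", geneName = "atpF", category = "PCG",
                copyIndex = 1L,
                location = FeatureLocation(c(9, 100), c(18, 190), "+"),
                startStrategy = "a", startCodon = "ATG",
                intronStatus = "intron_present", warnings = character(0),
                sourceReference = "ref", coverage = 1)
    writeGenBank(mini, list(ann2), out)
    expect_true(any(grepl("join\\(10\\.\\.18,101\\.\\.190\\)",
                          readLines(out))))
})

test_that("reference validation reports the paper's indispensable checks", {
    toy <- toyGenBank()
    rec <- parseGenBank(toy$path)
    expect_length(validateReference(rec), 0)

    ## drop the gene qualifier from the tRNA: exactly one issue naming it
    noname <- rec
    k <- which(vapply(recordFeatures(rec), function(f) f@kind, "") == "tRNA")
    f <- recordFeatures(rec)[[k]]
    f@geneName <- ""
    noname@features[[k]] <- f
    iss <- validateReference(noname)
    expect_length(iss, 1)
    expect_match(iss, "missing /gene")
    expect_match(iss, "tRNA")

    ## out-of-frame CDS (100 nt) is reported
    bad <- rec
    bad@features[[2]]@location <- FeatureLocation(9, 109, "+")
    expect_true(any(grepl("not a multiple of 3", validateReference(bad))))
})

test_that("fuzzy and order() locations become validation issues, not crashes", {
    toy <- toyGenBank()
    txt <- readLines(toy$path)
    txt <- sub("join\\(10\\.\\.18,101\\.\\.190\\)", "<10..190", txt)
    p <- tempfile(fileext = ".gb")
    writeLines(txt, p)
    rec <- parseGenBank(p)
    expect_true(any(grepl("fuzzy", validateReference(rec))))
})

test_that("an independent GenBank parser agrees on the written features", {
    ## Biopython as a cross-parser oracle on the package's own output
    toy <- toyGenBank()
    rec <- parseGenBank(toy$path)
    out <- tempfile(fileext = ".gb")
    writeGenBank(rec, NULL, out)
    py <- paste(
        "from Bio import SeqIO",
        sprintf("rec = next(SeqIO.parse(%s, 'genbank'))", shQuote(out)),
        "print(len(rec.seq))",
        "for f in rec.features:",
        "    if f.type == 'source': continue",
        "    locs = ';'.join('%d-%d' % (p.start, p.end) for p in f.location.parts)",
        "    print(f.type, f.qualifiers['gene'][0], locs, f.location.strand)",
        sep = "\n")
    res <- suppressWarnings(
        system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = FALSE))
    expect_identical(res[1], "500")
    got <- strsplit(res[-1], " ")
    feats <- recordFeatures(rec)
    expect_length(got, length(feats))
    for (i in seq_along(feats)) {
        f <- feats[[i]]
        expect_identical(got[[i]][1], f@kind)
        expect_identical(got[[i]][2], f@geneName)
        segs <- sort(locStarts(f@location))
        pySegs <- sort(as.integer(vapply(
            strsplit(got[[i]][3], ";")[[1]],
            function(x) strsplit(x, "-")[[1]][1], "")))
        expect_identical(pySegs, segs)
        expect_identical(got[[i]][4],
                         if (locStrand(f@location) == "+") "1" else "-1")
    }
})
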
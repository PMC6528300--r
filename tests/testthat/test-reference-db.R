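## a compact reference with a known composition: 1 rRNA, 2 tRNAs (one
## intron-containing), 2 CDS (one intron-containing)
.dbToyRecord <- function() {
    spacer <- function(n, seed) oracleRandSeq(n, seed)
    rrn <- oracleRandSeq(120, 11)
    trnA <- oracleRandSeq(72, 12)
    trnB1 <- oracleRandSeq(35, 13); trnB2 <- oracleRandSeq(38, 14)
    ## intron-free CDS, 20 aa
    cds1 <- paste0("ATG", paste(rep("GCT", 19), collapse = ""), "TAA")
    ## intron-containing CDS: exon1 9 nt, exon2 291 nt (=> 99 aa peptide)
    cds2 <- paste0("ATG", paste(rep("GTT", 98), collapse = ""), "TGA")
    ex1 <- substr(cds2, 1, 9); ex2 <- substr(cds2, 10, 300)
    seqStr <- paste0(spacer(50, 1), rrn, spacer(30, 2), trnA, spacer(30, 3),
                     trnB1, spacer(60, 4), trnB2, spacer(30, 5),
                     cds1, spacer(30, 6), ex1, spacer(80, 7), ex2,
                     spacer(40, 8))
    off <- function(x) cumsum(c(0, nchar(x)))
    p <- off(c(spacer(50, 1), rrn, spacer(30, 2), trnA, spacer(30, 3),
               trnB1, spacer(60, 4), trnB2, spacer(30, 5), cds1,
               spacer(30, 6), ex1, spacer(80, 7), ex2))
    feat <- function(name, kind, starts, ends, strand = "+")
        new("GeneFeature", geneName = name, kind = kind,
            location = FeatureLocation(starts, ends, strand),
            qualifiers = list(gene = name))
    feats <- list(
        feat("rrn16", "rRNA", p[2], p[3]),
        feat("trnA", "tRNA", p[4], p[5]),
        feat("trnB", "tRNA", c(p[6], p[8]), c(p[7], p[9])),
        feat("cds1", "CDS", p[10], p[11]),
        feat("cds2", "CDS", c(p[12], p[14]), c(p[13], p[15])))
    new("PlastomeRecord", recordId = "dbtoy",
        sequence = Biostrings::DNAString(seqStr), features = feats,
        parseIssues = character(0))
}

test_that("the database has exactly four components partitioning the genes", {
    rec <- .dbToyRecord()
    db <- buildReferenceDb(rec)
    ## 1 rRNA + 2 tRNA in the RNA component; 2 PCGs split by intron status
    expect_length(db@rnaNt, 3)
    expect_length(db@pcgNt, 2)
    expect_length(db@cdsAaIntronless, 1)
    expect_length(db@cdsAaIntron, 1)
    ## partition: every gene in exactly one nt component, every PCG in
    ## exactly one aa component
    rnaNames <- vapply(db@rnaNt, geneName, "")
    pcgNames <- vapply(db@pcgNt, geneName, "")
    expect_length(intersect(rnaNames, pcgNames), 0)
    expect_identical(length(db@rnaNt) + length(db@pcgNt),
                     length(unique(c(rnaNames, pcgNames))))
    expect_setequal(
        c(vapply(db@cdsAaIntronless, geneName, ""),
          vapply(db@cdsAaIntron, geneName, "")), pcgNames)
})

test_that("translation is verbatim table 11 and CDS entries carry peptides", {
    rec <- .dbToyRecord()
    db <- buildReferenceDb(rec)
    e <- db@cdsAaIntron[[1]]
    expect_identical(e@exonLengths, c(9L, 291L))
    expect_identical(nchar(e@aaSequence), 99L)
    nt <- e@ntSequence
    expect_identical(paste0(e@aaSequence, "*"), oracleTranslate(nt))
    ## per-exon peptides: exon1 keeps its 3 full codons
    expect_identical(e@aaExons[1], oracleTranslate(substr(nt, 1, 9)))

    expect_identical(translateCds("GTGGCTTAA"), "VA")    # no initiator forcing
    expect_identical(translateCds("ATGGCTTAA"), "MA")
    expect_error(translateCds("ATGGC"), "multiple of 3")
    ## internal stop retained for downstream pseudogene warnings
    expect_identical(translateCds("ATGTAAGCTTAA"), "M*A")
})

test_that("deduplication collapses IR copies and is idempotent", {
    rec <- .dbToyRecord()
    db1 <- buildReferenceDb(rec)
    db2 <- buildReferenceDb(list(rec, rec))
    expect_identical(length(db2@rnaNt), length(db1@rnaNt))
    expect_identical(length(db2@pcgNt), length(db1@pcgNt))

    ## two identical rRNA features (IR copies) give one entry
    f <- recordFeatures(rec)[[1]]
    rec2 <- rec
    rec2@features <- c(rec@features, list(f))
    expect_length(buildReferenceDb(rec2)@rnaNt, 3)
})

test_that("an empty feature set is a hard error", {
    empty <- new("PlastomeRecord", recordId = "e",
                 sequence = Biostrings::DNAString("ACGTACGT"),
                 features = list(), parseIssues = character(0))
    expect_error(buildReferenceDb(empty), "no annotatable features")
})

test_that("reference CDS with an internal stop is flagged, not dropped", {
    cds <- paste0("ATG", "TAA", "GCTGCT", "TAA")   # internal stop
    rec <- new("PlastomeRecord", recordId = "p",
               sequence = Biostrings::DNAString(
                   paste0(oracleRandSeq(20, 5), cds, oracleRandSeq(20, 6))),
               features = list(new("GeneFeature", geneName = "pseudo",
                   kind = "CDS",
                   location = FeatureLocation(20, 20 + nchar(cds), "+"),
                   qualifiers = list(gene = "pseudo"))),
               parseIssues = character(0))
    db <- buildReferenceDb(rec)
    expect_true(any(grepl("internal stop", db@pcgNt[[1]]@warnings)))
})
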
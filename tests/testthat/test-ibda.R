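.cods <- function(...) paste0(c(...), collapse = "")

test_that("inter-HSP classification follows the stop and mod-3 rules", {
    ## in-frame stop between the HSPs: intron present
    cs <- paste0(oracleRandSeq(30, 71), .cods("GCT", "TAG", "GCT"),
                 oracleRandSeq(30, 72))
    expect_identical(classifyInterHsp(cs, 30L, 39L), "intron_present")

    ## zero-length region: intron lost
    expect_identical(classifyInterHsp(cs, 30L, 30L), "intron_lost")

    ## 47 nt (not a multiple of three), no stop needed: intron present
    stopFree <- paste(rep("C", 47), collapse = "")
    cs2 <- paste0(oracleRandSeq(30, 73), stopFree, oracleRandSeq(30, 74))
    expect_identical(classifyInterHsp(cs2, 30L, 77L), "intron_present")

    ## multiple of three and stop-free: intron lost
    cs3 <- paste0(oracleRandSeq(30, 75), strrep("CAA", 5),
                  oracleRandSeq(30, 76))
    expect_identical(classifyInterHsp(cs3, 30L, 45L), "intron_lost")
})

## build a two-exon CDS planted in background with a stop-rich intron;
## returns coding-strand string plus the block-local truth
.intronGeneCase <- function(seed, len1 = NULL, ilen = NULL) {
    set.seed(seed)
    nAa <- sample(60:120, 1)
    pool <- setdiff(names(Biostrings::getGeneticCode("11")),
                    c("TAA", "TAG", "TGA"))
    cds <- paste0(c("ATG", sample(pool, nAa - 1, replace = TRUE), "TAA"),
                  collapse = "")
    if (is.null(len1)) len1 <- sample(40:(nchar(cds) - 60), 1)
    if (is.null(ilen)) ilen <- sample(70:160, 1)
    intron <- oracleRandSeq(ilen, seed + 1)
    r1 <- len1 %% 3
    ## plant an in-frame (HSP1 frame) stop mid-intron
    h1eLocal <- len1 - r1
    p <- h1eLocal + 3 * (((len1 + ilen %/% 2) - h1eLocal) %/% 3)
    substr(intron, p - len1 + 1, p - len1 + 3) <- "TAA"
    up <- oracleRandSeq(90, seed + 2)
    dn <- oracleRandSeq(60, seed + 3)
    cs <- paste0(up, substr(cds, 1, len1), intron,
                 substr(cds, len1 + 1, nchar(cds)), dn)
    list(cs = cs, geneStart = 90L, len1 = as.integer(len1),
         ilen = as.integer(ilen), lenTot = nchar(cds),
         cds = cds)
}

test_that("intron boundaries come from the probe search plus split-codon shift", {
    for (seed in c(81, 82, 83)) {
        g <- .intronGeneCase(seed)
        r1 <- g$len1 %% 3L
        carry <- (3L - r1) %% 3L
        h1e <- g$geneStart + g$len1 - r1
        x2 <- g$geneStart + g$len1 + g$ilen          # true exon2 start
        h2s <- x2 + carry
        len2 <- g$lenTot - g$len1
        ex1aa <- oracleTranslate(substr(g$cds, 1, g$len1 - r1))
        ex2aa <- oracleTranslate(substr(g$cds, g$len1 + carry + 1,
                                        g$lenTot - 3))
        expect_identical(classifyInterHsp(g$cs, h1e, h2s), "intron_present")
        b <- locatePcgIntronBoundaries(g$cs, h1e, h2s, ex1aa, ex2aa,
                                       g$len1, len2)
        expect_identical(b$splitCodonNt, len2 %% 3L)
        expect_identical(b$exon1End, g$geneStart + g$len1)
        expect_identical(b$exon2Start, x2)
        expect_identical(b$strategy, "probe")
    }
})

test_that("the probe shift bookkeeping matches the VAVG/VNVGFR worked example", {
    ## reference exon2 begins VAVGFR; the target region translates VNVGFR:
    ## two shifts, then the first codon of exon2 is the first V
    ex2aa <- "VAVGFRLLSE"
    exon2 <- .cods("GTT", "AAT", "GTA", "GGT", "TTT", "CGT",
                   "CTT", "CTT", "AGC", "GAA", "TAA")
    cs <- paste0(oracleRandSeq(32, 84), "TAA", exon2)
    b <- locatePcgIntronBoundaries(cs, 12L, 35L, "XXXX", ex2aa,
                                   refExon1LenNt = 30L,
                                   refExon2LenNt = 31L)
    ## split = 31 mod 3 = 1: boundary one nt left of the located first codon
    expect_identical(b$splitCodonNt, 1L)
    expect_identical(b$exon2Start, 35L - 1L)
})

test_that("probe failure falls back to the HSP2 end with a warning", {
    g <- .intronGeneCase(85)
    r1 <- g$len1 %% 3L
    carry <- (3L - r1) %% 3L
    h1e <- g$geneStart + g$len1 - r1
    h2s <- g$geneStart + g$len1 + g$ilen + carry
    len2 <- g$lenTot - g$len1
    b <- locatePcgIntronBoundaries(g$cs, h1e, h2s, "WWWW", "WWWW",
                                   g$len1, len2)
    expect_identical(b$strategy, "fallback_b")
    expect_identical(b$exon2Start, h2s - len2 %% 3L)
    expect_true(any(grepl("verify manually", b$warnings)))
})

test_that("split-codon arithmetic agrees with the brute-force phase oracle", {
    ## oracle: of the three possible exon2 phase shifts, exactly one yields
    ## a stop-free joined open reading frame; it must equal len(exon2) mod 3
    agree <- 0L; n <- 0L
    for (seed in 101:155) {
        g <- .intronGeneCase(seed)
        len2 <- g$lenTot - g$len1
        x2 <- g$geneStart + g$len1 + g$ilen
        firstCodon <- x2 + (len2 %% 3L)
        valid <- integer(0)
        for (delta in 0:2) {
            s2 <- firstCodon - delta
            joined <- paste0(substr(g$cs, g$geneStart + 1,
                                    g$geneStart + g$len1),
                             substr(g$cs, s2 + 1,
                                    s2 + (len2 - (len2 %% 3L)) + delta))
            if (nchar(joined) %% 3 != 0) next
            aa <- oracleTranslate(joined)
            if (!grepl("\\*", substr(aa, 1, nchar(aa) - 1))) valid <- c(valid, delta)
        }
        n <- n + 1L
        if (length(valid) == 1L && valid == len2 %% 3L) agree <- agree + 1L
    }
    expect_identical(agree, n)
    expect_gte(n, 50L)
})

test_that("tRNA intron boundaries: identity, substitution tolerance, loss", {
    set.seed(91)
    ex1 <- oracleRandSeq(36, 92); ex2 <- oracleRandSeq(38, 93)
    intron <- oracleRandSeq(80, 94)
    up <- oracleRandSeq(60, 95); dn <- oracleRandSeq(60, 96)
    cs <- paste0(up, ex1, intron, ex2, dn)
    h1 <- list(sStart = 60L, sEnd = 96L, qStart = 0L, qEnd = 36L)
    h2 <- list(sStart = 176L, sEnd = 214L, qStart = 36L, qEnd = 74L)
    r <- locateTrnaIntronBoundaries(cs, h1, h2, ex1, ex2)
    expect_identical(r$status, "intron_present")
    expect_identical(r$segments[[1]], c(60L, 96L))
    expect_identical(r$segments[[2]], c(176L, 214L))

    ## one substitution at the exon2 5' terminus: offset probes recover it
    csv <- strsplit(cs, "")[[1]]
    csv[177] <- setdiff(c("A", "C", "G", "T"), csv[177])[1]
    r2 <- locateTrnaIntronBoundaries(paste(csv, collapse = ""), h1, h2,
                                     ex1, ex2)
    expect_identical(r2$segments[[2]][1], 176L)

    ## intron deleted: single feature via the zero-gap rule
    csLost <- paste0(up, ex1, ex2, dn)
    h2l <- list(sStart = 96L, sEnd = 134L, qStart = 36L, qEnd = 74L)
    r3 <- locateTrnaIntronBoundaries(csLost,
        list(sStart = 60L, sEnd = 96L, qStart = 0L, qEnd = 36L),
        h2l, ex1, ex2)
    expect_identical(r3$status, "intron_lost")
    expect_length(r3$segments, 1)
    expect_identical(r3$segments[[1]], c(60L, 134L))
})
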
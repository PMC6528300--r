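.ntEntry <- function(name, seq, src = "ref") {
    new("ReferenceGeneEntry", geneName = name, category = "tRNA",
        ntSequence = seq, exonLengths = nchar(seq), hasIntron = FALSE,
        aaSequence = "", aaExons = character(0), sourceRecord = src,
        warnings = character(0))
}
.aaEntry <- function(name, nt, src = "ref") {
    new("ReferenceGeneEntry", geneName = name, category = "PCG",
        ntSequence = nt, exonLengths = nchar(nt), hasIntron = FALSE,
        aaSequence = translateCds(nt), aaExons = character(0),
        sourceRecord = src, warnings = character(0))
}
.bareTarget <- function(seqStr, id = "t")
    new("PlastomeRecord", recordId = id,
        sequence = Biostrings::DNAString(seqStr), features = list(),
        parseIssues = character(0))

test_that("nucleotide search finds planted queries on both strands", {
    bg <- oracleRandSeq(3000, 21)
    q <- oracleRandSeq(120, 22)
    seqStr <- paste0(substr(bg, 1, 1000), q, substr(bg, 1001, 3000))
    tgt <- .bareTarget(seqStr)
    h <- searchNucleotide(list(.ntEntry("g", q)), tgt)
    expect_identical(nrow(h), 1L)
    expect_identical(c(h$sStart, h$sEnd), c(1000L, 1120L))
    expect_identical(h$strand, "+")
    expect_equal(h$identity, 100)

    ## reverse-complemented occurrence: same span, reverse strand
    seqRc <- paste0(substr(bg, 1, 1000), oracleRevcomp(q),
                    substr(bg, 1001, 3000))
    h2 <- searchNucleotide(list(.ntEntry("g", q)), .bareTarget(seqRc))
    expect_identical(c(h2$sStart, h2$sEnd), c(1000L, 1120L))
    expect_identical(h2$strand, "-")
})

test_that("substitutions lower identity as the mismatch count dictates", {
    bg <- oracleRandSeq(2000, 31)
    q <- oracleRandSeq(100, 32)
    qv <- strsplit(q, "")[[1]]
    mut <- qv
    set.seed(33)
    at <- sample(100, 5)
    for (i in at) mut[i] <- setdiff(c("A", "C", "G", "T"), mut[i])[1]
    seqStr <- paste0(substr(bg, 1, 700), paste(mut, collapse = ""),
                     substr(bg, 701, 2000))
    h <- searchNucleotide(list(.ntEntry("g", q)), .bareTarget(seqStr))
    expect_identical(nrow(h), 1L)
    expect_equal(h$identity, 95)
    expect_identical(c(h$sStart, h$sEnd), c(700L, 800L))
})

test_that("protein search records frame and maps reverse hits to the forward axis", {
    set.seed(40)
    pool <- setdiff(names(Biostrings::getGeneticCode("11")),
                    c("TAA", "TAG", "TGA"))
    nt <- paste0(c("ATG", sample(pool, 60, replace = TRUE), "TAA"),
                 collapse = "")
    entry <- .aaEntry("p", nt)
    bg <- oracleRandSeq(4000, 41)
    for (off in 0:2) {
        seqStr <- paste0(substr(bg, 1, 1500 + off), nt,
                         substr(bg, 1501, 4000))
        h <- searchProtein(list(entry), .bareTarget(seqStr))
        expect_identical(nrow(h), 1L)
        expect_identical(h$frame, (1500L + off) %% 3L)
        expect_identical(h$sStart, 1500L + off)
        ## the aa hit excludes the stop codon
        expect_identical(h$sEnd, 1500L + off + nchar(nt) - 3L)
    }
    ## reverse strand: construct by reverse-complementing the forward case
    seqStr <- paste0(substr(bg, 1, 1500), nt, substr(bg, 1501, 4000))
    rcStr <- oracleRevcomp(seqStr)
    h <- searchProtein(list(entry), .bareTarget(rcStr))
    L <- nchar(rcStr)
    expect_identical(h$strand, "-")
    expect_identical(h$sStart, L - (1500L + nchar(nt) - 3L))
    expect_identical(h$sEnd, L - 1500L)
})

test_that("coordinate sanity: extracting the reported interval reproduces the query", {
    res <- cachedAnnotation(301)
    db <- res$db; tgt <- readTargetFasta(res$fx$targetPath)
    hs <- searchProtein(db@cdsAaIntronless, tgt)
    seqStr <- as.character(recordSequence(tgt))
    for (i in seq_len(nrow(hs))) {
        sub <- substr(seqStr, hs$sStart[i] + 1, hs$sEnd[i])
        if (hs$strand[i] == "-") sub <- oracleRevcomp(sub)
        aa <- oracleTranslate(sub)
        q <- db@cdsAaIntronless[[
            which(vapply(db@cdsAaIntronless, geneName, "") ==
                  hs$geneName[i])]]@aaSequence
        q <- substr(q, hs$qStart[i] + 1, hs$qEnd[i])
        m <- sum(strsplit(aa, "")[[1]] == strsplit(q, "")[[1]])
        expect_gte(100 * m / nchar(q), hs$identity[i] - 5)
    }
})

test_that("best-hit selection keeps only the highest-identity reference", {
    bg <- oracleRandSeq(3000, 51)
    q <- oracleRandSeq(150, 52)
    qv <- strsplit(q, "")[[1]]
    near <- qv; set.seed(53)
    for (i in sample(150, 3)) near[i] <- setdiff(c("A","C","G","T"), near[i])[1]
    far <- qv
    for (i in sample(150, 14)) far[i] <- setdiff(c("A","C","G","T"), far[i])[1]
    seqStr <- paste0(substr(bg, 1, 800), q, substr(bg, 801, 3000))
    tgt <- .bareTarget(seqStr)
    h <- searchNucleotide(list(.ntEntry("g", paste(near, collapse = ""), "refA"),
                               .ntEntry("g", paste(far, collapse = ""), "refB")),
                          tgt)
    sel <- selectBestHits(h)
    expect_length(sel$g, 1)
    expect_true(all(grepl("refA", sel$g[[1]]$entryId)))
})

test_that("IR-duplicated genes yield two clusters with mirrored strands", {
    res <- cachedAnnotation(302)
    db <- res$db; tgt <- readTargetFasta(res$fx$targetPath)
    h <- searchNucleotide(db@rnaNt, tgt)
    sel <- selectBestHits(h)
    rrn <- sel[["rrn16"]]
    expect_length(rrn, 2)
    expect_setequal(vapply(rrn, function(cl) cl$strand[1], ""), c("+", "-"))
    ## a single HSP forms a cluster of one
    single <- Filter(function(cls) length(cls) == 1 && nrow(cls[[1]]) == 1, sel)
    expect_gt(length(single), 0)
})

test_that("builtin and external backends agree on fixtures (Jaccard >= 0.9)", {
    res <- cachedAnnotation(303, divergence = 0.05)
    db <- res$db; tgt <- readTargetFasta(res$fx$targetPath)
    run <- function(be) {
        cfg <- searchConfig(backend = be)
        h <- rbind(searchNucleotide(db@rnaNt, tgt, cfg),
                   searchProtein(c(db@cdsAaIntronless, db@cdsAaIntron),
                                 tgt, cfg))
        selectBestHits(h, cfg)
    }
    sb <- run("builtin"); se <- run("external")
    expect_setequal(names(se), names(sb))
    for (g in names(se)) {
        ## same winning reference entry
        expect_identical(se[[g]][[1]]$entryId[1], sb[[g]][[1]]$entryId[1])
        ## every external HSP overlaps a builtin HSP at Jaccard >= 0.9
        eb <- do.call(rbind, sb[[g]])
        for (cl in se[[g]]) for (i in seq_len(nrow(cl))) {
            jac <- max(vapply(seq_len(nrow(eb)), function(k) {
                ov <- min(cl$sEnd[i], eb$sEnd[k]) -
                      max(cl$sStart[i], eb$sStart[k])
                un <- max(cl$sEnd[i], eb$sEnd[k]) -
                      min(cl$sStart[i], eb$sStart[k])
                if (ov <= 0) 0 else ov / un
            }, 0))
            expect_gte(jac, 0.9)
        }
    }
})

test_that("the search config rejects inconsistent coverage bounds", {
    expect_error(searchConfig(qcovMin = 2, qcovMax = 0.5), "smaller")
})
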
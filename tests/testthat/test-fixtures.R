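test_that("generated references always pass validation", {
    for (seed in 331:334) {
        fx <- generateFixture(fixtureSpec(seed = seed,
            perturbations = "short_exon1_gene"), dir = tempfile())
        rec <- parseGenBank(fx$referencePath)
        expect_length(validateReference(rec), 0)
    }
})

test_that("a fixed seed reproduces byte-identical fixture files", {
    spec <- fixtureSpec(seed = 335, divergence = 0.02,
                        perturbations = "intron_loss")
    a <- generateFixture(spec, dir = tempfile())
    b <- generateFixture(spec, dir = tempfile())
    expect_identical(readLines(a$referencePath), readLines(b$referencePath))
    expect_identical(readLines(a$targetPath), readLines(b$targetPath))
    expect_identical(a$truth, b$truth)
})

test_that("divergence 0 with no perturbations gives target == reference", {
    fx <- generateFixture(fixtureSpec(seed = 336), dir = tempfile())
    expect_identical(as.character(recordSequence(fx$targetRecord)),
                     as.character(recordSequence(fx$referenceRecord)))
})

test_that("each perturbation maps to its expected outcome class", {
    fx <- generateFixture(fixtureSpec(seed = 337,
        perturbations = c("intron_loss", "start_non_atg", "delete_gene")),
        dir = tempfile())
    t <- fx$truth
    expect_identical(t$intronStatus[t$perturbed == "intron_loss"],
                     "intron_lost")
    expect_identical(t$expectedWarning[t$perturbed == "start_non_atg"],
                     "non_atg_start")
    expect_identical(t$startCodon[t$perturbed == "start_non_atg"], "ACG")
    expect_identical(t$expectedOutcome[t$perturbed == "delete_gene"],
                     "missing")
    ## the deleted gene's sequence really is gone
    expect_lt(length(recordSequence(fx$targetRecord)),
              length(recordSequence(fx$referenceRecord)))
})

test_that("frameshift_stop_free introns exercise the mod-3 criterion alone", {
    fx <- generateFixture(fixtureSpec(seed = 338,
        intronMode = "frameshift_stop_free"), dir = tempfile())
    rec <- fx$referenceRecord
    seqStr <- as.character(recordSequence(rec))
    cds <- Filter(function(f) f@kind == "CDS" &&
                  length(locStarts(f@location)) == 2, recordFeatures(rec))
    expect_gt(length(cds), 0)
    for (f in cds) {
        segs <- sort(c(locStarts(f@location), locEnds(f@location)))
        ilen <- segs[3] - segs[2]
        expect_true(ilen %% 3 != 0)
    }
    ## the pipeline still classifies these introns as present
    db <- buildReferenceDb(parseGenBank(fx$referencePath))
    res <- annotateTarget(db, readTargetFasta(fx$targetPath))
    sc <- scoreAgainstTruth(res$annotations, fx$truth)
    expect_identical(sc$CG, sc$nTruth)
})

test_that("intron-loss detection never fires on intact introns", {
    ## seeded suite: stop-rich and frame-shifted introns, both modes
    for (seed in 341:346) {
        mode <- if (seed %% 2) "stop_rich" else "frameshift_stop_free"
        fx <- generateFixture(fixtureSpec(seed = seed, intronMode = mode),
                              dir = tempfile())
        db <- buildReferenceDb(parseGenBank(fx$referencePath))
        res <- annotateTarget(db, readTargetFasta(fx$targetPath))
        lost <- Filter(function(a) a@intronStatus == "intron_lost",
                       res$annotations)
        expect_length(lost, 0)
    }
})

test_that("scoring distinguishes exact, shifted and spurious annotations", {
    res <- cachedAnnotation(347)
    anns <- res$res$annotations
    truth <- res$fx$truth
    base <- scoreAgainstTruth(anns, truth)
    expect_identical(base$WGB, 0L)

    ## shift one boundary by 3 nt: exactly one WGB appears
    shifted <- anns
    a <- shifted[[1]]
    loc <- annotationLocation(a)
    a@location <- FeatureLocation(locStarts(loc) + c(3L,
        rep(0L, length(locStarts(loc)) - 1L)), locEnds(loc), locStrand(loc))
    shifted[[1]] <- a
    sc <- scoreAgainstTruth(shifted, truth)
    expect_identical(sc$WGB, 1L)
    expect_identical(sc$CG, base$CG - 1L)

    ## a spurious annotation for an absent gene: one WG
    fake <- new("GeneAnnotation", geneName = "ghost", category = "PCG",
        copyIndex = 1L, location = FeatureLocation(5, 50, "+"),
        startStrategy = "a", startCodon = "ATG", intronStatus = "none",
        warnings = character(0), sourceReference = "r", coverage = 1)
    sc2 <- scoreAgainstTruth(c(anns, list(fake)), truth)
    expect_identical(sc2$WG, 1L)
})

test_that("incompatible fixture specs raise spec errors", {
    expect_error(fixtureSpec(seed = 1, divergence = 0.9), "divergence")
    expect_error(fixtureSpec(seed = 1, perturbations = "no_such"),
                 "unknown perturbation")
    expect_error(generateFixture(fixtureSpec(seed = 1, irLength = 400),
                                 dir = tempfile()),
                 "too small")
})
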
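test_that("delta-C is modified minus canonical counterpart", {
    cm <- toyCanonical()
    em <- expandAlphabet(cm, cScheme(), stdvIncrement = 0)
    e <- modelEntries(em)
    e$level_mean[e$kmer == "AMA"] <- e$level_mean[e$kmer == "ACA"] - 7
    mm <- KmerModel(e)
    d <- computeDelta(cm, mm, cScheme(), "AMA")
    expect_equal(deltaRecords(d)$delta, -7)
    expect_identical(deltaRecords(d)$mod_position, 2L)
})

test_that("an expand-only modified table yields all-zero deltas", {
    cm <- simulateCanonicalModel(4L, seed = 9L)
    em <- expandAlphabet(cm, cpgScheme())
    d <- computeDelta(cm, em, cpgScheme())
    expect_identical(nrow(deltaRecords(d)), 48L)  # (4-2+1) * 4^2
    expect_true(all(deltaRecords(d)$delta == 0))
})

test_that("deltas of a forward-applied model equal the summed shifts", {
    tr <- simulateTruth(cpgScheme(), k = 4L, nPatternRules = 5L, seed = 21L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr), cpgScheme())
    rec <- deltaRecords(d)
    expected <- vapply(rec$kmer, bruteForceDelta, numeric(1L),
                       rules = truthRules(tr))
    expect_equal(rec$delta, unname(expected))
})

test_that("multi-modification and incomplete-motif k-mers are skipped", {
    cm <- simulateCanonicalModel(4L, seed = 9L)
    em <- expandAlphabet(cm, cpgScheme(), includeIncomplete = TRUE,
                         includeMulti = TRUE)
    expect_warning(
        d <- computeDelta(cm, em, cpgScheme(),
                          c("AMGA", "MGMG", "AAAM")),
        "skipping 2")
    expect_identical(deltaRecords(d)$kmer, "AMGA")
    expect_error(computeDelta(cm, em, cpgScheme(), "TMGT_missing"),
                 "absent")
})

test_that("the toy walkthrough derives position -4 then A-at-1 = -2", {
    rules <- deriveRules(toyDelta(), r = 0.01)
    rl <- ruleTable(rules)
    expect_identical(rl$kind[1L], "position")
    expect_equal(rl$shift[1L], -4)
    # medians of an even-sized group average the central pair:
    # (-3 + -1) / 2 = -2 for A at position 1
    expect_identical(rl$kind[2L], "pattern")
    expect_identical(rl$pattern_position[2L], 1L)
    expect_identical(rl$pattern_base[2L], "A")
    expect_equal(rl$shift[2L], -2)
})

test_that("constant deltas give one position rule per position, no patterns", {
    kmers <- enumerateModifiedKmers(4, cpgScheme())
    pos <- vapply(gregexpr("M", kmers, fixed = TRUE),
                  function(x) x[[1L]], integer(1L))
    d <- DeltaTable(data.frame(kmer = kmers, mod_position = pos,
                               delta = 3.5), cpgScheme(), 4L)
    rules <- deriveRules(d)
    rl <- ruleTable(rules)
    expect_identical(unique(rl$kind), "position")
    expect_identical(rl$mod_position, 1:3)
    expect_equal(rl$shift, rep(3.5, 3L))
})

test_that("identifiable synthetic rule sets are recovered shift-for-shift", {
    for (s in c(4L, 14L)) {
        tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 10L,
                            distinctPositions = TRUE, seed = s)
        d <- computeDelta(truthCanonical(tr), truthModified(tr), cpgScheme(),
                          trainedKmers(tr))
        rec <- ruleRecovery(truthRules(tr), deriveRules(d, r = 0.01))
        expect_identical(nrow(rec$only_truth), 0L)
        expect_identical(nrow(rec$only_derived), 0L)
        expect_lt(max(rec$matched$abs_error), 0.01)
    }
})

test_that("derivation leaves no candidate median above the threshold", {
    tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 25L,
                        noiseSd = 0.3, seed = 8L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr, noisy = TRUE),
                      cpgScheme())
    rules <- deriveRules(d, r = 0.01)
    scan <- ruleResidualScan(d, rules)
    expect_true(all(scan$max_abs_median <= 0.01))
})

test_that("record order does not change the derived rules", {
    tr <- simulateTruth(cpgScheme(), k = 4L, nPatternRules = 6L,
                        noiseSd = 0.1, seed = 3L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr, noisy = TRUE),
                      cpgScheme())
    r1 <- deriveRules(d)
    rec <- deltaRecords(d)
    set.seed(1)
    d2 <- DeltaTable(rec[sample.int(nrow(rec)), ], cpgScheme(), 4L)
    r2 <- deriveRules(d2)
    expect_equal(ruleTable(r2), ruleTable(r1))
})

test_that("adding a constant to one position shifts only its position rule", {
    tr <- simulateTruth(cpgScheme(), k = 4L, nPatternRules = 6L,
                        noiseSd = 0.1, seed = 31L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr, noisy = TRUE),
                      cpgScheme())
    r1 <- ruleTable(deriveRules(d))
    rec <- deltaRecords(d)
    rec$delta[rec$mod_position == 2L] <- rec$delta[rec$mod_position == 2L] + 5
    r2 <- ruleTable(deriveRules(DeltaTable(rec, cpgScheme(), 4L)))
    p1 <- r1$kind == "position" & r1$mod_position == 2L
    p2 <- r2$kind == "position" & r2$mod_position == 2L
    expect_equal(r2$shift[p2], r1$shift[p1] + 5)
    expect_equal(r2[!p2, c("kind", "pattern_position", "pattern_base",
                           "shift")],
                 r1[!p1, c("kind", "pattern_position", "pattern_base",
                           "shift")])
})

test_that("re-deriving from a rule-reconstructed table is idempotent", {
    # identifiable configuration: the decomposition itself is stable
    tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 9L,
                        distinctPositions = TRUE, seed = 12L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr), cpgScheme())
    r1 <- deriveRules(d)
    rebuilt <- forwardApply(truthCanonical(tr), r1)
    d2 <- computeDelta(truthCanonical(tr), rebuilt, cpgScheme(),
                       deltaRecords(d)$kmer)
    r2 <- deriveRules(d2)
    rec <- ruleRecovery(r1, r2)
    expect_identical(nrow(rec$only_truth), 0L)
    expect_lte(max(rec$matched$abs_error), 0.01)
    # overlapping-group rule sets: the decomposition is not unique, but the
    # reconstructed table re-derives to the same fitted function
    trn <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 20L,
                         noiseSd = 0.2, seed = 12L)
    dn <- computeDelta(truthCanonical(trn), truthModified(trn, noisy = TRUE),
                       cpgScheme())
    rn1 <- deriveRules(dn)
    rebuilt_n <- forwardApply(truthCanonical(trn), rn1)
    rn2 <- deriveRules(computeDelta(truthCanonical(trn), rebuilt_n,
                                    cpgScheme(), deltaRecords(dn)$kmer))
    f1 <- imputeModel(truthCanonical(trn), rn1, mode = "full")
    f2 <- imputeModel(truthCanonical(trn), rn2, mode = "full")
    mods <- modifiedKmers(f1)
    expect_lt(max(abs(levelMeans(f1, mods) - levelMeans(f2, mods))),
              6 * 0.01)
})

test_that("imputing the toy 3-mer adds the applicable rules to ACT = 11", {
    imp <- imputeModel(toyCanonical(), toyRules(), mode = "full")
    expect_equal(unname(levelMeans(imp, "AMT")), 6)  # 11 - 4 - 2 + 1
    # rules that do not apply stay out: GMG gets only the position rule
    expect_equal(unname(levelMeans(imp, "GMG")),
                 unname(levelMeans(toyCanonical(), "GCG")) - 4)
})

test_that("an empty rule set imputes canonical values everywhere", {
    cm <- simulateCanonicalModel(4L, seed = 6L)
    empty <- RuleSet(data.frame(order = integer(0),
                                mod_position = integer(0),
                                kind = character(0),
                                pattern_position = integer(0),
                                pattern_base = character(0),
                                shift = numeric(0)), cpgScheme(), 4L)
    imp <- imputeModel(cm, empty, mode = "full")
    mods <- modifiedKmers(imp)
    expect_equal(unname(levelMeans(imp, mods)),
                 unname(levelMeans(cm, canonicalizeKmers(mods, cpgScheme()))))
})

test_that("missing mode copies trained entries and imputes the rest", {
    tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 6L,
                        noiseSd = 0.4, trainedFraction = 0.3, seed = 17L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr, noisy = TRUE),
                      cpgScheme(), trainedKmers(tr))
    rules <- deriveRules(d)
    full <- imputeModel(truthCanonical(tr), rules, mode = "full")
    miss <- imputeModel(truthCanonical(tr), rules, mode = "missing",
                        trainedModel = truthModified(tr, noisy = TRUE),
                        trained = trainedKmers(tr))
    trained <- trainedKmers(tr)
    rest <- setdiff(modifiedKmers(full), trained)
    # trained entries bit-identical to the trained model
    expect_identical(levelMeans(miss, trained),
                     levelMeans(truthModified(tr, noisy = TRUE), trained))
    # everything else equals the fully-imputed output
    expect_identical(levelMeans(miss, rest), levelMeans(full, rest))
    expect_error(imputeModel(truthCanonical(tr), rules, mode = "missing"),
                 "requires")
})

test_that("multi-modification imputation sums per-position contributions", {
    cm <- simulateCanonicalModel(4L, seed = 13L)
    rules <- simulateRuleSet(cpgScheme(), 4L, nPatternRules = 5L, seed = 2L)
    imp <- imputeModel(cm, rules, mode = "full", includeMulti = TRUE)
    expect_true("MGMG" %in% modelKmers(imp))
    expect_equal(unname(levelMeans(imp, "MGMG")),
                 unname(levelMeans(cm, "CGCG")) +
                     bruteForceDelta("MGMG", rules))
    # a position holding M never matches a canonical-base pattern (checked
    # inside bruteForceDelta by matching the k-mer as written)
    fa <- forwardApply(cm, rules, includeMulti = TRUE)
    expect_equal(levelMeans(imp), levelMeans(fa))
})

test_that("k mismatch between rules and canonical model is rejected", {
    cm <- simulateCanonicalModel(4L, seed = 1L)
    rules <- simulateRuleSet(cpgScheme(), 6L, nPatternRules = 2L, seed = 1L)
    expect_error(imputeModel(cm, rules), "incompatible")
})

test_that("rule TSV round-trips and renders documented pattern strings", {
    rules <- RuleSet(data.frame(
        order = 1:3, mod_position = c(4L, 4L, 1L),
        kind = c("position", "pattern", "position"),
        pattern_position = c(NA, 3L, NA),
        pattern_base = c(NA, "T", NA),
        shift = c(-2.33, -4.10, -0.85)), cpgScheme(), 6L)
    ps <- patternStrings(rules)
    expect_identical(ps[2L], "NNTMGN")
    expect_identical(ps[3L], "MGNNNN")
    path <- tempfile(fileext = ".tsv")
    writeRules(rules, path)
    back <- readRules(path)
    expect_equal(ruleTable(back), ruleTable(rules))
    expect_identical(motif(back@scheme), "CG")
    expect_identical(back@k, 6L)
})

test_that("malformed pattern strings are rejected on read", {
    path <- tempfile()
    writeLines(c("#k=6", "#motif=CG", "#mod_offset=0", "#mod_code=M",
                 "order\tkind\tpattern\tshift",
                 "1\tpattern\tNNTTGN\t-4.1"), path)
    expect_error(readRules(path), "modification code")
    writeLines(c("#k=6", "#motif=CG", "#mod_offset=0", "#mod_code=M",
                 "order\tkind\tpattern\tshift",
                 "1\tpattern\tNATMGN\t-4.1"), path)
    expect_error(readRules(path), "more than one pattern base")
})

test_that("per-position summaries equal derived position-rule shifts", {
    tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 12L,
                        noiseSd = 0.25, seed = 19L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr, noisy = TRUE),
                      cpgScheme())
    s <- summarizeByPosition(d)
    expect_identical(s$mod_position, 1:5)
    expect_identical(sum(s$count), 1280L)
    rl <- ruleTable(deriveRules(d))
    expect_equal(s$median, rl$shift[rl$kind == "position"])
    # constant table: every median is the constant
    rec <- deltaRecords(d)
    rec$delta <- -1.25
    expect_true(all(summarizeByPosition(
        DeltaTable(rec, cpgScheme(), 6L))$median == -1.25))
})

test_that("noise-free position shifts are recovered exactly", {
    tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 0L, seed = 23L)
    d <- computeDelta(truthCanonical(tr), truthModified(tr), cpgScheme())
    s <- summarizeByPosition(d)
    truth <- ruleTable(truthRules(tr))
    expect_equal(s$median, truth$shift[truth$kind == "position"])
})

test_that("recovered shifts track the noise floor on site-based holdouts", {
    g <- simulateGenome(30000, seed = 77L)
    sel <- selectTrainingSites(g, cpgScheme(), 6L, 0.25, seed = 5L)
    trained <- coveredKmers(sel)
    maes <- sapply(c(0.1, 0.5), function(noise_sd) {
        mean(sapply(1:6, function(s) {
            tr <- simulateTruth(cpgScheme(), k = 6L, nPatternRules = 8L,
                                distinctPositions = TRUE, noiseSd = noise_sd,
                                seed = s)
            d <- computeDelta(truthCanonical(tr),
                              truthModified(tr, noisy = TRUE),
                              cpgScheme(), trained)
            rec <- ruleRecovery(truthRules(tr), deriveRules(d))
            mean(rec$matched$abs_error)
        }))
    })
    expect_lt(maes[1L], 0.1)
    expect_lt(maes[2L], 0.5)
    # and the error shrinks as the noise does
    expect_lt(maes[1L], maes[2L])
})
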
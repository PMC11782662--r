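test_that("link classification follows the positional definitions", {
    expect_equal(classifyLink(207, 207), "selflink")
    expect_equal(classifyLink(79, 338), "crosslink")
    expect_equal(classifyLink(150, NA), "monolink")
    expect_equal(classifyLink(420, 425, reagent = "PDH", zerolink = TRUE),
                 "zerolink")
    # symmetric in the position pair
    expect_equal(classifyLink(338, 79), classifyLink(79, 338))
    expect_equal(condensaxs:::peptideKey(338, 79, "crosslink", "DSS"),
                 condensaxs:::peptideKey(79, 338, "crosslink", "DSS"))
    expect_error(classifyLink(0, 10), "1..440")
    expect_error(classifyLink(10, 441), "1..440")
})

test_that("the DSS filter applies strict score and 2-of-3 replicate rules", {
    rec <- rbind(
        makeIdRecords(10, 50, c(19.9, 19.9, 19.9), "dilute", 1:3),
        makeIdRecords(11, 51, 25, "dilute", 2),
        makeIdRecords(12, 52, c(21, 21), "dilute", c(1, 3)),
        makeIdRecords(13, 53, c(20.0, 30), "dilute", c(1, 2)))
    out <- filterQualitativeDSS(rec)
    expect_false(any(out$posA == 10))   # below threshold in all replicates
    expect_false(any(out$posA == 11))   # one replicate only
    expect_equal(sum(out$posA == 12), 2L)  # 2-of-3 boundary case retained
    expect_false(any(out$posA == 13))   # 20.0 is not > 20; one survivor only
    # idempotence: filtering its own output changes nothing
    expect_identical(out, filterQualitativeDSS(out))
    # record order does not matter
    shuffled <- filterQualitativeDSS(rec[rev(seq_len(nrow(rec))), ])
    expect_setequal(condensaxs:::withKey(shuffled)$key,
                    condensaxs:::withKey(out)$key)
})

test_that("the PDH filter is a conjunction of three strict thresholds", {
    rec <- rbind(
        makeIdRecords(100, 200, 26, "dilute", 1, "PDH", 0.95, 0.01),
        makeIdRecords(101, 201, 26, "dilute", 1, "PDH", 0.85, 0.01),
        makeIdRecords(102, 202, 25, "dilute", 1, "PDH", 0.95, 0.01),
        makeIdRecords(103, 203, 26, "dilute", 1, "PDH", 0.95, 0.05),
        makeIdRecords(104, 204, 26, "dilute", 1, "PDH", NA, 0.01))
    expect_warning(out <- filterQualitativePDH(rec), "missing")
    expect_equal(out$posA, 100)   # only the fully passing record survives
    expect_identical(out, filterQualitativePDH(out))
    empty <- rec[0, ]
    expect_equal(nrow(filterQualitativePDH(empty)), 0L)
})

test_that("domain mapping uses the computed region boundaries", {
    map <- bik1Domains()
    top <- map[map$level == "top", ]
    expect_equal(sum(top$end - top$start + 1), 440)  # tiles the sequence
    rec <- assignDomains(data.frame(posA = c(79, 80, 81, 207, 395),
                                    posB = c(338, NA, NA, 207, 425)))
    expect_equal(rec$regionA, c("CAP-Gly", "CAP-Gly", "L1", "coiled coil",
                                "C-terminal"))
    expect_equal(rec$regionPair[1], "CAP-Gly / coiled coil")
    expect_equal(rec$regionPair[4], "coiled coil / coiled coil")
    # spectral counts aggregate over order-normalised region pairs
    cnt <- domainPairCounts(makeIdRecords(c(79, 338), c(338, 79), 30,
                                          "dilute", 1:2,
                                          spectraCount = c(2L, 5L)))
    expect_equal(cnt$spectra[cnt$regionPair == "CAP-Gly / coiled coil"], 7L)
})

test_that("quantification normalises ten transition areas by the householder", {
    mkpep <- function(id, areas, cond = "pellet", rep_ = 1L) {
        rbind(data.frame(peptideId = id, condition = cond, replicate = rep_,
                         form = "heavy", transition = 1:5, area = areas),
              data.frame(peptideId = id, condition = cond, replicate = rep_,
                         form = "light", transition = 1:5, area = areas))
    }
    hh <- data.frame(peptideId = "MVLEEVQPTFDR", condition = "pellet",
                     replicate = 1L, form = "light", transition = 1L,
                     area = 10)
    tr <- rbind(mkpep("207-207", c(1, 2, 3, 4, 5)), hh)
    ab <- normalizeQuant(tr)
    expect_equal(ab$abundance, 3.0)   # (15 + 15) / 10
    # doubling the householder halves every abundance in that replicate
    hh2 <- hh; hh2$area <- 20
    expect_equal(normalizeQuant(rbind(mkpep("207-207", c(1, 2, 3, 4, 5)),
                                      hh2))$abundance, 1.5)
    # fewer than five transitions per form is an error
    short <- rbind(mkpep("207-207", c(1, 2, 3, 4, 5))[-1, ], hh)
    expect_error(normalizeQuant(short), "fewer than 5")
    # a missing householder names the replicate
    expect_error(normalizeQuant(mkpep("207-207", c(1, 2, 3, 4, 5))),
                 "replicate 1")
})

test_that("differential analysis matches hand-computed fold changes and t", {
    ab <- data.frame(
        peptideId = rep(c("a", "b"), each = 6),
        condition = rep(rep(c("A", "B"), each = 3), 2),
        replicate = rep(1:3, 4),
        abundance = c(2, 4, 6, 1, 2, 3,    # a: exact doubling
                      5, 5, 5, 5, 5, 5))   # b: identical groups
    da <- differentialAnalysis(ab, "A", "B")
    expect_equal(da$log2FC[da$peptideId == "a"], 1)
    expect_false(da$enriched[da$peptideId == "a"])  # threshold is strict
    expect_equal(da$log2FC[da$peptideId == "b"], 0)
    expect_equal(da$pValue[da$peptideId == "b"], 1)
    # pooled-variance Student's t checked against the textbook formula
    a <- c(1, 2, 3); b <- c(2, 4, 6)
    sp2 <- ((2) * var(a) + (2) * var(b)) / 4
    tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    pHand <- 2 * pt(-abs(tHand), df = 4)
    ab2 <- data.frame(peptideId = "x",
                      condition = rep(c("A", "B"), each = 3),
                      replicate = rep(1:3, 2), abundance = c(a, b))
    expect_equal(differentialAnalysis(ab2, "A", "B")$pValue, pHand)
    # Welch variant differs when variances differ
    expect_equal(differentialAnalysis(ab2, "A", "B", varEqual = FALSE)$pValue,
                 t.test(a, b)$p.value)
    expect_true(differentialAnalysis(ab2, "B", "A")$enriched ==
                (log2(mean(b) / mean(a)) > 1))
    # optional multiple-testing adjustment (off by default)
    expect_null(differentialAnalysis(ab, "A", "B")$pAdjusted)
    bh <- differentialAnalysis(ab, "A", "B", pAdjust = "BH")
    expect_equal(bh$pAdjusted, p.adjust(bh$pValue, "BH"))
})

test_that("conformo-specific selection keeps single-condition peptides only", {
    rec <- rbind(
        makeIdRecords(211, 346, 30, "pellet", 1:2),
        makeIdRecords(207, 207, 30, "pellet", 1:2),
        makeIdRecords(207, 207, 30, "dilute", 1:2),
        makeIdRecords(207, 207, 30, "supernatant", 1:2),
        makeIdRecords(207, 207, 30, "phase_separated", 1:2))
    filt <- filterQualitativeDSS(rec)
    cs <- conformoSpecific(filt)
    expect_equal(nrow(cs), 1L)
    expect_equal(cs$posA, 211)
    expect_equal(cs$condition, "pellet")
    empty <- conformoSpecific(filt[0, ])
    expect_equal(nrow(empty), 0L)
})

test_that("category counts sum to the reported total", {
    expect_equal(summarizeCounts(makeIdRecords(1, 2, 30, "x", 1)[0, ]),
        list(crosslinks = 0L, monolinks = 0L, selflinks = 0L,
             zerolinks = 0L, total = 0L))
    rec <- rbind(
        makeIdRecords(c(10, 10), c(50, 50), 30, "pellet", 1:2),  # 1 crosslink
        makeIdRecords(c(20, 30), NA, 30, "pellet", 1),           # 2 monolinks
        makeIdRecords(60, 60, 30, "pellet", 1))                  # 1 selflink
    s <- summarizeCounts(rec, "pellet")
    expect_equal(s$crosslinks, 1L)
    expect_equal(s$monolinks, 2L)
    expect_equal(s$selflinks, 1L)
    expect_equal(s$total, s$crosslinks + s$monolinks + s$selflinks +
                     s$zerolinks)
    # generator-programmed composition is recovered exactly
    links <- data.frame(posA = c(79, 207, 150, 211, 23),
                        posB = c(338, 207, NA, 346, NA),
                        reagent = "DSS")
    presence <- matrix(1, 5, 1, dimnames = list(NULL, "pellet"))
    abundance <- matrix(1, 5, 1, dimnames = list(NULL, "pellet"))
    tabs <- generateXlTables(links, presence, abundance, seed = 3,
                             nReplicates = 3)
    s2 <- summarizeCounts(filterQualitativeDSS(tabs$identifications),
                          "pellet")
    expect_equal(s2$crosslinks, 2L)
    expect_equal(s2$monolinks, 2L)
    expect_equal(s2$selflinks, 1L)
    expect_equal(s2$total, 5L)
})
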
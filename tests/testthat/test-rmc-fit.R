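test_that("chi-squared uses the closed-form optimal scale", {
    p <- scatteringProfile(c(0.01, 0.02, 0.03), c(1, 2, 3))
    r <- chiSquared(c(1, 2, 3), p)
    expect_equal(r$chi2, 0)
    expect_equal(r$scale, 1)
    p3 <- scatteringProfile(c(0.01, 0.02, 0.03), c(3, 6, 9))
    r3 <- chiSquared(c(1, 2, 3), p3)
    expect_equal(r3$chi2, 0, tolerance = 1e-12)
    expect_equal(r3$scale, 3)
    # 3-point worked example validated by an exhaustive scan over the scale
    pex <- scatteringProfile(c(0.01, 0.02, 0.03), c(2, 4, 7),
                             uncertainty = c(1, 1, 1))
    Im <- c(1, 2, 3)
    rex <- chiSquared(Im, pex)
    cs <- seq(0.5, 5, by = 1e-4)
    chiOf <- vapply(cs, function(c0) sum((c0 * Im - c(2, 4, 7))^2), numeric(1))
    expect_equal(rex$scale, cs[which.min(chiOf)], tolerance = 1e-3)
    expect_equal(rex$chi2, min(chiOf), tolerance = 1e-6)
    expect_equal(rex$scale, sum(Im * c(2, 4, 7)) / sum(Im^2))
    expect_error(chiSquared(c(1, 2), p), "grid mismatch")
})

test_that("the fit window is refused below the window resolution", {
    expect_error(fitConfig("blobs", windowSigma = 3000, qMin = 0.0015),
                 "resolution")
    expect_error(fitConfig("model1", windowSigma = 1500, qMin = 0.002),
                 "resolution")
    # the conventional rounded value 0.002 for sigma_w = 3000 is accepted
    expect_s3_class(fitConfig("blobs", windowSigma = 3000, qMin = 0.002),
                    "FitConfig")
    expect_error(fitConfig("blobs", qMin = 0.03, qMax = 0.01), "smaller")
})

test_that("fitBlobs is greedy, monotone and reproducible", {
    truth <- generateRandomWalkStructure(120, 200, seed = 5, sigmaBlob = 40,
        confineRadius = 1500, containerDiameter = 4000)
    qg <- seq(0.002, 0.03, length.out = 20)
    target <- generateDropletProfile(truth, qg, noiseFraction = 0, seed = 5,
        windowSigma = 3000, nOrientations = 100)
    base <- list(nCopies = 120L, containerDiameter = 4000,
                 windowSigma = 3000, qMin = 0.002, qMax = 0.03,
                 nOrientations = 100L, translationStep = 150)
    # zero moves returns the seeded initial configuration with one entry
    f0 <- do.call(fitConfig, c(list("blobs", maxMoves = 0L, seed = 3L), base))
    r0 <- fitBlobs(target, f0)
    expect_length(chi2Trace(r0), 1L)
    expect_equal(nCopies(finalModel(r0)), 120L)
    for (seed in c(3L, 17L)) {
        cfg <- do.call(fitConfig,
                       c(list("blobs", maxMoves = 400L, seed = seed), base))
        r <- fitBlobs(target, cfg)
        expect_true(all(diff(chi2Trace(r)) <= 1e-9))
        expect_equal(r@nAccepted + r@nRejected, 400L)
        cen <- blobCenters(finalModel(r))
        expect_true(all(sqrt(rowSums(cen^2)) <= 2000 * (1 + 1e-9)))
    }
    # identical config and seed: bit-identical trace and structure
    cfg <- do.call(fitConfig, c(list("blobs", maxMoves = 300L, seed = 7L),
                                base))
    ra <- fitBlobs(target, cfg); rb <- fitBlobs(target, cfg)
    expect_identical(chi2Trace(ra), chi2Trace(rb))
    expect_identical(blobCenters(finalModel(ra)),
                     blobCenters(finalModel(rb)))
})

test_that("fitBlobs recovers a known structure at reduced scale", {
    truth <- generateRandomWalkStructure(200, 200, seed = 5, sigmaBlob = 40,
        confineRadius = 2000, containerDiameter = 5000)
    qg <- seq(0.002, 0.03, length.out = 25)
    target <- generateDropletProfile(truth, qg, noiseFraction = 0, seed = 5,
        windowSigma = 3000, nOrientations = 200)
    cfg <- fitConfig("blobs", nCopies = 200, containerDiameter = 5000,
        windowSigma = 3000, qMin = 0.002, qMax = 0.03, nOrientations = 200,
        maxMoves = 4000, translationStep = 150, seed = 9)
    fit <- fitBlobs(target, cfg)
    tr <- chi2Trace(fit)
    expect_lt(tr[length(tr)], 0.1 * tr[1])
})

test_that("copy placement tracks the blob mass distribution", {
    blobs <- generateRandomWalkStructure(200, 300, seed = 6, sigmaBlob = 150,
        confineRadius = 2500, containerDiameter = 6000)
    cfg <- fitConfig("model1", nCopies = 5000, containerDiameter = 6000,
        windowSigma = 1500, qMin = 0.0042, clashChecking = FALSE,
        maxMoves = 0, seed = 13)
    mod <- placeCopiesFromBlobs(blobs, modelGeometry("model1"), cfg)
    expect_equal(nCopies(mod), 5000L)
    pos <- t(vapply(chains(mod), chainCentroid, numeric(3)))
    expect_true(all(sqrt(rowSums(pos^2)) <= 3000 * (1 + 1e-9)))
    cellKey <- function(p) paste(floor(p[, 1] / 500), floor(p[, 2] / 500),
                                 floor(p[, 3] / 500))
    obs <- table(cellKey(pos))
    # reference occupancy from a direct large draw of the same mixture
    cen <- blobCenters(blobs)
    w <- windowWeight(cen, colMeans(cen), 1500)
    ref <- withr::with_seed(77, {
        k <- sample.int(nrow(cen), 2e5, replace = TRUE, prob = w)
        r <- cen[k, ] + matrix(rnorm(6e5), ncol = 3) * 150
        r[sqrt(rowSums(r^2)) <= 3000, ]
    })
    expc <- table(cellKey(ref))
    cells <- union(names(obs), names(expc))
    o <- as.numeric(obs[cells]); o[is.na(o)] <- 0
    e <- as.numeric(expc[cells]); e[is.na(e)] <- 0
    expect_gt(cor(o, e, method = "spearman"), 0.9)
})

test_that("clash-checked placement yields a clash-free ensemble", {
    blobs <- generateRandomWalkStructure(60, 300, seed = 8, sigmaBlob = 150,
        confineRadius = 1500, containerDiameter = 4000)
    cfg <- fitConfig("model1", nCopies = 300, containerDiameter = 4000,
        windowSigma = 1500, qMin = 0.0042, clashChecking = TRUE,
        maxMoves = 0, seed = 2)
    mod <- placeCopiesFromBlobs(blobs, modelGeometry("model1"), cfg)
    tab <- condensaxs:::chainSegTable(chains(mod))
    expect_false(condensaxs:::ensembleHasClash(tab, 24))
    # a single copy is a valid one-chain ensemble
    cfg1 <- fitConfig("model3", nCopies = 1, containerDiameter = 4000,
        windowSigma = 1500, qMin = 0.0042, maxMoves = 0, seed = 2)
    one <- placeCopiesFromBlobs(blobs, modelGeometry("model3"), cfg1)
    expect_equal(nCopies(one), 1L)
    expect_s4_class(chains(one)[[1]], "SpherocylinderChain")
})

test_that("refinement is greedy, clash-free and deterministic", {
    blobs <- generateRandomWalkStructure(60, 300, seed = 8, sigmaBlob = 150,
        confineRadius = 1500, containerDiameter = 4000)
    qg <- seq(0.0042, 0.03, length.out = 15)
    target <- generateDropletProfile(blobs, qg, noiseFraction = 0.02,
        seed = 8, windowSigma = 1500, nOrientations = 80)
    cfg <- fitConfig("model1", nCopies = 300, containerDiameter = 4000,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03, nOrientations = 80,
        maxMoves = 400, seed = 2)
    init <- placeCopiesFromBlobs(blobs, modelGeometry("model1"), cfg)
    # zero moves: initial returned unchanged
    cfg0 <- fitConfig("model1", nCopies = 300, containerDiameter = 4000,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03, nOrientations = 80,
        maxMoves = 0, seed = 2)
    r0 <- refineCopies(target, init, cfg0)
    expect_length(chi2Trace(r0), 1L)
    expect_equal(t(vapply(chains(finalModel(r0)), chainCentroid, numeric(3))),
                 t(vapply(chains(init), chainCentroid, numeric(3))))
    ra <- refineCopies(target, init, cfg)
    expect_true(all(diff(chi2Trace(ra)) <= 1e-9))
    tab <- condensaxs:::chainSegTable(chains(finalModel(ra)))
    expect_false(condensaxs:::ensembleHasClash(tab, 24))
    rb <- refineCopies(target, init, cfg)
    expect_identical(chi2Trace(ra), chi2Trace(rb))
    # clashing initial state is refused
    clashing <- ensembleModel(list(
        spherocylinderChain(c(0, 0, 0), c(1, 0, 0), 300, 12),
        spherocylinderChain(c(0, 10, 0), c(1, 0, 0), 300, 12)), 4000, 1500)
    expect_error(refineCopies(target, clashing, cfg), "clash")
})

test_that("refinement recovers a known rod ensemble at reduced scale", {
    truthBlobs <- generateRandomWalkStructure(100, 250, seed = 3,
        sigmaBlob = 100, confineRadius = 1800, containerDiameter = 4500)
    cfgT <- fitConfig("model1", nCopies = 1000, containerDiameter = 4500,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03, nOrientations = 100,
        maxMoves = 0, seed = 21)
    truthModel <- placeCopiesFromBlobs(truthBlobs, modelGeometry("model1"),
                                       cfgT)
    qg <- seq(0.0042, 0.03, length.out = 18)
    target <- scatteringProfile(qg,
        ensembleIntensity(truthModel, qg, orientationSet(100, 77)))
    # start from a deliberately wrong (uniform) mass distribution
    unif <- gaussianBlobEnsemble(
        condensaxs:::withSeed(1, condensaxs:::uniformInSphere(100, 2000)),
        200, 4500)
    cfgF <- fitConfig("model1", nCopies = 1000, containerDiameter = 4500,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03, nOrientations = 100,
        maxMoves = 8000, translationStep = 120, seed = 8)
    init <- placeCopiesFromBlobs(unif, modelGeometry("model1"), cfgF)
    fit <- refineCopies(target, init, cfgF)
    tr <- chi2Trace(fit)
    expect_lt(tr[length(tr)], 0.2 * tr[1])   # >= 80% chi2 reduction
})

test_that("the staged cascade seeds each model from the previous stage", {
    walk <- generateRandomWalkStructure(120, 300, seed = 2, sigmaBlob = 150,
        confineRadius = 1700, containerDiameter = 4500)
    place <- fitConfig("model3", nCopies = 400, containerDiameter = 4500,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03, nOrientations = 150,
        maxMoves = 0, seed = 31)
    truthModel <- placeCopiesFromBlobs(walk, modelGeometry("model3"), place)
    qg <- seq(0.0042, 0.03, length.out = 18)
    target <- generateDropletProfile(truthModel, qg, noiseFraction = 0.02,
        seed = 2, windowSigma = 1500, nOrientations = 150)
    mk <- function(g) fitConfig(g,
        nCopies = if (g == "blobs") 150 else 400, containerDiameter = 4500,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03, nOrientations = 150,
        maxMoves = 2500,
        translationStep = if (g == "blobs") 150 else 100,
        sigmaBlob = 40, seed = 4)
    res <- stagedPipeline(target, mk("blobs"), mk("model1"), mk("model2"),
                          mk("model3"))
    expect_named(res, c("blobs", "model1", "model2", "model3"))
    for (r in res) expect_true(all(diff(chi2Trace(r)) <= 1e-9))
    # model-2 seeding: first segment collinear with its model-1 parent and
    # sharing an endpoint
    init2 <- condensaxs:::extendEnsemble(finalModel(res$model1),
                                        modelGeometry("model2"), mk("model2"))
    m1 <- chains(finalModel(res$model1)); i2 <- chains(init2)
    dots <- vapply(seq_along(m1), function(i)
        sum(m1[[i]]@axes[1, ] * i2[[i]]@axes[1, ]), numeric(1))
    expect_equal(dots, rep(1, length(m1)), tolerance = 1e-9)
    starts <- vapply(seq_along(m1), function(i)
        max(abs(m1[[i]]@start - i2[[i]]@start)), numeric(1))
    expect_equal(max(starts), 0)
    expect_equal(vapply(i2, function(ch) length(ch@lengths), integer(1)),
                 rep(2L, length(i2)))
    # each chain stage ends within 2x of the blob-stage final chi2
    bf <- tail(chi2Trace(res$blobs), 1)
    for (nm in c("model1", "model2", "model3"))
        expect_lt(tail(chi2Trace(res[[nm]]), 1), 2 * bf)
})
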
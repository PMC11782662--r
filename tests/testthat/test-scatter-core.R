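test_that("blob form amplitude matches the analytic Gaussian and its transform", {
    expect_equal(blobFormAmplitude(0, 40), 1.0)
    expect_equal(blobFormAmplitude(1 / 40, 40), exp(-1 / 2))
    expect_equal(blobFormAmplitude(1 / 17, 17), exp(-1 / 2))
    q <- seq(0, 0.05, length.out = 20)
    expect_true(all(diff(blobFormAmplitude(q, 40)) < 0))
    expect_error(blobFormAmplitude(0.01, -1), "positive")
    # quadrature oracle: radial Fourier transform of the 3-D Gaussian density
    sigma <- 40
    rho <- function(r) (2 * pi * sigma^2)^(-3 / 2) * exp(-r^2 / (2 * sigma^2))
    for (qv in c(0.005, 0.02, 0.05)) {
        ft <- stats::integrate(function(r)
            4 * pi * r^2 * rho(r) * sin(qv * r) / (qv * r),
            0, 12 * sigma, rel.tol = 1e-10)$value
        expect_equal(blobFormAmplitude(qv, sigma)^2, ft^2, tolerance = 1e-6)
    }
})

test_that("window weight is 1 at the centre and decays monotonically", {
    expect_equal(windowWeight(c(1, 2, 3), c(1, 2, 3), 1500), 1.0)
    expect_equal(windowWeight(c(1500, 0, 0), c(0, 0, 0), 1500), exp(-1 / 2))
    r <- seq(0, 5000, by = 250)
    w <- windowWeight(cbind(r, 0, 0), c(0, 0, 0), 1500)
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= 1))
    expect_equal(windowWeight(c(900, 0, 0), windowSigma = Inf), 1.0)
})

test_that("spherocylinder amplitude reproduces the particle volume at q = 0", {
    rod <- spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 300, 12)
    V <- pi * 12^2 * 300 + 4 / 3 * pi * 12^3
    expect_equal(Mod(spherocylinderAmplitude(rod, c(0, 0, 0))), V,
                 tolerance = 1e-12)
    expect_equal(V, 142955, tolerance = 1e-4)  # approx 1.429e5 A^3
})

test_that("bead decomposition agrees with numeric integration over the volume", {
    rod <- spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 300, 12)
    # transverse amplitude within 1% of the exact disc transform up to qR = 1
    for (qR in c(0.2, 0.5, 1)) {
        q <- qR / 12
        expect_equal(Mod(spherocylinderAmplitude(rod, c(q, 0, 0))),
                     oracleSpherocylinderAmp(0, q, 300, 12),
                     tolerance = 0.01)
    }
    # orientation-averaged intensity within 1% across the fit window
    bd <- chainBeads(rod)
    for (q in c(0.005, 0.015, 0.03)) {
        Ib <- debyeIntensity(bd$positions, bd$weights,
                             function(q) exp(-q^2 * bd$sigma^2 / 2), q)
        expect_equal(Ib, oracleSpherocylinderIavg(q, 300, 12),
                     tolerance = 0.01)
    }
})

test_that("a collinear chain scatters like a single rod of the summed length", {
    ch <- rollCapExtend(
        spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 155, 12), 135, c(0, 0, 1))
    rod <- spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 290, 12)
    bc <- chainBeads(ch); br <- chainBeads(rod)
    qg <- seq(0.002, 0.03, length.out = 15)
    f <- function(q) exp(-q^2 * 36 / 2)
    Ic <- debyeIntensity(bc$positions, bc$weights, f, qg) / sum(bc$weights)^2
    Ir <- debyeIntensity(br$positions, br$weights, f, qg) / sum(br$weights)^2
    # residual deviation is the overlapping cap material buried at the joint
    expect_equal(Ic, Ir, tolerance = 0.05)
})

test_that("ensemble intensity handles the coherent single- and N-blob limits", {
    q <- seq(0.002, 0.03, length.out = 10)
    one <- gaussianBlobEnsemble(matrix(0, 1, 3), 40, 100)
    for (m in c(5, 50)) # independent of orientation count for a point source
        expect_equal(ensembleIntensity(one, q, orientationSet(m, 1)),
                     exp(-q^2 * 40^2))
    five <- gaussianBlobEnsemble(matrix(0, 5, 3), 40, 100)
    expect_equal(ensembleIntensity(five, q, orientationSet(20, 2)),
                 25 * exp(-q^2 * 40^2))
})

test_that("Monte-Carlo orientation average matches the two-point Debye closed form", {
    blobs <- gaussianBlobEnsemble(
        matrix(c(0, 0, 0, 0, 0, 400), 2, 3, byrow = TRUE), 40, 1000)
    qg <- seq(0.002, 0.03, length.out = 15)
    exact <- blobFormAmplitude(qg, 40)^2 * 2 * (1 + sin(qg * 400) / (qg * 400))
    I <- ensembleIntensity(blobs, qg, orientationSet(300, 1))
    expect_lt(max(abs(I / exact - 1)), 2 / sqrt(300))
    expect_true(all(I >= 0))
})

test_that("Debye oracle handles single points and sinc zeros exactly", {
    q <- c(0.005, 0.01, 0.02)
    f <- function(q) blobFormAmplitude(q, 40)
    expect_equal(debyeIntensity(matrix(0, 1, 3), 2, f, q), 4 * f(q)^2)
    # two unit points separated by pi/q: the cross term vanishes at that q
    q0 <- 0.01
    pts <- matrix(c(0, 0, 0, 0, 0, pi / q0), 2, 3, byrow = TRUE)
    expect_equal(debyeIntensity(pts, c(1, 1), qGrid = q0), 2,
                 tolerance = 1e-12)
})

test_that("orientation-set error shrinks as 1/sqrt(M) against the Debye oracle", {
    pts <- withr::with_seed(3, condensaxs:::uniformInSphere(50, 800))
    blobs <- gaussianBlobEnsemble(pts, 40, 1600)
    qg <- seq(0.002, 0.03, length.out = 15)
    Iex <- debyeIntensity(pts, rep(1, 50),
                          function(q) blobFormAmplitude(q, 40), qg)
    rms <- vapply(c(30, 300, 3000), function(M) {
        I <- ensembleIntensity(blobs, qg, orientationSet(M, 5))
        sqrt(mean((I / Iex - 1)^2))
    }, numeric(1))
    expect_true(all(diff(rms) < 0))
    # each tenfold increase in M shrinks the RMS deviation roughly sqrt(10)-fold
    expect_gt(rms[1] / rms[2], 1.8)
    expect_lt(rms[1] / rms[2], 6)
    expect_gt(rms[2] / rms[3], 1.8)
    expect_lt(rms[2] / rms[3], 6)
    expect_lt(rms[2], 0.1)
})

test_that("an infinitely wide window reproduces the unwindowed intensity", {
    pts <- withr::with_seed(7, condensaxs:::uniformInSphere(40, 900))
    blobs <- gaussianBlobEnsemble(pts, 40, 1800)
    qg <- seq(0.002, 0.03, length.out = 10)
    dirs <- orientationSet(50, 9)
    expect_equal(ensembleIntensity(blobs, qg, dirs, windowSigma = Inf),
                 ensembleIntensity(blobs, qg, dirs, windowSigma = 1e12),
                 tolerance = 1e-6)
})

test_that("window resolution arithmetic follows 2*pi/sigma_w", {
    expect_equal(fitResolution(3000), 2 * pi / 3000)
    expect_equal(fitResolution(1500), 2 * pi / 1500)
    expect_error(fitResolution(-1), "positive")
})
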
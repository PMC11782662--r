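# Shared fixtures and independent oracles, all built in code.

# Semi-analytic amplitude of an axis-aligned spherocylinder at (q_par,
# q_perp): 1-D quadrature over axial slices whose transverse transform is
# the exact uniform-disc result 2*pi*r^2*J1(x)/x. Independent of the bead
# decomposition it is used to validate.
oracleSpherocylinderAmp <- function(qpar, qperp, L, R) {
    disc <- function(z) {
        r2 <- ifelse(z < 0, R^2 - z^2,
                     ifelse(z > L, R^2 - (z - L)^2, R^2))
        r <- sqrt(pmax(r2, 0))
        x <- qperp * r
        ifelse(x < 1e-8, pi * r^2, 2 * pi * r^2 * besselJ(x, 1) / x)
    }
    re <- stats::integrate(function(z) disc(z) * cos(qpar * z), -R, L + R,
                           rel.tol = 1e-9)$value
    im <- stats::integrate(function(z) disc(z) * sin(qpar * z), -R, L + R,
                           rel.tol = 1e-9)$value
    sqrt(re^2 + im^2)
}

# Orientation-averaged intensity of the spherocylinder by quadrature over
# the polar angle of the momentum transfer
oracleSpherocylinderIavg <- function(q, L, R) {
    stats::integrate(Vectorize(function(t)
        oracleSpherocylinderAmp(q * t, q * sqrt(1 - t^2), L, R)^2),
        0, 1, rel.tol = 1e-7)$value
}

# Small synthetic identification table builder
makeIdRecords <- function(posA, posB, ldScore, condition, replicate,
                          reagent = "DSS", deltaS = 0.95, fdr = 0.01,
                          spectraCount = 3L) {
    data.frame(posA = posA, posB = posB, ldScore = ldScore,
               condition = condition, replicate = replicate,
               reagent = reagent, deltaS = deltaS, fdr = fdr,
               spectraCount = spectraCount)
}

# One cached heavy fixture shared by the acceptance-scale checks: a
# 5000-copy model-1 reverse-MC fit to a synthetic fractal droplet target.
.fitCache <- new.env(parent = emptyenv())

scaledDropletFit <- function(seed = 11) {
    key <- paste0("fit", seed)
    if (!is.null(.fitCache[[key]])) return(.fitCache[[key]])
    walk <- generateRandomWalkStructure(300, 300, seed = seed,
        sigmaBlob = 150, confineRadius = 2500, containerDiameter = 6000)
    qg <- seq(0.0042, 0.03, length.out = 20)
    target <- generateDropletProfile(walk, qg, noiseFraction = 0.02,
        seed = seed, windowSigma = 1500, nOrientations = 300)
    cfg <- fitConfig("model1", nCopies = 5000, containerDiameter = 6000,
        windowSigma = 1500, qMin = 0.0042, qMax = 0.03,
        nOrientations = 300, maxMoves = 4000, seed = seed)
    init <- placeCopiesFromBlobs(walk, modelGeometry("model1"), cfg)
    fit <- refineCopies(target, init, cfg)
    m <- finalModel(fit)
    out <- list(fit = fit,
                positions = t(vapply(chains(m), chainCentroid, numeric(3))),
                axes = do.call(rbind, lapply(chains(m),
                                             function(ch) ch@axes)))
    .fitCache[[key]] <- out
    out
}
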
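# Seeded generators producing inputs with the statistical structure the
# analysis assumes: fractal blob arrangements, noisy droplet and dilute
# scattering profiles, and crosslink identification/quantification tables.

#' Random-walk fractal blob structure
#'
#' Centres form a 3-D random walk with fixed step length and uniform step
#' directions — the ideal-chain arrangement, whose mass-fractal dimension
#' is exactly 2, matching the power-law regime observed for condensate
#' interiors. With \code{confineRadius} set, steps that would leave the
#' sphere of that radius around the walk origin are redrawn, so the
#' structure fits a prescribed container while remaining fractal below the
#' confinement scale.
#'
#' @param n number of blobs (walk vertices), at least 2.
#' @param stepLength fixed step length (\eqn{\mathrm{\AA}}).
#' @param seed integer seed; generation is a pure function of the
#'   arguments and the seed.
#' @param sigmaBlob blob standard deviation (\eqn{\mathrm{\AA}}).
#' @param containerDiameter bounding-sphere diameter; by default just
#'   enclosing the walk.
#' @param confineRadius optional confinement radius (\eqn{\mathrm{\AA}}).
#' @return A [GaussianBlobEnsemble-class].
#' @examples
#' s <- generateRandomWalkStructure(100, 200, seed = 7)
#' nCopies(s)
#' @export
generateRandomWalkStructure <- function(n, stepLength = 200, seed,
                                        sigmaBlob = 40,
                                        containerDiameter = NULL,
                                        confineRadius = NULL) {
    if (n < 2L) stop("at least two particles required", call. = FALSE)
    stopifnotScalarPositive(stepLength, "stepLength")
    centers <- withSeed(seed, {
        pos <- matrix(0, n, 3)
        for (i in 2:n) {
            repeat {
                cand <- pos[i - 1L, ] + stepLength * randomUnitVectors(1L)[1L, ]
                if (is.null(confineRadius) || sum(cand^2) <= confineRadius^2)
                    break
            }
            pos[i, ] <- cand
        }
        pos
    })
    if (is.null(containerDiameter))
        containerDiameter <- 2 * max(sqrt(rowSums(centers^2))) * (1 + 1e-6)
    gaussianBlobEnsemble(centers, sigmaBlob, containerDiameter)
}

addRelativeNoise <- function(I, noiseFraction, seed) {
    if (noiseFraction < 0) stop("noise fraction must be nonnegative",
                                call. = FALSE)
    if (noiseFraction == 0)
        return(list(intensity = I, uncertainty = NULL))
    noisy <- withSeed(seed, I * (1 + noiseFraction * stats::rnorm(length(I))))
    list(intensity = pmax(noisy, .Machine$double.xmin),
         uncertainty = noiseFraction * I)
}

#' Simulated droplet-interior scattering profile
#'
#' Noiseless intensity of the (optionally windowed) structure by
#' orientation-averaged coherent summation, then multiplicative Gaussian
#' noise of the stated fraction; uncertainties are set to the noise level.
#' This is the package's stand-in for a measured droplet curve.
#'
#' @param structure a [GaussianBlobEnsemble-class] or
#'   [EnsembleModel-class].
#' @param qGrid positive increasing momentum transfer (\eqn{\mathrm{\AA}^{-1}}).
#' @param noiseFraction relative Gaussian noise level; default 0.02.
#' @param seed integer seed (noise only; the intensity is deterministic
#'   apart from the orientation set).
#' @param windowSigma Gaussian window width (\eqn{\mathrm{\AA}}),
#'   \code{Inf} for none.
#' @param nOrientations orientation count for the average; default 300.
#' @param orientationSeed seed of the fixed orientation set.
#' @return A [ScatteringProfile-class].
#' @export
generateDropletProfile <- function(structure, qGrid, noiseFraction = 0.02,
                                   seed, windowSigma = Inf,
                                   nOrientations = 300,
                                   orientationSeed = seed) {
    dirs <- orientationSet(nOrientations, orientationSeed)
    I0 <- ensembleIntensity(structure, qGrid, dirs,
                            windowSigma = windowSigma)
    nz <- addRelativeNoise(I0, noiseFraction, seed)
    scatteringProfile(qGrid, nz$intensity, nz$uncertainty)
}

#' Simulated dilute-solution (form factor) profile
#'
#' Orientation-averaged single-chain intensity computed exactly with the
#' Debye formula over the chain's bead decomposition, plus multiplicative
#' noise — the stand-in for a dilute-solution form-factor measurement.
#'
#' @param geometry a [modelGeometry()] preset or a
#'   [SpherocylinderChain-class]; presets are built stretched (all
#'   segments collinear).
#' @param qGrid momentum-transfer values (\eqn{\mathrm{\AA}^{-1}}).
#' @param noiseFraction relative Gaussian noise level.
#' @param seed integer seed.
#' @return A [ScatteringProfile-class].
#' @export
generateDiluteProfile <- function(geometry, qGrid, noiseFraction = 0.02,
                                  seed) {
    chain <- if (is(geometry, "SpherocylinderChain")) geometry
        else spherocylinderChain(c(0, 0, 0),
            matrix(rep(c(0, 0, 1), length(geometry$lengths)),
                   ncol = 3, byrow = TRUE),
            geometry$lengths, geometry$radius)
    bd <- chainBeads(chain)
    I0 <- debyeIntensity(bd$positions, bd$weights,
                         function(q) exp(-q^2 * bd$sigma^2 / 2), qGrid)
    nz <- addRelativeNoise(I0, noiseFraction, seed)
    scatteringProfile(qGrid, nz$intensity, nz$uncertainty)
}

#' Synthetic crosslink identification and quantification tables
#'
#' Emulates post-identification XL-MS inputs: an identification table
#' (residue positions, link type, ld.Score, deltaS, FDR, condition,
#' replicate, spectral count) and a targeted-quantification transition
#' table (5 transitions for each of the heavy and light forms per peptide
#' and replicate, plus a householder reference peptide). Link populations
#' specify, per link and condition, the probability of being identified
#' and the true normalized abundance, so tests can compare pipeline output
#' against programmed ground truth (returned in \code{$truth}).
#'
#' @param links data.frame with columns \code{posA}, \code{posB}
#'   (\code{NA} for monolinks) and \code{reagent} (\code{"DSS"} or
#'   \code{"PDH"}).
#' @param presence links x conditions matrix of identification
#'   probabilities (1 = always identified, 0 = never).
#' @param abundance links x conditions matrix of true mean normalized
#'   abundances (used for the transition table).
#' @param conditions condition labels (columns of the two matrices).
#' @param nReplicates replicates per condition; default 3.
#' @param seed integer seed.
#' @param ldScoreMean per-link mean ld.Score; default 30.
#' @param ldScoreSd ld.Score spread; default 3.
#' @param noiseFraction relative noise on transition areas; default 0.1.
#' @param householder householder (reference) peptide identifier.
#' @param householderArea true householder area per replicate.
#' @return A list with \code{identifications}, \code{transitions} and
#'   \code{truth} (the inputs plus the per-link key used by the pipeline).
#' @export
generateXlTables <- function(links, presence, abundance,
                             conditions = colnames(presence),
                             nReplicates = 3, seed,
                             ldScoreMean = 30, ldScoreSd = 3,
                             noiseFraction = 0.1,
                             householder = "MVLEEVQPTFDR",
                             householderArea = 1e5) {
    nL <- nrow(links)
    if (is.null(conditions))
        stop("condition labels required (set colnames on 'presence')",
             call. = FALSE)
    presence <- as.matrix(presence); abundance <- as.matrix(abundance)
    if (!all(dim(presence) == c(nL, length(conditions))) ||
        !all(dim(abundance) == c(nL, length(conditions))))
        stop("presence and abundance must be links x conditions matrices",
             call. = FALSE)
    if (length(ldScoreMean) == 1L) ldScoreMean <- rep(ldScoreMean, nL)
    type <- classifyLink(links$posA, links$posB, links$reagent)
    key <- peptideKey(links$posA, links$posB, type, links$reagent)
    withSeed(seed, {
        idRows <- list(); trRows <- list()
        fractions <- c(1, 2, 3, 2, 2) / 10   # fixed transition split per form
        for (ci in seq_along(conditions)) {
            for (rep_ in seq_len(nReplicates)) {
                hhArea <- householderArea *
                    (1 + noiseFraction * stats::rnorm(1))
                trRows[[length(trRows) + 1L]] <- data.frame(
                    peptideId = householder, condition = conditions[ci],
                    replicate = rep_, form = "light", transition = 1L,
                    area = hhArea)
                for (li in seq_len(nL)) {
                    seen <- stats::runif(1) < presence[li, ci]
                    if (seen) {
                        idRows[[length(idRows) + 1L]] <- data.frame(
                            posA = links$posA[li], posB = links$posB[li],
                            linkType = type[li],
                            ldScore = stats::rnorm(1, ldScoreMean[li],
                                                   ldScoreSd),
                            deltaS = stats::runif(1, 0.91, 0.99),
                            fdr = stats::runif(1, 0, 0.04),
                            condition = conditions[ci], replicate = rep_,
                            spectraCount = stats::rpois(1, 5) + 1L,
                            reagent = links$reagent[li])
                    }
                    ab <- abundance[li, ci]
                    if (is.finite(ab) && ab > 0) {
                        total <- ab * hhArea *
                            (1 + noiseFraction * stats::rnorm(1))
                        total <- max(total, 1)
                        for (form in c("heavy", "light")) {
                            trRows[[length(trRows) + 1L]] <- data.frame(
                                peptideId = key[li],
                                condition = conditions[ci],
                                replicate = rep_, form = form,
                                transition = 1:5,
                                area = total / 2 * fractions)
                        }
                    }
                }
            }
        }
        ids <- if (length(idRows)) do.call(rbind, idRows)
            else data.frame(posA = integer(0), posB = integer(0),
                            linkType = character(0), ldScore = numeric(0),
                            deltaS = numeric(0), fdr = numeric(0),
                            condition = character(0), replicate = integer(0),
                            spectraCount = integer(0), reagent = character(0))
        list(identifications = ids, transitions = do.call(rbind, trRows),
             truth = list(links = links, key = key, presence = presence,
                          abundance = abundance, conditions = conditions,
                          householder = householder))
    })
}
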
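# Greedy reverse-Monte-Carlo fitting of blob and spherocylinder ensembles
# to a measured SAXS profile, with staged model-1 -> model-2 -> model-3
# refinement and clash avoidance.

#' Reverse-Monte-Carlo fit configuration
#'
#' Collects every tunable of a fit. Geometry-dependent defaults follow the
#' droplet-modelling setup: the blob stage uses 4000 blobs of
#' \eqn{\sigma} = 40 \eqn{\mathrm{\AA}} in a 10,000 \eqn{\mathrm{\AA}} sphere
#' with \eqn{\sigma_w} = 3000 \eqn{\mathrm{\AA}}; the spherocylinder stages
#' use 50,000 copies in a 6000 \eqn{\mathrm{\AA}} sphere with
#' \eqn{\sigma_w} = 1500 \eqn{\mathrm{\AA}}. Both use 300 momentum-transfer
#' orientations. The fit window must respect the window resolution: fits at
#' \eqn{q_{min} < 2\pi/\sigma_w} are refused (a 5\% grace factor accepts the
#' conventional rounded value 0.002 \eqn{\mathrm{\AA}^{-1}} for
#' \eqn{\sigma_w} = 3000 \eqn{\mathrm{\AA}}).
#'
#' @param modelGeometry one of \code{"blobs"}, \code{"model1"},
#'   \code{"model2"}, \code{"model3"}.
#' @param nCopies number of blobs or chain copies.
#' @param containerDiameter bounding-sphere diameter (\eqn{\mathrm{\AA}}).
#' @param windowSigma Gaussian window width \eqn{\sigma_w} (\eqn{\mathrm{\AA}}).
#' @param qMin,qMax fit window (\eqn{\mathrm{\AA}^{-1}}).
#' @param nOrientations orientation count M for the intensity average.
#' @param translationStep random translation scale (\eqn{\mathrm{\AA}}).
#' @param rotationStep maximum random reorientation angle (radians).
#' @param maxMoves number of proposals.
#' @param seed integer seed controlling every random draw of the fit.
#' @param sigmaBlob blob standard deviation (\eqn{\mathrm{\AA}}, blob stage).
#' @param clashChecking reject moves creating core overlaps (chain stages).
#' @param stallAfter stop early after this many consecutive rejections
#'   (\code{Inf} disables the stall criterion).
#' @param temperature optional Metropolis temperature; 0 (default) is the
#'   strictly greedy rule in which only improving moves are accepted.
#' @param placementRetries per-copy retry budget for clash-free placement.
#' @return A list of class \code{"FitConfig"}.
#' @export
fitConfig <- function(modelGeometry = c("blobs", "model1", "model2", "model3"),
                      nCopies = NULL, containerDiameter = NULL,
                      windowSigma = NULL, qMin = NULL, qMax = 0.03,
                      nOrientations = 300, translationStep = 50,
                      rotationStep = 0.3, maxMoves = 1000L, seed = 1L,
                      sigmaBlob = 40, clashChecking = NULL,
                      stallAfter = Inf, temperature = 0,
                      placementRetries = 500L) {
    modelGeometry <- match.arg(modelGeometry)
    blobStage <- modelGeometry == "blobs"
    if (is.null(nCopies)) nCopies <- if (blobStage) 4000L else 50000L
    if (is.null(containerDiameter)) containerDiameter <- if (blobStage) 10000 else 6000
    if (is.null(windowSigma)) windowSigma <- if (blobStage) 3000 else 1500
    if (is.null(qMin)) qMin <- if (blobStage) 0.002 else 0.0042
    if (is.null(clashChecking)) clashChecking <- !blobStage
    stopifnotScalarPositive(containerDiameter, "containerDiameter")
    stopifnotScalarPositive(windowSigma, "windowSigma")
    stopifnotScalarPositive(translationStep, "translationStep")
    stopifnotScalarPositive(rotationStep, "rotationStep")
    if (nCopies < 1L) stop("nCopies must be at least 1", call. = FALSE)
    if (maxMoves < 0L) stop("maxMoves must be nonnegative", call. = FALSE)
    if (qMin >= qMax) stop("qMin must be smaller than qMax", call. = FALSE)
    res <- fitResolution(windowSigma)
    if (qMin < res * 0.95)
        stop(sprintf(
            "fit window below the window resolution: qMin = %.4g < 2*pi/windowSigma = %.4g A^-1",
            qMin, res), call. = FALSE)
    structure(list(modelGeometry = modelGeometry, nCopies = as.integer(nCopies),
                   containerDiameter = containerDiameter,
                   windowSigma = windowSigma, qMin = qMin, qMax = qMax,
                   nOrientations = as.integer(nOrientations),
                   translationStep = translationStep,
                   rotationStep = rotationStep, maxMoves = as.integer(maxMoves),
                   seed = as.integer(seed), sigmaBlob = sigmaBlob,
                   clashChecking = isTRUE(clashChecking),
                   stallAfter = stallAfter, temperature = temperature,
                   placementRetries = as.integer(placementRetries)),
              class = "FitConfig")
}

#' Chi-squared objective with closed-form scale
#'
#' \eqn{\chi^2 = \sum_i [(c I_{mod}(q_i) - I_{exp}(q_i)) / \sigma_i]^2} with
#' the globally optimal scale
#' \eqn{c = \sum I_{mod} I_{exp}/\sigma_i^2 \,/\, \sum I_{mod}^2/\sigma_i^2};
#' unit weights are used when the profile carries no uncertainties. The
#' scale absorbs the unknown contrast, so models are compared on shape.
#'
#' @param modelIntensity model intensities on the experiment's q grid.
#' @param experiment a [ScatteringProfile-class].
#' @param qWindow optional length-2 fit window (\eqn{\mathrm{\AA}^{-1}});
#'   default uses all points.
#' @return A list with \code{chi2} and \code{scale}.
#' @examples
#' p <- scatteringProfile(c(0.01, 0.02, 0.03), c(2, 4, 7))
#' chiSquared(c(1, 2, 3), p)   # scale close to 7/3
#' @export
chiSquared <- function(modelIntensity, experiment, qWindow = NULL) {
    q <- qValues(experiment)
    if (length(modelIntensity) != length(q))
        stop("grid mismatch: model intensity must be given on the experiment's q grid",
             call. = FALSE)
    idx <- if (is.null(qWindow)) rep(TRUE, length(q))
           else q >= qWindow[1] & q <= qWindow[2]
    if (!any(idx)) stop("empty fit window", call. = FALSE)
    Ie <- intensities(experiment)[idx]
    Im <- modelIntensity[idx]
    sig <- uncertainties(experiment)
    sig <- if (is.null(sig)) rep(1, sum(idx)) else sig[idx]
    iv <- 1 / sig^2
    scale <- sum(Im * Ie * iv) / sum(Im^2 * iv)
    list(chi2 = sum(((scale * Im - Ie) / sig)^2), scale = scale)
}

# Shared pieces of a fit: window indices, target values, orientation set
fitContext <- function(experiment, config) {
    q <- qValues(experiment)
    idx <- which(q >= config$qMin & q <= config$qMax)
    if (length(idx) < 5L)
        stop("fewer than 5 profile points in the fit window", call. = FALSE)
    sig <- uncertainties(experiment)
    list(q = q[idx], Ie = intensities(experiment)[idx],
         iw = if (is.null(sig)) rep(1, length(idx)) else 1 / sig[idx]^2,
         sig = if (is.null(sig)) rep(1, length(idx)) else sig[idx])
}

chi2FromModel <- function(Im, ctx) {
    scale <- sum(Im * ctx$Ie * ctx$iw) / sum(Im^2 * ctx$iw)
    list(chi2 = sum(((scale * Im - ctx$Ie) / ctx$sig)^2), scale = scale)
}

#' Greedy reverse-Monte-Carlo fit of a Gaussian-blob ensemble
#'
#' Blobs start uniformly at random inside the container; proposals are
#' random single-blob translations and a move is accepted only when the
#' windowed, orientation-averaged \eqn{\chi^2} strictly decreases, so the
#' objective trace is non-increasing by construction. The Gaussian window
#' is centred on the configuration's centre of mass (computed at fit start)
#' and the orientation set is fixed for the whole fit, making the objective
#' deterministic for a given seed.
#'
#' @param experiment a [ScatteringProfile-class] to fit.
#' @param config a [fitConfig()] with \code{modelGeometry = "blobs"}.
#' @return A [FitResult-class] whose model is a
#'   [GaussianBlobEnsemble-class].
#' @export
fitBlobs <- function(experiment, config = fitConfig("blobs")) {
    if (config$modelGeometry != "blobs")
        stop("fitBlobs requires modelGeometry = 'blobs'", call. = FALSE)
    ctx <- fitContext(experiment, config)
    R <- config$containerDiameter / 2
    withSeed(config$seed, {
        dirs <- randomUnitVectors(config$nOrientations)
        centers <- uniformInSphere(config$nCopies, R)
        wc <- colMeans(centers)
        w <- windowWeight(centers, wc, config$windowSigma)
        f <- blobFormAmplitude(ctx$q, config$sigmaBlob)
        G <- cpp_phase_sum(centers, w, ctx$q, dirs)
        cur <- chi2FromModel(rowMeans(Mod(G * f)^2), ctx)
        trace <- numeric(config$maxMoves + 1L)
        trace[1L] <- cur$chi2
        acc <- 0L; stall <- 0L; nprop <- 0L
        for (p in seq_len(config$maxMoves)) {
            i <- sample.int(config$nCopies, 1L)
            newc <- centers[i, ] + stats::rnorm(3) * config$translationStep
            nprop <- p
            accepted <- FALSE
            if (sum(newc^2) <= R^2) {
                wn <- windowWeight(newc, wc, config$windowSigma)
                dG <- cpp_phase_sum(rbind(newc, centers[i, ]),
                                    c(wn, -w[i]), ctx$q, dirs)
                Gn <- G + dG
                cand <- chi2FromModel(rowMeans(Mod(Gn * f)^2), ctx)
                if (acceptMove(cand$chi2, cur$chi2, config$temperature)) {
                    G <- Gn; centers[i, ] <- newc; w[i] <- wn; cur <- cand
                    accepted <- TRUE
                }
            }
            if (accepted) { acc <- acc + 1L; stall <- 0L }
            else stall <- stall + 1L
            trace[p + 1L] <- cur$chi2
            if (stall >= config$stallAfter) break
        }
        new("FitResult",
            model = gaussianBlobEnsemble(centers, config$sigmaBlob,
                                         config$containerDiameter),
            chi2Trace = trace[seq_len(nprop + 1L)], scale = cur$scale,
            nAccepted = acc, nRejected = nprop - acc,
            seed = config$seed, config = unclass(config))
    })
}

# strictly greedy unless a positive Metropolis temperature is configured
acceptMove <- function(candChi2, curChi2, temperature = 0) {
    if (candChi2 < curChi2) return(TRUE)
    if (temperature > 0)
        return(stats::runif(1) < exp(-(candChi2 - curChi2) / temperature))
    FALSE
}

#' Place chain copies according to a blob mass distribution
#'
#' Copy reference points (chain centroids) are drawn from the
#' window-weighted Gaussian mixture defined by the blob fit, truncated to
#' the container; orientations are uniform on the sphere. With clash
#' checking on, a rejected placement redraws both centroid and orientation
#' until clash-free, within a per-copy retry budget.
#'
#' @param blobResult a [FitResult-class] from [fitBlobs()] or a
#'   [GaussianBlobEnsemble-class].
#' @param geometry a [modelGeometry()] preset.
#' @param config a [fitConfig()] for the chain stage (copy count,
#'   container, window, clash checking, seed).
#' @return An [EnsembleModel-class] of \code{config$nCopies} chains.
#' @export
placeCopiesFromBlobs <- function(blobResult, geometry, config) {
    blobs <- if (is(blobResult, "FitResult")) finalModel(blobResult)
             else blobResult
    if (!is(blobs, "GaussianBlobEnsemble"))
        stop("blobResult must provide a GaussianBlobEnsemble", call. = FALSE)
    cen <- blobCenters(blobs)
    R <- config$containerDiameter / 2
    sampW <- windowWeight(cen, colMeans(cen), config$windowSigma)
    n <- config$nCopies
    k <- length(geometry$lengths)
    lim <- 2 * geometry$radius
    withSeed(config$seed + 1L, {
        chainsOut <- vector("list", n)
        segs <- matrix(1e9, n * k, 7)   # far-away rows never clash
        segs[, 4:6] <- matrix(rep(c(0, 0, 1), n * k), ncol = 3, byrow = TRUE)
        segs[, 7] <- 1
        ids <- rep(seq_len(n), each = k)
        for (j in seq_len(n)) {
            placed <- FALSE
            for (try in seq_len(config$placementRetries)) {
                b <- sample.int(nrow(cen), 1L, prob = sampW)
                pt <- cen[b, ] + stats::rnorm(3) * sigmaBlob(blobs)
                if (sum(pt^2) > R^2) next
                ch <- randomChain(geometry, pt)
                if (clashWithinChain(ch)) next
                st <- segmentStarts(ch)
                cand <- cbind(st, ch@axes, ch@lengths)
                if (config$clashChecking &&
                    cpp_any_clash(cand, segs, ids, j, lim)) next
                chainsOut[[j]] <- ch
                segs[((j - 1L) * k + 1L):(j * k), ] <- cand
                placed <- TRUE
                break
            }
            if (!placed)
                stop(sprintf(
                    "overcrowded placement: retry budget exhausted at copy %d of %d",
                    j, n), call. = FALSE)
        }
        ensembleModel(chainsOut, config$containerDiameter, config$windowSigma)
    })
}

#' Greedy reverse-Monte-Carlo refinement of a chain ensemble
#'
#' Proposals are whole-chain translations, whole-chain reorientations
#' (single-segment chains) or single-segment reorientations about the
#' shared joint (multi-segment chains, preserving all links). A move is
#' accepted only if \eqn{\chi^2} strictly decreases, the chain centroid
#' stays inside the container and, with clash checking on, no new core
#' overlap appears — so every accepted state is clash-free and the
#' objective trace is non-increasing.
#'
#' @param experiment a [ScatteringProfile-class] to fit.
#' @param initial an [EnsembleModel-class], e.g. from
#'   [placeCopiesFromBlobs()]; must be clash-free when clash checking is on.
#' @param config a [fitConfig()] for this stage.
#' @return A [FitResult-class] whose model is an [EnsembleModel-class].
#' @export
refineCopies <- function(experiment, initial, config) {
    ctx <- fitContext(experiment, config)
    chs <- chains(initial)
    n <- length(chs)
    k <- length(chs[[1L]]@lengths)
    radius <- chs[[1L]]@radius
    lim <- 2 * radius
    R <- config$containerDiameter / 2
    tab <- chainSegTable(chs)
    if (config$clashChecking && ensembleHasClash(tab, lim))
        stop("initial model contains clashes", call. = FALSE)
    tmpl <- chainBeads(chs[[1L]])
    nb <- length(tmpl$weights)
    sigb <- tmpl$sigma
    beadPos <- do.call(rbind, lapply(chs, function(ch) chainBeads(ch)$positions))
    beadVol <- rep(tmpl$weights, n)   # identical template within a stage
    cenM <- t(vapply(chs, chainCentroid, numeric(3)))
    vols <- vapply(chs, function(ch) sum(segmentVolumes(ch)), numeric(1))
    wc <- colSums(cenM * vols) / sum(vols)
    wcopy <- windowWeight(cenM, wc, config$windowSigma)
    beadW <- beadVol * rep(wcopy, each = nb)
    withSeed(config$seed + 2L, {
        dirs <- randomUnitVectors(config$nOrientations)
        f <- exp(-ctx$q^2 * sigb^2 / 2)
        G <- cpp_phase_sum(beadPos, beadW, ctx$q, dirs)
        cur <- chi2FromModel(rowMeans(Mod(G * f)^2), ctx)
        trace <- numeric(config$maxMoves + 1L)
        trace[1L] <- cur$chi2
        acc <- 0L; stall <- 0L; nprop <- 0L
        for (p in seq_len(config$maxMoves)) {
            nprop <- p
            j <- sample.int(n, 1L)
            ch <- chs[[j]]
            u <- stats::runif(1)
            newch <- if (u < 0.4) {
                translateChain(ch, stats::rnorm(3) * config$translationStep)
            } else if (k == 1L) {
                reorientSegment(ch, 1L,
                    randomSmallRotation(config$rotationStep))
            } else {
                reorientSegment(ch, sample.int(k, 1L),
                    randomSmallRotation(config$rotationStep))
            }
            accepted <- FALSE
            cenNew <- chainCentroid(newch)
            # a pre-existing internal contact (possible after a folded-back
            # stage seeding) does not veto moves; creating a new one does
            ok <- sum(cenNew^2) <= R^2 &&
                (!clashWithinChain(newch) || clashWithinChain(ch))
            if (ok && config$clashChecking) {
                st <- segmentStarts(newch)
                cand <- cbind(st, newch@axes, newch@lengths)
                ok <- !cpp_any_clash(cand, tab$segs, tab$chainId, j, lim)
            }
            if (ok) {
                rows <- ((j - 1L) * nb + 1L):(j * nb)
                newPos <- chainBeads(newch)$positions
                wNew <- windowWeight(cenNew, wc, config$windowSigma)
                newW <- tmpl$weights * wNew
                dG <- cpp_phase_sum(rbind(newPos, beadPos[rows, , drop = FALSE]),
                                    c(newW, -beadW[rows]), ctx$q, dirs)
                Gn <- G + dG
                cand2 <- chi2FromModel(rowMeans(Mod(Gn * f)^2), ctx)
                if (acceptMove(cand2$chi2, cur$chi2, config$temperature)) {
                    G <- Gn; cur <- cand2
                    chs[[j]] <- newch
                    beadPos[rows, ] <- newPos
                    beadW[rows] <- newW
                    segRows <- ((j - 1L) * k + 1L):(j * k)
                    st <- segmentStarts(newch)
                    tab$segs[segRows, ] <- cbind(st, newch@axes, newch@lengths)
                    accepted <- TRUE
                }
            }
            if (accepted) { acc <- acc + 1L; stall <- 0L }
            else stall <- stall + 1L
            trace[p + 1L] <- cur$chi2
            if (stall >= config$stallAfter) break
        }
        new("FitResult",
            model = ensembleModel(chs, config$containerDiameter,
                                  config$windowSigma),
            chi2Trace = trace[seq_len(nprop + 1L)], scale = cur$scale,
            nAccepted = acc, nRejected = nprop - acc,
            seed = config$seed, config = unclass(config))
    })
}

randomSmallRotation <- function(maxAngle) {
    rotationMatrix(randomUnitVectors(1L)[1L, ], stats::runif(1, 0, maxAngle))
}

# any core-core approach below `lim` among distinct chains
ensembleHasClash <- function(tab, lim) {
    cpp_ensemble_clash(tab$segs, tab$chainId, lim)
}

#' Staged blob-to-chain fitting pipeline
#'
#' Runs the full refinement cascade: a blob fit establishes the coarse mass
#' distribution; model-1 rods are placed on it and refined; the model-2
#' stage superimposes the long (155 \eqn{\mathrm{\AA}}) segment on one end
#' of each refined rod and appends the second segment clash-free at a
#' random orientation; model 3 is seeded from model 2 analogously (76
#' \eqn{\mathrm{\AA}} segment superimposed on the old second segment, 50
#' \eqn{\mathrm{\AA}} segment appended).
#'
#' @param experiment a [ScatteringProfile-class].
#' @param blobConfig,model1Config,model2Config,model3Config per-stage
#'   [fitConfig()]s; later stages may be \code{NULL} to stop the cascade
#'   early. Chain-stage containers must agree.
#' @return A named list of [FitResult-class]s, one per executed stage.
#' @export
stagedPipeline <- function(experiment, blobConfig, model1Config,
                           model2Config = NULL, model3Config = NULL) {
    out <- list(blobs = fitBlobs(experiment, blobConfig))
    init1 <- placeCopiesFromBlobs(out$blobs, modelGeometry("model1"),
                                  model1Config)
    out$model1 <- refineCopies(experiment, init1, model1Config)
    if (is.null(model2Config)) return(out)
    init2 <- extendEnsemble(finalModel(out$model1), modelGeometry("model2"),
                            model2Config)
    out$model2 <- refineCopies(experiment, init2, model2Config)
    if (is.null(model3Config)) return(out)
    init3 <- extendEnsemble(finalModel(out$model2), modelGeometry("model3"),
                            model3Config)
    out$model3 <- refineCopies(experiment, init3, model3Config)
    out
}

# Seed the next chain geometry from a refined ensemble: predetermined
# segments (sub-segments of the previous stage, hence clash-free) are laid
# down first; the one appended segment per chain is then placed clash-free
# at a random orientation.
extendEnsemble <- function(model, geometry, config) {
    chs <- chains(model)
    n <- length(chs)
    kNew <- length(geometry$lengths)
    kOld <- length(chs[[1L]]@lengths)
    if (kNew != kOld + 1L)
        stop("stage extension must add exactly one segment", call. = FALSE)
    lim <- 2 * geometry$radius
    segs <- matrix(1e9, n * kNew, 7)
    segs[, 4:6] <- matrix(rep(c(0, 0, 1), n * kNew), ncol = 3, byrow = TRUE)
    segs[, 7] <- 1
    ids <- rep(seq_len(n), each = kNew)
    base <- vector("list", n)
    for (j in seq_len(n)) {
        ch <- chs[[j]]
        keep <- spherocylinderChain(ch@start,
            ch@axes[seq_len(kOld), , drop = FALSE],
            geometry$lengths[seq_len(kOld)], geometry$radius)
        base[[j]] <- keep
        st <- segmentStarts(keep)
        rows <- ((j - 1L) * kNew + 1L):((j - 1L) * kNew + kOld)
        segs[rows, ] <- cbind(st, keep@axes, keep@lengths)
    }
    withSeed(config$seed + 3L, {
        out <- vector("list", n)
        for (j in seq_len(n)) {
            placed <- FALSE
            # phase 2 drops the within-chain check: a strongly folded-back
            # parent (its consecutive segments are exempt from clash rules,
            # so their cores may almost coincide) can leave no orientation
            # of the appended segment clear of segment 1; refinement still
            # enforces the rule on every subsequent move.
            for (phase in 1:2) {
                for (try in seq_len(config$placementRetries)) {
                    cand <- rollCapExtend(base[[j]],
                                          geometry$lengths[kNew],
                                          randomUnitVectors(1L)[1L, ])
                    if (phase == 1L && clashWithinChain(cand)) next
                    if (sum(chainCentroid(cand)^2) >
                        (config$containerDiameter / 2)^2) next
                    st <- segmentStarts(cand)
                    newRow <- cbind(st[kNew, , drop = FALSE],
                                    cand@axes[kNew, , drop = FALSE],
                                    cand@lengths[kNew])
                    if (config$clashChecking &&
                        cpp_any_clash(newRow, segs, ids, j, lim)) next
                    out[[j]] <- cand
                    segs[j * kNew, ] <- newRow
                    placed <- TRUE
                    break
                }
                if (placed) break
            }
            if (!placed)
                stop(sprintf(
                    "overcrowded placement: could not append segment for copy %d",
                    j), call. = FALSE)
        }
        ensembleModel(out, config$containerDiameter, config$windowSigma)
    })
}
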
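#' @import methods
NULL

#' One-dimensional scattering profile
#'
#' Container for a measured or simulated small-angle scattering curve:
#' momentum transfer \eqn{q} (\eqn{\mathrm{\AA}^{-1}}), intensity (arbitrary
#' units) and, optionally, pointwise intensity uncertainties. \eqn{q} must be
#' strictly increasing and positive; an empty \code{uncertainty} slot means
#' no uncertainties are available.
#'
#' @slot q numeric, strictly increasing positive momentum-transfer values.
#' @slot intensity numeric, nonnegative intensities, same length as \code{q}.
#' @slot uncertainty numeric, positive, same length as \code{q}, or length 0.
#' @seealso [scatteringProfile()], [readSAXSProfile()]
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
    representation(q = "numeric", intensity = "numeric",
                   uncertainty = "numeric"))

setValidity("ScatteringProfile", function(object) {
    msg <- character()
    if (length(object@q) == 0L) msg <- c(msg, "profile must contain points")
    if (any(object@q <= 0)) msg <- c(msg, "q values must be positive")
    if (length(object@q) > 1L && any(diff(object@q) <= 0))
        msg <- c(msg, "q values must be strictly increasing")
    if (length(object@intensity) != length(object@q))
        msg <- c(msg, "intensity and q must have the same length")
    if (any(object@intensity < 0))
        msg <- c(msg, "intensities must be nonnegative")
    if (length(object@uncertainty) > 0L) {
        if (length(object@uncertainty) != length(object@q))
            msg <- c(msg, "uncertainty must match q in length")
        if (any(object@uncertainty <= 0))
            msg <- c(msg, "uncertainties must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ScatteringProfile
#'
#' @param q strictly increasing positive momentum transfer (\eqn{\mathrm{\AA}^{-1}}).
#' @param intensity nonnegative intensities (arbitrary units).
#' @param uncertainty optional positive uncertainties, same units as intensity.
#' @return A [ScatteringProfile-class] object.
#' @examples
#' p <- scatteringProfile(q = c(0.002, 0.01, 0.03), intensity = c(9, 4, 1))
#' qValues(p)
#' @export
scatteringProfile <- function(q, intensity, uncertainty = NULL) {
    new("ScatteringProfile", q = as.numeric(q),
        intensity = as.numeric(intensity),
        uncertainty = if (is.null(uncertainty)) numeric(0)
                      else as.numeric(uncertainty))
}

#' Gaussian-blob ensemble
#'
#' Coarse mass distribution: \eqn{N} isotropic Gaussian blobs of common
#' standard deviation \code{sigmaBlob} inside a bounding sphere centred at
#' the origin.
#'
#' @slot centers numeric N x 3 matrix of blob centres (\eqn{\mathrm{\AA}}).
#' @slot sigmaBlob positive scalar, common blob standard deviation (\eqn{\mathrm{\AA}}).
#' @slot containerDiameter positive scalar, bounding-sphere diameter (\eqn{\mathrm{\AA}}).
#' @exportClass GaussianBlobEnsemble
setClass("GaussianBlobEnsemble",
    representation(centers = "matrix", sigmaBlob = "numeric",
                   containerDiameter = "numeric"))

setValidity("GaussianBlobEnsemble", function(object) {
    msg <- character()
    if (ncol(object@centers) != 3L) msg <- c(msg, "centers must be N x 3")
    if (nrow(object@centers) < 1L) msg <- c(msg, "at least one blob required")
    if (length(object@sigmaBlob) != 1L || object@sigmaBlob <= 0)
        msg <- c(msg, "sigmaBlob must be a positive scalar")
    if (length(object@containerDiameter) != 1L || object@containerDiameter <= 0)
        msg <- c(msg, "containerDiameter must be a positive scalar")
    else {
        r <- sqrt(rowSums(object@centers^2))
        if (any(r > object@containerDiameter / 2 * (1 + 1e-9)))
            msg <- c(msg, "all centers must lie inside the bounding sphere")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GaussianBlobEnsemble
#'
#' @param centers N x 3 matrix of blob centres (\eqn{\mathrm{\AA}}), container
#'   centred at the origin.
#' @param sigmaBlob common blob standard deviation (\eqn{\mathrm{\AA}}).
#' @param containerDiameter bounding-sphere diameter (\eqn{\mathrm{\AA}}).
#' @return A [GaussianBlobEnsemble-class] object.
#' @export
gaussianBlobEnsemble <- function(centers, sigmaBlob, containerDiameter) {
    new("GaussianBlobEnsemble", centers = as.matrix(centers),
        sigmaBlob = as.numeric(sigmaBlob),
        containerDiameter = as.numeric(containerDiameter))
}

#' Chain of linked spherocylinders
#'
#' One to three capped cylinders (spherocylinders) of common radius, linked
#' end cap-centre to start: segment \eqn{i+1} starts where the core of
#' segment \eqn{i} ends. Segment starts are derived from the first start and
#' the axes, so joints coincide exactly by construction. The inter-segment
#' angle convention follows the stretched/folded picture: 180 degrees is a
#' collinear continuation, 0 degrees fully folded back.
#'
#' @slot start numeric length-3, core start of the first segment (\eqn{\mathrm{\AA}}).
#' @slot axes k x 3 matrix of unit axis vectors, one row per segment.
#' @slot lengths numeric k, core cylinder lengths (\eqn{\mathrm{\AA}}).
#' @slot radius positive scalar, common radius (\eqn{\mathrm{\AA}}).
#' @seealso [spherocylinderChain()], [rollCapExtend()], [segmentAngles()]
#' @exportClass SpherocylinderChain
setClass("SpherocylinderChain",
    representation(start = "numeric", axes = "matrix", lengths = "numeric",
                   radius = "numeric"))

setValidity("SpherocylinderChain", function(object) {
    msg <- character()
    k <- length(object@lengths)
    if (k < 1L || k > 3L) msg <- c(msg, "a chain has 1 to 3 segments")
    if (length(object@start) != 3L) msg <- c(msg, "start must be length 3")
    if (nrow(object@axes) != k || ncol(object@axes) != 3L)
        msg <- c(msg, "axes must be k x 3")
    else if (any(abs(sqrt(rowSums(object@axes^2)) - 1) > 1e-6))
        msg <- c(msg, "axis vectors must have unit norm")
    if (any(object@lengths <= 0)) msg <- c(msg, "segment lengths must be positive")
    if (length(object@radius) != 1L || object@radius <= 0)
        msg <- c(msg, "radius must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Construct a SpherocylinderChain
#'
#' @param start length-3 core start point of the first segment (\eqn{\mathrm{\AA}}).
#' @param axes k x 3 matrix (or length-3 vector for a single segment) of unit
#'   axis directions.
#' @param lengths core cylinder lengths (\eqn{\mathrm{\AA}}), one per segment.
#' @param radius common spherocylinder radius (\eqn{\mathrm{\AA}}).
#' @return A [SpherocylinderChain-class] object.
#' @examples
#' rod <- spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 300, 12)
#' aspectRatio(rod)
#' @export
spherocylinderChain <- function(start, axes, lengths, radius) {
    if (is.null(dim(axes))) axes <- matrix(axes, ncol = 3, byrow = TRUE)
    new("SpherocylinderChain", start = as.numeric(start),
        axes = as.matrix(axes), lengths = as.numeric(lengths),
        radius = as.numeric(radius))
}

#' Ensemble of spherocylinder chains in a windowed container
#'
#' Many copies of a chain model inside a bounding sphere, together with the
#' Gaussian window width used to suppress the container's own form factor
#' when computing scattering.
#'
#' @slot chains list of [SpherocylinderChain-class] copies.
#' @slot containerDiameter positive scalar (\eqn{\mathrm{\AA}}).
#' @slot windowSigma positive scalar \eqn{\sigma_w} (\eqn{\mathrm{\AA}}), may be \code{Inf}.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
    representation(chains = "list", containerDiameter = "numeric",
                   windowSigma = "numeric"))

setValidity("EnsembleModel", function(object) {
    msg <- character()
    if (length(object@chains) < 1L) msg <- c(msg, "ensemble must contain copies")
    if (!all(vapply(object@chains, is, logical(1), "SpherocylinderChain")))
        msg <- c(msg, "all copies must be SpherocylinderChain objects")
    if (length(object@containerDiameter) != 1L || object@containerDiameter <= 0)
        msg <- c(msg, "containerDiameter must be a positive scalar")
    if (length(object@windowSigma) != 1L || object@windowSigma <= 0)
        msg <- c(msg, "windowSigma must be positive (possibly Inf)")
    if (length(msg) == 0L) {
        cen <- t(vapply(object@chains, chainCentroid, numeric(3)))
        if (any(sqrt(rowSums(cen^2)) > object@containerDiameter / 2 * (1 + 1e-9)))
            msg <- c(msg, "all copy reference points must lie inside the container")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EnsembleModel
#'
#' @param chains list of [SpherocylinderChain-class] copies.
#' @param containerDiameter bounding-sphere diameter (\eqn{\mathrm{\AA}}).
#' @param windowSigma Gaussian window standard deviation \eqn{\sigma_w}
#'   (\eqn{\mathrm{\AA}}); use \code{Inf} for no window.
#' @return An [EnsembleModel-class] object.
#' @export
ensembleModel <- function(chains, containerDiameter, windowSigma = Inf) {
    new("EnsembleModel", chains = chains,
        containerDiameter = as.numeric(containerDiameter),
        windowSigma = as.numeric(windowSigma))
}

#' Result of a reverse-Monte-Carlo fit
#'
#' Holds the refined structure, the objective trace across proposals, the
#' fitted global intensity scale, acceptance bookkeeping and the seed, so a
#' fit can be audited and reproduced.
#'
#' @slot model the final [GaussianBlobEnsemble-class] or [EnsembleModel-class].
#' @slot chi2Trace numeric, objective after the initial state and after each
#'   proposal; non-increasing under greedy acceptance.
#' @slot scale fitted global intensity scale factor.
#' @slot nAccepted,nRejected integer move counts; their sum is the number of
#'   proposals.
#' @slot seed integer seed the fit was run with.
#' @slot config the fit configuration list used.
#' @exportClass FitResult
setClass("FitResult",
    representation(model = "ANY", chi2Trace = "numeric", scale = "numeric",
                   nAccepted = "integer", nRejected = "integer",
                   seed = "integer", config = "list"))

setValidity("FitResult", function(object) {
    msg <- character()
    tr <- object@chi2Trace
    if (length(tr) > 1L && any(diff(tr) > 1e-9 * pmax(tr[-length(tr)], 1)))
        msg <- c(msg, "chi2Trace must be non-increasing")
    if (object@nAccepted + object@nRejected != length(tr) - 1L)
        msg <- c(msg, "nAccepted + nRejected must equal the number of proposals")
    if (length(msg)) msg else TRUE
})
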
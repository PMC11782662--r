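# Scattering intensities of blob and spherocylinder ensembles: Gaussian
# form amplitudes, window weighting, orientation-averaged coherent sums and
# the exact Debye oracle.

#' Gaussian blob form amplitude
#'
#' Scattering amplitude of a normalised isotropic 3-D Gaussian density of
#' standard deviation \code{sigmaBlob}:
#' \eqn{f(q) = \exp(-q^2\sigma^2/2)}, with \eqn{f(0) = 1}. Both the real- and
#' reciprocal-space representations of a blob are Gaussian, which is what
#' makes blob ensembles convenient for fitting.
#'
#' @param q momentum transfer (\eqn{\mathrm{\AA}^{-1}}), scalar or vector, \eqn{q \ge 0}.
#' @param sigmaBlob blob standard deviation (\eqn{\mathrm{\AA}}), positive.
#' @return Amplitude value(s) in (0, 1].
#' @examples
#' blobFormAmplitude(0, 40)          # 1
#' blobFormAmplitude(1 / 40, 40)     # exp(-1/2)
#' @export
blobFormAmplitude <- function(q, sigmaBlob) {
    stopifnotScalarPositive(sigmaBlob, "sigmaBlob")
    if (any(q < 0)) stop("q must be nonnegative", call. = FALSE)
    exp(-q^2 * sigmaBlob^2 / 2)
}

#' Gaussian window weight
#'
#' Weight \eqn{\exp(-|r - r_{cm}|^2 / (2\sigma_w^2))} applied to every copy
#' amplitude so that the container's own form factor is suppressed and only
#' internal structure contributes to the fitted signal. Equals 1 at the
#' window centre and decays outward.
#'
#' @param position a length-3 point or an N x 3 matrix (\eqn{\mathrm{\AA}}).
#' @param center window centre, normally the ensemble centre of mass.
#' @param windowSigma window standard deviation \eqn{\sigma_w}
#'   (\eqn{\mathrm{\AA}}); \code{Inf} gives weight 1 everywhere.
#' @return Weight(s) in (0, 1].
#' @export
windowWeight <- function(position, center = c(0, 0, 0), windowSigma) {
    if (!is.numeric(windowSigma) || length(windowSigma) != 1L ||
        is.na(windowSigma) || windowSigma <= 0)
        stop("'windowSigma' must be a single positive number (possibly Inf)",
             call. = FALSE)
    if (is.null(dim(position))) position <- matrix(position, ncol = 3)
    if (!is.finite(windowSigma)) return(rep(1, nrow(position)))
    d2 <- rowSums(sweep(position, 2, center)^2)
    exp(-d2 / (2 * windowSigma^2))
}

#' Random orientation set for the momentum-transfer direction
#'
#' M unit vectors drawn uniformly on the sphere under the given seed. A fit
#' reuses one fixed set for every objective evaluation so that the greedy
#' acceptance decision is deterministic.
#'
#' @param m number of directions (the full-scale default is 300).
#' @param seed integer seed.
#' @return An M x 3 matrix of unit rows, with the seed kept as an attribute.
#' @export
orientationSet <- function(m = 300, seed = 1) {
    if (m < 1) stop("at least one orientation required", call. = FALSE)
    dirs <- withSeed(seed, randomUnitVectors(m))
    attr(dirs, "seed") <- as.integer(seed)
    dirs
}

#' Complex scattering amplitude of a spherocylinder chain
#'
#' Coherent amplitude \eqn{A(\vec q) = \sum_b v_b e^{-q^2\sigma_b^2/2}
#' e^{i \vec q \cdot \vec r_b}} over the chain's Gaussian-bead
#' decomposition; segments therefore sum with correct relative phases. At
#' \eqn{q \to 0} the modulus tends to the chain volume (unit contrast).
#'
#' @param chain a [SpherocylinderChain-class].
#' @param qVector one 3-D momentum-transfer vector, or an M x 3 matrix of
#'   them (\eqn{\mathrm{\AA}^{-1}}).
#' @return Complex amplitude(s), one per row of \code{qVector}.
#' @examples
#' rod <- spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 300, 12)
#' Mod(spherocylinderAmplitude(rod, c(0, 0, 0)))  # chain volume
#' @export
spherocylinderAmplitude <- function(chain, qVector) {
    if (is.null(dim(qVector))) qVector <- matrix(qVector, ncol = 3)
    bd <- chainBeads(chain)
    qmag <- sqrt(rowSums(qVector^2))
    dirs <- qVector
    nz <- qmag > 0
    dirs[nz, ] <- qVector[nz, , drop = FALSE] / qmag[nz]
    dirs[!nz, ] <- matrix(rep(c(0, 0, 1), sum(!nz)), ncol = 3, byrow = TRUE)
    out <- complex(length(qmag))
    for (i in seq_along(qmag)) {
        G <- cpp_phase_sum(bd$positions, bd$weights, qmag[i],
                           dirs[i, , drop = FALSE])
        out[i] <- G[1, 1]
    }
    out * exp(-qmag^2 * bd$sigma^2 / 2)
}

# Internal: bead groups (positions, weights incl. per-copy window weight,
# common bead sigma) for either model kind.
modelBeadGroups <- function(model, windowSigma = NULL, windowCenter = NULL) {
    if (is(model, "GaussianBlobEnsemble")) {
        if (is.null(windowSigma)) windowSigma <- Inf
        pos <- model@centers
        if (is.null(windowCenter)) windowCenter <- colMeans(pos)
        w <- windowWeight(pos, windowCenter, windowSigma)
        return(list(list(positions = pos, weights = w,
                         sigma = model@sigmaBlob)))
    }
    if (!is(model, "EnsembleModel"))
        stop("unsupported model type", call. = FALSE)
    if (length(model@chains) == 0L) stop("empty model", call. = FALSE)
    if (is.null(windowSigma)) windowSigma <- model@windowSigma
    cen <- t(vapply(model@chains, chainCentroid, numeric(3)))
    if (is.null(windowCenter)) {
        v <- vapply(model@chains, function(ch) sum(segmentVolumes(ch)),
                    numeric(1))
        windowCenter <- colSums(cen * v) / sum(v)
    }
    wcopy <- windowWeight(cen, windowCenter, windowSigma)
    beads <- lapply(seq_along(model@chains), function(i) {
        bd <- chainBeads(model@chains[[i]])
        bd$weights <- bd$weights * wcopy[i]
        bd
    })
    sig <- unique(vapply(beads, `[[`, numeric(1), "sigma"))
    if (length(sig) == 1L) {
        list(list(positions = do.call(rbind, lapply(beads, `[[`, "positions")),
                  weights = unlist(lapply(beads, `[[`, "weights")),
                  sigma = sig))
    } else beads
}

#' Orientation-averaged ensemble intensity
#'
#' \eqn{I(q) = \frac{1}{M}\sum_m \left|\sum_j w_j A_j(q\,\hat n_m)\right|^2},
#' where \eqn{w_j} is the Gaussian window weight of copy \eqn{j} and
#' \eqn{A_j} its amplitude with the phase of its position. The same finite
#' orientation set is used at every \eqn{q}, matching the Monte-Carlo
#' orientation average used during fitting.
#'
#' @param model a [GaussianBlobEnsemble-class] or [EnsembleModel-class].
#' @param qGrid positive increasing momentum-transfer values
#'   (\eqn{\mathrm{\AA}^{-1}}).
#' @param orientations an M x 3 matrix from [orientationSet()].
#' @param windowSigma window width override; defaults to the model's slot
#'   (ensembles) or \code{Inf} (blob ensembles).
#' @param windowCenter window centre override; defaults to the
#'   mass-weighted centre of the copies.
#' @return Nonnegative intensities on \code{qGrid} (arbitrary units).
#' @examples
#' one <- gaussianBlobEnsemble(matrix(0, 1, 3), 40, 100)
#' q <- seq(0.002, 0.03, length.out = 5)
#' all.equal(ensembleIntensity(one, q, orientationSet(10, 1)), exp(-q^2 * 40^2))
#' @export
ensembleIntensity <- function(model, qGrid, orientations = orientationSet(),
                              windowSigma = NULL, windowCenter = NULL) {
    if (any(qGrid < 0)) stop("qGrid must be nonnegative", call. = FALSE)
    groups <- modelBeadGroups(model, windowSigma, windowCenter)
    G <- 0
    for (g in groups) {
        f <- exp(-qGrid^2 * g$sigma^2 / 2)
        G <- G + cpp_phase_sum(g$positions, g$weights, qGrid, orientations) * f
    }
    rowMeans(Mod(G)^2)
}

#' Exact orientation-averaged intensity (Debye formula)
#'
#' Brute-force oracle
#' \eqn{I(q) = f(q)^2 \sum_j\sum_k w_j w_k \,\mathrm{sinc}(q r_{jk})} with
#' the \eqn{j = k} term equal to \eqn{w_j^2}; the exact orientational
#' average that [ensembleIntensity()] approaches as the orientation count
#' grows.
#'
#' @param points N x 3 matrix of scatterer positions (\eqn{\mathrm{\AA}}).
#' @param weights numeric N scatterer weights.
#' @param formAmplitude function of \eqn{q} returning the common form
#'   amplitude (defaults to 1, point scatterers).
#' @param qGrid momentum-transfer values (\eqn{\mathrm{\AA}^{-1}}).
#' @return Intensities on \code{qGrid}.
#' @export
debyeIntensity <- function(points, weights = rep(1, nrow(points)),
                           formAmplitude = function(q) rep(1, length(q)),
                           qGrid) {
    if (is.null(dim(points))) points <- matrix(points, ncol = 3)
    if (length(weights) != nrow(points))
        stop("one weight per point required", call. = FALSE)
    formAmplitude(qGrid)^2 * cpp_debye(points, weights, qGrid)
}

#' Fit resolution of a Gaussian window
#'
#' The smallest resolvable momentum transfer \eqn{2\pi/\sigma_w} implied by
#' a window of width \eqn{\sigma_w}: 3000 \eqn{\mathrm{\AA}} gives
#' \eqn{\approx 0.002~\mathrm{\AA}^{-1}}, 1500 \eqn{\mathrm{\AA}} gives
#' \eqn{\approx 0.004~\mathrm{\AA}^{-1}}. Fits below this resolution are
#' refused by [fitConfig()].
#'
#' @param windowSigma window standard deviation (\eqn{\mathrm{\AA}}).
#' @return Momentum transfer (\eqn{\mathrm{\AA}^{-1}}).
#' @export
fitResolution <- function(windowSigma) {
    stopifnotScalarPositive(windowSigma, "windowSigma")
    2 * pi / windowSigma
}
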
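# Real-space metrics for fitted structures: pair correlation in a bounded
# container, local nematic order, mass-fractal dimension, Guinier radius.

#' Radial distribution function in a bounded sphere
#'
#' \eqn{g(r)} as the ratio of observed pair counts per shell to the
#' expected counts for the same number of points distributed uniformly in
#' the same container. The uniform reference is estimated by Monte Carlo
#' (several seeded replicates, averaged), which handles the finite-volume
#' edge correction without shell-intersection formulas. A plateau at 1
#' means translational homogeneity; a fractal arrangement decays beyond the
#' nearest-neighbour peak without reaching 1.
#'
#' @param centers N x 3 matrix of particle centres (\eqn{\mathrm{\AA}});
#'   for chains use the [chainCentroid()]s.
#' @param rMax largest separation considered (\eqn{\mathrm{\AA}}), at most
#'   the container diameter.
#' @param dr shell width (\eqn{\mathrm{\AA}}).
#' @param containerDiameter bounding-sphere diameter (\eqn{\mathrm{\AA}}).
#' @param nReference number of uniform reference replicates.
#' @param seed seed for the reference replicates.
#' @return A data.frame with columns \code{r} (shell centres), \code{g} and
#'   \code{nPairs} (observed pair counts).
#' @export
radialDistribution <- function(centers, rMax, dr, containerDiameter,
                               nReference = 10, seed = 1) {
    if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
    if (nrow(centers) < 2L) stop("at least two centres required", call. = FALSE)
    stopifnotScalarPositive(dr, "dr")
    if (rMax > containerDiameter)
        stop("rMax must not exceed the container diameter", call. = FALSE)
    obs <- cpp_pair_hist(centers, rMax, dr)
    n <- nrow(centers)
    ref <- withSeed(seed, {
        acc <- 0
        for (i in seq_len(nReference))
            acc <- acc + cpp_pair_hist(
                uniformInSphere(n, containerDiameter / 2), rMax, dr)
        acc / nReference
    })
    nb <- length(obs)
    data.frame(r = dr * (seq_len(nb) - 0.5),
               g = ifelse(ref > 0, obs / ref, 0),
               nPairs = obs)
}

#' Local nematic order parameter in cubic boxes
#'
#' Partitions the container into an origin-centred grid of cubic boxes and,
#' in every box holding at least \code{minCount} particles, computes the
#' order-parameter tensor \eqn{T = \langle u \otimes u\rangle - I/3} over
#' the particle axes and reports \eqn{S = \frac{3}{2} e} with \eqn{e} its
#' largest eigenvalue. \eqn{S} is 0 for isotropic axes (up to finite-count
#' bias), 1 for perfect alignment, and is invariant under per-particle sign
#' flips \eqn{u \to -u}. Boxes below the count cutoff are omitted because
#' small samples make the estimator unreliable.
#'
#' @param positions N x 3 matrix of particle reference points
#'   (\eqn{\mathrm{\AA}}).
#' @param axes N x 3 matrix of unit axis vectors, one per particle.
#' @param boxSize cubic box side (\eqn{\mathrm{\AA}}); default 400.
#' @param minCount minimum particles per reported box; default 30.
#' @return A data.frame with box centre coordinates, particle count
#'   \code{n} and \code{S}; zero rows when no box qualifies.
#' @export
nematicOrder <- function(positions, axes, boxSize = 400, minCount = 30) {
    if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
    if (is.null(dim(axes))) axes <- matrix(axes, ncol = 3)
    if (nrow(positions) != nrow(axes))
        stop("one axis per particle required", call. = FALSE)
    if (any(abs(sqrt(rowSums(axes^2)) - 1) > 1e-6))
        stop("axes must be unit vectors", call. = FALSE)
    idx <- floor(sweep(positions, 2, 0) / boxSize + 0.5)  # origin-centred grid
    key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = "_")
    groups <- split(seq_len(nrow(positions)), key)
    groups <- groups[lengths(groups) >= minCount]
    if (length(groups) == 0L)
        return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          n = integer(0), S = numeric(0)))
    rows <- lapply(groups, function(g) {
        u <- axes[g, , drop = FALSE]
        Tm <- crossprod(u) / nrow(u) - diag(3) / 3
        e <- max(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values)
        c(colMeans(matrix(idx[g[1], ], 1, 3)) * boxSize, length(g), 1.5 * e)
    })
    out <- do.call(rbind, rows)
    data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
               n = as.integer(out[, 4]), S = out[, 5], row.names = NULL)
}

#' Mass-fractal dimension from a power-law scattering regime
#'
#' Fits a least-squares line to \eqn{\log I} versus \eqn{\log q} inside the
#' window and reports \eqn{d = -\mathrm{slope}} with its regression
#' standard error: a mass fractal of dimension \eqn{d} scatters as
#' \eqn{I(q) \propto q^{-d}}. When the constituent particle's form factor
#' is known (e.g. the blob width of a simulated structure), pass its
#' amplitude via \code{formFactor}: the fit is then performed on the
#' structure factor \eqn{S(q) = I(q)/f(q)^2}, the standard
#' \eqn{I = P \cdot S} decomposition, so the estimate reflects the particle
#' arrangement rather than the particle shape.
#'
#' @param profile a [ScatteringProfile-class].
#' @param qWindow length-2 window (\eqn{\mathrm{\AA}^{-1}}); default
#'   0.002-0.02.
#' @param formFactor optional function of \eqn{q} returning the constituent
#'   form amplitude \eqn{f(q)} to divide out (as \eqn{f^2}) before fitting.
#' @return A list of class \code{"FractalFit"} with \code{d}, \code{stderr}
#'   and \code{qWindow}.
#' @examples
#' q <- seq(0.002, 0.02, length.out = 20)
#' fractalDimension(scatteringProfile(q, q^-2))$d   # exactly 2
#' @export
fractalDimension <- function(profile, qWindow = c(0.002, 0.02),
                             formFactor = NULL) {
    q <- qValues(profile)
    idx <- q >= qWindow[1] & q <= qWindow[2]
    if (sum(idx) < 5L)
        stop("at least 5 points required inside the window", call. = FALSE)
    I <- intensities(profile)[idx]
    if (!is.null(formFactor)) I <- I / formFactor(q[idx])^2
    if (any(I <= 0))
        stop("non-positive intensities inside the window", call. = FALSE)
    x <- log(q[idx]); y <- log(I)
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    n <- length(x)
    # explicit slope standard error (a perfect power law has stderr 0)
    se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) /
               sum((x - mean(x))^2))
    structure(list(d = -slope, stderr = se, qWindow = qWindow),
              class = "FractalFit")
}

#' @export
print.FractalFit <- function(x, ...) {
    cat(sprintf("Fractal dimension d = %.3f +/- %.3f (q in [%.4g, %.4g] A^-1)\n",
                x$d, x$stderr, x$qWindow[1], x$qWindow[2]))
    invisible(x)
}

#' Guinier radius of gyration
#'
#' Iterative Guinier analysis: fits \eqn{\ln I} versus \eqn{q^2} over the
#' low-q points, restricting the admitted range to \eqn{q R_g \le} the
#' limit and refitting until the admitted set is stable. For a Gaussian
#' profile \eqn{I = \exp(-q^2\sigma^2)} this returns
#' \eqn{R_g = \sqrt{3}\,\sigma} exactly.
#'
#' @param profile a [ScatteringProfile-class] with low-q points.
#' @param qRgLimit admitted-range criterion, default 1.3.
#' @return Radius of gyration (\eqn{\mathrm{\AA}}).
#' @export
guinierRg <- function(profile, qRgLimit = 1.3) {
    q <- qValues(profile)
    I <- intensities(profile)
    keep <- I > 0
    q <- q[keep]; I <- I[keep]
    if (length(q) < 3L) stop("no admissible points for Guinier analysis",
                             call. = FALSE)
    idx <- seq_along(q)
    for (iter in 1:50) {
        if (length(idx) < 3L)
            stop("no admissible points for Guinier analysis", call. = FALSE)
        fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2))
        slope <- stats::coef(fit)[2]
        if (slope >= 0)
            stop("no admissible points for Guinier analysis", call. = FALSE)
        rg <- sqrt(-3 * slope)
        newIdx <- which(q * rg <= qRgLimit)
        if (identical(newIdx, idx)) break
        idx <- newIdx
    }
    unname(rg)
}
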
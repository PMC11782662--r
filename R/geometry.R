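# Spherocylinder-chain geometry: presets, derived quantities, bead
# decomposition for scattering, clash detection and the moves used by the
# reverse-Monte-Carlo refinement.

#' Preset chain geometries
#'
#' The three rod models used to approximate an elongated coiled-coil dimer:
#' model 1 is a single spherocylinder (R = 12, L = 300), model 2 two linked
#' segments (155 + 135), model 3 three linked segments (155 + 76 + 50), all
#' with radius 12 (lengths in \eqn{\mathrm{\AA}}). \code{"blobs"} is accepted
#' as a geometry name by the fitting configuration but has no chain preset.
#'
#' @param name one of \code{"model1"}, \code{"model2"}, \code{"model3"}.
#' @return A list with elements \code{name}, \code{lengths} and \code{radius}.
#' @examples
#' modelGeometry("model3")$lengths
#' @export
modelGeometry <- function(name = c("model1", "model2", "model3")) {
    name <- match.arg(name)
    lengths <- switch(name,
        model1 = 300,
        model2 = c(155, 135),
        model3 = c(155, 76, 50))
    list(name = name, lengths = lengths, radius = 12)
}

#' Spherocylinder volume
#'
#' \eqn{V = \pi R^2 L + \frac{4}{3}\pi R^3} per segment, summed over a chain.
#'
#' @param lengths core cylinder length(s) (\eqn{\mathrm{\AA}}).
#' @param radius spherocylinder radius (\eqn{\mathrm{\AA}}).
#' @return Volume in \eqn{\mathrm{\AA}^3}.
#' @export
spherocylinderVolume <- function(lengths, radius) {
    sum(pi * radius^2 * lengths + 4 / 3 * pi * radius^3)
}

segmentVolumes <- function(chain) {
    pi * chain@radius^2 * chain@lengths + 4 / 3 * pi * chain@radius^3
}

#' Derived segment start points of a chain
#'
#' Row \eqn{i} is the core start of segment \eqn{i}; by the joint rule it is
#' the end cap-centre of segment \eqn{i-1}.
#'
#' @param chain a [SpherocylinderChain-class].
#' @return A k x 3 matrix (\eqn{\mathrm{\AA}}).
#' @export
segmentStarts <- function(chain) {
    k <- length(chain@lengths)
    out <- matrix(0, k, 3)
    p <- chain@start
    for (i in seq_len(k)) {
        out[i, ] <- p
        p <- p + chain@lengths[i] * chain@axes[i, ]
    }
    out
}

chainEnd <- function(chain) {
    k <- length(chain@lengths)
    segmentStarts(chain)[k, ] + chain@lengths[k] * chain@axes[k, ]
}

#' Inter-segment angles of a chain
#'
#' Angles between consecutive segments in the stretched/folded convention:
#' 180 degrees for a collinear continuation, 0 degrees for a chain folded
#' back onto itself. For a three-segment chain the two values are the angles
#' usually called alpha (segments 1-2) and beta (segments 2-3).
#'
#' @param chain a [SpherocylinderChain-class].
#' @return Numeric vector of length k - 1 (degrees), empty for one segment.
#' @export
segmentAngles <- function(chain) {
    k <- length(chain@lengths)
    if (k < 2L) return(numeric(0))
    vapply(seq_len(k - 1L), function(i) {
        ca <- sum(chain@axes[i, ] * chain@axes[i + 1L, ])
        180 - acos(pmin(1, pmax(-1, ca))) * 180 / pi
    }, numeric(1))
}

#' Mass-weighted chain centroid
#'
#' Centroid of the segment core midpoints weighted by segment volume; used
#' as the copy reference point for placement, window weighting and the
#' radial distribution function.
#'
#' @param chain a [SpherocylinderChain-class].
#' @return Length-3 numeric (\eqn{\mathrm{\AA}}).
#' @export
chainCentroid <- function(chain) {
    st <- segmentStarts(chain)
    mid <- st + chain@axes * (chain@lengths / 2)
    v <- segmentVolumes(chain)
    colSums(mid * v) / sum(v)
}

#' Aspect ratio of a chain
#'
#' Summed core length divided by the diameter \eqn{2R}; for the single
#' 300 x 12 rod this is 12.5.
#'
#' @param chain a [SpherocylinderChain-class] or a [modelGeometry()] preset.
#' @return Dimensionless aspect ratio.
#' @export
aspectRatio <- function(chain) {
    if (is(chain, "SpherocylinderChain"))
        sum(chain@lengths) / (2 * chain@radius)
    else sum(chain$lengths) / (2 * chain$radius)
}

# --- bead decomposition ----------------------------------------------------

# Axial slice decomposition of one spherocylinder: slice centres z (measured
# from the core start along the axis, covering [-R, L+R]) and slice volumes.
# Volumes integrate pi r^2(z) analytically per slice, so they sum exactly to
# the spherocylinder volume. Bead width sigma = R/2 reproduces the
# cross-section radius of gyration of a uniform disc.
beadTemplate <- local({
    cache <- new.env(parent = emptyenv())
    capInt <- function(a, b, R) {
        # integral of (R^2 - u^2) over [a, b]
        (R^2 * b - b^3 / 3) - (R^2 * a - a^3 / 3)
    }
    sliceVolume <- function(z0, z1, L, R) {
        v <- 0
        lo <- max(z0, -R); hi <- min(z1, 0)
        if (hi > lo) v <- v + capInt(lo, hi, R)
        lo <- max(z0, 0); hi <- min(z1, L)
        if (hi > lo) v <- v + R^2 * (hi - lo)
        lo <- max(z0, L); hi <- min(z1, L + R)
        if (hi > lo) v <- v + capInt(lo - L, hi - L, R)
        pi * v
    }
    function(L, R, spacing = R / 2) {
        key <- sprintf("%.9g_%.9g_%.9g", L, R, spacing)
        if (!is.null(cache[[key]])) return(cache[[key]])
        total <- L + 2 * R
        n <- ceiling(total / spacing)
        h <- total / n
        edges <- -R + h * (0:n)
        z <- (edges[-1] + edges[-(n + 1)]) / 2
        w <- vapply(seq_len(n), function(i)
            sliceVolume(edges[i], edges[i + 1], L, R), numeric(1))
        out <- list(z = z, w = w, sigma = R / 2)
        cache[[key]] <- out
        out
    }
})

#' Gaussian-bead decomposition of a chain
#'
#' Represents each segment as a dense axial line of Gaussian beads (spacing
#' at most R/2, bead width R/2, slice-volume weights), giving a uniform code
#' path with the Gaussian-blob scattering machinery and phase-correct
#' amplitudes for linked segments. The weights sum exactly to the chain
#' volume.
#'
#' @param chain a [SpherocylinderChain-class].
#' @param spacing maximum bead spacing (\eqn{\mathrm{\AA}}); default R/2.
#' @return A list with \code{positions} (n x 3), \code{weights}
#'   (\eqn{\mathrm{\AA}^3}) and \code{sigma} (bead width, \eqn{\mathrm{\AA}}).
#' @export
chainBeads <- function(chain, spacing = chain@radius / 2) {
    st <- segmentStarts(chain)
    k <- length(chain@lengths)
    pos <- vector("list", k); wts <- vector("list", k)
    for (i in seq_len(k)) {
        tp <- beadTemplate(chain@lengths[i], chain@radius, spacing)
        pos[[i]] <- st[rep(i, length(tp$z)), , drop = FALSE] +
            outer(tp$z, chain@axes[i, ])
        wts[[i]] <- tp$w
    }
    list(positions = do.call(rbind, pos), weights = unlist(wts),
         sigma = chain@radius / 2)
}

# --- construction and moves ------------------------------------------------

#' Extend a chain by rolling a new cap onto its end
#'
#' Appends a segment whose core starts at the previous segment's end
#' cap-centre (the "rolled" contact point) with the requested axis, so the
#' joint coincides exactly and the inter-segment angle equals the angle
#' between \code{targetAxis} and the previous axis.
#'
#' @param chain a [SpherocylinderChain-class] with fewer than 3 segments.
#' @param newLength core length of the appended segment (\eqn{\mathrm{\AA}}).
#' @param targetAxis direction of the appended segment (normalised
#'   internally).
#' @return The extended [SpherocylinderChain-class].
#' @examples
#' rod <- spherocylinderChain(c(0, 0, 0), c(0, 0, 1), 155, 12)
#' two <- rollCapExtend(rod, 135, c(0, 0, 1))   # stretched, alpha = 180 deg
#' segmentAngles(two)
#' @export
rollCapExtend <- function(chain, newLength, targetAxis) {
    if (length(chain@lengths) >= 3L)
        stop("chain already has 3 segments", call. = FALSE)
    stopifnotScalarPositive(newLength, "newLength")
    spherocylinderChain(chain@start,
        rbind(chain@axes, normalize(as.numeric(targetAxis))),
        c(chain@lengths, newLength), chain@radius)
}

translateChain <- function(chain, delta) {
    spherocylinderChain(chain@start + delta, chain@axes, chain@lengths,
                        chain@radius)
}

rotateChainAbout <- function(chain, rot, pivot) {
    spherocylinderChain(pivot + as.numeric(rot %*% (chain@start - pivot)),
        chain@axes %*% t(rot), chain@lengths, chain@radius)
}

# Reorient segment s (and, for s >= 2, everything downstream) about the
# joint it shares with the fixed part of the chain; links are preserved by
# construction. For s = 1 the pivot is the joint with segment 2 (or, for a
# single rod, the centroid), so only segment 1 swings.
reorientSegment <- function(chain, s, rot) {
    k <- length(chain@lengths)
    axes <- chain@axes
    if (s == 1L) {
        if (k == 1L) return(rotateChainAbout(chain, rot, chainCentroid(chain)))
        pivot <- chain@start + chain@lengths[1] * axes[1, ]
        a1 <- as.numeric(rot %*% axes[1, ])
        start <- pivot - chain@lengths[1] * a1
        axes[1, ] <- a1
        return(spherocylinderChain(start, axes, chain@lengths, chain@radius))
    }
    idx <- s:k
    axes[idx, ] <- axes[idx, , drop = FALSE] %*% t(rot)
    spherocylinderChain(chain@start, axes, chain@lengths, chain@radius)
}

# Random chain of the given geometry with its centroid at `at`; axes drawn
# uniformly on the sphere from the current RNG stream.
randomChain <- function(geometry, at = c(0, 0, 0)) {
    axes <- randomUnitVectors(length(geometry$lengths))
    ch <- spherocylinderChain(c(0, 0, 0), axes, geometry$lengths,
                              geometry$radius)
    translateChain(ch, at - chainCentroid(ch))
}

# --- clash detection -------------------------------------------------------

#' Minimum distance between two spherocylinder core segments
#'
#' @param p1,p2 segment core start points (length 3).
#' @param d1,d2 unit axis directions.
#' @param l1,l2 core lengths (\eqn{\mathrm{\AA}}).
#' @return The minimum Euclidean distance between the two core line
#'   segments (\eqn{\mathrm{\AA}}).
#' @export
segmentDistance <- function(p1, d1, l1, p2, d2, l2) {
    cpp_seg_dist(as.numeric(p1), as.numeric(d1), l1,
                 as.numeric(p2), as.numeric(d2), l2)
}

# 7-column segment table (start, axis, length) for a list of chains
chainSegTable <- function(chains) {
    rows <- lapply(seq_along(chains), function(i) {
        ch <- chains[[i]]
        st <- segmentStarts(ch)
        cbind(st, ch@axes, ch@lengths)
    })
    tab <- do.call(rbind, rows)
    id <- rep.int(seq_along(chains),
                  vapply(chains, function(ch) length(ch@lengths), integer(1)))
    list(segs = tab, chainId = as.integer(id))
}

#' Do two chains clash?
#'
#' Two chains clash when any pair of core segments approaches closer than
#' the sum of the radii. Consecutive segments within one chain share a cap
#' by construction and are exempt; non-consecutive segments of a folded
#' three-segment chain are checked by [clashWithinChain()].
#'
#' @param chainA,chainB [SpherocylinderChain-class] objects.
#' @return \code{TRUE} if the chains clash.
#' @export
clashCheck <- function(chainA, chainB) {
    sa <- segmentStarts(chainA); sb <- segmentStarts(chainB)
    lim <- chainA@radius + chainB@radius
    for (i in seq_along(chainA@lengths))
        for (j in seq_along(chainB@lengths))
            if (cpp_seg_dist(sa[i, ], chainA@axes[i, ], chainA@lengths[i],
                             sb[j, ], chainB@axes[j, ], chainB@lengths[j]) < lim)
                return(TRUE)
    FALSE
}

#' Internal clash of a folded chain
#'
#' Checks non-consecutive segment pairs of a single chain (segments 1 and 3
#' of a three-segment chain) against the 2R core-distance rule; consecutive
#' segments are exempt at their shared joint.
#'
#' @param chain a [SpherocylinderChain-class].
#' @return \code{TRUE} if non-consecutive segments clash.
#' @export
clashWithinChain <- function(chain) {
    k <- length(chain@lengths)
    if (k < 3L) return(FALSE)
    st <- segmentStarts(chain)
    cpp_seg_dist(st[1, ], chain@axes[1, ], chain@lengths[1],
                 st[3, ], chain@axes[3, ], chain@lengths[3]) < 2 * chain@radius
}
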
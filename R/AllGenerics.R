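#' Accessors for condensaxs classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{qValues}, \code{intensities}, \code{uncertainties} for profiles;
#' \code{blobCenters}, \code{sigmaBlob} for blob ensembles; \code{chains},
#' \code{nCopies}, \code{windowSigma}, \code{containerDiameter} for
#' ensembles; \code{chi2Trace}, \code{finalModel}, \code{fitScale} for fit
#' results.
#'
#' @param object an object of the matching class.
#' @return The slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("uncertainties", function(object) standardGeneric("uncertainties"))
#' @rdname accessors
#' @export
setGeneric("blobCenters", function(object) standardGeneric("blobCenters"))
#' @rdname accessors
#' @export
setGeneric("sigmaBlob", function(object) standardGeneric("sigmaBlob"))
#' @rdname accessors
#' @export
setGeneric("containerDiameter", function(object) standardGeneric("containerDiameter"))
#' @rdname accessors
#' @export
setGeneric("chains", function(object) standardGeneric("chains"))
#' @rdname accessors
#' @export
setGeneric("nCopies", function(object) standardGeneric("nCopies"))
#' @rdname accessors
#' @export
setGeneric("windowSigma", function(object) standardGeneric("windowSigma"))
#' @rdname accessors
#' @export
setGeneric("chi2Trace", function(object) standardGeneric("chi2Trace"))
#' @rdname accessors
#' @export
setGeneric("finalModel", function(object) standardGeneric("finalModel"))
#' @rdname accessors
#' @export
setGeneric("fitScale", function(object) standardGeneric("fitScale"))

#' @rdname accessors
setMethod("qValues", "ScatteringProfile", function(object) object@q)
#' @rdname accessors
setMethod("intensities", "ScatteringProfile", function(object) object@intensity)
#' @rdname accessors
setMethod("uncertainties", "ScatteringProfile", function(object)
    if (length(object@uncertainty)) object@uncertainty else NULL)

#' @rdname accessors
setMethod("blobCenters", "GaussianBlobEnsemble", function(object) object@centers)
#' @rdname accessors
setMethod("sigmaBlob", "GaussianBlobEnsemble", function(object) object@sigmaBlob)
#' @rdname accessors
setMethod("containerDiameter", "GaussianBlobEnsemble",
          function(object) object@containerDiameter)
#' @rdname accessors
setMethod("nCopies", "GaussianBlobEnsemble", function(object) nrow(object@centers))

#' @rdname accessors
setMethod("chains", "EnsembleModel", function(object) object@chains)
#' @rdname accessors
setMethod("nCopies", "EnsembleModel", function(object) length(object@chains))
#' @rdname accessors
setMethod("containerDiameter", "EnsembleModel",
          function(object) object@containerDiameter)
#' @rdname accessors
setMethod("windowSigma", "EnsembleModel", function(object) object@windowSigma)

#' @rdname accessors
setMethod("chi2Trace", "FitResult", function(object) object@chi2Trace)
#' @rdname accessors
setMethod("finalModel", "FitResult", function(object) object@model)
#' @rdname accessors
setMethod("fitScale", "FitResult", function(object) object@scale)

#' @describeIn accessors number of points in a profile
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @rdname accessors
setMethod("nPoints", "ScatteringProfile", function(object) length(object@q))

setMethod("show", "ScatteringProfile", function(object) {
    cat(sprintf("ScatteringProfile: %d points, q in [%.4g, %.4g] A^-1, %s\n",
        length(object@q), min(object@q), max(object@q),
        if (length(object@uncertainty)) "with uncertainties"
        else "no uncertainties"))
})

setMethod("show", "GaussianBlobEnsemble", function(object) {
    cat(sprintf(
        "GaussianBlobEnsemble: %d blobs, sigma = %.3g A, container D = %.4g A\n",
        nrow(object@centers), object@sigmaBlob, object@containerDiameter))
})

setMethod("show", "SpherocylinderChain", function(object) {
    k <- length(object@lengths)
    cat(sprintf("SpherocylinderChain: %d segment%s, R = %.3g A, L = %s A",
        k, if (k > 1) "s" else "", object@radius,
        paste(signif(object@lengths, 4), collapse = " + ")))
    if (k > 1)
        cat(sprintf("; angles = %s deg",
            paste(sprintf("%.1f", segmentAngles(object)), collapse = ", ")))
    cat("\n")
})

setMethod("show", "EnsembleModel", function(object) {
    cat(sprintf(
        "EnsembleModel: %d copies, container D = %.4g A, sigma_w = %.4g A\n",
        length(object@chains), object@containerDiameter, object@windowSigma))
})

setMethod("show", "FitResult", function(object) {
    tr <- object@chi2Trace
    cat(sprintf(
        "FitResult: chi2 %.4g -> %.4g over %d proposals (%d accepted), scale = %.4g, seed = %d\n",
        tr[1], tr[length(tr)], length(tr) - 1L, object@nAccepted,
        object@scale, object@seed))
})
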
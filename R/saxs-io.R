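# Readers and writers for the plain-text interchange formats: 3-column
# SAXS profiles, pseudo-atom PDB and the XYZ-with-axis structure table.

#' Read a 1-D SAXS profile from text
#'
#' Whitespace- or comma-separated 2- or 3-column numeric text (q,
#' intensity, optional uncertainty); lines starting with '#' are comments.
#' Rows with non-positive q or non-positive intensity are dropped with a
#' message reporting the count.
#'
#' @param path file path.
#' @return A [ScatteringProfile-class].
#' @export
readSAXSProfile <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
    fields <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
    ncols <- unique(lengths(fields))
    if (length(ncols) != 1L || !ncols %in% 2:3)
        stop("expected 2 or 3 numeric columns in ", path, call. = FALSE)
    vals <- suppressWarnings(vapply(fields, as.numeric, numeric(ncols)))
    bad <- which(apply(is.na(vals), 2, any))
    if (length(bad))
        stop(sprintf("non-numeric content in %s at data line %d", path,
                     bad[1]), call. = FALSE)
    vals <- t(vals)
    drop_ <- vals[, 1] <= 0 | vals[, 2] <= 0
    if (any(drop_))
        message(sprintf("dropped %d row(s) with non-positive q or intensity",
                        sum(drop_)))
    vals <- vals[!drop_, , drop = FALSE]
    o <- order(vals[, 1])
    vals <- vals[o, , drop = FALSE]
    scatteringProfile(vals[, 1], vals[, 2],
                      if (ncols == 3L) vals[, 3] else NULL)
}

#' Write a SAXS profile as 3-column text
#'
#' @param profile a [ScatteringProfile-class].
#' @param path output path.
#' @return The path, invisibly. Values are written with 6 significant
#'   digits beyond round-trip needs (\code{\%.8e}).
#' @export
writeSAXSProfile <- function(profile, path) {
    unc <- uncertainties(profile)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# q(A^-1) intensity uncertainty", con)
    if (is.null(unc))
        writeLines(sprintf("%.8e %.8e", qValues(profile),
                           intensities(profile)), con)
    else
        writeLines(sprintf("%.8e %.8e %.8e", qValues(profile),
                           intensities(profile), unc), con)
    invisible(path)
}

#' Write a structure as a pseudo-atom PDB file
#'
#' One HETATM record per blob (blob ensembles) or per chain reference
#' point and segment midpoint (chain ensembles), coordinates in
#' \eqn{\mathrm{\AA}}. Intended for visual inspection in molecular
#' viewers, not for atomic interpretation.
#'
#' @param model a [GaussianBlobEnsemble-class] or [EnsembleModel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeStructurePDB <- function(model, path) {
    pts <- if (is(model, "GaussianBlobEnsemble")) blobCenters(model)
        else t(vapply(chains(model), chainCentroid, numeric(3)))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(pts))) {
        writeLines(sprintf(
            "HETATM%5d  C   BLB A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i %% 100000L, i %% 10000L, pts[i, 1], pts[i, 2], pts[i, 3]), con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Write a structure as an XYZ-with-axis table
#'
#' Plain-text table with one row per segment (chains) or per blob (blob
#' ensembles, axis zero): x, y, z of the segment core start, axis
#' components, core length, radius, segment index and chain id. This is
#' the format consumed by the structure metrics.
#'
#' @param model a [GaussianBlobEnsemble-class] or [EnsembleModel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeStructureXYZ <- function(model, path) {
    if (is(model, "GaussianBlobEnsemble")) {
        cen <- blobCenters(model)
        df <- data.frame(x = cen[, 1], y = cen[, 2], z = cen[, 3],
                         ax = 0, ay = 0, az = 0, length = 0,
                         radius = 0, segment = 1L,
                         chain = seq_len(nrow(cen)))
    } else {
        tab <- chainSegTable(chains(model))
        seg <- unlist(lapply(chains(model),
                             function(ch) seq_along(ch@lengths)))
        df <- data.frame(x = tab$segs[, 1], y = tab$segs[, 2],
                         z = tab$segs[, 3], ax = tab$segs[, 4],
                         ay = tab$segs[, 5], az = tab$segs[, 6],
                         length = tab$segs[, 7],
                         radius = vapply(chains(model)[tab$chainId],
                                         function(ch) ch@radius, numeric(1)),
                         segment = seg, chain = tab$chainId)
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", paste(names(df), collapse = " ")), con)
    writeLines(do.call(sprintf, c(
        list("%.6f %.6f %.6f %.8f %.8f %.8f %.6f %.6f %d %d"),
        as.list(df))), con)
    invisible(path)
}

#' Read an XYZ-with-axis structure table
#'
#' @param path a file written by [writeStructureXYZ()].
#' @param asModel reconstruct an [EnsembleModel-class] (requires
#'   \code{containerDiameter}); otherwise the raw table is returned.
#' @param containerDiameter,windowSigma container metadata for model
#'   reconstruction.
#' @return A data.frame, or an [EnsembleModel-class] when
#'   \code{asModel = TRUE}.
#' @export
readStructureXYZ <- function(path, asModel = FALSE,
                             containerDiameter = NULL, windowSigma = Inf) {
    df <- utils::read.table(path, header = FALSE, comment.char = "#",
        col.names = c("x", "y", "z", "ax", "ay", "az", "length",
                      "radius", "segment", "chain"))
    if (!asModel) return(df)
    if (is.null(containerDiameter))
        stop("containerDiameter required to rebuild a model", call. = FALSE)
    chs <- lapply(split(df, df$chain), function(d) {
        d <- d[order(d$segment), , drop = FALSE]
        spherocylinderChain(c(d$x[1], d$y[1], d$z[1]),
                            as.matrix(d[, c("ax", "ay", "az")]),
                            d$length, d$radius[1])
    })
    ensembleModel(unname(chs), containerDiameter, windowSigma)
}
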
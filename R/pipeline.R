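# One-call orchestration: simulate or read a profile, fit blobs, optionally
# place and refine rod copies, compute structure metrics, and leave a
# reproducible artifact directory behind.

pipelineStageNames <- c("simulate", "fit-blobs", "fit-cylinders", "metrics")

#' Run the droplet-modelling pipeline
#'
#' Executes the requested stages in order, writing every intermediate to
#' \code{outDir}: the (simulated or loaded) profile, fitted structures in
#' PDB and XYZ-with-axis form, \eqn{\chi^2} traces, and CSV tables for
#' g(r), the per-box nematic order and the fractal fit. A log records the
#' package version, a hash of the configuration, all seeds and per-stage
#' wall-clock times, so reruns with an identical configuration are
#' reproducible (deterministic stages are bit-identical).
#'
#' All randomness flows from \code{config$seed}; each stochastic stage
#' derives its own seed from it with a fixed offset.
#'
#' @param config a named list with \code{seed}, \code{stages} (subset of
#'   \code{"simulate"}, \code{"fit-blobs"}, \code{"fit-cylinders"},
#'   \code{"metrics"}) and per-stage parameter lists (\code{simulate},
#'   \code{profile}, \code{blobs}, \code{cylinders}, \code{metrics});
#'   unknown keys are rejected.
#' @param outDir artifact directory, created if needed.
#' @return Invisibly, a list with the stage outputs.
#' @export
runPipeline <- function(config, outDir) {
    allowed <- c("seed", "stages", "simulate", "profile", "blobs",
                 "cylinders", "metrics")
    unknown <- setdiff(names(config), allowed)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
    stages <- if (is.null(config$stages)) pipelineStageNames else config$stages
    if (!all(stages %in% pipelineStageNames))
        stop("unknown stage(s): ",
             paste(setdiff(stages, pipelineStageNames), collapse = ", "),
             call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(outDir, "run.log")
    cfgHash <- configHash(config)
    logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = log,
                                 append = TRUE)
    cat(sprintf("condensaxs %s\nconfig hash: %s\nseed: %d\n",
                as.character(utils::packageVersion("condensaxs")),
                cfgHash, as.integer(config$seed)),
        file = log)
    out <- list()
    runStage <- function(name, fun) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(fun(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
        logLine("stage %-14s %8.2f s", name,
                proc.time()[["elapsed"]] - t0)
        res
    }
    seed <- as.integer(config$seed)

    if ("simulate" %in% stages) {
        out$structure <- runStage("simulate", function() {
            p <- config$simulate
            structure_ <- generateRandomWalkStructure(
                n = p$n %||% 400, stepLength = p$stepLength %||% 200,
                seed = seed, sigmaBlob = p$sigmaBlob %||% 40,
                containerDiameter = p$containerDiameter,
                confineRadius = p$confineRadius)
            qGrid <- p$qGrid %||%
                exp(seq(log(0.002), log(0.03), length.out = 25))
            prof <- generateDropletProfile(structure_, qGrid,
                noiseFraction = p$noiseFraction %||% 0.02, seed = seed + 10L,
                windowSigma = p$windowSigma %||% Inf,
                nOrientations = p$nOrientations %||% 300)
            writeSAXSProfile(prof, file.path(outDir, "profile.dat"))
            writeStructureXYZ(structure_,
                              file.path(outDir, "true_structure.xyz"))
            list(structure = structure_, profile = prof)
        })
        profile <- out$structure$profile
    } else {
        if (is.null(config$profile$path))
            stop("config$profile$path required when not simulating",
                 call. = FALSE)
        profile <- readSAXSProfile(config$profile$path)
    }
    out$profile <- profile

    if ("fit-blobs" %in% stages) {
        out$blobFit <- runStage("fit-blobs", function() {
            cfg <- do.call(fitConfig, c(list(modelGeometry = "blobs"),
                config$blobs[setdiff(names(config$blobs), "modelGeometry")],
                if (is.null(config$blobs$seed)) list(seed = seed + 1L)))
            fit <- fitBlobs(profile, cfg)
            writeStructureXYZ(finalModel(fit), file.path(outDir, "blobs.xyz"))
            writeStructurePDB(finalModel(fit), file.path(outDir, "blobs.pdb"))
            utils::write.csv(data.frame(proposal =
                seq_along(chi2Trace(fit)) - 1L, chi2 = chi2Trace(fit)),
                file.path(outDir, "blob_chi2_trace.csv"), row.names = FALSE)
            logLine("blob fit seed %d, final chi2 %.6g", cfg$seed,
                    tail1(chi2Trace(fit)))
            fit
        })
    }

    if ("fit-cylinders" %in% stages) {
        if (is.null(out$blobFit))
            stop("fit-cylinders requires the fit-blobs stage", call. = FALSE)
        out$cylinderFit <- runStage("fit-cylinders", function() {
            p <- config$cylinders
            geomName <- p$modelGeometry %||% "model1"
            cfg <- do.call(fitConfig, c(list(modelGeometry = geomName),
                p[setdiff(names(p), "modelGeometry")],
                if (is.null(p$seed)) list(seed = seed + 2L)))
            init <- placeCopiesFromBlobs(out$blobFit, modelGeometry(geomName),
                                         cfg)
            fit <- refineCopies(profile, init, cfg)
            writeStructureXYZ(finalModel(fit),
                              file.path(outDir, "cylinders.xyz"))
            utils::write.csv(data.frame(proposal =
                seq_along(chi2Trace(fit)) - 1L, chi2 = chi2Trace(fit)),
                file.path(outDir, "cylinder_chi2_trace.csv"),
                row.names = FALSE)
            logLine("cylinder fit seed %d, final chi2 %.6g", cfg$seed,
                    tail1(chi2Trace(fit)))
            fit
        })
    }

    if ("metrics" %in% stages) {
        out$metrics <- runStage("metrics", function() {
            p <- config$metrics
            model <- if (!is.null(out$cylinderFit)) finalModel(out$cylinderFit)
                else if (!is.null(out$blobFit)) finalModel(out$blobFit)
                else out$structure$structure
            pts <- if (is(model, "GaussianBlobEnsemble")) blobCenters(model)
                else t(vapply(chains(model), chainCentroid, numeric(3)))
            D <- containerDiameter(model)
            gr <- radialDistribution(pts, rMax = p$rMax %||% (D / 2),
                dr = p$dr %||% 50, containerDiameter = D,
                seed = seed + 3L)
            utils::write.csv(gr, file.path(outDir, "gr.csv"),
                             row.names = FALSE)
            fd <- tryCatch(fractalDimension(profile,
                    p$fractalWindow %||% c(0.002, 0.02)),
                error = function(e) NULL)
            if (!is.null(fd))
                utils::write.csv(data.frame(d = fd$d, stderr = fd$stderr,
                    qMin = fd$qWindow[1], qMax = fd$qWindow[2]),
                    file.path(outDir, "fractal.csv"), row.names = FALSE)
            nem <- NULL
            if (is(model, "EnsembleModel")) {
                axes <- do.call(rbind, lapply(chains(model),
                                              function(ch) ch@axes))
                poss <- do.call(rbind, lapply(chains(model), function(ch) {
                    st <- segmentStarts(ch)
                    st + ch@axes * (ch@lengths / 2)
                }))
                nem <- nematicOrder(poss, axes,
                    boxSize = p$boxSize %||% 400,
                    minCount = p$minCount %||% 30)
                utils::write.csv(nem, file.path(outDir, "nematic.csv"),
                                 row.names = FALSE)
            }
            list(gr = gr, fractal = fd, nematic = nem)
        })
    }
    invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tail1 <- function(x) x[length(x)]

configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(config, f, version = 2)
    unname(tools::md5sum(f))
}
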
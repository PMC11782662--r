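# Flow-cell sampling arithmetic for droplet SAXS: how often the
# illuminated volume is renewed and how many droplets contribute to an
# averaged measurement.

#' Sample renewals per second in a flow cell
#'
#' A sample pumped at \code{flowVelocity} through a beam of width
#' \code{beamWidth} along the flow direction is fully renewed
#' \eqn{v / w} times per second; at 7.5 mm/s through a 12 um beam that is
#' 625 renewals per one-second exposure, which is why beam-induced aging
#' of the droplets can be ruled out.
#'
#' @param flowVelocity flow speed (mm/s).
#' @param beamWidth beam full width along the flow direction (um).
#' @return Renewals per second.
#' @examples
#' sampleRenewalsPerSecond(7.5, 12)   # 625
#' @export
sampleRenewalsPerSecond <- function(flowVelocity = 7.5, beamWidth = 12) {
    stopifnotScalarPositive(flowVelocity, "flowVelocity")
    stopifnotScalarPositive(beamWidth, "beamWidth")
    flowVelocity * 1000 / beamWidth
}

#' Droplets contributing to an averaged measurement
#'
#' With \code{dropletsInBeam} droplets illuminated at any instant,
#' \code{renewalsPerSecond} sample renewals per second and
#' \code{nExposures} averaged one-second exposures, roughly
#' \eqn{n_{beam} \times renewals \times exposures} droplets contribute:
#' about \eqn{10^6} for 40 droplets, 625 renewals and 40 exposures.
#'
#' @param dropletsInBeam droplets inside the illuminated volume at any
#'   instant.
#' @param renewalsPerSecond from [sampleRenewalsPerSecond()].
#' @param nExposures averaged one-second exposures.
#' @return Total droplet count.
#' @examples
#' dropletsPerMeasurement(40, 625, 40)   # 1e6
#' @export
dropletsPerMeasurement <- function(dropletsInBeam, renewalsPerSecond,
                                   nExposures) {
    dropletsInBeam * renewalsPerSecond * nExposures
}
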
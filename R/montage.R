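#' Standard 10-20 scalp montage (19 channels) on the unit sphere
#'
#' Electrode positions for the 19 scalp sites of the international 10-20
#' system (Fp1, Fp2, F7, F3, Fz, F4, F8, T7, C3, Cz, C4, T8, P7, P3, Pz,
#' P4, P8, O1, O2), idealised on a unit sphere.  Positions are derived
#' from the classic polar layout (angle from the nose direction, radius as
#' inclination from the vertex), the convention used by EEG topographic
#' plotting software.
#'
#' @param labels optional character vector restricting/ordering the result.
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit vectors;
#'   x = right, y = anterior, z = superior).
#' @export
#' @examples
#' m <- montage_1020()
#' stopifnot(nrow(m) == 19, all(abs(m$x^2 + m$y^2 + m$z^2 - 1) < 1e-12))
montage_1020 <- function(labels = NULL) {
  path <- system.file("extdata", "montage_1020.csv", package = "prestimlink")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  # polar: ang degrees clockwise from nose; rad 0 (vertex) .. ~0.511 (rim)
  incl <- tab$rad * pi            # inclination from +z, radians (rad*180 deg)
  azim <- tab$ang * pi / 180
  out <- data.frame(
    label = tab$label,
    x = sin(incl) * sin(azim),
    y = sin(incl) * cos(azim),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    idx <- match(labels, out$label)
    if (anyNA(idx)) {
      stop_invalid("unknown montage label(s): %s",
                   paste(labels[is.na(idx)], collapse = ", "))
    }
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' EEG and EOG channel label conventions
#'
#' The pipeline's canonical channel sets: 19 scalp EEG labels of the 10-20
#' montage and 4 EOG labels (above/below the left eye, outer canthi).
#' @return character vector of labels.
#' @export
eeg_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' @rdname eeg_labels
#' @export
eog_labels <- function() c("VEOGU", "VEOGL", "HEOGL", "HEOGR")

#' Smooth unit-max scalp topography centred on an electrode
#'
#' Builds a channel-weight vector by a spherical Gaussian falloff around a
#' named centre site, normalised to a maximum weight of exactly 1.  Used by
#' the synthetic-data generator to give oscillators and ERP templates a
#' plausible smooth topography.
#'
#' @param centre electrode label at which the weight is 1.
#' @param fwhm_deg full width at half maximum of the falloff, in degrees of
#'   great-circle distance (default 90).
#' @param montage montage data.frame as from [montage_1020()].
#' @return named numeric vector, one weight per montage channel, max 1.
#' @export
topography_gaussian <- function(centre, fwhm_deg = 90,
                                montage = montage_1020()) {
  i <- match(centre, montage$label)
  if (is.na(i)) stop_invalid("unknown centre electrode '%s'", centre)
  P <- as.matrix(montage[, c("x", "y", "z")])
  cosang <- pmin(1, pmax(-1, P %*% P[i, ]))
  ang <- acos(cosang) * 180 / pi          # great-circle distance, degrees
  sigma <- fwhm_deg / 2.354820045
  w <- exp(-0.5 * (ang / sigma)^2)
  w <- drop(w / max(w))
  stats::setNames(w, montage$label)
}
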
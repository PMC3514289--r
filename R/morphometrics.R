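#' Centroid size of a landmark configuration
#'
#' Centroid size is the standard geometric-morphometrics size measure:
#' the square root of the summed squared distances of all landmarks from
#' their centroid, multiplied by the pixel-to-mm scale factor. It is
#' invariant to translation and rotation and scales linearly with the
#' configuration. This is the "body size" metric of the pipeline.
#'
#' @param lm A landmark set (list with `landmarks` matrix and `scale`),
#'   or a bare n x 2 coordinate matrix.
#' @param scale mm-per-pixel scale factor; ignored when `lm` carries its
#'   own.
#' @return Centroid size in mm (a single non-negative number).
#' @export
centroid_size <- function(lm, scale = 1) {
  if (is.list(lm) && !is.null(lm$landmarks)) {
    scale <- lm$scale
    lm <- lm$landmarks
  }
  lm <- as.matrix(lm)
  if (nrow(lm) < 3)
    stop("degenerate configuration: centroid size needs >= 3 landmarks")
  if (!all(is.finite(lm))) stop("non-finite landmark coordinate")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  ctr <- colMeans(lm)
  scale * sqrt(sum(sweep(lm, 2, ctr)^2))
}

#' Centroid size for a list of specimens
#'
#' @param sets List of landmark sets (as from [read_tps()] or
#'   [gen_landmarks()]).
#' @return Data frame with `specimen_id`, `centroid_size` (mm) and
#'   `n_landmarks`.
#' @export
centroid_size_table <- function(sets) {
  data.frame(
    specimen_id = vapply(sets, function(s) s$specimen_id, character(1)),
    centroid_size = vapply(sets, centroid_size, numeric(1)),
    n_landmarks = vapply(sets, function(s) nrow(s$landmarks), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Mean egg dry mass of a clutch
#'
#' Egg size expressed as total clutch dry mass divided by total egg
#' number, i.e. the average dry mass of a single egg.
#'
#' @param fecundity Egg count per clutch (> 0); vectorised.
#' @param clutch_dry_mass Total clutch dry mass in mg (>= 0).
#' @return Per-egg dry mass in mg. `NA` inputs propagate.
#' @export
egg_size <- function(fecundity, clutch_dry_mass) {
  if (length(fecundity) != length(clutch_dry_mass))
    stop("fecundity and clutch_dry_mass must have equal length")
  if (any(fecundity <= 0, na.rm = TRUE))
    stop("undefined egg size: fecundity must be > 0")
  if (any(clutch_dry_mass < 0, na.rm = TRUE))
    stop("clutch_dry_mass must be >= 0")
  clutch_dry_mass / fecundity
}
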
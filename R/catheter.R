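#' Construct a 5-spline x 4-electrode mapping-catheter geometry
#'
#' Builds the electrode layout of a five-spline catheter with four electrodes
#' per spline, arranged as four concentric rings of five electrodes each.
#' Electrode numbering follows the clinical convention: electrodes 1--4 lie on
#' spline 1 (outermost to innermost), 5--8 on spline 2, and so on, so that
#' ring \eqn{r} consists of electrodes \eqn{r, r+4, r+8, r+12, r+16} (ring 1 =
#' electrodes 1, 5, 9, 13, 17 is the external ring).
#'
#' Bipolar channels are formed along each spline between adjacent electrodes:
#' the external bipolar ring pairs (1-2), (5-6), ..., (17-18), the middle ring
#' (2-3), ..., (18-19), and the internal ring (3-4), ..., (19-20).
#'
#' @param ring_radii_mm numeric(4), strictly decreasing ring radii in mm from
#'   the external ring inward. Default `c(10, 7, 4, 2)` (nominal, configurable;
#'   clinical spacing is not standardized in exported data).
#' @param deployment non-negative planarity parameter. 0 gives a perfectly
#'   planar (fully deployed, in-contact) catheter; positive values dome the
#'   inner rings out of plane by `deployment * (max radius - ring radius)` mm,
#'   producing fixtures that acquisition QC can reject.
#' @return an object of class `catheter_geometry`: list with
#'   `electrode_positions` (20 x 3 matrix, mm), `spline_index`, `ring_index`
#'   (integer vectors of length 20), `bipole_pairs` (15 x 2 integer matrix with
#'   a `ring` attribute column in `bipole_ring`), `ring_radii_mm`.
#' @examples
#' geo <- make_catheter_geometry()
#' table(geo$ring_index)
#' @export
make_catheter_geometry <- function(ring_radii_mm = c(10, 7, 4, 2),
                                   deployment = 0) {
  if (length(ring_radii_mm) != 4L || any(ring_radii_mm <= 0)) {
    stop("ring_radii_mm must be 4 positive values", call. = FALSE)
  }
  if (any(diff(ring_radii_mm) >= 0)) {
    stop("invalid geometry: ring radii must be strictly decreasing from external to internal",
         call. = FALSE)
  }
  if (deployment < 0) stop("deployment must be >= 0", call. = FALSE)

  electrode <- 1:20
  spline_index <- rep(1:5, each = 4L)          # electrodes 1-4 on spline 1, ...
  ring_index <- rep(1:4, times = 5L)           # position along spline = ring
  azimuth <- 2 * pi * (spline_index - 1L) / 5  # splines equally spaced, 72 deg
  radius <- ring_radii_mm[ring_index]
  z <- deployment * (max(ring_radii_mm) - radius)
  pos <- cbind(x = radius * cos(azimuth),
               y = radius * sin(azimuth),
               z = z)
  rownames(pos) <- paste("Penta", electrode)

  # bipoles along each spline: (1-2),(2-3),(3-4) per spline; bipolar ring k
  # pairs electrodes k and k+1 of every spline
  first <- as.vector(vapply(seq(1, 17, by = 4), function(s) s + 0:2, numeric(3)))
  bipole_pairs <- cbind(first = first, second = first + 1L)
  bipole_ring <- rep(1:3, times = 5L)
  rownames(bipole_pairs) <- paste0("Penta ", first, "-", first + 1L)

  structure(list(
    electrode_positions = pos,
    spline_index = spline_index,
    ring_index = ring_index,
    azimuth_rad = azimuth,
    bipole_pairs = bipole_pairs,
    bipole_ring = bipole_ring,
    ring_radii_mm = ring_radii_mm,
    deployment = deployment
  ), class = "catheter_geometry")
}

#' @export
print.catheter_geometry <- function(x, ...) {
  cat("catheter_geometry: 5 splines x 4 electrodes,",
      "ring radii", paste(x$ring_radii_mm, collapse = "/"), "mm,",
      "deployment", x$deployment, "\n")
  invisible(x)
}

#' Electrodes belonging to one concentric ring
#'
#' @param geometry a `catheter_geometry`
#' @param ring ring number 1 (external) to 4 (internal)
#' @return integer electrode indices ordered by spline azimuth
#' @export
ring_electrodes <- function(geometry, ring) {
  stopifnot(ring %in% 1:4)
  e <- which(geometry$ring_index == ring)
  e[order(geometry$azimuth_rad[e])]
}
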
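#' Spherical eye model with disc and fovea landmarks
#'
#' The geometric substrate for both simulation and measurement: a sphere of
#' the given radius, with the fovea at (or near) the posterior pole -- which
#' is also the tangent point of the image projection -- and the optic disc
#' displaced nasally. Laterality fixes the image-space convention: fundus
#' images are taken to be displayed anatomically upright, so for a right eye
#' (OD) the fovea lies to the image-left of the disc (temporal retina towards
#' image-left), and mirrored for a left eye (OS).
#'
#' @param radius Eye radius in mm; default 12 (emmetropic globe of about
#'   24 mm diameter).
#' @param disc_ecc_deg Eccentricity of the disc centre from the posterior
#'   pole, degrees; default 15 (typical disc-fovea angular separation).
#' @param disc_radius Optic disc radius in mm; default 0.9.
#' @param fovea_ecc_deg Eccentricity of the fovea from the tangent point,
#'   degrees; default 0 (fovea at the pole).
#' @param fovea_meridian_deg Meridian of the fovea in degrees (image
#'   convention: 0 = +x, measured towards +y). Default NULL places the
#'   fovea on the temporal meridian, opposite the disc.
#' @param laterality "OD" (right eye) or "OS" (left eye).
#' @return An object of class \code{eye_model} with fields \code{radius},
#'   \code{disc_center}, \code{disc_radius}, \code{fovea} (sphere points),
#'   and \code{laterality}.
#' @export
#' @examples
#' eye <- eye_model()
#' eye_os <- eye_model(laterality = "OS")
eye_model <- function(radius = 12, disc_ecc_deg = 15, disc_radius = 0.9,
                      fovea_ecc_deg = 0, fovea_meridian_deg = NULL,
                      laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  stopifnot(radius > 0, disc_radius > 0, disc_ecc_deg > 0,
            fovea_ecc_deg >= 0)
  if (disc_radius >= radius / 4)
    stop("disc_radius must be smaller than radius/4")
  # Nasal direction in image space: +x for OD, -x for OS; the fovea (if off
  # the pole) sits on the opposite, temporal, meridian unless overridden.
  nasal_mer <- if (laterality == "OD") 0 else pi
  disc_center <- sphere_point(disc_ecc_deg * pi / 180, nasal_mer)
  fovea_mer <- if (is.null(fovea_meridian_deg))
    (nasal_mer + pi) %% (2 * pi) else (fovea_meridian_deg * pi / 180)
  fovea <- sphere_point(fovea_ecc_deg * pi / 180, fovea_mer)
  if (isTRUE(all.equal(as.numeric(disc_center), as.numeric(fovea))))
    stop("fovea coincides with the disc centre: degenerate eye geometry")
  structure(list(radius = radius, disc_center = disc_center,
                 disc_radius = disc_radius, fovea = fovea,
                 laterality = laterality),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf(
    "Eye model (%s): radius %.1f mm, disc %.1f deg %s of pole (radius %.2f mm), fovea %.1f deg temporal\n",
    x$laterality, x$radius, x$disc_center[1] * 180 / pi,
    if (x$laterality == "OD") "right" else "left",
    x$disc_radius, x$fovea[1] * 180 / pi))
  invisible(x)
}

#' Projection model tangent at an eye's posterior pole
#'
#' @param eye An [eye_model()].
#' @param px_per_mm Central scale in px/mm.
#' @param center_px Image coordinates of the tangent point.
#' @return A [projection_model()].
#' @export
eye_projection <- function(eye, px_per_mm = 10, center_px = c(0, 0)) {
  projection_model(eye_radius = eye$radius, px_per_mm = px_per_mm,
                   center_px = center_px)
}

# Planar (projected) disc geometry: centre in px and radius in px, using the
# local planar magnification at the disc centre.
disc_planar <- function(eye, model) {
  center <- project_sphere(eye$disc_center, model)
  mag <- 1 / pixel_scale_mm(center, model)  # px per mm of retina, locally
  list(center_px = as.numeric(center), radius_px = eye$disc_radius * mag)
}
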
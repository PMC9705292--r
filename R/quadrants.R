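#' Image landmarks: disc, fovea, laterality
#'
#' @param disc_center Disc centre (x, y) in px (1-based, x rightward,
#'   y downward).
#' @param disc_radius Disc radius in px (> 0).
#' @param fovea Fovea (x, y) in px; must differ from the disc centre.
#' @param laterality "OD" or "OS".
#' @return An object of class \code{landmarks}.
#' @export
landmarks <- function(disc_center, disc_radius, fovea,
                      laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  disc_center <- as.numeric(disc_center)
  fovea <- as.numeric(fovea)
  stopifnot(length(disc_center) == 2, length(fovea) == 2,
            is.numeric(disc_radius), disc_radius > 0,
            all(is.finite(c(disc_center, fovea))))
  if (all(disc_center == fovea))
    stop("fovea coincides with the disc centre")
  structure(list(disc_center = disc_center, disc_radius = disc_radius,
                 fovea = fovea, laterality = laterality),
            class = "landmarks")
}

#' @export
print.landmarks <- function(x, ...) {
  cat(sprintf("Landmarks (%s): disc (%.1f, %.1f) r=%.1f px, fovea (%.1f, %.1f)\n",
              x$laterality, x$disc_center[1], x$disc_center[2],
              x$disc_radius, x$fovea[1], x$fovea[2]))
  invisible(x)
}

#' Classify image points into retinal quadrants
#'
#' Quadrants are demarcated by the line from the disc centre to the fovea
#' (separating superior from inferior) and its perpendicular through the
#' disc centre (separating temporal -- the fovea side -- from nasal).
#' Superior is the image-up side, assuming anatomically upright display;
#' laterality makes the labels mirror-symmetric between eyes. Points exactly
#' on an axis are assigned to the temporal and superior sides respectively
#' (a measure-zero tie-break, fixed for determinism).
#'
#' @param points Two-column (x, y) matrix of image points.
#' @param lm A [landmarks()] object.
#' @return Character vector of labels in \{"TS", "TI", "NS", "NI"\}.
#' @export
classify_quadrant <- function(points, lm) {
  points <- rbind(points)
  u <- lm$fovea - lm$disc_center
  u <- u / sqrt(sum(u^2))
  dx <- points[, 1] - lm$disc_center[1]
  dy <- points[, 2] - lm$disc_center[2]
  temporal <- (dx * u[1] + dy * u[2]) >= 0
  cz <- u[1] * dy - u[2] * dx
  sgn <- if (lm$laterality == "OD") 1 else -1
  superior <- (sgn * cz) >= 0
  paste0(ifelse(temporal, "T", "N"), ifelse(superior, "S", "I"))
}

#' Quadrant classifier bound to a set of landmarks
#'
#' @param lm A [landmarks()] object.
#' @return A function mapping an (x, y) point matrix to quadrant labels.
#' @export
demarcate_quadrants <- function(lm) {
  force(lm)
  function(points) classify_quadrant(points, lm)
}

#' Distance from the disc centre in disc radii
#'
#' @param points Two-column (x, y) matrix.
#' @param lm A [landmarks()] object.
#' @return Numeric vector of planar distances divided by the disc radius.
#' @export
disc_radii_distance <- function(points, lm) {
  points <- rbind(points)
  sqrt((points[, 1] - lm$disc_center[1])^2 +
       (points[, 2] - lm$disc_center[2])^2) / lm$disc_radius
}

#' Restrict points to the peripheral measurement annulus
#'
#' Retains points whose planar distance from the disc centre, in units of
#' the annotated disc radius, lies in [r_min, r_max], bounds inclusive.
#'
#' @param points Two-column (x, y) matrix.
#' @param lm A [landmarks()] object.
#' @param r_min,r_max Annulus bounds in disc radii; defaults 6.5 and 8.5.
#' @return The retained subset of \code{points} (possibly 0 rows).
#' @export
annulus_filter <- function(points, lm, r_min = 6.5, r_max = 8.5) {
  points <- rbind(points)
  points[in_annulus(points, lm, r_min, r_max), , drop = FALSE]
}

# Logical mask version, used internally where indices must be kept aligned.
in_annulus <- function(points, lm, r_min = 6.5, r_max = 8.5) {
  r <- disc_radii_distance(points, lm)
  r >= r_min & r <= r_max
}

#' Assign a vessel segment to a quadrant
#'
#' Majority vote over the segment's in-annulus centerline points; ties are
#' broken by the quadrant of the point nearest 7.5 disc radii (the annulus
#' midline).
#'
#' @param segment A \code{vessel_segment} (see [extract_centerlines()]).
#' @param lm A [landmarks()] object.
#' @param r_min,r_max Annulus bounds in disc radii.
#' @return A quadrant label, or \code{NA_character_} if the segment has no
#'   in-annulus centerline point (unmeasurable).
#' @export
assign_quadrant <- function(segment, lm, r_min = 6.5, r_max = 8.5) {
  pts <- segment$centerline
  keep <- in_annulus(pts, lm, r_min, r_max)
  if (!any(keep)) return(NA_character_)
  pts <- pts[keep, , drop = FALSE]
  labs <- classify_quadrant(pts, lm)
  tab <- table(labs)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) return(winners)
  mid_dist <- abs(disc_radii_distance(pts, lm) - 7.5)
  mid_dist[!(labs %in% winners)] <- Inf
  labs[which.min(mid_dist)]
}
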
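#' Measure a vessel segment's mean width in mm within the annulus
#'
#' Averages, over the segment's centerline points inside the 6.5--8.5
#' disc-radii annulus, the pixel width multiplied by the local mm-per-px
#' scale of the projection -- the standardised, position-corrected width.
#'
#' @param segment A \code{vessel_segment}.
#' @param lm A [landmarks()] object.
#' @param model A [projection_model()].
#' @param r_min,r_max Annulus bounds in disc radii.
#' @return One-row data.frame: \code{vessel_id}, \code{vessel_type},
#'   \code{quadrant}, \code{mean_width_mm}, \code{n_pixels}.
#' @export
measure_width <- function(segment, lm, model, r_min = 6.5, r_max = 8.5) {
  keep <- in_annulus(segment$centerline, lm, r_min, r_max)
  if (!any(keep))
    stop(sprintf("unmeasurable segment %s: no centerline point in the annulus",
                 segment$vessel_id))
  pts <- segment$centerline[keep, , drop = FALSE]
  w_mm <- segment$width_px[keep] * pixel_scale_mm(pts, model)
  data.frame(vessel_id = segment$vessel_id,
             vessel_type = segment$vessel_type,
             quadrant = assign_quadrant(segment, lm, r_min, r_max),
             mean_width_mm = mean(w_mm),
             n_pixels = sum(keep),
             stringsAsFactors = FALSE)
}

#' Select up to 8 vessels: one artery and one vein per quadrant
#'
#' For each (quadrant, type) pair the candidate segment with the most
#' in-annulus centerline points is chosen; ties go to the larger mean
#' measured width, then to the lexicographically smaller vessel id.
#' Pairs with no candidate are reported absent. Segments must carry
#' artery/vein labels (from ground truth or operator annotation).
#'
#' @param segments List of typed \code{vessel_segment}s.
#' @param lm A [landmarks()] object.
#' @param model A [projection_model()].
#' @param r_min,r_max Annulus bounds in disc radii.
#' @return List with \code{measurements} (data.frame, one row per selected
#'   vessel, as in [measure_width()]) and \code{absent} (data.frame of
#'   quadrant/type pairs with no candidate).
#' @export
select_vessels <- function(segments, lm, model, r_min = 6.5, r_max = 8.5) {
  cands <- list()
  for (seg in segments) {
    if (!(seg$vessel_type %in% c("artery", "vein"))) next
    if (!any(in_annulus(seg$centerline, lm, r_min, r_max))) next
    cands[[length(cands) + 1]] <- measure_width(seg, lm, model, r_min, r_max)
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(vessel_id = character(0), vessel_type = character(0),
               quadrant = character(0), mean_width_mm = numeric(0),
               n_pixels = integer(0))
  sel <- list(); absent <- list()
  for (q in quadrant_names()) for (type in c("artery", "vein")) {
    rows <- cands[cands$quadrant == q & cands$vessel_type == type, ,
                  drop = FALSE]
    if (nrow(rows) == 0) {
      absent[[length(absent) + 1]] <- data.frame(
        quadrant = q, vessel_type = type, stringsAsFactors = FALSE)
      next
    }
    ord <- order(-rows$n_pixels, -rows$mean_width_mm, rows$vessel_id)
    sel[[length(sel) + 1]] <- rows[ord[1], , drop = FALSE]
  }
  list(measurements = if (length(sel)) do.call(rbind, sel) else cands,
       absent = if (length(absent)) do.call(rbind, absent) else
         data.frame(quadrant = character(0), vessel_type = character(0)))
}

# Bilinear interpolation of an image at fractional (x, y) positions.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Sub-pixel vessel widths from perpendicular intensity profiles
#'
#' For each centerline point, samples the image along the local normal
#' (bilinear interpolation, 0.25 px steps) and locates, on each side of the
#' centerline, the first crossing of the half-way level between the local
#' vessel core and background intensities; the width is the distance
#' between the two interpolated crossings. This resolves the vessel edge to
#' sub-pixel precision, unlike the distance-transform width, which is
#' quantised by the binary segmentation grid. Points where no crossing is
#' found keep their distance-transform width.
#'
#' @param segment A \code{vessel_segment}.
#' @param image The intensity image the segmentation came from.
#' @param dark_vessels Are vessels darker than the background?
#' @return The segment with \code{width_px} replaced by profile widths.
#' @export
profile_widths <- function(segment, image, dark_vessels = TRUE) {
  if (length(dim(image)) == 3) image <- image[, , 1]
  if (!dark_vessels) image <- 1 - image
  pts <- segment$centerline
  n <- nrow(pts)
  w_out <- segment$width_px
  step <- 0.25
  for (i in seq_len(n)) {
    i0 <- max(1, i - 2); i1 <- min(n, i + 2)
    tang <- pts[i1, ] - pts[i0, ]
    tl <- sqrt(sum(tang^2))
    if (tl == 0) next
    nrm <- c(-tang[2], tang[1]) / tl
    L <- segment$width_px[i] / 2 + 3
    ts <- seq(-L, L, by = step)
    xs <- pts[i, 1] + ts * nrm[1]
    ys <- pts[i, 2] + ts * nrm[2]
    prof <- bilinear_sample(image, xs, ys)
    lo <- min(prof); hi <- max(prof)
    if (hi - lo < 1e-6) next
    level <- (lo + hi) / 2
    c0 <- which.min(abs(ts))
    above <- prof >= level   # background side (vessels dark)
    right <- which(above & seq_along(ts) > c0)
    left <- which(above & seq_along(ts) < c0)
    if (!length(right) || !length(left) || above[c0]) next
    kR <- right[1]; kL <- left[length(left)]
    tR <- ts[kR - 1] + step * (level - prof[kR - 1]) / (prof[kR] - prof[kR - 1])
    tL <- ts[kL + 1] - step * (level - prof[kL + 1]) / (prof[kL] - prof[kL + 1])
    if (tR > tL) w_out[i] <- tR - tL
  }
  segment$width_px <- w_out
  segment
}

#' Full image-to-measurements pipeline
#'
#' Runs segmentation (restricted to components touching the seed points),
#' centerline extraction, type attachment from the seeds, quadrant
#' assignment, the 8-vessel selection protocol, and the geometry-corrected
#' width measurement. Segments inherit the id and type of the seed lying on
#' their connected component (nearest seed if a component carries several).
#'
#' @param image Numeric [y, x] matrix (or [y, x, channel] array).
#' @param lm A [landmarks()] object.
#' @param model A [projection_model()] for the mm conversion.
#' @param seeds data.frame with columns \code{x}, \code{y},
#'   \code{vessel_id}, \code{vessel_type} ("artery"/"vein"); see
#'   [scene_seeds()].
#' @param r_min,r_max Annulus bounds in disc radii.
#' @param dark_vessels Passed to [segment_vessels()].
#' @param width_method "profile" (default) refines each centerline width to
#'   sub-pixel precision from the perpendicular intensity profile
#'   ([profile_widths()]); "dt" keeps the raw distance-transform widths.
#' @return List with \code{measurements} (one row per selected quadrant/type
#'   pair) and \code{absent} (pairs with no measurable vessel).
#' @export
image_to_measurements <- function(image, lm, model, seeds,
                                  r_min = 6.5, r_max = 8.5,
                                  dark_vessels = TRUE,
                                  width_method = c("profile", "dt")) {
  width_method <- match.arg(width_method)
  stopifnot(is.data.frame(seeds),
            all(c("x", "y", "vessel_id", "vessel_type") %in% names(seeds)))
  bw <- segment_vessels(image, seeds = seeds[, c("x", "y")],
                        dark_vessels = dark_vessels)
  segs <- extract_centerlines(bw)
  if (!length(segs))
    return(list(measurements = data.frame(
      vessel_id = character(0), vessel_type = character(0),
      quadrant = character(0), mean_width_mm = numeric(0),
      n_pixels = integer(0)),
      absent = expand.grid(quadrant = quadrant_names(),
                           vessel_type = c("artery", "vein"),
                           stringsAsFactors = FALSE)))
  comp <- label8(bw)
  seed_comp <- comp[cbind(round(seeds$y), round(seeds$x))]
  for (i in seq_along(segs)) {
    hits <- which(seed_comp == segs[[i]]$component & seed_comp > 0)
    if (length(hits) == 0) next
    if (length(hits) > 1) {
      mid <- segs[[i]]$centerline[ceiling(nrow(segs[[i]]$centerline) / 2), ]
      d2 <- (seeds$x[hits] - mid[1])^2 + (seeds$y[hits] - mid[2])^2
      hits <- hits[which.min(d2)]
    }
    segs[[i]]$vessel_id <- seeds$vessel_id[hits]
    segs[[i]]$vessel_type <- seeds$vessel_type[hits]
  }
  if (width_method == "profile")
    segs <- lapply(segs, profile_widths, image = image,
                   dark_vessels = dark_vessels)
  select_vessels(segs, lm, model, r_min, r_max)
}

#' Measure a rendered synthetic scene end to end
#'
#' Convenience wrapper: derives seeds from the scene's ground-truth vessels
#' and runs [image_to_measurements()], returning the measurements joined
#' with each vessel's true annulus-mean width.
#'
#' @param scene A \code{fundus_scene} from [render_fundus()].
#' @param r_min,r_max Annulus bounds in disc radii.
#' @param width_method Passed to [image_to_measurements()].
#' @return List with \code{measurements} (including a
#'   \code{true_annulus_mean_mm} column) and \code{absent}.
#' @export
measure_scene <- function(scene, r_min = 6.5, r_max = 8.5,
                          width_method = "profile") {
  seeds <- scene_seeds(scene)
  res <- image_to_measurements(scene$image, scene$landmarks, scene$model,
                               seeds, r_min, r_max,
                               width_method = width_method)
  truth <- data.frame(
    vessel_id = vapply(scene$vessels, `[[`, "", "vessel_id"),
    true_annulus_mean_mm = vapply(scene$vessels, `[[`, 0,
                                  "true_annulus_mean_mm"),
    stringsAsFactors = FALSE)
  res$measurements <- merge(res$measurements, truth, by = "vessel_id",
                            all.x = TRUE, sort = TRUE)
  res
}
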
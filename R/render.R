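#' Render a synthetic fundus image from a vessel tree
#'
#' Projects each vessel's spherical path into the image plane and stamps it
#' as a dark band on a bright background, with the local planar width set so
#' that the on-retina width (after the per-pixel mm conversion) equals the
#' vessel's true width at that point. Also returns a label map identifying
#' each vessel's pixels and the landmark annotation (projected disc centre
#' and radius, fovea, laterality) that the measurement pipeline consumes.
#'
#' Image coordinates: x rightward, y downward. In memory, images are
#' \code{[y, x]} matrices indexed from 1; files written by [write_scene()]
#' use 0-based pixel indices in the landmarks JSON.
#'
#' @param eye An [eye_model()].
#' @param vessels List of \code{gt_vessel} from [grow_vessel_tree()]; may be
#'   empty.
#' @param resolution Image side in px (>= 256); the image is square.
#' @param field_mm Planar field width in mm covered by the image; fixes the
#'   central scale at \code{resolution / field_mm} px/mm. Default 22, wide
#'   enough to contain the 8.5 disc-radii annulus of the default eye.
#' @param noise Standard deviation of additive Gaussian pixel noise.
#' @param bg,fg Background and vessel intensities in [0, 1].
#' @param seed Seed for the pixel noise (irrelevant when \code{noise = 0}).
#' @return A \code{fundus_scene}: list with \code{image} (numeric [y, x]
#'   matrix in [0, 1]), \code{label} (integer matrix, 0 = background,
#'   k = index of \code{vessels[[k]]}), \code{landmarks} (a [landmarks()]
#'   object), \code{model} (the [projection_model()]), and \code{vessels}.
#' @export
render_fundus <- function(eye, vessels, resolution = 1024, field_mm = 22,
                          noise = 0, bg = 0.85, fg = 0.25, seed = 1) {
  stopifnot(inherits(eye, "eye_model"), resolution >= 256, field_mm > 0,
            noise >= 0)
  px_per_mm <- resolution / field_mm
  ctr <- (resolution + 1) / 2
  model <- eye_projection(eye, px_per_mm = px_per_mm,
                          center_px = c(ctr, ctr))
  cov <- matrix(0, resolution, resolution)  # vessel coverage fraction
  lab <- matrix(0L, resolution, resolution)

  for (k in seq_along(vessels)) {
    v <- vessels[[k]]
    pts <- project_sphere(v$path, model)
    half_px <- (v$width_mm / 2) / pixel_scale_mm(pts, model)
    # Resample so consecutive stamps are <= 0.7 px apart (disk union then
    # approximates a smooth band).
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    n_s <- max(2L, ceiling(cum[length(cum)] / 0.7) + 1L)
    s_out <- seq(0, cum[length(cum)], length.out = n_s)
    xs <- stats::approx(cum, pts[, 1], xout = s_out)$y
    ys <- stats::approx(cum, pts[, 2], xout = s_out)$y
    hs <- stats::approx(cum, half_px, xout = s_out)$y
    clipped <- FALSE
    for (i in seq_len(n_s)) {
      x0 <- xs[i]; y0 <- ys[i]; r0 <- hs[i]
      xlo <- floor(x0 - r0 - 1); xhi <- ceiling(x0 + r0 + 1)
      ylo <- floor(y0 - r0 - 1); yhi <- ceiling(y0 + r0 + 1)
      if (xhi < 1 || ylo > resolution || yhi < 1 || xlo > resolution) {
        clipped <- TRUE
        next
      }
      if (xlo < 1 || ylo < 1 || xhi > resolution || yhi > resolution)
        clipped <- TRUE
      xr <- max(1L, xlo):min(resolution, xhi)
      yr <- max(1L, ylo):min(resolution, yhi)
      # Anti-aliased coverage: 1 inside the disk, 0 outside, linear ramp
      # across the one-pixel boundary band.
      d <- sqrt(outer((yr - y0)^2, (xr - x0)^2, `+`))
      cv <- pmin(1, pmax(0, r0 + 0.5 - d))
      blk <- cov[yr, xr, drop = FALSE]
      upd <- cv > blk
      if (any(upd)) {
        blk[upd] <- cv[upd]
        cov[yr, xr] <- blk
        lblk <- lab[yr, xr, drop = FALSE]
        lblk[upd & cv >= 0.5] <- k
        lab[yr, xr] <- lblk
      }
    }
    if (clipped)
      warning(sprintf("vessel %s partially outside the image frame; clipped",
                      v$vessel_id))
  }
  img <- bg + (fg - bg) * cov

  if (noise > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(length(img), 0, noise),
                        nrow(img), ncol(img))
    img <- pmin(1, pmax(0, img))
  }

  dp <- disc_planar(eye, model)
  fov <- as.numeric(project_sphere(eye$fovea, model))
  lm <- landmarks(disc_center = dp$center_px, disc_radius = dp$radius_px,
                  fovea = fov, laterality = eye$laterality)
  structure(list(image = img, label = lab, landmarks = lm, model = model,
                 vessels = vessels, resolution = resolution,
                 field_mm = field_mm),
            class = "fundus_scene")
}

#' Seed points and vessel types for a rendered scene
#'
#' One click point per ground-truth vessel (its centerline sample nearest
#' 7.5 disc radii, i.e. mid-annulus), with the vessel's identity and type --
#' the synthetic stand-in for the operator's manual vessel selection.
#'
#' @param scene A \code{fundus_scene}.
#' @return data.frame with columns \code{x}, \code{y} (px), \code{vessel_id},
#'   \code{vessel_type}.
#' @export
scene_seeds <- function(scene) {
  out <- lapply(scene$vessels, function(v) {
    i <- which.min(abs(v$r_disc - 7.5))
    q <- project_sphere(v$path[i, , drop = FALSE], scene$model)
    data.frame(x = q[1], y = q[2], vessel_id = v$vessel_id,
               vessel_type = v$vessel_type, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a rendered scene to disk
#'
#' Writes the image as PNG, the label map as a 16-bit TIFF, the landmarks as
#' JSON (0-based pixel indices, origin top-left), and the scene parameters
#' as YAML for provenance.
#'
#' @param scene A \code{fundus_scene}.
#' @param dir Output directory (created if needed).
#' @param name Basename for the four files.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(name, ".png"))
  p_lab <- file.path(dir, paste0(name, "_label.tif"))
  p_lmk <- file.path(dir, paste0(name, "_landmarks.json"))
  p_cfg <- file.path(dir, paste0(name, "_scene.yaml"))
  png::writePNG(scene$image, p_img)
  tiff::writeTIFF(scene$label / 65535, p_lab, bits.per.sample = 16)
  lm <- scene$landmarks
  jsonlite::write_json(list(
    disc_center_px = lm$disc_center - 1, disc_radius_px = lm$disc_radius,
    fovea_px = lm$fovea - 1, laterality = lm$laterality,
    eye_radius_mm = scene$model$eye_radius,
    px_per_mm_at_center = scene$model$px_per_mm,
    projection_center_px = scene$model$center_px - 1),
    p_lmk, auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(resolution = scene$resolution,
                        field_mm = scene$field_mm,
                        n_vessels = length(scene$vessels),
                        laterality = lm$laterality), p_cfg)
  invisible(c(p_img, p_lab, p_lmk, p_cfg))
}

#' Read a landmarks JSON written by [write_scene()]
#'
#' Converts the file's 0-based pixel indices back to the 1-based in-memory
#' convention and reconstructs the projection model if present.
#'
#' @param path Path to the JSON file.
#' @return List with \code{landmarks} (a [landmarks()] object) and
#'   \code{model} (a [projection_model()] or NULL).
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- landmarks(disc_center = unlist(j$disc_center_px) + 1,
                  disc_radius = j$disc_radius_px,
                  fovea = unlist(j$fovea_px) + 1,
                  laterality = j$laterality)
  model <- NULL
  if (!is.null(j$eye_radius_mm))
    model <- projection_model(j$eye_radius_mm, j$px_per_mm_at_center,
                              unlist(j$projection_center_px) + 1)
  list(landmarks = lm, model = model)
}
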
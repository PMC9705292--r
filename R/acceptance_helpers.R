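#' Maximum relative error of geometry-corrected length measurement
#'
#' Draws random great-circle arcs on a model eye with both endpoints within
#' a given eccentricity, projects them at a sampling spacing of at most
#' 2 px, measures each with [corrected_polyline_length()], and compares to
#' the closed-form geodesic length. This quantifies the accuracy of
#' on-image geometric measurement under the stereographic model.
#'
#' @param n_arcs Number of random arcs.
#' @param max_ecc_deg Endpoint eccentricity bound in degrees (default 100).
#' @param eye_radius Eye radius in mm.
#' @param px_per_mm Central scale.
#' @param seed RNG seed.
#' @return List with \code{max_rel_error_pct} and the per-arc errors.
#' @export
projection_accuracy_check <- function(n_arcs = 100, max_ecc_deg = 100,
                                      eye_radius = 12, px_per_mm = 10,
                                      seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  pm <- projection_model(eye_radius, px_per_mm)
  errs <- vapply(seq_len(n_arcs), function(i) {
    repeat {
      a <- sphere_point(stats::runif(1, 0.01, max_ecc_deg * pi / 180),
                        stats::runif(1, 0, 2 * pi))
      b <- sphere_point(stats::runif(1, 0.01, max_ecc_deg * pi / 180),
                        stats::runif(1, 0, 2 * pi))
      L <- geodesic_distance(a, b, pm)
      if (L > 0.5) break                      # skip near-degenerate arcs
    }
    va <- as.numeric(sphere_to_xyz(a)); vb <- as.numeric(sphere_to_xyz(b))
    ang <- acos(max(-1, min(1, sum(va * vb))))
    # sample the arc densely enough for <= 2 px spacing after projection
    n <- max(8, ceiling(L * px_per_mm))       # ~1 px steps on the sphere
    ts <- seq(0, 1, length.out = n)
    arc <- t(vapply(ts, function(t)
      (sin((1 - t) * ang) * va + sin(t * ang) * vb) / sin(ang),
      numeric(3)))
    sp <- sphere_point(acos(pmin(1, pmax(-1, arc[, 3]))),
                       atan2(arc[, 2], arc[, 1]))
    q <- project_sphere(sp, pm)
    abs(corrected_polyline_length(q, pm) - L) / L
  }, 0)
  list(max_rel_error_pct = 100 * max(errs), rel_errors_pct = 100 * errs)
}

#' Count vessels selected by the full pipeline on a canonical scene
#'
#' Generates the canonical synthetic fundus scene (one artery and one vein
#' crossing the measurement annulus in every quadrant), runs segmentation,
#' centerline extraction, quadrant assignment and the selection protocol,
#' and counts the selected vessels.
#'
#' @param seed Seed for the vessel tree.
#' @param resolution Render resolution in px.
#' @return List with \code{n_selected}, the measurement table and the
#'   absence report.
#' @export
vessel_selection_check <- function(seed = 1, resolution = 1024) {
  eye <- eye_model()
  tree <- grow_vessel_tree(eye, n_per_quadrant = 1, seed = seed)
  scene <- render_fundus(eye, tree, resolution = resolution)
  res <- measure_scene(scene)
  list(n_selected = nrow(res$measurements),
       measurements = res$measurements, absent = res$absent)
}
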
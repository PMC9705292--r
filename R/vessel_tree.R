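#' Default per-quadrant target vessel widths (mm)
#'
#' Healthy-eye mean widths at the measurement annulus, by quadrant and vessel
#' type. Veins are wider than arteries and temporal vessels wider than nasal,
#' in the 0.07--0.12 mm range typical of peripheral retinal vessels.
#'
#' @return Named numeric vector keyed "<quadrant>_<type>", widths in mm.
#' @export
default_vessel_widths <- function() {
  c(TI_artery = 0.0955, TI_vein = 0.1115,
    TS_artery = 0.1040, TS_vein = 0.1180,
    NI_artery = 0.0710, NI_vein = 0.0830,
    NS_artery = 0.0780, NS_vein = 0.0920)
}

quadrant_names <- function() c("TS", "TI", "NS", "NI")

# Central planar direction (unit vector, image coords, y down) of each
# quadrant around the disc, given the eye's laterality. Temporal is the
# fovea side; superior is image-up.
quadrant_directions <- function(laterality) {
  tx <- if (laterality == "OD") -1 else 1  # temporal: towards the fovea
  s2 <- sqrt(2) / 2
  list(TS = c(tx * s2, -s2), TI = c(tx * s2, s2),
       NS = c(-tx * s2, -s2), NI = c(-tx * s2, s2))
}

#' Grow a ground-truth vessel tree on a model eye
#'
#' Generates unbranched artery and vein centerlines radiating from the optic
#' disc margin into the retinal periphery, one set per quadrant. Paths are
#' built in the projected plane as gently wobbling radial curves, then lifted
#' to the sphere, so their planar distance from the disc centre (in disc
#' radii) is known exactly. Widths taper monotonically with on-sphere arc
#' length from the disc; each vessel records its true mean width over the
#' 6.5--8.5 disc-radii measurement annulus as ground truth for validating
#' the measurement pipeline.
#'
#' @param eye An [eye_model()].
#' @param n_per_quadrant Number of vessels of each type (artery and vein) to
#'   grow per quadrant; the default 1 yields the canonical 8-vessel scene.
#' @param taper List with elements \code{family} ("linear" or "exponential"),
#'   optional \code{w0} (width in mm at the disc margin; default 1.45 times
#'   the annulus target width), optional \code{annulus_width} (scalar or
#'   named vector keyed "<quadrant>_<type>" overriding
#'   [default_vessel_widths()]), and optional \code{width_jitter}
#'   (multiplicative log-uniform jitter half-range, default 0.06).
#' @param reach_disc_radii How far beyond the disc centre vessels extend, in
#'   planar disc radii; must exceed 8.5. Default 9.6.
#' @param seed Integer seed; the same seed and arguments reproduce the tree
#'   bit-for-bit.
#' @return List of \code{gt_vessel} objects. Each has \code{vessel_id},
#'   \code{vessel_type}, \code{quadrant}, \code{path} (sphere points),
#'   \code{width_mm} and \code{arc_mm} per path sample, \code{r_disc}
#'   (planar distance in disc radii, projection-resolution invariant), and
#'   \code{true_annulus_mean_mm}.
#' @export
#' @examples
#' tree <- grow_vessel_tree(eye_model(), seed = 7)
#' length(tree)  # 8
#' sapply(tree, function(v) v$true_annulus_mean_mm)
grow_vessel_tree <- function(eye, n_per_quadrant = 1,
                             taper = list(family = "linear"),
                             reach_disc_radii = 9.6, seed = 1) {
  stopifnot(inherits(eye, "eye_model"), n_per_quadrant >= 0,
            reach_disc_radii > 8.5)
  if (n_per_quadrant == 0) return(list())
  family <- if (is.null(taper$family)) "linear" else
    match.arg(taper$family, c("linear", "exponential"))
  widths <- default_vessel_widths()
  if (!is.null(taper$annulus_width)) {
    aw <- taper$annulus_width
    if (length(aw) == 1 && is.null(names(aw))) {
      widths[] <- aw
    } else widths[names(aw)] <- aw
  }
  jit <- if (is.null(taper$width_jitter)) 0.06 else taper$width_jitter

  # Planar geometry at unit central scale (planar coordinates in mm).
  model <- eye_projection(eye, px_per_mm = 1, center_px = c(0, 0))
  dp <- disc_planar(eye, model)
  dirs <- quadrant_directions(eye$laterality)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  vessels <- list()
  for (q in quadrant_names()) {
    psi_c <- atan2(dirs[[q]][2], dirs[[q]][1])
    for (type in c("artery", "vein")) {
      for (k in seq_len(n_per_quadrant)) {
        base_off <- (if (type == "artery") -18 else 18) * pi / 180
        spread <- (k - (n_per_quadrant + 1) / 2) * 8 * pi / 180
        psi0 <- psi_c + base_off + spread + stats::runif(1, -8, 8) * pi / 180
        amp <- stats::runif(1, 3, 7) * pi / 180
        lam <- stats::runif(1, 6, 10)
        phase <- stats::runif(1, 0, 2 * pi)
        w_ann <- unname(widths[paste(q, type, sep = "_")]) *
          exp(stats::runif(1, -jit, jit))
        w0 <- if (is.null(taper$w0)) 1.45 * w_ann else taper$w0

        r <- seq(1, reach_disc_radii, by = 0.01)  # planar disc-radius units
        psi <- psi0 + amp * sin(2 * pi * (r - 1) / lam + phase)
        pts_planar <- cbind(dp$center_px[1] + r * dp$radius_px * cos(psi),
                            dp$center_px[2] + r * dp$radius_px * sin(psi))
        path <- unproject_image(pts_planar, model)
        seg <- geodesic_distance(path[-nrow(path), ], path[-1, ], model)
        arc <- c(0, cumsum(seg))
        s_mid <- stats::approx(r, arc, xout = 7.5)$y
        wfun <- switch(family,
          linear = {
            k_t <- (w0 - w_ann) / s_mid
            function(s) w_ann + k_t * (s_mid - s)
          },
          exponential = {
            c_t <- log(w0 / w_ann) / s_mid
            function(s) w0 * exp(-c_t * s)
          })
        w <- wfun(arc)
        if (any(w <= 0))
          stop("taper produces non-positive width along the vessel path")
        in_ann <- r >= 6.5 & r <= 8.5
        seg_len <- sqrt(rowSums((pts_planar[-1, , drop = FALSE] -
                                 pts_planar[-nrow(pts_planar), , drop = FALSE])^2))
        wt <- c(seg_len[1], (seg_len[-1] + seg_len[-length(seg_len)]) / 2,
                seg_len[length(seg_len)])
        true_mean <- sum(w[in_ann] * wt[in_ann]) / sum(wt[in_ann])
        vessels[[length(vessels) + 1]] <- structure(list(
          vessel_id = sprintf("%s_%s_%d", q, type, k),
          vessel_type = type, quadrant = q, path = path,
          width_mm = w, arc_mm = arc, r_disc = r,
          true_annulus_mean_mm = true_mean), class = "gt_vessel")
      }
    }
  }
  vessels
}

#' @export
print.gt_vessel <- function(x, ...) {
  cat(sprintf("Ground-truth %s %s: %d samples, annulus mean width %.4f mm\n",
              x$quadrant, x$vessel_type, nrow(x$path),
              x$true_annulus_mean_mm))
  invisible(x)
}
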
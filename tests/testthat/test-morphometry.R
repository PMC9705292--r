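lm_od <- landmarks(disc_center = c(500, 300), disc_radius = 10,
                   fovea = c(400, 300), laterality = "OD")

test_that("quadrant demarcation follows the disc-fovea axis", {
  cls <- demarcate_quadrants(lm_od)
  # the fovea itself is temporal
  expect_true(cls(rbind(lm_od$fovea)) %in% c("TS", "TI"))
  # disc->fovea vector rotated +90 degrees lands superior (OD convention)
  u <- lm_od$fovea - lm_od$disc_center
  rot <- c(-u[2], u[1])  # rotation by +90 in (x, y)
  expect_true(cls(rbind(lm_od$disc_center + rot)) %in% c("TS", "NS"))
  # the four diagonal directions get four distinct labels
  pts <- rbind(c(450, 250), c(450, 350), c(550, 250), c(550, 350))
  expect_setequal(cls(pts), c("TS", "TI", "NS", "NI"))
})

test_that("mirrored OS landmarks reproduce OD quadrant labels", {
  W <- 1000
  lm_os <- landmarks(disc_center = c(W + 1 - 500, 300), disc_radius = 10,
                     fovea = c(W + 1 - 400, 300), laterality = "OS")
  set.seed(1)
  pts <- cbind(runif(200, 1, W), runif(200, 1, 600))
  mirrored <- cbind(W + 1 - pts[, 1], pts[, 2])
  expect_equal(classify_quadrant(pts, lm_od),
               classify_quadrant(mirrored, lm_os))
})

test_that("quadrant labels are invariant under rigid scene motion", {
  set.seed(2)
  pts <- cbind(runif(100, 0, 900), runif(100, 0, 900))
  theta <- 0.61; tr <- c(31, -17)
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  move <- function(p) sweep(p %*% t(Rm), 2, -tr)
  lm2 <- landmarks(disc_center = as.numeric(move(rbind(lm_od$disc_center))),
                   disc_radius = 10,
                   fovea = as.numeric(move(rbind(lm_od$fovea))),
                   laterality = "OD")
  expect_equal(classify_quadrant(pts, lm_od),
               classify_quadrant(move(pts), lm2))
})

test_that("annulus filter bounds are inclusive and exact", {
  mk <- function(r) rbind(lm_od$disc_center + c(r * 10, 0))
  expect_equal(nrow(annulus_filter(mk(6.5), lm_od)), 1)   # boundary kept
  expect_equal(nrow(annulus_filter(mk(8.5), lm_od)), 1)
  expect_equal(nrow(annulus_filter(mk(6.49), lm_od)), 0)
  expect_equal(nrow(annulus_filter(mk(8.51), lm_od)), 0)
  # radial centerline sampled every 0.1 radii from 5.0 to 10.0: 21 retained
  r <- seq(50, 100, by = 1)  # px; disc radius 10 -> 5.0 to 10.0 radii
  pts <- cbind(lm_od$disc_center[1] + r, lm_od$disc_center[2])
  expect_equal(nrow(annulus_filter(pts, lm_od)), 21)
})

test_that("annulus filter is idempotent and order-independent", {
  set.seed(3)
  pts <- cbind(runif(500, 400, 700), runif(500, 100, 500))
  once <- annulus_filter(pts, lm_od)
  expect_equal(annulus_filter(once, lm_od), once)
  perm <- sample(nrow(pts))
  reord <- annulus_filter(pts[perm, ], lm_od)
  expect_setequal(paste(reord[, 1], reord[, 2]),
                  paste(once[, 1], once[, 2]))
})

make_seg <- function(pts, widths = rep(5, nrow(pts)), id = "s1",
                     type = "artery") {
  structure(list(vessel_id = id, vessel_type = type,
                 centerline = pts, width_px = widths,
                 nodes = NULL, component = 1L), class = "vessel_segment")
}

test_that("segment quadrant assignment: majority and tie-break", {
  d <- lm_od$disc_center
  # 10 points at 7 radii: all in NI (down-right of disc for OD)
  ni <- cbind(d[1] + 70, d[2] + seq(5, 50, by = 5))
  expect_equal(assign_quadrant(make_seg(ni), lm_od), "NI")
  # 6 points TS vs 4 points TI -> TS
  ts <- cbind(d[1] - 70, d[2] - seq(2, 12, by = 2))
  ti <- cbind(d[1] - 70, d[2] + seq(2, 8, by = 2))
  expect_equal(assign_quadrant(make_seg(rbind(ts, ti)), lm_od), "TS")
  # 1-1 tie: the point nearer 7.5 radii decides (TI point at 7.5 exactly)
  tie <- rbind(c(d[1] - 70, d[2] - 1),   # TS at 7.0 radii
               c(d[1] - 75, d[2] + 1))   # TI at ~7.5 radii
  expect_equal(assign_quadrant(make_seg(tie), lm_od), "TI")
  # no in-annulus points -> unmeasurable
  near <- cbind(d[1] + 20, d[2] + 1:5)
  expect_true(is.na(assign_quadrant(make_seg(near), lm_od)))
})

test_that("width measurement converts px to mm at the local scale", {
  model <- projection_model(eye_radius = 12, px_per_mm = 10,
                            center_px = c(0, 0))
  # annulus around a disc 75 px left of the tangent point passes through it
  lmk <- landmarks(disc_center = c(-75, 0), disc_radius = 10,
                   fovea = c(-175, 0), laterality = "OD")
  pts <- cbind(seq(-3, 3), 0)  # at the tangent point, scale = 1/10 mm/px
  m <- measure_width(make_seg(pts, widths = rep(1, 7)), lmk, model)
  expect_equal(m$mean_width_mm, 0.1, tolerance = 1e-4)
  expect_equal(m$n_pixels, 7)
  seg_out <- make_seg(cbind(seq(-3, 3), 500))  # far outside the annulus
  expect_error(measure_width(seg_out, lmk, model), "unmeasurable")
})

test_that("selection keeps one artery and one vein per quadrant", {
  model <- projection_model(12, 10, c(500, 300))
  d <- lm_od$disc_center
  mk_q <- function(dx, dy, id, type, n = 10) {
    ang <- atan2(dy, dx)
    r <- seq(66, 84, length.out = n)
    make_seg(cbind(d[1] + r * cos(ang), d[2] + r * sin(ang)),
             id = id, type = type)
  }
  segs <- list(
    mk_q(-1, -1, "a_ts", "artery"), mk_q(-1.2, -0.8, "v_ts", "vein"),
    mk_q(-1, 1, "a_ti", "artery"),  mk_q(-0.8, 1.2, "v_ti", "vein"),
    mk_q(1, -1, "a_ns", "artery"),  mk_q(1.2, -0.8, "v_ns", "vein"),
    mk_q(1, 1, "a_ni", "artery"),   mk_q(0.8, 1.2, "v_ni", "vein"))
  sel <- select_vessels(segs, lm_od, model)
  expect_equal(nrow(sel$measurements), 8)
  expect_equal(nrow(sel$absent), 0)
  # drop the NI artery: 7 selected, the pair reported absent
  sel7 <- select_vessels(segs[-7], lm_od, model)
  expect_equal(nrow(sel7$measurements), 7)
  expect_equal(sel7$absent,
               data.frame(quadrant = "NI", vessel_type = "artery",
                          stringsAsFactors = FALSE))
  # two NI arteries: the one with more in-annulus points wins
  extra <- mk_q(1.05, 0.95, "a_ni_big", "artery", n = 25)
  sel2 <- select_vessels(c(segs, list(extra)), lm_od, model)
  ni_a <- sel2$measurements[sel2$measurements$quadrant == "NI" &
                            sel2$measurements$vessel_type == "artery", ]
  expect_equal(ni_a$vessel_id, "a_ni_big")
  # selection is invariant to input order
  set.seed(4)
  for (i in 1:5) {
    perm <- sample(length(segs))
    selp <- select_vessels(segs[perm], lm_od, model)
    expect_equal(selp$measurements[order(selp$measurements$vessel_id), ],
                 sel$measurements[order(sel$measurements$vessel_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("full scene measurement recovers ground truth and is deterministic", {
  eye <- eye_model()
  tree <- grow_vessel_tree(eye, seed = 7)
  scene <- render_fundus(eye, tree, resolution = 768)
  r1 <- measure_scene(scene)
  r2 <- measure_scene(scene)
  expect_identical(r1, r2)
  m <- r1$measurements
  expect_equal(nrow(m), 8)
  expect_equal(nrow(r1$absent), 0)
  expect_true(all(m$n_pixels >= 20))
  expect_true(all(m$quadrant == vapply(
    strsplit(m$vessel_id, "_"), `[[`, "", 1)))
  rel <- abs(m$mean_width_mm - m$true_annulus_mean_mm) /
    m$true_annulus_mean_mm
  expect_lt(max(rel), 0.05)
})

test_that("mirror-symmetric eyes yield matching measurements", {
  for (lat in c("OD", "OS")) {
    eye <- eye_model(laterality = lat)
    tree <- grow_vessel_tree(eye, seed = 21)
    scene <- suppressWarnings(render_fundus(eye, tree, resolution = 512))
    m <- measure_scene(scene)$measurements
    expect_equal(nrow(m), 8)
    expect_true(all(m$quadrant == vapply(
      strsplit(m$vessel_id, "_"), `[[`, "", 1)))
  }
})

test_that("blank image produces no measurements and a full absence report", {
  lmk <- lm_od
  res <- suppressWarnings(
    image_to_measurements(matrix(0.85, 256, 256), lmk,
                          projection_model(12, 10, c(128, 128)),
                          seeds = data.frame(x = 1, y = 1,
                                             vessel_id = "v",
                                             vessel_type = "artery")))
  expect_equal(nrow(res$measurements), 0)
  expect_equal(nrow(res$absent), 8)
})
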
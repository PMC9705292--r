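test_that("eye model construction and laterality symmetry", {
  od <- eye_model(laterality = "OD")
  os <- eye_model(laterality = "OS")
  m <- eye_projection(od, px_per_mm = 10, center_px = c(0, 0))
  disc_od <- project_sphere(od$disc_center, m)
  disc_os <- project_sphere(os$disc_center, m)
  # OD: disc nasal = image-right of the fovea; OS mirrored
  expect_gt(disc_od[1], 0)
  expect_lt(disc_os[1], 0)
  expect_equal(disc_od[1], -disc_os[1])
  e <- eye_model(radius = 12, disc_ecc_deg = 15, disc_radius = 0.9)
  expect_s3_class(e, "eye_model")
})

test_that("degenerate eye geometry is rejected", {
  expect_error(eye_model(fovea_ecc_deg = 15, fovea_meridian_deg = 0),
               "coincides")
  expect_error(eye_model(disc_radius = 4), "radius/4")
  expect_error(eye_model(radius = -1))
})

test_that("vessel tree has one artery and one vein per quadrant", {
  tree <- grow_vessel_tree(eye_model(), n_per_quadrant = 1, seed = 3)
  expect_length(tree, 8)
  key <- sapply(tree, function(v) paste(v$quadrant, v$vessel_type))
  expect_setequal(key, c(outer(c("TS", "TI", "NS", "NI"),
                               c("artery", "vein"), paste)))
  for (v in tree) {
    expect_true(all(diff(v$width_mm) < 0))      # strictly tapering
    expect_true(all(v$width_mm > 0))
    expect_gte(max(v$r_disc), 8.5)              # reaches past the annulus
    expect_equal(v$r_disc[1], 1)                # starts at the disc margin
    expect_gte(sum(v$r_disc >= 6.5 & v$r_disc <= 8.5), 20)
  }
  expect_length(grow_vessel_tree(eye_model(), n_per_quadrant = 0), 0)
})

test_that("vessel tree generation is deterministic in the seed", {
  t1 <- grow_vessel_tree(eye_model(), seed = 1)
  t2 <- grow_vessel_tree(eye_model(), seed = 1)
  t3 <- grow_vessel_tree(eye_model(), seed = 2)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("linear taper hits the configured annulus mean analytically", {
  tree <- grow_vessel_tree(eye_model(),
                           taper = list(family = "linear", w0 = 0.12,
                                        annulus_width = 0.084,
                                        width_jitter = 0),
                           seed = 1)
  for (v in tree)
    expect_equal(v$true_annulus_mean_mm, 0.084, tolerance = 0.01)
})

test_that("non-positive taper widths are rejected", {
  expect_error(grow_vessel_tree(eye_model(),
                                taper = list(w0 = 0.6,
                                             annulus_width = 0.02,
                                             width_jitter = 0),
                                seed = 1),
               "non-positive")
})

test_that("rendering: empty scene, determinism, landmark annotation", {
  eye <- eye_model()
  blank <- render_fundus(eye, list(), resolution = 256)
  expect_equal(diff(range(blank$image)), 0)
  expect_s3_class(blank$landmarks, "landmarks")
  expect_equal(blank$landmarks$laterality, "OD")
  tree <- grow_vessel_tree(eye, seed = 5)
  s1 <- suppressWarnings(
    render_fundus(eye, tree, resolution = 512, noise = 0.02, seed = 9))
  s2 <- suppressWarnings(
    render_fundus(eye, tree, resolution = 512, noise = 0.02, seed = 9))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$label, s2$label)
  # label map covers each vessel
  expect_setequal(setdiff(unique(as.integer(s1$label)), 0L),
                  seq_along(tree))
})

test_that("a straight constant-width vessel renders true to width at the tangent point", {
  eye <- eye_model()
  # synthetic straight vessel through the projection centre
  ecc <- c(seq(0.35, 0.002, by = -0.002), seq(0.002, 0.35, by = 0.002))
  mer <- c(rep(pi / 2, sum(ecc <= 0.35) / 2), rep(3 * pi / 2, sum(ecc <= 0.35) / 2))
  n <- length(ecc)
  w_mm <- 0.25
  v <- structure(list(vessel_id = "straight", vessel_type = "artery",
                      quadrant = "TS",
                      path = sphere_point(ecc, mer[seq_len(n)]),
                      width_mm = rep(w_mm, n),
                      arc_mm = seq_len(n), r_disc = rep(7.5, n),
                      true_annulus_mean_mm = w_mm),
                 class = "gt_vessel")
  scene <- render_fundus(eye, list(v), resolution = 512)
  bw <- segment_vessels(scene$image)
  segs <- extract_centerlines(bw)
  expect_gte(length(segs), 1)
  seg <- segs[[which.max(sapply(segs, function(s) nrow(s$centerline)))]]
  ctr <- scene$model$center_px
  i <- which.min((seg$centerline[, 1] - ctr[1])^2 +
                 (seg$centerline[, 2] - ctr[2])^2)
  w_meas <- seg$width_px[i] * pixel_scale_mm(seg$centerline[i, , drop = FALSE],
                                             scene$model)
  px_mm <- 1 / pixel_scale_mm(cbind(ctr[1], ctr[2]), scene$model)
  expect_lt(abs(w_meas - w_mm) * px_mm, 1)  # within one pixel
})

test_that("cohort nulls: zero effects give identical group means", {
  cfg <- null_cohort_config(n = 20, noise = 0)
  ch <- simulate_cohort(cfg)
  b <- merge(ch$baseline, ch$subjects[, c("subject_id", "group")])
  for (o in c("rnfl_global", "macular_volume", "width_artery_ni")) {
    expect_equal(mean(b[[o]][b$group == "MS"]),
                 mean(b[[o]][b$group == "HV"]))
  }
})

test_that("a configured disease effect appears exactly without noise", {
  outs <- c(oct_outcomes(), vessel_outcomes())
  zero <- setNames(rep(0, length(outs)), outs)
  bd <- zero; bd["rnfl_global"] <- -10
  cfg <- cohort_config(n_per_group = c(MS = 15, HV = 15),
                       beta_disease = bd, beta_age = zero, beta_sex = zero,
                       noise_sd = zero, seed = 4)
  ch <- simulate_cohort(cfg)
  b <- merge(ch$baseline, ch$subjects[, c("subject_id", "group")])
  expect_equal(mean(b$rnfl_global[b$group == "MS"]) -
               mean(b$rnfl_global[b$group == "HV"]), -10)
  expect_equal(mean(b$rnfl_t[b$group == "MS"]) -
               mean(b$rnfl_t[b$group == "HV"]), 0)
})

test_that("generator faithfulness: mean difference converges (CLT check)", {
  outs <- c(oct_outcomes(), vessel_outcomes())
  zero <- setNames(rep(0, length(outs)), outs)
  bd <- zero; bd["rnfl_global"] <- -10
  ns <- zero; ns["rnfl_global"] <- 5
  cfg <- cohort_config(n_per_group = c(MS = 10000, HV = 10000),
                       beta_disease = bd, beta_age = zero, beta_sex = zero,
                       noise_sd = ns, seed = 11)
  ch <- simulate_cohort(cfg)
  b <- merge(ch$baseline, ch$subjects[, c("subject_id", "group")])
  b <- b[b$eye == "OD", ]
  d <- mean(b$rnfl_global[b$group == "MS"]) -
    mean(b$rnfl_global[b$group == "HV"])
  se <- 5 * sqrt(2 / 10000)
  expect_lt(abs(d - (-10)), 3 * se)
})

test_that("cohort simulation is reproducible and validates group size", {
  cfg <- null_cohort_config(n = 5, seed = 7)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_error(simulate_cohort(cohort_config(n_per_group = c(MS = 1, HV = 10))),
               "at least 2")
})

test_that("visits: spans within configured range, slopes exact when noiseless", {
  outs <- c(oct_outcomes(), vessel_outcomes())
  zero <- setNames(rep(0, length(outs)), outs)
  cfg <- cohort_config(n_per_group = c(MS = 12, HV = 12),
                       beta_disease = zero, beta_age = zero, beta_sex = zero,
                       noise_sd = zero, visit_noise_sd = zero,
                       p_optic_neuritis = 0, seed = 3)
  ch <- simulate_cohort(cfg)
  vis <- simulate_visits(ch, cfg)
  expect_identical(vis, simulate_visits(ch, cfg))  # deterministic
  for (sid in unique(vis$subject_id)) {
    v <- vis[vis$subject_id == sid & vis$eye == "OD", ]
    g <- ch$subjects$group[ch$subjects$subject_id == sid]
    nv <- nrow(v)
    expect_true(nv >= cfg$visits_range[[g]][1] &&
                nv <= cfg$visits_range[[g]][2])
    if (nv >= 2) {
      span <- as.numeric(max(v$visit_date) - min(v$visit_date))
      expect_true(span >= cfg$visit_interval_range[[g]][1] &&
                  span <= cfg$visit_interval_range[[g]][2])
      # noiseless evolution is exactly linear at the configured slope
      yrs <- as.numeric(v$visit_date - min(v$visit_date)) / 365.25
      slope <- cfg$annual_slope[[g]][["rnfl_global"]]
      expect_equal(v$rnfl_global, v$rnfl_global[1] + slope * yrs,
                   tolerance = 1e-10)
    }
  }
})

test_that("zero slope and zero noise give constant visit values", {
  outs <- c(oct_outcomes(), vessel_outcomes())
  zero <- setNames(rep(0, length(outs)), outs)
  cfg <- cohort_config(n_per_group = c(MS = 6, HV = 6),
                       beta_disease = zero, beta_age = zero, beta_sex = zero,
                       noise_sd = zero, visit_noise_sd = zero,
                       annual_slope = list(MS = zero, HV = zero),
                       p_optic_neuritis = 0, seed = 5)
  ch <- simulate_cohort(cfg)
  vis <- simulate_visits(ch, cfg)
  for (o in oct_outcomes())
    expect_equal(length(unique(round(
      tapply(vis[[o]], paste(vis$subject_id, vis$eye),
             function(x) diff(range(x))), 12))), 1)
})

test_that("scene and cohort files round-trip through disk formats", {
  dir <- tempfile()
  eye <- eye_model(laterality = "OS")
  tree <- grow_vessel_tree(eye, seed = 2)
  scene <- render_fundus(eye, tree, resolution = 256, field_mm = 24)
  suppressWarnings(write_scene(scene, dir, "t"))
  expect_true(all(file.exists(file.path(dir, c(
    "t.png", "t_label.tif", "t_landmarks.json", "t_scene.yaml")))))
  rl <- read_landmarks(file.path(dir, "t_landmarks.json"))
  expect_equal(rl$landmarks$disc_center, scene$landmarks$disc_center)
  expect_equal(rl$landmarks$laterality, "OS")
  expect_equal(rl$model$px_per_mm, scene$model$px_per_mm)
  img <- png::readPNG(file.path(dir, "t.png"))
  expect_equal(dim(img), c(256, 256))
  cfg <- null_cohort_config(n = 3)
  ch <- simulate_cohort(cfg)
  paths <- write_cohort(ch, simulate_visits(ch, cfg), cfg, dir)
  expect_true(all(file.exists(paths)))
  rec <- load_oct_records(paths[["visits"]])
  expect_s3_class(rec$visit_date, "Date")
  expect_equal(nrow(rec), sum(!is.na(read.csv(paths[["visits"]])$subject_id)))
})
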
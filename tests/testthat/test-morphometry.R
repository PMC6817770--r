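test_that("areas are pixel counts times squared calibration", {
  lab <- matrix(0L, 8, 8)
  lab[3:6, 3:6] <- 2L          # 16 px frame-ish block
  lab[4:5, 4:5] <- 1L          # 4 lumen px, leaving 12 wall px
  v <- segmented_vessel(lab, 0.5)
  a <- compute_areas(v)
  expect_equal(unname(a), c(4 * 0.25, 12 * 0.25))
  # conservation: all pixels accounted for
  expect_identical(sum(v$labels == 0L) + sum(v$labels == 1L) + sum(v$labels == 2L),
                   length(v$labels))
})

test_that("rasterized annulus areas and ratios match the analytic circle", {
  res <- make_vessel(annulus_spec(5, 3), 0.05)
  a <- compute_areas(res$vessel)
  expect_lt(abs(a[["lumen_area"]] - 78.53982) / 78.53982, 0.01)
  expect_lt(abs(a[["wall_area"]] - 122.5221) / 122.5221, 0.01)
  m <- measure(res$vessel)
  expect_lt(abs(m$area_ratio - 25 / 39) / (25 / 39), 0.01)
})

test_that("rescaling the calibration scales areas by k^2 and fixes ratios", {
  v1 <- make_vessel(annulus_spec(3, 1.2), 0.1)$vessel
  v2 <- segmented_vessel(v1$labels, 0.1 * 3, vessel_id = v1$vessel_id)
  a1 <- compute_areas(v1); a2 <- compute_areas(v2)
  expect_equal(unname(a2), unname(a1) * 9)
  m1 <- measure(v1, area_floor = 0); m2 <- measure(v2, area_floor = 0)
  expect_equal(m1$area_ratio, m2$area_ratio)
  expect_equal(m1$diameter_ratio, m2$diameter_ratio, tolerance = 1e-6)
})

test_that("equivalent diameter follows its closed form", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(2 * pi), 2 * sqrt(2))
  a <- 3.7
  expect_equal(equivalent_diameter(2 * a), sqrt(2) * equivalent_diameter(a))
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(-1), "positive")
})

test_that("Feret diameters bracket the equivalent diameter on an ellipse", {
  v <- make_vessel(vessel_spec(c(4, 2), 1), 0.05)$vessel
  expect_lt(abs(lumen_diameter(v, "feret_max") - 8) / 8, 0.02)
  expect_lt(abs(lumen_diameter(v, "feret_min") - 4) / 4, 0.02)
  d_eq <- lumen_diameter(v, "equivalent")
  expect_lt(lumen_diameter(v, "feret_min"), d_eq)
  expect_gt(lumen_diameter(v, "feret_max"), d_eq)
})

test_that("ray-cast thickness recovers constant-thickness rings", {
  res <- make_vessel(annulus_spec(1, 1), 0.02)
  tw <- mean_wall_thickness(res$vessel)
  expect_lt(abs(as.numeric(tw) - 1), 0.02)
  expect_identical(attr(tw, "method"), "ray")
  expect_gt(attr(tw, "valid_ray_fraction"), 0.99)

  # constant radial offset on a perturbed ellipse
  res2 <- make_vessel(vessel_spec(c(4, 2), 0.5, boundary_perturbation = 0.08,
                                  seed = 11L), 0.02)
  expect_lt(abs(as.numeric(mean_wall_thickness(res2$vessel)) - 0.5) / 0.5, 0.05)
})

test_that("thickness is insensitive to 90-degree mask rotation", {
  v <- make_vessel(vessel_spec(c(5, 3), 1.5, seed = 4L), 0.05)$vessel
  t0 <- as.numeric(mean_wall_thickness(v))
  vr <- segmented_vessel(rot90(v$labels), v$microns_per_pixel)
  t1 <- as.numeric(mean_wall_thickness(vr))
  expect_lt(abs(t1 - t0) / t0, 0.01)
})

test_that("centroid outside the lumen triggers the distance-transform fallback", {
  # C-shaped lumen: annular band with an angular gap; centroid in the hole
  n <- 101L
  ctr <- (n + 1) / 2
  xy <- expand.grid(row = 1:n, col = 1:n)
  dx <- xy$col - ctr; dy <- xy$row - ctr
  r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
  lab <- matrix(0L, n, n)
  lumen <- r >= 18 & r <= 30 & abs(th) > pi / 5
  lab[lumen] <- 1L
  wall <- !lumen & r >= 14 & r <= 34 &
    (abs(th) > pi / 5 - 0.35 | (r >= 18 & r <= 30))
  lab[wall & lab == 0L] <- 2L
  v <- segmented_vessel(lab, 0.1, validate = FALSE)
  expect_warning(tw <- mean_wall_thickness(v), "distance-transform")
  expect_identical(attr(tw, "method"), "distance_transform")
  expect_true(is.finite(as.numeric(tw)) && as.numeric(tw) > 0)
})

test_that("the distance-transform estimator is accurate on rings", {
  v <- make_vessel(annulus_spec(2, 1.5), 0.02)$vessel
  t_dt <- vesselmorph:::.thickness_distance_transform(v)
  expect_lt(abs(t_dt - 1.5) / 1.5, 0.05)
})

test_that("the exclusion filter uses a strict 70 um^2 floor, in order", {
  # block vessel: 6x6 lumen + 2px wall frame -> 100 total px
  mk <- function(total_um2, ...) {
    block_vessel(6L, 2L, microns_per_pixel = sqrt(total_um2 / 100), ...)
  }
  just_below <- measure(mk(69.9, vessel_id = "below"))
  at_floor <- measure(mk(70.0, vessel_id = "at"))
  large <- measure(mk(250, vessel_id = "large"))
  expect_true(just_below$excluded)
  expect_identical(just_below$exclusion_reason, "too_small")
  expect_false(at_floor$excluded)      # strictly less-than floor
  expect_false(large$excluded)

  # excluded vessels still carry their measurements
  expect_true(is.finite(just_below$area_ratio))

  # precedence: pathology and plane beat size
  path <- measure(mk(69.9, vessel_id = "p", pathology_flag = TRUE))
  expect_identical(path$exclusion_reason, "pathology")
  obl <- measure(mk(69.9, vessel_id = "o", transverse_plane = FALSE))
  expect_identical(obl$exclusion_reason, "not_transverse")
})

test_that("unit annulus yields the closed-form ratios", {
  res <- make_vessel(annulus_spec(1, 1), 0.01)
  m <- measure(res$vessel, area_floor = 0)
  expect_lt(abs(m$area_ratio - 1 / 3) / (1 / 3), 0.01)
  expect_lt(abs(m$diameter_ratio - 2) / 2, 0.02)
})

test_that("growing the wall outward strictly decreases the area ratio", {
  thicknesses <- c(0.5, 1, 1.5, 2.5)
  ratios <- vapply(thicknesses, function(t) {
    measure(make_vessel(annulus_spec(4, t), 0.1)$vessel, area_floor = 0)$area_ratio
  }, 0)
  expect_true(all(diff(ratios) < 0))
})

test_that("measured quantities agree with generator truth", {
  pop <- population_spec(n_group1 = 4, n_group2 = 3, microns_per_pixel = 0.05,
                         master_seed = 21L)
  vs <- sample_population(pop)
  tr <- truth_table(vs)
  mm <- measure_batch(vs)
  expect_true(all(abs(mm$lumen_area - tr$true_lumen_area) /
                    tr$true_lumen_area < 0.01))
  expect_true(all(abs(mm$wall_area - tr$true_wall_area) /
                    tr$true_wall_area < 0.01))
})

test_that("thickness cross-check reports both estimators when they disagree", {
  v <- make_vessel(annulus_spec(3, 1), 0.05)$vessel
  rec <- measure(v, thickness_check = TRUE)
  expect_true("thickness_dt" %in% names(rec))
  expect_lt(abs(rec$thickness_dt - rec$mean_thickness) / rec$mean_thickness, 0.1)
})
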
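test_that("annulus truth matches the analytic circle areas", {
  res <- make_vessel(annulus_spec(5, 3), microns_per_pixel = 0.05)
  expect_equal(res$truth$true_lumen_area, pi * 25, tolerance = 1e-10)
  expect_equal(res$truth$true_wall_area, pi * (64 - 25), tolerance = 1e-10)
  expect_equal(res$truth$true_total_area,
               res$truth$true_lumen_area + res$truth$true_wall_area)
  expect_equal(res$truth$true_area_ratio,
               res$truth$true_lumen_area / res$truth$true_wall_area)
  expect_equal(res$truth$true_mean_thickness, 3, tolerance = 1e-12)

  areas <- compute_areas(res$vessel)
  expect_lt(abs(areas[["lumen_area"]] - pi * 25) / (pi * 25), 0.01)
  expect_lt(abs(areas[["wall_area"]] - pi * 39) / (pi * 39), 0.01)
})

test_that("rotation leaves the truth identical and raster areas nearly so", {
  base <- make_vessel(vessel_spec(c(6, 3), 1.2, thickness_modulation = 0.3,
                                  boundary_perturbation = 0.1, seed = 42L),
                      microns_per_pixel = 0.05)
  rot <- make_vessel(vessel_spec(c(6, 3), 1.2, thickness_modulation = 0.3,
                                 boundary_perturbation = 0.1, seed = 42L,
                                 rotation = pi / 5),
                     microns_per_pixel = 0.05)
  expect_identical(base$truth[names(base$truth) != "spec"],
                   rot$truth[names(rot$truth) != "spec"])
  a0 <- compute_areas(base$vessel)
  a1 <- compute_areas(rot$vessel)
  expect_lt(abs(a1[["lumen_area"]] - a0[["lumen_area"]]) / a0[["lumen_area"]], 0.005)
  expect_lt(abs(a1[["wall_area"]] - a0[["wall_area"]]) / a0[["wall_area"]], 0.005)
})

test_that("elliptical lumen with constant offset wall reproduces closed forms", {
  res <- make_vessel(vessel_spec(c(4, 2), 1), microns_per_pixel = 0.05)
  expect_equal(res$truth$true_lumen_area, 8 * pi, tolerance = 1e-9)
  expect_equal(res$truth$true_equiv_diameter, 2 * sqrt(8), tolerance = 1e-9)
  tw <- mean_wall_thickness(res$vessel)
  expect_lt(abs(as.numeric(tw) - 1), 0.05)
})

test_that("identical spec and seed give identical raster and truth", {
  s <- vessel_spec(c(5, 4), 0.8, thickness_modulation = 0.4,
                   boundary_perturbation = 0.15, seed = 7L)
  r1 <- make_vessel(s, 0.1)
  r2 <- make_vessel(s, 0.1)
  expect_identical(r1$vessel$labels, r2$vessel$labels)
  expect_identical(r1$truth, r2$truth)

  pop <- population_spec(n_group1 = 3, n_group2 = 2, microns_per_pixel = 0.2,
                         master_seed = 5L)
  t1 <- attr(sample_population(pop), "truth_table")
  t2 <- attr(sample_population(pop), "truth_table")
  expect_identical(t1, t2)
})

test_that("raster areas converge to truth as the pixel size shrinks", {
  specs <- list(annulus_spec(4, 1.5),
                vessel_spec(c(5, 2.5), 1, thickness_modulation = 0.3,
                            boundary_perturbation = 0.12, seed = 3L),
                vessel_spec(c(3, 2.8), 2.2, seed = 9L))
  err_at <- function(mpp) {
    mean(vapply(specs, function(s) {
      res <- make_vessel(s, mpp)
      a <- compute_areas(res$vessel)
      abs(a[["lumen_area"]] - res$truth$true_lumen_area) / res$truth$true_lumen_area +
        abs(a[["wall_area"]] - res$truth$true_wall_area) / res$truth$true_wall_area
    }, 0))
  }
  errs <- vapply(c(0.2, 0.1, 0.05), err_at, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("sampled true ratios always lie inside the group supports", {
  pop <- population_spec(master_seed = 13L)
  specs <- sample_population_specs(pop)
  truths <- vapply(specs, function(s) vessel_truth(s)$true_area_ratio, 0)
  groups <- vapply(specs, function(s) s$group_label, "")
  expect_length(truths, 112L)
  expect_identical(sum(groups == "venule_like"), 81L)
  expect_identical(sum(groups == "arteriole_like"), 31L)
  g1 <- truths[groups == "venule_like"]
  g2 <- truths[groups == "arteriole_like"]
  expect_true(all(g1 >= 1.89 & g1 <= 10.96))
  expect_true(all(g2 >= 0.27 & g2 <= 1.57))
})

test_that("wall thickness is solved to hit the sampled target ratio", {
  # a near-degenerate sampler support pins every target ratio at 3
  narrow <- ratio_sampler(c(3, 3 + 1e-9), mean = 3 + 5e-10, shape1 = 1)
  pop <- population_spec(n_group1 = 4, n_group2 = 0,
                         ratio_sampler_group1 = narrow, master_seed = 2L)
  truths <- vapply(sample_population_specs(pop),
                   function(s) vessel_truth(s)$true_area_ratio, 0)
  expect_true(all(abs(truths - 3) < 1e-6))
})

test_that("degenerate population sizes work", {
  pop <- population_spec(n_group1 = 0, n_group2 = 1, microns_per_pixel = 0.2,
                         master_seed = 1L)
  vs <- sample_population(pop)
  expect_length(vs, 1L)
  expect_identical(vs[[1]]$truth$spec$group_label, "arteriole_like")
})

test_that("invalid specs and undersized images are rejected", {
  expect_error(vessel_spec(c(2, 3), 1), "a >= b")
  expect_error(vessel_spec(c(3, 2), -1), "wall_thickness_base")
  expect_error(vessel_spec(c(3, 2), 1, thickness_modulation = 0.6), "0, 0.5")
  expect_error(vessel_spec(c(3, 2), 1, boundary_perturbation = 0.3), "0, 0.2")
  expect_error(make_vessel(annulus_spec(5, 3), 0.05, image_size = 100),
               "does not fit")
})

test_that("pathology flag renders normally but is carried on the mask", {
  s <- annulus_spec(4, 1, pathology_flag = TRUE)
  res <- make_vessel(s, 0.1)
  expect_true(res$vessel$pathology_flag)
  plain <- make_vessel(annulus_spec(4, 1), 0.1)
  expect_identical(res$vessel$labels, plain$vessel$labels)
})
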
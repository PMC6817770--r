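## Synthetic vessel cross-sections with exact geometric ground truth.
##
## A vessel is built in polar coordinates about its lumen centre. The lumen
## boundary is a polar ellipse modulated by a low-order Fourier perturbation,
##   rho_L(theta) = r_e(theta) * (1 + sum_k c_k cos(k theta + phi_k)),  k = 2..4
## and the wall is a radial offset band of angularly varying thickness,
##   rho_out(theta) = rho_L(theta) + t0 * (1 + m cos(2 theta + phi_t)).
## Both curves are star-shaped by construction, so they can never
## self-intersect while the radii stay positive, and the wall is always a
## topologically closed annulus. All truth quantities are computed by
## trapezoidal quadrature on the periodic boundary functions (spectrally
## accurate for these smooth curves), never from the raster.

# quadrature grid size for truth integrals
.NQ <- 4096L

.quad_theta <- function() {
  seq(0, 2 * pi, length.out = .NQ + 1L)[-(.NQ + 1L)]
}

# polar radius of an axis-aligned ellipse with semi-axes a >= b
.ellipse_rho <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# lumen polar radius for a spec (rotation excluded: truth is rotation-invariant)
.lumen_rho <- function(theta, spec) {
  p <- 0
  ck <- spec$perturbation_coef
  ph <- spec$perturbation_phase
  if (length(ck)) {
    for (j in seq_along(ck)) p <- p + ck[j] * cos((j + 1L) * theta + ph[j])
  }
  .ellipse_rho(theta, spec$lumen_semi_axes[1L], spec$lumen_semi_axes[2L]) * (1 + p)
}

# angular thickness profile
.thickness_profile <- function(theta, spec) {
  spec$wall_thickness_base *
    (1 + spec$thickness_modulation * cos(2 * theta + spec$thickness_phase))
}

#' Specify one synthetic vessel cross-section
#'
#' Defines the exact geometry of a synthetic vessel: an elliptical lumen with
#' a low-order Fourier boundary perturbation, surrounded by a radial-offset
#' wall band of angularly varying thickness. The perturbation amplitude is
#' split across angular modes `k = 2, 3, 4` (mode weights and phases default to
#' a deterministic draw from `seed`, so a spec is fully reproducible).
#'
#' @param lumen_semi_axes Numeric length-2 `(a, b)` in micrometers, `a >= b > 0`.
#' @param wall_thickness_base Base (angular-mean) wall thickness `t0` in
#'   micrometers, strictly positive.
#' @param thickness_modulation Amplitude `m` in `[0, 0.5]` of the `cos(2 theta)`
#'   thickness variation; `m < 1` keeps the wall closed everywhere.
#' @param boundary_perturbation Total amplitude in `[0, 0.2]` of the lumen
#'   boundary perturbation (sum of the mode amplitudes).
#' @param rotation Rotation of the whole vessel in radians (affects only the
#'   raster; all truth quantities are rotation-invariant).
#' @param group_label `"venule_like"` or `"arteriole_like"`.
#' @param pathology_flag Logical, propagated to the mask; exercises the
#'   upstream exclusion plumbing only (the geometry is rendered normally).
#' @param seed Integer seed identifying the vessel; used to derive the
#'   perturbation mode weights/phases when they are not given explicitly.
#' @param thickness_phase Phase of the thickness modulation in radians,
#'   measured from the lumen major axis (`pi` puts the thickest wall on the
#'   flattened sides, as in a collapsed venule). Default: drawn from `seed`.
#' @param perturbation_weights Optional length-3 non-negative weights for modes
#'   2..4 (normalized to sum to 1). Default: drawn from `seed`.
#' @param perturbation_phases Optional length-3 phases in radians for modes
#'   2..4. Default: drawn from `seed`.
#'
#' @return An object of class `vessel_spec`.
#' @seealso [make_vessel()], [sample_population()]
#' @export
vessel_spec <- function(lumen_semi_axes, wall_thickness_base,
                        thickness_modulation = 0, boundary_perturbation = 0,
                        rotation = 0,
                        group_label = c("venule_like", "arteriole_like"),
                        pathology_flag = FALSE, seed = 1L,
                        thickness_phase = NULL,
                        perturbation_weights = NULL,
                        perturbation_phases = NULL) {
  group_label <- match.arg(group_label)
  a <- lumen_semi_axes[1L]; b <- lumen_semi_axes[2L]
  if (!(is.finite(a) && is.finite(b) && a >= b && b > 0)) {
    stop("invalid lumen semi-axes: need a >= b > 0")
  }
  if (!(is.finite(wall_thickness_base) && wall_thickness_base > 0)) {
    stop("wall_thickness_base must be > 0")
  }
  if (thickness_modulation < 0 || thickness_modulation > 0.5) {
    stop("thickness_modulation must lie in [0, 0.5]")
  }
  if (boundary_perturbation < 0 || boundary_perturbation > 0.2) {
    stop("boundary_perturbation must lie in [0, 0.2]")
  }
  seed <- as.integer(seed)

  need_draw <- is.null(thickness_phase) || is.null(perturbation_weights) ||
    is.null(perturbation_phases)
  if (need_draw) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(seed)
    if (is.null(thickness_phase)) thickness_phase <- stats::runif(1, 0, 2 * pi)
    if (is.null(perturbation_weights)) {
      perturbation_weights <- stats::runif(3, 0.2, 1)
    }
    if (is.null(perturbation_phases)) {
      perturbation_phases <- stats::runif(3, 0, 2 * pi)
    }
  }
  w <- perturbation_weights
  if (length(w) != 3L || any(w < 0) || sum(w) <= 0) {
    stop("perturbation_weights must be 3 non-negative values, not all zero")
  }
  ck <- boundary_perturbation * w / sum(w)

  spec <- structure(
    list(
      lumen_semi_axes = c(a = a, b = b),
      wall_thickness_base = wall_thickness_base,
      thickness_modulation = thickness_modulation,
      thickness_phase = as.numeric(thickness_phase),
      boundary_perturbation = boundary_perturbation,
      perturbation_coef = ck,
      perturbation_phase = as.numeric(perturbation_phases),
      rotation = as.numeric(rotation),
      group_label = group_label,
      pathology_flag = isTRUE(pathology_flag),
      seed = seed
    ),
    class = "vessel_spec"
  )
  # construction check: boundaries must keep strictly positive radius
  th <- .quad_theta()
  if (min(.lumen_rho(th, spec)) <= 0) {
    stop("self-intersecting lumen boundary: perturbation drives the radius to zero")
  }
  if (spec$thickness_modulation >= 1) {
    stop("self-intersecting wall: thickness modulation amplitude must be < 1")
  }
  spec
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Exact ground truth of a vessel specification
#'
#' Computes the analytic truth record of a [vessel_spec()] — areas, area
#' ratio, equivalent diameter and mean thickness — by trapezoidal quadrature
#' of the parametric boundary curves (spectrally accurate for these smooth
#' periodic boundaries), without rasterizing anything.
#'
#' @param spec A [vessel_spec()].
#' @return A `vessel_truth` object; see [make_vessel()].
#' @export
vessel_truth <- function(spec) {
  stopifnot(inherits(spec, "vessel_spec"))
  .vessel_truth(spec)
}

# exact truth quantities by quadrature of the parametric boundaries
.vessel_truth <- function(spec) {
  th <- .quad_theta()
  rho_l <- .lumen_rho(th, spec)
  tt <- .thickness_profile(th, spec)
  lumen_area <- mean(rho_l^2) * pi          # (1/2) int rho^2 dtheta
  total_area <- mean((rho_l + tt)^2) * pi
  wall_area <- total_area - lumen_area
  structure(
    list(
      true_lumen_area = lumen_area,
      true_wall_area = wall_area,
      true_total_area = total_area,
      true_area_ratio = lumen_area / wall_area,
      true_equiv_diameter = 2 * sqrt(lumen_area / pi),
      true_mean_thickness = mean(tt),
      spec = spec
    ),
    class = "vessel_truth"
  )
}

#' @export
print.vessel_truth <- function(x, ...) {
  cat("vessel_truth (", x$spec$group_label, ", seed ", x$spec$seed, ")\n", sep = "")
  cat(sprintf("  lumen %.3f um^2, wall %.3f um^2, ratio %.4f\n",
              x$true_lumen_area, x$true_wall_area, x$true_area_ratio))
  cat(sprintf("  equiv diameter %.3f um, mean thickness %.4f um\n",
              x$true_equiv_diameter, x$true_mean_thickness))
  invisible(x)
}

# solve the base thickness that makes the wall area hit a target exactly.
# wall area is exactly quadratic in t0:
#   A_W(t0) = alpha t0 + beta t0^2,
#   alpha = int rho_L g dtheta,  beta = (1/2) int g^2 dtheta,
#   g(theta) = 1 + m cos(2 theta + phi_t)
.solve_wall_thickness <- function(lumen_semi_axes, perturbation_coef,
                                  perturbation_phase, thickness_modulation,
                                  thickness_phase, target_wall_area) {
  th <- .quad_theta()
  fake <- list(lumen_semi_axes = lumen_semi_axes,
               perturbation_coef = perturbation_coef,
               perturbation_phase = perturbation_phase)
  rho_l <- .lumen_rho(th, fake)
  g <- 1 + thickness_modulation * cos(2 * th + thickness_phase)
  alpha <- mean(rho_l * g) * 2 * pi
  beta <- mean(g^2) * pi
  (-alpha + sqrt(alpha^2 + 4 * beta * target_wall_area)) / (2 * beta)
}

#' Rasterize one synthetic vessel with its analytic ground truth
#'
#' Renders the geometry of a [vessel_spec()] to a calibrated 3-label raster
#' (pixel-center-in-region rule, no anti-aliasing) and returns it together
#' with the exact truth record. Truth areas and thickness come from quadrature
#' of the parametric boundaries, never from the raster, so rasterization error
#' can be measured against them.
#'
#' @param spec A [vessel_spec()].
#' @param microns_per_pixel Pixel calibration in micrometers per pixel.
#' @param image_size Optional square image side in pixels. Default `NULL`
#'   auto-sizes the grid to the vessel (outer boundary plus a 3-pixel margin).
#'   If given and the vessel does not fit, a sizing error is raised.
#' @param vessel_id Identifier for the emitted mask; defaults to
#'   `"<group>_<seed>"`.
#'
#' @return A list with elements `vessel` (a [segmented_vessel()]) and `truth`
#'   (a `vessel_truth` with fields `true_lumen_area`, `true_wall_area`,
#'   `true_total_area`, `true_area_ratio`, `true_equiv_diameter`,
#'   `true_mean_thickness`, `spec`).
#' @examples
#' res <- make_vessel(vessel_spec(c(5, 5), 3), microns_per_pixel = 0.1)
#' res$truth$true_lumen_area   # pi * 25
#' @export
make_vessel <- function(spec, microns_per_pixel, image_size = NULL,
                        vessel_id = NULL) {
  stopifnot(inherits(spec, "vessel_spec"))
  truth <- .vessel_truth(spec)
  th <- .quad_theta()
  rho_out_max <- max(.lumen_rho(th, spec) + .thickness_profile(th, spec))

  half_px_needed <- ceiling(rho_out_max / microns_per_pixel) + 3L
  if (is.null(image_size)) {
    n <- as.integer(2L * half_px_needed + 1L)
  } else {
    n <- as.integer(image_size)
    if ((n - 1L) / 2 < half_px_needed) {
      stop(sprintf(
        "vessel does not fit: outer radius %.2f um needs an image of at least %d px at %.4g um/px (got %d)",
        rho_out_max, 2L * half_px_needed + 1L, microns_per_pixel, n))
    }
  }

  # pixel centers at integer coordinates; vessel centre mid-grid
  cx <- (n + 1) / 2
  idx <- seq_len(n)
  dx <- (matrix(idx, n, n, byrow = TRUE) - cx) * microns_per_pixel  # column -> x
  dy <- (matrix(idx, n, n, byrow = FALSE) - cx) * microns_per_pixel # row -> y
  # undo the vessel rotation
  co <- cos(spec$rotation); si <- sin(spec$rotation)
  x <- co * dx + si * dy
  y <- -si * dx + co * dy
  r2 <- x * x + y * y
  r <- sqrt(r2)
  r[r == 0] <- .Machine$double.eps
  ct <- x / r
  st <- y / r

  # Fourier terms from cos/sin(theta) by recurrence (no per-pixel atan2)
  c2 <- ct * ct - st * st
  s2 <- 2 * ct * st
  c3 <- ct * c2 - st * s2
  s3 <- st * c2 + ct * s2
  c4 <- c2 * c2 - s2 * s2
  s4 <- 2 * s2 * c2

  a <- spec$lumen_semi_axes[1L]; b <- spec$lumen_semi_axes[2L]
  rho_l <- a * b / sqrt((b * ct)^2 + (a * st)^2)
  ck <- spec$perturbation_coef; ph <- spec$perturbation_phase
  pert <- ck[1L] * (c2 * cos(ph[1L]) - s2 * sin(ph[1L])) +
    ck[2L] * (c3 * cos(ph[2L]) - s3 * sin(ph[2L])) +
    ck[3L] * (c4 * cos(ph[3L]) - s4 * sin(ph[3L]))
  rho_l <- rho_l * (1 + pert)
  tt <- spec$wall_thickness_base *
    (1 + spec$thickness_modulation *
       (c2 * cos(spec$thickness_phase) - s2 * sin(spec$thickness_phase)))

  labels <- matrix(0L, n, n)
  labels[r < rho_l + tt] <- 2L
  labels[r < rho_l] <- 1L

  if (is.null(vessel_id)) {
    vessel_id <- paste0(spec$group_label, "_", spec$seed)
  }
  vessel <- segmented_vessel(labels, microns_per_pixel, vessel_id = vessel_id,
                             transverse_plane = TRUE,
                             pathology_flag = spec$pathology_flag,
                             validate = FALSE)
  list(vessel = vessel, truth = truth)
}

#' Scaled-Beta sampler for true lumen:wall area ratios
#'
#' The generator draws each vessel's true area ratio from a Beta distribution
#' rescaled to a bounded support, so sampled ratios can never leave the
#' configured range. Exactly one Beta shape parameter is supplied; the other is
#' solved so the distribution mean equals `mean`.
#'
#' @param support Numeric length-2 `(lo, hi)`, `lo < hi`.
#' @param mean Target mean of the scaled distribution, strictly inside the
#'   support.
#' @param shape1,shape2 The Beta shapes. Supply one and the other is solved
#'   from the mean constraint; supply both (e.g. when restoring a sampler from
#'   a config file) and they are used as-is.
#' @return An object of class `ratio_sampler` with fields `support`, `mean`,
#'   `shape1`, `shape2`.
#' @export
ratio_sampler <- function(support, mean, shape1 = NULL, shape2 = NULL) {
  lo <- support[1L]; hi <- support[2L]
  stopifnot(lo < hi, mean > lo, mean < hi)
  mu <- (mean - lo) / (hi - lo)
  if (is.null(shape1) && is.null(shape2)) {
    stop("supply shape1 and/or shape2")
  }
  if (!is.null(shape1) && !is.null(shape2)) {
    # both given (e.g. restored from a config file): taken as-is
  } else if (is.null(shape2)) {
    shape2 <- shape1 * (1 - mu) / mu
  } else {
    shape1 <- shape2 * mu / (1 - mu)
  }
  structure(list(support = c(lo, hi), mean = mean,
                 shape1 = shape1, shape2 = shape2),
            class = "ratio_sampler")
}

.sample_ratio <- function(sampler, n = 1L) {
  u <- stats::rbeta(n, sampler$shape1, sampler$shape2)
  list(ratio = sampler$support[1L] + diff(sampler$support) * u,
       percentile = stats::pbeta(u, sampler$shape1, sampler$shape2))
}

#' Default area-ratio sampler for the venule-like population
#'
#' Scaled Beta(1, 3.40529) on `[1.89, 10.96]` with mean 3.9489: right-skewed
#' (the ratio rises steeply for the largest vessels) with positive density at
#' the lower support edge, so the expected sample minimum over a realistic
#' group size sits close to the edge.
#' @return A [ratio_sampler()].
#' @export
default_venule_sampler <- function() {
  ratio_sampler(c(1.89, 10.96), mean = 3.9489, shape1 = 1)
}

#' Default area-ratio sampler for the arteriole-like population
#'
#' Scaled Beta(1.03674, 1) on `[0.27, 1.57]` with mean 0.9317, nearly flat with
#' positive density at the upper edge.
#' @return A [ratio_sampler()].
#' @export
default_arteriole_sampler <- function() {
  ratio_sampler(c(0.27, 1.57), mean = 0.9317, shape2 = 1)
}

#' Specify a two-group synthetic vessel population
#'
#' Defines the study conditions for a synthetic run: group sizes, the
#' true-area-ratio samplers for the venule-like (group 1) and arteriole-like
#' (group 2) populations, the pixel calibration, and the master seed from
#' which all per-vessel seeds are derived.
#'
#' @param n_group1,n_group2 Number of venule-like and arteriole-like vessels
#'   (defaults 81 and 31).
#' @param ratio_sampler_group1,ratio_sampler_group2 [ratio_sampler()] objects;
#'   defaults [default_venule_sampler()] and [default_arteriole_sampler()].
#' @param microns_per_pixel Raster calibration (default 0.05 um/px).
#' @param image_size Square image side in pixels, or `NULL` (default) to
#'   auto-size each mask to its vessel.
#' @param master_seed Integer master seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_group1 = 81L, n_group2 = 31L,
                            ratio_sampler_group1 = default_venule_sampler(),
                            ratio_sampler_group2 = default_arteriole_sampler(),
                            microns_per_pixel = 0.05, image_size = NULL,
                            master_seed = 1L) {
  stopifnot(inherits(ratio_sampler_group1, "ratio_sampler"),
            inherits(ratio_sampler_group2, "ratio_sampler"),
            n_group1 >= 0, n_group2 >= 0, microns_per_pixel > 0)
  structure(
    list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
         ratio_sampler_group1 = ratio_sampler_group1,
         ratio_sampler_group2 = ratio_sampler_group2,
         microns_per_pixel = microns_per_pixel,
         image_size = if (is.null(image_size) || length(image_size) == 0L) {
           NULL
         } else {
           as.integer(image_size)
         },
         master_seed = as.integer(master_seed)),
    class = "population_spec"
  )
}

# counter-based per-vessel seed derivation: stable under population-size
# changes and independent of R's global RNG stream
.derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 2654435761 + counter * 40503) %%
               2147483629) + 1L
}

## Group geometry models (the generator's vessel-morphology priors).
##
## Venule-like vessels emulate thin-walled, often collapsed venules: the lumen
## flattening (polar-ellipse aspect up to ~6.5) and the apposed-wall thickening
## (thickness modulation phased onto the flattened sides) both increase as the
## area ratio decreases, because venule collapse shrinks the lumen while the
## wall is conserved. Lumen size correlates positively with the ratio (the
## largest vessels carry the largest ratios).
##
## Arteriole-like vessels are rounder (aspect <= 2.5) with a continuous,
## thicker wall whose angular asymmetry has a free phase.
.draw_venule_geometry <- function(draw) {
  ur <- draw$percentile
  r <- 4.8 + 7.4 * ur^0.7 + stats::rnorm(1, 0, 0.6)
  r <- min(max(r, 4.5), 12.5)
  collapse <- min(1, max(0, (1 - ur) + stats::rnorm(1, 0, 0.15)))
  q <- 1.2 + 5.3 * collapse
  list(
    a = r * sqrt(q), b = r / sqrt(q),
    thickness_modulation = 0.2 + 0.3 * collapse,
    thickness_phase = pi + stats::rnorm(1, 0, 0.3),
    boundary_perturbation = stats::runif(1, 0.05, 0.2)
  )
}

.draw_arteriole_geometry <- function(draw) {
  r <- stats::runif(1, 4, 9)
  q <- stats::runif(1, 1, 2.5)
  list(
    a = r * sqrt(q), b = r / sqrt(q),
    thickness_modulation = stats::runif(1, 0, 0.5),
    thickness_phase = stats::runif(1, 0, 2 * pi),
    boundary_perturbation = stats::runif(1, 0, 0.1)
  )
}

# draw one vessel_spec for a group, hitting the target area ratio exactly
.sample_vessel_spec <- function(group, sampler, seed, vessel_id) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  draw <- .sample_ratio(sampler)
  geom <- if (group == "venule_like") {
    .draw_venule_geometry(draw)
  } else {
    .draw_arteriole_geometry(draw)
  }
  w <- stats::runif(3, 0.2, 1)
  ph <- stats::runif(3, 0, 2 * pi)
  rotation <- stats::runif(1, 0, 2 * pi)
  ck <- geom$boundary_perturbation * w / sum(w)
  th <- .quad_theta()
  fake <- list(lumen_semi_axes = c(geom$a, geom$b),
               perturbation_coef = ck, perturbation_phase = ph)
  lumen_area <- mean(.lumen_rho(th, fake)^2) * pi
  t0 <- .solve_wall_thickness(c(geom$a, geom$b), ck, ph,
                              geom$thickness_modulation, geom$thickness_phase,
                              target_wall_area = lumen_area / draw$ratio)
  vessel_spec(
    lumen_semi_axes = c(geom$a, geom$b),
    wall_thickness_base = t0,
    thickness_modulation = geom$thickness_modulation,
    thickness_phase = geom$thickness_phase,
    boundary_perturbation = geom$boundary_perturbation,
    perturbation_weights = w,
    perturbation_phases = ph,
    rotation = rotation,
    group_label = group,
    seed = seed
  )
}

#' Generate a two-group synthetic vessel population
#'
#' Draws each vessel's true area ratio from its group sampler, solves the wall
#' thickness so the analytic area ratio equals the sampled target exactly (to
#' quadrature precision, far below 1e-6), renders the mask, and returns mask
#' plus truth for every vessel. Per-vessel seeds are derived from
#' `master_seed` by a counter scheme, so runs are reproducible and individual
#' vessels are stable under changes of the population size.
#'
#' @param pop A [population_spec()].
#' @return A list of `list(vessel, truth)` pairs (group 1 first), with the
#'   truth table ([truth_table()]) attached as attribute `"truth_table"`.
#' @examples
#' pop <- population_spec(n_group1 = 2, n_group2 = 1, microns_per_pixel = 0.2)
#' vessels <- sample_population(pop)
#' truth_table(vessels)
#' @export
sample_population <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  specs <- sample_population_specs(pop)
  out <- lapply(seq_along(specs), function(i) {
    make_vessel(specs[[i]], pop$microns_per_pixel, pop$image_size,
                vessel_id = names(specs)[i])
  })
  names(out) <- names(specs)
  attr(out, "truth_table") <- truth_table(out)
  out
}

#' Draw the vessel specifications of a population without rasterizing
#'
#' The sampling stage of [sample_population()]: returns the named list of
#' [vessel_spec()] objects (ids `g1_###`, `g2_###`). Useful for streaming
#' pipelines that rasterize, measure and discard one mask at a time.
#'
#' @inheritParams sample_population
#' @return Named list of `vessel_spec` objects.
#' @export
sample_population_specs <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  n1 <- pop$n_group1; n2 <- pop$n_group2
  ids <- c(if (n1 > 0) sprintf("g1_%03d", seq_len(n1)),
           if (n2 > 0) sprintf("g2_%03d", seq_len(n2)))
  specs <- vector("list", n1 + n2)
  for (i in seq_len(n1)) {
    specs[[i]] <- .sample_vessel_spec("venule_like", pop$ratio_sampler_group1,
                                      .derive_seed(pop$master_seed, i), ids[i])
  }
  for (j in seq_len(n2)) {
    specs[[n1 + j]] <- .sample_vessel_spec(
      "arteriole_like", pop$ratio_sampler_group2,
      .derive_seed(pop$master_seed, n1 + j), ids[n1 + j])
  }
  names(specs) <- ids
  specs
}

#' Tabulate ground-truth records of a generated population
#'
#' @param vessels The list returned by [sample_population()], or any list of
#'   `list(vessel, truth)` pairs.
#' @return A data.frame with one row per vessel: `vessel_id`, `group_label`,
#'   the exact areas and ratio, equivalent diameter, mean thickness, the
#'   pathology flag and the per-vessel seed.
#' @export
truth_table <- function(vessels) {
  rows <- lapply(seq_along(vessels), function(i) {
    tr <- vessels[[i]]$truth
    data.frame(
      vessel_id = vessels[[i]]$vessel$vessel_id,
      group_label = tr$spec$group_label,
      true_lumen_area = tr$true_lumen_area,
      true_wall_area = tr$true_wall_area,
      true_total_area = tr$true_total_area,
      true_area_ratio = tr$true_area_ratio,
      true_equiv_diameter = tr$true_equiv_diameter,
      true_mean_thickness = tr$true_mean_thickness,
      pathology_flag = tr$spec$pathology_flag,
      seed = tr$spec$seed,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
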
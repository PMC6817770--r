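## Morphometric estimators.
##
## Measured quantities per vessel: lumen area A_L and wall area A_W (pixel
## counts times the squared calibration), total area, area ratio
## R_A = A_L / A_W, lumen equivalent diameter D_L, mean wall thickness T_W,
## and diameter ratio R_D = D_L / T_W. The area ratio is the discriminating
## statistic; the diameter ratio is the traditional criterion it is tested
## against.

#' Lumen and wall areas of a segmented vessel
#'
#' Area is the label pixel count times the squared calibration; no smoothing
#' or boundary interpolation is applied, so areas are exact in pixel
#' arithmetic and `total = lumen + wall` holds identically.
#'
#' @param v A [segmented_vessel()].
#' @return Named numeric vector `c(lumen_area, wall_area)` in square
#'   micrometers.
#' @export
compute_areas <- function(v) {
  stopifnot(inherits(v, "segmented_vessel"))
  n_lumen <- sum(v$labels == 1L)
  n_wall <- sum(v$labels == 2L)
  if (n_lumen == 0L) stop("measurement error: no lumen pixels in ", v$vessel_id)
  if (n_wall == 0L) stop("measurement error: no wall pixels in ", v$vessel_id)
  px_area <- v$microns_per_pixel^2
  c(lumen_area = n_lumen * px_area, wall_area = n_wall * px_area)
}

#' Area-equivalent circular diameter
#'
#' Diameter of the circle with the given area, `2 * sqrt(area / pi)`. Small
#' vessels are rarely circular, so a single caliper width is ill-defined;
#' the area-equivalent diameter is the reproducible default "lumen diameter".
#'
#' @param lumen_area Area in square micrometers, strictly positive.
#' @return Diameter in micrometers.
#' @export
equivalent_diameter <- function(lumen_area) {
  if (any(!is.finite(lumen_area) | lumen_area <= 0)) {
    stop("equivalent_diameter: area must be positive")
  }
  2 * sqrt(lumen_area / pi)
}

#' Lumen diameter of a segmented vessel
#'
#' The default is the area-equivalent circular diameter; maximum and minimum
#' Feret (caliper) diameters over the lumen's convex hull are available for
#' users who want an explicit width measurement. Feret diameters include one
#' pixel of extent (pixel centers alone underestimate the caliper width).
#'
#' @param v A [segmented_vessel()].
#' @param method `"equivalent"` (default), `"feret_max"` or `"feret_min"`.
#' @return Diameter in micrometers.
#' @export
lumen_diameter <- function(v, method = c("equivalent", "feret_max", "feret_min")) {
  method <- match.arg(method)
  if (method == "equivalent") {
    return(unname(equivalent_diameter(compute_areas(v)[["lumen_area"]])))
  }
  idx <- which(v$labels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("measurement error: no lumen pixels in ", v$vessel_id)
  pts <- idx[grDevices::chull(idx[, 1L], idx[, 2L]), , drop = FALSE]
  if (method == "feret_max") {
    d2max <- 0
    for (i in seq_len(nrow(pts))) {
      d2 <- (pts[, 1L] - pts[i, 1L])^2 + (pts[, 2L] - pts[i, 2L])^2
      d2max <- max(d2max, d2)
    }
    return((sqrt(d2max) + 1) * v$microns_per_pixel)
  }
  # feret_min: rotating calipers over hull edge directions
  n <- nrow(pts)
  if (n == 1L) return(v$microns_per_pixel)
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2L], e[1L]) / len
    proj <- pts[, 1L] * nrm[1L] + pts[, 2L] * nrm[2L]
    wmin <- min(wmin, max(proj) - min(proj))
  }
  (wmin + 1) * v$microns_per_pixel
}

# distance-transform wall thickness: 2 x mean distance-to-boundary over the
# wall's medial-axis pixels (local maxima of the distance map), minus the
# half-pixel offset at each side. Fallback estimator for strongly non-convex
# lumens where the centroid leaves the lumen.
.thickness_distance_transform <- function(v) {
  wall <- v$labels == 2L
  dm <- EBImage::distmap(EBImage::Image(wall * 1))
  dm <- dm@.Data
  nr <- nrow(dm); nc <- ncol(dm)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- dm
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ismax <- wall & ctr > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ismax <- ismax & ctr >= pad[(2 + dr):(nr + 1L + dr), (2 + dc):(nc + 1L + dc)]
  }
  if (!any(ismax)) return(NA_real_)
  (2 * mean(ctr[ismax]) - 1) * v$microns_per_pixel
}

#' Mean wall thickness by radial ray casting
#'
#' Casts `n_rays` equally spaced rays from the lumen centroid and measures,
#' along each ray, the distance from the lumen/wall crossing to the
#' wall/background crossing. Rays that do not cross each boundary exactly once
#' (grazing a concavity, re-entering the wall) are dropped; the mean over the
#' valid rays is returned with the valid fraction as attribute
#' `"valid_ray_fraction"` and the estimator as attribute `"method"`.
#'
#' If the centroid falls outside the lumen (strongly non-convex lumen) the
#' function falls back, with a warning, to a distance-transform estimator:
#' twice the mean distance-to-boundary over the wall's medial-axis pixels.
#'
#' @param v A [segmented_vessel()].
#' @param n_rays Number of rays, at least 8 (default 360).
#' @return Mean thickness in micrometers (attributes: `valid_ray_fraction`,
#'   `method`).
#' @export
mean_wall_thickness <- function(v, n_rays = 360L) {
  stopifnot(inherits(v, "segmented_vessel"))
  if (n_rays < 8L) stop("n_rays must be at least 8")
  lab <- v$labels
  idx <- which(lab == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("measurement error: no lumen pixels in ", v$vessel_id)
  c_row <- mean(idx[, 1L]); c_col <- mean(idx[, 2L])
  inside <- lab[round(c_row), round(c_col)] == 1L
  if (!inside) {
    warning("lumen centroid of ", v$vessel_id,
            " lies outside the lumen; using distance-transform estimator")
    t_dt <- .thickness_distance_transform(v)
    if (!is.finite(t_dt)) {
      stop("measurement error: no valid thickness estimate for ", v$vessel_id)
    }
    return(structure(t_dt, valid_ray_fraction = 0, method = "distance_transform"))
  }

  # ray extent: cover the bounding box of all non-background pixels
  nr <- nrow(lab); nc <- ncol(lab)
  fg_rows <- range(which(.rowSums(lab != 0L, nr, nc) > 0))
  fg_cols <- range(which(.colSums(lab != 0L, nr, nc) > 0))
  rmax <- sqrt(max(abs(fg_rows - c_row))^2 + max(abs(fg_cols - c_col))^2) + 2
  step <- 0.25
  radii <- seq(0, rmax, by = step)
  ang <- (seq_len(n_rays) - 1L) / n_rays * 2 * pi
  rows <- round(outer(radii, sin(ang)) + c_row)
  cols <- round(outer(radii, cos(ang)) + c_col)
  ok <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
  samp <- matrix(0L, length(radii), n_rays)
  samp[ok] <- lab[rows[ok] + (cols[ok] - 1L) * nr]

  measure_ray <- function(s) {
    i1 <- match(2L, s)                      # first wall sample
    if (is.na(i1) || i1 == 1L) return(NA_real_)
    if (any(s[seq_len(i1 - 1L)] != 1L)) return(NA_real_)  # must start inside lumen
    rest <- s[i1:length(s)]
    i2 <- match(0L, rest)                   # first background sample after wall
    if (is.na(i2)) return(NA_real_)
    if (any(rest[seq_len(i2 - 1L)] != 2L)) return(NA_real_)
    if (any(rest[i2:length(rest)] != 0L)) return(NA_real_) # single crossing only
    (i2 - 1L) * step
  }
  t_px <- apply(samp, 2L, measure_ray)
  valid <- is.finite(t_px)
  if (!any(valid)) stop("measurement error: no valid rays for ", v$vessel_id)
  structure(mean(t_px[valid]) * v$microns_per_pixel,
            valid_ray_fraction = mean(valid), method = "ray")
}

#' Exclusion reasons
#' @format Character vector of the four possible `exclusion_reason` values.
#' @export
EXCLUSION_REASONS <- c("none", "too_small", "not_transverse", "pathology")

#' Measure one vessel cross-section
#'
#' Assembles the full morphometric record and applies the exclusion rules in
#' order: pathology flag, non-transverse section, then total cross-sectional
#' area strictly below `area_floor` (default 70 um^2, the floor that removes
#' capillaries and post-capillary venules). Excluded vessels are still
#' measured — they carry data and a reason, and are only skipped downstream —
#' so a batch is always fully accounted for.
#'
#' @param v A [segmented_vessel()].
#' @param area_floor Exclusion floor on total (lumen + wall) area in square
#'   micrometers; vessels strictly below it are flagged `too_small`.
#' @param n_rays Rays for [mean_wall_thickness()].
#' @param diameter_method Passed to [lumen_diameter()].
#' @param thickness_check If `TRUE`, also compute the distance-transform
#'   thickness estimate and report it in column `thickness_dt`; a warning is
#'   issued when the two estimators disagree by more than 10 percent.
#' @return A one-row data.frame: `vessel_id`, `lumen_area`, `wall_area`,
#'   `total_area`, `area_ratio`, `equiv_diameter`, `mean_thickness`,
#'   `diameter_ratio`, `excluded`, `exclusion_reason`, `valid_ray_fraction`,
#'   `thickness_method` (plus `thickness_dt` when requested).
#' @export
measure <- function(v, area_floor = 70, n_rays = 360L,
                    diameter_method = "equivalent", thickness_check = FALSE) {
  stopifnot(inherits(v, "segmented_vessel"))
  areas <- compute_areas(v)
  lumen_area <- unname(areas[["lumen_area"]])
  wall_area <- unname(areas[["wall_area"]])
  total_area <- lumen_area + wall_area
  d <- lumen_diameter(v, method = diameter_method)
  tw <- mean_wall_thickness(v, n_rays = n_rays)

  reason <- if (v$pathology_flag) {
    "pathology"
  } else if (!v$transverse_plane) {
    "not_transverse"
  } else if (total_area < area_floor) {
    "too_small"
  } else {
    "none"
  }

  rec <- data.frame(
    vessel_id = v$vessel_id,
    lumen_area = lumen_area,
    wall_area = wall_area,
    total_area = total_area,
    area_ratio = lumen_area / wall_area,
    equiv_diameter = d,
    mean_thickness = as.numeric(tw),
    diameter_ratio = d / as.numeric(tw),
    excluded = reason != "none",
    exclusion_reason = reason,
    valid_ray_fraction = attr(tw, "valid_ray_fraction"),
    thickness_method = attr(tw, "method"),
    stringsAsFactors = FALSE
  )
  if (thickness_check) {
    t_dt <- .thickness_distance_transform(v)
    rec$thickness_dt <- t_dt
    if (is.finite(t_dt) && abs(t_dt - rec$mean_thickness) > 0.1 * rec$mean_thickness) {
      warning(sprintf(
        "%s: ray (%.3f um) and distance-transform (%.3f um) thickness estimates disagree by more than 10%%",
        v$vessel_id, rec$mean_thickness, t_dt))
    }
  }
  rec
}

#' Measure a batch of vessels
#'
#' @param vessels A list of [segmented_vessel()] objects, or the output of
#'   [sample_population()] (`list(vessel, truth)` pairs).
#' @param ... Passed to [measure()].
#' @return data.frame with one row per vessel.
#' @export
measure_batch <- function(vessels, ...) {
  rows <- lapply(vessels, function(item) {
    v <- if (inherits(item, "segmented_vessel")) item else item$vessel
    tryCatch(measure(v, ...), error = function(e) {
      stop("measure stage, vessel ", v$vessel_id, ": ", conditionMessage(e),
           call. = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
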
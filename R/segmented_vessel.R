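#' Labels used in a segmented vessel mask
#'
#' A segmented cross-section uses exactly three integer labels:
#' `0` background, `1` lumen, `2` wall.
#'
#' @format Named integer vector of length 3.
#' @export
VESSEL_LABELS <- c(background = 0L, lumen = 1L, wall = 2L)

#' Construct a calibrated segmented vessel cross-section
#'
#' A `segmented_vessel` holds one transverse vessel cross-section as a 2-D
#' integer label grid (`0` background, `1` lumen, `2` wall) together with its
#' pixel calibration in microns per pixel and acquisition flags. It is the
#' common currency of the package: the synthetic generator emits it, the mask
#' reader produces it, and every morphometric estimator consumes it.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}` (row-major grid,
#'   origin at the top-left; pixel centers sit at integer coordinates).
#' @param microns_per_pixel Strictly positive, finite pixel calibration
#'   (micrometers per pixel side; areas are pixel counts times its square).
#' @param vessel_id Character identifier carried into all downstream records.
#' @param transverse_plane Logical; `FALSE` marks a section that is not
#'   perpendicular to the vessel axis (such vessels are measured but excluded).
#' @param pathology_flag Logical; `TRUE` marks wall-altering pathology noted at
#'   acquisition (lipofuscin cuffs, perivenous collagenosis, dilated
#'   perivascular spaces). The mask itself is unaffected; the flag only drives
#'   the exclusion filter.
#' @param validate If `TRUE` (default), run [validate_segmented_vessel()].
#'
#' @return An object of class `segmented_vessel`.
#' @seealso [read_mask()], [write_mask()], [measure()]
#' @export
segmented_vessel <- function(labels, microns_per_pixel, vessel_id = "vessel",
                             transverse_plane = TRUE, pathology_flag = FALSE,
                             validate = TRUE) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single finite positive number")
  }
  v <- structure(
    list(
      vessel_id = as.character(vessel_id),
      labels = labels,
      microns_per_pixel = as.numeric(microns_per_pixel),
      transverse_plane = isTRUE(transverse_plane),
      pathology_flag = isTRUE(pathology_flag)
    ),
    class = "segmented_vessel"
  )
  if (validate) validate_segmented_vessel(v)
  v
}

#' Validate a segmented vessel mask
#'
#' Checks the structural invariants a measurable cross-section must satisfy:
#' only the three declared label values occur, at least one lumen and one wall
#' pixel exist, the lumen does not touch the image border, and the lumen forms
#' a single 4-connected region.
#'
#' @param v A [segmented_vessel()].
#' @return `v`, invisibly, if valid; otherwise an error naming the violated
#'   invariant.
#' @export
validate_segmented_vessel <- function(v) {
  stopifnot(inherits(v, "segmented_vessel"))
  lab <- v$labels
  bad <- setdiff(unique(as.vector(lab)), unname(VESSEL_LABELS))
  if (length(bad)) {
    stop("unknown label value(s) in mask: ", paste(bad, collapse = ", "),
         " (expected 0 = background, 1 = lumen, 2 = wall)")
  }
  n_lumen <- sum(lab == 1L)
  n_wall <- sum(lab == 2L)
  if (n_lumen == 0L) stop("invalid vessel: mask contains no lumen pixels")
  if (n_wall == 0L) stop("invalid vessel: mask contains no wall pixels")
  nr <- nrow(lab); nc <- ncol(lab)
  if (any(lab[1L, ] == 1L) || any(lab[nr, ] == 1L) ||
      any(lab[, 1L] == 1L) || any(lab[, nc] == 1L)) {
    stop("invalid vessel: lumen touches the image border ",
         "(vessel not fully contained in the field of view)")
  }
  # 4-connectivity of the lumen (EBImage::bwlabel labels 4-connected sets)
  comp <- EBImage::bwlabel(lab == 1L)
  if (max(comp) > 1L) {
    stop("invalid vessel: lumen is not a single 4-connected region (",
         max(comp), " components found)")
  }
  invisible(v)
}

#' @export
print.segmented_vessel <- function(x, ...) {
  lab <- x$labels
  cat("segmented_vessel '", x$vessel_id, "'\n", sep = "")
  cat(sprintf("  grid: %d x %d px at %.4g um/px\n",
              nrow(lab), ncol(lab), x$microns_per_pixel))
  cat(sprintf("  pixels: %d lumen, %d wall, %d background\n",
              sum(lab == 1L), sum(lab == 2L), sum(lab == 0L)))
  cat(sprintf("  transverse_plane: %s, pathology_flag: %s\n",
              x$transverse_plane, x$pathology_flag))
  invisible(x)
}

#' @export
plot.segmented_vessel <- function(x, ...) {
  pal <- c("grey95", "firebrick", "steelblue")
  graphics::image(t(x$labels[nrow(x$labels):1, , drop = FALSE]),
                  col = pal, axes = FALSE, asp = nrow(x$labels) / ncol(x$labels),
                  main = x$vessel_id, ...)
  invisible(x)
}
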
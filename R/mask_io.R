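## Lossless mask I/O.
##
## Canonical on-disk form: a single-channel 8-bit PNG or TIFF whose raw pixel
## values are drawn from a 3-value palette, plus a JSON sidecar declaring the
## palette mapping, the pixel calibration and the acquisition flags. Only
## lossless formats are accepted; JPEG would corrupt labels.

.raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported raster format '", ext, "' for ", path,
       " (lossless PNG or TIFF required; JPEG is rejected because lossy ",
       "compression corrupts label values)")
}

#' Default sidecar path for a raster path
#' @param raster_path Path to a mask raster.
#' @return The raster path with its extension replaced by `.json`.
#' @export
sidecar_path <- function(raster_path) {
  paste0(tools::file_path_sans_ext(raster_path), ".json")
}

#' Write a segmented vessel to a raster file plus JSON sidecar
#'
#' Encodes the label grid as a single-channel 8-bit raster (values are the
#' palette values, by default the labels 0/1/2 themselves) and records the
#' palette mapping, calibration and flags in a JSON sidecar so the pair can be
#' read back to an identical object.
#'
#' @param v A [segmented_vessel()].
#' @param raster_path Output raster path; `.png`, `.tif` or `.tiff`.
#' @param sidecar Output sidecar path (default: raster path with `.json`).
#' @param palette Named integer vector mapping `background`, `lumen`, `wall`
#'   to the raw pixel values used in the raster (all distinct, in 0..255).
#' @return Invisibly, a list with the two paths written.
#' @seealso [read_mask()]
#' @export
write_mask <- function(v, raster_path, sidecar = sidecar_path(raster_path),
                       palette = VESSEL_LABELS) {
  stopifnot(inherits(v, "segmented_vessel"))
  fmt <- .raster_format(raster_path)
  if (!all(c("background", "lumen", "wall") %in% names(palette))) {
    stop("palette must name background, lumen and wall values")
  }
  palette <- vapply(palette[c("background", "lumen", "wall")], as.integer, 0L)
  if (anyDuplicated(palette) || any(palette < 0L) || any(palette > 255L)) {
    stop("palette values must be distinct integers in 0..255")
  }
  px <- matrix(palette[v$labels + 1L], nrow(v$labels), ncol(v$labels))
  ok <- tryCatch({
    if (fmt == "png") {
      png::writePNG(px / 255, target = raster_path)
    } else {
      tiff::writeTIFF(px / 255, where = raster_path, bits.per.sample = 8L,
                      compression = "none")
    }
    TRUE
  }, error = function(e) {
    stop("failed to write raster ", raster_path, ": ", conditionMessage(e))
  })
  meta <- list(
    vessel_id = v$vessel_id,
    microns_per_pixel = v$microns_per_pixel,
    palette = as.list(palette),
    transverse_plane = v$transverse_plane,
    pathology_flag = v$pathology_flag
  )
  tryCatch(
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE),
    error = function(e) {
      stop("failed to write sidecar ", sidecar, ": ", conditionMessage(e))
    }
  )
  invisible(list(raster = raster_path, sidecar = sidecar))
}

#' Read a segmented vessel from a raster file plus JSON sidecar
#'
#' Maps the raster's raw pixel values to labels through the palette declared
#' in the sidecar and validates the result (label set, non-empty lumen and
#' wall, lumen 4-connected and away from the border). A pixel value outside
#' the declared palette is a format error naming the offending value; a
#' sidecar without `microns_per_pixel` is a metadata error.
#'
#' @param raster_path Path to the mask raster (PNG or TIFF).
#' @param sidecar Path to the JSON sidecar (default: raster path with `.json`).
#' @param validate Passed to [segmented_vessel()]; default `TRUE`.
#' @return A [segmented_vessel()].
#' @export
read_mask <- function(raster_path, sidecar = sidecar_path(raster_path),
                      validate = TRUE) {
  fmt <- .raster_format(raster_path)
  if (!file.exists(raster_path)) stop("raster not found: ", raster_path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$microns_per_pixel)) {
    stop("metadata error in ", sidecar, ": missing microns_per_pixel")
  }
  palette <- meta$palette
  if (is.null(palette)) palette <- as.list(VESSEL_LABELS)
  needed <- c("background", "lumen", "wall")
  if (!all(needed %in% names(palette))) {
    stop("metadata error in ", sidecar,
         ": palette must map background, lumen and wall")
  }
  img <- if (fmt == "png") png::readPNG(raster_path) else tiff::readTIFF(raster_path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  px <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))

  lut <- rep(NA_integer_, 256L)
  for (k in seq_along(needed)) {
    lut[as.integer(palette[[needed[k]]]) + 1L] <- k - 1L  # 0, 1, 2
  }
  labels <- matrix(lut[px + 1L], nrow(px), ncol(px))
  if (anyNA(labels)) {
    offending <- sort(unique(px[is.na(labels)]))
    stop("format error in ", raster_path, ": pixel value(s) ",
         paste(offending, collapse = ", "),
         " not in the declared 3-value palette")
  }
  segmented_vessel(
    labels, meta$microns_per_pixel,
    vessel_id = if (is.null(meta$vessel_id)) "vessel" else meta$vessel_id,
    transverse_plane = if (is.null(meta$transverse_plane)) TRUE else isTRUE(meta$transverse_plane),
    pathology_flag = isTRUE(meta$pathology_flag),
    validate = validate
  )
}

#' Write a batch manifest of raster/sidecar pairs
#'
#' @param pairs data.frame with columns `raster` and `sidecar` (paths).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(pairs, path) {
  stopifnot(all(c("raster", "sidecar") %in% names(pairs)))
  utils::write.csv(pairs[, c("raster", "sidecar")], path, row.names = FALSE)
  invisible(path)
}

#' Read a batch manifest of raster/sidecar pairs
#'
#' Relative paths in the manifest are resolved against the manifest's own
#' directory.
#'
#' @param path Manifest CSV path with columns `raster` and `sidecar`.
#' @return data.frame with absolute-ish `raster` and `sidecar` columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raster", "sidecar") %in% names(m))) {
    stop("manifest ", path, " must have columns 'raster' and 'sidecar'")
  }
  if (nrow(m) == 0L) stop("manifest ", path, " lists no vessels")
  base <- dirname(path)
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$raster <- fix(m$raster)
  m$sidecar <- fix(m$sidecar)
  m
}
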
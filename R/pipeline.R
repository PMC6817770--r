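## End-to-end pipeline: generate or ingest, filter, measure, classify, test.
##
## A run is fully determined by its RunConfig (including the master seed), and
## all outputs are plain CSV/JSON without timestamps, so identical configs
## produce byte-identical output files.

#' Configure a pipeline run
#'
#' @param mode `"synthetic"` (generate the population defined by `population`)
#'   or `"masks"` (read raster/sidecar pairs listed in `manifest`).
#' @param population A [population_spec()] (synthetic mode).
#' @param manifest Path to a manifest CSV (masks mode), see [read_manifest()].
#' @param exclusion_area_floor Total-area exclusion floor in square
#'   micrometers (default 70).
#' @param rule Area-ratio [decision_rule()].
#' @param thickness_rays Rays for [mean_wall_thickness()] (default 360).
#' @param threshold_retest Diameter-ratio threshold for the subgroup re-test
#'   (default [DIAMETER_RATIO_SUBGROUP_THRESHOLD]).
#' @param master_seed Integer master seed; in synthetic mode it overrides the
#'   population spec's seed so one argument controls the whole run.
#' @param output_dir Directory for the run outputs (created if missing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "masks"),
                       population = population_spec(),
                       manifest = NULL,
                       exclusion_area_floor = 70,
                       rule = decision_rule(),
                       thickness_rays = 360L,
                       threshold_retest = DIAMETER_RATIO_SUBGROUP_THRESHOLD,
                       master_seed = 1L,
                       output_dir = "vesselmorph_run") {
  mode <- match.arg(mode)
  if (mode == "masks" && is.null(manifest)) {
    stop("masks mode requires a manifest path")
  }
  if (mode == "synthetic") {
    stopifnot(inherits(population, "population_spec"))
    population$master_seed <- as.integer(master_seed)
  }
  structure(
    list(mode = mode, population = population, manifest = manifest,
         exclusion_area_floor = exclusion_area_floor, rule = rule,
         thickness_rays = as.integer(thickness_rays),
         threshold_retest = threshold_retest,
         master_seed = as.integer(master_seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

# canonical JSON serialization of a config (stable field order from the
# constructors), used for the manifest hash and for round-tripping
.config_to_list <- function(config) {
  pop <- config$population
  list(
    mode = config$mode,
    population = if (config$mode == "synthetic") list(
      n_group1 = pop$n_group1, n_group2 = pop$n_group2,
      ratio_sampler_group1 = unclass(pop$ratio_sampler_group1),
      ratio_sampler_group2 = unclass(pop$ratio_sampler_group2),
      microns_per_pixel = pop$microns_per_pixel,
      image_size = pop$image_size,
      master_seed = pop$master_seed
    ) else NULL,
    manifest = config$manifest,
    exclusion_area_floor = config$exclusion_area_floor,
    rule = unclass(config$rule),
    thickness_rays = config$thickness_rays,
    threshold_retest = config$threshold_retest,
    master_seed = config$master_seed,
    output_dir = config$output_dir
  )
}

#' Write a run configuration to a YAML (or JSON) file
#' @param config A [run_config()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- .config_to_list(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15L)
  }
  invisible(path)
}

#' Read a run configuration from a YAML or JSON file
#' @param path Path written by [write_run_config()] (or hand-authored with the
#'   same fields).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pop <- if (identical(lst$mode, "synthetic")) {
    ps <- lst$population
    population_spec(
      n_group1 = ps$n_group1, n_group2 = ps$n_group2,
      ratio_sampler_group1 = ratio_sampler(
        support = ps$ratio_sampler_group1$support,
        mean = ps$ratio_sampler_group1$mean,
        shape1 = ps$ratio_sampler_group1$shape1,
        shape2 = ps$ratio_sampler_group1$shape2),
      ratio_sampler_group2 = ratio_sampler(
        support = ps$ratio_sampler_group2$support,
        mean = ps$ratio_sampler_group2$mean,
        shape1 = ps$ratio_sampler_group2$shape1,
        shape2 = ps$ratio_sampler_group2$shape2),
      microns_per_pixel = ps$microns_per_pixel,
      image_size = ps$image_size,
      master_seed = ps$master_seed
    )
  } else {
    population_spec()
  }
  run_config(
    mode = lst$mode, population = pop, manifest = lst$manifest,
    exclusion_area_floor = lst$exclusion_area_floor,
    rule = decision_rule(lst$rule$arteriole_upper, lst$rule$venule_lower),
    thickness_rays = lst$thickness_rays,
    threshold_retest = lst$threshold_retest,
    master_seed = lst$master_seed,
    output_dir = lst$output_dir
  )
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(.config_to_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Generates (or reads) the vessels, measures every one, applies the exclusion
#' filter, classifies the non-excluded vessels by both criteria, summarizes
#' the groups, runs the rank tests, and writes all results under
#' `config$output_dir`:
#' \describe{
#'   \item{measurements.csv}{one morphometry record per vessel (excluded
#'     vessels included, flagged with their reason)}
#'   \item{classifications.csv}{area-ratio and diameter-ratio class per
#'     non-excluded vessel}
#'   \item{truth.csv}{generator ground truth (synthetic mode only)}
#'   \item{group_summaries.csv}{n/mean/min/max per group and metric}
#'   \item{tests.json}{rank tests and range-overlap results}
#'   \item{manifest.json}{config echo, config hash, seed, package version,
#'     vessel accounting (input = excluded + classified)}
#' }
#'
#' In synthetic mode masks are rasterized, measured and discarded one at a
#' time, so memory use is one image, and groups in the statistics are the
#' generator's true group labels. In masks mode groups are the assigned
#' area-ratio classes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `run_report` list: `measurements`, `classifications`,
#'   `summaries`, `tests`, `accounting`, `truth` (synthetic mode), `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (config$mode == "synthetic") {
    pop <- config$population
    if (pop$n_group1 + pop$n_group2 == 0L) {
      stop("validation error: synthetic population is empty")
    }
    specs <- sample_population_specs(pop)
    records <- vector("list", length(specs))
    truth_rows <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      id <- names(specs)[i]
      res <- tryCatch(
        make_vessel(specs[[i]], pop$microns_per_pixel, pop$image_size,
                    vessel_id = id),
        error = function(e) stop("generate stage, vessel ", id, ": ",
                                 conditionMessage(e), call. = FALSE))
      records[[i]] <- tryCatch(
        measure(res$vessel, area_floor = config$exclusion_area_floor,
                n_rays = config$thickness_rays),
        error = function(e) stop("measure stage, vessel ", id, ": ",
                                 conditionMessage(e), call. = FALSE))
      truth_rows[[i]] <- truth_table(list(res))
      rm(res)
    }
    measurements <- do.call(rbind, records)
    truth <- do.call(rbind, truth_rows)
    group_of <- setNames(ifelse(truth$group_label == "venule_like",
                                "group1", "group2"), truth$vessel_id)
  } else {
    manifest <- read_manifest(config$manifest)
    vessels <- lapply(seq_len(nrow(manifest)), function(i) {
      tryCatch(read_mask(manifest$raster[i], manifest$sidecar[i]),
               error = function(e) stop("ingest stage, ", manifest$raster[i],
                                        ": ", conditionMessage(e), call. = FALSE))
    })
    measurements <- measure_batch(vessels,
                                  area_floor = config$exclusion_area_floor,
                                  n_rays = config$thickness_rays)
    group_of <- NULL
  }
  rownames(measurements) <- NULL

  cls_area <- classify_batch(measurements, "area_ratio", rule = config$rule)
  cls_diam <- classify_batch(measurements, "diameter_ratio",
                             threshold = config$threshold_retest)
  classifications <- rbind(cls_area, cls_diam)

  kept <- measurements[!measurements$excluded, , drop = FALSE]
  if (is.null(group_of)) {
    group_of <- setNames(ifelse(cls_area$assigned_class == "venule", "group1",
                                ifelse(cls_area$assigned_class == "arteriole",
                                       "group2", "indeterminate")),
                         cls_area$vessel_id)
  }
  kept$group <- unname(group_of[kept$vessel_id])

  g1 <- kept[kept$group == "group1", , drop = FALSE]
  g2 <- kept[kept$group == "group2", , drop = FALSE]

  summaries <- NULL
  tests <- list()
  if (nrow(g1) && nrow(g2)) {
    summaries <- rbind(
      group_summary(g1$area_ratio, "group1", "area_ratio"),
      group_summary(g2$area_ratio, "group2", "area_ratio"),
      group_summary(g1$diameter_ratio, "group1", "diameter_ratio"),
      group_summary(g2$diameter_ratio, "group2", "diameter_ratio")
    )
    mwu_area <- mann_whitney_u(g1$area_ratio, g2$area_ratio)
    mwu_diam <- mann_whitney_u(g1$diameter_ratio, g2$diameter_ratio)
    ov_area <- range_overlap(g1$area_ratio, g2$area_ratio)
    ov_diam <- range_overlap(g1$diameter_ratio, g2$diameter_ratio)
    retest <- tryCatch(
      unclass(below_threshold_retest(g1, g2, config$threshold_retest)),
      error = function(e) list(not_applicable = conditionMessage(e)))
    tests <- list(
      mwu_area_ratio = unclass(mwu_area),
      mwu_diameter_ratio = unclass(mwu_diam),
      range_overlap_area_ratio = ov_area,
      range_overlap_diameter_ratio = ov_diam,
      below_threshold_retest = retest,
      threshold_retest = config$threshold_retest
    )
  }

  accounting <- list(
    n_input = nrow(measurements),
    n_excluded = sum(measurements$excluded),
    n_classified = nrow(cls_area),
    n_indeterminate_area_ratio =
      sum(cls_area$assigned_class == "indeterminate"),
    exclusion_reasons = as.list(table(
      factor(measurements$exclusion_reason[measurements$excluded],
             levels = EXCLUSION_REASONS)))
  )
  stopifnot(accounting$n_input == accounting$n_excluded + accounting$n_classified)

  paths <- list(
    measurements = file.path(out_dir, "measurements.csv"),
    classifications = file.path(out_dir, "classifications.csv"),
    summaries = file.path(out_dir, "group_summaries.csv"),
    tests = file.path(out_dir, "tests.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(measurements, paths$measurements, row.names = FALSE)
  utils::write.csv(classifications, paths$classifications, row.names = FALSE)
  if (!is.null(summaries)) {
    utils::write.csv(summaries, paths$summaries, row.names = FALSE)
  }
  jsonlite::write_json(tests, paths$tests, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(truth)) {
    paths$truth <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth, paths$truth, row.names = FALSE)
  }
  run_manifest <- list(
    package = "vesselmorph",
    version = as.character(utils::packageVersion("vesselmorph")),
    config = .config_to_list(config),
    config_hash = .config_hash(config),
    master_seed = config$master_seed,
    accounting = accounting
  )
  jsonlite::write_json(run_manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  report <- structure(
    list(measurements = measurements, classifications = classifications,
         summaries = summaries, tests = tests, accounting = accounting,
         truth = truth, paths = paths),
    class = "run_report")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("vesselmorph run report\n")
  acc <- x$accounting
  cat(sprintf("  vessels: %d input, %d excluded, %d classified\n",
              acc$n_input, acc$n_excluded, acc$n_classified))
  cls <- x$classifications
  ar <- cls[cls$criterion == "area_ratio", ]
  tab <- table(ar$assigned_class)
  cat("  area-ratio classes:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$tests$mwu_area_ratio)) {
    cat(sprintf("  area-ratio rank test: U = %g, p = %.3g\n",
                x$tests$mwu_area_ratio$U, x$tests$mwu_area_ratio$p_two_sided))
  }
  invisible(x)
}
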
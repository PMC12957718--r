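# End-to-end pipeline runner: detect -> model -> suite -> associations.

#' Run the full roosting analysis pipeline
#'
#' Executes the stages of the analysis on fixture-format inputs: projection
#' and night-location extraction, interval assignment, communal-roost
#' detection and weighting, attendance models per cohort, the
#' plasticity-vs-mortality suite (when deaths are known), and the
#' association/permutation analysis (when registries are present). Each
#' stage's outputs are written as CSV into `out_dir` together with a
#' machine-readable `summary.json` carrying the run's provenance (seed,
#' configuration hash, package version).
#'
#' @param input Either a directory of fixture files (see [write_fixture()])
#'   or a list as returned by [read_fixture()].
#' @param out_dir Output directory; created if missing. `NULL` skips file
#'   output.
#' @param config A [detection_config()].
#' @param n_iter Permutation iterations (default 1000).
#' @param seed Integer seed for all stochastic stages.
#' @param cohorts Cohorts to model (default both present in the data).
#' @return List of class `roost_pipeline`: `night_locations`, `units`,
#'   `roost_sites`, `fits`, `suite`, `records`, `permutation`, `trend`,
#'   `summary`.
#' @export
run_pipeline <- function(input, out_dir = NULL, config = detection_config(),
                         n_iter = 1000, seed = 1,
                         cohorts = c("juvenile", "adult")) {
  dat <- if (is.character(input)) read_fixture(input) else input
  if (nrow(dat$fixes) == 0) stop("pipeline stage 'detect': no fixes")
  set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  prj <- dat$projection %||% default_projection()
  area <- if (!is.null(dat$study_area_lonlat))
    project_lonlat(dat$study_area_lonlat, prj) else NULL

  nights <- stage("detect", {
    fx <- if (is.null(dat$fixes$x)) project_coordinates(dat$fixes, prj) else dat$fixes
    assign_intervals(extract_night_locations(fx, twilight = config$twilight))
  })
  det <- stage("detect", detect_attendance(nights, config))
  units <- stage("detect", build_interval_units(det$units, dat$individuals))
  if (!is.null(area)) units <- compute_weights(units, det$nights, area)
  else units$weight <- 1
  sites <- stage("detect", cluster_roost_sites(nights, config$radius))

  fits <- list()
  for (ch in intersect(cohorts, unique(units$tag_class)))
    fits[[ch]] <- stage("model", fit_attendance(units, ch))

  suite <- NULL
  deaths <- .deaths_from_individuals(dat$individuals)
  if (!is.null(deaths) && nrow(deaths) >= 2 &&
      any(units$tag_class == "juvenile" & units$bird_id %in% deaths$bird_id))
    suite <- stage("suite", plasticity_mortality_suite(units, deaths))

  records <- permutation <- trend <- NULL
  if (!is.null(dat$broods) && nrow(dat$broods)) {
    registry <- stage("associations",
                      build_relatedness_registry(dat$broods, dat$pairs,
                                                 dat$individuals))
    records <- stage("associations",
                     classify_association_nights(nights, det$units, registry,
                                                 config))
    permutation <- stage("associations",
                         permute_nests(records, registry, nights,
                                       n_iter = n_iter, seed = seed))
    trend <- stage("associations", withCallingHandlers(
      seasonal_association_trend(records),
      warning = function(w) {
        message(conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
  }

  summary <- list(
    provenance = list(seed = seed, config_hash = .config_hash(config),
                      package_version = as.character(utils::packageVersion("roostkit"))),
    counts = list(
      n_fixes = nrow(dat$fixes), n_nights = nrow(nights),
      n_units = nrow(units), n_birds = length(unique(units$bird_id)),
      n_winters = length(unique(units$winter_id)),
      attendance_rate = mean(units$attendance)),
    estimates = lapply(fits, function(f)
      stats::setNames(as.list(f$coefficients$estimate), f$coefficients$term)),
    suite_label = if (!is.null(suite)) suite$label else NULL,
    permutation_p = if (!is.null(permutation))
      stats::setNames(as.list(permutation$p_value), permutation$statistic)
      else NULL)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_csv(nights, file.path(out_dir, "night_locations.csv"))
    .write_csv(units, file.path(out_dir, "interval_units.csv"))
    .write_csv(sites, file.path(out_dir, "roost_sites.csv"))
    for (ch in names(fits))
      .write_csv(fits[[ch]]$coefficients,
                 file.path(out_dir, paste0("fit_summary_", ch, ".csv")))
    if (!is.null(suite))
      .write_csv(suite$comparison, file.path(out_dir, "suite_summary.csv"))
    if (!is.null(records))
      .write_csv(records, file.path(out_dir, "association_records.csv"))
    if (!is.null(permutation))
      .write_csv(as.data.frame(permutation),
                 file.path(out_dir, "permutation_results.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(night_locations = nights, units = units, roost_sites = sites,
                 fits = fits, suite = suite, records = records,
                 permutation = permutation, trend = trend, summary = summary),
            class = "roost_pipeline")
}

#' @export
print.roost_pipeline <- function(x, ...) {
  cnt <- x$summary$counts
  cat(sprintf("Roosting pipeline run: %d fixes -> %d nights -> %d units (%d birds, %d winters)\n",
              cnt$n_fixes, cnt$n_nights, cnt$n_units, cnt$n_birds, cnt$n_winters))
  cat(sprintf("  communal attendance rate %.3f\n", cnt$attendance_rate))
  for (ch in names(x$fits)) cat(sprintf("  [%s cohort model]\n", ch))
  if (!is.null(x$suite)) cat("  suite interpretation:", x$suite$label, "\n")
  invisible(x)
}

# longevity (age at death, in winters) for juvenile-tagged birds with a
# confirmed death date
.deaths_from_individuals <- function(ind) {
  k <- which(!is.na(ind$death_date) & ind$tag_class == "juvenile" &
               !is.na(ind$birth_year))
  if (!length(k)) return(NULL)
  death_winter <- as.integer(format(ind$death_date[k], "%Y")) -
    as.integer(format(ind$death_date[k], "%m") < "07")
  data.frame(bird_id = ind$bird_id[k],
             longevity = pmax(1L, death_winter - ind$birth_year[k] + 1L))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(unclass(config)))]), f)
  unname(tools::md5sum(f))
}
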
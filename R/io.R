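#' Read a single-cycle wave from CSV
#'
#' Expected format: two columns with header exactly \code{time_s,value},
#' strictly increasing times. If spacing deviates from uniform by more than
#' \code{tol_s}, the wave is resampled onto a uniform grid with a warning.
#'
#' @param path CSV file path.
#' @param kind "pressure" or "flow".
#' @param tol_s tolerated deviation from uniform spacing (s).
#' @return a \code{\link{uniform_wave}}.
#' @export
read_wave <- function(path, kind = c("pressure", "flow"), tol_s = 1e-6) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    cbp_stop(sprintf("wave file not found: %s", path), "cbpkit_error_io")
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "time_s,value"))
    cbp_stop(sprintf("%s line 1: expected header 'time_s,value', got '%s'",
                     path, header), "cbpkit_error_io")
  d <- utils::read.csv(path)
  t <- as.numeric(d$time_s); v <- as.numeric(d$value)
  if (length(t) < 32L)
    cbp_stop(sprintf("%s: fewer than 32 samples", path), "cbpkit_error_io")
  if (any(!is.finite(t)) || any(!is.finite(v)))
    cbp_stop(sprintf("%s: non-finite entries", path), "cbpkit_error_io")
  if (any(diff(t) <= 0))
    cbp_stop(sprintf("%s: times are not strictly increasing", path),
             "cbpkit_error_io")
  dts <- diff(t)
  dt <- (t[length(t)] - t[1L]) / (length(t) - 1L)
  if (max(abs(dts - dt)) > tol_s) {
    warning(sprintf("%s: non-uniform sampling (max deviation %.3g s); resampling onto a uniform grid",
                    path, max(abs(dts - dt))))
    v <- stats::approx(t, v, xout = t[1L] + (seq_along(t) - 1L) * dt)$y
  }
  uniform_wave(v, dt, t0 = t[1L], kind = kind)
}

#' Write a wave to CSV
#'
#' Inverse of \code{\link{read_wave}}; the round trip is lossless to better
#' than 1e-9 relative.
#'
#' @param w a \code{\link{uniform_wave}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_wave <- function(w, path) {
  assert_wave(w)
  lines <- c("time_s,value",
             sprintf("%.12g,%.12g", wave_times(w), w$values))
  writeLines(lines, path)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable settings of the toolkit in one serializable list: population
#' means/spreads, wave generation settings, solver settings, method
#' selections per scenario, exclusion bounds, and the seed. Reloading a
#' written configuration reproduces runs exactly.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    population = lapply(unclass(cv_parameter_spec()), as.numeric),
    wave = list(dt = 1e-3, k_lvet = 0.293, m = 1, asymmetry = 1, q_th = 0.02),
    solver = list(tol = 1e-6, max_cycles = 200),
    methods = list(`carotid+` = as.list(select_methods("carotid+", "0D")),
                   `carotid-` = as.list(select_methods("carotid-", "0D"))),
    exclusions = default_exclusion_bounds(),
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    cbp_stop(sprintf("config file not found: %s", path), "cbpkit_error_io")
  cfg <- run_config()
  utils::modifyList(cfg, yaml::read_yaml(path))
}

#' Hash of a configuration or manifest
#'
#' MD5 of the canonical JSON serialization; used for provenance checks that
#' two runs used identical settings.
#'
#' @param x any serializable list.
#' @return character MD5 hash.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tf))
}

#' Write a generated dataset to disk
#'
#' Layout: one directory per subject (\code{q_in.csv}, \code{cbp.csv},
#' \code{truth.json}) plus a top-level \code{manifest.json} recording the
#' specification, settings, counts and package version.
#'
#' @param ds a \code{cbp_dataset}.
#' @param dir output directory (created if needed).
#' @param ids subject rows to write; default all valid subjects.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, dir, ids = NULL) {
  if (is.null(ids)) ids <- which(ds$truth$valid)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- ds$manifest
  manifest$hash <- config_hash(list(spec = manifest$spec,
                                    settings = manifest$settings,
                                    bounds = manifest$bounds))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in ids) {
    sdir <- file.path(dir, sprintf("subject_%05d", ds$truth$id[i]))
    dir.create(sdir, showWarnings = FALSE)
    w <- subject_waves(ds, i)
    write_wave(w$q_in, file.path(sdir, "q_in.csv"))
    write_wave(w$cbp, file.path(sdir, "cbp.csv"))
    jsonlite::write_json(as.list(ds$truth[i, ]), file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset directory written by \code{\link{write_dataset}}
#'
#' Rebuilds the \code{cbp_dataset} object from the manifest and per-subject
#' truth records; waves are regenerated on demand from the stored parameters.
#'
#' @param dir dataset directory.
#' @return a \code{cbp_dataset}.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    cbp_stop(sprintf("no manifest.json in %s", dir), "cbpkit_error_io")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  rows <- lapply(sdirs, function(sd) {
    as.data.frame(jsonlite::read_json(file.path(sd, "truth.json"),
                                      simplifyVector = TRUE))
  })
  truth <- do.call(rbind, rows)
  spec <- do.call(cv_parameter_spec, lapply(manifest$spec, as.numeric))
  settings <- manifest$settings
  settings$bounds <- manifest$bounds
  structure(list(truth = truth, spec = spec, settings = settings,
                 manifest = manifest, waves = NULL),
            class = "cbp_dataset")
}
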
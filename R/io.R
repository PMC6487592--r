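#' Read a weather CSV
#'
#' Two dialects are supported:
#'
#' * `daily`: columns `date` (ISO-8601), `tmin_c`, `tmax_c` and either
#'   `par_mol_m2` (daily PAR, mol m-2 d-1) or `srad_mj_m2` (global solar
#'   radiation, MJ m-2 d-1, converted to PAR with `par_fraction *
#'   mj_to_mol`). Latitude comes from a `# latitude: <deg>` header comment
#'   or the `latitude` argument.
#' * `subdaily`: columns `day`, `hour`, `tair_c`, `par_umol_m2_s`, optional
#'   `tapex_c`.
#'
#' @param path CSV path.
#' @param dialect `"daily"` or `"subdaily"`.
#' @param latitude Site latitude (overrides any header comment).
#' @param par_fraction PAR fraction of global solar radiation (default 0.50).
#' @param mj_to_mol Conversion, mol PAR per MJ PAR (default 4.57).
#' @return A `daily_weather` or `subdaily_weather` object.
#' @export
read_weather <- function(path, dialect = c("daily", "subdaily"),
                         latitude = NULL, par_fraction = 0.50,
                         mj_to_mol = 4.57) {
  dialect <- match.arg(dialect)
  header <- readLines(path, n = 5)
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (dialect == "subdaily") {
    need <- c("day", "hour", "tair_c", "par_umol_m2_s")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      abort(paste("missing columns:", paste(miss, collapse = ", ")),
            class = "larwheat_missing_columns")
    }
    return(subdaily_weather(x$day, x$hour, x$tair_c, x$par_umol_m2_s,
                            tapex_c = x$tapex_c))
  }
  need <- c("date", "tmin_c", "tmax_c")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
          class = "larwheat_missing_columns")
  }
  if (!is.null(x$par_mol_m2)) {
    par <- x$par_mol_m2
  } else if (!is.null(x$srad_mj_m2)) {
    par <- x$srad_mj_m2 * par_fraction * mj_to_mol
  } else {
    abort("missing columns: par_mol_m2 or srad_mj_m2",
          class = "larwheat_missing_columns")
  }
  if (is.null(latitude)) {
    m <- regmatches(header, regexec("^#\\s*latitude:\\s*(-?[0-9.]+)", header))
    hit <- vapply(m, length, integer(1)) == 2
    latitude <- if (any(hit)) as.numeric(m[hit][[1]][2]) else 45
  }
  daily_weather(x$date, x$tmin_c, x$tmax_c, par, latitude = latitude)
}

#' Write a weather series to CSV
#'
#' Daily series carry their latitude in a `# latitude:` header comment so
#' that [read_weather()] round-trips losslessly.
#'
#' @param weather A `daily_weather` or `subdaily_weather` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  if (inherits(weather, "daily_weather")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# latitude: %.6g", attr(weather, "latitude")), con)
    df <- as.data.frame(weather)[, c("date", "tmin_c", "tmax_c", "par_mol_m2")]
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else if (inherits(weather, "subdaily_weather")) {
    df <- as.data.frame(weather)
    names(df)[names(df) == "par_umol"] <- "par_umol_m2_s"
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    abort("not a weather series", class = "larwheat_bad_weather")
  }
  invisible(path)
}

#' Read an observed Haun-stage series
#'
#' Accepts either a ready `haun_stage` column or the raw leaf measurements
#' (`ligulated_count`, `expanding_len_cm`, `ligulated_len_cm`), which are
#' reduced with [haun_stage()]. Other columns (e.g. `date`, `day`,
#' `replicate`) pass through.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_observations <- function(path) {
  x <- as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
  if (!"haun_stage" %in% names(x)) {
    need <- c("ligulated_count", "expanding_len_cm", "ligulated_len_cm")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      abort(paste("missing columns:", paste(miss, collapse = ", ")),
            class = "larwheat_missing_columns")
    }
    x$haun_stage <- haun_stage(x$ligulated_count, x$expanding_len_cm,
                               x$ligulated_len_cm)
  }
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory A `haun_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report to JSON
#'
#' @param evaluation A `lar_evaluation` from [mse_decomposition()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the report (e.g. seed,
#'   model kind).
#' @return `path`, invisibly.
#' @export
write_report <- function(evaluation, path, extra = list()) {
  stopifnot(inherits(evaluation, "lar_evaluation"))
  out <- c(list(mse = evaluation$mse, sb = evaluation$sb, nu = evaluation$nu,
                lc = evaluation$lc, rmsre_pct = evaluation$rmsre_pct,
                ef = evaluation$ef, n = evaluation$n), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a synth -> simulate -> evaluate pipeline
#'
#' Generates (or reads) weather, simulates a Haun-stage trajectory for the
#' requested model, optionally evaluates it against observations, and
#' writes all artifacts under `out_dir`: per-sowing weather CSVs, trajectory
#' CSVs, evaluation JSONs and a `run.json` log echoing the seed and
#' parameters. Outputs are byte-identical for identical config and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param model An LAR model object ([m1_params()], [m2_params()],
#'   [m3_params()]).
#' @param scenario A [field_scenario()] or [chamber_scenario()]; ignored if
#'   `weather_path` is given.
#' @param weather_path Optional path of an existing daily weather CSV.
#' @param observations Optional tibble (or list, one per sowing) with `day`
#'   and `haun_stage` columns for evaluation.
#' @param config A [sim_config()].
#' @param seed Integer seed recorded in the log and used for any synthesis.
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(out_dir, model, scenario = NULL, weather_path = NULL,
                         observations = NULL, config = sim_config(),
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(weather_path)) {
    series <- list(weather = read_weather(weather_path))
  } else if (inherits(scenario, "field_scenario")) {
    scenario$seed <- as.integer(seed)
    series <- build_field_weather(scenario)
  } else if (inherits(scenario, "chamber_scenario")) {
    series <- list(chamber = build_chamber_weather(scenario))
  } else {
    abort("supply either `weather_path` or a scenario",
          class = "larwheat_bad_config")
  }
  if (!is.null(observations) && inherits(observations, "data.frame")) {
    observations <- rep(list(observations), length(series))
  }
  paths <- list()
  for (i in seq_along(series)) {
    nm <- names(series)[i]
    wpath <- file.path(out_dir, paste0("weather_", nm, ".csv"))
    write_weather(series[[i]], wpath)
    traj <- simulate_haun(series[[i]], model, config = config)
    tpath <- file.path(out_dir, paste0("trajectory_", nm, ".csv"))
    write_trajectory(traj, tpath)
    paths[[paste0("weather_", nm)]] <- wpath
    paths[[paste0("trajectory_", nm)]] <- tpath
    if (!is.null(observations)) {
      o <- observations[[i]]
      idx <- match(o$day, traj$day)
      ok <- !is.na(idx)
      ev <- mse_decomposition(traj$haun_stage[idx[ok]], o$haun_stage[ok])
      rpath <- file.path(out_dir, paste0("evaluation_", nm, ".json"))
      write_report(ev, rpath, extra = list(series = nm, seed = seed))
      paths[[paste0("evaluation_", nm)]] <- rpath
    }
  }
  log <- list(seed = seed, model_class = class(model)[1],
              parameters = unclass_deep(model),
              n_series = length(series),
              package_version = as.character(utils::packageVersion("larwheat")))
  lpath <- file.path(out_dir, "run.json")
  jsonlite::write_json(log, lpath, auto_unbox = TRUE, digits = NA)
  paths$log <- lpath
  invisible(paths)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
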
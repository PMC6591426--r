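#' Load a run configuration
#'
#' Reads a JSON run configuration, applies defaults and validates it. For
#' CPG runs the defaults are the reference parameter set
#' (`k1 = k3 = 400`, `m1 = m3 = 100`, `N1 = N3 = 2`, `k4 = 800`, `N4 = 3`),
#' so a minimal config such as `{"p1": 5, "p3": 110, "p4": 32}` is complete.
#' Unknown keys produce a warning, not an error.
#'
#' @param path Path to a JSON file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(command = "cpg", seed = 1L,
                   k1 = 400L, m1 = 100L, N1 = 2L,
                   k3 = 400L, m3 = 100L, N3 = 2L,
                   k4 = 800L, N4 = 3L,
                   p1 = 5L, p3 = 110L, p4 = 32L,
                   phases = c(0L, 0L, 0L),
                   burn_in = 3000L, window = 4400L,
                   n_runs = 50L)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    warning("config: ignoring unknown key(s): ",
            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw),
                                                   names(defaults))])
  num_keys <- c("seed", "k1", "m1", "N1", "k3", "m3", "N3", "k4", "N4",
                "p1", "p3", "p4", "burn_in", "window", "n_runs")
  for (key in num_keys) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1L)
      stop("config error: field '", key, "' must be a positive number")
    cfg[[key]] <- as.integer(v)
  }
  if (!cfg$command %in% c("simulate", "predict", "classify", "scan", "cpg",
                          "ensemble"))
    stop("config error: field 'command' has unknown value '", cfg$command, "'")
  cfg$phases <- as.integer(cfg$phases)
  if (length(cfg$phases) != 3L || any(is.na(cfg$phases)) ||
      any(cfg$phases < 0L))
    stop("config error: field 'phases' must be 3 non-negative integers")
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg A `run_config` (or plain named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

cpg_params_from_config <- function(cfg) {
  cpg_params(x1 = net_b_params(cfg$k1, cfg$m1, cfg$N1),
             x3 = net_b_params(cfg$k3, cfg$m3, cfg$N3),
             x4 = net_a_params(cfg$k4, cfg$N4),
             p1 = cfg$p1, p3 = cfg$p3, p4 = cfg$p4,
             phases = cfg$phases)
}

#' Write run outputs to a directory
#'
#' Writes the pieces present in `results`: a trajectory TSV (`trajectory`
#' entry, a `bn_trajectory` or plain matrix with a `step` column), a JSON
#' summary (`summary` entry) and a plain-text run log recording the seed,
#' package version and wall time. Re-runs with an identical config and seed
#' produce byte-identical TSV/JSON output.
#'
#' @param results Named list with any of `trajectory`, `summary`, `config`.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the log.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(results, dir, seed = NA_integer_) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  if (!is.null(results$trajectory))
    write_trajectory_tsv(results$trajectory, file.path(dir, "trajectory.tsv"))
  if (!is.null(results$summary))
    jsonlite::write_json(results$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(results$config))
    write_config(results$config, file.path(dir, "config.json"))
  log <- c(paste0("seed: ", seed),
           paste0("boolcpg version: ",
                  as.character(utils::packageVersion("boolcpg"))),
           paste0("R version: ", R.version.string),
           paste0("wall time (s): ",
                  round(proc.time()[["elapsed"]] - t0, 3)))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}
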
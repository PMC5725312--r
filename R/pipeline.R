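# Configuration, pipeline composition and the command-line interface.
# Configs are YAML; results are JSON/TSV; every output embeds the config
# hash and seed so a run is reproducible from config + inputs alone.

config_defaults <- function() {
  list(
    seed = 1,
    library = list(Nb = 27, degree = 20, mesh_level = 3, position_sd = 0.15,
                   folding_sd = 2.5, sulcal_amplitude = 20),
    sensors = list(n = 274, radius = 0.12, file = NULL),
    grid = list(orders = c(6, 9), deltas_a = -2:2, deltas_b = -2:2,
                step_mode = "sd", convention = "order"),
    data = list(file = NULL, fs = 600),
    simulate = list(n_sources = 2, correlated = FALSE, snr_db = 0,
                    Nt = 420, fs = 600, noise_only = FALSE),
    inversion = list(temporal_modes = 16, tol = 1e-2, max_iter = 128),
    output_dir = "anatomeg-out"
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset fields with package defaults
#' and validates the schema; violations are reported field by field.
#'
#' @param path YAML file path.
#' @return object of class `run_config` (a named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single integer required")
  chk(cfg$library$Nb >= 2, "library.Nb: at least 2 subjects")
  chk(cfg$library$degree >= 2, "library.degree: >= 2")
  chk(cfg$library$mesh_level %in% 0:4, "library.mesh_level: 0..4")
  chk(length(cfg$grid$orders) == 2 && cfg$grid$orders[1] != cfg$grid$orders[2],
      "grid.orders: two distinct harmonic orders")
  chk(all(cfg$grid$orders >= 1 & cfg$grid$orders <= cfg$library$degree + 1),
      "grid.orders: within 1..degree+1")
  chk(cfg$grid$step_mode %in% c("sd", "literal"), "grid.step_mode: 'sd' or 'literal'")
  chk(cfg$grid$convention %in% c("order", "degree"), "grid.convention: 'order' or 'degree'")
  chk(cfg$sensors$n >= 3 || !is.null(cfg$sensors$file), "sensors.n: >= 3 channels")
  chk(cfg$simulate$n_sources %in% 1:2, "simulate.n_sources: 1 or 2")
  chk(cfg$inversion$temporal_modes >= 2, "inversion.temporal_modes: >= 2")
  if (!is.null(cfg$data$file)) {
    chk(file.exists(cfg$data$file),
        sprintf("data.file: file not found: %s", cfg$data$file))
  }
  if (!is.null(cfg$sensors$file)) {
    chk(file.exists(cfg$sensors$file),
        sprintf("sensors.file: file not found: %s", cfg$sensors$file))
  }
  if (length(problems)) {
    stop(paste(c("invalid configuration:", paste(" -", problems)), collapse = "\n"),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) digest::digest(unclass(cfg))

#' Read / write sensor geometry files
#'
#' JSON files with `positions` and `orientations` (`Nc x 3` each, metres)
#' and optional `sphere_centre`.
#'
#' @param sensors a [sensor_array].
#' @param path file path.
#' @return `read_sensor_file` returns a [sensor_array].
#' @export
write_sensor_file <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  jsonlite::write_json(list(positions = sensors$positions,
                            orientations = sensors$orientations,
                            sphere_centre = sensors$sphere_centre,
                            names = sensors$names),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_file
#' @export
read_sensor_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("sensor file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensor_array(x$positions, x$orientations,
               sphere_centre = if (is.null(x$sphere_centre)) c(0, 0, 0) else x$sphere_centre,
               names = x$names)
}

#' Read / write MEG data as TSV
#'
#' Plain-text exchange format: one row per channel, one column per
#' sample.
#'
#' @param Y a [meg_data].
#' @param path file path.
#' @param fs sampling rate used when reading.
#' @return `read_meg_tsv` returns a [meg_data].
#' @export
write_meg_tsv <- function(Y, path) {
  Y <- as_meg(Y)
  utils::write.table(Y$Y, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_meg_tsv
#' @export
read_meg_tsv <- function(path, fs = 600) {
  if (!file.exists(path)) stop(sprintf("data file not found: %s", path), call. = FALSE)
  meg_data(as.matrix(utils::read.table(path, sep = "\t")), fs)
}

pipeline_sensors <- function(cfg) {
  if (!is.null(cfg$sensors$file)) return(read_sensor_file(cfg$sensors$file))
  default_sensor_array(cfg$sensors$n, cfg$sensors$radius)
}

pipeline_grid <- function(cfg) {
  lib <- generate_library(Nb = cfg$library$Nb, degree = cfg$library$degree,
                          seed = cfg$seed,
                          param = icosphere_param(cfg$library$mesh_level),
                          position_sd = cfg$library$position_sd,
                          folding_sd = cfg$library$folding_sd,
                          sulcal_amplitude = cfg$library$sulcal_amplitude)
  build_grid(lib, orders = cfg$grid$orders, deltas_a = cfg$grid$deltas_a,
             deltas_b = cfg$grid$deltas_b, step_mode = cfg$grid$step_mode,
             convention = cfg$grid$convention)
}

#' Run the full anatomy-estimation pipeline from a configuration
#'
#' Composes: synthetic library -> deformation grid -> sensor array ->
#' data (loaded from `data.file`, or simulated on the grid-origin surface
#' per the `simulate` block) -> free-energy scoring -> posterior. The
#' result carries the config hash and seed.
#'
#' @param cfg a [load_config] result (or path to a YAML config).
#' @return an `anatomy_score_map` with extra fields `posterior`,
#'   `credible_95`, `truth_compare` (when the data were simulated),
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  grid <- pipeline_grid(cfg)
  sensors <- pipeline_sensors(cfg)
  i0 <- which.min(abs(grid$deltas_a)); j0 <- which.min(abs(grid$deltas_b))
  origin <- grid$surfaces[[i0, j0]]
  truth <- NULL
  if (!is.null(cfg$data$file)) {
    Y <- read_meg_tsv(cfg$data$file, cfg$data$fs)
  } else if (isTRUE(cfg$simulate$noise_only)) {
    Y <- noise_only_dataset(sensors, cfg$simulate$Nt, cfg$simulate$fs, cfg$seed)
  } else {
    sc <- sim_config(n_sources = cfg$simulate$n_sources,
                     correlated = cfg$simulate$correlated,
                     snr_db = cfg$simulate$snr_db, Nt = cfg$simulate$Nt,
                     fs = cfg$simulate$fs, seed = cfg$seed)
    ds <- simulate_dataset(origin, sensors, sc)
    Y <- ds$Y
    truth <- origin
  }
  map <- score_grid(Y, grid, sensors,
                    temporal_modes = cfg$inversion$temporal_modes,
                    tol = cfg$inversion$tol, max_iter = cfg$inversion$max_iter)
  map$posterior <- model_posterior(map)
  map$credible_95 <- credible_region(map$posterior)
  if (!is.null(truth)) map$truth_compare <- compare_to_truth(map, truth)
  map$config_hash <- config_hash(cfg)
  map$seed <- cfg$seed
  map
}

#' Export a pipeline result to an output directory
#'
#' Writes `map.tsv` (contour-ready: delta_a, delta_b, F, p, dist) and
#' `map.json` (peak, 95% credible set, provenance).
#'
#' @param map a [run_pipeline] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
export_report <- function(map, dir) {
  stopifnot(inherits(map, "anatomy_score_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- expand.grid(delta_a = map$deltas_a, delta_b = map$deltas_b)
  df$F <- as.vector(map$F)
  df$p <- as.vector(model_posterior(map))
  if (!is.null(map$truth_compare)) df$dist <- as.vector(map$truth_compare$distance)
  utils::write.table(df, file.path(dir, "map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pk <- peak_cell(map)
  p <- model_posterior(map)
  cr <- credible_region(p)
  jsonlite::write_json(
    list(peak = list(delta_a = map$deltas_a[pk[1]], delta_b = map$deltas_b[pk[2]],
                     F = max(map$F, na.rm = TRUE)),
         credible_95 = data.frame(delta_a = map$deltas_a[cr$ia],
                                  delta_b = map$deltas_b[cr$ib], p = cr$p),
         distance_at_peak = if (is.null(map$truth_compare)) NULL else
           map$truth_compare$distance_at_peak,
         config_hash = map$config_hash, seed = map$seed),
    file.path(dir, "map.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a simulated dataset and truth sidecar),
#' `build-space` (write the grid manifest and OBJ surfaces), `run`
#' (full pipeline -> report), `report` (re-export a saved map). Exit
#' codes: 0 ok, 1 user error, 2 numerical failure.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit code, invisibly.
#' @export
anatomeg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: anatomeg <command> --config cfg.yaml [--out dir]",
    "commands: simulate | build-space | run | report", sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(0L))
  }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "build-space", "run", "report")) {
    message(sprintf("unknown command '%s'\n%s", cmd, usage)); return(invisible(1L))
  }
  code <- tryCatch({
    cfg <- load_config(opt("--config", stop("--config is required", call. = FALSE)))
    out <- opt("--out", cfg$output_dir)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    if (cmd == "simulate") {
      grid <- pipeline_grid(cfg)
      sensors <- pipeline_sensors(cfg)
      i0 <- which.min(abs(grid$deltas_a)); j0 <- which.min(abs(grid$deltas_b))
      sc <- sim_config(n_sources = cfg$simulate$n_sources,
                       correlated = cfg$simulate$correlated,
                       snr_db = cfg$simulate$snr_db, Nt = cfg$simulate$Nt,
                       fs = cfg$simulate$fs, seed = cfg$seed)
      ds <- simulate_dataset(grid$surfaces[[i0, j0]], sensors, sc)
      write_meg_tsv(ds$Y, file.path(out, "data.tsv"))
      write_sensor_file(sensors, file.path(out, "sensors.json"))
      jsonlite::write_json(list(vertices = ds$vertices, snr_db = ds$snr_db,
                                snr_achieved_db = ds$snr_achieved_db,
                                seed = ds$seed, config_hash = config_hash(cfg)),
                           file.path(out, "truth.json"), auto_unbox = TRUE,
                           digits = NA)
    } else if (cmd == "build-space") {
      grid <- pipeline_grid(cfg)
      write_grid_manifest(grid, file.path(out, "manifest.json"),
                          surfaces_dir = file.path(out, "surfaces"))
    } else if (cmd == "run") {
      map <- run_pipeline(cfg)
      export_report(map, out)
    } else if (cmd == "report") {
      map_path <- opt("--map", file.path(out, "map.json"))
      if (!file.exists(map_path)) stop(sprintf("map not found: %s", map_path), call. = FALSE)
      cat(readLines(map_path), sep = "\n")
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("singular|non-finite|numerical", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
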
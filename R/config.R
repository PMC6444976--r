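#' Load a run configuration from YAML (or JSON)
#'
#' A configuration fully describes a reproducible run: field protocol,
#' fragments, chamber geometry, mobility model and simulation settings. All
#' physical quantities carry unit-suffixed key names (e.g. `E1_V_per_cm`) to
#' keep units explicit. Unknown keys are rejected with their full path;
#' defaults are materialized into the returned object (and echoed by
#' [run_experiment()]'s manifest), so nothing is defaulted silently.
#'
#' Schema (defaults in parentheses):
#' ```
#' protocol:   E1_V_per_cm, E2_V_per_cm, theta1_deg, theta2_deg,
#'             f_Hz (0), duty (0.5)
#' fragments:  list of {length_bp, label (auto)}  -- or bare lengths
#' chamber:    width_cm (1), height_cm (1), injection_y_cm (0.01),
#'             injection_band_width_um (110)
#' mobility:   mode ("builtin") | "table" + table_csv | "parametric" +
#'             mu0, beta (0), gamma (0), kuhn_bp (300); extrapolate (FALSE)
#' simulation: n_particles (1000), seed, diffusion_cm2_per_s (0)
#' analysis:   rs_values (optional, for purity tables)
#' sweep:      f_min_Hz (0.016), f_max_Hz (33), n_points (25)
#' ```
#'
#' @param path YAML or JSON file.
#' @return A validated `run_config`.
#' @seealso [save_config()], [run_experiment()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_user("cannot parse config: ",
                                                conditionMessage(e)))
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param raw Nested list following the [load_config()] schema.
#' @return A `run_config`.
#' @export
as_run_config <- function(raw) {
  if (!is.list(raw)) stop_user("config must be a mapping")
  .reject_unknown(raw, c("protocol", "fragments", "chamber", "mobility",
                         "simulation", "analysis", "sweep"), "")
  if (is.null(raw$protocol)) stop_user("config needs a 'protocol' block")
  if (is.null(raw$fragments)) stop_user("config needs a 'fragments' list")

  p <- raw$protocol
  .reject_unknown(p, c("E1_V_per_cm", "E2_V_per_cm", "theta1_deg",
                       "theta2_deg", "f_Hz", "duty"), "protocol")
  for (k in c("E1_V_per_cm", "E2_V_per_cm", "theta1_deg", "theta2_deg"))
    if (is.null(p[[k]])) stop_user("protocol.", k, " is required")
  protocol <- field_protocol(p$E1_V_per_cm, p$E2_V_per_cm, p$theta1_deg,
                             p$theta2_deg, f_Hz = p$f_Hz %||% 0,
                             duty = p$duty %||% 0.5)

  frs <- raw$fragments
  fragments <- if (is.numeric(frs)) {
    lapply(frs, fragment_spec)
  } else {
    lapply(frs, function(fr) {
      if (is.numeric(fr) && length(fr) == 1) return(fragment_spec(fr))
      .reject_unknown(fr, c("length_bp", "label"), "fragments[]")
      if (is.null(fr$length_bp)) stop_user("fragments[].length_bp is required")
      fragment_spec(fr$length_bp, label = fr$label)
    })
  }

  ch <- raw$chamber %||% list()
  .reject_unknown(ch, c("width_cm", "height_cm", "injection_y_cm",
                        "injection_band_width_um"), "chamber")
  chamber <- chamber_spec(
    width_cm = ch$width_cm %||% 1, height_cm = ch$height_cm %||% 1,
    injection_y_cm = ch$injection_y_cm %||% 0.01,
    injection_band_width_um = ch$injection_band_width_um %||% 110)

  mb <- raw$mobility %||% list(mode = "builtin")
  .reject_unknown(mb, c("mode", "table_csv", "mu0", "beta", "gamma",
                        "kuhn_bp", "extrapolate"), "mobility")
  mode <- mb$mode %||% "builtin"
  model <- switch(
    mode,
    builtin = builtin_mobility_model(extrapolate = isTRUE(mb$extrapolate)),
    table = {
      if (is.null(mb$table_csv))
        stop_user("mobility.table_csv is required for mode: table")
      mobility_model_table(read_mobility_table(mb$table_csv),
                           extrapolate = isTRUE(mb$extrapolate))
    },
    parametric = mobility_model_parametric(
      mu0 = mb$mu0, beta = mb$beta %||% 0, gamma = mb$gamma %||% 0,
      kuhn_bp = mb$kuhn_bp %||% 300),
    stop_user("mobility.mode must be one of builtin, table, parametric"))

  sm <- raw$simulation %||% list()
  .reject_unknown(sm, c("n_particles", "seed", "diffusion_cm2_per_s"),
                  "simulation")
  simulation <- list(n_particles = sm$n_particles %||% 1000,
                     seed = sm$seed,
                     diffusion_cm2_per_s = sm$diffusion_cm2_per_s %||% 0)

  an <- raw$analysis %||% list()
  .reject_unknown(an, c("rs_values"), "analysis")
  sw <- raw$sweep %||% list()
  .reject_unknown(sw, c("f_min_Hz", "f_max_Hz", "n_points"), "sweep")
  sweep <- list(f_min_Hz = sw$f_min_Hz %||% 0.016,
                f_max_Hz = sw$f_max_Hz %||% 33,
                n_points = sw$n_points %||% 25)

  structure(
    list(protocol = protocol, fragments = fragments, chamber = chamber,
         mobility = list(mode = mode, spec = mb, model = model),
         simulation = simulation, analysis = an, sweep = sweep),
    class = "run_config"
  )
}

.reject_unknown <- function(x, known, where) {
  if (!is.list(x)) return(invisible())
  extra <- setdiff(names(x), c(known, ""))
  if (length(extra))
    stop_user("unknown config key", if (length(extra) > 1) "s" else "", ": ",
              paste0(if (nzchar(where)) paste0(where, ".") else "", extra,
                     collapse = ", "))
  invisible()
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n  ")
  print(x$protocol)
  cat(sprintf("  fragments: %s\n",
              paste(vapply(x$fragments, `[[`, "", "label"), collapse = ", ")))
  cat(sprintf("  mobility: %s | n_particles: %g | seed: %s | D: %g cm^2/s\n",
              x$mobility$mode, x$simulation$n_particles,
              x$simulation$seed %||% "unset",
              x$simulation$diffusion_cm2_per_s))
  invisible(x)
}

#' Save a run configuration as YAML
#'
#' Writes the fully materialized configuration (all defaults made explicit),
#' so that load -> save -> load round-trips to an identical object.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}

.config_as_list <- function(config) {
  p <- config$protocol
  mb <- config$mobility$spec
  mb$mode <- config$mobility$mode
  list(
    protocol = list(E1_V_per_cm = p$E1, E2_V_per_cm = p$E2,
                    theta1_deg = p$theta1_deg, theta2_deg = p$theta2_deg,
                    f_Hz = p$f_Hz, duty = p$duty),
    fragments = lapply(config$fragments, function(fr)
      list(length_bp = fr$length_bp, label = fr$label)),
    chamber = list(
      width_cm = config$chamber$width_cm,
      height_cm = config$chamber$height_cm,
      injection_y_cm = config$chamber$injection_y_cm,
      injection_band_width_um = config$chamber$injection_band_width_um),
    mobility = mb[order(names(mb))],
    simulation = config$simulation,
    analysis = config$analysis,
    sweep = config$sweep)
}

#' Run a configured experiment and write its artifact bundle
#'
#' Executes one of the package's standard workflows and writes a
#' deterministic directory of outputs plus a run manifest (`manifest.json`:
#' echoed configuration, its hash, the seed actually used, package version,
#' mode and file list). Modes:
#'
#' * `angle-sweep`: deflection-angle spectra of all fragments over the
#'   configured frequency grid (`sweep.csv`);
#' * `simulate`: stochastic stream simulation; exit samples
#'   (`exit_samples.csv`: `length_bp,y_exit_um`), per-fragment profiles
#'   (`profile_<label>.csv`: `y_um,count`) and a summary JSON;
#' * `analyze`: simulate, render a synthetic micrograph (`streams.tif` +
#'   ground-truth sidecar), run the image chain and write the separation
#'   report (`report.json`, `report.csv`);
#' * `purity-table`: resolution/overlap/purity table from
#'   `analysis.rs_values` (`purity_table.csv`), rounded like a published
#'   peak-purity table (Rs and purity to 1 decimal, overlap to 2).
#'
#' On failure, files already written for this run are removed and the error
#' is re-raised.
#'
#' @param config A `run_config` (see [load_config()]).
#' @param mode One of `"angle-sweep"`, `"simulate"`, `"analyze"`,
#'   `"purity-table"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `simulation.seed`.
#' @return Invisibly, the manifest as a list.
#' @export
run_experiment <- function(config, mode = "simulate", out_dir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  modes <- c("angle-sweep", "simulate", "analyze", "purity-table")
  if (length(mode) != 1 || !mode %in% modes)
    stop_user("mode must be one of ", paste(modes, collapse = ", "))
  if (missing(out_dir) || !nzchar(out_dir)) stop_user("out_dir is required")
  if (!is.null(seed)) config$simulation$seed <- seed
  existed <- dir.exists(out_dir)
  if (!existed) dir.create(out_dir, recursive = TRUE)
  written <- character()
  reg <- function(...) {
    f <- file.path(out_dir, paste0(...))
    written <<- c(written, f)
    f
  }
  res <- tryCatch({
    switch(mode,
      "angle-sweep" = .run_sweep(config, reg),
      "simulate" = .run_simulate(config, reg),
      "analyze" = .run_analyze(config, reg),
      "purity-table" = .run_purity_table(config, reg))
    manifest <- list(
      package = "pulsegel",
      version = as.character(utils::packageVersion("pulsegel")),
      mode = mode,
      seed = config$simulation$seed,
      config = .config_as_list(config),
      config_hash = .config_hash(config),
      outputs = basename(written))
    jsonlite::write_json(manifest, reg("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    unlink(written)            # partial-output cleanup
    if (!existed) unlink(out_dir, recursive = TRUE)
    stop(e)
  })
  invisible(res)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(.config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.need_seed <- function(config) {
  if (is.null(config$simulation$seed))
    stop_user("simulation.seed is mandatory for stochastic runs")
  config$simulation$seed
}

.run_sweep <- function(config, reg) {
  f_grid <- exp(seq(log(config$sweep$f_min_Hz), log(config$sweep$f_max_Hz),
                    length.out = config$sweep$n_points))
  sw <- frequency_sweep(config$protocol, config$fragments, f_grid,
                        config$mobility$model)
  write_sweep_csv(sw, reg("sweep.csv"))
}

.run_simulate <- function(config, reg) {
  seed <- .need_seed(config)
  sim <- simulate_streams(
    config$protocol, config$fragments, config$chamber,
    config$mobility$model, n_particles = config$simulation$n_particles,
    seed = seed, diffusion_coeff = config$simulation$diffusion_cm2_per_s)
  ok <- sim$samples$collected
  write.csv(data.frame(length_bp = sim$samples$length_bp[ok],
                       y_exit_um = sim$samples$y_exit_cm[ok] * 1e4),
            reg("exit_samples.csv"), row.names = FALSE, quote = FALSE)
  for (nm in names(sim$per_fragment)) {
    p <- sim$per_fragment[[nm]]
    if (p$n_collected == 0) next
    prof <- exit_profile(p$samples$y_exit_cm[p$samples$collected] * 1e4)
    safe <- gsub("[^A-Za-z0-9_-]+", "_", nm)
    write.csv(data.frame(y_um = prof$positions_um, count = prof$intensities),
              reg("profile_", safe, ".csv"), row.names = FALSE, quote = FALSE)
  }
  summary <- lapply(sim$per_fragment, function(p) list(
    label = p$fragment$label, length_bp = p$fragment$length_bp,
    n_collected = p$n_collected, n_in_chamber = p$n_in_chamber,
    exit_mean_um = p$exit_mean_cm * 1e4, exit_sd_um = p$exit_sd_cm * 1e4,
    angle_mean_deg = p$angle_mean_deg))
  jsonlite::write_json(unname(summary), reg("summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  sim
}

.run_analyze <- function(config, reg) {
  sim <- .run_simulate(config, reg)
  img <- render_image(sim, chamber = config$chamber,
                      noise_seed = config$simulation$seed + 1)
  write_gel_image(img, reg("streams.tif"), reg("streams.tif.json"))
  proc <- process_image(img$image, contrast = FALSE)
  # single-column extraction: with diagonal streams, multi-column averaging
  # would broaden each peak by tan(phi) x column pitch
  prof <- extract_profile(proc, line_position_px = ncol(proc) - 1L,
                          averaging_width_px = 1, um_per_px = img$um_per_px_y)
  peaks <- fit_peaks(prof, n_peaks = nrow(img$ground_truth))
  rep <- separation_report(peaks, chamber = config$chamber,
                           labels = img$ground_truth$label[
                             order(img$ground_truth$center_um)])
  write_report_json(rep, reg("report.json"))
  write.csv(cbind(rep$pairs[, c("a", "b")],
                  Rs = round(rep$pairs$Rs, 1),
                  overlap_pct = round(rep$pairs$overlap_pct, 2),
                  purity_pct = round(rep$pairs$purity_pct, 1)),
            reg("report.csv"), row.names = FALSE, quote = FALSE)
  rep
}

.run_purity_table <- function(config, reg) {
  rs <- config$analysis$rs_values
  if (is.null(rs) || !is.numeric(unlist(rs)))
    stop_user("purity-table mode needs analysis.rs_values in the config")
  op <- overlap_purity(unlist(rs))
  out <- data.frame(pair = seq_len(nrow(op)),
                    Rs = round(op$Rs, 1),
                    overlap_pct = round(op$overlap_percent, 2),
                    purity_pct = round(op$purity_percent, 1))
  write.csv(out, reg("purity_table.csv"), row.names = FALSE, quote = FALSE)
  out
}

#' Command-line entry point
#'
#' Thin front end used by the `inst/cli/pulsegel.R` script:
#' `Rscript pulsegel.R --config cfg.yaml --mode simulate --out dir [--seed N]`.
#' Exit status 0 on success, 1 for user errors (bad config, bad flags), 2 for
#' internal errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
pulsegel_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the optparse package is required for the command line interface")
    return(2L)
  }
  parser <- optparse::OptionParser(
    usage = "pulsegel.R --config FILE --mode MODE --out DIR [--seed N]",
    option_list = list(
      optparse::make_option("--config", type = "character"),
      optparse::make_option("--mode", type = "character",
                            default = "simulate"),
      optparse::make_option("--out", type = "character"),
      optparse::make_option("--seed", type = "integer", default = NULL)))
  status <- tryCatch({
    opt <- optparse::parse_args(parser, args = args)
    if (is.null(opt$config) || is.null(opt$out))
      stop_user("--config and --out are required")
    cfg <- load_config(opt$config)
    run_experiment(cfg, mode = opt$mode, out_dir = opt$out, seed = opt$seed)
    message("wrote ", normalizePath(opt$out), " (mode: ", opt$mode, ")")
    0L
  },
  pulsegel_user_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  },
  error = function(e) {
    message("internal error: ", conditionMessage(e))
    2L
  })
  status
}
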
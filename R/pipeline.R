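#' Read and write experiment configurations
#'
#' An experiment configuration is a plain list (JSON on disk, SI units)
#' with fields: `name`; `seed`; `sampling_rate` (Hz); `snr_db` (dB or
#' `NULL`); `method` (`"xcorr"` or `"envelope_peak"`); `pulse`
#' (`center_frequency`, `fractional_bandwidth`, `amplitude`); `indenter`
#' (`contact_radius_a`); `phantoms` (named list of [tissue_phantom()]
#' arguments); `loads` (`type` `"force"` with `values_N`, or `"pressure"`
#' with `values_kPa`; the first value is the baseline); and optionally
#' `lesion` (`reference` and `test` phantom names, `n_repeats`,
#' `threshold`). A schema with key descriptions ships as
#' `system.file("extdata", "config_schema.json", package = "sonodent")`.
#'
#' @param path JSON file path.
#' @param config Configuration list.
#' @return `read_experiment_config` returns the configuration list;
#'   `write_experiment_config` returns `path` invisibly.
#' @rdname experiment_config_io
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_config(cfg)
  cfg
}

#' @rdname experiment_config_io
#' @export
write_experiment_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

validate_config <- function(cfg) {
  req <- c("name", "seed", "phantoms", "loads")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("invalid configuration: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(cfg$phantoms) == 0 || is.null(names(cfg$phantoms)))
    stop("invalid configuration: `phantoms` must be a non-empty named list",
         call. = FALSE)
  type <- cfg$loads$type %||% "force"
  if (!type %in% c("force", "pressure"))
    stop("invalid configuration: loads$type must be 'force' or 'pressure'",
         call. = FALSE)
  vals <- cfg$loads$values_N %||% cfg$loads$values_kPa
  if (length(vals) == 0)
    stop("invalid configuration: empty load protocol", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  invisible(cfg)
}

config_phantom <- function(p) {
  do.call(tissue_phantom, p[names(p) %in% names(formals(tissue_phantom))])
}

config_pulse <- function(cfg) {
  if (is.null(cfg$pulse)) pulse_model() else do.call(pulse_model, cfg$pulse)
}

config_indenter <- function(cfg) {
  if (is.null(cfg$indenter)) indenter()
  else indenter(cfg$indenter$contact_radius_a)
}

config_loads <- function(cfg) {
  if ((cfg$loads$type %||% "force") == "pressure")
    pressure_steps(cfg$loads$values_kPa)
  else force_steps(cfg$loads$values_N)
}

#' Run a configured end-to-end experiment
#'
#' For every phantom in the configuration: simulate the load sweep,
#' estimate the ToF-difference table against the baseline, fit tau against
#' load, and recover the Young's modulus from the sweep. With two or more
#' phantoms, ranks them by stiffness from tau at the final load; with a
#' `lesion` block, runs the repeated-pair lesion screen between the two
#' named phantoms. The run is deterministic given the configured seed;
#' every numeric result traces back to the echoed configuration.
#'
#' @param config A configuration list (see [read_experiment_config()]) or
#'   a path to a JSON configuration file.
#' @param out_dir Optional output directory; when given, per-phantom
#'   signal and ToF CSVs and a `report.json` are written there.
#' @param quiet Suppress per-stage progress messages.
#' @return The experiment report: configuration echo, package version,
#'   per-phantom ToF tables / fits / recovered moduli, optional
#'   `ranking` and `lesion` results.
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_experiment_config(config)
  else validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  ind <- config_indenter(cfg)
  pulse <- config_pulse(cfg)
  loads <- config_loads(cfg)
  fs <- cfg$sampling_rate %||% 50e6
  method <- cfg$method %||% "xcorr"
  forces <- vapply(loads, resolve_force, numeric(1), ind = ind)
  load_axis <- if ((cfg$loads$type %||% "force") == "pressure")
    cfg$loads$values_kPa else cfg$loads$values_N

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  phantom_results <- list()
  final_taus <- numeric(0)
  for (i in seq_along(cfg$phantoms)) {
    name <- names(cfg$phantoms)[i]
    say("[simulate] phantom '%s': %d loads, seed %d", name, length(loads),
        cfg$seed + 1000L * (i - 1L))
    ph <- config_phantom(cfg$phantoms[[i]])
    sweep <- simulate_sweep(ph, ind, loads, pulse, sampling_rate = fs,
                            snr_db = cfg$snr_db,
                            seed = cfg$seed + 1000L * (i - 1L))
    say("[estimate] phantom '%s': method %s", name, method)
    tt <- tof_table(sweep, forces_N = forces, method = method)
    fit <- fit_tof_vs_load(load_axis, tt$tau_s)
    modulus <- tryCatch(
      estimate_modulus_from_sweep(tt, v = ph$sound_speed_v, ind = ind),
      error = function(e) NULL)
    phantom_results[[name]] <- list(
      tof = tt, fit = unclass(fit),
      recovered_modulus_Pa = modulus$youngs_modulus_E,
      modulus_fit = modulus$fit)
    final_taus[name] <- tt$tau_s[nrow(tt)]
    if (!is.null(out_dir)) {
      sig_dir <- file.path(out_dir, paste0(name, "_signals"))
      dir.create(sig_dir, showWarnings = FALSE)
      for (s in sweep)
        write_ascan(s, file.path(sig_dir, paste0(s$load_label, ".csv")))
      write_tof_table(tt, file.path(out_dir, paste0(name, "_tof.csv")),
                      contact_area = ind$contact_area)
    }
  }

  ranking <- if (length(phantom_results) >= 2) {
    say("[rank] %d phantoms at final load", length(phantom_results))
    rk <- rank_stiffness(final_taus)
    list(labels = rk$labels, groups = rk$groups)
  } else NULL

  lesion <- NULL
  if (!is.null(cfg$lesion)) {
    say("[lesion] reference '%s' vs test '%s', %d repeats",
        cfg$lesion$reference, cfg$lesion$test, cfg$lesion$n_repeats %||% 8L)
    lesion <- run_lesion_block(cfg, ind, pulse, loads, fs, method)
  }

  report <- list(
    config = cfg, seed = cfg$seed,
    package_version = as.character(packageVersion("sonodent")),
    phantoms = phantom_results, ranking = ranking, lesion = lesion)
  if (!is.null(out_dir)) {
    out <- c(report, list(generated = format(Sys.time(), tz = "UTC")))
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
  }
  report
}

run_lesion_block <- function(cfg, ind, pulse, loads, fs, method) {
  n_rep <- cfg$lesion$n_repeats %||% 8L
  thr <- cfg$lesion$threshold %||% 0.2
  base_load <- loads[[1]]
  test_load <- loads[[length(loads)]]
  pair_for <- function(phantom_name, offset) {
    ph <- config_phantom(cfg$phantoms[[phantom_name]])
    lapply(seq_len(n_rep), function(r) list(
      baseline = simulate_ascan(ph, ind, base_load, pulse, sampling_rate = fs,
                                snr_db = cfg$snr_db,
                                seed = cfg$seed + offset + 2L * r),
      loaded = simulate_ascan(ph, ind, test_load, pulse, sampling_rate = fs,
                              snr_db = cfg$snr_db,
                              seed = cfg$seed + offset + 2L * r + 1L)))
  }
  res <- lesion_screen_signals(
    pair_for(cfg$lesion$reference, 100000L),
    pair_for(cfg$lesion$test, 200000L),
    method = method, min_relative_reduction = thr)
  list(reference = unclass(res$tau_reference), test = unclass(res$tau_test),
       relative_reduction = res$relative_reduction,
       separated = res$separated, flagged = res$flagged,
       low_confidence = res$low_confidence, method = res$method,
       threshold = res$threshold)
}

#' Read and write ToF-measurement tables
#'
#' On-disk CSV columns are `load_label, force_N, pressure_kPa, tau_us,
#' method, uncertainty_us` (display units); in memory the table uses SI
#' (`tau_s`).
#'
#' @param tt ToF table from [tof_table()] (needs a `force_N` column).
#' @param path CSV path.
#' @param contact_area Indenter contact area (m^2) used to derive the
#'   pressure column.
#' @return `write_tof_table` returns `path` invisibly; `read_tof_table` a
#'   `data.frame` with SI columns.
#' @rdname tof_table_io
#' @export
write_tof_table <- function(tt, path, contact_area = pi * 0.01^2) {
  stopifnot(is.data.frame(tt), "tau_s" %in% names(tt))
  out <- data.frame(
    load_label = tt$load_label,
    force_N = tt$force_N %||% NA_real_,
    pressure_kPa = (tt$force_N %||% NA_real_) / contact_area / 1e3,
    tau_us = tt$tau_s * 1e6,
    method = tt$method,
    uncertainty_us = NA_real_)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tof_table_io
#' @export
read_tof_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(load_label = as.character(df$load_label), force_N = df$force_N,
             tau_s = df$tau_us / 1e6, method = df$method,
             stringsAsFactors = FALSE)
}
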
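#' Bundled experiment scenarios
#'
#' Five ready-made configurations covering the study designs the package
#' targets:
#'
#' * `silicone_hardness_series` — silicone pads (10 mm thick, Shore
#'   hardness 0-60 HA in steps of 10, moduli via [shore_to_young()]) at
#'   0 N and 15 N: the hardness calibration line (negative tau-vs-HA
#'   slope).
#' * `force_sweep` — a 10 HA silicone pad under 0-35 N in 5 N steps: the
#'   linear force calibration line.
#' * `exvivo_nonlinear` — three strain-stiffening phantoms (adipose 12
#'   kPa, lean pork 25 kPa, lean beef 50 kPa; beta = 3) under 0-10 N in
#'   1 N steps: concave tau(P) and stiffness ranking.
#' * `lesion_pair` — lean-pork host with and without a stiff embedded
#'   inclusion (30 HA silicone, 35% of thickness) at 0 N and 3 N with 8
#'   repeated pairs: the lesion screen.
#' * `muscle_states` — a relaxed (15 kPa) vs contracted (45 kPa) muscle
#'   phantom pair under 1-5 kPa cuff pressure: state discrimination.
#'
#' @param seed Base seed recorded in every configuration.
#' @return Named list of configuration lists for [run_experiment()].
#' @export
scenario_configs <- function(seed = 42) {
  seed <- as.integer(seed)
  silicone <- function(HA) list(
    thickness_h = 10e-3, sound_speed_v = 1000,
    youngs_modulus_E = shore_to_young(HA), poisson_ratio_nu = 0.5)
  tissue <- function(E, beta = 3, h = 30e-3, inclusion = NULL) list(
    thickness_h = h, sound_speed_v = 1540, youngs_modulus_E = E,
    poisson_ratio_nu = 0.5, stiffening_beta = beta, inclusion = inclusion)

  hardness_phantoms <- lapply(seq(0, 60, by = 10), silicone)
  names(hardness_phantoms) <- sprintf("silicone_%02dHA", seq(0, 60, by = 10))

  list(
    silicone_hardness_series = list(
      name = "silicone_hardness_series", seed = seed, snr_db = 30,
      method = "xcorr", phantoms = hardness_phantoms,
      loads = list(type = "force", values_N = c(0, 15))),
    force_sweep = list(
      name = "force_sweep", seed = seed + 1L, snr_db = 30, method = "xcorr",
      phantoms = list(silicone_10HA = silicone(10)),
      loads = list(type = "force", values_N = seq(0, 35, by = 5))),
    exvivo_nonlinear = list(
      name = "exvivo_nonlinear", seed = seed + 2L, snr_db = 30,
      method = "xcorr",
      phantoms = list(bovine_lean = tissue(50e3),
                      porcine_lean = tissue(25e3),
                      porcine_adipose = tissue(12e3)),
      loads = list(type = "force", values_N = seq(0, 10, by = 1))),
    lesion_pair = list(
      name = "lesion_pair", seed = seed + 3L, snr_db = 25, method = "xcorr",
      phantoms = list(
        host = tissue(25e3, beta = 0),
        embedded = tissue(25e3, beta = 0, inclusion = list(
          depth_fraction = 0.3, thickness_fraction = 0.35,
          youngs_modulus_E_inc = shore_to_young(30)))),
      loads = list(type = "force", values_N = c(0, 3)),
      lesion = list(reference = "host", test = "embedded",
                    n_repeats = 8L, threshold = 0.2)),
    muscle_states = list(
      name = "muscle_states", seed = seed + 4L, snr_db = 30, method = "xcorr",
      phantoms = list(relaxed = tissue(15e3, beta = 0, h = 40e-3),
                      contracted = tissue(45e3, beta = 0, h = 40e-3)),
      loads = list(type = "pressure", values_kPa = 1:5))
  )
}

#' Generate the bundled scenario fixtures on disk
#'
#' Runs every [scenario_configs()] experiment and writes each bundle
#' (config JSON, per-load signal CSVs, ToF tables, report) under its own
#' directory, plus a top-level `manifest.json`.
#'
#' @param out_dir Output directory (created if needed). A non-empty
#'   existing directory is refused unless `force = TRUE`.
#' @param seed Base seed.
#' @param force Overwrite a non-empty directory.
#' @param quiet Suppress progress messages.
#' @return Path to the manifest, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 42, force = FALSE,
                              quiet = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("refusing to overwrite non-empty directory '", out_dir,
         "' (use force = TRUE)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfgs <- scenario_configs(seed)
  entries <- list()
  for (name in names(cfgs)) {
    sub <- file.path(out_dir, name)
    dir.create(sub, showWarnings = FALSE)
    write_experiment_config(cfgs[[name]], file.path(sub, "config.json"))
    run_experiment(cfgs[[name]], out_dir = sub, quiet = quiet)
    entries[[name]] <- list(directory = name,
                            files = sort(dir(sub, recursive = TRUE)))
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = as.integer(seed), scenarios = entries),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
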
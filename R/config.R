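default_config <- function() {
  list(
    phantom = list(
      size = c(55, 55, 15), spacing = 1, refractive_index = 1.33,
      targets = list(
        list(centre = c(0, -8, 0), radius = 1, height = 2),
        list(centre = c(0, 8, 0), radius = 1, height = 2))),
    tissue = list(a = 1.89, b = 1.286, blood = 0.0511, saturation = 0.8,
                  water = 0, fat = 0, melanosome = 0),
    fluorophore = list(quantum_yield = 0.6, extinction = 2e4,
                       concentration = 1e20),
    imaging = list(instrument = "full_field", mode = "reflection",
                   lambda_ex = 600, lambda_em = 620, fov = c(-26, 26)),
    source = list(radius = 20, power_density = 1),
    scan = list(span = c(-22, 22), step = 1, detector_radius = 7.5),
    sweeps = list(depth = NULL, wavelength = NULL),
    autofluorescence = list(beta = NULL, spacing = 5),
    solver = list(cg_tol = 1e-8),
    seed = 1
  )
}

# recursively merge user config into defaults, tracking unknown keys
merge_config <- function(defaults, user, path = character()) {
  bad <- character()
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults)) {
      bad <- c(bad, here)
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
               key != "targets") {
      if (!is.list(user[[key]])) {
        bad <- c(bad, here)
      } else {
        sub <- merge_config(defaults[[key]], user[[key]], c(path, key))
        defaults[[key]] <- sub$config
        bad <- c(bad, sub$bad)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, bad = bad)
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$phantom$size) && length(cfg$phantom$size) == 3 &&
        all(cfg$phantom$size > 0), "phantom$size")
  chk(is.numeric(cfg$phantom$spacing) && cfg$phantom$spacing > 0,
      "phantom$spacing")
  chk(cfg$imaging$instrument %in% c("full_field", "scanning"),
      "imaging$instrument")
  chk(cfg$imaging$mode %in% c("reflection", "transmission"), "imaging$mode")
  chk(is.numeric(cfg$imaging$lambda_ex) && cfg$imaging$lambda_ex > 0,
      "imaging$lambda_ex")
  chk(all(unlist(cfg$imaging$lambda_em) > 0), "imaging$lambda_em")
  chk(cfg$scan$step > 0, "scan$step")
  chk(cfg$source$radius > 0, "source$radius")
  for (f in c("blood", "saturation", "water", "fat", "melanosome"))
    chk(cfg$tissue[[f]] >= 0 && cfg$tissue[[f]] <= 1, paste0("tissue$", f))
  if (length(problems))
    abort(paste0("Invalid configuration value(s) for key(s): ",
                 paste(problems, collapse = ", ")))
  cfg
}

#' Build an experiment configuration
#'
#' Returns the fully validated configuration with defaults filled in: the
#' standard 55 x 55 x 15 mm slab, two targets at (0, +-8, 0), whole-blood
#' tissue optics (a = 1.89, b = 1.286, B = 0.0511, S = 0.8), quantum-dot
#' fluorophore defaults and the standard instrument geometries.  Every
#' simulation driven by a configuration is deterministic; the `seed` only
#' affects optional randomised fixtures.
#'
#' @param ... Named overrides, nested lists mirroring the default structure
#'   (see `load_config()` for the file-based equivalent).
#' @return Object of class `fs_config`.
#' @export
experiment_config <- function(...) {
  user <- list(...)
  m <- merge_config(default_config(), user)
  if (length(m$bad))
    abort(paste0("Unknown configuration key(s): ",
                 paste(m$bad, collapse = ", ")))
  structure(validate_config(m$config), class = "fs_config")
}

#' Load an experiment configuration from a YAML file
#'
#' Reads the file, validates it against the configuration schema (unknown
#' keys and out-of-range values are errors naming the offending keys) and
#' fills every unspecified field with the standard defaults.  An empty file
#' yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Object of class `fs_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
    user <- yaml::read_yaml(path) %||% list()
  }
  m <- merge_config(default_config(), user)
  if (length(m$bad))
    abort(paste0("Unknown configuration key(s): ",
                 paste(m$bad, collapse = ", ")))
  structure(validate_config(m$config), class = "fs_config")
}

#' @export
print.fs_config <- function(x, ...) {
  cat(sprintf("<experiment config>  %s/%s, lambda %g -> %s nm, %d target(s), h = %g mm\n",
              x$imaging$instrument, x$imaging$mode, x$imaging$lambda_ex,
              paste(unlist(x$imaging$lambda_em), collapse = "/"),
              length(x$phantom$targets), x$phantom$spacing))
  invisible(x)
}

# realise package objects from a configuration
config_phantom <- function(cfg) {
  fp <- fluorophore_params(cfg$fluorophore$quantum_yield,
                           cfg$fluorophore$extinction,
                           cfg$fluorophore$concentration)
  targets <- map(cfg$phantom$targets, function(t)
    cylindrical_target(unlist(t$centre), t$radius %||% 1, t$height %||% 2,
                       fluorophore = fp))
  slab_phantom(size = unlist(cfg$phantom$size), spacing = cfg$phantom$spacing,
               targets = targets, n = cfg$phantom$refractive_index)
}

config_props <- function(cfg, lambda) {
  optical_properties(
    lambda,
    scatter = scattering_params(cfg$tissue$a, cfg$tissue$b),
    composition = tissue_composition(cfg$tissue$blood, cfg$tissue$saturation,
                                     cfg$tissue$water, cfg$tissue$fat,
                                     cfg$tissue$melanosome))
}

#' Shrunken configuration for fast tests
#'
#' A deliberately small, non-standard geometry (20 x 20 x 10 mm slab, one
#' centred target, 5 x 5 scan of step 2 mm) whose solves complete in well
#' under a second.  It exists for unit testing and demonstrations only and
#' does not correspond to the study geometry.
#'
#' @return Object of class `fs_config`.
#' @export
make_mini_fixture <- function() {
  experiment_config(
    phantom = list(size = c(20, 20, 10),
                   targets = list(list(centre = c(0, 0, 0), radius = 1,
                                       height = 2))),
    imaging = list(fov = c(-9, 9)),
    source = list(radius = 6),
    scan = list(span = c(-4, 4), step = 2, detector_radius = 4))
}

#' Run a configured experiment
#'
#' Executes the simulation(s) requested by a configuration — the primary
#' image for the configured instrument plus any depth/wavelength sweeps —
#' and writes the results as CSV files together with a JSON manifest
#' (configuration hash, package and R versions) for reproducibility.  The
#' forward model contains no stochastic component: identical configurations
#' produce identical outputs.
#'
#' @param config An `fs_config` from [experiment_config()] or
#'   [load_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed `image`, `resolution`, any
#'   `sweeps`, and the `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "fs_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  ph <- config_phantom(config)
  pex <- config_props(config, config$imaging$lambda_ex)
  lam_em <- unlist(config$imaging$lambda_em)[1]
  pem <- config_props(config, lam_em)
  cfg_scan <- scan_config(unlist(config$scan$span), config$scan$step,
                          config$scan$detector_radius)
  src <- disc_source(radius = config$source$radius,
                     power_density = config$source$power_density)
  fov <- unlist(config$imaging$fov)
  say("simulating %s image (%s mode, %g -> %g nm)",
      config$imaging$instrument, config$imaging$mode,
      pex$lambda, pem$lambda)
  img <- sweep_image(config$imaging$instrument, ph, pex, pem,
                     config$imaging$mode, cfg_scan, src, fov)
  res <- tryCatch(sparrow_resolution(img), error = function(e) NULL)
  sweeps <- list()
  if (!is.null(config$sweeps$depth)) {
    say("depth sweep: z = %s", paste(unlist(config$sweeps$depth), collapse = ", "))
    sweeps$depth <- run_depth_sweep(
      z = unlist(config$sweeps$depth),
      instrument = config$imaging$instrument, mode = config$imaging$mode,
      props_ex = pex, props_em = pem, spacing = config$phantom$spacing,
      config = cfg_scan, source = src, fov = fov)
  }
  if (!is.null(config$sweeps$wavelength)) {
    say("wavelength sweep: lambda_em = %s",
        paste(unlist(config$sweeps$wavelength), collapse = ", "))
    sweeps$wavelength <- run_wavelength_sweep(
      lambda_em = unlist(config$sweeps$wavelength),
      z = config$phantom$targets[[1]]$centre[3],
      instrument = config$imaging$instrument, mode = config$imaging$mode,
      props_ex = pex, spacing = config$phantom$spacing,
      config = cfg_scan, source = src, fov = fov)
  }
  manifest <- list(
    config_hash = hash(unclass(config)),
    package = as.character(utils::packageVersion("fluorscan")),
    r_version = R.version.string,
    created = "run_experiment",
    image = list(instrument = config$imaging$instrument,
                 mode = config$imaging$mode,
                 max = max(img$values),
                 resolution_mm = if (is.null(res)) NA else res$resolution))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tidy(img), file.path(out_dir, "image.csv"), row.names = FALSE)
    for (nm in names(sweeps))
      write.csv(as.data.frame(sweeps[[nm]]),
                file.path(out_dir, paste0("sweep_", nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("results written to %s", out_dir)
  }
  invisible(list(image = img, resolution = res, sweeps = sweeps,
                 manifest = manifest))
}
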
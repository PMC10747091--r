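#' Default run configuration
#'
#' The reference parameter set: light regulator `v0 = 0.7`, `vmax = 255`;
#' filter `beta_ph = 0`, `alpha_ph = 1`, `tau_ph = 1`; conventional training
#' defaults; rasterization geometry of 2 px joint discs and 1 px bones at
#' 200 x 200 source scale.
#'
#' @return Nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    photoreceptor = list(beta_ph = 0, alpha_ph = 1, tau_ph = 1),
    adaptation = list(v0 = 0.7, vmax = 255),
    train = list(epochs = 20, batch_size = 32, lr = 1e-3,
                 optimizer = "adam", seed = 7),
    raster = list(radius = 2, thickness = 1),
    fixtures = list(n_classes = 29, samples_per_class = 20,
                    size = c(200, 200), dark_bias = 0.9))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML run configuration over the defaults
#'
#' Keys absent from the file fall back to [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path), call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

config_params <- function(cfg) {
  list(ph = photoreceptor_params(cfg$photoreceptor$beta_ph,
                                 cfg$photoreceptor$alpha_ph,
                                 cfg$photoreceptor$tau_ph),
       ad = adaptation_params(cfg$adaptation$v0, cfg$adaptation$vmax))
}

# reproducibility manifest dropped next to every artifact-producing run
write_manifest <- function(dir, command, cfg, extra = list()) {
  man <- c(list(command = command,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = cfg),
           extra)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(man, file.path(dir, "run_manifest.yaml"))
  invisible(man)
}
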
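#' Default pipeline configuration
#'
#' Nested list of every tunable parameter: the enhancement thresholds and
#' gains, the vesselness scales and weights, the segmentation threshold
#' fraction and label codes, and the mediation bootstrap settings. A YAML
#' file with the same structure can override any subset via
#' [load_config()]; unknown keys are rejected.
#'
#' @param seed master seed recorded in the config.
#' @return A nested list of class `hv_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    enhance = list(alpha1 = 60, alpha2 = 30, beta = 10, gamma1 = 40,
                   gamma2 = 20, cube_size = 7L, intensity_scale_max = 255),
    vesselness = list(scales = c(0.5, 0.75, 1.0, 1.5), alpha_f = 0.5,
                      beta_f = 0.5, c_f = NULL),
    segment = list(threshold_frac = 0.05,
                   threshold_reference = "max",   # or "percentile"
                   connectivity = 26L,
                   left_hippo_code = 17L, right_hippo_code = 53L,
                   excluded_codes = default_excluded_codes()),
    mediation = list(n_boot = 5000L, confirm_boot = 50000L, level = 0.95,
                     covariates = c("age", "sex", "icv"),
                     log1p_vars = log1p_variables()),
    li_test = list(n_perm = 10000L, method = "signflip")   # or "ttest"
  ), class = "hv_config")
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("config: unknown key '", key, "'", call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML configuration over the defaults
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param seed master seed when the file does not set one.
#' @return An `hv_config` list.
#' @export
load_config <- function(path = NULL, seed = 1L) {
  cfg <- default_config(seed)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("load_config: file not found: ", path, call. = FALSE)
  override <- yaml::read_yaml(path)
  out <- merge_config(unclass(cfg), override)
  structure(out, class = "hv_config")
}

#' Write the resolved configuration next to a run's outputs
#'
#' @param config an `hv_config`.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
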
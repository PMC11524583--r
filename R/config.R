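#' Default run configuration
#'
#' Central place for the constants of the Transwell permeability pipeline:
#' insert geometry, sampling time, QC thresholds, the in-vitro-to-in-vivo
#' scaling factor and the fold-success bounds. Every downstream function
#' takes the relevant value as an argument, so the config is a convenience
#' container for pipeline runs, not hidden global state.
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#'
#' @return A named list of class `bbb_config` with elements:
#' \describe{
#'   \item{area_cm2}{insert membrane area, cm^2 (0.33 for 6.5 mm inserts;
#'     24 mm inserts have 4.46).}
#'   \item{t_sample_s}{receiver sampling time, seconds (1800 = 30 min).}
#'   \item{v_donor_ml, v_receiver_ml}{apical (donor) and basolateral
#'     (receiver) chamber volumes, mL. Conventional 24-well Transwell
#'     volumes; adjust for other plate formats.}
#'   \item{sink_threshold}{maximum fraction of dose transported before the
#'     sink-condition assumption is flagged (default 0.10).}
#'   \item{recovery_band}{acceptable mass-balance recovery interval.}
#'   \item{vsa_cm2_g}{luminal vascular surface area of brain, cm^2 per g,
#'     used to scale per-area permeability to per-gram clearance
#'     (default 150).}
#'   \item{fold_bounds}{inclusive predicted/observed fold-ratio interval
#'     counted as a successful prediction (default 0.5 to 2).}
#'   \item{min_replicates}{replicate count below which results are flagged
#'     LOW_N (default 3).}
#'   \item{output_digits}{decimals used when serializing result tables.}
#' }
#' @export
#' @examples
#' cfg <- bbb_config(sink_threshold = 0.05)
#' cfg$vsa_cm2_g
bbb_config <- function(...) {
  cfg <- list(
    area_cm2       = 0.33,
    t_sample_s     = 1800,
    v_donor_ml     = 0.1,
    v_receiver_ml  = 0.6,
    sink_threshold = 0.10,
    recovery_band  = c(0.8, 1.2),
    vsa_cm2_g      = 150,
    fold_bounds    = c(0.5, 2.0),
    min_replicates = 3,
    output_digits  = 2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "bbb_config")
}

#' Read a YAML run configuration
#'
#' Reads a YAML file whose keys are a subset of [bbb_config()] fields and
#' merges it over the defaults.
#'
#' @param path path to a YAML file.
#' @return A `bbb_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(bbb_config, vals)
}

#' Write a configuration to YAML
#'
#' Serializes an effective configuration next to a run's outputs so the run
#' can be repeated from it.
#'
#' @param config a `bbb_config` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$area_cm2 > 0, cfg$t_sample_s > 0,
    cfg$v_donor_ml > 0, cfg$v_receiver_ml > 0,
    cfg$sink_threshold > 0, cfg$sink_threshold < 1,
    length(cfg$recovery_band) == 2,
    cfg$recovery_band[1] < cfg$recovery_band[2],
    cfg$vsa_cm2_g > 0,
    length(cfg$fold_bounds) == 2,
    cfg$fold_bounds[1] > 0, cfg$fold_bounds[1] < cfg$fold_bounds[2],
    cfg$min_replicates >= 1, cfg$output_digits >= 0
  )
  invisible(cfg)
}
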
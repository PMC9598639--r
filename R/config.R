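# Configuration surface: named presets for the reference geometries and
# protocols, and a validated YAML config loader.

#' Named network geometry presets
#'
#' `network1` (300 x 75 x 1200 um^3), `network2` (600 x 150 x 1200) and
#' `network3` (1200 x 300 x 1200) are the reference large-scale geometries;
#' `tiny` (60 x 60 x 120) is a small test geometry (4 GOCs, 1728 GRCs,
#' 130 GLOs, 7 MFs at the default densities).
#'
#' @param name preset name.
#' @return List with `volume` ([volume_spec()]) and `densities`
#'   ([density_config()]).
#' @export
network_preset <- function(name) {
  name <- match.arg(tolower(name), c("tiny", "network1", "network2", "network3"))
  vol <- switch(name,
                tiny = volume_spec(60, 60, 120),
                network1 = volume_spec(300, 75, 1200),
                network2 = volume_spec(600, 150, 1200),
                network3 = volume_spec(1200, 300, 1200))
  list(name = name, volume = vol, densities = density_config())
}

config_defaults <- function() {
  list(preset = NULL, volume = NULL, densities = list(), rules = list(),
       protocol = "prot1", h = 0.1, tfin_ms = 1000, scheme = "implicit",
       seed = 1L, record = list(), n_parts = 1L, delay_mode = "per_connection",
       output_dir = ".")
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML file, fills defaults, rejects unknown keys, and expands
#' presets: `preset:` names a [network_preset()] geometry, `protocol:` either
#' a [protocol_preset()] name or a mapping of [protocol_spec()] fields.
#' Either `preset` or an explicit `volume: {x, y, z}` must be given.
#'
#' @param path path to a YAML configuration file.
#' @return Object of class `gl_config`: `volume`, `densities`, `rules`,
#'   `protocol`, `h`, `tfin_ms`, `scheme`, `seed`, `record`, `n_parts`,
#'   `delay_mode`, `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw))
    stop("load_config: empty configuration; required: one of 'preset' or ",
         "'volume: {x, y, z}'; optional: ",
         paste(setdiff(names(config_defaults()), c("preset", "volume")),
               collapse = ", "))
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("load_config: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(cfg$preset) && is.null(cfg$volume))
    stop("load_config: missing required field: one of 'preset' or 'volume'")
  if (!is.null(cfg$preset)) {
    p <- network_preset(cfg$preset)
    volume <- p$volume
    densities <- do.call(density_config, cfg$densities)
  } else {
    need <- setdiff(c("x", "y", "z"), names(cfg$volume))
    if (length(need))
      stop("load_config: 'volume' is missing field(s): ",
           paste(need, collapse = ", "))
    volume <- do.call(volume_spec, cfg$volume[c("x", "y", "z")])
    densities <- do.call(density_config, cfg$densities)
  }
  bad_rule <- setdiff(names(cfg$rules), names(formals(rule_config)))
  if (length(bad_rule))
    stop("load_config: unknown rule field(s): ", paste(bad_rule, collapse = ", "))
  rules <- do.call(rule_config, cfg$rules)
  protocol <- if (is.character(cfg$protocol)) protocol_preset(cfg$protocol)
  else {
    bad <- setdiff(names(cfg$protocol), names(formals(protocol_spec)))
    if (length(bad))
      stop("load_config: unknown protocol field(s): ", paste(bad, collapse = ", "))
    do.call(protocol_spec, cfg$protocol)
  }
  if (cfg$h <= 0) stop("load_config: field 'h' must be > 0")
  if (cfg$tfin_ms < 0) stop("load_config: field 'tfin_ms' must be >= 0")
  scheme <- match.arg(cfg$scheme, c("implicit", "explicit"))
  structure(list(preset = cfg$preset, volume = volume, densities = densities,
                 rules = rules, protocol = protocol, h = cfg$h,
                 tfin_ms = cfg$tfin_ms, scheme = scheme,
                 seed = as.integer(cfg$seed), record = cfg$record,
                 n_parts = as.integer(cfg$n_parts),
                 delay_mode = match.arg(cfg$delay_mode,
                                        c("per_connection", "per_event")),
                 output_dir = cfg$output_dir),
            class = "gl_config")
}
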
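#' Default run configuration
#'
#' Every tunable of every module with its default, tagged by provenance:
#' values printed in the source experiments' methods (`"printed"`) versus
#' defaults chosen by this package (`"package"`). The `desk_scale` preset is
#' the reduced system used throughout; `paper_scale` records the full
#' published protocol for cluster use.
#'
#' @param preset `"desk_scale"` or `"paper_scale"`.
#' @return Nested list of class `nj_config`.
#' @export
default_config <- function(preset = c("desk_scale", "paper_scale")) {
  preset <- match.arg(preset)
  desk <- preset == "desk_scale"
  cfg <- list(
    preset = preset,
    seed = 1L,
    geometry = list(
      aperture_diameter = 10,     # printed
      cone_half_angle = 8,        # package
      pipette_length = if (desk) 130 else 1100,
      bath_width = if (desk) 52 else 160,
      bath_depth = if (desk) 32 else 80,
      spacing = 1                 # package
    ),
    dna = list(
      n_bp = if (desk) 300 else 2700,  # printed (2.7 kbp) at paper scale
      nt_per_bead = if (desk) 20 else 10,
      rise_per_bp = 0.34,
      persistence_length = 50,
      charge_per_nt = -0.25,      # package
      rmin = 1.1                  # printed
    ),
    crowders = list(
      rmin = 3.9,                 # printed
      epsilon = 0.1,              # printed
      damping = 215,              # printed
      concentration = 4.5e-3,     # printed (4.5 mM)
      epsilon_cd_per_nt = 0.05,   # printed (0.05 x Nnt)
      cross_rmin = "lorentz"
    ),
    grids = list(
      steric_k = 2,               # printed (kcal/mol/A^2)
      wall_penalty = 10,          # printed (kcal/mol)
      kernel_inner = 2.5,         # printed
      kernel_outer = 4.5,         # printed
      kernel_ramp = "decreasing"  # package (see vignette)
    ),
    simulation = list(
      timestep = if (desk) 2e-3 else 4e-5, # printed: 40 fs at paper scale
      temperature = 291,          # printed
      bias = 600,                 # printed (mV)
      equilibration_time = if (desk) 50 else 75000, # printed: 50-100 us
      max_time = if (desk) 2500 else 3e5,
      post_eject_time = if (desk) 500 else 5000,
      start_depths = if (desk) c(10, 18.5, 27) else c(100, 185, 270),
      n_replicas = if (desk) 8L else 24L,   # printed: 24
      frame_interval = if (desk) 2 else 100
    ),
    sem = list(
      dna_enhancement = 1.5,      # package (stand-in profile)
      dna_outer = 2,
      crowder_inner = 2.5,        # printed
      crowder_outer = 4,          # printed
      bulk_conductivity = 2.0,    # package (170 mM KCl)
      kcl_mM = 170                # printed
    ),
    detection = list(
      k_sigma = 5,                # printed (5 sigma)
      sample_interval = 1e-5,     # printed (100 kHz)
      filter_kHz = 10,            # printed
      lambda = 1e9, p = 1e-3, n_iter = 10L,
      min_dwell = 3L, merge_gap = 2L
    ),
    analysis = list(
      cylinder_radius = 15,       # printed
      cylinder_height = 30        # printed
    ),
    delivery = list(
      flow_rate_fl_s = 33         # printed estimate
    )
  )
  class(cfg) <- c("nj_config", "list")
  cfg
}

#' Load a configuration file
#'
#' Reads a JSON or YAML configuration, validates it against the known keys
#' (unknown keys are rejected with the offending name), and merges it over
#' the preset defaults.
#'
#' @param path File path (.json, .yaml/.yml). An empty file yields all
#'   defaults (desk_scale preset).
#' @return An `nj_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list()
    else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path) %||% list()
  } else {
    stop("unsupported config format (use .json or .yaml): ", path)
  }
  preset <- raw$preset %||% "desk_scale"
  cfg <- default_config(preset)
  merge_config(cfg, raw, path = "")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: '", full, "'")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration key '", full, "' must be a table of settings")
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      val <- override[[key]]
      if (is.numeric(base[[key]]) && !is.numeric(val))
        stop("unit/type mismatch for configuration key '", full,
             "': expected a number")
      base[[key]] <- val
    }
  }
  base
}

#' Estimate the solution volume delivered by a nanoinjection
#'
#' Multiplies a volumetric flow rate by the injection duration. The default
#' flow rate is the published estimate of 33 fl/s for a ~24 nm pipette at
#' the standard driving voltage, under which a one-minute injection delivers
#' approximately 2 pl.
#'
#' @param flow_rate Flow rate (fl/s, default 33).
#' @param duration Injection duration (s).
#' @return List with `fl` and `pl`.
#' @export
estimate_delivered_volume <- function(flow_rate = 33, duration) {
  if (flow_rate < 0 || duration < 0) stop("flow rate and duration must be >= 0")
  fl <- flow_rate * duration
  list(fl = fl, pl = fl / 1000)
}

#' Configuration hash
#'
#' MD5 digest of the canonical JSON serialisation of a configuration; equal
#' configs hash equal, any tampering changes the hash.
#'
#' @param cfg An `nj_config` (or any serialisable list).
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              sort = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a reproducibility manifest
#'
#' JSON manifest with the configuration, its hash, the seed, the package
#' version and per-replica completion status.
#'
#' @param cfg An `nj_config`.
#' @param path Output path (.json).
#' @param replicas Optional data frame or list of per-replica statuses.
#' @return The manifest (invisibly), after writing it.
#' @export
write_manifest <- function(cfg, path, replicas = NULL) {
  man <- list(
    package = "nanoject",
    version = as.character(utils::packageVersion("nanoject")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    config = unclass(cfg),
    replicas = replicas
  )
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(man)
}

#' Read a manifest and verify its hash
#'
#' @param path Manifest path.
#' @return The manifest list, with `hash_ok` indicating whether the stored
#'   configuration still matches its recorded hash.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- merge_config(default_config(man$config$preset %||% "desk_scale"),
                      man$config)
  man$hash_ok <- identical(config_hash(cfg), man$config_hash)
  man
}

#' Write particle snapshots as XYZ
#'
#' One record per frame: count line, comment with the time stamp, then one
#' species-tagged row per particle (DNA / CRW).
#'
#' @param traj An `nj_trajectory`.
#' @param path Output .xyz path.
#' @param frames Frame indices to write (default: all).
#' @export
write_xyz <- function(traj, path, frames = seq_along(traj$times)) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$frames)[1]
  tag <- c(rep("DNA", traj$n_dna), rep("CRW", n - traj$n_dna))
  for (i in frames) {
    pos <- frame_positions(traj, i)
    writeLines(c(as.character(n), sprintf("t = %.4f ns", traj$times[i])), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", tag, pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  invisible(path)
}
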
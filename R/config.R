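#' Read a run configuration
#'
#' A run configuration is a YAML file with an integer `rng_seed`, optional
#' `paths`, and per-stage parameter blocks (`simulation`, `inference`,
#' `spatial`).  Only `rng_seed` is mandatory.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rng_seed)) stop("run config must set rng_seed")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "run_config")
}

#' Derive a per-stage child seed from a master seed
#'
#' Counter-based scheme so each pipeline stage is independently
#' reproducible from the master seed.  Keeps the result a valid 32-bit
#' integer seed.
#'
#' @param seed master integer seed.
#' @param stage stage index (1, 2, ...) or stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage))
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 69069 + as.double(stage) * 1234567) %%
               .Machine$integer.max)
}

#' Echo a configuration (plus seed and package version) into an output dir
#'
#' Every analysis stage writes this alongside its outputs so a result
#' directory is self-describing.
#'
#' @param cfg named list (typically a `run_config`).
#' @param dir output directory (created if needed).
#' @param seed the RNG seed in force.
#' @return The path of the written YAML, invisibly.
#' @export
write_config_echo <- function(cfg, dir, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg$rng_seed <- seed
  cfg$package_version <- as.character(utils::packageVersion("switchtissue"))
  path <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write per-cell profile sets to JSON
#'
#' @param sets list of [profile_set()] objects.
#' @param path output JSON path.
#' @param seed RNG seed to embed.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(sets, path, seed = NA_integer_) {
  payload <- list(
    package_version = as.character(utils::packageVersion("switchtissue")),
    rng_seed = seed,
    cells = lapply(sets, function(ps) {
      list(cell_id = ps$cell_id,
           profiles = lapply(ps$profiles, function(p) {
             list(switch_times = p$switch_times, rates = p$rates,
                  window = p$window, weight = p$weight)
           }))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-cell profile sets from JSON
#'
#' @param path JSON path written by [write_profiles()].
#' @return list of [profile_set()] objects.
#' @export
read_profiles <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload$cells, function(cell) {
    profs <- lapply(cell$profiles, function(p)
      transcription_profile(as.numeric(p$switch_times), as.numeric(p$rates),
                            as.numeric(p$window), p$weight))
    profile_set(cell$cell_id, profs)
  })
}
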
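# Pipeline orchestration: one configuration, one seeded invocation, one
# directory of tables plus a manifest.

#' Pipeline configuration
#'
#' Bundles generator settings and analysis selections.  The object
#' round-trips losslessly through its JSON file representation
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param generator List of [generator_config()] arguments (stored as
#'   given, so the file form stays plain data).
#' @param observables Helical parameters to profile at the target pair
#'   and its step.
#' @param target_pair Pair index analyzed.
#' @param bin_width_angle,bin_width_translation Histogram bin widths.
#' @param temperature Kelvin.
#' @param hbond List with `max_distance`, `min_angle`.
#' @param out_dir Output directory.
#' @param seed Integer seed for the whole pipeline.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(generator = list(),
                            observables = c("opening", "shear", "stretch",
                                            "twist", "shift"),
                            target_pair = 9,
                            bin_width_angle = 2,
                            bin_width_translation = 0.2,
                            temperature = 300,
                            hbond = list(max_distance = 3.0, min_angle = 135),
                            out_dir = "duplexflip_out",
                            seed = 1) {
  structure(list(generator = generator, observables = observables,
                 target_pair = target_pair,
                 bin_width_angle = bin_width_angle,
                 bin_width_translation = bin_width_translation,
                 temperature = temperature, hbond = hbond,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic ensemble, measures all observables, writes the
#' per-observable free-energy profiles (per-run average with SE and 99
#' percent CI), the Watson-Crick hydrogen-bond occupancy table of the
#' target pair, and a run manifest.  Deterministic given the seed:
#' rerunning a configuration reproduces every table byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the ensemble, the measurement table,
#'   the profiles, the occupancy table and the written file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gen_args <- config$generator
  gen_args$seed <- config$seed
  gen <- do.call(generator_config, gen_args)
  if (config$target_pair > length(gen$sequence)) {
    stop("stage generate: target pair ", config$target_pair,
         " outside the ", length(gen$sequence), "-bp duplex")
  }
  ens <- generate_trajectory(gen)
  meas <- measure_all(ens, flip_spec = flip_angle_spec("I", config$target_pair))

  paths <- character()
  profiles <- list()
  for (obs in config$observables) {
    idx <- config$target_pair
    angular <- obs %in% c("buckle", "propeller", "opening",
                          "tilt", "roll", "twist", "flip_angle")
    spec <- histogram_spec(
      bin_width = if (angular) config$bin_width_angle else config$bin_width_translation,
      temperature = config$temperature)
    ser <- tryCatch(observable_series(meas, obs, idx),
                    error = function(e) stop("stage pmf (", obs, "): ",
                                             conditionMessage(e)))
    runs <- lapply(ser, pmf_from_series, spec = spec)
    prof <- if (length(runs) >= 2) average_profiles(runs) else runs[[1]]
    p <- file.path(config$out_dir, paste0("pmf_", obs, ".tsv"))
    write_profile_tsv(prof, p)
    profiles[[obs]] <- prof
    paths <- c(paths, p)
  }

  crit <- hbond_criteria(config$hbond$max_distance, config$hbond$min_angle)
  occ <- wc_occupancy_table(ens, config$target_pair, crit)
  p_occ <- file.path(config$out_dir, "hbond_occupancy.tsv")
  utils::write.table(occ, p_occ, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p_occ)

  manifest <- list(
    package = "duplexflip",
    version = as.character(utils::packageVersion("duplexflip")),
    seed = config$seed,
    config_hash = config_hash(config),
    outputs = basename(paths))
  p_man <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p_man)
  invisible(list(ensemble = ens, measurements = meas, profiles = profiles,
                 occupancy = occ, paths = paths))
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @noRd
#' Canonical intra-pair hydrogen bonds of a pair, as donor/acceptor specs
wc_bond_specs <- function(duplex, pair) {
  b_i <- duplex$sequence[pair]
  b_ii <- duplex$pairing[pair]
  combos <- list(
    c("G", "C"), c("C", "G"), c("A", "T"), c("T", "A"))
  bonds <- list(
    "G:C" = list(list(d = c("II", "N1"), a = c("I", "N3")),
                 list(d = c("II", "N2"), a = c("I", "O2")),
                 list(d = c("I", "N4"), a = c("II", "O6"))),
    "A:T" = list(list(d = c("II", "N6"), a = c("I", "O4")),
                 list(d = c("I", "N3"), a = c("II", "N1"))))
  key <- paste(b_i, b_ii, sep = ":")
  sw <- function(spec) lapply(spec, function(b) {
    flip <- function(x) c(if (x[1] == "I") "II" else "I", x[2])
    list(d = flip(b$d), a = flip(b$a))
  })
  def <- switch(key,
                "C:G" = bonds$`G:C`, "G:C" = sw(bonds$`G:C`),
                "T:A" = bonds$`A:T`, "A:T" = sw(bonds$`A:T`),
                stop("no canonical bond table for pair ", key))
  lapply(def, function(b) list(
    donor = list(strand = b$d[1], pair = pair, atom = b$d[2]),
    acceptor = list(strand = b$a[1], pair = pair, atom = b$a[2])))
}

#' Occupancy table of the canonical intra-pair bonds at one pair
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param pair Pair index (must be a canonical C:G or T:A pair).
#' @param criteria An [hbond_criteria()].
#' @return Data frame, one row per canonical bond, in the shape of a
#'   donor/acceptor occupancy table.
#' @export
wc_occupancy_table <- function(ensemble, pair, criteria = hbond_criteria()) {
  specs <- wc_bond_specs(ensemble$topology, pair)
  do.call(rbind, lapply(specs, function(s) {
    hbond_occupancy(ensemble, s$donor, s$acceptor, criteria)
  }))
}
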
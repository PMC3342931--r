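# Configuration, snapshot and report I/O.  Run configuration is YAML;
# snapshots are serialized state objects plus an optional legacy-ASCII
# VTK structured-points export of the cell lattice and fields for volume
# viewers; records and reports are CSV.

#' Default run configuration
#'
#' Every parameter of a run with its default: geometry, engine, field
#' cadence, scenario selector, duration, scale preset, seed and output
#' cadence.  Scale presets: `"full"` (120 x 120 um, 12 months) and
#' `"mini"` (48 x 48 um, 1 month), the desk-scale preset used by the
#' test and acceptance protocols.
#'
#' @param scale `"mini"` or `"full"`.
#' @return A nested list (YAML-serializable).
#' @export
default_config <- function(scale = "mini") {
  stopifnot(scale %in% c("mini", "full"))
  list(
    scale = scale,
    geometry = list(lateral_um = if (scale == "mini") 48 else 120,
                    voxel_um = 2, choroid_um = 14, cc_um = 8,
                    L_BrM = 6, L_RPE = 12, L_OS = 30, L_IS = 24),
    engine = default_engine(scale),
    fields = list(update_every_h = 6),
    scenario = list(id = 1),
    tip_cell = TRUE,
    months = if (scale == "mini") 1 else 12,
    seed = 1,
    record_every_h = 6
  )
}

#' Read / write a run configuration
#'
#' YAML round trips are lossless: `read_config(write_config(cfg, f))`
#' returns `cfg`.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `write_config` the path invisibly; `read_config` the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  # small rolling hash; stable across platforms for provenance stamping
  v <- utf8ToInt(txt)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Build a state from a configuration
#'
#' @param config A configuration list (see [default_config()]).
#' @return A `cpm_state` (tip cell seeded when `config$tip_cell`).
#' @export
state_from_config <- function(config) {
  g <- config$geometry
  geom <- retinal_geometry(lateral_um = g$lateral_um, voxel_um = g$voxel_um,
                           choroid_um = g$choroid_um, cc_um = g$cc_um,
                           L_BrM = g$L_BrM, L_RPE = g$L_RPE,
                           L_OS = g$L_OS, L_IS = g$L_IS)
  set.seed(config$seed)
  sc <- config$scenario
  scenario <- if (!is.null(sc$id)) sc$id else
    scenario_by_id(scenario_from_levels(sc$RRl, sc$RRp, sc$RBl, sc$RBp,
                                        sc$ROl))
  st <- build_retina(geom, scenario = scenario, engine = config$engine)
  st$params$field_update_every <- config$fields$update_every_h
  st$params$config_hash <- config_hash(config)
  st$params$seed <- config$seed
  if (isTRUE(config$tip_cell)) st <- seed_tip_cell(st)
  st
}

#' Snapshot a state to disk
#'
#' Serializes the full state (site map, cell table, links, fields,
#' clock) so a run can be restarted at a snapshot boundary;
#' [read_snapshot()] restores it bit-identically.
#'
#' @param state A `cpm_state`.
#' @param path Output file path (`.rds`).
#' @return The path, invisibly.
#' @export
write_snapshot <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  st <- readRDS(path)
  stopifnot(inherits(st, "cpm_state"))
  st
}

#' Cell table of a state
#'
#' @param state A `cpm_state`.
#' @return Data frame: id, type, volume, target, com, alive, frozen.
#' @export
cell_table <- function(state) {
  n <- n_cells(state)
  data.frame(id = seq_len(n), type = type_name(state$cell_type),
             volume = state$volume, target = state$target_volume,
             comx = state$comx, comy = state$comy, comz = state$comz,
             alive = state$alive, frozen = state$frozen,
             birth_time = state$birth_time)
}

#' Export a state as legacy-ASCII VTK structured points
#'
#' Writes the cell-id lattice, the cell-type lattice and optionally each
#' field as point data on a structured-points grid readable by standard
#' volume viewers.
#'
#' @param state A `cpm_state`.
#' @param path Output `.vtk` path.
#' @param fields Include the chemical fields (default TRUE).
#' @return The path, invisibly.
#' @export
write_vtk <- function(state, path, fields = TRUE) {
  d <- state$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("cnvpotts snapshot t=%.2fh", state$clock),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", state$voxel_size,
                       state$voxel_size, state$voxel_size),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS cell_id int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(state$site), collapse = " "), con)
  typ <- array(0L, dim = d)
  occ <- state$site > 0L
  typ[occ] <- state$cell_type[state$site[occ]]
  writeLines(c("SCALARS cell_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(typ), collapse = " "), con)
  if (fields) {
    all_fields <- c(state$chem_fields, state$fields)
    for (nm in names(all_fields)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(paste(signif(as.numeric(all_fields[[nm]]), 7),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write a morphometric record stream as CSV
#'
#' One row per sampling cadence tick, stamped with the seed and config
#' hash when available.
#'
#' @param records Data frame of morphometric records.
#' @param path Output path.
#' @param state Optional state supplying the provenance stamp.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path, state = NULL) {
  if (!is.null(state)) {
    records$seed <- state$params$seed %||% NA
    records$config <- state$params$config_hash %||% NA
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) utils::read.csv(path)

#' Write a per-replica classification report as CSV
#'
#' @param outcome A `scenario_outcome` from [run_replicas()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(outcome, path) {
  reps <- outcome$replicas
  reps$scenario <- outcome$scenario$id
  utils::write.csv(reps, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
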
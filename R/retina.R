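# Construction of the simulated outer retina and the cell-fate rules.
#
# The scene, bottom to top along z: a choroidal margin of Medium topped by
# a labyrinthine sheet of Vascular cells (the choriocapillaris, ~70%
# coverage of the BrM choroidal face, lumen gaps as Medium); a slab of
# frozen BrM blocks; a confluent monolayer of cuboidal RPE cells;
# columnar photoreceptors as paired POS and PIS compartments; the fixed
# plane at the top is the outer limiting membrane.

#' Retinal geometry
#'
#' @param lateral_um Lateral extent (um); must accommodate a whole number
#'   of RPE cells and photoreceptor columns.
#' @param voxel_um Voxel edge (um).
#' @param choroid_um Choroidal margin below BrM (um); the CC sheet
#'   occupies its top `cc_um`.
#' @param cc_um Thickness of the CC endothelial sheet (um).
#' @param L_BrM,L_RPE,L_OS,L_IS Layer thicknesses (um).
#' @return A `retinal_geometry` list with voxel-resolved layer bounds.
#' @export
retinal_geometry <- function(lateral_um = 120, voxel_um = 2,
                             choroid_um = 14, cc_um = 8,
                             L_BrM = 6, L_RPE = 12, L_OS = 30,
                             L_IS = 24) {
  h <- voxel_um
  stopifnot(lateral_um %% (6 * h) == 0)  # RPE cells are 12 um wide
  if (lateral_um < 4 * 12)
    stop("lateral extent cannot host a confluent RPE monolayer")
  nxy <- as.integer(lateral_um / h)
  nv <- function(um) as.integer(round(um / h))
  z_choroid <- nv(choroid_um)
  g <- list(
    lateral_um = lateral_um, voxel_um = h,
    nx = nxy, ny = nxy,
    nz = z_choroid + nv(L_BrM) + nv(L_RPE) + nv(L_OS) + nv(L_IS),
    # 1-based inclusive z ranges per layer
    z_cc = c(z_choroid - nv(cc_um) + 1L, z_choroid),
    z_brm = c(z_choroid + 1L, z_choroid + nv(L_BrM)),
    z_rpe = c(z_choroid + nv(L_BrM) + 1L,
              z_choroid + nv(L_BrM) + nv(L_RPE)),
    z_pos = c(z_choroid + nv(L_BrM) + nv(L_RPE) + 1L,
              z_choroid + nv(L_BrM) + nv(L_RPE) + nv(L_OS)),
    z_pis = c(z_choroid + nv(L_BrM) + nv(L_RPE) + nv(L_OS) + 1L,
              z_choroid + nv(L_BrM) + nv(L_RPE) + nv(L_OS) + nv(L_IS)),
    L_BrM = L_BrM, L_RPE = L_RPE, L_OS = L_OS, L_IS = L_IS)
  class(g) <- "retinal_geometry"
  g
}

#' Cell type catalog
#'
#' Target volumes (voxels), chemotaxis couplings, secretion/uptake roles
#' and motility per generalized-cell type at 2-um voxels.  Endothelial
#' cells chemotax up the short-diffusing VEGF-A gradient; activated ECs
#' (Stalk, Tip) additionally up the RPE-derived VEGF-A gradient; all
#' chemotaxis is contact-inhibited.  Tip cells live exactly 24 h.
#'
#' @param geom A [retinal_geometry()].
#' @return Data frame, one row per type.
#' @export
cell_type_catalog <- function(geom = retinal_geometry()) {
  h <- geom$voxel_um
  vcell <- function(w_um, h_um) as.integer(round(w_um^2 * h_um / h^3))
  data.frame(
    type = c("Vascular", "Stalk", "Tip", "RPE", "POS", "PIS", "BrM"),
    target_volume = c(vcell(12, 8), 64L, 64L, vcell(12, 12),
                      vcell(6, 30), vcell(6, 24), vcell(6, 6)),
    lambda_rpe_vegf = c(0, 21500, 21500, 0, 0, 0, 0),
    lambda_short_vegf = c(500, 500, 500, 0, 0, 0, 0),
    motile = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    tip_lifetime_h = c(NA, NA, 24, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# deterministic choriocapillaris lumen mask over an n x n block grid:
# blocks with (i + 2 j) mod 3 == 0 are lumen gaps (~2/3 coverage,
# laterally connected under periodic wrap)
cc_mask <- function(nblocks) {
  outer(0:(nblocks - 1), 0:(nblocks - 1),
        function(i, j) (i + 2 * j) %% 3 != 0)
}

vox_block <- function(xr, yr, zr) {
  as.matrix(expand.grid(x = xr, y = yr, z = zr))
}

#' Build the simulated retina
#'
#' Constructs the full scene for an adhesion scenario, creates the
#' junctional springs of the intact tissue, solves the intact-retina
#' steady states of the chemical fields and calibrates the
#' concentration-referenced rates (EC survival threshold, stalk growth
#' rate) against them.
#'
#' @param geom A [retinal_geometry()].
#' @param scenario Adhesion scenario (id or row from
#'   [enumerate_scenarios()]).
#' @param catalog Optional [cell_type_catalog()] override.
#' @param engine List of engine parameters: `temperature`, `lambda_vol`,
#'   `mcs_per_hour` (see [default_engine()]).
#' @return A `cpm_state` ready for [simulate_cnv()].
#' @export
build_retina <- function(geom = retinal_geometry(), scenario = 1,
                         catalog = cell_type_catalog(geom),
                         engine = default_engine()) {
  # uniform interface tension: every unlike-pair contact (including
  # cell-Medium) costs surface_tension on top of the adhesion table, so
  # boundaries have positive energy while all adhesion differences
  # between type pairs keep their tabulated values
  J <- contact_energy_table(scenario) + engine$surface_tension
  J["Medium", "Medium"] <- 0
  st <- new_cpm_state(c(geom$nx, geom$ny, geom$nz),
                      voxel_size = geom$voxel_um,
                      temperature = engine$temperature,
                      lambda_vol = engine$lambda_vol,
                      mcs_per_hour = engine$mcs_per_hour, J = J,
                      spring_scale = engine$spring_scale)
  st$params$spring_lambda <- spring_lambda_table(scenario)
  st$params$scenario <- if (is.numeric(scenario)) scenario_by_id(scenario)
    else scenario
  st$params$geom <- geom
  tv <- function(ty) catalog$target_volume[catalog$type == ty]

  # choriocapillaris: 12-um vascular blocks with lumen gaps
  wb <- as.integer(12 / geom$voxel_um)
  nb <- geom$nx %/% wb
  keep <- cc_mask(nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (!keep[i, j]) next
    st <- add_cell(st, vox_block(((i - 1) * wb + 1):(i * wb),
                                 ((j - 1) * wb + 1):(j * wb),
                                 geom$z_cc[1]:geom$z_cc[2]),
                   "Vascular", target_volume = tv("Vascular"))
  }
  # Bruch's membrane: frozen 6-um blocks
  bb <- as.integer(6 / geom$voxel_um)
  nbb <- geom$nx %/% bb
  for (i in seq_len(nbb)) for (j in seq_len(nbb)) {
    st <- add_cell(st, vox_block(((i - 1) * bb + 1):(i * bb),
                                 ((j - 1) * bb + 1):(j * bb),
                                 geom$z_brm[1]:geom$z_brm[2]),
                   "BrM", frozen = TRUE)
  }
  # RPE monolayer: 12-um cuboidal cells
  wr <- as.integer(12 / geom$voxel_um)
  nr <- geom$nx %/% wr
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    st <- add_cell(st, vox_block(((i - 1) * wr + 1):(i * wr),
                                 ((j - 1) * wr + 1):(j * wr),
                                 geom$z_rpe[1]:geom$z_rpe[2]),
                   "RPE", target_volume = tv("RPE"))
  }
  # photoreceptor columns: paired POS / PIS compartments, 6-um footprint
  wc <- as.integer(6 / geom$voxel_um)
  nc <- geom$nx %/% wc
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    xr <- ((i - 1) * wc + 1):(i * wc); yr <- ((j - 1) * wc + 1):(j * wc)
    st <- add_cell(st, vox_block(xr, yr, geom$z_pos[1]:geom$z_pos[2]),
                   "POS", target_volume = tv("POS"))
    st <- add_cell(st, vox_block(xr, yr, geom$z_pis[1]:geom$z_pis[2]),
                   "PIS", target_volume = tv("PIS"))
  }

  # chemotaxis couplings
  for (r in seq_len(nrow(catalog))) {
    code <- cell_types()[[catalog$type[r]]]
    st$lambda_chem[code + 1, "rpe_vegf"] <- catalog$lambda_rpe_vegf[r]
    st$lambda_chem[code + 1, "short_vegf"] <- catalog$lambda_short_vegf[r]
  }

  # junctional springs of the intact tissue
  st <- maintain_links(st)

  # intact-retina field steady states and calibration references
  st$chem_fields$rpe_vegf <- steady_field(st, "rpe_vegf")
  st$chem_fields$short_vegf <- steady_field(st, "short_vegf")
  st$fields$mmp <- array(0, dim = st$dims)
  apical <- st$chem_fields$rpe_vegf[, , geom$z_pos[1]]
  subrpe <- st$chem_fields$rpe_vegf[, , geom$z_brm[2]]
  st$params$c_apical_ref <- mean(apical)
  st$params$c_subrpe_ref <- mean(subrpe)
  st$params$survival_threshold <- 0.1 * st$params$c_apical_ref
  st$params$stalk_target <- tv("Stalk")
  st$params$doubling_volume <- 2L * tv("Stalk")
  # free stalk at sub-RPE VEGF doubles its target in ~12 h
  st$params$growth_rate <- tv("Stalk") / (12 * st$params$c_subrpe_ref)
  st$params$inhibition_threshold <- 0.28
  st$params$growth_pressure_cap <- 12
  st$params$ec_grace <- 6; st$params$rpe_grace <- 12
  st$params$death_ramp <- 6
  st$params$tip_lifetime <- 24
  st$params$mmp_rate <- default_engine()$mmp_rate
  st$params$field_update_every <- 6
  st
}

#' Default engine parameters
#'
#' Fluctuation temperature, volume-constraint stiffness and the
#' MCS-to-time conversion, fixed by the calibration protocol: the intact
#' all-normal retina is stable over a scaled month and a free stalk cell
#' at sub-RPE VEGF divides about every 12 h.  The full-scale preset
#' resolves time at 1 MCS per simulated minute; the desk-scale mini
#' preset coarsens this to 1 MCS per 6 simulated minutes, which leaves
#' cell motility much faster than every fate timescale (tip lifetime,
#' doubling, death ramps) while cutting the replica cost.  `mmp_rate` is
#' the BrM degradation constant, calibrated so 24 h of tip-cell
#' secretion opens a roughly one-cell-diameter hole.
#'
#' @param scale `"full"` or `"mini"`.
#' @return Named list of engine parameters.
#' @export
default_engine <- function(scale = "full") {
  list(temperature = 20, lambda_vol = 5,
       mcs_per_hour = if (scale == "mini") 15 else 60,
       mmp_rate = 3e-4, surface_tension = 56, spring_scale = 0.1)
}

#' Seed the endothelial tip cell
#'
#' Converts one choriocapillaris Vascular cell into the (single) Tip
#' cell: MMP secretion starts and the 24-h differentiation clock begins.
#'
#' @param state A `cpm_state` from [build_retina()].
#' @param location Optional lateral voxel coordinates `c(x, y)`; the
#'   Vascular cell with the nearest center of mass is converted.  The
#'   default is the lateral domain center.
#' @return The updated state.
#' @export
seed_tip_cell <- function(state, location = NULL) {
  ct <- cell_types()
  if (any(state$cell_type == ct[["Tip"]] & state$alive))
    stop("a tip cell already exists: single-tip protocol")
  if (is.null(location)) location <- state$dims[1:2] / 2
  vasc <- which(state$cell_type == ct[["Vascular"]] & state$alive &
                  state$volume > 0)
  if (length(vasc) == 0) stop("no choriocapillaris cell to convert")
  d2 <- (pmin(abs(state$comx[vasc] - location[1]),
              state$dims[1] - abs(state$comx[vasc] - location[1])))^2 +
    (pmin(abs(state$comy[vasc] - location[2]),
          state$dims[2] - abs(state$comy[vasc] - location[2])))^2
  id <- vasc[which.min(d2)]
  if (sqrt(min(d2)) > max(state$dims[1:2]))
    stop("no choriocapillaris cell at location")
  state$cell_type[id] <- ct[["Tip"]]
  state$birth_time[id] <- state$clock
  state$target_volume[id] <- state$params$stalk_target
  state$events <- rbind(state$events,
                        data.frame(time = state$clock, cell = id,
                                   type = "tip_seeded", detail = ""))
  state
}

#' Differentiate expired tip cells
#'
#' Every Tip cell older than its 24-h lifetime becomes a Stalk cell and
#' stops secreting MMP.
#'
#' @param state A `cpm_state`.
#' @return The updated state.
#' @export
differentiate_tips <- function(state) {
  ct <- cell_types()
  hit <- which(state$cell_type == ct[["Tip"]] & state$alive &
                 (state$clock - state$birth_time) >=
                 state$params$tip_lifetime)
  if (length(hit)) {
    state$cell_type[hit] <- ct[["Stalk"]]
    state$events <- rbind(state$events,
                          data.frame(time = state$clock, cell = hit,
                                     type = "tip_differentiated",
                                     detail = ""))
  }
  state
}

begin_death <- function(state, ids, cause) {
  ids <- ids[!state$dying[ids]]
  if (!length(ids)) return(state)
  state$dying[ids] <- TRUE
  state$death_start[ids] <- state$clock
  state$death_rate[ids] <- state$target_volume[ids] /
    state$params$death_ramp
  state$events <- rbind(state$events,
                        data.frame(time = state$clock, cell = ids,
                                   type = "death", detail = cause))
  state
}

#' Apply the survival rules
#'
#' Endothelial cells starve when their mean RPE-derived VEGF-A stays
#' below the survival threshold for the grace period.  RPE cells die
#' only when they have had neither RPE-neighbor contact nor BrM contact
#' for the grace period (detachment from BrM alone is survivable while
#' lateral junctions persist).  Death ramps the target volume to zero
#' over 6 h; every death is logged with its cause.
#'
#' @param state A `cpm_state` with current fields.
#' @param areas Optional precomputed [contact_areas()] table (order 6).
#' @return The updated state.
#' @export
update_survival <- function(state, areas = NULL) {
  ct <- cell_types()
  now <- state$clock
  live <- state$alive & state$volume > 0 & !state$dying
  # endothelial starvation
  ecs <- which(live & state$cell_type %in% c(ct[["Vascular"]],
                                             ct[["Stalk"]], ct[["Tip"]]))
  if (length(ecs)) {
    cmean <- .field_mean_by_cell_cpp(as.integer(state$site),
                                     as.numeric(state$chem_fields$rpe_vegf),
                                     n_cells(state))
    starv <- ecs[!is.na(cmean[ecs]) &
                   cmean[ecs] < state$params$survival_threshold]
    fed <- setdiff(ecs, starv)
    state$starved_since[fed] <- NA_real_
    fresh <- starv[is.na(state$starved_since[starv])]
    state$starved_since[fresh] <- now
    expired <- starv[!is.na(state$starved_since[starv]) &
                       now - state$starved_since[starv] >=
                       state$params$ec_grace]
    state <- begin_death(state, expired, "vegf_starvation")
  }
  # RPE isolation
  rpes <- which(live & state$cell_type == ct[["RPE"]])
  if (length(rpes)) {
    if (is.null(areas)) areas <- contact_areas(state, order = 6)
    has_contact <- function(id) {
      rows <- areas[areas$a == id | areas$b == id, , drop = FALSE]
      other <- ifelse(rows$a == id, rows$b, rows$a)
      other <- other[other > 0]
      oty <- state$cell_type[other]
      any(oty == ct[["RPE"]] | oty == ct[["BrM"]])
    }
    attached <- vapply(rpes, has_contact, logical(1))
    state$isolated_since[rpes[attached]] <- NA_real_
    iso <- rpes[!attached]
    fresh <- iso[is.na(state$isolated_since[iso])]
    state$isolated_since[fresh] <- now
    expired <- iso[!is.na(state$isolated_since[iso]) &
                     now - state$isolated_since[iso] >=
                     state$params$rpe_grace]
    state <- begin_death(state, expired, "rpe_isolation")
  }
  state
}

# advance death ramps by dt hours and clear emptied cells
apply_death_ramps <- function(state, dt) {
  dy <- which(state$dying & state$alive)
  if (!length(dy)) return(state)
  state$target_volume[dy] <- pmax(0, state$target_volume[dy] -
                                    state$death_rate[dy] * dt)
  done <- dy[state$target_volume[dy] <= 0 &
               (state$volume[dy] <= 3 |
                  state$clock - state$death_start[dy] >=
                  2 * state$params$death_ramp)]
  for (id in done) {
    state$site[state$site == id] <- 0L
    state$volume[id] <- 0L
    state$alive[id] <- FALSE
    drop <- (state$link_a == id | state$link_b == id) & state$link_active
    state$link_active[drop] <- FALSE
  }
  state$alive[dy[state$volume[dy] == 0L]] <- FALSE
  state
}

#' Grow stalk cells
#'
#' Each living Stalk cell's target volume grows at
#' `growth_rate * mean(RPE-derived VEGF-A over the cell) * dt` unless the
#' endothelial fraction of its boundary exceeds the contact-inhibition
#' threshold.  Cells at or above the doubling volume are reported for
#' division.
#'
#' @param state A `cpm_state`.
#' @param dt Time step (hours).
#' @return List with the updated `state` and `to_divide` (cell ids).
#' @export
grow_stalk_cells <- function(state, dt = 1) {
  ct <- cell_types()
  stalks <- which(state$alive & !state$dying & state$volume > 0 &
                    state$cell_type == ct[["Stalk"]])
  if (!length(stalks))
    return(list(state = state, to_divide = integer(0)))
  bs <- .boundary_stats_cpp(as.integer(state$site), state$dims,
                            state$cell_type)
  frac <- ifelse(bs$boundary > 0, bs$ec_contact / bs$boundary, 0)
  cmean <- .field_mean_by_cell_cpp(as.integer(state$site),
                                   as.numeric(state$chem_fields$rpe_vegf),
                                   n_cells(state))
  cap <- state$params$growth_pressure_cap %||% Inf
  grow <- stalks[frac[stalks] <= state$params$inhibition_threshold &
                   !is.na(cmean[stalks]) &
                   (state$target_volume[stalks] - state$volume[stalks]) <
                     cap]
  state$target_volume[grow] <- state$target_volume[grow] +
    state$params$growth_rate * cmean[grow] * dt
  to_divide <- stalks[state$volume[stalks] >=
                        state$params$doubling_volume]
  list(state = state, to_divide = to_divide)
}

#' Deterministic test fixtures
#'
#' Small states for unit testing: `two_cell_toy` (two cells and Medium on
#' a small lattice), `mini_retina` (a 48 x 48 um retina with all seven
#' cell types), `uniform_slab` (laterally uniform layered retina for
#' field tests, one whole-layer cell per tissue layer).
#'
#' @param kind One of `"two_cell_toy"`, `"mini_retina"`,
#'   `"uniform_slab"`.
#' @param scenario Adhesion scenario for `mini_retina` (default
#'   all-normal).
#' @return A `cpm_state`.
#' @export
make_fixture <- function(kind = c("two_cell_toy", "mini_retina",
                                  "uniform_slab"), scenario = 1) {
  kind <- match.arg(kind)
  if (kind == "two_cell_toy") {
    st <- new_cpm_state(c(8, 8, 8), J = contact_energy_table(1))
    st <- add_cell(st, vox_block(3:4, 3:4, 3:4), "RPE")
    st <- add_cell(st, vox_block(5:6, 3:4, 3:4), "RPE")
    st
  } else if (kind == "mini_retina") {
    build_retina(retinal_geometry(lateral_um = 48), scenario = scenario)
  } else {
    g <- retinal_geometry(lateral_um = 48)
    st <- new_cpm_state(c(g$nx, g$ny, g$nz), voxel_size = g$voxel_um,
                        J = contact_energy_table(1))
    st$params$geom <- g
    lay <- list(Vascular = g$z_cc, BrM = g$z_brm, RPE = g$z_rpe,
                POS = g$z_pos, PIS = g$z_pis)
    for (ty in names(lay)) {
      zr <- lay[[ty]]
      st <- add_cell(st, vox_block(1:g$nx, 1:g$ny, zr[1]:zr[2]), ty,
                     frozen = ty == "BrM")
    }
    st
  }
}
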
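# Replica driver: alternates lattice Monte Carlo with field updates,
# junction maintenance, Bruch's-membrane degradation and the cell-fate
# rules, sampling a morphometric record every 6 simulated hours.

#' Simulate one replica
#'
#' Advances a built retina for a span of simulated time.  Each 1-h tick
#' runs `mcs_per_hour` Monte Carlo steps, then (while a tip cell is
#' active) re-solves the MMP quasi-steady state and degrades BrM,
#' differentiates expired tip cells, refreshes the VEGF steady states at
#' the field-update cadence, applies the survival rules and death ramps,
#' grows and divides stalk cells, and maintains the junctional springs.
#'
#' @param state A `cpm_state` from [build_retina()] (with or without a
#'   seeded tip cell).
#' @param hours Simulated duration in hours (or give `months`).
#' @param months Simulated duration in months of 730 h.
#' @param record_every Morphometric sampling cadence in hours.
#' @param progress If `TRUE`, print a line per sampled record.
#' @return List with the final `state`, the data frame of morphometric
#'   `records`, and `events` (the state's event log).
#' @export
simulate_cnv <- function(state, hours = NULL, months = NULL,
                         record_every = 6, progress = FALSE) {
  if (is.null(hours)) {
    stopifnot(!is.null(months))
    hours <- months * 730
  }
  ct <- cell_types()
  records <- morphometric_record(state)
  t_end <- state$clock + hours
  next_record <- state$clock + record_every
  upd <- state$params$field_update_every
  next_field <- state$clock  # fields were solved at build time
  while (state$clock < t_end - 1e-9) {
    res <- run_mcs(state, state$mcs_per_hour)  # advances clock by 1 h
    state <- res$state

    tip_active <- any(state$cell_type == ct[["Tip"]] & state$alive &
                        state$volume > 0)
    if (tip_active) {
      state$fields$mmp <- steady_field(state, "mmp",
                                       init = state$fields$mmp,
                                       tol = 1e-6, max_iter = 200)
      dg <- degrade_brm(state, state$fields$mmp,
                        rate = state$params$mmp_rate, dt = 3600)
      state <- dg$state
    } else if (any(state$fields$mmp > 0)) {
      state$fields$mmp <- array(0, dim = state$dims)
    }

    state <- differentiate_tips(state)

    if (state$clock >= next_field - 1e-9) {
      state$chem_fields$rpe_vegf <-
        steady_field(state, "rpe_vegf", init = state$chem_fields$rpe_vegf,
                     tol = 3e-6, max_iter = 400)
      state$chem_fields$short_vegf <-
        steady_field(state, "short_vegf",
                     init = state$chem_fields$short_vegf,
                     tol = 3e-6, max_iter = 400)
      next_field <- state$clock + upd
    }

    areas <- contact_areas(state, order = 6)
    state <- update_survival(state, areas = areas)
    state <- apply_death_ramps(state, dt = 1)

    gr <- grow_stalk_cells(state, dt = 1)
    state <- gr$state
    divided <- length(gr$to_divide) > 0
    for (id in gr$to_divide) {
      sp <- split_cell(state, id)
      state <- sp$state
      state$events <- rbind(state$events,
                            data.frame(time = state$clock, cell = id,
                                       type = "division",
                                       detail = paste0("daughter=",
                                                       sp$daughter)))
    }
    if (divided) areas <- contact_areas(state, order = 6)

    state <- maintain_links(state, areas = areas)

    if (state$clock >= next_record - 1e-9) {
      rec <- morphometric_record(state, areas = areas)
      records <- rbind(records, rec)
      next_record <- next_record + record_every
      if (progress)
        cat(sprintf("t=%7.1f h  stalk=%3d  MW=%s\n", rec$time,
                    rec$n_stalk,
                    formatC(compute_mw(rec), digits = 3, format = "f")))
    }
  }
  list(state = state, records = records, events = state$events)
}

#' Simulated hours per month
#'
#' One simulated month is 1/12 of a 365-day year, 730 h.
#'
#' @return 730
#' @export
hours_per_month <- function() 730
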
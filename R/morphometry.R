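# Morphometric quantification of simulated CNV.  The morphometric weight
# MW locates the stalk-cell population between Bruch's membrane (MW -> 1,
# sub-RPE, Type 1) and the photoreceptor outer segments (MW -> 0,
# sub-retinal, Type 2); intermediate MW indicates both loci (Type 3).

#' Morphometric record of a state
#'
#' Contact areas (voxel faces) and cell counts from which the
#' morphometric weight, CNV type and dynamics class are computed.
#'
#' @param state A `cpm_state`.
#' @param areas Optional precomputed [contact_areas()] table (order 6).
#' @return One-row data frame: `time` (h), `n_stalk`, `ca_stalk_brm`,
#'   `ca_stalk_pos`, `ca_rpe_brm`, `ca_pos_brm`, `n_rpe`,
#'   `n_stalk_subrpe` (stalk cells touching BrM), `n_stalk_subretinal`
#'   (stalk cells touching POS), and `flag_interposed` (stalk cells whose
#'   dominant contact is lateral RPE, the exceptional mid-MW case).
#' @export
morphometric_record <- function(state, areas = NULL) {
  if (is.null(areas)) areas <- contact_areas(state, order = 6)
  ct <- cell_types()
  live <- state$alive & state$volume > 0
  stalk_ids <- which(live & state$cell_type == ct[["Stalk"]])
  rpe_ids <- which(live & state$cell_type == ct[["RPE"]])
  ty <- function(v) ifelse(v > 0, state$cell_type[pmax(v, 1L)], 0L)
  ta <- ty(areas$a); tb <- ty(areas$b)
  pair_area <- function(c1, c2)
    sum(areas$area[(ta == c1 & tb == c2) | (ta == c2 & tb == c1)])
  per_stalk <- function(other_code) {
    hit <- (areas$a %in% stalk_ids & tb == other_code) |
      (areas$b %in% stalk_ids & ta == other_code)
    ids <- c(areas$a[hit & areas$a %in% stalk_ids],
             areas$b[hit & areas$b %in% stalk_ids])
    tapply(c(areas$area[hit & areas$a %in% stalk_ids],
             areas$area[hit & areas$b %in% stalk_ids]), ids, sum)
  }
  brm_by <- per_stalk(ct[["BrM"]]); pos_by <- per_stalk(ct[["POS"]])
  rpe_by <- per_stalk(ct[["RPE"]])
  tot_brm <- sum(brm_by); tot_pos <- sum(pos_by)
  # stalk cells dominated by lateral RPE contact (exceptional Type-3 case)
  interposed <- 0L
  if (length(stalk_ids)) {
    for (id in stalk_ids) {
      rb <- if (as.character(id) %in% names(brm_by)) brm_by[[as.character(id)]] else 0
      rp <- if (as.character(id) %in% names(pos_by)) pos_by[[as.character(id)]] else 0
      rr <- if (as.character(id) %in% names(rpe_by)) rpe_by[[as.character(id)]] else 0
      if (rr > rb + rp && rr > 0) interposed <- interposed + 1L
    }
  }
  data.frame(
    time = state$clock,
    n_stalk = length(stalk_ids),
    ca_stalk_brm = tot_brm,
    ca_stalk_pos = tot_pos,
    ca_rpe_brm = pair_area(ct[["RPE"]], ct[["BrM"]]),
    ca_pos_brm = pair_area(ct[["POS"]], ct[["BrM"]]),
    n_rpe = length(rpe_ids),
    n_stalk_subrpe = sum(names(brm_by) %in% as.character(stalk_ids) &
                           brm_by > 0),
    n_stalk_subretinal = sum(names(pos_by) %in% as.character(stalk_ids) &
                               pos_by > 0),
    flag_interposed = interposed)
}

#' Morphometric weight
#'
#' `MW = ca_stalk_brm / (ca_stalk_brm + ca_stalk_pos)`: 1 when all stalk
#' contact is with BrM (sub-RPE confinement), 0 when all is with the POS
#' (sub-retinal).  Undefined (NA) when stalk cells touch neither.
#'
#' @param record A morphometric record row (or data frame of rows).
#' @return MW in `[0, 1]`, or NA where undefined.
#' @export
compute_mw <- function(record) {
  den <- record$ca_stalk_brm + record$ca_stalk_pos
  ifelse(den > 0, record$ca_stalk_brm / den, NA_real_)
}

#' Classify CNV type from a morphometric weight
#'
#' Type 1 (sub-RPE) iff MW >= 0.75; Type 2 (sub-retinal) iff MW <= 0.25;
#' Type 3 otherwise.  An undefined MW yields NA ("no CNV locus").
#'
#' @param mw Morphometric weight(s) in `[0, 1]` or NA.
#' @return Character vector in `{"Type1", "Type2", "Type3"}` or NA.
#' @export
classify_type <- function(mw) {
  stopifnot(all(is.na(mw) | (mw >= 0 & mw <= 1)))
  ifelse(is.na(mw), NA_character_,
         ifelse(mw >= 0.75, "Type1",
                ifelse(mw <= 0.25, "Type2", "Type3")))
}

#' Stalk-weighted mean morphometric weight over a window
#'
#' The mean MW over the records in the window, weighted by the stalk-cell
#' count of each record; records with undefined MW are skipped.  NA when
#' no record in the window has a defined MW.
#'
#' @param records Data frame of morphometric records.
#' @param window Length-2 numeric: time window `[from, to]` in hours.
#' @return The weighted mean MW, or NA.
#' @export
window_mean_mw <- function(records, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  w <- records[records$time >= window[1] & records$time <= window[2], ,
               drop = FALSE]
  if (nrow(w) == 0) stop("empty window: no records in [",
                         window[1], ", ", window[2], "] h")
  mw <- compute_mw(w)
  ok <- !is.na(mw) & w$n_stalk > 0
  if (!any(ok)) return(NA_real_)
  sum(w$n_stalk[ok] * mw[ok]) / sum(w$n_stalk[ok])
}

#' Classify CNV progression dynamics
#'
#' Maps the ordered pair of early-window and late-window CNV types to the
#' nine dynamics classes: stable (S11, S22, S33), translocation (T12,
#' T21, T31, T32) and progression (P13, P23).
#'
#' @param early_type,late_type Types in `{"Type1","Type2","Type3"}` (NA
#'   allowed).
#' @return The dynamics class, or NA ("not classifiable, no CNV") when
#'   either type is undefined.
#' @export
classify_dynamics <- function(early_type, late_type) {
  if (is.na(early_type) || is.na(late_type)) return(NA_character_)
  tab <- matrix(c("S11", "T12", "P13",
                  "T21", "S22", "P23",
                  "T31", "T32", "S33"),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("Type1", "Type2", "Type3"),
                                c("Type1", "Type2", "Type3")))
  tab[early_type, late_type]
}

#' Detect CNV initiation
#'
#' CNV onset is the first time at which the total stalk-cell count
#' exceeds three.
#'
#' @param records Time-ordered data frame of morphometric records.
#' @return The onset time in hours, or NA if initiation never occurs.
#' @export
detect_initiation <- function(records) {
  if (is.unsorted(records$time)) stop("records must be time-ordered")
  hit <- which(records$n_stalk > 3)
  if (length(hit) == 0) NA_real_ else records$time[hit[1]]
}

#' Classify a replica's record stream
#'
#' Computes onset, early and late CNV types (stalk-weighted mean MW over
#' the first and last three months of a full-year run, or the first and
#' last quarter of a shorter run) and the dynamics class.
#'
#' @param records Data frame of morphometric records.
#' @param total_hours Run duration in hours (defaults to the last record
#'   time).
#' @return One-row data frame: `onset`, `early_mw`, `late_mw`,
#'   `early_type`, `late_type`, `dynamics`, `initiated`, `mean_mw`.
#' @export
classify_records <- function(records, total_hours = NULL) {
  if (is.null(total_hours)) total_hours <- max(records$time)
  month <- 730  # simulated hours per month (1/12 year)
  if (total_hours >= 12 * month - 1e-6) {
    early <- c(0, 3 * month); late <- c(total_hours - 3 * month,
                                        total_hours)
  } else {
    early <- c(0, total_hours / 4)
    late <- c(3 * total_hours / 4, total_hours)
  }
  early_mw <- window_mean_mw(records, early)
  late_mw <- window_mean_mw(records, late)
  early_type <- classify_type(early_mw)
  late_type <- classify_type(late_mw)
  onset <- detect_initiation(records)
  mwall <- compute_mw(records)
  ok <- !is.na(mwall) & records$n_stalk > 0
  data.frame(onset = onset, early_mw = early_mw, late_mw = late_mw,
             early_type = early_type, late_type = late_type,
             dynamics = classify_dynamics(early_type, late_type),
             initiated = !is.na(onset),
             mean_mw = if (any(ok))
               sum(records$n_stalk[ok] * mwall[ok]) /
               sum(records$n_stalk[ok]) else NA_real_,
             stringsAsFactors = FALSE)
}
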
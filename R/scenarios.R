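# The adhesion-scenario factorial.  Five graded adhesion parameters:
#   RRl  RPE-RPE labile adhesion        levels {3, 1}
#   RRp  RPE-RPE plastic coupling       levels {3, 2, 1}
#   RBl  RPE-BrM labile adhesion        levels {3, 2, 1}
#   RBp  RPE-BrM plastic coupling       levels {3, 2, 1}
#   ROl  RPE-POS labile adhesion        levels {3, 1}
# (3 = normal, 2 = moderately impaired, 1 = severely impaired.)
# That gives 2*3*3*3*2 = 108 scenarios.  Ids follow a lexicographic order
# with key priority (RBl, ROl, RRl, RRp, RBp), levels descending, which is
# the unique lexicographic rule consistent with every published id anchor
# (id 1 = all-normal, 108 = all-severe, 38 = (3,3,2,2,3), 93 =
# (3,3,1,1,1), 16 = (1,1,3,3,3), 83 = (1,3,1,2,3), 53 = (1,1,2,2,3),
# 10 = (1,3,3,3,3), 19 = (3,3,3,3,1), and the 22/24 and 82/85/88
# families).

scenario_level_sets <- function() {
  list(RRl = c(3L, 1L), RRp = c(3L, 2L, 1L), RBl = c(3L, 2L, 1L),
       RBp = c(3L, 2L, 1L), ROl = c(3L, 1L))
}

#' Enumerate the 108 adhesion scenarios
#'
#' @return Data frame with columns `id`, `RRl`, `RRp`, `RBl`, `RBp`,
#'   `ROl`; row `k` has id `k`.  Scenario 1 is all-normal, scenario 108
#'   all-severely-impaired.
#' @export
enumerate_scenarios <- function() {
  ls <- scenario_level_sets()
  # key priority (slowest to fastest): RBl, ROl, RRl, RRp, RBp
  grid <- expand.grid(RBp = ls$RBp, RRp = ls$RRp, RRl = ls$RRl,
                      ROl = ls$ROl, RBl = ls$RBl,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(id = seq_len(nrow(grid)),
                    RRl = grid$RRl, RRp = grid$RRp, RBl = grid$RBl,
                    RBp = grid$RBp, ROl = grid$ROl)
  out
}

#' Look up an adhesion scenario
#'
#' @param id Scenario id in 1..108.
#' @return A one-row data frame (see [enumerate_scenarios()]).
#' @export
scenario_by_id <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:108)
  enumerate_scenarios()[id, , drop = FALSE]
}

#' Scenario id from adhesion levels
#'
#' @param RRl,RRp,RBl,RBp,ROl Adhesion levels (3 = normal, 2 = moderate
#'   impairment where available, 1 = severe impairment).
#' @return The scenario id.
#' @export
scenario_from_levels <- function(RRl, RRp, RBl, RBp, ROl) {
  validate_levels(RRl, RRp, RBl, RBp, ROl)
  sc <- enumerate_scenarios()
  sc$id[sc$RRl == RRl & sc$RRp == RRp & sc$RBl == RBl &
          sc$RBp == RBp & sc$ROl == ROl]
}

validate_levels <- function(RRl, RRp, RBl, RBp, ROl) {
  ls <- scenario_level_sets()
  lv <- list(RRl = RRl, RRp = RRp, RBl = RBl, RBp = RBp, ROl = ROl)
  for (nm in names(lv))
    if (!lv[[nm]] %in% ls[[nm]])
      stop(sprintf("inadmissible level %s = %s (allowed: %s)", nm,
                   lv[[nm]], paste(ls[[nm]], collapse = ", ")))
  invisible(TRUE)
}

# level -> parameter maps (labile contact energies; spring strengths)
labile_levels <- function() {
  list(RRl = c(`3` = -40, `1` = -18),
       RBl = c(`3` = -38, `2` = -28, `1` = -18),
       ROl = c(`3` = -16, `1` = -1))
}

plastic_levels <- function() {
  c(`3` = 300, `2` = 60, `1` = 30)
}

#' Adhesion parameters of a scenario
#'
#' Maps the scenario's graded levels to labile contact-energy overrides
#' and plastic-coupling (spring stiffness) overrides.  All other entries
#' stay at the baseline tables (e.g. EC-EC contact energy -20, EC-Medium
#' 3, POS-POS -16; Stalk-Stalk spring 50, Vascular-Vascular 200).
#'
#' @param scenario A scenario row (from [scenario_by_id()] or
#'   [enumerate_scenarios()]), or a scenario id.
#' @return List with `J_overrides` (named list of contact energies for
#'   RPE-RPE, RPE-BrM, RPE-POS and RPE-PIS) and `spring_overrides`
#'   (stiffness for RPE-RPE and RPE-BrM).
#' @export
scenario_parameters <- function(scenario) {
  if (is.numeric(scenario) && length(scenario) == 1)
    scenario <- scenario_by_id(scenario)
  validate_levels(scenario$RRl, scenario$RRp, scenario$RBl,
                  scenario$RBp, scenario$ROl)
  ll <- labile_levels(); pl <- plastic_levels()
  list(
    J_overrides = list(
      RPE_RPE = unname(ll$RRl[as.character(scenario$RRl)]),
      RPE_BrM = unname(ll$RBl[as.character(scenario$RBl)]),
      RPE_POS = unname(ll$ROl[as.character(scenario$ROl)]),
      RPE_PIS = unname(ll$ROl[as.character(scenario$ROl)])),
    spring_overrides = list(
      RPE_RPE = unname(pl[as.character(scenario$RRp)]),
      RPE_BrM = unname(pl[as.character(scenario$RBp)]))
  )
}

#' Baseline contact-energy table
#'
#' The labile-adhesion contact energies between cell types at normal
#' adhesion.  All three endothelial types (Vascular, Stalk, Tip) share
#' the endothelial row.  More negative means stronger adhesion;
#' cell-Medium contact is mildly repulsive.
#'
#' @param scenario Optional scenario (id or row); its level overrides are
#'   applied to the RPE-RPE, RPE-BrM and RPE-POS/PIS entries.
#' @return 8 x 8 symmetric matrix indexed by the [cell_types()] order.
#' @export
contact_energy_table <- function(scenario = NULL) {
  tn <- names(cell_types())
  J <- matrix(0, 8, 8, dimnames = list(tn, tn))
  setJ <- function(a, b, v) {
    J[a, b] <<- v; J[b, a] <<- v
  }
  ec <- c("Vascular", "Stalk", "Tip")
  for (a in ec) for (b in ec) J[a, b] <- -20
  for (a in ec) {
    setJ(a, "BrM", -10); setJ(a, "RPE", -10)
    setJ(a, "POS", -10); setJ(a, "PIS", -10)
    setJ(a, "Medium", 3)
  }
  setJ("BrM", "BrM", -12)
  setJ("BrM", "RPE", -38)
  setJ("BrM", "POS", 0); setJ("BrM", "PIS", 0)
  setJ("BrM", "Medium", -1)
  setJ("RPE", "RPE", -40)
  setJ("RPE", "POS", -16); setJ("RPE", "PIS", -16)
  setJ("RPE", "Medium", 3)
  setJ("POS", "POS", -16); setJ("POS", "PIS", -16)
  setJ("POS", "Medium", 3)
  setJ("PIS", "PIS", -16); setJ("PIS", "Medium", 3)
  J["Medium", "Medium"] <- 0
  if (!is.null(scenario)) {
    ov <- scenario_parameters(scenario)$J_overrides
    setJ("RPE", "RPE", ov$RPE_RPE)
    setJ("RPE", "BrM", ov$RPE_BrM)
    setJ("RPE", "POS", ov$RPE_POS)
    setJ("RPE", "PIS", ov$RPE_PIS)
  }
  J
}

#' Spring-stiffness table for a scenario
#'
#' @param scenario Optional scenario (id or row).
#' @return Data frame of junctional type pairs and stiffnesses (see
#'   Table of plastic couplings), with scenario overrides applied to the
#'   RPE-RPE and RPE-BrM rows.
#' @export
spring_lambda_table <- function(scenario = NULL) {
  tab <- default_spring_lambda()
  if (!is.null(scenario)) {
    ov <- scenario_parameters(scenario)$spring_overrides
    tab$lambda[tab$type_a == "RPE" & tab$type_b == "RPE"] <- ov$RPE_RPE
    tab$lambda[tab$type_a == "RPE" & tab$type_b == "BrM"] <- ov$RPE_BrM
  }
  tab
}

#' Clinical condition presets
#'
#' Maps pathological conditions and experimental injuries to the
#' adhesion-level constraints they impose and the CNV outcome classes
#' simulations produce under those constraints.  Level constraints are
#' given as allowed level sets per parameter.
#'
#' @return Named list of presets, each with `levels` (named list of
#'   allowed level vectors) and `expected` (character vector of expected
#'   outcome classes, or "none" for no initiation).
#' @export
condition_presets <- function() {
  all3 <- c(3L, 2L, 1L)
  list(
    "Normal Aging (No Drusen)" = list(
      levels = list(RRl = 3L, RRp = 3L, RBl = 3L, RBp = 3L, ROl = 3L),
      expected = "none"),
    "Hard Drusen" = list(
      levels = list(RRl = c(3L, 1L), RRp = c(3L, 2L), RBl = c(3L, 2L),
                    RBp = c(3L, 2L), ROl = 3L),
      expected = "none"),
    "Soft Drusen" = list(
      levels = list(RRl = c(3L, 1L), RRp = c(3L, 2L), RBl = c(2L, 1L),
                    RBp = c(2L, 1L), ROl = c(3L, 1L)),
      expected = c("S11", "T12", "P13")),
    "Sub-Retinal Drusenoid" = list(
      levels = list(RRl = 1L, RRp = c(2L, 1L), RBl = all3, RBp = all3,
                    ROl = 1L),
      expected = c("T12", "S22", "P23")),
    "Active Inflammation" = list(
      levels = list(RRl = 1L, RRp = c(2L, 1L), RBl = 3L, RBp = 3L,
                    ROl = c(3L, 1L)),
      expected = "S22"),
    "Retinal Detachment" = list(
      levels = list(RRl = 1L, RRp = 1L, RBl = 3L, RBp = 3L, ROl = 1L),
      expected = "S22"),
    "High Fat Diet" = list(
      levels = list(RRl = c(3L, 1L), RRp = c(3L, 2L), RBl = c(2L, 1L),
                    RBp = c(2L, 1L), ROl = 3L),
      expected = "ET1"),
    "Chemotoxicity" = list(
      levels = list(RRl = 1L, RRp = 1L, RBl = c(2L, 1L), RBp = c(2L, 1L),
                    ROl = 1L),
      expected = "P23"),
    "Sub-Retinal Injection" = list(
      levels = list(RRl = 1L, RRp = c(2L, 1L), RBl = c(3L, 2L),
                    RBp = c(3L, 2L), ROl = 1L),
      expected = c("S22", "P23")),
    "Sub-Retinal Injection + VEGF Overexpression" = list(
      levels = list(RRl = 1L, RRp = c(2L, 1L), RBl = c(3L, 2L),
                    RBp = c(3L, 2L), ROl = 1L),
      expected = c("S22", "P23"))
  )
}

#' Look up one condition preset
#'
#' @param condition Condition name (see [condition_presets()]).
#' @return The preset list.
#' @export
condition_preset <- function(condition) {
  p <- condition_presets()
  if (!condition %in% names(p))
    stop("unknown condition: ", condition, "; known: ",
         paste(names(p), collapse = "; "))
  p[[condition]]
}

#' Write / read the scenario table as CSV
#'
#' @param path File path.
#' @return `write_scenarios` returns the path invisibly; `read_scenarios`
#'   the scenario data frame.
#' @export
write_scenarios <- function(path) {
  utils::write.csv(enumerate_scenarios(), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(identical(names(out), c("id", "RRl", "RRp", "RBl", "RBp",
                                    "ROl")))
  out
}
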
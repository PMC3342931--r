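# Replica management over adhesion scenarios and the response-surface
# regression analysis (CNV initiation probability, mean morphometric
# weight and dynamics-class occurrence vs the five adhesion levels).

#' Derive a replica seed
#'
#' One deterministic RNG stream per replica, derived from the base seed,
#' the scenario id and the replica index (kept below 2^31).
#'
#' @param base_seed Integer base seed.
#' @param scenario_id Scenario id.
#' @param replica Replica index (1-based).
#' @return An integer seed.
#' @export
replica_seed <- function(base_seed, scenario_id, replica) {
  as.integer((as.numeric(base_seed) %% 1e6 * 2099 +
                scenario_id * 2111 + replica * 101) %% 2147483647)
}

#' Run simulation replicas of one adhesion scenario
#'
#' Executes `n` independent replicas (each with its own seed and, unless
#' `no_tip`, a single seeded tip cell) and classifies each record
#' stream.
#'
#' @param scenario Scenario id or row.
#' @param n Number of replicas.
#' @param seeds Integer seeds, one per replica.
#' @param months Simulated duration per replica (months of 730 h).
#' @param lateral_um Lateral domain size (48 for the mini preset, 120
#'   for the full reference domain).
#' @param no_tip If `TRUE`, run the tip-free control protocol.
#' @param engine Engine parameters; defaults to the preset matching the
#'   domain size (`"mini"` for 48 um, `"full"` otherwise).
#' @param progress Print one line per finished replica.
#' @return A `scenario_outcome` list: `scenario`, `replicas` (per-replica
#'   classification data frame), `p_init`, `mean_mw`,
#'   `dynamics_freq`.
#' @export
run_replicas <- function(scenario, n = 10,
                         seeds = NULL, months = 1, lateral_um = 48,
                         no_tip = FALSE, engine = NULL,
                         progress = FALSE) {
  stopifnot(n >= 1)
  if (is.numeric(scenario) && length(scenario) == 1)
    scenario <- scenario_by_id(scenario)
  if (is.null(seeds))
    seeds <- vapply(seq_len(n), function(r)
      replica_seed(1L, scenario$id, r), integer(1))
  stopifnot(length(seeds) == n, !anyDuplicated(seeds))
  if (is.null(engine))
    engine <- default_engine(if (lateral_um <= 48) "mini" else "full")
  geom <- retinal_geometry(lateral_um = lateral_um)
  # the initial scene is deterministic: build once, reuse per replica
  st0 <- build_retina(geom, scenario = scenario, engine = engine)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    res <- tryCatch({
      set.seed(seeds[r])
      st <- st0
      if (!no_tip) st <- seed_tip_cell(st)
      sim <- simulate_cnv(st, months = months)
      cl <- classify_records(sim$records)
      cbind(data.frame(replica = r, seed = seeds[r], failed = FALSE), cl)
    }, error = function(e) {
      warning("replica ", r, " failed: ", conditionMessage(e))
      data.frame(replica = r, seed = seeds[r], failed = TRUE,
                 onset = NA_real_, early_mw = NA_real_,
                 late_mw = NA_real_, early_type = NA_character_,
                 late_type = NA_character_, dynamics = NA_character_,
                 initiated = NA, mean_mw = NA_real_)
    })
    rows[[r]] <- res
    if (progress)
      cat(sprintf("scenario %d replica %d: initiated=%s dynamics=%s\n",
                  scenario$id, r, res$initiated, res$dynamics))
  }
  reps <- do.call(rbind, rows)
  ok <- !reps$failed
  dyn <- table(factor(reps$dynamics[ok],
                      levels = c("S11", "T12", "P13", "T21", "S22",
                                 "P23", "T31", "T32", "S33")))
  out <- list(scenario = scenario, replicas = reps,
              p_init = mean(reps$initiated[ok]),
              mean_mw = mean(reps$mean_mw[ok], na.rm = TRUE),
              dynamics_freq = dyn / max(1, sum(ok)))
  class(out) <- "scenario_outcome"
  out
}

#' @export
print.scenario_outcome <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("Scenario %d (RRl=%d RRp=%d RBl=%d RBp=%d ROl=%d)\n",
              s$id, s$RRl, s$RRp, s$RBl, s$RBp, s$ROl))
  cat(sprintf("  replicas: %d   P(init) = %.2f   mean MW = %s\n",
              nrow(x$replicas), x$p_init,
              formatC(x$mean_mw, digits = 3, format = "f")))
  dom <- x$dynamics_freq[x$dynamics_freq > 0]
  if (length(dom))
    cat("  dynamics:", paste(names(dom), round(dom, 2), sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Response-surface regression over the adhesion factorial
#'
#' Ordinary least squares of a per-scenario response on the five
#' adhesion levels (entered numerically, 1-3) plus all ten pairwise
#' products and an intercept.
#'
#' @param design Data frame with columns `RRl`, `RRp`, `RBl`, `RBp`,
#'   `ROl` (one row per scenario).
#' @param response Numeric response, one value per design row.
#' @param include_interactions Include the pairwise products (default
#'   TRUE).
#' @return An `adhesion_regression` object wrapping the `lm` fit, with
#'   `r_squared` and `adj_r_squared`.
#' @export
fit_regression <- function(design, response, include_interactions = TRUE) {
  vars <- c("RRl", "RRp", "RBl", "RBp", "ROl")
  stopifnot(all(vars %in% names(design)),
            length(response) == nrow(design))
  dat <- cbind(design[vars], .y = response)
  form <- if (include_interactions)
    stats::as.formula(".y ~ (RRl + RRp + RBl + RBp + ROl)^2")
  else stats::as.formula(".y ~ RRl + RRp + RBl + RBp + ROl")
  fit <- stats::lm(form, data = dat)
  qrr <- fit$qr
  if (qrr$rank < length(stats::coef(fit)))
    warning("rank-deficient design: ",
            length(stats::coef(fit)) - qrr$rank,
            " coefficient(s) not estimable")
  sm <- summary(fit)
  r2 <- sm$r.squared
  ar2 <- sm$adj.r.squared
  if (stats::var(response) == 0) r2 <- ar2 <- 0  # constant response
  out <- list(fit = fit, r_squared = r2,
              adj_r_squared = ar2,
              coefficients = stats::coef(fit))
  class(out) <- "adhesion_regression"
  out
}

#' @export
print.adhesion_regression <- function(x, ...) {
  cat(sprintf("Adhesion response surface: R^2 = %.3f (adjusted %.3f)\n",
              x$r_squared, x$adj_r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from an adhesion regression
#'
#' @param object An `adhesion_regression`.
#' @param newdata Data frame with the five level columns.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.adhesion_regression <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Evaluate the fitted surface on the symmetric 3D reduction
#'
#' Reduces the five-parameter surface to three dimensions by the
#' symmetric constraint `RRp = RRl` and `RBp = RBl` and tabulates the
#' fitted response on a grid over (RR, RB, RO), the form used for
#' isosurface-style reporting.
#'
#' @param result An `adhesion_regression`.
#' @param grid Number of grid points per axis over `[1, 3]`, or a
#'   numeric vector of level values.
#' @return Data frame with columns `RR`, `RB`, `RO`, `fitted`.
#' @export
project_symmetric <- function(result, grid = 9) {
  g <- if (length(grid) == 1) seq(1, 3, length.out = grid) else grid
  tab <- expand.grid(RR = g, RB = g, RO = g)
  nd <- data.frame(RRl = tab$RR, RRp = tab$RR, RBl = tab$RB,
                   RBp = tab$RB, ROl = tab$RO)
  tab$fitted <- predict(result, nd)
  tab
}

#' Run a scenario sweep
#'
#' Replica batches over a set of scenarios, with aggregate table and
#' optional regressions of initiation probability and mean morphometric
#' weight on the adhesion levels.
#'
#' @param scenario_ids Scenario ids to run.
#' @param replicas Replicas per scenario.
#' @param months,lateral_um Passed to [run_replicas()].
#' @param base_seed Base seed for [replica_seed()].
#' @param progress Print progress lines.
#' @return List with `outcomes` (per-scenario list), `summary` (data
#'   frame), and `regressions` (fits for `p_init` and `mean_mw` when 3+
#'   scenarios were run).
#' @export
run_sweep <- function(scenario_ids, replicas = 10, months = 1,
                      lateral_um = 48, base_seed = 1, progress = FALSE) {
  outcomes <- lapply(scenario_ids, function(id) {
    seeds <- vapply(seq_len(replicas), function(r)
      replica_seed(base_seed, id, r), integer(1))
    run_replicas(id, n = replicas, seeds = seeds, months = months,
                 lateral_um = lateral_um, progress = progress)
  })
  summ <- do.call(rbind, lapply(outcomes, function(o)
    cbind(o$scenario, data.frame(p_init = o$p_init,
                                 mean_mw = o$mean_mw))))
  regressions <- NULL
  if (length(scenario_ids) >= 3) {
    regressions <- list(
      p_init = fit_regression(summ, summ$p_init,
                              include_interactions =
                                length(scenario_ids) > 20),
      mean_mw = if (all(is.finite(summ$mean_mw)))
        fit_regression(summ, summ$mean_mw,
                       include_interactions =
                         length(scenario_ids) > 20) else NULL)
  }
  list(outcomes = outcomes, summary = summ, regressions = regressions)
}
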
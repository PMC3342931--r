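# Reaction-diffusion fields: oxygen (mmHg), RPE-derived VEGF-A,
# short-diffusing VEGF-A and MMP (molecules/voxel).  Fields share the cell
# lattice's resolution; secretion is deposited uniformly over a secreting
# cell's voxels.  The two VEGF-A pools share a decay rate and differ only
# in diffusion length (50 um vs 10 um, a 25-fold ratio of diffusion
# constants); MMP is nearly immobile (diffusion length under one voxel).

#' Default field kinetic parameters
#'
#' Diffusion constants (um^2/s), first-order decay rates (1/s) and
#' secretion/uptake rates by cell type for the four fields.  Only the
#' VEGF diffusion-length ratio is constrained by the biology (long/short
#' = 5, i.e. a 25-fold ratio of diffusion constants at equal decay);
#' absolute magnitudes are set for solver stability at 2-um voxels and
#' are normalized out by the calibration of thresholds and growth rates
#' against the intact-retina steady state.
#'
#' @return Named list of per-field parameter lists.
#' @export
field_params <- function() {
  list(
    rpe_vegf = list(D = 2.5, k = 1e-3,
                    secrete = c(RPE = 1e-3),
                    uptake = c(Vascular = 2e-4, Stalk = 2e-4, Tip = 2e-4)),
    short_vegf = list(D = 0.1, k = 1e-3,
                      secrete = c(Vascular = 1e-3, Stalk = 1e-3,
                                  Tip = 1e-3),
                      uptake = c()),
    mmp = list(D = 2e-3, k = 1e-3, secrete = c(Tip = 1e-3), uptake = c()),
    oxygen = list(D = 2000, k = 0, secrete = c(), uptake = c())
  )
}

# per-voxel first-order loss and constant source for a named field
field_sources <- function(state, name, params = field_params()[[name]]) {
  typ <- array(0L, dim = state$dims)
  occ <- state$site > 0L
  typ[occ] <- state$cell_type[state$site[occ]]
  kloc <- array(params$k, dim = state$dims)
  src <- array(0, dim = state$dims)
  ct <- cell_types()
  for (ty in names(params$secrete))
    src[typ == ct[[ty]]] <- src[typ == ct[[ty]]] + params$secrete[[ty]]
  for (ty in names(params$uptake))
    kloc[typ == ct[[ty]]] <- kloc[typ == ct[[ty]]] + params$uptake[[ty]]
  list(kloc = kloc, src = src)
}

#' One explicit diffusion-decay-secretion step
#'
#' Advances one field by forward-Euler finite differences: secretion by
#' the secreting cell types, first-order uptake and decay, diffusion, and
#' clamping of Dirichlet faces.  Refuses a time step violating the
#' explicit stability bound `dt <= h^2 / (6 D)`.
#'
#' @param field 3D array of concentrations.
#' @param state The `cpm_state` supplying the cell lattice.
#' @param name Field name in [field_params()].
#' @param dt Time step (seconds).
#' @param params Kinetic parameter list (defaults per field name).
#' @param dirichlet Length-2 numeric, clamped values at the bottom/top z
#'   faces (`NA` = zero-flux).
#' @return The stepped field (non-negative everywhere).
#' @export
step_field <- function(field, state, name, dt,
                       params = field_params()[[name]],
                       dirichlet = c(NA, NA)) {
  h <- state$voxel_size
  if (params$D > 0 && dt > h^2 / (6 * params$D))
    stop(sprintf("unstable dt = %g; explicit bound is dt <= %g",
                 dt, h^2 / (6 * params$D)))
  ks <- field_sources(state, name, params)
  out <- .step_field_cpp(as.numeric(field), state$dims, params$D, dt, h,
                         as.numeric(ks$kloc), as.numeric(ks$src),
                         dirichlet[1], dirichlet[2])
  array(out, dim = state$dims)
}

#' Steady state of a field
#'
#' Solves `D lap(c) - k_loc c + s = 0` by successive over-relaxation with
#' the lattice's boundary conditions (periodic x/y; Dirichlet or
#' zero-flux z faces).
#'
#' @inheritParams step_field
#' @param init Optional initial guess (3D array).
#' @param extra_src Optional 3D array added to the constant source term
#'   (negative entries model zero-order consumption).
#' @param tol,max_iter Convergence controls.
#' @return The steady field as a 3D array.
#' @export
steady_field <- function(state, name, params = field_params()[[name]],
                         dirichlet = c(NA, NA), init = NULL,
                         extra_src = NULL, tol = 1e-8, max_iter = 5000) {
  ks <- field_sources(state, name, params)
  src <- ks$src
  if (!is.null(extra_src)) src <- src + extra_src
  if (is.null(init)) init <- array(0, dim = state$dims)
  res <- .steady_field_cpp(as.numeric(init), state$dims, params$D,
                           state$voxel_size, as.numeric(ks$kloc),
                           as.numeric(src), dirichlet[1], dirichlet[2],
                           tol, as.integer(max_iter))
  out <- array(res$field, dim = state$dims)
  if (min(out) < -1e-9)
    warning("steady field has negative values: non-physical parameterization")
  out
}

#' Degrade Bruch's membrane by the MMP field
#'
#' Each frozen BrM voxel converts to Medium with probability
#' `min(1, rate * c_MMP * dt)`; BrM block volume ledgers are updated.
#'
#' @param state A `cpm_state`.
#' @param mmp 3D array of MMP concentration.
#' @param rate Degradation rate constant (1 / (concentration * s)).
#' @param dt Time step (seconds).
#' @return List with the updated `state` and `removed` (voxel count).
#' @export
degrade_brm <- function(state, mmp, rate, dt) {
  stopifnot(rate >= 0)
  hit <- .degrade_brm_cpp(as.integer(state$site), state$cell_type,
                          as.numeric(mmp), rate, dt)
  if (length(hit)) {
    ids <- state$site[hit]
    state$site[hit] <- 0L
    cnt <- table(ids)
    idx <- as.integer(names(cnt))
    state$volume[idx] <- state$volume[idx] - as.integer(cnt)
    state$target_volume[idx] <- pmin(state$target_volume[idx],
                                     state$volume[idx])
    state$alive[idx[state$volume[idx] == 0L]] <- FALSE
  }
  list(state = state, removed = length(hit))
}

# ---- 1D oxygen profile across the outer retina ------------------------

#' Layered geometry for the 1D oxygen profile
#'
#' Depths are measured from the choriocapillaris face of Bruch's
#' membrane.  Defaults: BrM 6 um, RPE 12 um, POS 30 um, PIS 24 um, outer
#' limiting membrane 67 um from the RPE side of BrM.
#'
#' @param L_BrM,L_RPE,L_OS,L_IS Layer thicknesses (um).
#' @param L_OLM Distance of the OLM from the RPE side of BrM (um).
#' @param P_cc,P_olm Oxygen tension (mmHg) clamped at the CC face and the
#'   OLM.
#' @param Q_pis Uniform volumetric consumption in the PIS layer, expressed
#'   as mmHg/um^2 (consumption rate over diffusivity).
#' @return An `oxygen_geometry` list.
#' @export
oxygen_geometry <- function(L_BrM = 6, L_RPE = 12, L_OS = 30, L_IS = 24,
                            L_OLM = 67, P_cc = 80, P_olm = 20,
                            Q_pis = 0) {
  stopifnot(L_BrM > 0, L_RPE > 0, L_OS > 0, L_IS > 0, L_OLM > 0)
  if (abs((L_RPE + L_OS + L_IS) - L_OLM) > 0.1 * L_OLM)
    stop("layer thicknesses inconsistent with the OLM location")
  g <- list(L_BrM = L_BrM, L_RPE = L_RPE, L_OS = L_OS, L_IS = L_IS,
            L_OLM = L_OLM, P_cc = P_cc, P_olm = P_olm, Q_pis = Q_pis)
  class(g) <- "oxygen_geometry"
  g
}

#' Steady-state 1D oxygen profile
#'
#' Closed-form piecewise profile with Dirichlet ends (`P_cc` at the CC
#' face of BrM, `P_olm` at the OLM): linear through BrM, RPE and POS
#' (no consumption; RPE oxygen uptake is negligible), quadratic through
#' the uniformly consuming PIS, flux-continuous at every interface.
#'
#' @param geom An [oxygen_geometry()].
#' @param x Depths (um from the CC face) at which to evaluate; defaults
#'   to a fine grid over the whole span.
#' @return A data frame with columns `depth_um` and `po2_mmhg`, with
#'   attribute `p_rpe` = the tension at the RPE-POS interface ("PO2 at
#'   the RPE").
#' @export
oxygen_profile_1d <- function(geom, x = NULL) {
  L <- geom$L_BrM + geom$L_OLM            # full span, CC face to OLM
  a <- geom$L_BrM + geom$L_RPE + geom$L_OS  # PIS start
  b <- a + geom$L_IS                        # PIS end
  q <- geom$Q_pis
  # P(L) = P_cc + s0 L + q [ (b-a)^2/2 + (b-a)(L-b) ]  =>  solve for s0
  cc <- (b - a)^2 / 2 + (b - a) * (L - b)
  s0 <- (geom$P_olm - geom$P_cc - q * cc) / L
  if (is.null(x)) x <- seq(0, L, length.out = 512)
  p <- ifelse(x <= a,
              geom$P_cc + s0 * x,
              ifelse(x <= b,
                     geom$P_cc + s0 * x + q * (x - a)^2 / 2,
                     geom$P_cc + s0 * x + q * ((b - a)^2 / 2 +
                                                 (b - a) * (x - b))))
  if (min(p) < 0)
    warning("non-physical parameterization: negative oxygen tension")
  out <- data.frame(depth_um = x, po2_mmhg = p)
  x_rpe <- geom$L_BrM + geom$L_RPE
  attr(out, "p_rpe") <- geom$P_cc + s0 * x_rpe +
    if (x_rpe > a) q * (x_rpe - a)^2 / 2 else 0
  out
}

#' Oxygen tension at the RPE
#'
#' @param geom An [oxygen_geometry()].
#' @return PO2 (mmHg) at the RPE-POS interface.
#' @export
p_rpe <- function(geom) attr(oxygen_profile_1d(geom, x = 0), "p_rpe")

#' Calibrate photoreceptor inner-segment oxygen consumption
#'
#' Inverts [oxygen_profile_1d()]: finds the uniform PIS consumption for
#' which the steady profile passes through `target_p_rpe` at the RPE-POS
#' interface.  The tension there decreases strictly with consumption, so
#' the inverse is unique when it exists.
#'
#' @param geom An [oxygen_geometry()] (its `Q_pis` is ignored).
#' @param target_p_rpe Desired PO2 (mmHg) at the RPE-POS interface.
#' @return The consumption `Q_pis` (mmHg/um^2).
#' @export
calibrate_pis_uptake <- function(geom, target_p_rpe) {
  g0 <- geom; g0$Q_pis <- 0
  p0 <- p_rpe(g0)
  if (target_p_rpe > p0 + 1e-12)
    stop(sprintf(paste0("target %.3f mmHg unattainable: the consumption-",
                        "free profile already gives %.3f mmHg"),
                 target_p_rpe, p0))
  if (abs(target_p_rpe - p0) <= 1e-12) return(0)
  # p_rpe is linear in Q: p(Q) = p0 - m Q
  g1 <- geom; g1$Q_pis <- 1
  m <- p0 - p_rpe(g1)
  q <- (p0 - target_p_rpe) / m
  if (q < 0) stop("unattainable target")
  q
}
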
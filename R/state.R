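# Core lattice state for the retinal Cellular Potts model.
#
# A `cpm_state` is a plain list: a 3D integer lattice mapping voxels to
# generalized-cell ids (0 = Medium) plus per-cell ledgers (type, volume,
# target volume, center of mass, frozen/alive flags), the contact-energy
# table, breakable-spring links, chemotaxis couplings and the chemical
# fields.  Boundary conditions are periodic in x and y and fixed planes in
# z (choroidal base below, outer limiting membrane above).

#' Cell type codes
#'
#' Integer codes for the generalized-cell types of the retinal model:
#' Medium (0), Vascular (choriocapillaris endothelium), Stalk, Tip, RPE,
#' POS and PIS photoreceptor segments, and BrM (frozen Bruch's membrane
#' blocks).
#'
#' @return Named integer vector of type codes.
#' @export
cell_types <- function() {
  c(Medium = 0L, Vascular = 1L, Stalk = 2L, Tip = 3L,
    RPE = 4L, POS = 5L, PIS = 6L, BrM = 7L)
}

type_name <- function(code) names(cell_types())[match(code, cell_types())]
is_ec_type <- function(code) code %in% c(1L, 2L, 3L)

#' Create an empty simulation state
#'
#' @param dims Integer triple: lattice size in voxels (x, y, z).
#' @param voxel_size Edge length of a voxel in micrometres.
#' @param temperature Metropolis fluctuation amplitude (contact-energy
#'   units).
#' @param lambda_vol Volume-constraint stiffness (energy per voxel^2).
#' @param mcs_per_hour Monte Carlo steps per simulated hour.
#' @param J 8 x 8 contact-energy matrix indexed by type code + 1 (see
#'   [cell_types()]); more negative means stronger adhesion.
#' @param break_factor A spring breaks when its length exceeds
#'   `break_factor * rest_length`.
#' @param spring_scale Global multiplier applied to all tabulated spring
#'   stiffnesses (units conversion; the tabulated gradings keep their
#'   ratios).
#' @return A `cpm_state` object.
#' @export
new_cpm_state <- function(dims, voxel_size = 2,
                          temperature = 20, lambda_vol = 5,
                          mcs_per_hour = 60,
                          J = matrix(0, 8, 8), break_factor = 2,
                          spring_scale = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), temperature > 0,
            mcs_per_hour > 0)
  tn <- names(cell_types())
  dimnames(J) <- list(tn, tn)
  st <- list(
    dims = dims, voxel_size = voxel_size,
    site = array(0L, dim = dims),
    cell_type = integer(0), volume = integer(0),
    target_volume = numeric(0),
    comx = numeric(0), comy = numeric(0), comz = numeric(0),
    frozen = logical(0), alive = logical(0), birth_time = numeric(0),
    dying = logical(0), death_start = numeric(0),
    death_rate = numeric(0),
    starved_since = numeric(0), isolated_since = numeric(0),
    J = J, temperature = temperature, lambda_vol = lambda_vol,
    mcs_per_hour = mcs_per_hour,
    link_a = integer(0), link_b = integer(0), link_lambda = numeric(0),
    link_rest = numeric(0), link_active = logical(0),
    link_last_contact = numeric(0), link_broken = logical(0),
    break_factor = break_factor, spring_scale = spring_scale,
    lambda_chem = matrix(0, 8, 2,
                         dimnames = list(tn, c("rpe_vegf", "short_vegf"))),
    chem_fields = list(rpe_vegf = array(0, dims),
                       short_vegf = array(0, dims)),
    fields = list(),          # full field set incl. oxygen and mmp
    clock = 0,
    events = data.frame(time = numeric(0), cell = integer(0),
                        type = character(0), detail = character(0),
                        stringsAsFactors = FALSE),
    params = list(link_formation_area = 8, link_persistence = 6,
                  spring_lambda = default_spring_lambda())
  )
  class(st) <- "cpm_state"
  st
}

# Baseline plastic-coupling strengths by type pair (scenario levels
# override the RPE-RPE and RPE-BrM entries).
default_spring_lambda <- function() {
  data.frame(
    type_a = c("RPE", "RPE", "POS", "PIS", "PIS", "Vascular", "Stalk",
               "Tip", "Stalk", "Stalk", "Vascular", "Stalk", "Tip"),
    type_b = c("RPE", "BrM", "POS", "PIS", "POS", "Vascular", "Vascular",
               "Vascular", "Stalk", "Tip", "BrM", "BrM", "BrM"),
    lambda = c(300, 300, 30, 30, 30, 200, 150, 50, 50, 50, 200, 25, 25),
    stringsAsFactors = FALSE)
}

#' Add a generalized cell to a state
#'
#' Claims a set of voxels for a new cell id and initializes its ledgers.
#'
#' @param state A `cpm_state`.
#' @param voxels Integer matrix (n x 3) of 1-based voxel indices, or a
#'   3-column data frame.
#' @param type Cell type name (see [cell_types()]).
#' @param target_volume Target volume in voxels (defaults to the claimed
#'   volume).
#' @param frozen Logical; frozen cells never move (BrM blocks).
#' @return The updated state (the new cell id is `n_cells(state)`).
#' @export
add_cell <- function(state, voxels, type, target_volume = NULL,
                     frozen = FALSE) {
  voxels <- as.matrix(voxels)
  storage.mode(voxels) <- "integer"
  stopifnot(ncol(voxels) == 3, nrow(voxels) >= 1)
  code <- cell_types()[[type]]
  id <- length(state$cell_type) + 1L
  occ <- state$site[voxels]
  if (any(occ != 0L))
    stop("voxels already claimed by cell(s) ", paste(unique(occ[occ != 0]),
                                                     collapse = ", "))
  state$site[voxels] <- id
  state$cell_type <- c(state$cell_type, code)
  state$volume <- c(state$volume, nrow(voxels))
  state$target_volume <- c(state$target_volume,
                           if (is.null(target_volume)) nrow(voxels)
                           else target_volume)
  com <- com_recount_one(voxels, state$dims)
  state$comx <- c(state$comx, com[1])
  state$comy <- c(state$comy, com[2])
  state$comz <- c(state$comz, com[3])
  state$frozen <- c(state$frozen, frozen)
  state$alive <- c(state$alive, TRUE)
  state$birth_time <- c(state$birth_time, state$clock)
  state$dying <- c(state$dying, FALSE)
  state$death_start <- c(state$death_start, NA_real_)
  state$death_rate <- c(state$death_rate, NA_real_)
  state$starved_since <- c(state$starved_since, NA_real_)
  state$isolated_since <- c(state$isolated_since, NA_real_)
  state
}

n_cells <- function(state) length(state$cell_type)

# brute-force COM of a voxel set (voxel-center coordinates, periodic x/y
# images taken nearest the first voxel)
com_recount_one <- function(voxels, dims) {
  ctr <- voxels - 0.5
  ref <- ctr[1, ]
  for (ax in 1:2) {
    L <- dims[ax]
    d <- ctr[, ax] - ref[ax]
    ctr[, ax] <- ctr[, ax] - L * round(d / L)
  }
  com <- colMeans(ctr)
  for (ax in 1:2) com[ax] <- com[ax] %% dims[ax]
  com
}

#' Recount centers of mass from the lattice
#'
#' Brute-force audit of the incrementally maintained centers of mass.
#'
#' @param state A `cpm_state`.
#' @return Matrix (cells x 3) of COM coordinates in voxel units.
#' @export
com_recount <- function(state) {
  out <- matrix(NA_real_, n_cells(state), 3)
  for (id in seq_len(n_cells(state))) {
    if (state$volume[id] == 0) next
    vox <- which(state$site == id, arr.ind = TRUE)
    out[id, ] <- com_recount_one(vox, state$dims)
  }
  out
}

check_state <- function(state) {
  vol <- tabulate(state$site[state$site > 0L], nbins = n_cells(state))
  if (!identical(as.integer(vol), as.integer(state$volume)))
    stop("volume ledger inconsistent with lattice")
  invisible(TRUE)
}

# ---- total energy (brute-force oracle) --------------------------------

#' Total effective energy of a state
#'
#' Brute-force sum of the contact term over unlike-cell neighbor pairs in
#' the 26-neighborhood (unit weights), the quadratic volume constraint and
#' the spring energy of active links.  Serves as the oracle against which
#' the incremental `delta_energy` bookkeeping is audited.
#'
#' @param state A `cpm_state` with consistent ledgers.
#' @return Total energy (scalar).
#' @export
total_energy <- function(state) {
  check_state(state)
  e <- contact_energy_brute(state) + volume_energy(state) +
    spring_energy(state)
  e
}

contact_energy_brute <- function(state) {
  d <- state$dims
  site <- state$site
  typ <- function(m) {
    out <- array(0L, dim = dim(m))
    out[m > 0L] <- state$cell_type[m[m > 0L]]
    out
  }
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  # forward half so each unordered pair counts once
  keep <- off$dz > 0 | (off$dz == 0 & (off$dy > 0 | (off$dy == 0 & off$dx > 0)))
  off <- off[keep, ]
  e <- 0
  shift_idx <- function(n, k) ((seq_len(n) - 1 + k) %% n) + 1
  for (r in seq_len(nrow(off))) {
    sx <- shift_idx(d[1], off$dx[r]); sy <- shift_idx(d[2], off$dy[r])
    zmax <- d[3] - off$dz[r]
    if (zmax < 1) next
    z1 <- seq_len(zmax); z2 <- z1 + off$dz[r]
    a <- site[, , z1, drop = FALSE]
    b <- site[sx, sy, z2, drop = FALSE]
    unlike <- a != b
    if (!any(unlike)) next
    ta <- typ(a)[unlike]; tb <- typ(b)[unlike]
    e <- e + sum(state$J[cbind(ta + 1L, tb + 1L)])
  }
  e
}

volume_energy <- function(state) {
  use <- state$cell_type != 0L & !state$frozen & state$volume > 0
  sum(state$lambda_vol *
        (state$volume[use] - state$target_volume[use])^2)
}

spring_energy <- function(state) {
  if (!any(state$link_active)) return(0)
  k <- which(state$link_active)
  len <- link_lengths(state)[k]
  sum(0.5 * state$spring_scale * state$link_lambda[k] *
        (len - state$link_rest[k])^2)
}

link_lengths <- function(state) {
  if (length(state$link_a) == 0) return(numeric(0))
  a <- state$link_a; b <- state$link_b
  dx <- state$comx[a] - state$comx[b]
  dy <- state$comy[a] - state$comy[b]
  dz <- state$comz[a] - state$comz[b]
  L1 <- state$dims[1]; L2 <- state$dims[2]
  dx <- dx - L1 * round(dx / L1)
  dy <- dy - L2 * round(dy / L2)
  sqrt(dx^2 + dy^2 + dz^2)
}

# ---- engine wrappers ---------------------------------------------------

engine_list <- function(state) {
  list(dims = state$dims, site = state$site,
       cell_type = state$cell_type, volume = state$volume,
       target_volume = state$target_volume, frozen = state$frozen,
       comx = state$comx, comy = state$comy, comz = state$comz,
       J = state$J, lambda_vol = state$lambda_vol,
       temperature = state$temperature,
       link_a = state$link_a, link_b = state$link_b,
       link_lambda = state$link_lambda, link_rest = state$link_rest,
       link_active = state$link_active,
       break_factor = state$break_factor,
       spring_scale = state$spring_scale,
       lambda_chem = state$lambda_chem,
       chem_fields = state$chem_fields)
}

#' Energy change of one index-copy proposal
#'
#' Computes the change in effective energy of copying the cell id at
#' `source_voxel` onto `target_voxel` (lattice neighbors), summing the
#' contact, volume, spring and contact-inhibited chemotaxis
#' contributions, without modifying the state.
#'
#' @param state A `cpm_state`.
#' @param source_voxel,target_voxel Integer triples of 1-based voxel
#'   indices; must be neighbors in the 6-neighborhood.
#' @return The energy change (scalar).
#' @export
delta_energy <- function(state, source_voxel, target_voxel) {
  source_voxel <- as.integer(source_voxel)
  target_voxel <- as.integer(target_voxel)
  dd <- abs(source_voxel - target_voxel)
  for (ax in 1:2) dd[ax] <- min(dd[ax], state$dims[ax] - dd[ax])
  if (sum(dd) != 1L)
    stop("source and target must be 6-neighborhood lattice neighbors")
  tid <- state$site[matrix(target_voxel, 1)]
  if (tid > 0L && state$frozen[tid])
    stop("target voxel belongs to a frozen cell", call. = FALSE)
  .delta_energy_cpp(engine_list(state), source_voxel - 1L,
                    target_voxel - 1L)
}

#' Attempt a single Metropolis index copy
#'
#' Picks a random target voxel and a random copy-neighborhood source (or
#' uses the supplied `pair`) and accepts the copy with probability
#' `min(1, exp(-dH / temperature))`.
#'
#' @param state A `cpm_state`.
#' @param pair Optional list with elements `source` and `target` (1-based
#'   voxel triples) to probe a specific proposal.
#' @return List with `state` (updated on acceptance), `accepted`, and
#'   `delta` (NA for no-op / frozen proposals).
#' @export
attempt_index_copy <- function(state, pair = NULL) {
  d <- state$dims
  if (is.null(pair)) {
    tgt <- c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
    off6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    o <- off6[sample.int(6, 1), ]
    src <- tgt + o
    if (src[3] < 1 || src[3] > d[3])
      return(list(state = state, accepted = FALSE, delta = NA_real_))
    src[1] <- ((src[1] - 1) %% d[1]) + 1
    src[2] <- ((src[2] - 1) %% d[2]) + 1
  } else {
    src <- as.integer(pair$source); tgt <- as.integer(pair$target)
  }
  sid <- state$site[matrix(src, 1)]
  tid <- state$site[matrix(tgt, 1)]
  if (sid == tid)
    return(list(state = state, accepted = FALSE, delta = NA_real_))
  if ((sid > 0L && state$frozen[sid]) || (tid > 0L && state$frozen[tid]))
    return(list(state = state, accepted = FALSE, delta = NA_real_))
  dH <- .delta_energy_cpp(engine_list(state), src - 1L, tgt - 1L)
  acc <- dH <= 0 || stats::runif(1) < exp(-dH / state$temperature)
  if (acc) state <- apply_copy_r(state, src, tgt)
  list(state = state, accepted = acc, delta = dH)
}

# mirror of the C++ copy bookkeeping, used by the single-attempt probe
apply_copy_r <- function(state, src, tgt) {
  sid <- state$site[matrix(src, 1)]
  tid <- state$site[matrix(tgt, 1)]
  d <- state$dims
  xt <- tgt - 0.5
  near_image <- function(x, c0, L) {
    dd <- x - c0
    if (dd > L / 2) x - L else if (dd < -L / 2) x + L else x
  }
  state$site[matrix(tgt, 1)] <- sid
  if (sid > 0L) {
    v <- state$volume[sid]
    xi <- near_image(xt[1], state$comx[sid], d[1])
    yi <- near_image(xt[2], state$comy[sid], d[2])
    state$comx[sid] <- ((v * state$comx[sid] + xi) / (v + 1)) %% d[1]
    state$comy[sid] <- ((v * state$comy[sid] + yi) / (v + 1)) %% d[2]
    state$comz[sid] <- (v * state$comz[sid] + xt[3]) / (v + 1)
    state$volume[sid] <- v + 1L
  }
  if (tid > 0L) {
    v <- state$volume[tid]
    if (v > 1) {
      xi <- near_image(xt[1], state$comx[tid], d[1])
      yi <- near_image(xt[2], state$comy[tid], d[2])
      state$comx[tid] <- ((v * state$comx[tid] - xi) / (v - 1)) %% d[1]
      state$comy[tid] <- ((v * state$comy[tid] - yi) / (v - 1)) %% d[2]
      state$comz[tid] <- (v * state$comz[tid] - xt[3]) / (v - 1)
    }
    state$volume[tid] <- v - 1L
    if (state$volume[tid] == 0L) {
      drop <- state$link_a == tid | state$link_b == tid
      state$link_active[drop] <- FALSE
    }
  }
  len <- link_lengths(state)
  over <- state$link_active & len > state$break_factor * state$link_rest
  state$link_active[over] <- FALSE
  state$link_broken[over] <- TRUE
  state
}

#' Run Monte Carlo steps
#'
#' Performs `n_mcs` Monte Carlo steps; each step makes one copy attempt
#' per non-frozen voxel.  Advances the simulated clock by
#' `n_mcs / mcs_per_hour` hours.
#'
#' @param state A `cpm_state`.
#' @param n_mcs Number of Monte Carlo steps (>= 0).
#' @return List with the updated `state` and `stats` (attempts, accepted,
#'   acceptance rate).
#' @export
run_mcs <- function(state, n_mcs) {
  stopifnot(n_mcs >= 0)
  if (n_mcs == 0)
    return(list(state = state,
                stats = list(attempts = 0, accepted = 0,
                             acceptance_rate = NA_real_)))
  res <- .run_mcs_cpp(engine_list(state), as.integer(n_mcs))
  state$site <- array(res$site, dim = state$dims)
  state$volume <- res$volume
  state$comx <- res$comx; state$comy <- res$comy; state$comz <- res$comz
  newly_broken <- state$link_active & !res$link_active
  state$link_broken[newly_broken] <- TRUE
  state$link_active <- res$link_active
  state$alive[state$volume == 0L & state$cell_type != 0L &
                !state$frozen] <- FALSE
  state$clock <- state$clock + n_mcs / state$mcs_per_hour
  list(state = state,
       stats = list(attempts = res$attempts, accepted = res$accepted,
                    acceptance_rate = res$accepted / res$attempts))
}

#' Contact areas between cells
#'
#' Recounts pairwise contact areas from the lattice.  `order = 6` counts
#' voxel faces (used for morphometry and junction formation); `order = 26`
#' matches the contact-energy neighborhood.
#'
#' @param state A `cpm_state`.
#' @param order Neighborhood order, 6 or 26.
#' @return Data frame with columns `a`, `b` (cell ids, `a < b`, 0 =
#'   Medium) and `area`.
#' @export
contact_areas <- function(state, order = 6) {
  stopifnot(order %in% c(6, 26))
  .contact_areas_cpp(as.integer(state$site), state$dims, as.integer(order))
}

# contact area between two type groups, from a contact_areas() table
type_pair_area <- function(state, areas, types_a, types_b) {
  ca <- cell_types()
  ta <- ifelse(areas$a > 0, state$cell_type[pmax(areas$a, 1)], 0L)
  ta[areas$a == 0] <- 0L
  tb <- ifelse(areas$b > 0, state$cell_type[pmax(areas$b, 1)], 0L)
  tb[areas$b == 0] <- 0L
  codes_a <- ca[types_a]; codes_b <- ca[types_b]
  hit <- (ta %in% codes_a & tb %in% codes_b) |
    (tb %in% codes_a & ta %in% codes_b)
  sum(areas$area[hit])
}

#' Create and retire junctional springs
#'
#' Creates a breakable spring between every eligible junctional cell pair
#' whose voxel-face contact area reaches the formation threshold, with the
#' rest length set to the current center-of-mass separation.  Retires
#' springs whose pair has had no contact for the persistence window, and
#' forgets broken springs once their pair has separated so the pair may
#' re-junction on renewed contact.
#'
#' @param state A `cpm_state`.
#' @param areas Optional precomputed [contact_areas()] table (order 6).
#' @return The updated state.
#' @export
maintain_links <- function(state, areas = NULL) {
  if (is.null(areas)) areas <- contact_areas(state, order = 6)
  areas <- areas[areas$a > 0L & areas$b > 0L, , drop = FALSE]
  lam_tab <- state$params$spring_lambda
  ca <- cell_types()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  existing <- key(state$link_a, state$link_b)
  now <- state$clock

  # refresh last-contact clock for linked pairs still touching
  touch <- key(areas$a, areas$b)
  state$link_last_contact[existing %in% touch] <- now

  # retire active links with no contact for the persistence window
  stale <- state$link_active &
    (now - state$link_last_contact) >= state$params$link_persistence
  state$link_active[stale] <- FALSE
  # forget broken/retired rows whose pair is no longer in contact
  gone <- !state$link_active & !(existing %in% touch)
  if (any(gone)) {
    keep <- !gone
    state$link_a <- state$link_a[keep]
    state$link_b <- state$link_b[keep]
    state$link_lambda <- state$link_lambda[keep]
    state$link_rest <- state$link_rest[keep]
    state$link_active <- state$link_active[keep]
    state$link_last_contact <- state$link_last_contact[keep]
    state$link_broken <- state$link_broken[keep]
    existing <- key(state$link_a, state$link_b)
  }

  # create links for eligible pairs at/above the formation threshold
  cand <- areas[areas$area >= state$params$link_formation_area, ,
                drop = FALSE]
  if (nrow(cand)) {
    ta <- state$cell_type[cand$a]; tb <- state$cell_type[cand$b]
    la <- ca[lam_tab$type_a]; lb <- ca[lam_tab$type_b]
    lam <- rep(NA_real_, nrow(cand))
    for (r in seq_len(nrow(lam_tab))) {
      hit <- (ta == la[r] & tb == lb[r]) | (ta == lb[r] & tb == la[r])
      lam[hit] <- lam_tab$lambda[r]
    }
    ok <- !is.na(lam) & state$alive[cand$a] & state$alive[cand$b] &
      !(key(cand$a, cand$b) %in% existing)
    if (any(ok)) {
      cand <- cand[ok, , drop = FALSE]; lam <- lam[ok]
      ids_a <- pmin(cand$a, cand$b); ids_b <- pmax(cand$a, cand$b)
      dx <- state$comx[ids_a] - state$comx[ids_b]
      dy <- state$comy[ids_a] - state$comy[ids_b]
      dz <- state$comz[ids_a] - state$comz[ids_b]
      L1 <- state$dims[1]; L2 <- state$dims[2]
      dx <- dx - L1 * round(dx / L1)
      dy <- dy - L2 * round(dy / L2)
      rest <- sqrt(dx^2 + dy^2 + dz^2)
      state$link_a <- c(state$link_a, ids_a)
      state$link_b <- c(state$link_b, ids_b)
      state$link_lambda <- c(state$link_lambda, lam)
      state$link_rest <- c(state$link_rest, rest)
      state$link_active <- c(state$link_active, rep(TRUE, length(lam)))
      state$link_last_contact <- c(state$link_last_contact,
                                   rep(now, length(lam)))
      state$link_broken <- c(state$link_broken, rep(FALSE, length(lam)))
    }
  }
  state
}

#' Divide a stalk cell
#'
#' Partitions the cell's voxels by a random plane through its center of
#' mass.  Both daughters keep type Stalk and receive half the parent's
#' target volume; the parent's springs are released for re-evaluation at
#' the next [maintain_links()].
#'
#' @param state A `cpm_state`.
#' @param cell_id Id of the dividing cell (must be a non-frozen Stalk).
#' @return List with the updated `state`, `parent` and `daughter` ids.
#' @export
split_cell <- function(state, cell_id) {
  if (cell_id < 1 || cell_id > n_cells(state))
    stop("no such cell")
  if (state$frozen[cell_id] || state$cell_type[cell_id] != cell_types()[["Stalk"]])
    stop("only non-frozen Stalk cells divide")
  vox <- which(state$site == cell_id, arr.ind = TRUE)
  if (nrow(vox) < 2) stop("cell too small to divide")
  ctr <- sweep(vox - 0.5, 2, com_recount_one(vox, state$dims))
  for (ax in 1:2) {
    L <- state$dims[ax]
    ctr[, ax] <- ctr[, ax] - L * round(ctr[, ax] / L)
  }
  side <- NULL
  for (try in 1:25) {
    nrm <- stats::rnorm(3)
    nrm <- nrm / sqrt(sum(nrm^2))
    s <- drop(ctr %*% nrm) > 0
    if (any(s) && any(!s)) { side <- s; break }
  }
  if (is.null(side)) {  # degenerate shape: split by rank along max spread
    ax <- which.max(apply(ctr, 2, stats::var))
    side <- rank(ctr[, ax], ties.method = "first") > nrow(ctr) / 2
  }
  half_target <- state$target_volume[cell_id] / 2
  new_vox <- vox[side, , drop = FALSE]
  state$site[new_vox] <- 0L  # release, re-claim as daughter
  state$volume[cell_id] <- sum(!side)
  state$target_volume[cell_id] <- half_target
  keep_vox <- vox[!side, , drop = FALSE]
  com <- com_recount_one(keep_vox, state$dims)
  state$comx[cell_id] <- com[1]; state$comy[cell_id] <- com[2]
  state$comz[cell_id] <- com[3]
  state <- add_cell(state, new_vox, "Stalk", target_volume = half_target)
  new_id <- n_cells(state)
  drop <- (state$link_a == cell_id | state$link_b == cell_id) &
    state$link_active
  state$link_active[drop] <- FALSE
  list(state = state, parent = cell_id, daughter = new_id)
}

#' @export
print.cpm_state <- function(x, ...) {
  alive <- x$alive & x$volume > 0
  tys <- table(type_name(x$cell_type[alive]))
  cat("Cellular Potts state: ", paste(x$dims, collapse = " x "),
      " voxels (", x$voxel_size, " um), t = ", round(x$clock, 2),
      " h\n", sep = "")
  cat("  cells:", sum(alive), "alive;",
      paste(names(tys), tys, sep = "=", collapse = ", "), "\n")
  cat("  links:", sum(x$link_active), "active of", length(x$link_a), "\n")
  invisible(x)
}
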
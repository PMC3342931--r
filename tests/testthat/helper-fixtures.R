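# Shared fixture builders for the test suite.  All states are built in
# code; nothing is read from disk.

# small multi-cell state with adjustable couplings, for energy tests
toy_state <- function(J = contact_energy_table(1), lambda_vol = 5,
                      temperature = 20, chem = FALSE) {
  st <- new_cpm_state(c(12, 12, 12), J = J, lambda_vol = lambda_vol,
                      temperature = temperature)
  st <- add_cell(st, as.matrix(expand.grid(3:5, 3:5, 3:5)), "RPE")
  st <- add_cell(st, as.matrix(expand.grid(6:8, 3:5, 3:5)), "RPE")
  st <- add_cell(st, as.matrix(expand.grid(3:5, 6:8, 3:5)), "Stalk")
  st <- add_cell(st, as.matrix(expand.grid(6:8, 6:8, 3:5)), "POS")
  if (chem) {
    st$chem_fields$rpe_vegf <- array(rep(seq(0, 1, length.out = 12),
                                         each = 144), dim = c(12, 12, 12))
    st$lambda_chem["Stalk", "rpe_vegf"] <- 10
  }
  st
}

# two single-voxel cells side by side; J set so their one face contact
# carries a known energy
two_voxel_toy <- function(J_rpe_rpe = -40) {
  J <- matrix(0, 8, 8)
  J[5, 5] <- J_rpe_rpe  # RPE-RPE (code 4 -> index 5)
  st <- new_cpm_state(c(6, 6, 6), J = J, lambda_vol = 0)
  st <- add_cell(st, matrix(c(3L, 3L, 3L), 1), "RPE")
  st <- add_cell(st, matrix(c(4L, 3L, 3L), 1), "RPE")
  st
}

# uniform random multi-cell state (blocky Voronoi-ish seeds) for
# property tests; all cells one type, optional links disabled
random_state <- function(n_cells = 6, dims = c(10, 10, 10),
                         types = c("RPE", "Stalk", "POS"),
                         lambda_vol = 60, seed = 1) {
  set.seed(seed)
  # positive interface tension keeps cells compact (as in built scenes)
  J <- contact_energy_table(1) + 56
  J["Medium", "Medium"] <- 0
  st <- new_cpm_state(dims, J = J, lambda_vol = lambda_vol)
  # random 3x3x3 blocks (large enough to be stable under the interface
  # tension; non-overlapping by construction attempt)
  for (i in seq_len(n_cells)) {
    for (try in 1:50) {
      o <- c(sample(dims[1] - 3, 1), sample(dims[2] - 3, 1),
             sample(dims[3] - 3, 1))
      vox <- as.matrix(expand.grid(o[1]:(o[1] + 2), o[2]:(o[2] + 2),
                                   o[3]:(o[3] + 2)))
      if (all(st$site[vox] == 0)) {
        st <- add_cell(st, vox, sample(types, 1))
        break
      }
    }
  }
  st
}

mini_engine <- function() default_engine("mini")

# cached mini retina (expensive enough to share across tests)
cached_mini_retina <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("mini_retina")
    cache
  }
})

expect_rel_equal <- function(a, b, tol = 1e-9) {
  expect_lt(abs(a - b) / max(1, abs(a), abs(b)), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
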
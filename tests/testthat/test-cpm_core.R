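# Lattice Monte Carlo engine: energy accounting, Metropolis dynamics,
# ledger bookkeeping, springs and mitosis.

test_that("energy terms vanish for an isolated cell at target volume", {
  st <- new_cpm_state(c(6, 6, 6), J = contact_energy_table(1),
                      lambda_vol = 5)
  st <- add_cell(st, as.matrix(expand.grid(3:4, 3:4, 3:4)), "RPE")
  # the cell touches Medium: subtract the known contact contribution by
  # zeroing the cell-Medium energies
  st$J["RPE", "Medium"] <- 0; st$J["Medium", "RPE"] <- 0
  expect_equal(total_energy(st), 0)
})

test_that("one-face contact between two cells carries J once", {
  st <- two_voxel_toy(J_rpe_rpe = -40)
  expect_equal(total_energy(st), -40)
})

test_that("volume strain energy is lambda times squared excess", {
  st <- new_cpm_state(c(6, 6, 6), lambda_vol = 2)  # all J zero
  st <- add_cell(st, as.matrix(expand.grid(2:3, 2:3, 2:3)), "RPE",
                 target_volume = 6)  # volume 8 = target + 2
  expect_equal(total_energy(st), 2 * 2^2)
})

test_that("delta energy matches the full-Hamiltonian oracle", {
  set.seed(99)
  st <- toy_state()
  st <- maintain_links(st)
  checked <- 0
  for (i in 1:1200) {
    # sample near the occupied region so proposals hit boundaries often
    tgt <- c(sample(2:9, 1), sample(2:9, 1), sample(2:7, 1))
    o <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
               c(0,0,1), c(0,0,-1))[sample(6, 1), ]
    src <- tgt + o
    if (src[3] < 1 || src[3] > 12) next
    src[1:2] <- (src[1:2] - 1) %% 12 + 1
    sid <- st$site[matrix(src, 1)]; tid <- st$site[matrix(tgt, 1)]
    if (sid == tid) next
    dH <- delta_energy(st, src, tgt)
    e0 <- total_energy(st)
    st2 <- cnvpotts:::apply_copy_r(st, src, tgt)
    e1 <- total_energy(st2)
    expect_rel_equal(dH, e1 - e0, tol = 1e-9)
    checked <- checked + 1
    st <- st2
  }
  expect_gt(checked, 100)
})

test_that("copying within one cell is a strict no-op", {
  st <- toy_state()
  expect_equal(delta_energy(st, c(3, 3, 3), c(4, 3, 3)), 0)
})

test_that("chemotaxis adds -lambda times the concentration step", {
  # all J zero, no volume term: pure chemotaxis reading
  st <- new_cpm_state(c(8, 8, 8), lambda_vol = 0)
  st <- add_cell(st, matrix(c(4L, 4L, 4L), 1), "Stalk",
                 target_volume = NULL)
  st$lambda_vol <- 0
  st$lambda_chem["Stalk", "rpe_vegf"] <- 10
  f <- array(0, dim = c(8, 8, 8))
  f[4, 4, 4] <- 1; f[4, 4, 5] <- 3   # step of +2 upward
  st$chem_fields$rpe_vegf <- f
  dH <- delta_energy(st, c(4, 4, 4), c(4, 4, 5))
  expect_equal(dH, -10 * 2)
  # retraction (Medium advancing into the EC) carries no chemotaxis term
  dH2 <- delta_energy(st, c(4, 4, 5), c(4, 4, 4))
  expect_equal(dH2, 0)
})

test_that("Metropolis acceptance follows exp(-dH/T)", {
  # fixed positive dH via the volume term on a two-cell probe
  T <- 20
  dH <- T * log(2)  # acceptance probability exactly 1/2
  st <- new_cpm_state(c(4, 4, 4), lambda_vol = dH / 2, temperature = T)
  st <- add_cell(st, matrix(c(2L, 2L, 2L), 1), "RPE", target_volume = 1)
  st <- add_cell(st, matrix(c(3L, 2L, 2L), 1), "RPE", target_volume = 1)
  # probe the proposal once, then rescale lambda_vol so its energy
  # change is exactly T ln 2
  pair <- list(source = c(2, 2, 2), target = c(3, 2, 2))
  d_probe <- delta_energy(st, pair$source, pair$target)
  st$lambda_vol <- dH / d_probe * st$lambda_vol
  expect_equal(delta_energy(st, pair$source, pair$target), dH,
               tolerance = 1e-9)
  set.seed(123)
  n <- 10000
  acc <- 0
  for (i in 1:n) {
    res <- attempt_index_copy(st, pair = pair)
    if (res$accepted) acc <- acc + 1
    # state deliberately NOT updated: independent trials of the same move
  }
  p <- 0.5
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("zero energy change is always accepted", {
  st <- new_cpm_state(c(4, 4, 4), lambda_vol = 0)
  st <- add_cell(st, matrix(c(2L, 2L, 2L), 1), "RPE")
  st <- add_cell(st, matrix(c(3L, 2L, 2L), 1), "RPE")
  pair <- list(source = c(2, 2, 2), target = c(3, 2, 2))
  expect_equal(delta_energy(st, pair$source, pair$target), 0)
  set.seed(1)
  res <- attempt_index_copy(st, pair = pair)
  expect_true(res$accepted)
})

test_that("frozen cells are never sources or targets", {
  st <- new_cpm_state(c(6, 6, 6))
  st <- add_cell(st, as.matrix(expand.grid(1:6, 1:6, 3)), "BrM",
                 frozen = TRUE)
  st <- add_cell(st, as.matrix(expand.grid(3:4, 3:4, 4:5)), "Stalk")
  expect_error(delta_energy(st, c(3, 3, 4), c(3, 3, 3)), "frozen")
  res <- attempt_index_copy(st, pair = list(source = c(3, 3, 4),
                                            target = c(3, 3, 3)))
  expect_false(res$accepted)
  expect_equal(res$state$site, st$site)
  # frozen source likewise refused
  res2 <- attempt_index_copy(st, pair = list(source = c(3, 3, 3),
                                             target = c(3, 3, 4)))
  expect_false(res2$accepted)
})

test_that("run_mcs with zero steps changes nothing", {
  st <- toy_state()
  res <- run_mcs(st, 0)
  expect_identical(res$state$site, st$site)
  expect_equal(res$state$clock, st$clock)
})

test_that("low temperature relaxes volumes to their targets", {
  set.seed(5)
  st <- new_cpm_state(c(20, 20, 20), temperature = 0.1, lambda_vol = 5)
  st <- add_cell(st, as.matrix(expand.grid(5:10, 5:10, 5:10)), "RPE",
                 target_volume = 150)
  st <- add_cell(st, as.matrix(expand.grid(12:15, 12:15, 12:15)), "RPE",
                 target_volume = 100)
  res <- run_mcs(st, 50)
  expect_lt(max(abs(res$state$volume - res$state$target_volume)), 3)
})

test_that("ledgers agree with brute-force recounts after evolution", {
  set.seed(17)
  # low temperature keeps cells compact, where the center of mass is
  # well defined and the incremental ledger must match a recount
  st <- random_state(n_cells = 8, seed = 17)
  st$temperature <- 4
  res <- run_mcs(st, 40)
  st2 <- res$state
  # volume ledger
  vol <- tabulate(st2$site[st2$site > 0], nbins = length(st2$volume))
  expect_equal(as.integer(vol), as.integer(st2$volume))
  # COM ledger within float tolerance (wrap-aware in x and y)
  rc <- com_recount(st2)
  wrap_diff <- function(d, L) pmin(abs(d), L - abs(d))
  for (id in which(st2$volume > 0)) {
    dd <- c(wrap_diff(rc[id, 1] - st2$comx[id], st2$dims[1]),
            wrap_diff(rc[id, 2] - st2$comy[id], st2$dims[2]),
            abs(rc[id, 3] - st2$comz[id]))
    expect_lt(max(dd), 1e-6)
  }
})

test_that("contact areas are symmetric and match a brute-force count", {
  set.seed(31)
  st <- random_state(n_cells = 6, seed = 31)
  st <- run_mcs(st, 30)$state
  for (ord in c(6, 26)) {
    areas <- contact_areas(st, order = ord)
    expect_true(all(areas$a < areas$b))
    # brute-force recount
    d <- st$dims
    count <- new.env()
    offs <- if (ord == 6) rbind(c(1,0,0), c(0,1,0), c(0,0,1)) else {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g <- g[!(g[,1]==0 & g[,2]==0 & g[,3]==0), ]
      g[g[,3] > 0 | (g[,3]==0 & (g[,2] > 0 | (g[,2]==0 & g[,1] > 0))), ]
    }
    tab <- list()
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- st$site[x, y, z]
      for (r in seq_len(nrow(offs))) {
        zz <- z + offs[r, 3]
        if (zz < 1 || zz > d[3]) next
        xx <- (x + offs[r, 1] - 1) %% d[1] + 1
        yy <- (y + offs[r, 2] - 1) %% d[2] + 1
        b <- st$site[xx, yy, zz]
        if (a == b) next
        key <- paste(min(a, b), max(a, b))
        tab[[key]] <- (tab[[key]] %||% 0) + 1
      }
    }
    got <- setNames(areas$area, paste(areas$a, areas$b))
    expect_equal(sort(names(got)), sort(names(tab)))
    for (k in names(tab)) expect_equal(unname(got[[k]]), tab[[k]],
                                       info = paste("order", ord, k))
  }
})

test_that("identical seeds give bit-identical trajectories", {
  st <- cached_mini_retina()
  set.seed(42); a <- run_mcs(st, 10)
  set.seed(42); b <- run_mcs(st, 10)
  expect_identical(a$state$site, b$state$site)
  expect_identical(a$state$comx, b$state$comx)
  set.seed(43); c <- run_mcs(st, 10)
  expect_false(identical(a$state$site, c$state$site))
})

test_that("junctional springs form once per touching pair and break", {
  st <- toy_state()
  st <- maintain_links(st)
  # RPE cells 1 and 2 touch through 9 faces under an RPE-RPE junctional
  # scenario: exactly one link at the tabulated stiffness
  k <- which((st$link_a == 1 & st$link_b == 2))
  expect_equal(length(k), 1)
  expect_true(st$link_active[k])
  expect_equal(st$link_lambda[k], 300)
  expect_equal(unname(st$link_rest[k]),
               sqrt(sum((c(st$comx[1], st$comy[1], st$comz[1]) -
                           c(st$comx[2], st$comy[2], st$comz[2]))^2)))
  # maintaining again does not duplicate
  st <- maintain_links(st)
  expect_equal(sum(st$link_a == 1 & st$link_b == 2), 1)
  # stretch the pair beyond the break length by teleporting a COM
  # (along z, the non-periodic axis) and touching cell 1 with a copy so
  # its links are re-checked
  st$comz[2] <- st$comz[2] + 4 * unname(st$link_rest[k]) + 2
  st2 <- cnvpotts:::apply_copy_r(st, c(3, 3, 3), c(3, 3, 2))
  expect_false(st2$link_active[k])
  expect_equal(cnvpotts:::spring_energy(st2), 0,
               tolerance = 1e-12)
})

test_that("stale springs retire after the persistence window", {
  st <- toy_state()
  st <- maintain_links(st)
  k <- which(st$link_a == 1 & st$link_b == 2)
  # separate the cells on the lattice, then advance past the window
  vox <- which(st$site == 2L)
  st$site[vox] <- 0L
  st$volume[2] <- 0L
  st$alive[2] <- FALSE
  st$clock <- st$clock + 7  # > 6 h persistence
  st <- maintain_links(st)
  expect_false(any(st$link_active[st$link_a == 1 & st$link_b == 2]))
})

test_that("mitosis conserves volume and types across random shapes", {
  set.seed(77)
  for (rep in 1:20) {
    st <- random_state(n_cells = 4, types = "Stalk", seed = rep)
    st <- run_mcs(st, 10)$state
    id <- which(st$cell_type == 2L & st$volume >= 4)[1]
    if (is.na(id)) next
    v0 <- st$volume[id]
    t0 <- st$target_volume[id]
    sp <- split_cell(st, id)
    st2 <- sp$state
    expect_equal(st2$volume[sp$parent] + st2$volume[sp$daughter], v0)
    expect_gt(st2$volume[sp$parent], 0)
    expect_gt(st2$volume[sp$daughter], 0)
    expect_equal(st2$cell_type[sp$daughter], 2L)  # stalk stays stalk
    expect_equal(st2$target_volume[sp$parent], t0 / 2)
    expect_equal(st2$target_volume[sp$daughter], t0 / 2)
  }
})

test_that("an eight-voxel cube splits into two four-voxel daughters", {
  found <- FALSE
  set.seed(3)
  for (try in 1:20) {
    st <- new_cpm_state(c(6, 6, 6))
    st <- add_cell(st, as.matrix(expand.grid(3:4, 3:4, 3:4)), "Stalk")
    sp <- split_cell(st, 1)
    if (sp$state$volume[1] == 4) { found <- TRUE; break }
  }
  expect_true(found)  # axis-aligned planes split the cube evenly
})

test_that("only non-frozen stalk cells divide", {
  st <- toy_state()
  expect_error(split_cell(st, 1), "Stalk")  # RPE cell
  st <- add_cell(st, as.matrix(expand.grid(10:11, 10:11, 10:11)), "BrM",
                 frozen = TRUE)
  expect_error(split_cell(st, cnvpotts:::n_cells(st)), "Stalk")
})
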
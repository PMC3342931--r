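# Diffusion-decay dynamics, steady states and the analytic 1D oxygen
# profile.

test_that("mass is conserved without sources, decay or open boundaries", {
  st <- new_cpm_state(c(8, 8, 8))
  f <- array(stats::runif(512), dim = c(8, 8, 8))
  p <- list(D = 0.2, k = 0, secrete = c(), uptake = c())
  g <- f
  for (i in 1:1000) g <- step_field(g, st, "rpe_vegf", dt = 1, params = p)
  expect_lt(abs(sum(g) - sum(f)) / sum(f), 1e-8)
  expect_true(all(g >= 0))
})

test_that("pure decay follows the closed form", {
  st <- new_cpm_state(c(6, 6, 6))
  f <- array(2, dim = c(6, 6, 6))
  k <- 0.01
  p <- list(D = 0, k = k, secrete = c(), uptake = c())
  g <- f
  for (i in 1:100) g <- step_field(g, st, "rpe_vegf", dt = 0.5, params = p)
  # forward Euler of dc/dt = -kc: (1 - k dt)^n
  expect_equal(max(abs(g - 2 * (1 - k * 0.5)^100)), 0, tolerance = 1e-6)
  expect_lt(abs(g[1] - 2 * exp(-k * 50)), 3e-3)
})

test_that("unstable time steps are refused with the admissible bound", {
  st <- new_cpm_state(c(6, 6, 6))
  f <- array(0, dim = c(6, 6, 6))
  p <- list(D = 10, k = 0, secrete = c(), uptake = c())
  expect_error(step_field(f, st, "rpe_vegf", dt = 1, params = p),
               "unstable")
})

test_that("Dirichlet faces hold their values exactly", {
  st <- new_cpm_state(c(6, 6, 8))
  f <- array(0, dim = c(6, 6, 8))
  p <- list(D = 0.2, k = 0, secrete = c(), uptake = c())
  g <- f
  for (i in 1:2000)
    g <- step_field(g, st, "rpe_vegf", dt = 1, params = p,
                    dirichlet = c(5, 1))
  expect_true(all(g[, , 1] == 5))
  expect_true(all(g[, , 8] == 1))
  expect_true(all(diff(apply(g, 3, mean)) < 0))  # monotone gradient
})

test_that("RPE oxygen uptake is zero by construction", {
  p <- field_params()
  expect_false("RPE" %in% names(p$oxygen$uptake))
  expect_equal(length(p$oxygen$uptake), 0)
})

test_that("VEGF diffusion constants keep the 25-fold ratio", {
  p <- field_params()
  expect_equal(p$rpe_vegf$D / p$short_vegf$D, 25)
  expect_equal(p$rpe_vegf$k, p$short_vegf$k)
  # MMP diffusion length below one 2-um voxel
  expect_lt(sqrt(p$mmp$D / p$mmp$k), 2)
})

test_that("steady short-VEGF decay length is a fifth of the long one", {
  st <- new_cpm_state(c(4, 4, 60), voxel_size = 2)
  # plane source at the bottom
  src <- array(0, dim = c(4, 4, 60)); src[, , 1] <- 1e-3
  fit_len <- function(name) {
    p <- field_params()[[name]]
    f <- steady_field(st, name, params = list(D = p$D, k = p$k,
                                              secrete = c(), uptake = c()),
                      extra_src = src, tol = 1e-12, max_iter = 20000)
    prof <- apply(f, 3, mean)
    z <- 5:30
    fit <- stats::lm(log(prof[z]) ~ z)
    unname(-2 / stats::coef(fit)[2])  # decay length, um
  }
  l_long <- fit_len("rpe_vegf")
  l_short <- fit_len("short_vegf")
  expect_equal(l_long / l_short, 5, tolerance = 0.15)
})

test_that("BrM degradation follows the per-voxel hazard", {
  st <- new_cpm_state(c(10, 10, 4))
  st <- add_cell(st, as.matrix(expand.grid(1:10, 1:10, 2:3)), "BrM",
                 frozen = TRUE)
  # zero MMP: nothing happens
  res0 <- degrade_brm(st, array(0, dim = st$dims), rate = 1, dt = 1)
  expect_equal(res0$removed, 0)
  # uniform MMP slab: removals binomial(n, p)
  set.seed(42)
  p_vox <- 0.3
  mmp <- array(p_vox, dim = st$dims)
  removed <- replicate(40, degrade_brm(st, mmp, rate = 1, dt = 1)$removed)
  n <- 200
  expect_lt(abs(mean(removed) - n * p_vox),
            3 * sqrt(n * p_vox * (1 - p_vox) / 40))
  # ledgers updated
  res <- degrade_brm(st, mmp, rate = 1, dt = 1)
  expect_equal(sum(res$state$volume), 200 - res$removed)
})

test_that("oxygen profile is linear without consumption", {
  g <- oxygen_geometry(P_cc = 80, P_olm = 20, Q_pis = 0)
  prof <- oxygen_profile_1d(g, x = c(0, 18, 73))
  expect_equal(prof$po2_mmhg[1], 80)
  expect_equal(prof$po2_mmhg[3], 20)
  expect_equal(prof$po2_mmhg[2], 80 - 60 * 18 / 73, tolerance = 1e-12)
  expect_equal(attr(prof, "p_rpe"), 80 - 60 * 18 / 73)
  # flat when ends agree and no consumption
  gf <- oxygen_geometry(P_cc = 50, P_olm = 50, Q_pis = 0)
  pf <- oxygen_profile_1d(gf)
  expect_true(all(abs(pf$po2_mmhg - 50) < 1e-9))
})

test_that("consumption calibration round-trips and is monotone", {
  g <- oxygen_geometry(P_cc = 80, P_olm = 20)
  # target equal to the consumption-free value needs no consumption
  expect_equal(calibrate_pis_uptake(g, p_rpe(g)), 0)
  q <- calibrate_pis_uptake(g, 65)
  expect_gt(q, 0)
  g$Q_pis <- q
  expect_equal(p_rpe(g), 65, tolerance = 1e-6)
  # strictly decreasing in consumption
  ps <- sapply(c(0, 1, 2, 4) * q, function(qq) {
    gg <- g; gg$Q_pis <- qq; p_rpe(gg)
  })
  expect_true(all(diff(ps) < 0))
  expect_error(calibrate_pis_uptake(g, 90), "unattainable")
})

test_that("hypoxic choriocapillaris lowers the RPE tension to ~49 mmHg", {
  g80 <- oxygen_geometry(P_cc = 80, P_olm = 20)
  q <- calibrate_pis_uptake(g80, 65)
  g60 <- oxygen_geometry(P_cc = 60, P_olm = 20, Q_pis = q)
  expect_equal(p_rpe(g60), 49, tolerance = 1)
})

test_that("3D steady oxygen on a uniform retina matches the 1D profile", {
  st <- make_fixture("uniform_slab")
  g <- st$params$geom
  q <- calibrate_pis_uptake(oxygen_geometry(P_cc = 80, P_olm = 20), 65)
  D <- field_params()$oxygen$D
  h <- st$voxel_size
  nz <- st$dims[3]
  # zero-order sink in the PIS voxels (src = -q D gives P'' = q there);
  # the top Dirichlet plane overrides its own voxel layer
  sink <- array(0, dim = st$dims)
  sink[, , g$z_pis[1]:g$z_pis[2]] <- -q * D
  f <- steady_field(st, "oxygen",
                    params = list(D = D, k = 0, secrete = c(),
                                  uptake = c()),
                    dirichlet = c(80, 20), extra_src = sink,
                    tol = 1e-9, max_iter = 30000)
  prof3 <- apply(f, 3, mean)
  # continuum analog on the voxel-center span [0, (nz-1) h], with the
  # consuming region covering the unclamped PIS voxels' support
  a <- (g$z_pis[1] - 1.5) * h
  b <- min((g$z_pis[2] - 0.5), nz - 1) * h
  L <- (nz - 1) * h
  L_BrM <- 6
  L_IS <- b - a
  L_OS <- a - L_BrM - 12
  g1d <- oxygen_geometry(L_BrM = L_BrM, L_RPE = 12, L_OS = L_OS,
                         L_IS = L_IS, L_OLM = L - L_BrM,
                         P_cc = 80, P_olm = 20, Q_pis = q)
  x <- (seq_len(nz) - 1) * h
  p1d <- oxygen_profile_1d(g1d, x = x)$po2_mmhg
  expect_lt(max(abs(prof3 - p1d) / 80), 0.02)
})
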
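# Scene construction, fixtures and the cell-fate rules.

test_that("fixtures have the advertised composition", {
  st <- make_fixture("two_cell_toy")
  expect_equal(sum(st$volume > 0), 2)
  expect_true(all(st$cell_type == cell_types()[["RPE"]]))

  st <- cached_mini_retina()
  tn <- names(cell_types())
  present <- sort(unique(tn[st$cell_type + 1]))
  expect_setequal(present, c("Vascular", "BrM", "RPE", "POS", "PIS"))
  # layer order bottom-up by mean COM height
  mz <- function(ty) mean(st$comz[st$cell_type == cell_types()[[ty]]])
  expect_true(mz("Vascular") < mz("BrM"))
  expect_true(mz("BrM") < mz("RPE"))
  expect_true(mz("RPE") < mz("POS"))
  expect_true(mz("POS") < mz("PIS"))
  expect_error(make_fixture("nope"))
})

test_that("fixture construction is deterministic", {
  a <- make_fixture("two_cell_toy")
  b <- make_fixture("two_cell_toy")
  expect_identical(a, b)
})

test_that("the reference domain hosts about a hundred RPE cells", {
  # 120 um / 12 um footprint = 10 cells per side
  g <- retinal_geometry(lateral_um = 120)
  expect_equal((g$nx * g$voxel_um / 12)^2, 100)
  # the mini preset hosts 16
  g48 <- retinal_geometry(lateral_um = 48)
  expect_equal((g48$nx * g48$voxel_um / 12)^2, 16)
  expect_error(retinal_geometry(lateral_um = 24), "monolayer")
})

test_that("the built retina starts with no CNV and a sealed monolayer", {
  st <- cached_mini_retina()
  m <- morphometric_record(st)
  expect_equal(m$n_stalk, 0)
  expect_equal(m$ca_stalk_brm + m$ca_stalk_pos, 0)
  expect_equal(m$ca_pos_brm, 0)       # POS never touches BrM at rest
  # RPE covers essentially the whole BrM apical face
  apical_faces <- st$dims[1] * st$dims[2]
  expect_gt(m$ca_rpe_brm / apical_faces, 0.95)
  check_state <- cnvpotts:::check_state
  expect_true(check_state(st))
})

test_that("emergent polarity: RPE contacts BrM below, RPE beside, POS above", {
  st <- cached_mini_retina()
  areas <- contact_areas(st, order = 6)
  ct <- cell_types()
  rpe <- which(st$cell_type == ct[["RPE"]])
  id <- rpe[1]
  rows <- areas[areas$a == id | areas$b == id, ]
  other <- ifelse(rows$a == id, rows$b, rows$a)
  oty <- ifelse(other > 0, st$cell_type[pmax(other, 1)], 0L)
  expect_true(any(oty == ct[["BrM"]]))
  expect_true(any(oty == ct[["RPE"]]))
  expect_true(any(oty == ct[["POS"]]))
})

test_that("tip seeding converts one CC cell under the single-tip protocol", {
  st <- cached_mini_retina()
  st <- seed_tip_cell(st)
  ct <- cell_types()
  expect_equal(sum(st$cell_type == ct[["Tip"]]), 1)
  tid <- which(st$cell_type == ct[["Tip"]])
  expect_equal(st$birth_time[tid], st$clock)
  # near the lateral center
  expect_lt(abs(st$comx[tid] - st$dims[1] / 2), 6)
  expect_error(seed_tip_cell(st), "single-tip")
  # no CC anywhere: placement error
  st2 <- make_fixture("two_cell_toy")
  st2$params$stalk_target <- 64
  expect_error(seed_tip_cell(st2), "no choriocapillaris")
})

test_that("tip cells differentiate exactly at 24 h and stop MMP", {
  st <- cached_mini_retina()
  st <- seed_tip_cell(st)
  tid <- which(st$cell_type == cell_types()[["Tip"]])
  st$clock <- 23.9
  st <- differentiate_tips(st)
  expect_equal(st$cell_type[tid], cell_types()[["Tip"]])
  st$clock <- 24.0
  st <- differentiate_tips(st)
  expect_equal(st$cell_type[tid], cell_types()[["Stalk"]])
  # MMP secretion is tied to the Tip type
  src <- cnvpotts:::field_sources(st, "mmp")
  expect_equal(sum(src$src), 0)
  # no tips present: no-op
  st2 <- differentiate_tips(st)
  expect_identical(st2$cell_type, st$cell_type)
})

test_that("endothelial cells starve below the VEGF threshold", {
  st <- cached_mini_retina()
  st$chem_fields$rpe_vegf <- array(0, dim = st$dims)  # total starvation
  ct <- cell_types()
  vasc <- which(st$cell_type == ct[["Vascular"]])
  st <- update_survival(st)
  expect_false(any(st$dying[vasc]))       # grace period not yet elapsed
  expect_true(all(!is.na(st$starved_since[vasc])))
  st$clock <- st$clock + st$params$ec_grace + 0.1
  st <- update_survival(st)
  expect_true(all(st$dying[vasc]))
  ev <- st$events
  expect_true(all(ev$detail[ev$type == "death"] == "vegf_starvation"))
})

test_that("RPE survives detachment from BrM while laterally joined", {
  st <- cached_mini_retina()
  ct <- cell_types()
  rpe <- which(st$cell_type == ct[["RPE"]])
  st$clock <- 100
  st <- update_survival(st)
  expect_false(any(st$dying[rpe]))
  # fully isolated RPE cell: dies only after the grace period
  iso <- new_cpm_state(c(10, 10, 10), J = contact_energy_table(1))
  iso <- add_cell(iso, as.matrix(expand.grid(4:6, 4:6, 4:6)), "RPE")
  iso$params <- st$params
  iso$chem_fields$rpe_vegf <- array(1, dim = iso$dims)
  iso <- update_survival(iso)
  expect_false(iso$dying[1])
  iso$clock <- iso$params$rpe_grace + 1
  iso <- update_survival(iso)
  expect_true(iso$dying[1])
  ev <- iso$events
  expect_equal(ev$detail[ev$type == "death"], "rpe_isolation")
  # detached from BrM but still beside another RPE cell: survives
  duo <- new_cpm_state(c(10, 10, 10), J = contact_energy_table(1))
  duo <- add_cell(duo, as.matrix(expand.grid(2:4, 4:6, 4:6)), "RPE")
  duo <- add_cell(duo, as.matrix(expand.grid(5:7, 4:6, 4:6)), "RPE")
  duo$params <- st$params
  duo$chem_fields$rpe_vegf <- array(1, dim = duo$dims)
  duo$clock <- duo$params$rpe_grace + 5
  duo <- update_survival(duo)
  expect_false(any(duo$dying))
})

test_that("every death is logged with exactly one cause", {
  st <- cached_mini_retina()
  st$chem_fields$rpe_vegf <- array(0, dim = st$dims)
  st <- update_survival(st)
  st$clock <- st$clock + st$params$ec_grace + 0.1
  st <- update_survival(st)
  st <- update_survival(st)   # repeated calls must not double-log
  ev <- st$events[st$events$type == "death", ]
  expect_false(any(duplicated(ev$cell)))
})

test_that("stalk growth tracks VEGF and is contact-inhibited", {
  st <- new_cpm_state(c(12, 12, 12), J = contact_energy_table(1))
  st <- add_cell(st, as.matrix(expand.grid(3:5, 3:5, 3:5)), "Stalk")
  st$params$growth_rate <- 10
  st$params$inhibition_threshold <- 0.18
  st$params$doubling_volume <- 128
  # zero VEGF: no growth
  st$chem_fields$rpe_vegf <- array(0, dim = st$dims)
  t0 <- st$target_volume[1]
  st2 <- grow_stalk_cells(st, dt = 1)$state
  expect_equal(st2$target_volume[1], t0)
  # uniform VEGF: growth at rate * c
  st$chem_fields$rpe_vegf <- array(0.5, dim = st$dims)
  st3 <- grow_stalk_cells(st, dt = 2)$state
  expect_equal(st3$target_volume[1], t0 + 10 * 0.5 * 2)
  # fully enclosed by endothelium: zero growth
  enc <- new_cpm_state(c(8, 8, 8), J = contact_energy_table(1))
  enc <- add_cell(enc, as.matrix(expand.grid(3:5, 3:5, 3:5)), "Stalk")
  shell <- as.matrix(expand.grid(2:6, 2:6, 2:6))
  shell <- shell[!(shell[, 1] %in% 3:5 & shell[, 2] %in% 3:5 &
                     shell[, 3] %in% 3:5), ]
  enc <- add_cell(enc, shell, "Vascular")
  enc$params <- st$params
  enc$chem_fields$rpe_vegf <- array(1, dim = enc$dims)
  t0 <- enc$target_volume[1]
  enc2 <- grow_stalk_cells(enc, dt = 1)$state
  expect_equal(enc2$target_volume[1], t0)
  # at the doubling volume the cell is queued for division
  st$volume[1] <- 130
  expect_equal(grow_stalk_cells(st, dt = 1)$to_divide, 1L)
})
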
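test_that("phantom generation is deterministic and label-consistent", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), noise_sd_hu = 20, rng_seed = 7)
  ph1 <- make_thorax_phantom(spec, 0.3)
  ph2 <- make_thorax_phantom(spec, 0.3)
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(ph1$truth$compartment_labels, ph2$truth$compartment_labels)

  # every voxel carries exactly one compartment code
  labs <- ph1$truth$compartment_labels
  expect_true(all(labs %in% 0:5))

  # stored truth equals brute-force recounting of the labels
  vx_ml <- spec$spacing_mm^3 / 1000
  expect_identical(ph1$truth$aerated_volume_ml, sum(labs == 1) * vx_ml)
  expect_identical(ph1$truth$tumour_volume_ml, sum(labs == 3) * vx_ml)

  # HU volume invariants
  expect_true(all(ph1$volume$data >= -1024 & ph1$volume$data <= 3071))
})

test_that("zero burden places no nodules and burden targets are matched", {
  ph0 <- make_thorax_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                          noise_sd_hu = 0), 0)
  expect_identical(ph0$truth$tumour_volume_ml, 0)

  # the late-disease burden: tumour fraction of (tumour + lung) within 0.02
  ph <- make_thorax_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                         noise_sd_hu = 0, rng_seed = 3), 0.65)
  labs <- ph$truth$compartment_labels
  frac <- sum(labs == 3) / (sum(labs == 3) + sum(labs == 1))
  expect_lt(abs(frac - 0.65), 0.02)
})

test_that("invalid phantom requests are rejected", {
  expect_error(make_thorax_phantom(phantom_spec(), -0.1), "burden_fraction")
  expect_error(make_thorax_phantom(phantom_spec(), 1), "burden_fraction")
  expect_error(make_thorax_phantom(phantom_spec(grid_shape = c(16, 16, 16)), 0),
               "too small")
  expect_error(phantom_spec(tissue_hu = c(background_air = -1000, lung = -650,
                                          soft_tissue = -500, tumour = 30,
                                          bone = 700, airway = -1000)),
               "outside any aerated-lung acceptance window")
})

test_that("airway provides a face-connected air path from lung to the border", {
  ph <- make_thorax_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                         noise_sd_hu = 0), 0)
  labs <- ph$truth$compartment_labels
  # flood (oracle) through sub- -300 HU voxels from an airway-adjacent lung voxel
  air <- ph$volume$data < -300
  start <- which(labs == 5, arr.ind = TRUE)[1, , drop = FALSE]
  reach <- oracle_flood_fill(ph$volume$data, start, -1100, -300, 6)
  d <- dim(reach)
  expect_true(any(reach[, , 1]))            # reaches the z-min border
  expect_true(any(reach & labs == 1))       # and the lung interior
  # without the airway, no sub-threshold path from lung reaches the border
  ph2 <- make_thorax_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                          noise_sd_hu = 0, airway = FALSE), 0)
  start2 <- which(ph2$truth$compartment_labels == 1, arr.ind = TRUE)[1, , drop = FALSE]
  reach2 <- oracle_flood_fill(ph2$volume$data, start2, -1100, -300, 6)
  expect_false(any(reach2[1, , ]) || any(reach2[d[1], , ]) ||
                 any(reach2[, 1, ]) || any(reach2[, d[2], ]) ||
                 any(reach2[, , 1]) || any(reach2[, , d[3]]))
})

test_that("cohort simulation follows the linear model exactly at zero noise", {
  g0 <- growth_params(noise_sd_ml = 0)
  tab <- simulate_cohort(9, 3, months = c(1, 11), growth = g0, rng_seed = 1)
  tg <- tab[tab$genotype == "transgenic", ]
  expect_equal(unique(tg$volume_ml[tg$month == 1]), 0.315)
  diffs <- tg$volume_ml[tg$month == 11] - tg$volume_ml[tg$month == 1]
  expect_equal(unique(diffs), -0.10)
})

test_that("cohort tables have the right shape and are reproducible", {
  tab <- simulate_cohort(9, 3, months = 1:12, rng_seed = 5)
  expect_identical(nrow(tab), 144L)  # 12 animals x 12 months
  expect_identical(tab, simulate_cohort(9, 3, months = 1:12, rng_seed = 5))
  expect_true(all(tab$volume_ml >= 0))
  expect_false(anyDuplicated(tab[, c("animal_id", "month")]) > 0)
  expect_error(simulate_cohort(0, 3), "positive")
  expect_error(simulate_cohort(2, 2, months = c(3, 2)), "increasing")
})

test_that("wildtype trajectories rise through normal growth and then plateau", {
  g0 <- growth_params(noise_sd_ml = 0)
  tab <- simulate_cohort(2, 2, months = 2:8, growth = g0, rng_seed = 1)
  wt <- tab[tab$animal_id == "wt01", ]
  wt <- wt[order(wt$month), ]
  rise <- wt$volume_ml[wt$month <= 4]
  expect_true(all(diff(rise) > 0))
  flat <- wt$volume_ml[wt$month >= 4]
  expect_true(all(abs(diff(flat)) < 1e-12))
})

test_that("piecewise-realistic transgenic mode rises then declines at the model slope", {
  g <- growth_params(noise_sd_ml = 0, mode = "piecewise_realistic")
  tab <- simulate_cohort(1, 1, months = 2:10, growth = g, rng_seed = 1)
  tg <- tab[tab$genotype == "transgenic", ]
  tg <- tg[order(tg$month), ]
  expect_true(all(diff(tg$volume_ml[tg$month <= 4]) > 0))
  late <- tg$volume_ml[tg$month >= 4]
  expect_equal(unique(round(diff(late), 12)), -0.01)
})
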
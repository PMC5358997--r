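test_that("gut physiology satisfies its structural invariants", {
  fasted <- build_physiology("fasted")
  fed <- build_physiology("fed")
  expect_equal(sum(fasted$cyp3a4_weights), 1)
  expect_equal(sum(fasted$pgp_weights), 1)
  expect_true(all(diff(fasted$cyp3a4_weights) < 0))   # ab-oral decline
  expect_true(all(diff(fasted$pgp_weights) >= 0))
  expect_gt(fed$gastric_emptying_halflife_h,
            fasted$gastric_emptying_halflife_h)
  expect_equal(fed$segments$luminal_volume_ml,
               1.5 * fasted$segments$luminal_volume_ml)
  expect_equal(fed$medium, "FeSSIF")
  # mean small-intestinal transit under the CAT convention
  expect_equal(sum(1 / fasted$segments$transit_rate), 3.3, tolerance = 1e-9)
  expect_error(build_physiology("fasted", cyp3a4_weights = rep(1, 7)),
               "decrease")
})

test_that("physiology YAML round trip preserves the segment table", {
  f <- tempfile(fileext = ".yaml")
  phys <- build_physiology("fed")
  write_physiology_yaml(phys, f)
  back <- read_physiology_yaml(f)
  expect_equal(back$segments$transit_rate, phys$segments$transit_rate)
  expect_equal(back$gastric_emptying_halflife_h, 1.0)
  unlink(f)
})

test_that("segmental ka follows the 2 Peff / r scaling", {
  expect_equal(segment_ka(1.35e-4, 1.25), 2 * 1.35e-4 / 1.25 * 3600)
  expect_equal(segment_ka(1.35e-4, 1.25) / 3600, 2.16e-4)
  expect_equal(segment_ka(0, 1.25), 0)
  expect_equal(segment_ka(1e-4, 2.5), segment_ka(1e-4, 1.25) / 2)
})

test_that("P-gp efflux shows Michaelis-Menten limits", {
  vmax <- pgp_efflux_rate(1e9, 151, 115, 8.7, 0.2, 100)
  expect_equal(vmax, 8.7 * 0.2 * 151 * 100, tolerance = 1e-6)
  expect_equal(pgp_efflux_rate(115, 151, 115, 8.7, 0.2, 100), vmax / 2,
               tolerance = 1e-6)
  lin <- pgp_efflux_rate(0.01, 151, 115, 8.7, 0.2, 100)
  expect_equal(lin, 8.7 * 0.2 * 151 * 100 * 0.01 / 115, tolerance = 1e-3)
})

test_that("limiting cases: no metabolism with high permeability absorbs all", {
  probe <- linear_compound(peff = 5e-3)
  res <- simulate_gut(probe, "instant", dose_mg = 10,
                      prandial_state = "fasted")
  expect_gt(res$fa, 0.999)
  expect_equal(res$fg, 1)
  expect_equal(res$mass_check, 1, tolerance = 1e-6)

  none <- linear_compound(peff = 0)
  res0 <- simulate_gut(none, "instant", dose_mg = 10,
                       prandial_state = "fasted")
  expect_equal(res0$fa, 0)
  expect_true(all(res0$portal$rate_mg_h == 0))
})

test_that("mass is conserved and regional fa sums to fa", {
  rel <- preset_release("atorvastatin", "single", "fed")
  res <- simulate_gut(ator, rel, prandial_state = "fed")
  expect_equal(res$mass_check, 1, tolerance = 1e-6)
  expect_equal(sum(res$regional_fa), res$fa, tolerance = 1e-6)
  expect_true(res$fa >= 0 && res$fa <= 1 && res$fg >= 0 && res$fg <= 1)
})

test_that("instant release reproduces the linear CAT cascade", {
  probe <- linear_compound(peff = 2e-4)
  phys <- build_physiology("fasted")
  res <- simulate_gut(probe, "instant", dose_mg = 10, physiology = phys,
                      times = seq(0, 200, by = 0.5))
  seg <- phys$segments
  ka <- segment_ka(probe$peff, 1.25)
  ka_col <- segment_ka(probe$peff, phys$colon$radius_cm) *
    phys$colon$ka_scale
  fa_oracle <- cat_cascade_fa(log(2) / phys$gastric_emptying_halflife_h,
                              seg$transit_rate, rep(ka, 7),
                              phys$colon$transit_rate, ka_col)
  expect_equal(res$fa, fa_oracle, tolerance = 1e-3)

  # second, matrix-based oracle: exponential of the linear generator
  skip_if_not_installed("Matrix")
  n <- 9
  A <- matrix(0, n + 1, n + 1)   # stomach, 7 SI, colon, absorbed
  kge <- log(2) / phys$gastric_emptying_halflife_h
  A[1, 1] <- -kge; A[2, 1] <- kge
  for (i in 1:7) {
    A[i + 1, i + 1] <- -(seg$transit_rate[i] + ka)
    A[i + 2, i + 1] <- seg$transit_rate[i]
    A[n + 1, i + 1] <- A[n + 1, i + 1] + ka
  }
  A[9, 9] <- -(phys$colon$transit_rate + ka_col)
  A[n + 1, 9] <- ka_col
  y0 <- c(1, rep(0, n))
  yT <- as.numeric(Matrix::expm(A * 200) %*% y0)
  expect_equal(res$fa, yT[n + 1], tolerance = 1e-3)
})

test_that("fed atorvastatin shifts absorption distally and spares gut CYP3A4", {
  fa_res <- simulate_gut(ator, preset_release("atorvastatin", "single",
                                              "fasted"),
                         prandial_state = "fasted")
  fe_res <- simulate_gut(ator, preset_release("atorvastatin", "single",
                                              "fed"),
                         prandial_state = "fed")
  ileal <- function(r) sum(r$regional_fa[4:8]) / r$fa
  expect_gt(ileal(fe_res), ileal(fa_res))          # distal shift
  met <- function(r) r$fa * (1 - r$fg)
  expect_lt(met(fe_res), met(fa_res))              # less gut metabolism fed
  expect_gt(fe_res$fg, fa_res$fg)
})

test_that("the CYP3A4 gradient drives the fed-state fg gain", {
  # with a nearly flat gradient the fed-vs-fasted fg difference collapses
  graded_fa <- simulate_gut(ator, preset_release("atorvastatin", "single",
                                                 "fasted"),
                            prandial_state = "fasted")
  graded_fe <- simulate_gut(ator, preset_release("atorvastatin", "single",
                                                 "fed"),
                            prandial_state = "fed")
  flat <- 1 + 1e-4 * (7:1)     # satisfies strict decrease, essentially flat
  p_fa <- build_physiology("fasted", cyp3a4_weights = flat)
  p_fe <- build_physiology("fed", cyp3a4_weights = flat)
  flat_fa <- simulate_gut(ator, preset_release("atorvastatin", "single",
                                               "fasted"), physiology = p_fa)
  flat_fe <- simulate_gut(ator, preset_release("atorvastatin", "single",
                                               "fed"), physiology = p_fe)
  expect_lt(flat_fe$fg - flat_fa$fg, graded_fe$fg - graded_fa$fg)
})
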
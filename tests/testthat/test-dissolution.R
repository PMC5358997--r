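test_that("sampling-withdrawal correction reproduces hand summation", {
  p <- correct_cumulative(c(1, 2, 3), sample_volume = 5, vessel_volume = 900,
                          dose = 5)
  expect_equal(attr(p, "mass_ug"), c(900, 1805, 2715))
  expect_equal(profile_means(p), c(900, 1805, 2715) / 5000 * 100)

  # no-withdrawal limit
  p0 <- correct_cumulative(c(1, 2, 3), 0, 900, 5)
  expect_equal(attr(p0, "mass_ug"), c(1, 2, 3) * 900)

  # constant raw concentration: masses increase by v_s * c each step
  pc <- correct_cumulative(rep(2, 4), 5, 900, 5)
  expect_equal(diff(attr(pc, "mass_ug")), rep(5 * 2, 3))

  expect_error(correct_cumulative(c(1, -2, 3), 5, 900, 5), "time point 2")
})

test_that("f1 and f2 evaluate the printed formulas", {
  r <- c(50, 80, 95); tt <- c(45, 85, 90)
  expect_equal(f1_factor(r, r), 0)
  expect_equal(f2_factor(r, r), 100)
  expect_equal(f1_factor(r, tt), 15 / 225 * 100)
  expect_equal(f2_factor(r, tt), 50 * log10(100 / sqrt(26)))
  expect_error(f1_factor(r, tt[1:2]), "common time grid")

  # growing offset: f1 strictly increases, f2 strictly decreases
  offs <- seq(1, 20, by = 1)
  f1s <- sapply(offs, function(o) f1_factor(r, r + o))
  f2s <- sapply(offs, function(o) f2_factor(r, r + o))
  expect_true(all(diff(f1s) > 0))
  expect_true(all(diff(f2s) < 0))
})

test_that("similarity verdict applies the biowaiver and threshold rules", {
  t5 <- c(5, 10, 15, 30, 60)
  rapid <- dissolution_profile(t5, cbind(c(60, 80, 90, 95, 96)))
  rapid2 <- dissolution_profile(t5, cbind(c(55, 82, 91, 96, 97)))
  v <- similarity_verdict(rapid, rapid2)
  expect_true(v$rapid_both)
  expect_equal(v$verdict, "waived")
  expect_equal(similarity_verdict(rapid, rapid2,
                                  use_85_rule = FALSE)$verdict, "pass")

  slow <- dissolution_profile(t5, cbind(c(10, 25, 40, 60, 75)))
  v2 <- similarity_verdict(slow, slow)
  expect_equal(v2$f1, 0)
  expect_equal(v2$f2, 100)
  expect_equal(v2$verdict, "pass")

  expect_error(similarity_verdict(
    dissolution_profile(c(5, 10), cbind(c(10, 20))),
    dissolution_profile(c(5, 10), cbind(c(10, 20)))), "3 usable")
  expect_error(similarity_verdict(
    slow, dissolution_profile(t5 + 1, cbind(c(10, 25, 40, 60, 75)))),
    "different time grids")
})

test_that("verdict agrees with brute-force threshold evaluation", {
  set.seed(11)
  t5 <- c(5, 10, 15, 20, 30, 45, 60)
  for (i in 1:1000) {
    r <- cumsum(runif(7, 0, 15)) + runif(1, 0, 30)
    d <- r + rnorm(7, 0, runif(1, 0, 12))
    r <- pmin(pmax(r, 0), 84.9); d <- pmin(pmax(d, 0), 84.9)  # below waiver
    v <- similarity_verdict(dissolution_profile(t5, cbind(r)),
                            dissolution_profile(t5, cbind(d)))
    brute <- if (v$f1 < 15 && v$f2 > 50) "pass" else "fail"
    expect_identical(v$verdict, brute)
  }
})

test_that("release-model fitting recovers noiseless parameters", {
  truth <- dissolution_truth(94.9, 8, weibull_beta = 1.3, noise_sd = 0)
  prof <- gen_dissolution(truth, seed = 1)
  fit <- fit_release_model(prof, "weibull")
  expect_equal(fit$plateau, 94.9, tolerance = 1e-4)
  expect_equal(fit$td, 8, tolerance = 1e-4)
  expect_equal(fit$beta, 1.3, tolerance = 1e-4)

  # nested family: beta fixed at 1 equals the first-order fit
  truth1 <- dissolution_truth(80, 10, weibull_beta = 1, noise_sd = 0)
  prof1 <- gen_dissolution(truth1, seed = 1)
  w <- fit_release_model(prof1, "weibull")
  fo <- fit_release_model(prof1, "first-order")
  expect_equal(fo$beta, 1)
  expect_equal(fo$td, w$td, tolerance = 1e-3)

  tab <- fit_release_model(prof1, "tabulated")
  expect_equal(fraction_dissolved(tab, 1e5),
               profile_means(prof1)[10] / 100)  # clamped to plateau
})

test_that("fraction dissolved is bounded, monotone and anchored at zero", {
  m <- release_model("weibull", plateau = 94.9, td = 5, beta = 1)
  expect_equal(fraction_dissolved(m, 0), 0)
  expect_equal(fraction_dissolved(m, 1e6), 0.949)
  tt <- seq(0, 200, by = 1)
  fd <- fraction_dissolved(m, tt)
  expect_true(all(diff(fd) >= 0))
  expect_true(all(fd >= 0 & fd <= 0.949 + 1e-12))
  # bundled fasted amlodipine releases at least half the dose by 5 min
  pre <- dissolution_preset("amlodipine-FaSSIF-single")
  rel <- release_model("weibull", plateau = pre$plateau_percent,
                       td = pre$weibull_td, beta = pre$weibull_beta)
  expect_gte(fraction_dissolved(rel, 5), 0.50)
})

test_that("dissolution CSV round trip preserves the profile", {
  prof <- gen_dissolution(dissolution_preset("atorvastatin-FaSSIF-single",
                                             noise_sd = 2), seed = 4)
  f <- tempfile(fileext = ".csv")
  write_dissolution_csv(prof, f)
  back <- read_dissolution_csv(f)[[1]]
  expect_equal(back$times, prof$times)
  expect_equal(unname(as.matrix(back$percent)), unname(prof$percent),
               tolerance = 1e-12)
  unlink(f)
})
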
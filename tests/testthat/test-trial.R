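test_that("degenerate bolus configuration matches the one-compartment closed form", {
  probe <- linear_compound(vss = 10)
  design <- trial_design(probe, dose_mg = 10, n_subjects = 1,
                         sampling_times_h = seq(0.5, 24, by = 0.5),
                         release = "instant")
  cl <- 20
  prof <- simulate_subject(probe, design, absorption = "bolus",
                           first_pass = FALSE, cl_systemic = cl)
  v <- 10 * 70
  expected <- 10 / v * exp(-cl / v * prof$time_h) * 1000
  expect_equal(prof$conc_ngml, expected, tolerance = 1e-4)
})

test_that("zero dose gives an identically zero profile", {
  design <- trial_design(amlo, dose_mg = 0, n_subjects = 1,
                         sampling_times_h = c(1, 2, 4),
                         release = "instant")
  prof <- simulate_subject(amlo, design)
  expect_true(all(prof$conc_ngml == 0))
  expect_equal(attr(prof, "fa"), 0)
})

test_that("linear kinetics double with dose (no saturable efflux)", {
  d1 <- trial_design(amlo, dose_mg = 5, n_subjects = 1,
                     sampling_times_h = seq(1, 24, by = 1))
  d2 <- trial_design(amlo, dose_mg = 10, n_subjects = 1,
                     sampling_times_h = seq(1, 24, by = 1))
  p1 <- simulate_subject(amlo, d1)
  p2 <- simulate_subject(amlo, d2)
  expect_equal(p2$conc_ngml, 2 * p1$conc_ngml, tolerance = 1e-5)
  pk1 <- pk_parameters(p1); pk2 <- pk_parameters(p2)
  expect_equal(pk2$auc, 2 * pk1$auc, tolerance = 0.005)
})

test_that("AUC approaches F * dose / CL over a long horizon", {
  probe <- linear_compound(peff = 3e-4, vss = 5)
  design <- trial_design(probe, dose_mg = 10, n_subjects = 1,
                         duration_h = 240,
                         sampling_times_h = seq(0.5, 240, by = 0.5),
                         release = "instant")
  prof <- simulate_subject(probe, design)
  pk <- pk_parameters(prof)
  hep <- vbesim:::compound_hepatic(probe)
  f_oral <- attr(prof, "fa") * attr(prof, "fg") * hep$f_h
  # AUC in ng/mL h on plasma; dose mg -> F*D/CL_plasma, CL_p = CL_b * B:P
  auc_pred <- f_oral * 10 / (hep$cl_h * probe$bp_ratio) * 1e3
  expect_equal(pk$auc, auc_pred, tolerance = 0.02)
})

test_that("noncompartmental parameters match hand computation", {
  pk <- pk_parameters(time_h = c(0, 1, 2, 3), conc_ngml = c(0, 10, 5, 2.5))
  expect_equal(pk$cmax, 10)
  expect_equal(pk$tmax, 1)
  expect_equal(pk$auc, 16.25)

  expect_equal(pk_parameters(time_h = 0:5, conc_ngml = rep(3, 6))$auc, 15)
  expect_equal(pk_parameters(time_h = 0:5, conc_ngml = 0:5)$tmax, 5)
  pk0 <- pk_parameters(time_h = 0:3, conc_ngml = rep(0, 4))
  expect_equal(pk0$cmax, 0)
  expect_true(is.na(pk0$tmax))
  expect_equal(pk0$auc, 0)
})

test_that("PK summaries use geometric Cmax and median (range) elsewhere", {
  s <- summarize_pk(cmax = c(1, 10, 100), auc = c(2, 4, 9),
                    tmax = c(1, 2, 8))
  expect_equal(s$cmax_geomean, 10)
  expect_equal(s$auc_median, 4)
  expect_equal(s$auc_range, c(2, 9))
  s1 <- summarize_pk(5, 7, 2)
  expect_equal(s1$auc_range, c(7, 7))
  set.seed(3)
  x <- rlnorm(1e4, meanlog = 1.3, sdlog = 0.4)
  expect_equal(summarize_pk(x, x, x)$cmax_geomean, exp(1.3),
               tolerance = 0.02)
})

test_that("trials are reproducible and collapse correctly for n = 1", {
  design <- trial_design(amlo, n_subjects = 1, seed = 4,
                         cv_set = list(cl = 0, vss = 0, gut_cyp = 0,
                                       liver_cyp = 0),
                         sampling_times_h = seq(0.5, 24, by = 0.5))
  tr <- run_trial(design)
  expect_equal(tr$summary$cmax_geomean, tr$subjects$cmax)
  expect_equal(tr$summary$auc_median, tr$subjects$auc)

  d2 <- trial_design(amlo, n_subjects = 3, seed = 9,
                     sampling_times_h = seq(1, 24, by = 1))
  a <- run_trial(d2); b <- run_trial(d2)
  expect_identical(a$subjects, b$subjects)
  d3 <- trial_design(amlo, n_subjects = 3, seed = 10,
                     sampling_times_h = seq(1, 24, by = 1))
  expect_false(identical(run_trial(d3)$subjects$cmax, a$subjects$cmax))
})

test_that("group comparison matches the hand-computed Welch t statistic", {
  mk <- function(vals) structure(list(subjects = data.frame(auc = vals)),
                                 class = "trial_result")
  a <- c(10, 12, 14, 11, 13); b <- c(15, 17, 13, 16, 18)
  cmp <- compare_groups(mk(a), mk(b), "auc")
  t_hand <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(cmp$t, t_hand)
  df_hand <- (var(a) / 5 + var(b) / 5)^2 /
    ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(cmp$df, df_hand)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), df_hand))

  # pooled-variance variant against the textbook formula
  cmp_p <- compare_groups(mk(a), mk(b), "auc", var_equal = TRUE)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  expect_equal(cmp_p$t, (mean(a) - mean(b)) / sqrt(sp2 * (2 / 5)))
  expect_equal(cmp_p$df, 8)

  # identical groups: t = 0
  expect_equal(compare_groups(mk(a), mk(a), "auc")$t, 0)
  # zero-variance groups produce an exact-equality report
  z <- compare_groups(mk(rep(2, 4)), mk(rep(2, 4)), "auc")
  expect_true(z$exact_equal)

  # p decreases monotonically with shift
  ps <- sapply(c(1, 2, 4), function(s) {
    set.seed(1); x <- rnorm(40); compare_groups(mk(x), mk(x + s), "auc")$p_value
  })
  expect_true(all(diff(ps) < 0))
})

test_that("objective is near zero at the true parameters with clean data", {
  truth <- plasma_truth(amlo, n_subjects = 1, cv_cl = 0, cv_vss = 0,
                        residual_cv = 0,
                        sampling_times_h = c(1, 2, 4, 8, 12, 24))
  obs <- gen_plasma(truth, seed = 2)
  # symmetric log-bounds make the single midpoint start the truth itself
  prob <- estimation_problem(amlo, obs, free = c("peff", "vss"),
                             lower = c(peff = 1.35e-4 / 4, vss = 13.78 / 4),
                             upper = c(peff = 1.35e-4 * 4, vss = 13.78 * 4),
                             n_starts = 1, seed = 1)
  fit <- estimate_parameters(prob)
  expect_lt(fit$objective, 1e-6 * sum(obs$conc_ngml^2))
  expect_equal(unname(fit$par["peff"]), 1.35e-4, tolerance = 0.01)
  expect_equal(unname(fit$par["vss"]), 13.78, tolerance = 0.01)
})
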
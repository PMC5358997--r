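test_that("ionization follows Henderson-Hasselbalch for each class", {
  acid <- compound_profile("acid", "monoprotic_acid", mw = 500, pka = 4.46,
                           fu = 0.05, bp_ratio = 0.61, vss = 5, clpo = 900,
                           peff = 6e-4)
  # at pH = pKa exactly half the acid is un-ionized
  expect_equal(fraction_unionized(acid, 4.46), 0.5)
  expect_equal(fraction_unionized(ator, 6.5), 1 / (1 + 10^2.04),
               tolerance = 1e-10)
  expect_equal(fraction_unionized(amlo, 6.5), 1.258e-3, tolerance = 1e-3)
  neutral <- linear_compound()
  expect_equal(fraction_unionized(neutral, c(2, 7, 12)), rep(1, 3))
  expect_error(fraction_unionized(acid, 15), "pH")

  # monotone: un-ionized fraction of an acid falls with pH, of a base rises
  grid <- seq(1, 13, by = 0.5)
  expect_true(all(diff(fraction_unionized(acid, grid)) < 0))
  expect_true(all(diff(fraction_unionized(amlo, grid)) > 0))
})

test_that("blood/plasma conversion and hepatic extraction algebra", {
  expect_equal(fu_blood(0.07, 1), 0.07)
  expect_equal(fu_blood(0.051, 0.61), 0.051 / 0.61)

  h <- hepatic_extraction(0.1, 450, 90)
  expect_equal(h$cl_h, 30)
  expect_equal(h$e_h, 1 / 3)
  expect_equal(h$f_h, 2 / 3)
  # low-extraction limit: E_h ~ fu_b * CLu / q_h
  expect_equal(hepatic_extraction(0.01, 10, 90)$e_h, 0.01 * 10 / 90,
               tolerance = 2e-3)
  # flow limit
  expect_gt(hepatic_extraction(1, 1e9, 90)$e_h, 0.999999)
  # E_h strictly in (0,1) and CL_h < q_h over random parameter sets
  set.seed(42)
  for (i in 1:200) {
    fu <- runif(1, 0.01, 1); cl <- 10^runif(1, -1, 4); q <- runif(1, 30, 120)
    hh <- hepatic_extraction(fu, cl, q)
    expect_true(hh$e_h > 0 && hh$e_h < 1)
    expect_lt(hh$cl_h, q)
  }
})

test_that("oral bioavailability is the fa*fg*fh product", {
  expect_equal(oral_bioavailability(1, 0.24, 1), 0.24)
  expect_equal(oral_bioavailability(1, 0.24, 0.9), 0.216)
  expect_equal(oral_bioavailability(0.5, 0, 0.9), 0)
  expect_error(oral_bioavailability(1.2, 1, 1), "0, 1")
})

test_that("retrograde clearance inverts the forward clearance chain", {
  # forward: CLpo = CL_h / (fa*fg*fh) for a chosen intrinsic clearance;
  # retrograde must recover it exactly (property over random sets)
  set.seed(7)
  for (i in 1:1000) {
    fu_b <- runif(1, 0.01, 1); clu <- 10^runif(1, 0, 4)
    q <- runif(1, 50, 120); fa <- runif(1, 0.2, 1); fg <- runif(1, 0.1, 1)
    hep <- hepatic_extraction(fu_b, clu, q)
    clpo <- hep$cl_h / (fa * fg * hep$f_h)
    rg <- retrograde_clint(clpo, fa, fg, fu_b, q, enzyme_abundance = 1e6)
    expect_equal(rg$clu_int_liver, clu, tolerance = 1e-9)
  }
})

test_that("retrograde clearance matches a brute-force root-finding oracle", {
  # oracle: solve CLpo(x) = clpo for whole-liver CLu_int x by bisection
  cases <- list(c(clpo = 100, fa = 1, fg = 1, fu_b = 0.1, q = 90),
                c(clpo = 949 / 0.61, fa = 1, fg = 0.24,
                  fu_b = 0.051 / 0.61, q = 97),
                c(clpo = 5, fa = 0.8, fg = 0.9, fu_b = 0.5, q = 97))
  for (cs in cases) {
    fwd <- function(x) {
      h <- hepatic_extraction(cs["fu_b"], x, cs["q"])
      h$cl_h / (cs["fa"] * cs["fg"] * h$f_h) - cs["clpo"]
    }
    oracle <- uniroot(fwd, c(1e-6, 1e9), tol = 1e-10)$root
    rg <- retrograde_clint(cs["clpo"], cs["fa"], cs["fg"], cs["fu_b"],
                           cs["q"], enzyme_abundance = 1e6)
    expect_equal(rg$clu_int_liver, oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # the bundled atorvastatin inputs admit a positive finite solution
  rg <- retrograde_clint(949, 1, 0.24, fu_blood(0.051, 0.61), 97, 9e6,
                         bp_ratio = 0.61)
  expect_true(is.finite(rg$clint_per_pmol) && rg$clint_per_pmol > 0)
})

test_that("compound presets load with validated fields", {
  expect_s3_class(amlo, "compound_profile")
  expect_equal(amlo$pka, c(9.4, 1.90))
  expect_equal(amlo$vss, 13.78)
  expect_equal(amlo$clpo_lh, 24.8)        # unit tag normalized to L/h
  expect_null(amlo$clint_3a4)
  expect_equal(ator$peff, 6.12e-4)
  expect_equal(ator$raf_pgp, 8.7)
  expect_equal(ator$fg_assumed, 0.24)

  expect_error(compound_profile("x", "monoprotic_acid", mw = 100,
                                pka = c(1, 5), fu = 0.5, bp_ratio = 1,
                                vss = 1, clpo = 1, peff = 1e-4),
               "descending")
  expect_error(compound_profile("x", "neutral", mw = 100, fu = 0.5,
                                bp_ratio = 1, vss = 1, clpo = 1,
                                peff = 1e-4, jmax_pgp = 100),
               "all present or all absent")
})
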
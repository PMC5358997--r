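# Virtual clinical trials: minimal PBPK disposition coupled to the gut
# model, population simulation, PK summaries, formulation/state comparison
# and parameter estimation against observed plasma data.

#' Construct a trial design
#'
#' @param compound a `compound_profile`.
#' @param dose_mg dose, mg.
#' @param formulation `"single"` or `"FDC"`.
#' @param prandial_state `"fasted"` or `"fed"`.
#' @param n_subjects number of virtual subjects.
#' @param duration_h simulation horizon, h.
#' @param sampling_times_h plasma sampling grid, h.
#' @param seed trial seed (controls the population draw).
#' @param cv_set population CVs passed to [gen_population()].
#' @param release a `release_model`, `"instant"`, or `NULL` to use the
#'   bundled preset for the compound/formulation/prandial state.
#' @param peff_scale optional Peff scaling (combination/single Papp ratio);
#'   default 1 (off).
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(compound, dose_mg = compound$dose_mg,
                         formulation = c("single", "FDC"),
                         prandial_state = c("fasted", "fed"),
                         n_subjects = 50, duration_h = 24,
                         sampling_times_h = seq(0.25, 24, by = 0.25),
                         seed = 1,
                         cv_set = list(cl = 0.3, vss = 0.3,
                                       gut_cyp = 0.4, liver_cyp = 0.4),
                         release = NULL, peff_scale = 1) {
  formulation <- match.arg(formulation)
  prandial_state <- match.arg(prandial_state)
  stopifnot(inherits(compound, "compound_profile"))
  if (!is.numeric(dose_mg) || length(dose_mg) != 1L || dose_mg < 0)
    stop("`dose_mg` must be a single number >= 0", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  stop_if_not_scalar_pos(duration_h, "duration_h")
  if (is.null(release))
    release <- preset_release(compound$name, formulation, prandial_state)
  structure(list(compound = compound, dose_mg = dose_mg,
                 formulation = formulation, prandial_state = prandial_state,
                 n_subjects = n_subjects, duration_h = duration_h,
                 sampling_times_h = sampling_times_h, seed = seed,
                 cv_set = cv_set, release = release,
                 peff_scale = peff_scale),
            class = "trial_design")
}

default_subject <- function() {
  data.frame(subject_id = 1L, body_weight = 70, cl_mult = 1, vss_mult = 1,
             gut_cyp_mult = 1, liver_cyp_mult = 1)
}

#' Simulate one subject's plasma profile
#'
#' Solves the full coupled system in one pass: gut absorption feeding a
#' well-stirred liver compartment (first-pass extraction) that drains into a
#' central compartment of volume `Vss * body weight` with hepatic (and
#' optionally renal) elimination.  Plasma concentration is the central blood
#' concentration divided by the blood-to-plasma ratio.
#'
#' @param compound a `compound_profile`.
#' @param design a `trial_design`.
#' @param subject one-row data frame of subject parameters (multipliers); a
#'   reference subject when `NULL`.
#' @param sys a `system_physiology`.
#' @param physiology a `gut_physiology`; built from the design's prandial
#'   state when `NULL`.
#' @param absorption `"gut"` (mechanistic) or `"bolus"` (dose placed in the
#'   central compartment at t = 0, for degenerate/validation
#'   configurations).
#' @param first_pass include the liver compartment; when `FALSE` elimination
#'   acts directly on the central compartment with clearance `cl_systemic`.
#' @param cl_systemic systemic (blood) clearance, L/h, used when
#'   `first_pass = FALSE`.
#' @param rtol,atol solver tolerances.
#' @return data frame `time_h`, `conc_ngml` with attributes `fa`, `fg`.
#' @export
simulate_subject <- function(compound, design, subject = NULL,
                             sys = system_physiology(),
                             physiology = NULL,
                             absorption = c("gut", "bolus"),
                             first_pass = TRUE, cl_systemic = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  absorption <- match.arg(absorption)
  if (is.null(subject)) subject <- default_subject()
  times <- sort(unique(c(0, design$sampling_times_h)))
  # Vss is plasma-referenced (standard reporting); the central state holds
  # blood amounts, so the blood-referenced volume is Vss * BW / (B:P)
  bp <- compound$bp_ratio
  v_plasma <- compound$vss * subject$body_weight * subject$vss_mult
  v_cen <- v_plasma / bp

  if (absorption == "bolus" && !first_pass) {
    cl <- cl_systemic %||% compound_hepatic(compound, sys,
                                            subject$liver_cyp_mult,
                                            subject$cl_mult)$cl_h
    k <- cl / v_cen
    conc <- design$dose_mg / v_cen * exp(-k * 0)  # shape via ODE below
    f <- function(t, y, p) list(-k * y)
    out <- deSolve::lsoda(c(a = design$dose_mg), times, f, NULL,
                          rtol = rtol, atol = atol)
    conc <- out[, 2] / v_cen / bp * 1000
    res <- data.frame(time_h = out[, 1], conc_ngml = conc)
    attr(res, "fa") <- 1; attr(res, "fg") <- 1
    return(res)
  }

  hep <- compound_hepatic(compound, sys, subject$liver_cyp_mult,
                          subject$cl_mult)
  if (is.null(physiology)) physiology <- build_physiology(design$prandial_state)
  p_gut <- gut_parameters(compound, design$release, physiology, sys,
                          gut_cyp_mult = subject$gut_cyp_mult,
                          peff_scale = design$peff_scale)
  v_liv <- sys$liver_volume
  q_h <- sys$q_h
  clu <- hep$fu_b * hep$clu_int
  cl_renal <- sys$renal_fraction / (1 - sys$renal_fraction) * hep$cl_h
  n_gut <- GUT_NSTATE
  y0 <- c(gut_init(if (absorption == "bolus") 0 else design$dose_mg,
                   p_gut$instant),
          a_liv = 0,
          a_cen = if (absorption == "bolus") design$dose_mg else 0)
  f <- function(t, y, p) {
    g <- gut_deriv(t, y[1:n_gut], p)
    c_liv <- y[n_gut + 1] / v_liv
    c_cen <- y[n_gut + 2] / v_cen
    d_liv <- g$portal + q_h * c_cen - q_h * c_liv - clu * c_liv
    d_cen <- q_h * c_liv - q_h * c_cen - cl_renal * c_cen
    list(c(g$dy, d_liv, d_cen))
  }
  out <- deSolve::lsoda(y0, times, f, p_gut, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("subject ODE solver failed near t = %.3f h (subject %s)",
                 out[nrow(out), 1], subject$subject_id), call. = FALSE)
  last <- out[nrow(out), -1]
  cum_abs <- last[26:32]; abs_tot <- sum(cum_abs) + last[41]
  portal_tot <- sum(last[33:39]) + last[41]
  res <- data.frame(time_h = out[, 1],
                    conc_ngml = out[, n_gut + 3] / v_cen / bp * 1000)
  attr(res, "fa") <- unname(if (design$dose_mg > 0)
    abs_tot / design$dose_mg else 0)
  attr(res, "fg") <- unname(if (abs_tot > 0) portal_tot / abs_tot else 1)
  attr(res, "f_h") <- hep$f_h
  res
}

#' Noncompartmental PK parameters of one profile
#'
#' @param profile data frame with `time_h` and `conc_ngml` (or two numeric
#'   vectors via `time_h`, `conc_ngml` arguments).
#' @param time_h,conc_ngml alternative vector interface.
#' @return list with `cmax` (ng/mL), `tmax` (h, first time of the maximum;
#'   `NA` for an all-zero profile) and `auc` (ng/mL h, linear trapezoid).
#' @export
pk_parameters <- function(profile = NULL, time_h = profile$time_h,
                          conc_ngml = profile$conc_ngml) {
  if (length(time_h) < 2L) stop("need >= 2 points", call. = FALSE)
  cmax <- max(conc_ngml)
  list(cmax = cmax,
       tmax = if (cmax <= 0) NA_real_ else time_h[which.max(conc_ngml)],
       auc = trapz(time_h, conc_ngml))
}

#' Summarize per-subject PK parameters
#'
#' Geometric mean and geometric SD for Cmax; median and (min-max) range for
#' AUC and tmax.
#'
#' @param cmax,auc,tmax per-subject values.
#' @return list of class `pk_summary`.
#' @export
summarize_pk <- function(cmax, auc, tmax) {
  if (any(cmax <= 0)) {
    warning("non-positive Cmax values excluded from geometric summary",
            call. = FALSE)
    keep <- cmax > 0
    cmax <- cmax[keep]
  }
  structure(list(
    cmax_geomean = geomean(cmax),
    cmax_gsd = if (length(cmax) > 1) gsd(cmax) else NA_real_,
    auc_median = stats::median(auc), auc_range = range(auc),
    tmax_median = stats::median(tmax, na.rm = TRUE),
    tmax_range = range(tmax, na.rm = TRUE),
    n = length(auc)), class = "pk_summary")
}

#' @export
print.pk_summary <- function(x, ...) {
  cat(sprintf("<pk_summary> n = %d\n", x$n))
  cat(sprintf("  Cmax geomean %.3g ng/mL (GSD %.3g)\n",
              x$cmax_geomean, x$cmax_gsd))
  cat(sprintf("  AUC median %.4g ng/mL h (%.4g-%.4g)\n",
              x$auc_median, x$auc_range[1], x$auc_range[2]))
  cat(sprintf("  tmax median %.3g h (%.3g-%.3g)\n",
              x$tmax_median, x$tmax_range[1], x$tmax_range[2]))
  invisible(x)
}

#' Run a virtual clinical trial
#'
#' Generates the population (seeded), simulates every subject through the
#' coupled gut + minimal PBPK model and summarizes the PK parameters.
#'
#' @param design a `trial_design`.
#' @param sys a `system_physiology`.
#' @param keep_profiles keep the per-subject concentration profiles.
#' @param rtol,atol solver tolerances (the trial default trades a little
#'   tolerance for speed; mass-balance work uses [simulate_gut()] at tighter
#'   settings).
#' @return an object of class `trial_result`: `subjects` (per-subject
#'   parameters, Cmax/tmax/AUC, fa, fg), `summary` (a `pk_summary`),
#'   `profiles` (long data frame) and the design.
#' @export
run_trial <- function(design, sys = system_physiology(),
                      keep_profiles = TRUE, rtol = 1e-6, atol = 1e-9) {
  pop <- gen_population(design$n_subjects, design$cv_set, design$seed)
  physiology <- build_physiology(design$prandial_state)
  rows <- vector("list", design$n_subjects)
  profs <- if (keep_profiles) vector("list", design$n_subjects)
  for (i in seq_len(design$n_subjects)) {
    prof <- tryCatch(
      simulate_subject(design$compound, design, subject = pop[i, ],
                       sys = sys, physiology = physiology,
                       rtol = rtol, atol = atol),
      error = function(e) stop(sprintf("subject %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    pk <- pk_parameters(prof)
    rows[[i]] <- data.frame(pop[i, ], cmax = pk$cmax, tmax = pk$tmax,
                            auc = pk$auc, fa = attr(prof, "fa"),
                            fg = attr(prof, "fg"))
    if (keep_profiles)
      profs[[i]] <- data.frame(subject = i, prof)
  }
  subjects <- do.call(rbind, rows)
  structure(list(
    subjects = subjects,
    summary = summarize_pk(subjects$cmax, subjects$auc, subjects$tmax),
    profiles = if (keep_profiles) do.call(rbind, profs),
    design = design), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  d <- x$design
  cat(sprintf("<trial_result> %s %g mg, %s, %s, n = %d\n",
              d$compound$name, d$dose_mg, d$formulation, d$prandial_state,
              d$n_subjects))
  print(x$summary)
  cat(sprintf("  mean fa %.3f, mean fg %.3f\n", mean(x$subjects$fa),
              mean(x$subjects$fg)))
  invisible(x)
}

#' Plot a trial result
#'
#' Mean plasma profile with 5th/95th percentile band.
#'
#' @param x a `trial_result` with kept profiles.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trial_result <- function(x, ...) {
  if (is.null(x$profiles)) stop("profiles were not kept", call. = FALSE)
  sp <- split(x$profiles$conc_ngml, x$profiles$time_h)
  t <- as.numeric(names(sp))
  o <- order(t); t <- t[o]; sp <- sp[o]
  m <- vapply(sp, mean, numeric(1))
  lo <- vapply(sp, stats::quantile, numeric(1), probs = 0.05)
  hi <- vapply(sp, stats::quantile, numeric(1), probs = 0.95)
  graphics::plot(t, m, type = "l", lwd = 2, ylim = c(0, max(hi)),
                 xlab = "time (h)", ylab = "plasma concentration (ng/mL)",
                 ...)
  graphics::lines(t, lo, lty = 2)
  graphics::lines(t, hi, lty = 2)
  invisible(x)
}

#' Compare a PK parameter between two trials
#'
#' Unpaired two-tailed t test (Welch by default) on the untransformed
#' per-subject values, plus the geometric-mean ratio with a 90% confidence
#' interval as a bioequivalence-style diagnostic.
#'
#' @param result_a,result_b `trial_result` objects.
#' @param parameter `"auc"`, `"cmax"` or `"tmax"`.
#' @param var_equal pooled-variance t test instead of Welch.
#' @return list of class `group_comparison` with `t`, `df`, `p_value`,
#'   `mean_a`, `mean_b`, `gmr` and `gmr_ci90`; when both groups have zero
#'   variance an exact-equality report is returned instead.
#' @export
compare_groups <- function(result_a, result_b,
                           parameter = c("auc", "cmax", "tmax"),
                           var_equal = FALSE) {
  parameter <- match.arg(parameter)
  a <- result_a$subjects[[parameter]]
  b <- result_b$subjects[[parameter]]
  if (!length(a) || !length(b)) stop("empty trial", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(structure(list(parameter = parameter, exact_equal =
                            isTRUE(all.equal(mean(a), mean(b))),
                          mean_a = mean(a), mean_b = mean(b),
                          t = NA_real_, df = NA_real_, p_value = NA_real_,
                          gmr = mean(b) / mean(a), gmr_ci90 = c(NA, NA)),
                     class = "group_comparison"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  la <- log(a[a > 0]); lb <- log(b[b > 0])
  lt <- stats::t.test(lb, la, conf.level = 0.90)
  structure(list(parameter = parameter, exact_equal = FALSE,
                 mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 gmr = exp(mean(lb) - mean(la)),
                 gmr_ci90 = exp(lt$conf.int)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: mean A %.4g vs B %.4g\n",
              x$parameter, x$mean_a, x$mean_b))
  if (isTRUE(x$exact_equal)) cat("  groups exactly equal (zero variance)\n")
  else cat(sprintf("  t = %.3f (df %.1f), p = %.3g; GMR %.3f (90%% CI %.3f-%.3f)\n",
                   x$t, x$df, x$p_value, x$gmr, x$gmr_ci90[1],
                   x$gmr_ci90[2]))
  invisible(x)
}

#' Define a parameter-estimation problem
#'
#' @param compound a `compound_profile`.
#' @param observed data frame with `time_h`, `conc_ngml` (multiple subjects
#'   may be pooled) and optionally `dose_mg`.
#' @param free names of free parameters, subset of
#'   `c("peff", "vss", "raf_pgp")`.
#' @param lower,upper named bounds for the free parameters (finite,
#'   positive).
#' @param dose_mg dose of the observed study, mg.
#' @param prandial_state,formulation,release study conditions for the
#'   simulation (see [trial_design()]).
#' @param weighting `"uniform"`, `"1/y"` or `"1/y2"` residual weighting.
#' @param n_starts number of multi-start optimizations.
#' @param seed optimizer seed (start placement).
#' @return list of class `estimation_problem`.
#' @export
estimation_problem <- function(compound, observed,
                               free = c("peff", "vss"),
                               lower, upper,
                               dose_mg = compound$dose_mg,
                               prandial_state = "fasted",
                               formulation = "single", release = NULL,
                               weighting = c("uniform", "1/y", "1/y2"),
                               n_starts = 5, seed = 1) {
  weighting <- match.arg(weighting)
  if (!all(free %in% c("peff", "vss", "raf_pgp")))
    stop("free parameters must be among peff, vss, raf_pgp", call. = FALSE)
  if (!all(c("time_h", "conc_ngml") %in% names(observed)) ||
      nrow(observed) == 0)
    stop("observed data must have time_h and conc_ngml", call. = FALSE)
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(unlist(lower))) || any(!is.finite(unlist(upper))) ||
      any(unlist(lower) <= 0) || any(unlist(upper) <= unlist(lower)))
    stop("bounds must be finite, positive and ordered", call. = FALSE)
  structure(list(compound = compound, observed = observed, free = free,
                 lower = unlist(lower), upper = unlist(upper),
                 dose_mg = dose_mg, prandial_state = prandial_state,
                 formulation = formulation, release = release,
                 weighting = weighting, n_starts = n_starts, seed = seed),
            class = "estimation_problem")
}

# predict the reference-subject profile at the observed times for candidate
# parameter values
predict_for_estimate <- function(problem, pars) {
  cmp <- problem$compound
  for (nm in names(pars)) cmp[[nm]] <- unname(pars[nm])
  design <- trial_design(cmp, dose_mg = problem$dose_mg,
                         formulation = problem$formulation,
                         prandial_state = problem$prandial_state,
                         n_subjects = 1,
                         sampling_times_h = sort(unique(problem$observed$time_h)),
                         release = problem$release)
  prof <- simulate_subject(cmp, design, rtol = 1e-6, atol = 1e-9)
  prof$conc_ngml[match(problem$observed$time_h, prof$time_h)]
}

#' Estimate uncertain model parameters from observed plasma data
#'
#' Bounded weighted least squares of simulated versus observed
#' concentrations, with seeded multi-start local optimization (L-BFGS-B on
#' the log scale).
#'
#' @param problem an `estimation_problem`.
#' @return list of class `estimation_result`: `par` (best-fit values),
#'   `objective`, `starts` (per-start table) and `convergence`.
#' @export
estimate_parameters <- function(problem) {
  obs <- problem$observed$conc_ngml
  w <- switch(problem$weighting,
              uniform = rep(1, length(obs)),
              "1/y" = 1 / pmax(obs, 1e-6),
              "1/y2" = 1 / pmax(obs, 1e-6)^2)
  objective <- function(lp) {
    pars <- exp(lp); names(pars) <- problem$free
    pred <- tryCatch(predict_for_estimate(problem, pars),
                     error = function(e) rep(NA_real_, length(obs)))
    if (any(!is.finite(pred))) return(1e12)
    sum(w * (obs - pred)^2)
  }
  llo <- log(problem$lower); lup <- log(problem$upper)
  starts <- with_seed(seed_stream(problem$seed, "estimation"), {
    s <- matrix(stats::runif((problem$n_starts - 1) * length(llo)),
                ncol = length(llo))
    rbind((llo + lup) / 2,
          sweep(sweep(s, 2, lup - llo, "*"), 2, llo, "+"))
  })
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = llo, upper = lup,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimization starts failed", call. = FALSE)
  fits <- fits[ok]
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  par <- exp(best$par); names(par) <- problem$free
  start_tab <- data.frame(
    start = seq_along(fits),
    objective = vals,
    t(vapply(fits, function(f) exp(f$par), numeric(length(problem$free)))))
  names(start_tab)[-(1:2)] <- problem$free
  structure(list(par = par, objective = best$value, starts = start_tab,
                 convergence = best$convergence),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result>\n  best fit:",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
      sprintf("\n  objective %.6g (%d starts)\n", x$objective,
              nrow(x$starts)))
  invisible(x)
}
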
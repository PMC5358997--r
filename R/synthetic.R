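# Seeded synthetic-data generators for every input the pipeline consumes:
# dissolution curves, Caco-2 transport runs, observed plasma tables and
# virtual populations.  Noiseless generators are exact inverses of the
# corresponding analysis operations, so round-trip tests have known truth.

#' Dissolution ground truth
#'
#' Parameters of a Weibull-shaped dissolution curve
#' `F(t) = plateau * (1 - exp(-(t/td)^beta))` plus i.i.d. Gaussian sampling
#' noise (truncated at 0).  First-order release is the `beta = 1` case.
#'
#' @param plateau_percent plateau, percent of dose (0-110).
#' @param weibull_td time scale, min.
#' @param weibull_beta shape, dimensionless.
#' @param noise_sd additive noise SD, percent of dose.
#' @param n_replicates replicate vessels.
#' @param sampling_times min, strictly increasing, first > 0.
#' @param medium,label,dose_mg metadata carried onto the generated profile.
#' @return an object of class `dissolution_truth`.
#' @export
dissolution_truth <- function(plateau_percent, weibull_td, weibull_beta = 1,
                              noise_sd = 0, n_replicates = 3,
                              sampling_times = c(2, 5, 10, 15, 20, 30,
                                                 45, 60, 90, 120),
                              medium = "custom", label = "formulation",
                              dose_mg = NA_real_) {
  stop_if_not_scalar_pos(plateau_percent, "plateau_percent")
  if (plateau_percent > 110) stop("plateau above 110% of dose", call. = FALSE)
  stop_if_not_scalar_pos(weibull_td, "weibull_td")
  stop_if_not_scalar_pos(weibull_beta, "weibull_beta")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  assert_increasing(sampling_times, "sampling_times")
  if (sampling_times[1] <= 0)
    stop("first sampling time must be > 0", call. = FALSE)
  structure(list(plateau_percent = plateau_percent, weibull_td = weibull_td,
                 weibull_beta = weibull_beta, noise_sd = noise_sd,
                 n_replicates = n_replicates,
                 sampling_times = sampling_times, medium = medium,
                 label = label, dose_mg = dose_mg),
            class = "dissolution_truth")
}

#' Generate a dissolution profile from ground truth
#'
#' @param truth a `dissolution_truth`.
#' @param seed integer seed (named stream `"dissolution"`).
#' @return a `dissolution_profile`; with `noise_sd = 0` the replicate curves
#'   equal the Weibull mean exactly.
#' @export
gen_dissolution <- function(truth, seed = 1) {
  mu <- truth$plateau_percent *
    (1 - exp(-(truth$sampling_times / truth$weibull_td)^truth$weibull_beta))
  pct <- with_seed(seed_stream(seed, "dissolution"), {
    m <- matrix(rep(mu, truth$n_replicates), ncol = truth$n_replicates)
    if (truth$noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, truth$noise_sd),
                      ncol = truth$n_replicates)
    pmax(m, 0)
  })
  out <- dissolution_profile(truth$sampling_times, pmin(pct, 115),
                             medium = truth$medium, label = truth$label,
                             dose_mg = truth$dose_mg)
  attr(out, "truth") <- truth
  out
}

#' Bundled dissolution presets
#'
#' Weibull ground truths emulating the eight measured immediate-release
#' profiles (amlodipine 5 mg and atorvastatin 10 mg, single and FDC, in
#' FaSSIF and FeSSIF), reaching the reported plateaus: 94.9 / 101.2 / 87.9 /
#' 79.9 percent for amlodipine and 80.0 / 89.3 / 76.9 / 86.2 percent for
#' atorvastatin.  FaSSIF time scales are fast (amlodipine exceeds 50%
#' dissolution by 5 min and 85% by 15 min); FeSSIF time scales are slower,
#' consistent with neither fed-state amlodipine formulation reaching 85%
#' within 15 min.
#'
#' @param name preset name `"<compound>-<medium>-<formulation>"`, e.g.
#'   `"amlodipine-FaSSIF-single"`; `NULL` lists all presets.
#' @param noise_sd,n_replicates noise structure applied to the preset.
#' @return a `dissolution_truth`, or a named list of them.
#' @export
dissolution_preset <- function(name = NULL, noise_sd = 2, n_replicates = 3) {
  spec <- list(
    "amlodipine-FaSSIF-single"  = c(94.9,  4),
    "amlodipine-FaSSIF-FDC"     = c(101.2, 4),
    "amlodipine-FeSSIF-single"  = c(87.9,  25),
    "amlodipine-FeSSIF-FDC"     = c(79.9,  18),
    "atorvastatin-FaSSIF-single" = c(80.0, 6),
    "atorvastatin-FaSSIF-FDC"    = c(89.3, 6),
    "atorvastatin-FeSSIF-single" = c(76.9, 60),
    "atorvastatin-FeSSIF-FDC"    = c(86.2, 60))
  build <- function(nm) {
    parts <- strsplit(nm, "-", fixed = TRUE)[[1]]
    dissolution_truth(spec[[nm]][1], spec[[nm]][2], weibull_beta = 1,
                      noise_sd = noise_sd, n_replicates = n_replicates,
                      medium = parts[2],
                      label = paste(parts[1], parts[3], sep = "-"),
                      dose_mg = if (parts[1] == "amlodipine") 5 else 10)
  }
  if (is.null(name)) {
    out <- lapply(names(spec), build)
    names(out) <- names(spec)
    return(out)
  }
  if (!name %in% names(spec))
    stop("unknown preset; see dissolution_preset() for the list",
         call. = FALSE)
  build(name)
}

#' Transport-run ground truth
#'
#' Sink-regime monolayer transport: receiver mass grows linearly at
#' `papp_true * c0 * area`, and recorded concentrations reflect sampling
#' withdrawal and replacement dilution (the exact inverse of
#' [cumulative_mass()]).
#'
#' @param papp_true apparent permeability, cm/s.
#' @param c0 donor concentration, ug/mL.
#' @param area cm^2; `donor_volume`, `receiver_volume`, `sample_volume` mL.
#' @param donor_volume,receiver_volume,sample_volume compartment and aliquot
#'   volumes, mL.
#' @param sampling_times min.
#' @param noise_cv multiplicative measurement noise CV (fraction).
#' @return an object of class `transport_truth`.
#' @export
transport_truth <- function(papp_true, c0 = 20, area = 1.12,
                            donor_volume = 0.5, receiver_volume = 1.5,
                            sample_volume = 0.2,
                            sampling_times = c(15, 30, 45, 60, 90, 120),
                            noise_cv = 0) {
  if (papp_true < 0) stop("papp_true must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(c0, "c0")
  stop_if_not_scalar_pos(area, "area")
  stop_if_not_scalar_pos(donor_volume, "donor_volume")
  stop_if_not_scalar_pos(receiver_volume, "receiver_volume")
  if (sample_volume <= 0 || sample_volume >= receiver_volume)
    stop("need 0 < sample_volume < receiver_volume", call. = FALSE)
  assert_increasing(sampling_times, "sampling_times")
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(papp_true = papp_true, c0 = c0, area = area,
                 donor_volume = donor_volume,
                 receiver_volume = receiver_volume,
                 sample_volume = sample_volume,
                 sampling_times = sampling_times, noise_cv = noise_cv),
            class = "transport_truth")
}

#' Generate a transport experiment from ground truth
#'
#' @param truth a `transport_truth`.
#' @param seed integer seed (named stream `"transport"`).
#' @param direction transport direction label.
#' @return a `transport_experiment`; a noiseless run recovers `papp_true`
#'   exactly through [apparent_permeability()].
#' @export
gen_transport <- function(truth, seed = 1, direction = "A->B") {
  t_min <- truth$sampling_times
  mass_true <- truth$papp_true * truth$c0 * truth$area * 60 * t_min  # ug
  # invert the withdrawal correction to get recorded concentrations
  conc <- numeric(length(t_min))
  acc <- 0
  for (i in seq_along(t_min)) {
    conc[i] <- (mass_true[i] - truth$sample_volume * acc) /
      truth$receiver_volume
    acc <- acc + conc[i]
  }
  conc <- with_seed(seed_stream(seed, "transport"), {
    if (truth$noise_cv > 0)
      conc * stats::rlnorm(length(conc),
                           meanlog = -cv_to_sdlog(truth$noise_cv)^2 / 2,
                           sdlog = cv_to_sdlog(truth$noise_cv))
    else conc
  })
  donor_end <- (truth$c0 * truth$donor_volume - mass_true[length(mass_true)]) /
    truth$donor_volume
  out <- transport_experiment(direction = direction, c0 = truth$c0,
                              area = truth$area,
                              donor_volume = truth$donor_volume,
                              receiver_volume = truth$receiver_volume,
                              sample_volume = truth$sample_volume,
                              times = t_min,
                              receiver_concentrations = pmax(conc, 0),
                              donor_conc_t0 = truth$c0,
                              donor_conc_end = donor_end)
  attr(out, "truth") <- truth
  out
}

#' Generate a virtual population
#'
#' Per-subject multipliers for clearance, Vss and hepatic / gut CYP3A4
#' abundance, drawn log-normal with arithmetic mean 1.
#'
#' @param n number of subjects.
#' @param cv_set named list of coefficients of variation: `cl`, `vss`,
#'   `gut_cyp`, `liver_cyp`.
#' @param seed integer seed (named stream `"population"`).
#' @param body_weight kg, applied to all subjects.
#' @return data frame with one row per subject: `subject_id`, `body_weight`,
#'   `cl_mult`, `vss_mult`, `gut_cyp_mult`, `liver_cyp_mult`.
#' @export
gen_population <- function(n,
                           cv_set = list(cl = 0.3, vss = 0.3,
                                         gut_cyp = 0.4, liver_cyp = 0.4),
                           seed = 1, body_weight = 70) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(unlist(cv_set) < 0)) stop("CVs must be >= 0", call. = FALSE)
  with_seed(seed_stream(seed, "population"), {
    data.frame(subject_id = seq_len(n), body_weight = body_weight,
               cl_mult = rlnorm_mean1(n, cv_set$cl %||% 0),
               vss_mult = rlnorm_mean1(n, cv_set$vss %||% 0),
               gut_cyp_mult = rlnorm_mean1(n, cv_set$gut_cyp %||% 0),
               liver_cyp_mult = rlnorm_mean1(n, cv_set$liver_cyp %||% 0))
  })
}

#' Plasma-data ground truth
#'
#' Describes a synthetic single-dose oral study: per-subject log-normal CL
#' and Vss variability around the compound file plus multiplicative residual
#' assay error.  A stand-in for digitized clinical plasma sets.
#'
#' @param compound a `compound_profile`.
#' @param dose_mg dose, mg.
#' @param n_subjects subjects.
#' @param cv_cl,cv_vss between-subject log-normal CVs.
#' @param residual_cv multiplicative residual error CV (fraction).
#' @param prandial_state,formulation study conditions.
#' @param sampling_times_h plasma sampling grid, h.
#' @return an object of class `plasma_truth`.
#' @export
plasma_truth <- function(compound, dose_mg = compound$dose_mg,
                         n_subjects = 12, cv_cl = 0.3, cv_vss = 0.3,
                         residual_cv = 0.1,
                         prandial_state = "fasted", formulation = "single",
                         sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4, 6, 8,
                                              10, 12, 16, 24)) {
  stopifnot(inherits(compound, "compound_profile"))
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(c(cv_cl, cv_vss, residual_cv) < 0))
    stop("CVs must be >= 0", call. = FALSE)
  structure(list(compound = compound, dose_mg = dose_mg,
                 n_subjects = n_subjects, cv_cl = cv_cl, cv_vss = cv_vss,
                 residual_cv = residual_cv, prandial_state = prandial_state,
                 formulation = formulation,
                 sampling_times_h = sampling_times_h),
            class = "plasma_truth")
}

#' Generate observed plasma tables
#'
#' Forward-simulates each subject with the trial engine (per-subject
#' log-normal CL and Vss multipliers) and applies multiplicative residual
#' error.  Bit-reproducible under a fixed seed.
#'
#' @param truth a `plasma_truth`.
#' @param seed integer seed (named stream `"plasma"`).
#' @return data frame with columns `subject`, `time_h`, `conc_ngml`; the
#'   subject multipliers are attached as attribute `"subjects"`.
#' @export
gen_plasma <- function(truth, seed = 1) {
  cmp <- truth$compound
  subs <- with_seed(seed_stream(seed, "plasma"), {
    data.frame(subject_id = seq_len(truth$n_subjects), body_weight = 70,
               cl_mult = rlnorm_mean1(truth$n_subjects, truth$cv_cl),
               vss_mult = rlnorm_mean1(truth$n_subjects, truth$cv_vss),
               gut_cyp_mult = 1, liver_cyp_mult = 1)
  })
  design <- trial_design(cmp, dose_mg = truth$dose_mg,
                         formulation = truth$formulation,
                         prandial_state = truth$prandial_state,
                         n_subjects = truth$n_subjects,
                         sampling_times_h = truth$sampling_times_h,
                         seed = seed)
  rows <- lapply(seq_len(truth$n_subjects), function(i) {
    prof <- simulate_subject(cmp, design, subject = subs[i, ])
    keep <- prof$time_h %in% truth$sampling_times_h
    data.frame(subject = i, time_h = prof$time_h[keep],
               conc_ngml = prof$conc_ngml[keep])
  })
  d <- do.call(rbind, rows)
  if (truth$residual_cv > 0) {
    s <- cv_to_sdlog(truth$residual_cv)
    d$conc_ngml <- with_seed(seed_stream(seed, "plasma-residual"),
      d$conc_ngml * stats::rlnorm(nrow(d), -s^2 / 2, s))
  }
  attr(d, "subjects") <- subs
  attr(d, "truth") <- truth
  d
}

#' Write a generated table with its truth sidecar
#'
#' Writes the data as CSV and the generating parameters as a YAML sidecar
#' (`<path>.truth.yaml`), so downstream stages remain testable against known
#' ground truth.
#'
#' @param x a generated object with a `"truth"` attribute, or a data frame.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(x, path) {
  truth <- attr(x, "truth")
  if (inherits(x, "dissolution_profile")) write_dissolution_csv(x, path)
  else if (inherits(x, "transport_experiment")) {
    utils::write.csv(data.frame(direction = x$direction, time_min = x$times,
                                receiver_conc = x$receiver_concentrations,
                                c0 = x$c0, area = x$area,
                                donor_volume = x$donor_volume,
                                receiver_volume = x$receiver_volume,
                                sample_volume = x$sample_volume,
                                donor_conc_t0 = x$donor_conc_t0,
                                donor_conc_end = x$donor_conc_end),
                     path, row.names = FALSE)
  } else utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (!is.null(truth)) {
    t2 <- truth
    t2$compound <- NULL
    class(t2) <- NULL
    yaml::write_yaml(t2, paste0(path, ".truth.yaml"))
  }
  invisible(path)
}
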
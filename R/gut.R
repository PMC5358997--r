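# Segmented-gut absorption model: stomach + 7 small-intestinal segments +
# colon.  Luminal release driven by the in vitro dissolution profile,
# first-order transit of solid and dissolved drug, permeability-limited
# uptake into enterocytes, enterocyte CYP3A4 metabolism with an ab-orally
# decreasing abundance gradient, saturable P-gp efflux back to the lumen,
# and basolateral transfer to portal blood.

SI_SEGMENTS <- c("duodenum", "jejunum I", "jejunum II",
                 "ileum I", "ileum II", "ileum III", "ileum IV")

#' Build gut physiology for a prandial state
#'
#' Stomach + seven small-intestinal segments + colon.  Transit constants
#' follow the standard compartmental absorption and transit convention:
#' equal first-order rates over the seven segments giving a mean
#' small-intestinal transit of about 3.3 h.  CYP3A4 abundance weights
#' decrease steeply (halving per segment) from duodenum to distal ileum
#' (expression is greatest duodenally and falls ab orally, with reported
#' proximal-to-distal protein ratios of an order of magnitude); P-gp
#' weights increase linearly.  The fed
#' state differs only in gastric emptying half-life (0.25 h fasted vs 1.0 h
#' fed), luminal volumes (+50%) and the dissolution-medium mapping
#' (fasted -> FaSSIF, fed -> FeSSIF).
#'
#' @param prandial_state `"fasted"` or `"fed"`.
#' @param si_transit_h mean small-intestinal transit time, h.
#' @param q_gut total villous (enterocyte) blood flow, L/h.
#' @param enterocyte_volume_l total small-intestinal enterocyte volume, L.
#' @param cyp3a4_weights,pgp_weights optional user overrides (length 7,
#'   normalized internally; CYP weights must decrease ab orally, P-gp
#'   weights must not decrease).
#' @param colon_ka_scale scaling of colonic absorption rate relative to the
#'   small-intestinal permeability scaling (low mucosal surface area);
#'   set to 0 to disable colonic absorption.
#' @return an object of class `gut_physiology`.
#' @export
build_physiology <- function(prandial_state = c("fasted", "fed"),
                             si_transit_h = 3.3, q_gut = 18,
                             enterocyte_volume_l = 0.4,
                             cyp3a4_weights = NULL, pgp_weights = NULL,
                             colon_ka_scale = 0.1) {
  prandial_state <- match.arg(prandial_state)
  fed <- prandial_state == "fed"
  length_cm <- c(30, 62, 62, 31, 31, 31, 32)
  radius_cm <- rep(1.25, 7)
  area_cm2 <- 2 * pi * radius_cm * length_cm
  vol_scale <- if (fed) 1.5 else 1.0
  segments <- data.frame(
    name = SI_SEGMENTS,
    radius_cm = radius_cm,
    length_cm = length_cm,
    area_cm2 = area_cm2,
    transit_rate = rep(7 / si_transit_h, 7),
    luminal_volume_ml = vol_scale * 105 * length_cm / sum(length_cm),
    pH = if (fed) c(5.4, 5.6, 5.9, 6.3, 6.7, 7.0, 7.2)
         else c(6.4, 6.5, 6.7, 7.0, 7.2, 7.4, 7.4),
    enterocyte_volume_l = enterocyte_volume_l * area_cm2 / sum(area_cm2),
    enterocyte_flow_lh = q_gut * area_cm2 / sum(area_cm2))
  w_cyp <- cyp3a4_weights %||% 2^-(0:6)
  w_pgp <- pgp_weights %||% (1:7)
  if (length(w_cyp) != 7 || any(w_cyp < 0))
    stop("cyp3a4_weights must be 7 nonnegative values", call. = FALSE)
  if (length(w_pgp) != 7 || any(w_pgp < 0))
    stop("pgp_weights must be 7 nonnegative values", call. = FALSE)
  w_cyp <- w_cyp / sum(w_cyp)
  w_pgp <- w_pgp / sum(w_pgp)
  if (any(diff(w_cyp) >= 0))
    stop("cyp3a4_weights must strictly decrease ab orally", call. = FALSE)
  if (any(diff(w_pgp) < 0))
    stop("pgp_weights must be non-decreasing ab orally", call. = FALSE)
  structure(list(
    prandial_state = prandial_state,
    gastric_emptying_halflife_h = if (fed) 1.0 else 0.25,
    stomach_volume_ml = vol_scale * 50,
    stomach_pH = if (fed) 4.0 else 1.5,
    segments = segments,
    cyp3a4_weights = w_cyp,
    pgp_weights = w_pgp,
    colon = list(radius_cm = 2.5, transit_rate = 1 / 24,
                 luminal_volume_ml = vol_scale * 100, pH = 6.8,
                 ka_scale = colon_ka_scale),
    medium = if (fed) "FeSSIF" else "FaSSIF",
    medium_pH = if (fed) 5.0 else 6.5,
    q_gut = q_gut),
    class = "gut_physiology")
}

#' @export
print.gut_physiology <- function(x, ...) {
  cat(sprintf("<gut_physiology> %s state (medium %s)\n", x$prandial_state,
              x$medium))
  cat(sprintf("  gastric emptying t1/2 %.2f h; SI transit %.2f h; Qgut %.1f L/h\n",
              x$gastric_emptying_halflife_h,
              7 / x$segments$transit_rate[1], x$q_gut))
  print(x$segments[c("name", "radius_cm", "length_cm", "transit_rate",
                     "luminal_volume_ml")], row.names = FALSE)
  invisible(x)
}

#' Read / write gut physiology as YAML
#'
#' @param physiology a `gut_physiology`.
#' @param path file path.
#' @export
write_physiology_yaml <- function(physiology, path) {
  y <- unclass(physiology)
  y$segments <- as.list(y$segments)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_physiology_yaml
#' @export
read_physiology_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  y$segments <- as.data.frame(y$segments)
  structure(y, class = "gut_physiology")
}

#' Segmental absorption rate constant
#'
#' `ka = 2 * Peff / radius`, the cylinder surface-to-volume scaling of
#' effective permeability, converted from 1/s to 1/h.
#'
#' @param peff effective permeability, cm/s.
#' @param radius segment radius, cm.
#' @return first-order absorption rate constant, 1/h.
#' @export
segment_ka <- function(peff, radius) {
  stop_if_not_scalar_pos(radius, "radius")
  if (any(peff < 0)) stop("peff must be >= 0", call. = FALSE)
  2 * peff / radius * 3600
}

#' Michaelis-Menten P-gp efflux rate
#'
#' `v = RAF * weight * Jmax * area * C / (Km + C)`, pmol/min.
#'
#' @param c_ent unbound enterocyte concentration, uM.
#' @param jmax maximal transport rate, pmol/cm^2/min.
#' @param km Michaelis constant, uM.
#' @param raf relative activity factor.
#' @param weight segmental abundance weight.
#' @param area segment surface area, cm^2.
#' @return efflux rate, pmol/min.
#' @export
pgp_efflux_rate <- function(c_ent, jmax, km, raf, weight, area) {
  if (any(c_ent < 0)) stop("concentration must be >= 0", call. = FALSE)
  raf * weight * jmax * area * c_ent / (km + c_ent)
}

# Precompute all gut rate constants for a compound + physiology; returns a
# parameter list used by the shared derivative function.
gut_parameters <- function(compound, release, physiology,
                           sys = system_physiology(),
                           gut_cyp_mult = 1, peff_scale = 1) {
  seg <- physiology$segments
  peff <- compound$peff * peff_scale
  ka <- segment_ka(peff, seg$radius_cm[1]) *
    seg$radius_cm[1] / seg$radius_cm        # per-segment radii
  ka_colon <- segment_ka(peff, physiology$colon$radius_cm) *
    physiology$colon$ka_scale
  has_cyp <- !is.null(compound$clint_3a4)
  clint_seg <- if (has_cyp)
    compound$clint_3a4 * physiology$cyp3a4_weights *
      sys$gut_cyp3a4_abundance * gut_cyp_mult * 60 / 1e6   # L/h per segment
  else rep(0, 7)
  has_pgp <- !is.null(compound$jmax_pgp)
  vmax_mgh <- if (has_pgp)
    compound$raf_pgp * physiology$pgp_weights * compound$jmax_pgp *
      seg$area_cm2 * 60 * compound$mw * 1e-9               # mg/h saturated
  else rep(0, 7)
  # Gastric release scaling: the in vitro profile was measured in simulated
  # *intestinal* fluid, so in the stomach the release hazard is scaled by the
  # ionization-driven solubility ratio S(stomach pH)/S(medium pH), with total
  # solubility proportional to 1/fraction un-ionized.  Acids (atorvastatin)
  # barely dissolve at gastric pH; bases (amlodipine) dissolve faster there.
  stomach_scale <- if (compound$ionization_class == "neutral") 1 else
    min(fraction_unionized(compound, physiology$medium_pH %||% 6.5) /
          fraction_unionized(compound, physiology$stomach_pH), 100)
  instant <- identical(release, "instant")
  list(
    instant = instant,
    hazard = if (instant) function(t_h) 0
             else function(t_h) release_hazard(release, t_h * 60) * 60, # 1/h
    stomach_scale = stomach_scale,
    kge = log(2) / physiology$gastric_emptying_halflife_h,
    kt = seg$transit_rate,
    ktc = physiology$colon$transit_rate,
    ka = ka, ka_colon = ka_colon,
    kmet = clint_seg / seg$enterocyte_volume_l,     # 1/h
    kbl = seg$enterocyte_flow_lh / seg$enterocyte_volume_l,  # 1/h
    vmax_mgh = vmax_mgh, km_um = compound$km_pgp %||% 1,
    vent = seg$enterocyte_volume_l, mw = compound$mw)
}

# Gut state vector layout (amounts in mg):
#  1 stomach solid, 2 stomach dissolved, 3:9 SI solid, 10:16 SI dissolved,
#  17:23 enterocyte, 24 colon solid, 25 colon dissolved,
#  26:32 cumulative net absorbed per SI segment, 33:39 cumulative to portal
#  per SI segment, 40 cumulative gut metabolism, 41 colonic absorbed,
#  42 exited colon.
GUT_NSTATE <- 42L

gut_init <- function(dose_mg, instant) {
  y <- numeric(GUT_NSTATE)
  if (instant) y[2] <- dose_mg else y[1] <- dose_mg
  y
}

# Derivatives of the gut states; returns list(dy, portal_rate_mg_h).
gut_deriv <- function(t, y, p) {
  h <- p$hazard(t)
  h_st <- min(h * p$stomach_scale, 600)   # 1/h, gastric solubility scaling
  st_solid <- y[1]; st_diss <- y[2]
  si_solid <- y[3:9]; si_diss <- y[10:16]; si_ent <- y[17:23]
  co_solid <- y[24]; co_diss <- y[25]
  c_um <- 1000 * si_ent / (p$mw * p$vent)
  pgp <- p$vmax_mgh * c_um / (p$km_um + c_um)
  abs_flux <- p$ka * si_diss
  met <- p$kmet * si_ent
  bl <- p$kbl * si_ent
  co_abs_flux <- p$ka_colon * co_diss
  dy <- numeric(GUT_NSTATE)
  dy[1] <- -(h_st + p$kge) * st_solid
  dy[2] <- h_st * st_solid - p$kge * st_diss
  dy[3:9] <- c(p$kge * st_solid, p$kt[-7] * si_solid[-7]) -
    (h + p$kt) * si_solid
  dy[10:16] <- c(p$kge * st_diss, p$kt[-7] * si_diss[-7]) +
    h * si_solid - p$kt * si_diss - abs_flux + pgp
  dy[17:23] <- abs_flux - pgp - met - bl
  dy[24] <- p$kt[7] * si_solid[7] - (h + p$ktc) * co_solid
  dy[25] <- p$kt[7] * si_diss[7] + h * co_solid - p$ktc * co_diss -
    co_abs_flux
  dy[26:32] <- abs_flux - pgp
  dy[33:39] <- bl
  dy[40] <- sum(met)
  dy[41] <- co_abs_flux
  dy[42] <- p$ktc * (co_solid + co_diss)
  list(dy = dy, portal = sum(bl) + co_abs_flux)
}

#' Simulate gut absorption of an oral dose
#'
#' Solves the coupled stomach / small-intestine / colon ODE system for one
#' dose and returns the fractions absorbed (fa) and escaping gut-wall
#' metabolism (fg), their regional decomposition, the portal input-rate time
#' course and a mass-conservation check.
#'
#' @param compound a `compound_profile`.
#' @param release a `release_model` (the in vitro profile for the medium
#'   matching the prandial state) or `"instant"` for immediate release of
#'   dissolved drug into the stomach.
#' @param dose_mg dose, mg.
#' @param physiology a `gut_physiology`; built for `prandial_state` when
#'   missing.
#' @param prandial_state used when `physiology` is missing.
#' @param sys a `system_physiology` (gut CYP3A4 abundance).
#' @param times output grid, h.
#' @param gut_cyp_mult subject multiplier on gut CYP3A4 abundance.
#' @param peff_scale optional scaling of Peff (e.g. by the combination/single
#'   Papp ratio); default 1 (off).
#' @param rtol,atol solver tolerances.
#' @return an object of class `absorption_result` with fields `fa`, `fg`,
#'   `regional_fa`, `regional_fg` (seven small-intestinal segments plus
#'   colon), `portal` (data frame `time_h`, `rate_mg_h`), `series` (full
#'   state time courses), `mass_check` (total recovered / dose) and
#'   `f_oral_gut` (= fa * fg).
#' @export
simulate_gut <- function(compound, release, dose_mg = compound$dose_mg,
                         physiology = NULL,
                         prandial_state = c("fasted", "fed"),
                         sys = system_physiology(),
                         times = seq(0, 24, by = 0.1),
                         gut_cyp_mult = 1, peff_scale = 1,
                         rtol = 1e-8, atol = 1e-10) {
  prandial_state <- match.arg(prandial_state)
  if (is.null(physiology)) physiology <- build_physiology(prandial_state)
  stop_if_not_scalar_pos(dose_mg, "dose_mg")
  p <- gut_parameters(compound, release, physiology, sys,
                      gut_cyp_mult, peff_scale)
  y0 <- gut_init(dose_mg, p$instant)
  f <- function(t, y, parms) {
    d <- gut_deriv(t, y, parms)
    list(d$dy, portal_rate = d$portal)
  }
  out <- deSolve::lsoda(y0, times, f, p, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("gut ODE solver failed near t = %.3f h",
                 out[nrow(out), 1]), call. = FALSE)
  if (min(out[, 2:(GUT_NSTATE + 1)]) < -1e-9)
    stop("negative state beyond tolerance in gut simulation", call. = FALSE)
  last <- out[nrow(out), -1]
  cum_abs <- last[26:32]; cum_portal <- last[33:39]
  abs_tot <- sum(cum_abs) + last[41]
  portal_tot <- sum(cum_portal) + last[41]
  fa <- abs_tot / dose_mg
  fg <- if (abs_tot > 0) portal_tot / abs_tot else 1
  regional_fa <- c(cum_abs, last[41]) / dose_mg
  regional_fg <- ifelse(cum_abs > 0, cum_portal / cum_abs, NA_real_)
  names(regional_fa) <- c(SI_SEGMENTS, "colon")
  regional_fg <- c(regional_fg, colon = 1)
  names(regional_fg) <- c(SI_SEGMENTS, "colon")
  mass_check <- (sum(last[c(1:25, 40:42)]) + sum(cum_portal)) / dose_mg
  structure(list(
    fa = unname(fa), fg = unname(fg),
    regional_fa = regional_fa, regional_fg = regional_fg,
    portal = data.frame(time_h = out[, 1],
                        rate_mg_h = out[, "portal_rate"]),
    series = as.data.frame(out),
    mass_check = unname(mass_check),
    f_oral_gut = unname(fa * fg),
    dose_mg = dose_mg, prandial_state = physiology$prandial_state),
    class = "absorption_result")
}

#' @export
print.absorption_result <- function(x, ...) {
  cat(sprintf("<absorption_result> %s state, dose %.3g mg\n",
              x$prandial_state, x$dose_mg))
  cat(sprintf("  fa = %.3f, fg = %.3f (fa*fg = %.3f); mass check %.8f\n",
              x$fa, x$fg, x$f_oral_gut, x$mass_check))
  cat("  regional fa:\n")
  print(round(x$regional_fa, 4))
  invisible(x)
}

#' Export an absorption result
#'
#' Writes the per-segment time series as CSV and the scalar summary (fa, fg,
#' regional vectors, mass check) as YAML.
#'
#' @param result an `absorption_result`.
#' @param series_csv,summary_yaml output paths (either may be `NULL`).
#' @export
write_absorption_result <- function(result, series_csv = NULL,
                                    summary_yaml = NULL) {
  if (!is.null(series_csv))
    utils::write.csv(result$series, series_csv, row.names = FALSE)
  if (!is.null(summary_yaml))
    yaml::write_yaml(list(fa = result$fa, fg = result$fg,
                          regional_fa = as.list(result$regional_fa),
                          regional_fg = as.list(result$regional_fg),
                          mass_check = result$mass_check,
                          dose_mg = result$dose_mg,
                          prandial_state = result$prandial_state),
                     summary_yaml)
  invisible(result)
}

#' Release model for a bundled formulation preset
#'
#' Builds the Weibull release model of a bundled dissolution preset for the
#' medium mapped to the prandial state (fasted -> FaSSIF, fed -> FeSSIF).
#'
#' @param compound_name `"amlodipine"` or `"atorvastatin"`.
#' @param formulation `"single"` or `"FDC"`.
#' @param prandial_state `"fasted"` or `"fed"`.
#' @return a `release_model`.
#' @export
preset_release <- function(compound_name,
                           formulation = c("single", "FDC"),
                           prandial_state = c("fasted", "fed")) {
  formulation <- match.arg(formulation)
  prandial_state <- match.arg(prandial_state)
  medium <- if (prandial_state == "fed") "FeSSIF" else "FaSSIF"
  truth <- dissolution_preset(paste(compound_name, medium, formulation,
                                    sep = "-"))
  release_model("weibull", plateau = truth$plateau_percent,
                td = truth$weibull_td, beta = truth$weibull_beta)
}
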
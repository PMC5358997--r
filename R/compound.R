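# Compound parameterization and scalar pharmacokinetic algebra:
# ionization, blood/plasma conversion, well-stirred hepatic extraction,
# oral bioavailability decomposition and retrograde intrinsic clearance.

#' Construct a compound profile
#'
#' Bundles the drug-specific physicochemical, binding, clearance, permeability
#' and transporter parameters used throughout the absorption and disposition
#' models.  Presets for amlodipine and atorvastatin are shipped as YAML files
#' (see [preset_compound()]).
#'
#' @param name compound name.
#' @param ionization_class one of `"diprotic_base"`, `"monoprotic_base"`,
#'   `"monoprotic_acid"`, `"neutral"`.
#' @param mw molecular weight, g/mol.
#' @param logp octanol-water log partition coefficient (descriptive).
#' @param pka acid dissociation constants, sorted descending; `NULL` for
#'   neutral compounds.
#' @param fu unbound fraction in plasma, (0, 1].
#' @param bp_ratio blood-to-plasma concentration ratio.
#' @param vss steady-state volume of distribution, L/kg.
#' @param clpo in vivo oral clearance.  The unit is carried by `clpo_units`
#'   (`"L/h"`, `"L/min"` or `"mL/min"`) and normalized internally to L/h;
#'   `clpo_basis` says whether it refers to plasma or blood concentrations.
#' @param clpo_units,clpo_basis unit and reference matrix tags for `clpo`.
#' @param clint_3a4 CYP3A4 intrinsic clearance, uL/min/pmol enzyme, or `NULL`
#'   when the compound is not a CYP3A4 substrate (gut-wall metabolism is then
#'   off and hepatic clearance is lumped).
#' @param peff human jejunal effective permeability, cm/s.
#' @param jmax_pgp,km_pgp,raf_pgp P-glycoprotein efflux kinetics:
#'   Jmax (pmol/cm^2/min), Km (uM) and relative activity factor.  Provide all
#'   three or none.
#' @param fa_assumed,fg_assumed fractions absorbed / escaping gut metabolism
#'   assumed when back-calculating hepatic intrinsic clearance from `clpo`.
#' @param dose_mg default single dose, mg.
#' @return an object of class `compound_profile`.
#' @export
compound_profile <- function(name,
                             ionization_class = c("diprotic_base",
                                                  "monoprotic_base",
                                                  "monoprotic_acid",
                                                  "neutral"),
                             mw, logp = NA_real_, pka = NULL,
                             fu, bp_ratio, vss,
                             clpo, clpo_units = c("L/h", "L/min", "mL/min"),
                             clpo_basis = c("plasma", "blood"),
                             clint_3a4 = NULL,
                             peff,
                             jmax_pgp = NULL, km_pgp = NULL, raf_pgp = NULL,
                             fa_assumed = 1, fg_assumed = 1,
                             dose_mg = NA_real_) {
  ionization_class <- match.arg(ionization_class)
  clpo_units <- match.arg(clpo_units)
  clpo_basis <- match.arg(clpo_basis)
  stop_if_not_scalar_pos(mw, "mw")
  if (!is.numeric(fu) || fu <= 0 || fu > 1)
    stop("`fu` must lie in (0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(bp_ratio, "bp_ratio")
  stop_if_not_scalar_pos(vss, "vss")
  stop_if_not_scalar_pos(clpo, "clpo")
  if (peff < 0) stop("`peff` must be >= 0", call. = FALSE)
  if (ionization_class != "neutral") {
    if (is.null(pka)) stop("`pka` required for ionizable compounds",
                           call. = FALSE)
    if (is.unsorted(rev(pka))) stop("`pka` must be sorted descending",
                                    call. = FALSE)
    if (ionization_class == "diprotic_base" && length(pka) != 2L)
      stop("diprotic base needs two pKa values", call. = FALSE)
  }
  pgp <- list(jmax_pgp, km_pgp, raf_pgp)
  n_pgp <- sum(!vapply(pgp, is.null, logical(1)))
  if (n_pgp != 0L && n_pgp != 3L)
    stop("P-gp parameters must be all present or all absent", call. = FALSE)
  clpo_lh <- switch(clpo_units,
                    "L/h" = clpo,
                    "L/min" = clpo * 60,
                    "mL/min" = clpo * 60 / 1000)
  structure(list(
    name = name, ionization_class = ionization_class, mw = mw, logp = logp,
    pka = pka, fu = fu, bp_ratio = bp_ratio, vss = vss,
    clpo = clpo, clpo_units = clpo_units, clpo_basis = clpo_basis,
    clpo_lh = clpo_lh,
    clint_3a4 = clint_3a4, peff = peff,
    jmax_pgp = jmax_pgp, km_pgp = km_pgp, raf_pgp = raf_pgp,
    fa_assumed = fa_assumed, fg_assumed = fg_assumed,
    dose_mg = dose_mg
  ), class = "compound_profile")
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf("<compound_profile> %s (%s)\n", x$name, x$ionization_class))
  cat(sprintf("  MW %.2f g/mol, logP %.2f, pKa %s\n", x$mw, x$logp,
              paste(x$pka, collapse = ", ")))
  cat(sprintf("  fu %.3f, B:P %.2f, Vss %.2f L/kg, Peff %.3g cm/s\n",
              x$fu, x$bp_ratio, x$vss, x$peff))
  cat(sprintf("  CLpo %.4g %s (%s basis; normalized %.4g L/h)\n",
              x$clpo, x$clpo_units, x$clpo_basis, x$clpo_lh))
  if (!is.null(x$clint_3a4))
    cat(sprintf("  CLint,3A4 %.3g uL/min/pmol\n", x$clint_3a4))
  if (!is.null(x$jmax_pgp))
    cat(sprintf("  P-gp Jmax %.3g pmol/cm2/min, Km %.3g uM, RAF %.3g\n",
                x$jmax_pgp, x$km_pgp, x$raf_pgp))
  invisible(x)
}

#' Load a compound profile from YAML
#'
#' @param path path to a YAML file with keys matching the arguments of
#'   [compound_profile()].
#' @return a `compound_profile`.
#' @export
load_compound <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(compound_profile)))]
  if (!is.null(args$pka)) args$pka <- as.numeric(args$pka)
  cp <- do.call(compound_profile, args)
  if (identical(cp$clpo_units, "L/h") && !is.null(y$clpo_note))
    message(sprintf("%s: CLpo read as %s (%s)", cp$name, cp$clpo_units,
                    y$clpo_note))
  cp
}

#' Bundled compound presets
#'
#' Parameter files for amlodipine (5 mg, BCS class I diprotic base) and
#' atorvastatin (10 mg, BCS class II monoprotic acid, CYP3A4 and P-gp
#' substrate), including the parameter-estimated Peff and Vss values.
#'
#' @param name `"amlodipine"` or `"atorvastatin"`.
#' @return a `compound_profile`.
#' @export
preset_compound <- function(name = c("amlodipine", "atorvastatin")) {
  name <- match.arg(name)
  path <- system.file("extdata", "compounds", paste0(name, ".yaml"),
                      package = "vbesim", mustWork = TRUE)
  suppressMessages(load_compound(path))
}

#' System (population-typical) physiology for disposition
#'
#' @param q_h hepatic blood flow, L/h.
#' @param liver_cyp3a4_abundance total hepatic CYP3A4, pmol.
#' @param gut_cyp3a4_abundance total small-intestinal CYP3A4, pmol
#'   (distributed over segments by the gut physiology weights).
#' @param body_weight kg.
#' @param renal_fraction fraction of systemic clearance that is renal.
#' @param liver_volume liver (blood) compartment volume for the minimal PBPK
#'   model, L.
#' @return a list of class `system_physiology`.
#' @export
system_physiology <- function(q_h = 97,
                              liver_cyp3a4_abundance = 9.0e6,
                              gut_cyp3a4_abundance = 66200,
                              body_weight = 70,
                              renal_fraction = 0,
                              liver_volume = 1.0) {
  stop_if_not_scalar_pos(q_h, "q_h")
  stop_if_not_scalar_pos(liver_cyp3a4_abundance, "liver_cyp3a4_abundance")
  stop_if_not_scalar_pos(gut_cyp3a4_abundance, "gut_cyp3a4_abundance")
  stop_if_not_scalar_pos(body_weight, "body_weight")
  if (renal_fraction < 0 || renal_fraction >= 1)
    stop("`renal_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(q_h = q_h,
                 liver_cyp3a4_abundance = liver_cyp3a4_abundance,
                 gut_cyp3a4_abundance = gut_cyp3a4_abundance,
                 body_weight = body_weight,
                 renal_fraction = renal_fraction,
                 liver_volume = liver_volume),
            class = "system_physiology")
}

#' Fraction of drug un-ionized at a given pH
#'
#' Henderson-Hasselbalch speciation for the compound's ionization class.  For
#' a diprotic base both protonation steps are included.
#'
#' @param compound a `compound_profile`.
#' @param pH pH value(s) in \[0, 14\].
#' @return fraction un-ionized, same length as `pH`.
#' @export
fraction_unionized <- function(compound, pH) {
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]", call. = FALSE)
  switch(compound$ionization_class,
    neutral = rep(1, length(pH)),
    monoprotic_acid = 1 / (1 + 10^(pH - compound$pka[1])),
    monoprotic_base = 1 / (1 + 10^(compound$pka[1] - pH)),
    diprotic_base = {
      pka1 <- compound$pka[1]; pka2 <- compound$pka[2]
      1 / (1 + 10^(pka1 - pH) + 10^(pka1 + pka2 - 2 * pH))
    },
    stop("unsupported ionization class", call. = FALSE)
  )
}

#' Unbound fraction in whole blood
#'
#' `fu_b = fu_plasma / (B:P)`: unbound drug equilibrates across plasma and
#' cells, so the blood-referenced unbound fraction is the plasma value scaled
#' by the blood-to-plasma ratio.
#'
#' @param fu_plasma unbound fraction in plasma.
#' @param bp_ratio blood-to-plasma concentration ratio.
#' @param hematocrit retained for interface completeness (the ratio form does
#'   not need it); default 0.45.
#' @return unbound fraction referenced to whole blood.
#' @export
fu_blood <- function(fu_plasma, bp_ratio, hematocrit = 0.45) {
  stopifnot(fu_plasma > 0, fu_plasma <= 1, bp_ratio > 0)
  fu_plasma / bp_ratio
}

#' Well-stirred hepatic extraction
#'
#' @param fu_b unbound fraction in blood.
#' @param clu_int_liver whole-liver unbound intrinsic clearance, L/h.
#' @param q_h hepatic blood flow, L/h.
#' @return list with `cl_h` (hepatic blood clearance, L/h), `e_h` (extraction
#'   ratio) and `f_h` (fraction escaping first pass).
#' @export
hepatic_extraction <- function(fu_b, clu_int_liver, q_h) {
  stopifnot(fu_b > 0, clu_int_liver > 0, q_h > 0)
  x <- fu_b * clu_int_liver
  cl_h <- q_h * x / (q_h + x)
  e_h <- cl_h / q_h
  list(cl_h = cl_h, e_h = e_h, f_h = 1 - e_h)
}

#' Oral bioavailability decomposition
#'
#' `F_oral = fa * fg * fh`.
#'
#' @param fa,fg,fh fractions in \[0, 1\].
#' @return oral bioavailability.
#' @export
oral_bioavailability <- function(fa, fg, fh) {
  if (any(c(fa, fg, fh) < 0) || any(c(fa, fg, fh) > 1))
    stop("fa, fg, fh must lie in [0, 1]", call. = FALSE)
  fa * fg * fh
}

#' Retrograde intrinsic clearance from in vivo oral clearance
#'
#' Inverts `CLpo = CL_h / (fa * fg * fh)` under the well-stirred liver model.
#' Because `fh = Q_h / (Q_h + fu_b * CLu_int)` and
#' `CL_h = Q_h * fu_b * CLu_int / (Q_h + fu_b * CLu_int)`, the flow terms
#' cancel and the inversion is closed-form:
#' `CLu_int = CLpo_blood * fa * fg / fu_b`.  The whole-liver value is then
#' scaled by the hepatic enzyme abundance to a per-pmol intrinsic clearance.
#'
#' @param clpo oral clearance (blood basis unless `bp_ratio` is supplied to
#'   convert from plasma), L/h.
#' @param fa,fg assumed fraction absorbed / escaping gut metabolism, (0, 1].
#' @param fu_b unbound fraction in blood.
#' @param q_h hepatic blood flow, L/h (reported in diagnostics; the closed
#'   form is flow-independent).
#' @param enzyme_abundance hepatic enzyme amount, pmol.
#' @param bp_ratio if given, `clpo` is taken as plasma-referenced and
#'   converted via `clpo_blood = clpo / bp_ratio`.
#' @return list with `clint_per_pmol` (uL/min/pmol), `clu_int_liver` (L/h),
#'   and the implied `cl_h`, `e_h`, `f_h`, `f_oral`.
#' @export
retrograde_clint <- function(clpo, fa, fg, fu_b, q_h, enzyme_abundance,
                             bp_ratio = NULL) {
  stop_if_not_scalar_pos(clpo, "clpo")
  if (fa <= 0 || fa > 1 || fg <= 0 || fg > 1)
    stop("fa and fg must lie in (0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(fu_b, "fu_b")
  stop_if_not_scalar_pos(q_h, "q_h")
  stop_if_not_scalar_pos(enzyme_abundance, "enzyme_abundance")
  clpo_b <- if (is.null(bp_ratio)) clpo else clpo / bp_ratio
  clu_int <- clpo_b * fa * fg / fu_b            # L/h, whole liver, unbound
  hep <- hepatic_extraction(fu_b, clu_int, q_h)
  list(clint_per_pmol = clu_int * 1e6 / 60 / enzyme_abundance,
       clu_int_liver = clu_int,
       cl_h = hep$cl_h, e_h = hep$e_h, f_h = hep$f_h,
       f_oral = fa * fg * hep$f_h)
}

# Hepatic disposition parameters for a compound under a system physiology.
# CYP3A4 substrates use the mechanistic clint_3a4 * abundance route (scaled by
# the subject's liver CYP multiplier); others use the lumped retrograde
# clearance (scaled by the subject's clearance multiplier).
compound_hepatic <- function(compound, sys = system_physiology(),
                             liver_cyp_mult = 1, cl_mult = 1) {
  fu_b <- fu_blood(compound$fu, compound$bp_ratio)
  if (!is.null(compound$clint_3a4)) {
    clu_int <- compound$clint_3a4 * sys$liver_cyp3a4_abundance * 60 / 1e6 # L/h
    clu_int <- clu_int * liver_cyp_mult
  } else {
    rg <- retrograde_clint(compound$clpo_lh,
                           fa = compound$fa_assumed, fg = compound$fg_assumed,
                           fu_b = fu_b, q_h = sys$q_h,
                           enzyme_abundance = sys$liver_cyp3a4_abundance,
                           bp_ratio = if (compound$clpo_basis == "plasma")
                             compound$bp_ratio else NULL)
    clu_int <- rg$clu_int_liver * cl_mult
  }
  hep <- hepatic_extraction(fu_b, clu_int, sys$q_h)
  c(list(fu_b = fu_b, clu_int = clu_int), hep)
}
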
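# Dissolution profiles: sampling-withdrawal correction, f1/f2 difference and
# similarity factor testing with the regulatory decision rules, and release
# models that feed the gut absorption simulation.

#' Construct a dissolution profile
#'
#' @param times sampling times, min, strictly increasing, first > 0.
#' @param percent matrix of percent-of-dose dissolved, one column per
#'   replicate (a vector is treated as a single replicate).
#' @param medium dissolution medium (`"FaSSIF"`, `"FeSSIF"`, `"FaSSGF"` or a
#'   custom label).
#' @param label formulation identifier.
#' @param dose_mg dose, mg.
#' @param vessel_volume_ml vessel volume, mL.
#' @return an object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, percent, medium = "custom",
                                label = "formulation", dose_mg = NA_real_,
                                vessel_volume_ml = 900) {
  assert_increasing(times, "times")
  if (times[1] <= 0) stop("first sampling time must be > 0", call. = FALSE)
  percent <- as.matrix(percent)
  if (nrow(percent) != length(times))
    stop("`percent` must have one row per time point", call. = FALSE)
  if (any(percent < 0) || any(percent > 115))
    stop("percent dissolved must lie in [0, 115]", call. = FALSE)
  structure(list(times = as.numeric(times), percent = percent,
                 medium = medium, label = label, dose_mg = dose_mg,
                 vessel_volume_ml = vessel_volume_ml),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> %s in %s: %d points x %d replicates\n",
              x$label, x$medium, length(x$times), ncol(x$percent)))
  cat(sprintf("  final mean %% dissolved: %.1f\n",
              mean(x$percent[nrow(x$percent), ])))
  invisible(x)
}

#' Replicate-mean dissolution curve
#'
#' @param profile a `dissolution_profile` (numeric vectors pass through).
#' @return numeric vector of mean percent dissolved per time point.
#' @export
profile_means <- function(profile) {
  if (inherits(profile, "dissolution_profile")) rowMeans(profile$percent)
  else as.numeric(profile)
}

#' Correct sampled concentrations for media replacement
#'
#' During the dissolution test an aliquot `v_s` is withdrawn at each sampling
#' time and replaced with fresh medium, so measured concentrations
#' underestimate cumulative release.  The cumulative dissolved mass is
#' `M_n = C_n * V + v_s * sum_{i<n} C_i`.
#'
#' @param raw_concentrations measured concentrations, ug/mL, one per sampling
#'   time (single vessel).
#' @param sample_volume withdrawn volume per sample, mL.
#' @param vessel_volume vessel volume, mL.
#' @param dose dose, mg.
#' @param times sampling times, min (optional; defaults to index minutes).
#' @param ... passed to [dissolution_profile()] (e.g. `medium`, `label`).
#' @return a `dissolution_profile` whose percent values are
#'   `100 * M_n / dose`; the corrected masses (ug) are attached as attribute
#'   `"mass_ug"`.
#' @export
correct_cumulative <- function(raw_concentrations, sample_volume,
                               vessel_volume, dose, times = NULL, ...) {
  if (sample_volume < 0 || sample_volume >= vessel_volume)
    stop("need 0 <= sample_volume < vessel_volume", call. = FALSE)
  stop_if_not_scalar_pos(dose, "dose")
  bad <- which(raw_concentrations < 0)
  if (length(bad))
    stop(sprintf("negative concentration at time point %d", bad[1]),
         call. = FALSE)
  c_prev <- c(0, cumsum(raw_concentrations))[seq_along(raw_concentrations)]
  mass <- raw_concentrations * vessel_volume + sample_volume * c_prev
  if (is.null(times)) times <- seq_along(raw_concentrations)
  out <- dissolution_profile(times, 100 * mass / (dose * 1000),
                             dose_mg = dose,
                             vessel_volume_ml = vessel_volume, ...)
  attr(out, "mass_ug") <- mass
  out
}

check_common_grid <- function(r, t, ref, test) {
  if (inherits(ref, "dissolution_profile") &&
      inherits(test, "dissolution_profile") &&
      !isTRUE(all.equal(ref$times, test$times)))
    stop("profiles are on different time grids; no silent interpolation",
         call. = FALSE)
  if (length(r) != length(t))
    stop("reference and test must share a common time grid", call. = FALSE)
}

#' Difference factor f1
#'
#' `f1 = 100 * sum(|R_t - T_t|) / sum(R_t)` over the included time points.
#' Profiles differ when f1 exceeds 15.
#'
#' @param reference,test replicate-mean percent-dissolved values on a common
#'   time grid (`dissolution_profile` objects are reduced with
#'   [profile_means()]).
#' @return f1, dimensionless.
#' @export
f1_factor <- function(reference, test) {
  r <- profile_means(reference); tt <- profile_means(test)
  check_common_grid(r, tt, reference, test)
  if (sum(r) <= 0) stop("reference profile sums to zero", call. = FALSE)
  100 * sum(abs(r - tt)) / sum(r)
}

#' Similarity factor f2
#'
#' `f2 = 50 * log10(100 / sqrt(1 + mean((R_t - T_t)^2)))`, the standard FDA
#' form: 100 for identical profiles, above 50 for similar ones.
#'
#' @inheritParams f1_factor
#' @return f2, dimensionless (<= 100).
#' @export
f2_factor <- function(reference, test) {
  r <- profile_means(reference); tt <- profile_means(test)
  check_common_grid(r, tt, reference, test)
  50 * log10(100 / sqrt(1 + mean((r - tt)^2)))
}

#' Apply the f1/f2 similarity thresholds
#'
#' @param f1,f2 difference and similarity factors.
#' @return `"pass"` if `f1 < 15` and `f2 > 50`, else `"fail"`.
#' @export
similarity_rule <- function(f1, f2) {
  if (f1 < 15 && f2 > 50) "pass" else "fail"
}

#' Dissolution similarity verdict
#'
#' Compares a reference and a test profile with the regulatory decision
#' rules: if both formulations are rapidly dissolving (over 85% of dose in 15
#' minutes or less) the comparison is waived; otherwise f1/f2 are evaluated
#' on the common scheduled points, by default truncated at one point after
#' both profiles exceed 85% dissolved (the statistics are insensitive past
#' the plateau and would otherwise be diluted).
#'
#' @param ref,test `dissolution_profile` objects on a common grid.
#' @param use_85_rule apply the rapid-dissolution biowaiver rule.
#' @param truncate_after_85 keep at most one common point after both profiles
#'   exceed 85%.
#' @return an object of class `similarity_result` with fields `f1`, `f2`,
#'   `n_points`, `rapid_both`, `verdict` (`"pass"`, `"fail"` or `"waived"`)
#'   and `points_used`.
#' @export
similarity_verdict <- function(ref, test, use_85_rule = TRUE,
                               truncate_after_85 = TRUE) {
  r <- profile_means(ref); tt <- profile_means(test)
  check_common_grid(r, tt, ref, test)
  times <- if (inherits(ref, "dissolution_profile")) ref$times
           else seq_along(r)
  rapid_both <- any(times <= 15 & r > 85) && any(times <= 15 & tt > 85)
  keep <- seq_along(times)
  if (truncate_after_85) {
    over <- which(r > 85 & tt > 85)
    if (length(over)) keep <- seq_len(min(length(times), over[1]))
  }
  if (length(keep) < 3L)
    stop("fewer than 3 usable common time points for f1/f2", call. = FALSE)
  f1 <- f1_factor(r[keep], tt[keep])
  f2 <- f2_factor(r[keep], tt[keep])
  verdict <- if (use_85_rule && rapid_both) "waived" else similarity_rule(f1, f2)
  structure(list(f1 = f1, f2 = f2, n_points = length(keep),
                 rapid_both = rapid_both, verdict = verdict,
                 points_used = times[keep]),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> f1 = %.2f, f2 = %.2f (n = %d)\n",
              x$f1, x$f2, x$n_points))
  cat(sprintf("  both >85%% within 15 min: %s -> verdict: %s\n",
              ifelse(x$rapid_both, "yes", "no"), x$verdict))
  invisible(x)
}

#' Construct a release model directly
#'
#' @param family `"weibull"`, `"first-order"` or `"tabulated"`.
#' @param plateau maximal percent dissolved.
#' @param td time scale, min.
#' @param beta Weibull shape (1 for first-order).
#' @param times,values tabulated family: times (min) and mean percent.
#' @param residual_sse fit residual sum of squares (percent^2).
#' @return an object of class `release_model`.
#' @export
release_model <- function(family = c("weibull", "first-order", "tabulated"),
                          plateau = NULL, td = NULL, beta = NULL,
                          times = NULL, values = NULL,
                          residual_sse = NA_real_) {
  family <- match.arg(family)
  if (family == "tabulated") {
    assert_increasing(times, "times")
    plateau <- values[length(values)]
  } else {
    if (family == "first-order") beta <- 1
    stop_if_not_scalar_pos(plateau, "plateau")
    stop_if_not_scalar_pos(td, "td")
    stop_if_not_scalar_pos(beta, "beta")
  }
  structure(list(family = family, plateau = plateau, td = td, beta = beta,
                 times = times, values = values, residual_sse = residual_sse),
            class = "release_model")
}

#' Fit a release model to a dissolution profile
#'
#' Least-squares fit of the replicate-mean curve.  The Weibull family is
#' `F(t) = plateau * (1 - exp(-(t/td)^beta))`; the first-order family is the
#' `beta = 1` special case; the tabulated family passes the data through with
#' monotone piecewise-linear interpolation clamped to the plateau beyond the
#' last point.
#'
#' @param profile a `dissolution_profile` with at least 4 points.
#' @param family model family.
#' @return a `release_model`.
#' @export
fit_release_model <- function(profile,
                              family = c("weibull", "first-order",
                                         "tabulated")) {
  family <- match.arg(family)
  y <- profile_means(profile)
  t <- profile$times
  if (length(t) < 4L) stop("need at least 4 time points", call. = FALSE)
  if (family == "tabulated")
    return(release_model("tabulated", times = t, values = cummax(y),
                         residual_sse = 0))
  pred <- function(p, tt) p[1] * (1 - exp(-(tt / p[2])^p[3]))
  sse <- function(lp) {
    p <- exp(lp); if (family == "first-order") p[3] <- 1
    sum((y - pred(p, t))^2)
  }
  # initial values: plateau from the tail, td from time to 63% of plateau
  p0 <- max(y)
  i63 <- which(y >= 0.632 * p0)[1]
  td0 <- if (is.na(i63)) stats::median(t) else max(t[i63] / 2, t[1] / 2)
  fit <- stats::optim(log(c(p0, td0, 1)), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop(sprintf("release-model fit did not converge (last iterate: %s)",
                 paste(signif(exp(fit$par), 4), collapse = ", ")),
         call. = FALSE)
  p <- exp(fit$par); if (family == "first-order") p[3] <- 1
  release_model(family, plateau = p[1], td = p[2], beta = p[3],
                residual_sse = fit$value)
}

#' Fraction of dose dissolved at time t
#'
#' @param model a `release_model`.
#' @param t time, min (vectorized, t >= 0).
#' @return fraction of dose in `[0, plateau/100]`, non-decreasing in `t`.
#' @export
fraction_dissolved <- function(model, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (model$family == "tabulated") {
    xs <- c(0, model$times); ys <- c(0, model$values)
    out <- stats::approx(xs, ys, xout = pmin(t, max(xs)), rule = 2)$y
    return(out / 100)
  }
  model$plateau / 100 * (1 - exp(-(t / model$td)^model$beta))
}

# In vivo release hazard (1/min) of the *normalized* profile shape
# f(t) = F(t)/plateau: h = f' / (1 - f).  The in vitro plateau is treated as
# an assay recovery limit, not an in vivo cap, so the full solid dose remains
# releasable (see the methods vignette).  Capped for numerical safety near
# singular starts (beta < 1).
release_hazard <- function(model, t, cap = 10) {
  if (model$family %in% c("weibull", "first-order")) {
    h <- ifelse(t <= 0 & model$beta < 1, cap,
                model$beta / model$td * (pmax(t, 1e-12) / model$td)^(model$beta - 1))
  } else {
    f <- fraction_dissolved(model, t) / (model$plateau / 100)
    eps <- 1e-3
    f2 <- fraction_dissolved(model, t + eps) / (model$plateau / 100)
    h <- (f2 - f) / eps / pmax(1 - f, 1e-9)
  }
  pmin(h, cap)
}

#' Read / write dissolution profiles as CSV
#'
#' Long format with columns `label`, `medium`, `replicate`, `time_min`,
#' `percent`.
#'
#' @param path file path.
#' @param profile a `dissolution_profile` (for writing).
#' @return `read_dissolution_csv()` returns a list of `dissolution_profile`
#'   objects, one per label/medium combination.
#' @export
read_dissolution_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "medium", "replicate", "time_min", "percent")
  if (!all(need %in% names(d)))
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(d, interaction(d$label, d$medium, drop = TRUE)),
                function(g) {
    wide <- stats::reshape(g[c("replicate", "time_min", "percent")],
                           idvar = "time_min", timevar = "replicate",
                           direction = "wide")
    wide <- wide[order(wide$time_min), ]
    dissolution_profile(wide$time_min, as.matrix(wide[-1]),
                        medium = g$medium[1], label = g$label[1])
  })
  names(out) <- NULL
  out
}

#' @rdname read_dissolution_csv
#' @export
write_dissolution_csv <- function(profile, path) {
  n_rep <- ncol(profile$percent)
  d <- data.frame(label = profile$label, medium = profile$medium,
                  replicate = rep(seq_len(n_rep), each = length(profile$times)),
                  time_min = rep(profile$times, n_rep),
                  percent = as.vector(profile$percent))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
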
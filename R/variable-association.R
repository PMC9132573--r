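#' Variable-association-time analysis of biphasic dissociation
#'
#' Reproduces the experimental design in which analyte is flowed at a
#' fixed concentration for increasing association times and the
#' dissociation phase of each cycle is fit biphasically. The fast-phase
#' percentage declines with association time as the partially engaged
#' complexes convert to fully engaged ones; the series is summarized by a
#' single-exponential fit
#' \deqn{f(t) = f_{eq} + (f_0 - f_{eq}) e^{-\ln 2 \, t / t_{1/2}}}
#' whose plateau `f_eq` reflects the equilibrium partial-state fraction
#' `100 k_{-2} / (k_2 + k_{-2})` of the engagement scheme.
#'
#' @param sensorgrams list of `sensorgram` objects sharing one analyte
#'   concentration, with >= 4 distinct association durations.
#' @param monotone_tolerance fractional rise (relative to the series
#'   range) above which a non-monotone fast-phase series triggers a
#'   warning; the fit is still returned.
#' @return A `variable_association_result` list: `association_times` (s),
#'   `fraction_fast_series` (%), `plateau_fraction` (%),
#'   `initial_fraction` (%), `t_half` (s), `fits` (per-cycle
#'   [fit_dissociation()] results).
#' @export
variable_association_analysis <- function(sensorgrams,
                                          monotone_tolerance = 0.05) {
  stopifnot(is.list(sensorgrams))
  t_assoc <- vapply(sensorgrams, attr, numeric(1), "association_end")
  if (length(unique(t_assoc)) < 4) {
    stop("need at least 4 distinct association durations", call. = FALSE)
  }
  concs <- vapply(sensorgrams, attr, numeric(1), "analyte_concentration")
  if (length(unique(signif(concs, 10))) != 1) {
    stop("all cycles must share one analyte concentration", call. = FALSE)
  }
  ord <- order(t_assoc)
  t_assoc <- t_assoc[ord]
  sensorgrams <- sensorgrams[ord]

  fits <- lapply(sensorgrams, function(sg) {
    suppressWarnings(fit_dissociation(sg, n_phases = 2))
  })
  f_pct <- vapply(fits, function(f) 100 * f$fraction_fast, numeric(1))

  rng <- diff(range(f_pct))
  rises <- diff(f_pct)
  if (rng > 0 && any(rises > monotone_tolerance * rng)) {
    warning("fast-phase series is not monotone beyond noise tolerance",
            call. = FALSE)
  }

  if (diff(range(f_pct)) < 1e-6) {
    # no relaxation at all (e.g. k2 = 0: every cycle is 100% fast phase)
    return(structure(list(
      association_times = t_assoc,
      fraction_fast_series = f_pct,
      plateau_fraction = mean(f_pct),
      initial_fraction = mean(f_pct),
      t_half = NA_real_,
      fits = fits),
      class = "variable_association_result"))
  }

  f0_0 <- max(f_pct)
  feq_0 <- min(f_pct)
  th_0 <- max(t_assoc[which(f_pct <= (f0_0 + feq_0) / 2)][1], t_assoc[2],
              na.rm = TRUE)
  fit <- minpack.lm::nlsLM(
    f ~ feq + (f0 - feq) * exp(-log(2) * t / th),
    data = data.frame(t = t_assoc, f = f_pct),
    start = list(feq = feq_0, f0 = f0_0, th = th_0),
    lower = c(feq = 0, f0 = 0, th = 1e-6),
    upper = c(feq = 100, f0 = 100, th = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)

  structure(list(
    association_times = t_assoc,
    fraction_fast_series = f_pct,
    plateau_fraction = cf[["feq"]],
    initial_fraction = cf[["f0"]],
    t_half = cf[["th"]],
    fits = fits),
    class = "variable_association_result")
}

#' Analytic steady-state partial-engagement fraction of a scheme
#'
#' At binding steady state the fully:partially engaged ratio is
#' `k2 / k_minus2`, so the partial-state fraction of all bound complexes
#' is `k_minus2 / (k2 + k_minus2)` — the plateau the variable-association
#' fast-phase percentage converges to.
#'
#' @param scheme a [two_step_scheme()].
#' @return Percent (0-100).
#' @export
steady_state_partial_fraction <- function(scheme) {
  stopifnot(inherits(scheme, "two_step_scheme"))
  if (scheme$k2 == 0) return(100)
  100 * scheme$k_minus2 / (scheme$k2 + scheme$k_minus2)
}

#' @export
print.variable_association_result <- function(x, ...) {
  cat("Variable-association analysis\n")
  cat(sprintf("  association times: %s s\n",
              paste(signif(x$association_times, 3), collapse = ", ")))
  cat(sprintf("  %% fast phase: from %.1f%% to plateau %.1f%%, t1/2 = %.3g s\n",
              x$initial_fraction, x$plateau_fraction, x$t_half))
  invisible(x)
}
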
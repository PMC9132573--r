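#' Exchange time course container
#'
#' Fluorescent-GDP nucleotide-exchange time course: BODIPY-FL-GDP gains
#' fluorescence on loading onto eIF2 (`phase = "loading"`) and loses it on
#' unloading.
#'
#' @param times seconds, strictly increasing.
#' @param fluorescence arbitrary units, finite.
#' @param substrate_concentration eIF2 concentration (M).
#' @param enzyme_concentration eIF2B concentration (M).
#' @param reaction_volume liters.
#' @param phase `"loading"` or `"unloading"`.
#' @return An `exchange_timecourse` data frame with metadata attributes.
#' @export
exchange_timecourse <- function(times, fluorescence,
                                substrate_concentration = NA_real_,
                                enzyme_concentration = NA_real_,
                                reaction_volume = 20e-6,
                                phase = c("loading", "unloading")) {
  phase <- match.arg(phase)
  stopifnot(length(times) == length(fluorescence), all(diff(times) > 0),
            all(is.finite(fluorescence)))
  structure(data.frame(time = times, fluorescence = fluorescence),
            substrate_concentration = substrate_concentration,
            enzyme_concentration = enzyme_concentration,
            reaction_volume = reaction_volume,
            phase = phase,
            class = c("exchange_timecourse", "data.frame"))
}

#' First-order exponential fit of an exchange time course
#'
#' Loading curves are fit to
#' `F(t) = baseline + amplitude * (1 - exp(-rate * t))`, unloading curves
#' to `F(t) = baseline + amplitude * exp(-rate * t)`, by nonlinear least
#' squares with a floating baseline. Rates are reported per minute and the
#' half-life in minutes (`t_half = ln 2 / rate`).
#'
#' A time course whose total signal change is below three times the noise
#' estimate (from first differences) is classified as no exchange.
#'
#' @param tc an `exchange_timecourse` (times in seconds).
#' @return An `exponential_fit` list: `t_half` (min), `rate` (min^-1),
#'   `amplitude`, `baseline`, `no_exchange`.
#' @export
fit_exponential <- function(tc) {
  stopifnot(inherits(tc, "exchange_timecourse"))
  if (nrow(tc) < 20) {
    stop("need at least 20 time points for an exponential fit",
         call. = FALSE)
  }
  t_min <- tc$time / 60
  y <- tc$fluorescence
  loading <- attr(tc, "phase") == "loading"

  noise <- stats::mad(diff(y)) / sqrt(2)
  span <- abs(max(y) - min(y))
  if (span < 3 * max(noise, .Machine$double.eps)) {
    return(structure(list(
      t_half = NA_real_, rate = NA_real_, amplitude = 0,
      baseline = mean(y), no_exchange = TRUE),
      class = "exponential_fit"))
  }

  b0 <- if (loading) min(y) else max(y) - span
  a0 <- span
  # seed rate from time to half signal change
  target <- if (loading) b0 + a0 / 2 else b0 + a0 / 2
  ihalf <- if (loading) which(y >= target)[1] else which(y <= target)[1]
  r0 <- if (is.na(ihalf) || t_min[ihalf] <= 0) 1 else log(2) / t_min[ihalf]

  form <- if (loading) {
    yfit ~ b + a * (1 - exp(-r * tfit))
  } else {
    yfit ~ b + a * exp(-r * tfit)
  }
  fit <- minpack.lm::nlsLM(
    form, data = data.frame(tfit = t_min, yfit = y),
    start = list(b = b0, a = a0, r = r0),
    lower = c(b = -Inf, a = 0, r = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)

  structure(list(
    t_half = log(2) / cf[["r"]],
    rate = cf[["r"]],
    amplitude = cf[["a"]],
    baseline = cf[["b"]],
    no_exchange = FALSE),
    class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (x$no_exchange) {
    cat("Exponential fit: no exchange detected\n")
  } else {
    cat(sprintf("First-order exponential: t1/2 = %.3g min (rate %.3g min^-1), amplitude %.3g\n",
                x$t_half, x$rate, x$amplitude))
  }
  invisible(x)
}

#' Fluorescence-to-amount calibration from endpoint gains
#'
#' Linear regression of the endpoint fluorescence gain against the amount
#' of substrate in the reaction (concentration x reaction volume, pmol).
#' The calibration range follows the experimental design (31.5 nM to 1 uM
#' substrate).
#'
#' @param concentrations substrate concentrations (M), >= 3 points.
#' @param gains endpoint fluorescence gains (a.u.).
#' @param reaction_volume liters.
#' @return A `calibration` list: `slope` (a.u. per pmol), `intercept`,
#'   `concentration_range` (M), `reaction_volume`.
#' @export
build_calibration <- function(concentrations, gains,
                              reaction_volume = 20e-6) {
  stopifnot(length(concentrations) == length(gains),
            length(concentrations) >= 3)
  pmol <- concentrations * reaction_volume * 1e12  # mol -> pmol
  fit <- stats::lm(gains ~ pmol)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; check the endpoint gains",
         call. = FALSE)
  }
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    concentration_range = range(concentrations),
    reaction_volume = reaction_volume),
    class = "calibration")
}

#' Initial reaction velocity from the early linear window
#'
#' Linear fit of fluorescence vs time inside the window (default 50-200 s
#' after enzyme addition), converted to pmol/min through the calibration
#' slope. Without a calibration the velocity is returned in fluorescence
#' units per minute and tagged accordingly.
#'
#' @param tc an `exchange_timecourse` (times in seconds).
#' @param window two-element window (s).
#' @param calibration optional [build_calibration()] result.
#' @return Velocity (pmol/min, or a.u./min when uncalibrated), with
#'   attribute `units`.
#' @export
initial_velocity <- function(tc, window = c(50, 200), calibration = NULL) {
  stopifnot(inherits(tc, "exchange_timecourse"), length(window) == 2)
  sel <- tc$time >= window[1] & tc$time <= window[2]
  if (sum(sel) < 5) {
    stop("need at least 5 points inside the initial-velocity window",
         call. = FALSE)
  }
  slope_per_min <- unname(stats::coef(
    stats::lm(fluorescence ~ time, data = tc[sel, ]))[2]) * 60
  if (is.null(calibration)) {
    return(structure(slope_per_min, units = "au/min"))
  }
  stopifnot(inherits(calibration, "calibration"))
  structure(slope_per_min / calibration$slope, units = "pmol/min")
}

#' Michaelis-Menten fit of initial velocities
#'
#' Nonlinear least-squares fit of `v = Vmax C / (KM + C)` to
#' concentration-velocity points, with optional replicate grouping: each
#' replicate is fit individually (for replicate-level statistics) and the
#' reported `v_max` / `k_m` are the means of the per-replicate estimates,
#' falling back to a pooled fit when no grouping is given.
#'
#' @param concentrations substrate concentrations (M).
#' @param velocities initial velocities (pmol/min).
#' @param replicates optional replicate labels, same length.
#' @param enzyme_concentration,reaction_volume,sites_per_complex passed to
#'   [kcat_from_vmax()] for the turnover number; the default catalytic
#'   convention is two epsilon subunits per decamer.
#' @return A `michaelis_menten_fit` list: `v_max` (pmol/min), `k_m` (M),
#'   `k_cat` (min^-1), `specificity` (min^-1 uM^-1), `replicate_values`
#'   (data frame of per-replicate v_max/k_m), `ill_conditioned`.
#' @export
fit_michaelis_menten <- function(concentrations, velocities,
                                 replicates = NULL,
                                 enzyme_concentration = 10e-9,
                                 reaction_volume = 20e-6,
                                 sites_per_complex = 2) {
  stopifnot(length(concentrations) == length(velocities))
  if (length(unique(concentrations)) < 5) {
    stop("need at least 5 distinct substrate concentrations", call. = FALSE)
  }

  fit_one <- function(cc, vv) {
    vmax0 <- max(vv)
    km0 <- cc[which.min(abs(vv - vmax0 / 2))]
    if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(cc[cc > 0])
    fit <- minpack.lm::nlsLM(
      v ~ vmax * conc / (km + conc),
      data = data.frame(conc = cc, v = vv),
      start = list(vmax = vmax0, km = km0),
      lower = c(vmax = 0, km = 0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    stats::coef(fit)
  }

  ill <- max(concentrations) < 2 * {
    pooled0 <- fit_one(concentrations, velocities); pooled0[["km"]]
  }
  if (ill) {
    warning("substrate range barely exceeds KM; fit is ill-conditioned ",
            "(linear-regime slope kcat/KM is still meaningful)",
            call. = FALSE)
  }

  if (is.null(replicates)) {
    cf <- fit_one(concentrations, velocities)
    rep_tab <- data.frame(replicate = "pooled", v_max = cf[["vmax"]],
                          k_m = cf[["km"]])
  } else {
    stopifnot(length(replicates) == length(velocities))
    rep_tab <- do.call(rbind, lapply(split(
      data.frame(conc = concentrations, v = velocities), replicates),
      function(d) {
        cf <- fit_one(d$conc, d$v)
        data.frame(v_max = cf[["vmax"]], k_m = cf[["km"]])
      }))
    rep_tab <- data.frame(replicate = rownames(rep_tab), rep_tab,
                          row.names = NULL)
  }

  v_max <- mean(rep_tab$v_max)
  k_m <- mean(rep_tab$k_m)
  k_cat <- kcat_from_vmax(v_max, enzyme_concentration, reaction_volume,
                          sites_per_complex)
  structure(list(
    v_max = v_max, k_m = k_m, k_cat = k_cat,
    specificity = k_cat / (k_m * 1e6),  # min^-1 uM^-1
    replicate_values = rep_tab,
    ill_conditioned = ill,
    enzyme_concentration = enzyme_concentration,
    reaction_volume = reaction_volume,
    sites_per_complex = sites_per_complex),
    class = "michaelis_menten_fit")
}

#' @export
print.michaelis_menten_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Vmax = %.3g pmol/min, KM = %.3g uM\n", x$v_max,
              x$k_m * 1e6))
  cat(sprintf("  kcat = %.3g min^-1 (%d sites/complex), kcat/KM = %.3g min^-1 uM^-1\n",
              x$k_cat, x$sites_per_complex, x$specificity))
  if (nrow(x$replicate_values) > 1) {
    cat(sprintf("  %d replicates fit individually\n",
                nrow(x$replicate_values)))
  }
  invisible(x)
}

#' Turnover number from maximal velocity
#'
#' `kcat = Vmax / (catalytic amount)`, where the catalytic amount is
#' `enzyme_concentration * reaction_volume * sites_per_complex` in pmol.
#' The default stoichiometry counts the two catalytic epsilon subunits of
#' the eIF2B decamer, so 10 nM decamer in 20 uL is 0.4 pmol of catalytic
#' sites.
#'
#' @param v_max maximal velocity (pmol/min).
#' @param enzyme_concentration enzyme complex concentration (M), > 0.
#' @param reaction_volume liters, > 0.
#' @param sites_per_complex catalytic sites per complex, >= 1.
#' @return `kcat` (min^-1).
#' @examples
#' kcat_from_vmax(0.66, 10e-9, 20e-6, 2)  # 1.65 min^-1
#' @export
kcat_from_vmax <- function(v_max, enzyme_concentration,
                           reaction_volume = 20e-6, sites_per_complex = 2) {
  stopifnot(is.finite(v_max), v_max >= 0, sites_per_complex >= 1)
  if (!is.finite(enzyme_concentration) || enzyme_concentration <= 0 ||
      !is.finite(reaction_volume) || reaction_volume <= 0) {
    stop("catalytic amount must be positive", call. = FALSE)
  }
  pmol_sites <- enzyme_concentration * reaction_volume * 1e12 *
    sites_per_complex
  v_max / pmol_sites
}

#' Two-sided t-test on per-replicate fitted parameters
#'
#' Compares parameter estimates (e.g. per-replicate Vmax or KM) between
#' two groups with a two-sided Student t-test at `alpha` (Welch's
#' correction by flag). With fewer than two replicates in either group the
#' test is refused and only the descriptive difference is returned.
#'
#' @param a,b numeric vectors of per-replicate parameter values.
#' @param alpha significance level for the decision flag.
#' @param welch use Welch's unequal-variance t-test.
#' @return A `replicate_comparison` list: `statistic`, `p_value`,
#'   `significant`, `mean_difference`, `test`.
#' @export
compare_replicates <- function(a, b, alpha = 0.05, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2 || length(b) < 2) {
    warning("fewer than 2 replicates per group: t-test refused, ",
            "descriptive difference only", call. = FALSE)
    return(structure(list(
      statistic = NA_real_, p_value = NA_real_, significant = NA,
      mean_difference = mean(a) - mean(b), test = "none"),
      class = "replicate_comparison"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  structure(list(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    significant = tt$p.value < alpha,
    mean_difference = mean(a) - mean(b),
    test = if (welch) "welch" else "student"),
    class = "replicate_comparison")
}

#' @export
print.replicate_comparison <- function(x, ...) {
  if (x$test == "none") {
    cat(sprintf("Descriptive difference only: mean diff = %.4g\n",
                x$mean_difference))
  } else {
    cat(sprintf("Two-sided %s t-test: t = %.3g, p = %.3g (%ssignificant)\n",
                x$test, x$statistic, x$p_value,
                if (x$significant) "" else "not "))
  }
  invisible(x)
}
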
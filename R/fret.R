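#' FRET assembly titration container
#'
#' Dose-titration of a dimerizing agent (ISRIB or the alpha2 dimer)
#' against fluorescently tagged eIF2B tetramers, read out as the
#' acceptor/donor emission ratio E592/E516.
#'
#' @param concentrations dimerizer concentrations (M), >= 0, at least 5
#'   levels for fitting.
#' @param response FRET ratios (dimensionless).
#' @param tetramer_concentration tetramer concentration (M); the
#'   experimental design uses 50 nM.
#' @return A `titration_series` data frame with metadata attributes.
#' @export
titration_series <- function(concentrations, response,
                             tetramer_concentration = 50e-9) {
  stopifnot(length(concentrations) == length(response),
            all(concentrations >= 0))
  structure(data.frame(concentration = concentrations, response = response),
            tetramer_concentration = tetramer_concentration,
            class = c("titration_series", "data.frame"))
}

#' Four-parameter logistic EC50 fit of an assembly titration
#'
#' Fits the FRET ratio vs log10 concentration to a four-parameter
#' logistic
#' \deqn{y = floor + \frac{ceiling - floor}{1 + (EC_{50}/C)^{h}}}
#' with free Hill slope `h` (fixable to 1 via `hill`). Zero-concentration
#' points are retained through a log-offset: they are placed at
#' `log10(offset_factor * smallest positive concentration)`.
#'
#' A series whose fitted dynamic range (`ceiling - floor`) is below
#' `noise_multiple` times the residual noise of the fit is classified as
#' not assembling (`assembled = FALSE`, no EC50) — the behavior of
#' betaH160D tetramers titrated with ISRIB. A non-monotone response
#' beyond noise raises a warning but the fit is still attempted.
#'
#' @param series a [titration_series()].
#' @param hill `NULL` for a free Hill slope or a fixed value.
#' @param noise_multiple dynamic-range threshold in noise units.
#' @param offset_factor placement of zero-concentration points relative
#'   to the smallest positive concentration.
#' @return An `ec50_fit` list: `ec50` (M), `hill`, `floor`, `ceiling`,
#'   `assembled`, `rss`.
#' @export
fit_ec50 <- function(series, hill = NULL, noise_multiple = 3,
                     offset_factor = 0.1) {
  stopifnot(inherits(series, "titration_series"))
  if (length(unique(series$concentration)) < 5) {
    stop("need at least 5 concentration levels", call. = FALSE)
  }
  conc <- series$concentration
  y <- series$response
  cmin <- min(conc[conc > 0])
  lc <- log10(ifelse(conc > 0, conc, offset_factor * cmin))

  ord <- order(lc)
  # second differences de-trend the sigmoid before estimating noise
  noise <- stats::mad(diff(y[ord], differences = 2)) / sqrt(6)
  span <- diff(range(y))

  # warn if the dose response declines beyond noise
  drops <- -diff(y[ord])
  if (span > 0 && any(drops > 3 * max(noise, .Machine$double.eps))) {
    warning("response is not monotone in concentration beyond noise; ",
            "fit attempted anyway", call. = FALSE)
  }

  not_assembled <- function() {
    structure(list(
      ec50 = NA_real_, hill = NA_real_, floor = mean(y),
      ceiling = mean(y), assembled = FALSE, rss = NA_real_),
      class = "ec50_fit")
  }
  fl0 <- min(y); ce0 <- max(y)
  lec0 <- lc[ord][which(y[ord] >= (fl0 + ce0) / 2)[1]]
  if (is.na(lec0)) lec0 <- stats::median(lc)

  fit <- tryCatch(if (is.null(hill)) {
    minpack.lm::nlsLM(
      y ~ fl + (ce - fl) / (1 + 10^(h * (lec - lcx))),
      data = data.frame(lcx = lc, y = y),
      start = list(fl = fl0, ce = ce0, lec = lec0, h = 1),
      lower = c(fl = -Inf, ce = -Inf, lec = log10(cmin) - 4, h = 0.1),
      upper = c(fl = Inf, ce = Inf, lec = log10(max(conc)) + 4, h = 10),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    h_fixed <- hill
    minpack.lm::nlsLM(
      y ~ fl + (ce - fl) / (1 + 10^(h_fixed * (lec - lcx))),
      data = data.frame(lcx = lc, y = y),
      start = list(fl = fl0, ce = ce0, lec = lec0),
      lower = c(fl = -Inf, ce = -Inf, lec = log10(cmin) - 4),
      upper = c(fl = Inf, ce = Inf, lec = log10(max(conc)) + 4),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }, error = function(e) NULL)
  if (is.null(fit)) return(not_assembled())
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  sigma_resid <- sqrt(rss / max(1, length(y) - length(cf)))
  dyn_range <- cf[["ce"]] - cf[["fl"]]
  ec50_fit <- 10^cf[["lec"]]
  # an assembly transition must clear the noise floor and occur inside
  # the tested concentration range
  if (dyn_range < noise_multiple * max(sigma_resid, .Machine$double.eps) ||
      ec50_fit < cmin || ec50_fit > max(conc)) {
    return(not_assembled())
  }
  structure(list(
    ec50 = 10^cf[["lec"]],
    hill = if (is.null(hill)) cf[["h"]] else hill,
    floor = cf[["fl"]],
    ceiling = cf[["ce"]],
    assembled = TRUE,
    rss = rss),
    class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  if (!x$assembled) {
    cat("Assembly titration: no assembly detected (flat response)\n")
  } else {
    cat(sprintf("Assembly EC50 = %.3g nM (Hill %.2f, ratio %.3g -> %.3g)\n",
                x$ec50 * 1e9, x$hill, x$floor, x$ceiling))
  }
  invisible(x)
}
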
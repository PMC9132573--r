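#' Two-step substrate-engagement scheme
#'
#' Microscopic rate constants of the sequential engagement model by which
#' eIF2 binds the eIF2B decamer: a bimolecular first step forming a
#' partially engaged complex through interfaces IF1-IF3, followed by a
#' unimolecular second step that docks the fourth interface (IF4) on the
#' opposing tetramer half to form the fully engaged complex.
#'
#' \deqn{U + L \mathrel{\mathop{\rightleftharpoons}^{k_1 C}_{k_{-1}}} P
#'       \mathrel{\mathop{\rightleftharpoons}^{k_2}_{k_{-2}}} F}
#'
#' At equilibrium the ratio of fully- to partially-engaged complexes is
#' `k2 / k_minus2`.
#'
#' @param k1 bimolecular association rate constant (M^-1 s^-1).
#' @param k_minus1 first-step dissociation rate constant (s^-1).
#' @param k2 second-step engagement rate constant (s^-1).
#' @param k_minus2 second-step retraction rate constant (s^-1).
#' @return An object of class `two_step_scheme`.
#' @examples
#' two_step_scheme(7e5, 0.12, 0.352, 0.044)
#' @export
two_step_scheme <- function(k1, k_minus1, k2 = 0, k_minus2 = 0) {
  rates <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2)
  if (!all(is.finite(rates))) {
    stop("all rate constants must be finite numbers", call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("rate constants must be non-negative", call. = FALSE)
  }
  structure(as.list(rates), class = "two_step_scheme")
}

#' @export
print.two_step_scheme <- function(x, ...) {
  cat("Two-step engagement scheme\n")
  cat(sprintf("  k1      = %.3g M^-1 s^-1\n", x$k1))
  cat(sprintf("  k-1     = %.3g s^-1\n", x$k_minus1))
  cat(sprintf("  k2      = %.3g s^-1\n", x$k2))
  cat(sprintf("  k-2     = %.3g s^-1\n", x$k_minus2))
  if (x$k_minus2 > 0) {
    cat(sprintf("  K2 = k2/k-2 = %.3g (full : partial at equilibrium)\n",
                x$k2 / x$k_minus2))
  }
  invisible(x)
}

#' Equilibrium full:partial occupancy ratio of a scheme
#'
#' @param scheme a [two_step_scheme()].
#' @return `k2 / k_minus2`; `Inf` when `k_minus2` is 0 and `k2 > 0`,
#'   `0` when `k2` is 0.
#' @export
scheme_occupancy_ratio <- function(scheme) {
  stopifnot(inherits(scheme, "two_step_scheme"))
  if (scheme$k2 == 0) return(0)
  if (scheme$k_minus2 == 0) return(Inf)
  scheme$k2 / scheme$k_minus2
}

#' Reference schemes for the WT and betaH160D eIF2B decamers
#'
#' Defaults follow the SPR-derived estimates for the decamer-eIF2
#' interaction: `k1 = 7.0e5` M^-1 s^-1 and `k_minus1 = 0.12` s^-1, with
#' `k_minus2 = 0.044` s^-1 obtained from the fast and slow dissociation
#' rates. The second-step on-rate `k2` is not directly observed; it is
#' inferred from the plateau occupancy ratio (full:partial ~ 8 for WT,
#' ~ 1 for betaH160D) as `k2 = ratio * k_minus2`.
#'
#' @param occupancy_ratio equilibrium full:partial ratio fixing `k2`.
#' @param k1,k_minus1,k_minus2 microscopic rates (see above for defaults).
#' @return A [two_step_scheme()].
#' @export
reference_scheme <- function(occupancy_ratio = 8, k1 = 7.0e5,
                             k_minus1 = 0.12, k_minus2 = 0.044) {
  two_step_scheme(k1, k_minus1, k2 = occupancy_ratio * k_minus2,
                  k_minus2 = k_minus2)
}

#' Dissociation-phase rate matrix of a two-step scheme
#'
#' The 2x2 generator of the bound-state dynamics `(P, F)` once analyte
#' flow stops (free analyte concentration 0):
#' `[[-(k_minus1 + k2), k_minus2], [k2, -k_minus2]]`.
#'
#' @param scheme a [two_step_scheme()].
#' @return A 2x2 numeric matrix.
#' @export
dissociation_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "two_step_scheme"))
  matrix(c(-(scheme$k_minus1 + scheme$k2), scheme$k2,
           scheme$k_minus2, -scheme$k_minus2),
         nrow = 2, dimnames = list(c("P", "F"), c("P", "F")))
}

#' Analytic biexponential dissociation decay from the rate matrix
#'
#' Eigen-decomposition of [dissociation_matrix()]: the total bound signal
#' `P(t) + F(t)` is a sum of two exponentials whose rates are the negated
#' eigenvalues and whose amplitudes follow from projecting the initial
#' bound-state vector onto the eigenvectors. Serves as the closed-form
#' oracle for the ODE integrator.
#'
#' @param scheme a [two_step_scheme()].
#' @param p0,f0 initial partially- and fully-engaged populations.
#' @param times evaluation times (s), measured from dissociation start.
#' @return A list with `rates` (two decay rates, fast first), `amplitudes`
#'   (matching signal amplitudes) and `signal` (evaluated decay).
#' @export
dissociation_eigen_decay <- function(scheme, p0, f0, times) {
  m <- dissociation_matrix(scheme)
  eg <- eigen(m)
  coef <- solve(eg$vectors, c(p0, f0))
  # signal amplitude of each mode = coefficient * column sum of eigenvector
  amp <- coef * colSums(eg$vectors)
  rates <- -eg$values
  ord <- order(rates, decreasing = TRUE)
  rates <- rates[ord]
  amp <- amp[ord]
  signal <- drop(exp(outer(times, -rates)) %*% amp)
  list(rates = rates, amplitudes = amp, signal = signal)
}
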
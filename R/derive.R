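#' Second-step retraction rate from fast and slow dissociation rates
#'
#' The fast dissociation phase is identified with the first-step off-rate
#' (`k_minus1 = kd_fast`) and the slow phase with complexes that must
#' retract the fourth interface before leaving, so that the slow rate is
#' the product of the two off-rates: `k_minus1 * k_minus2 = kd_slow`.
#' Taken literally this relation is dimensionally inconsistent (the right
#' side is s^-1, the left s^-2), so the quotient is evaluated on a 1 s^-1
#' scale: `k_minus2 = (kd_slow / kd_fast) * 1 s^-1`. For the decamer
#' reference rates (`kd_fast = 0.12`, `kd_slow = 5.3e-3`) this gives
#' ~0.044 s^-1.
#'
#' An alternative, dimensionally consistent estimator that matches the
#' slow eigenvalue of the dissociation rate matrix is provided by
#' [derive_k_minus2_eigen()].
#'
#' @param kd_fast fast-phase dissociation rate (s^-1), > 0.
#' @param kd_slow slow-phase dissociation rate (s^-1), in \[0, kd_fast\].
#' @return `k_minus2` (s^-1).
#' @examples
#' derive_k_minus2(0.12, 5.3e-3)  # ~0.044
#' @export
derive_k_minus2 <- function(kd_fast, kd_slow) {
  if (!is.finite(kd_fast) || kd_fast <= 0) {
    stop("kd_fast must be positive", call. = FALSE)
  }
  if (!is.finite(kd_slow) || kd_slow < 0 || kd_slow > kd_fast) {
    stop("kd_slow must lie in [0, kd_fast]", call. = FALSE)
  }
  kd_slow / kd_fast
}

#' Eigenvalue-consistent second-step retraction rate
#'
#' Solves for the `k_minus2` that makes the slow eigenvalue of the
#' dissociation rate matrix
#' `[[-(k_minus1 + k2), k_minus2], [k2, -k_minus2]]` equal the observed
#' slow decay rate. The eigenvalues satisfy
#' `lambda^2 + (k_minus1 + k2 + k_minus2) lambda + k_minus1 k_minus2 = 0`,
#' so with `lambda = -kd_slow`:
#' \deqn{k_{-2} = \frac{k_{slow} (k_{-1} + k_2 - k_{slow})}{k_{-1} - k_{slow}}}
#'
#' @param kd_slow observed slow decay rate (s^-1).
#' @param k_minus1 first-step off-rate (s^-1), > `kd_slow`.
#' @param k2 second-step on-rate (s^-1).
#' @return `k_minus2` (s^-1).
#' @export
derive_k_minus2_eigen <- function(kd_slow, k_minus1, k2) {
  stopifnot(is.finite(kd_slow), is.finite(k_minus1), is.finite(k2),
            kd_slow >= 0, k2 >= 0)
  if (k_minus1 <= kd_slow) {
    stop("k_minus1 must exceed the observed slow rate", call. = FALSE)
  }
  kd_slow * (k_minus1 + k2 - kd_slow) / (k_minus1 - kd_slow)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `KD = kd / ka`. Full precision is retained in the `kd_molar` field; the
#' `kd_nm_display` field carries the two-significant-figure nanomolar
#' value used for reporting.
#'
#' @param ka association rate constant (M^-1 s^-1), > 0.
#' @param kd dissociation rate constant (s^-1), >= 0.
#' @param phase_label one of `"fast"`, `"slow"`, `"single"`.
#' @return An `affinity_record` list: `kd_molar`, `kd_nm_display`,
#'   `phase_label`, `ka`, `kd_rate`.
#' @examples
#' compute_affinity(7.0e5, 4.2e-3, "slow")  # 6.0 nM
#' @export
compute_affinity <- function(ka, kd, phase_label = c("single", "fast", "slow")) {
  phase_label <- match.arg(phase_label)
  if (!is.finite(ka) || ka <= 0) stop("ka must be positive", call. = FALSE)
  if (!is.finite(kd) || kd < 0) stop("kd must be non-negative", call. = FALSE)
  kd_m <- kd / ka
  structure(list(
    kd_molar = kd_m,
    kd_nm_display = signif(kd_m * 1e9, 2),
    phase_label = phase_label,
    ka = ka, kd_rate = kd),
    class = "affinity_record")
}

#' @export
print.affinity_record <- function(x, ...) {
  cat(sprintf("KD (%s phase) = %g nM  [kd/ka = %.4g / %.4g]\n",
              x$phase_label, x$kd_nm_display, x$kd_rate, x$ka))
  invisible(x)
}

#' Fully- to partially-engaged occupancy ratio from the fast-phase percent
#'
#' Interpreting the fast-phase dissociation amplitude as the partially
#' engaged (IF1-IF3) population and the slow phase as the fully engaged
#' (IF1-IF4) population, the equilibrium occupancy ratio is
#' `(100 - f) / f` for fast-phase percentage `f`. The ~11% WT plateau
#' gives a ratio of ~8; the ~55% mutant plateau gives ~0.8 (~1).
#'
#' @param fraction_fast_percent fast-phase dissociation amplitude (%),
#'   strictly between 0 and 100.
#' @return Dimensionless ratio full:partial.
#' @examples
#' occupancy_ratio(11)  # ~8
#' @export
occupancy_ratio <- function(fraction_fast_percent) {
  f <- fraction_fast_percent
  if (!is.finite(f)) stop("fraction must be finite", call. = FALSE)
  if (f <= 0) {
    warning("fast-phase fraction is 0%: ratio is infinite", call. = FALSE)
    return(Inf)
  }
  if (f >= 100) {
    warning("fast-phase fraction is 100%: ratio is zero", call. = FALSE)
    return(0)
  }
  (100 - f) / f
}

#' Gas constant (J mol^-1 K^-1)
#' @keywords internal
.R_GAS <- 8.31446261815324

#' Free-energy profile of the two-step engagement
#'
#' State-level free energies of the unbound, partially engaged (IF1-IF3)
#' and fully engaged (IF1-IF4) states from the equilibrium constants of
#' each step: the first-step binding free energy is
#' `-RT ln(k1 C0 / k_minus1)` (standard state `C0`, default 1 M) and the
#' second step adds `-RT ln(k2 / k_minus2)`. Transition-state barriers are
#' optionally attached via the Eyring relation
#' `dG* = -RT ln(k h / (kappa kB T))`.
#'
#' @param scheme a [two_step_scheme()] with all rates > 0.
#' @param temperature kelvin.
#' @param standard_concentration reference concentration for the
#'   bimolecular step (M).
#' @param barriers include Eyring barrier heights.
#' @param kappa Eyring transmission prefactor.
#' @return An `energy_profile` list: `state_labels`,
#'   `state_free_energies` (kJ/mol, unbound = 0), optional
#'   `barrier_free_energies`, `temperature`.
#' @examples
#' free_energy_profile(reference_scheme(8), 298)
#' @export
free_energy_profile <- function(scheme, temperature = 298.15,
                                standard_concentration = 1,
                                barriers = FALSE, kappa = 1) {
  stopifnot(inherits(scheme, "two_step_scheme"), temperature > 0)
  rates <- unlist(scheme[c("k1", "k_minus1", "k2", "k_minus2")])
  if (any(rates == 0)) {
    stop("free-energy profile requires all four rates > 0 (a zero rate ",
         "implies an infinite free-energy difference)", call. = FALSE)
  }
  rt <- .R_GAS * temperature / 1000  # kJ/mol
  dg1 <- -rt * log(scheme$k1 * standard_concentration / scheme$k_minus1)
  dg2 <- -rt * log(scheme$k2 / scheme$k_minus2)
  out <- list(
    state_labels = c("unbound", "partial_IF1_3", "full_IF1_4"),
    state_free_energies = c(0, dg1, dg1 + dg2),
    temperature = temperature,
    standard_concentration = standard_concentration)
  if (barriers) {
    kb_h <- 1.380649e-23 / 6.62607015e-34  # kB/h, s^-1 K^-1
    eyring <- function(k) -rt * log(k / (kappa * kb_h * temperature))
    # barrier tops relative to the preceding state
    out$barrier_free_energies <- c(
      eyring(scheme$k1 * standard_concentration),
      out$state_free_energies[2] + eyring(scheme$k2))
  }
  structure(out, class = "energy_profile")
}

#' Difference of two free-energy profiles (ddG)
#'
#' @param a,b `energy_profile` objects on matching state labels.
#' @return Numeric vector of `a - b` state free energies (kJ/mol).
#' @export
energy_profile_difference <- function(a, b) {
  stopifnot(inherits(a, "energy_profile"), inherits(b, "energy_profile"),
            identical(a$state_labels, b$state_labels))
  stats::setNames(a$state_free_energies - b$state_free_energies,
                  a$state_labels)
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile at %g K (reference: unbound = 0)\n",
              x$temperature))
  for (i in seq_along(x$state_labels)) {
    cat(sprintf("  %-14s %8.2f kJ/mol\n", x$state_labels[i],
                x$state_free_energies[i]))
  }
  invisible(x)
}
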
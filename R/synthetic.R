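#' Additive Gaussian instrument-noise model
#'
#' The single noise family used by the generators. `sigma` is in signal
#' units unless `relative = TRUE`, in which case it is a fraction of the
#' trace amplitude. Identical seeds give identical output.
#'
#' @param sigma standard deviation, >= 0.
#' @param seed integer seed.
#' @param relative interpret `sigma` as a fraction of signal amplitude.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = 0, seed = 1L, relative = FALSE) {
  stopifnot(is.finite(sigma), sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed),
                 relative = relative),
            class = "noise_model")
}

# evaluate fn() under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

.add_noise <- function(signal, noise, amplitude = NULL) {
  if (is.null(noise) || noise$sigma == 0) return(signal)
  sd <- if (noise$relative) {
    noise$sigma * if (is.null(amplitude)) max(abs(signal)) else amplitude
  } else {
    noise$sigma
  }
  signal + .with_seed(noise$seed, function() {
    stats::rnorm(length(signal), 0, sd)
  })
}

#' Generate a synthetic SPR sensorgram set
#'
#' Simulates one cycle per (concentration, association duration) pair
#' from a two-step scheme via [simulate_sensorgram()] and adds additive
#' Gaussian instrument noise. With `sigma = 0` the traces equal the ODE
#' (or phase-model) simulation exactly. The default design mirrors the
#' titration protocol: 2-fold dilutions, 60 s association, 600 s
#' dissociation.
#'
#' @param scheme a [two_step_scheme()].
#' @param concentrations analyte concentrations (M).
#' @param association_durations association times (s); recycled against
#'   `concentrations` if length 1, otherwise paired elementwise when the
#'   lengths match, else the full cross design is generated.
#' @param dissociation_duration seconds.
#' @param capacity Rmax (RU).
#' @param time_step seconds.
#' @param noise a [noise_model()]; per-cycle seeds are derived as
#'   `seed + cycle index`.
#' @param dissociation passed to [simulate_sensorgram()].
#' @return List of `sensorgram` objects.
#' @export
make_sensorgram_set <- function(scheme,
                                concentrations = 62.5e-9 / 2^(0:5),
                                association_durations = 60,
                                dissociation_duration = 600,
                                capacity = 100, time_step = 0.5,
                                noise = noise_model(0),
                                dissociation = c("ode", "phase")) {
  dissociation <- match.arg(dissociation)
  nc <- length(concentrations); na <- length(association_durations)
  design <- if (na == 1) {
    data.frame(conc = concentrations, ta = association_durations)
  } else if (nc == na) {
    data.frame(conc = concentrations, ta = association_durations)
  } else {
    expand.grid(conc = concentrations, ta = association_durations)
  }
  lapply(seq_len(nrow(design)), function(i) {
    sg <- simulate_sensorgram(scheme, design$conc[i], design$ta[i],
                              dissociation_duration, capacity, time_step,
                              dissociation = dissociation)
    cyc_noise <- noise
    cyc_noise$seed <- noise$seed + i
    sg$signal <- .add_noise(sg$signal, cyc_noise, amplitude = capacity)
    sg
  })
}

#' Generate a synthetic nucleotide-exchange time course
#'
#' First-order exponential fluorescence gain (loading) or loss
#' (unloading) sampled on a regular cadence, plus additive Gaussian
#' noise. The default design matches the plate-reader protocol: one
#' point every 10 s for 60 min.
#'
#' @param t_half half-life (minutes), > 0.
#' @param amplitude signal change (a.u.).
#' @param baseline starting signal (a.u.).
#' @param duration minutes.
#' @param cadence seconds between points.
#' @param phase `"loading"` or `"unloading"`.
#' @param noise a [noise_model()]; relative sigma scales `amplitude`.
#' @param substrate_concentration,enzyme_concentration,reaction_volume
#'   metadata carried on the result.
#' @return An `exchange_timecourse`.
#' @export
make_exchange_timecourse <- function(t_half, amplitude = 1000,
                                     baseline = 100, duration = 60,
                                     cadence = 10,
                                     phase = c("loading", "unloading"),
                                     noise = noise_model(0),
                                     substrate_concentration = NA_real_,
                                     enzyme_concentration = 10e-9,
                                     reaction_volume = 20e-6) {
  phase <- match.arg(phase)
  stopifnot(t_half > 0)
  times <- seq(0, duration * 60, by = cadence)
  rate <- log(2) / t_half  # per minute
  frac <- 1 - exp(-rate * times / 60)
  y <- if (phase == "loading") baseline + amplitude * frac else
    baseline + amplitude * (1 - frac)
  y <- .add_noise(y, noise, amplitude = amplitude)
  exchange_timecourse(times, y,
                      substrate_concentration = substrate_concentration,
                      enzyme_concentration = enzyme_concentration,
                      reaction_volume = reaction_volume, phase = phase)
}

#' Generate a synthetic Michaelis-Menten titration
#'
#' Initial velocities `v = Vmax C / (KM + C)` per replicate with additive
#' Gaussian noise (relative sigma scales Vmax). The default concentration
#' design spans 0-4 uM substrate.
#'
#' @param v_max pmol/min.
#' @param k_m molar.
#' @param concentrations substrate concentrations (M).
#' @param replicates number of replicates.
#' @param noise a [noise_model()]; per-replicate seeds derived from
#'   `seed + replicate`.
#' @return Data frame `concentration`, `velocity`, `replicate`.
#' @export
make_mm_titration <- function(v_max, k_m,
                              concentrations = c(0.0625, 0.125, 0.25, 0.5,
                                                 1, 2, 4) * 1e-6,
                              replicates = 3,
                              noise = noise_model(0)) {
  stopifnot(v_max >= 0, k_m > 0, replicates >= 1)
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    v <- v_max * concentrations / (k_m + concentrations)
    rep_noise <- noise
    rep_noise$seed <- noise$seed + r
    v <- .add_noise(v, rep_noise, amplitude = v_max)
    data.frame(concentration = concentrations, velocity = v, replicate = r)
  }))
}

#' Generate a synthetic FRET assembly titration
#'
#' Four-parameter logistic dose response on log concentration, averaged
#' over technical replicates after independent noise draws (the
#' experimental design averages four technical replicates per point).
#'
#' @param ec50 molar; `NA` generates a flat (non-assembling) series at
#'   `floor`.
#' @param concentrations dimerizer concentrations (M); the default is the
#'   standard dose-response design of twelve 2-fold dilutions from 1 uM
#'   plus a zero point.
#' @param floor,ceiling FRET ratio limits.
#' @param hill Hill slope.
#' @param technical_replicates replicate draws averaged per point.
#' @param noise a [noise_model()]; relative sigma scales the dynamic
#'   range.
#' @return A [titration_series()].
#' @export
make_fret_titration <- function(ec50,
                                concentrations = c(0, 1e-6 / 2^(11:0)),
                                floor = 0.3, ceiling = 0.8, hill = 1,
                                technical_replicates = 4,
                                noise = noise_model(0)) {
  y0 <- if (is.na(ec50)) rep(floor, length(concentrations)) else {
    floor + (ceiling - floor) /
      (1 + ifelse(concentrations > 0, (ec50 / concentrations)^hill, Inf))
  }
  reps <- vapply(seq_len(technical_replicates), function(r) {
    rep_noise <- noise
    rep_noise$seed <- noise$seed + r
    .add_noise(y0, rep_noise, amplitude = abs(ceiling - floor))
  }, numeric(length(y0)))
  titration_series(concentrations, rowMeans(reps))
}

#' Generate a toy two-domain structure pair with known hinge and shift
#'
#' Builds a pair of synthetic poly-alanine models mimicking the
#' two-tetramer-half architecture: chain A is a fixed reference domain,
#' chain B a mobile domain, chain C carries two marker residues for
#' pocket measurements. The second model differs from the first by an
#' exact rotation of chain B by `hinge_angle` degrees (about the z axis
#' through chain B's centroid) and an exact displacement of chain C's
#' second marker residue by `pocket_shift` Angstrom along the marker-pair
#' axis. Ground truth is recorded in the `ground_truth` attribute.
#'
#' @param hinge_angle degrees, in \[0, 30\].
#' @param pocket_shift Angstrom.
#' @param n_residues residues per domain.
#' @param seed integer; jitters the helical backbone reproducibly.
#' @return List with `reference` and `moved` [structure_model()] objects
#'   and a `ground_truth` list.
#' @export
make_toy_structures <- function(hinge_angle = 3.5, pocket_shift = 2.9,
                                n_residues = 60, seed = 1L) {
  stopifnot(hinge_angle >= 0, hinge_angle <= 30)
  helix <- function(n, origin) {
    i <- seq_len(n) - 1
    cbind(origin[1] + 2.3 * cos(i * 100 * pi / 180),
          origin[2] + 2.3 * sin(i * 100 * pi / 180),
          origin[3] + 1.5 * i)
  }
  jitter <- .with_seed(seed, function() {
    matrix(stats::rnorm(2 * n_residues * 3, 0, 0.05), ncol = 3)
  })
  xyz_a <- helix(n_residues, c(0, 0, 0)) +
    jitter[seq_len(n_residues), , drop = FALSE]
  xyz_b <- helix(n_residues, c(25, 0, 0)) +
    jitter[n_residues + seq_len(n_residues), , drop = FALSE]
  marker <- rbind(c(10, 12, 20), c(10, 12 + 8, 20))  # 8 A apart, along y

  build <- function(xa, xb, xm, name) {
    atoms <- data.frame(
      chain = c(rep("A", nrow(xa)), rep("B", nrow(xb)), rep("C", nrow(xm))),
      resno = c(seq_len(nrow(xa)), seq_len(nrow(xb)), seq_len(nrow(xm))),
      resid = "ALA", atom = "CA",
      x = c(xa[, 1], xb[, 1], xm[, 1]),
      y = c(xa[, 2], xb[, 2], xm[, 2]),
      z = c(xa[, 3], xb[, 3], xm[, 3]),
      stringsAsFactors = FALSE)
    structure_model(atoms, name = name)
  }
  reference <- build(xyz_a, xyz_b, marker, "toy_reference")

  theta <- hinge_angle * pi / 180
  rot_z <- matrix(c(cos(theta), sin(theta), 0,
                    -sin(theta), cos(theta), 0,
                    0, 0, 1), 3, 3)
  ctr <- colMeans(xyz_b)
  xyz_b2 <- sweep(sweep(xyz_b, 2, ctr) %*% t(rot_z), 2, ctr, "+")
  axis <- (marker[2, ] - marker[1, ])
  axis <- axis / sqrt(sum(axis^2))
  marker2 <- marker
  marker2[2, ] <- marker2[2, ] + pocket_shift * axis
  moved <- build(xyz_a, xyz_b2, marker2, "toy_moved")

  list(reference = reference, moved = moved,
       ground_truth = list(hinge_angle = hinge_angle,
                           pocket_shift = pocket_shift,
                           rotation_axis = c(0, 0, 1),
                           marker_pair = list(c("C", 1), c("C", 2)),
                           reference_selection = atom_selection("A"),
                           mobile_selection = atom_selection("B")))
}
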
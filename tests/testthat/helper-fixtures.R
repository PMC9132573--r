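# shared fixtures for the test suite

# WT-like decamer scheme: k-1 = 0.12 s^-1, k-2 = 0.044 s^-1,
# second-step equilibrium fixed by the full:partial occupancy ratio of 8
wt_scheme <- function() reference_scheme(occupancy_ratio = 8)

# biphasic reference dissociation parameters (WT decamer style)
biphasic_truth <- function() {
  list(kd_fast = 0.12, kd_slow = 4.2e-3, fraction_fast = 0.29)
}

# a phase-model scheme whose dissociation is exactly the biphasic truth:
# k_minus2 chosen so k_minus1 * k_minus2 = kd_slow, k2 from the plateau
biphasic_scheme <- function() {
  tr <- biphasic_truth()
  km2 <- tr$kd_slow / tr$kd_fast
  ratio <- (1 - tr$fraction_fast) / tr$fraction_fast
  two_step_scheme(7.0e5, tr$kd_fast, k2 = ratio * km2, k_minus2 = km2)
}

# small PDB writer for structure-model fixtures (CA-only models)
write_toy_pdb <- function(model, path) {
  at <- model$atoms
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, at$atom[i], at$resid[i], at$chain[i], at$resno[i],
            at$x[i], at$y[i], at$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
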
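test_that("self-superposition gives zero rmsd and the identity rotation", {
  toy <- make_toy_structures(0, 0)
  sup <- superpose(toy$reference, toy$reference, atom_selection("A"))
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  expect_equal(rotation_angle(sup$rotation), 0, tolerance = 1e-6)
})

test_that("a constructed 10-degree rotation is recovered to 1e-6 degrees", {
  toy <- make_toy_structures(0, 0)
  theta <- 10 * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  moved <- transform_structure(toy$reference, rot, c(4, -2, 7))
  sup <- superpose(moved, toy$reference, atom_selection(c("A", "B")))
  expect_lt(abs(rotation_angle(sup$rotation) - 10), 1e-6)
  expect_lt(sup$rmsd, 1e-8)
})

test_that("in-package Kabsch agrees with the bio3d superposition", {
  toy <- make_toy_structures(0, 0)
  set.seed(31)
  rot <- random_rotation()
  moved <- transform_structure(toy$reference, rot, c(1, 2, 3))
  sel <- atom_selection("A")
  sup <- superpose(moved, toy$reference, sel)

  a <- moved$atoms[moved$atoms$chain == "A", c("x", "y", "z")]
  b <- toy$reference$atoms[toy$reference$atoms$chain == "A",
                           c("x", "y", "z")]
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(as.matrix(b))),
                   mobile = as.numeric(t(as.matrix(a)))))
  rmsd_bio3d <- sqrt(mean(colSums(
    (matrix(xyz_fit, nrow = 3) - t(as.matrix(b)))^2)))
  expect_equal(sup$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("hinge angle recovers the constructed domain rotation", {
  expect_equal(hinge_angle(
    make_toy_structures(0, 0)$reference,
    make_toy_structures(0, 0)$reference,
    atom_selection("A"), atom_selection("B"))$angle, 0, tolerance = 1e-6)

  toy <- make_toy_structures(3.5, 0)
  hm <- hinge_angle(toy$reference, toy$moved,
                    toy$ground_truth$reference_selection,
                    toy$ground_truth$mobile_selection)
  expect_lt(abs(hm$angle - 3.5), 1e-6)
  expect_lt(hm$reference_rmsd, 1e-8)
  expect_equal(abs(hm$axis[3]), 1, tolerance = 1e-6)
})

test_that("hinge angle is invariant to joint rigid motions", {
  toy <- make_toy_structures(6.2, 0)
  set.seed(99)
  for (i in 1:5) {
    rot <- random_rotation()
    shift <- stats::rnorm(3, 0, 20)
    a2 <- transform_structure(toy$reference, rot, shift)
    b2 <- transform_structure(toy$moved, rot, shift)
    hm <- hinge_angle(a2, b2, atom_selection("A"), atom_selection("B"))
    expect_equal(hm$angle, 6.2, tolerance = 1e-8)
  }
})

test_that("pocket distances are exact and rigid-motion invariant", {
  atoms <- data.frame(chain = c("A", "B"), resno = c(1, 1),
                      resid = c("GLU", "ARG"), atom = c("CA", "CA"),
                      x = c(0, 3), y = c(0, 4), z = c(0, 0))
  m <- structure_model(atoms)
  expect_equal(pocket_distance(m, list(c("A", 1), c("B", 1)))$distance, 5)

  toy <- make_toy_structures(0, 2.9)
  pm <- pocket_distance(toy$moved, toy$ground_truth$marker_pair,
                        reference = toy$reference)
  expect_equal(pm$delta_vs_reference, 2.9, tolerance = 1e-9)

  set.seed(7)
  shifted <- transform_structure(toy$moved, random_rotation(), c(5, 5, 5))
  pm2 <- pocket_distance(shifted, toy$ground_truth$marker_pair)
  expect_equal(pm2$distance, pm$distance, tolerance = 1e-9)

  expect_error(pocket_distance(m, list(c("A", 1), c("Z", 9))), "not found")
})

test_that("the side-chain tip rule selects the documented atoms", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 2, 2),
    resid = c("ARG", "ARG", "GLU", "GLU"),
    atom = c("CA", "CZ", "CA", "CD"),
    x = c(0, 0, 10, 6), y = 0, z = 0)
  m <- structure_model(atoms)
  expect_equal(pocket_distance(m, list(c("A", 1), c("A", 2)),
                               atom_rule = "CA")$distance, 10)
  expect_equal(pocket_distance(m, list(c("A", 1), c("A", 2)),
                               atom_rule = "tip")$distance, 6)
})

test_that("PDB files round-trip through read_structure with altloc resolution", {
  toy <- make_toy_structures(3.5, 2.9)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(toy$moved, path)
  model <- read_structure(path)
  expect_equal(nrow(model$atoms), nrow(toy$moved$atoms))
  got <- model$atoms[order(model$atoms$chain, model$atoms$resno), ]
  want <- toy$moved$atoms[order(toy$moved$atoms$chain,
                                toy$moved$atoms$resno), ]
  expect_equal(got$x, want$x, tolerance = 1e-3)
  expect_equal(got$z, want$z, tolerance = 1e-3)

  # alternate locations resolve to the higher-occupancy conformer
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
    "END")
  alt_path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, alt_path)
  m2 <- suppressMessages(read_structure(alt_path))
  expect_equal(nrow(m2$atoms), 2)
  expect_equal(m2$atoms$x[m2$atoms$resno == 1], 9)
})
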
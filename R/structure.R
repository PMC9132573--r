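#' Structure model container
#'
#' A light atomic model for conformation measurements: one row per atom
#' with chain, residue number, residue name, atom name and coordinates in
#' Angstrom. Chain-to-subunit mapping between depositions (the alpha-
#' through-epsilon subunits and their primed copies) is handled by the
#' caller via selections, since chain IDs differ between PDB entries.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`,
#'   `atom`, `x`, `y`, `z` (and optionally `occupancy`, `alt`).
#' @param name optional model label.
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms, name = "model") {
  req <- c("chain", "resno", "resid", "atom", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom,
               if ("alt" %in% names(atoms)) atoms$alt else "")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom, altloc) records", call. = FALSE)
  }
  structure(list(atoms = atoms, name = name), class = "structure_model")
}

#' Read a structure model from a PDB or mmCIF file
#'
#' Files are parsed with bio3d; alternate locations are resolved to the
#' highest-occupancy conformer (logged via message).
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param name model label; defaults to the file name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, name = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE) else
    bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid,
    atom = at$elety, x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    stringsAsFactors = FALSE)
  # resolve altlocs: keep highest occupancy per (chain, resno, atom)
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$atom)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      idx[which.max(atoms$occupancy[idx])]
    }), use.names = FALSE)
    dropped <- nrow(atoms) - length(keep)
    if (dropped > 0) {
      message(sprintf(
        "resolved %d alternate-location atoms to highest occupancy", dropped))
    }
    atoms <- atoms[sort(keep), ]
    atoms$alt <- ""
  }
  structure_model(atoms, name = name)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d atoms, chains %s\n", x$name,
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Atom selection by chain and residue range
#'
#' @param chain chain identifier(s).
#' @param resno optional residue numbers (vector or range); `NULL` keeps
#'   all residues of the chain(s).
#' @param atom atom-name filter, default `"CA"`.
#' @return A `selection` list usable by [superpose()] and [hinge_angle()].
#' @export
atom_selection <- function(chain, resno = NULL, atom = "CA") {
  structure(list(chain = chain, resno = resno, atom = atom),
            class = "selection")
}

# coordinate matrix of the selection, ordered by (chain, resno)
.select_coords <- function(model, sel) {
  at <- model$atoms
  keep <- at$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & at$resno %in% sel$resno
  if (!is.null(sel$atom)) keep <- keep & at$atom %in% sel$atom
  at <- at[keep, ]
  at <- at[order(at$chain, at$resno, at$atom), ]
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       key = paste(at$chain, at$resno, at$atom))
}

# paired coordinates shared by both models under a selection
.paired_coords <- function(a, b, sel) {
  ca <- .select_coords(a, sel)
  cb <- .select_coords(b, sel)
  shared <- intersect(ca$key, cb$key)
  list(a = ca$xyz[match(shared, ca$key), , drop = FALSE],
       b = cb$xyz[match(shared, cb$key), , drop = FALSE],
       n = length(shared))
}

#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation and translation mapping `mobile` selection
#' coordinates onto `reference`, by SVD of the covariance matrix with the
#' usual determinant sign correction; the rotation matrix itself is
#' returned so that downstream hinge measurements can convert residual
#' rotations to axis-angle form.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param selection an [atom_selection()] resolvable in both models
#'   (>= 3 shared atoms; >= 50 recommended for domain alignments).
#' @return A `superposition` list: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (A), `atom_count`. Applying
#'   `x %*% t(rotation) + translation` maps mobile coordinates onto the
#'   reference frame.
#' @export
superpose <- function(mobile, reference, selection) {
  p <- .paired_coords(mobile, reference, selection)
  if (p$n < 3) {
    stop(sprintf("selection maps only %d shared atoms (need >= 3)", p$n),
         call. = FALSE)
  }
  km <- .kabsch(p$a, p$b)
  aligned <- p$a %*% t(km$rotation) +
    matrix(km$translation, p$n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((aligned - p$b)^2)))
  structure(list(rotation = km$rotation, translation = km$translation,
                 rmsd = rmsd, atom_count = p$n),
            class = "superposition")
}

# Kabsch core on paired coordinate matrices (rows = atoms)
.kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  h <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(ct - rot %*% cf))
}

#' Apply a rigid transform to a structure model
#'
#' @param model a [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (A).
#' @return Transformed [structure_model()].
#' @export
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  out <- model
  out$atoms[, c("x", "y", "z")] <- xyz
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d atoms, rmsd = %.3f A, rotation angle = %.3f deg\n",
              x$atom_count, x$rmsd, rotation_angle(x$rotation)))
  invisible(x)
}

#' Rotation angle of a rotation matrix (degrees)
#'
#' `acos((trace(R) - 1) / 2)`, clamped against round-off.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(rotation) {
  ctheta <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Hinge angle between two models' mobile domains
#'
#' Measures the rocking of one tetramer half relative to the other:
#' model `b` is first superposed onto model `a` over
#' `reference_selection`; the residual rotation that then best maps `b`'s
#' `mobile_selection` onto `a`'s is converted to axis-angle form. The
#' angle is invariant to any rigid motion applied jointly to either
#' model.
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param reference_selection selection defining the common frame (the
#'   fixed tetramer half).
#' @param mobile_selection selection of the moving half.
#' @return A `hinge_measure` list: `angle` (degrees), `axis` (unit
#'   vector), `reference_rmsd`, `mobile_rmsd`, `atom_count`.
#' @export
hinge_angle <- function(model_a, model_b, reference_selection,
                        mobile_selection) {
  for (sel in list(reference_selection, mobile_selection)) {
    for (m in list(model_a, model_b)) {
      got <- .select_coords(m, sel)
      if (nrow(got$xyz) == 0) {
        stop(sprintf(
          "selection (chain %s) resolves no atoms in model '%s'",
          paste(sel$chain, collapse = ","), m$name), call. = FALSE)
      }
    }
  }
  ref_sup <- superpose(model_b, model_a, reference_selection)
  b_aligned <- transform_structure(model_b, ref_sup$rotation,
                                   ref_sup$translation)
  mob <- .paired_coords(b_aligned, model_a, mobile_selection)
  km <- .kabsch(mob$a, mob$b)
  angle <- rotation_angle(km$rotation)
  aligned <- mob$a %*% t(km$rotation) +
    matrix(km$translation, mob$n, 3, byrow = TRUE)
  structure(list(
    angle = angle,
    axis = .rotation_axis(km$rotation),
    reference_rmsd = ref_sup$rmsd,
    mobile_rmsd = sqrt(mean(rowSums((aligned - mob$b)^2))),
    atom_count = mob$n),
    class = "hinge_measure")
}

.rotation_axis <- function(rot) {
  v <- c(rot[3, 2] - rot[2, 3], rot[1, 3] - rot[3, 1], rot[2, 1] - rot[1, 2])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0, 1))  # angle ~0 or 180: axis ill-defined
  v / n
}

#' @export
print.hinge_measure <- function(x, ...) {
  cat(sprintf("Hinge angle = %.3f deg over %d atoms (axis %s)\n",
              x$angle, x$atom_count,
              paste(sprintf("%.2f", x$axis), collapse = ", ")))
  invisible(x)
}

# side-chain tip atoms by residue type, for the "tip" atom rule
.TIP_ATOMS <- c(ARG = "CZ", LYS = "NZ", GLU = "CD", ASP = "CG", GLN = "CD",
                ASN = "CG", HIS = "NE2", PHE = "CZ", TYR = "OH", TRP = "CZ2",
                LEU = "CG", ILE = "CD1", VAL = "CB", MET = "SD", CYS = "SG",
                SER = "OG", THR = "OG1", ALA = "CB", GLY = "CA", PRO = "CG")

#' Residue-pair pocket distance
#'
#' Euclidean distance between two residues under a named atom rule:
#' `"CA"` (default, alpha carbons) or `"tip"` (side-chain tip atoms, e.g.
#' CZ for Arg, CD for Glu). When a reference model is supplied the same
#' distance is measured there and the widening
#' `delta_vs_reference = distance(model) - distance(reference)` is
#' reported.
#'
#' @param model a [structure_model()].
#' @param pair list of two `c(chain, resno)` vectors (resno may be
#'   numeric).
#' @param atom_rule `"CA"` or `"tip"`.
#' @param reference optional reference [structure_model()].
#' @return A `pocket_measure` list: `distance` (A),
#'   `delta_vs_reference` (A or NA), `residue_pair`, `atom_rule`.
#' @export
pocket_distance <- function(model, pair, atom_rule = c("CA", "tip"),
                            reference = NULL) {
  atom_rule <- match.arg(atom_rule)
  stopifnot(is.list(pair), length(pair) == 2)
  d <- .pair_distance(model, pair, atom_rule)
  delta <- NA_real_
  if (!is.null(reference)) {
    delta <- d - .pair_distance(reference, pair, atom_rule)
  }
  structure(list(distance = d, delta_vs_reference = delta,
                 residue_pair = pair, atom_rule = atom_rule),
            class = "pocket_measure")
}

.pair_distance <- function(model, pair, atom_rule) {
  pt <- lapply(pair, function(p) {
    chain <- as.character(p[1]); resno <- as.numeric(p[2])
    at <- model$atoms
    rows <- at[at$chain == chain & at$resno == resno, ]
    if (nrow(rows) == 0) {
      stop(sprintf("residue %s:%g not found in model '%s'", chain, resno,
                   model$name), call. = FALSE)
    }
    want <- if (atom_rule == "CA") "CA" else {
      tip <- .TIP_ATOMS[rows$resid[1]]
      if (is.na(tip)) "CA" else tip
    }
    hit <- rows[rows$atom == want, ]
    if (nrow(hit) == 0) hit <- rows[rows$atom == "CA", ]
    if (nrow(hit) == 0) {
      stop(sprintf("no %s (or CA) atom for residue %s:%g", want, chain,
                   resno), call. = FALSE)
    }
    as.numeric(hit[1, c("x", "y", "z")])
  })
  sqrt(sum((pt[[1]] - pt[[2]])^2))
}

#' @export
print.pocket_measure <- function(x, ...) {
  cat(sprintf("Pocket distance (%s rule) = %.3f A", x$atom_rule, x$distance))
  if (!is.na(x$delta_vs_reference)) {
    cat(sprintf(" (delta vs reference = %+.3f A)", x$delta_vs_reference))
  }
  cat("\n")
  invisible(x)
}
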
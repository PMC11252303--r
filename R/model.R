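# Atomic / pseudo-atomic coordinate models.

#' Construct an atomic model
#'
#' A minimal coordinate container: one row per atom (or pseudo-atom), a
#' positive mass weight per atom and a free-text label. Positions are in
#' Angstrom. Real structures parsed from PDB files and the single-Gaussian
#' pseudo-atom subunits produced by the synthetic generators share this type.
#'
#' @param xyz numeric matrix, n x 3, atom positions in Angstrom.
#' @param mass_weight positive per-atom weights (recycled from length 1).
#' @param label per-atom labels (recycled).
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(xyz, mass_weight = 1, label = "ATOM") {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0L) stop("empty model: no atoms")
  if (ncol(xyz) != 3L) stop("`xyz` must have 3 columns")
  if (!all(is.finite(xyz))) stop("atom positions must be finite")
  mass_weight <- rep_len(as.numeric(mass_weight), nrow(xyz))
  if (any(!is.finite(mass_weight)) || any(mass_weight <= 0))
    stop("`mass_weight` must be positive and finite")
  structure(list(xyz = unname(xyz), mass_weight = mass_weight,
                 label = rep_len(as.character(label), nrow(xyz))),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, total mass weight %.4g\n",
              nrow(x$xyz), sum(x$mass_weight)))
  ext <- apply(x$xyz, 2, range)
  cat(sprintf("  extent (A): x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

# approximate atomic masses for element-weighted parsing
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, FE = 55.845, MG = 24.305,
                     ZN = 65.38, CA = 40.078, "NA" = 22.990, K = 39.098)

#' Read a PDB coordinate file
#'
#' Parses ATOM (and optionally HETATM) records via \pkg{bio3d} into an
#' [atomic_model]. By default every atom gets mass weight 1; with
#' `weights = "element"` approximate atomic masses are used instead.
#'
#' @param path path to a PDB file.
#' @param het include HETATM records? Default `FALSE`.
#' @param weights `"uniform"` (weight 1 per atom) or `"element"`.
#' @return An [atomic_model].
#' @export
read_model <- function(path, het = FALSE, weights = c("uniform", "element")) {
  weights <- match.arg(weights)
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  if (!het) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty model: no ", if (het) "ATOM/HETATM" else "ATOM",
         " records in ", path)
  w <- if (weights == "element") {
    el <- toupper(trimws(atoms$elesy))
    m <- .element_masses[el]
    m[is.na(m)] <- 12
    unname(m)
  } else 1
  atomic_model(cbind(atoms$x, atoms$y, atoms$z), mass_weight = w,
               label = trimws(atoms$elety))
}

#' Write an atomic model as PDB
#'
#' Writes positions as ATOM records (single chain, one residue per atom) via
#' \pkg{bio3d}. Coordinates survive a write/read round trip to the 1e-3 A
#' precision of the PDB fixed-width format.
#'
#' @param model an [atomic_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  n <- nrow(model$xyz)
  bio3d::write.pdb(file = path, xyz = as.vector(t(model$xyz)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = rep("GLY", n), elety = rep("CA", n),
                   chain = rep("A", n), o = rep(1, n),
                   b = rep(0, n))
  invisible(path)
}

# rotation matrices (degrees); z-y-z Euler convention for rigid fits
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' z-y-z Euler rotation matrix
#'
#' @param alpha,beta,gamma rotation angles in degrees; the realized rotation
#'   is `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' @return 3 x 3 rotation matrix.
#' @export
euler_zyz <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_y(beta) %*% rot_z(gamma)
}

#' Angle between two rotations
#'
#' Geodesic distance on SO(3) in degrees; used to compare a recovered rigid
#' fit with a known ground-truth rotation without Euler-angle gauge issues.
#'
#' @param R1,R2 3 x 3 rotation matrices.
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(R1 %*% t(R2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' Apply a rigid transform to a model
#'
#' Rotates the model about `center` (its centroid by default) and then
#' translates it.
#'
#' @param model an [atomic_model].
#' @param R 3 x 3 rotation matrix (e.g. from [euler_zyz()]).
#' @param translation length-3 translation, Angstrom.
#' @param center rotation centre; defaults to the model centroid.
#' @return The transformed [atomic_model].
#' @export
transform_model <- function(model, R = diag(3), translation = c(0, 0, 0),
                            center = NULL) {
  if (is.null(center)) center <- colMeans(model$xyz)
  xyz <- sweep(model$xyz, 2, center) %*% t(R)
  xyz <- sweep(xyz, 2, center + translation, "+")
  model$xyz <- xyz
  model
}
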
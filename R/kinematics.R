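## Dihedral-space kinematics: the search's degrees of freedom are the
## backbone phi/psi torsions.  A conformation caches its dihedral vector;
## set_dihedral() rotates all atoms C-terminal to the rotated bond (up to the
## next chain gap) so bond lengths, bond angles and all other torsions are
## untouched.

#' Construct a conformation from a structure
#'
#' @param structure A `pw_structure`.
#' @return A `pw_conformation`: list with `structure` and cached `phi`/`psi`
#'   per-residue torsions in degrees (NA where undefined: chain termini and
#'   gap-adjacent residues).
#' @export
new_conformation <- function(structure) {
  structure <- as_structure(structure)
  dih <- compute_dihedrals(structure)
  structure(list(structure = structure, phi = dih$phi, psi = dih$psi),
            class = "pw_conformation")
}

#' @export
print.pw_conformation <- function(x, ...) {
  cat(sprintf("pw_conformation: %d residues (%d defined phi, %d defined psi)\n",
              n_residues(x$structure), sum(!is.na(x$phi)), sum(!is.na(x$psi))))
  invisible(x)
}

#' Compute backbone phi/psi dihedral angles
#'
#' phi(i) = torsion(C(i-1), N(i), CA(i), C(i)); psi(i) = torsion(N(i), CA(i),
#' C(i), N(i+1)), IUPAC sign convention, degrees in (-180, 180].  The first
#' residue has no phi, the last no psi, and torsions spanning a chain gap are
#' undefined (NA).
#'
#' @param x A `pw_conformation` or `pw_structure`.
#' @return List with numeric vectors `phi` and `psi` (length = residue count).
#' @export
compute_dihedrals <- function(x) {
  s <- as_structure(x)
  n <- n_residues(s)
  xyz <- s$xyz; ra <- s$res_atoms
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !s$gap_after[i - 1]) {
      phi[i] <- torsion_angle(xyz[ra[i - 1, "C"], ], xyz[ra[i, "N"], ],
                              xyz[ra[i, "CA"], ], xyz[ra[i, "C"], ])
    }
    if (i < n && !s$gap_after[i]) {
      psi[i] <- torsion_angle(xyz[ra[i, "N"], ], xyz[ra[i, "CA"], ],
                              xyz[ra[i, "C"], ], xyz[ra[i + 1, "N"], ])
    }
  }
  list(phi = phi, psi = psi)
}

#' Set one backbone torsion, propagating C-terminally
#'
#' Returns a new conformation in which the named torsion equals `new_value`.
#' All atoms C-terminal to the rotated bond move rigidly about the bond axis:
#' for phi(i) these are CB(i), C(i), O(i) and every atom of residues i+1
#' onward; for psi(i), O(i) and residues i+1 onward.  Propagation stops at
#' the next chain gap, which acts as a rotation barrier.
#'
#' @param conformation A `pw_conformation`.
#' @param residue_index 1-based residue index.
#' @param angle_kind `"phi"` or `"psi"`.
#' @param new_value Target torsion, degrees (interpreted mod 360).
#' @return A new `pw_conformation` with refreshed dihedral cache.
#' @export
set_dihedral <- function(conformation, residue_index, angle_kind, new_value) {
  stopifnot(inherits(conformation, "pw_conformation"))
  angle_kind <- match.arg(angle_kind, c("phi", "psi"))
  s <- conformation$structure
  n <- n_residues(s)
  if (residue_index < 1 || residue_index > n)
    stop("residue_index out of range")
  cur <- if (angle_kind == "phi") conformation$phi[residue_index]
         else conformation$psi[residue_index]
  if (is.na(cur))
    stop(sprintf("%s is undefined at residue %d", angle_kind, residue_index))
  delta <- new_value - cur
  ra <- s$res_atoms
  xyz <- s$xyz
  i <- residue_index
  if (angle_kind == "phi") {
    origin <- xyz[ra[i, "N"], ]
    axis <- xyz[ra[i, "CA"], ] - origin
    local <- ra[i, c("CB", "C", "O")]
  } else {
    origin <- xyz[ra[i, "CA"], ]
    axis <- xyz[ra[i, "C"], ] - origin
    local <- ra[i, "O"]
  }
  gaps <- which(s$gap_after)
  stop_res <- if (any(gaps >= i)) min(gaps[gaps >= i]) else n
  down <- if (stop_res > i) as.vector(ra[(i + 1):stop_res, ]) else integer(0)
  moving <- c(local[!is.na(local)], down[!is.na(down)])
  if (abs(delta) > 0) {
    xyz[moving, ] <- rotate_about_axis(xyz[moving, , drop = FALSE],
                                       origin, axis, delta)
  }
  s$xyz <- xyz
  out <- conformation
  out$structure <- s
  val <- wrap_angle(new_value)
  if (angle_kind == "phi") out$phi[i] <- val else out$psi[i] <- val
  out
}

wrap_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

#' CA coordinates of paired residues
#'
#' @param x A `pw_conformation` or `pw_structure`.
#' @param residue_index Integer vector of residue indices (default all).
#' @return M x 3 matrix of CA coordinates.
#' @export
ca_coords <- function(x, residue_index = NULL) {
  s <- as_structure(x)
  if (is.null(residue_index)) residue_index <- seq_len(n_residues(s))
  s$xyz[s$res_atoms[residue_index, "CA"], , drop = FALSE]
}

#' Least RMSD between two conformations
#'
#' Optimal-superposition RMSD over the CA atoms of paired residues.
#'
#' @param a,b `pw_conformation` or `pw_structure` objects.
#' @param pairing A `pw_pairing` from [pair_residues()]; identity pairing is
#'   assumed when omitted and the structures have equal residue counts.
#' @return lRMSD in Angstrom.
#' @export
lrmsd <- function(a, b, pairing = NULL) {
  sa <- as_structure(a); sb <- as_structure(b)
  if (is.null(pairing)) {
    if (n_residues(sa) != n_residues(sb))
      stop("pairing required for structures of different length")
    mapping <- cbind(seq_len(n_residues(sa)), seq_len(n_residues(sa)))
  } else {
    mapping <- pairing$mapping
  }
  superpose(ca_coords(sa, mapping[, 1]), ca_coords(sb, mapping[, 2]))$rmsd
}
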
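## Synthetic fixtures: ideal-geometry peptides built from specified torsions
## (NeRF-style sequential placement) and transition pairs with engineered
## hinges.  The ideal-geometry table below is shared with the default energy
## parameters so a freshly built fixture sits at the minimum of the bonded
## terms.

#' Ideal covalent geometry shared by the fixture builder and energy defaults
#'
#' Bond lengths in Angstrom; placement bond angles and torsions in degrees.
#' `omega` is the peptide-bond torsion (trans), `cb_torsion` is
#' torsion(C, N, CA, CB) fixing the L-configuration of the C-beta.
#'
#' @return Named list of geometric constants.
#' @export
ideal_geometry <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
    b_c_o = 1.231, b_ca_cb = 1.530,
    a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.9,
    a_ca_c_o = 120.4, a_n_ca_cb = 110.5,
    omega = 180, cb_torsion = 122.6
  )
}

#' Specification of a synthetic peptide fixture
#'
#' @param n_residues Number of residues.
#' @param sequence 1-letter amino-acid string (recycled single letter
#'   allowed); default all-alanine.
#' @param phi,psi Per-residue target torsions in degrees (scalars recycled).
#'   phi of the first and psi of the last residue are ignored (undefined).
#' @param hinge_residues Integer residue indices designated as the engineered
#'   hinge.
#' @param seed Integer seed for any randomized fixture content.
#' @return A `pw_fixture_spec` list.
#' @export
fixture_spec <- function(n_residues, sequence = NULL, phi = -57, psi = -47,
                         hinge_residues = integer(0), seed = 1L) {
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  if (nchar(sequence) == 1) sequence <- strrep(sequence, n_residues)
  if (nchar(sequence) != n_residues)
    stop("sequence length must equal n_residues")
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% AA_321)) stop("invalid sequence letter: ",
                                 paste(setdiff(aa, AA_321), collapse = ""))
  if (length(hinge_residues) > 0 &&
      (min(hinge_residues) < 1 || max(hinge_residues) > n_residues))
    stop("hinge_residues out of range")
  structure(list(n_residues = as.integer(n_residues), sequence = sequence,
                 phi = rep_len(phi, n_residues), psi = rep_len(psi, n_residues),
                 hinge_residues = as.integer(hinge_residues),
                 seed = as.integer(seed)),
            class = "pw_fixture_spec")
}

#' Build an ideal-geometry peptide from a fixture spec
#'
#' Places N, CA, C sequentially with ideal bond lengths and angles and the
#' requested phi/psi (omega fixed trans), then adds the carbonyl O (anti to
#' the next amide N) and C-beta (L-configuration); glycine gets no C-beta.
#' Recomputing dihedrals from the built coordinates reproduces the requested
#' torsions to better than 1e-6 degrees.
#'
#' @param spec A `pw_fixture_spec`.
#' @return A `pw_conformation`.
#' @export
build_peptide <- function(spec) {
  stopifnot(inherits(spec, "pw_fixture_spec"))
  g <- ideal_geometry()
  n <- spec$n_residues
  aa3 <- names(AA_321)[match(strsplit(spec$sequence, "")[[1]], AA_321)]
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  ## first residue frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ]  <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            g$b_c_n, g$a_ca_c_n, spec$psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ]  <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                            g$b_ca_c, g$a_n_ca_c, spec$phi[i])
    }
    if (aa3[i] != "GLY") {
      CB[i, ] <- nerf_place(C[i, ], N[i, ], CA[i, ],
                            g$b_ca_cb, g$a_n_ca_cb, g$cb_torsion)
    }
  }
  for (i in seq_len(n)) {
    psi_i <- if (i < n) spec$psi[i] else 180
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi_i + 180)
  }
  ## assemble atom records in fixed order N, CA, C, O, CB
  rows <- list()
  for (i in seq_len(n)) {
    nm <- if (aa3[i] == "GLY") c("N", "CA", "C", "O") else RETAINED_ATOMS
    co <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ],
                if (aa3[i] != "GLY") CB[i, ])
    rows[[i]] <- data.frame(name = nm, resname = aa3[i], resno = i,
                            icode = "", chain = "A",
                            x = co[, 1], y = co[, 2], z = co[, 3],
                            occ = 1, element = NA, serial = NA,
                            alt = "", stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, rows)
  new_conformation(build_structure(recs, "A"))
}

#' Build a start/goal transition pair with an engineered hinge
#'
#' The goal conformation equals the start with the named hinge torsions
#' offset by `hinge_deltas`; all other torsions are identical, so the true
#' flexible residues are exactly `spec$hinge_residues` by construction.
#' Optional `decoy_deltas` add small torsion offsets at non-hinge residues,
#' emulating the small uncorrelated torsion differences real structure pairs
#' show away from their hinges (with decoys the goal is no longer reachable
#' by hinge-only moves).
#'
#' @param spec A `pw_fixture_spec` with non-empty `hinge_residues` (empty is
#'   allowed and yields an identical pair).
#' @param hinge_deltas Named list keyed by residue index as character, each
#'   entry a named numeric like `c(psi = 40)` or `c(phi = -30, psi = 20)`.
#'   Keys must be hinge residues.
#' @param decoy_deltas Optional, same format, keys must be non-hinge
#'   residues.
#' @return List with `start` and `goal` conformations.
#' @export
make_transition_pair <- function(spec, hinge_deltas = list(),
                                 decoy_deltas = list()) {
  start <- build_peptide(spec)
  hk <- as.integer(names(hinge_deltas))
  if (length(hk) > 0 && !all(hk %in% spec$hinge_residues))
    stop("hinge_deltas given for a non-hinge residue")
  dk <- as.integer(names(decoy_deltas))
  if (length(dk) > 0 && any(dk %in% spec$hinge_residues))
    stop("decoy_deltas must name non-hinge residues")
  goal <- start
  apply_deltas <- function(conf, idx, deltas) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      for (kind in names(deltas[[k]])) {
        cur <- if (kind == "phi") conf$phi[i] else conf$psi[i]
        if (is.na(cur))
          stop(sprintf("%s undefined at residue %d", kind, i))
        conf <- set_dihedral(conf, i, kind, cur + deltas[[k]][[kind]])
      }
    }
    conf
  }
  goal <- apply_deltas(goal, hk, hinge_deltas)
  goal <- apply_deltas(goal, dk, decoy_deltas)
  list(start = start, goal = goal)
}

#' The canonical two-domain study fixture
#'
#' A 20-residue peptide with two alpha-helical hydrophobic domains (residues
#' 1-8 and 12-20, LEU/ALA) joined by a 3-residue extended serine hinge
#' (residues 9-11).  The transition pair opens the hinge by the given psi
#' offsets and, by default, carries two 8-degree psi decoys inside the helix
#' cores (residues 4 and 16) standing in for the small non-hinge torsion
#' differences of real conformational pairs.
#'
#' @param hinge_delta Psi offset in degrees applied at each hinge residue
#'   (default 40).
#' @param decoys Logical; include the in-core decoy torsion offsets.
#' @return List with `spec`, `start`, `goal` and `hinge_residues`.
#' @export
two_domain_fixture <- function(hinge_delta = 40, decoys = TRUE) {
  seqs <- paste0("LALLALAL", "SGS", "LALLALALA")
  n <- nchar(seqs)
  phi <- c(rep(-57, 8), rep(-120, 3), rep(-57, 9))
  psi <- c(rep(-47, 8), rep(130, 3), rep(-47, 9))
  spec <- fixture_spec(n, seqs, phi, psi, hinge_residues = 9:11)
  hd <- list(`9` = c(psi = hinge_delta), `10` = c(psi = -hinge_delta),
             `11` = c(psi = hinge_delta))
  dd <- if (decoys) list(`4` = c(psi = 8), `16` = c(psi = 8)) else list()
  pair <- make_transition_pair(spec, hd, dd)
  list(spec = spec, start = pair$start, goal = pair$goal,
       hinge_residues = 9:11)
}
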
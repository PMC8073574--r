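## Coarse-grained composite potential
##
##   E_total = E_HB + E_burial + E_water + E_bond + E_angle + E_VdW
##
## E_bond/E_angle are harmonic terms and E_VdW a soft Lennard-Jones with
## AMBER-flavoured parameters reduced to the five retained atom classes;
## E_HB, E_burial and E_water are simplified coarse forms (square-well
## hydrogen bond on O...N geometry, hydrophobicity-weighted burial sigmoid on
## CB contact counts, and a CB-CB water-shell well).  Units are nominal
## kcal/mol: the only consumer of absolute values is the k*n_residues
## acceptance gate, so only relative scale matters.

#' Default energy parameters
#'
#' Equilibrium bond lengths and angles are taken from the same ideal-geometry
#' table the fixture builder uses, with derived angles (O-C-N, CB-CA-C)
#' computed from the placement geometry, so ideal-geometry fixtures score
#' exactly zero bonded energy.
#'
#' @param vdw_softening Fraction in (0, 1]: Lennard-Jones repulsion is
#'   clamped to its value at `vdw_softening * rmin`, tolerating the soft
#'   collisions a reduced representation produces. Default 0.8.
#' @return A `pw_energy_params` list (force constants, VdW classes, H-bond
#'   well, burial and water weights).
#' @export
default_energy_params <- function(vdw_softening = 0.8) {
  g <- ideal_geometry()
  ## derived equilibrium angles implied by the placement geometry:
  ## two directions at angles a and b from a common axis, separated by
  ## dihedral dt, subtend acos(cos a cos b + sin a sin b cos dt).
  derived <- function(a, b, dt) {
    a <- a * pi / 180; b <- b * pi / 180; dt <- dt * pi / 180
    acos(cos(a) * cos(b) + sin(a) * sin(b) * cos(dt)) * 180 / pi
  }
  a_o_c_n <- derived(g$a_ca_c_o, g$a_ca_c_n, 180)
  a_cb_ca_c <- derived(g$a_n_ca_cb, g$a_n_ca_c, g$cb_torsion)
  p <- list(
    vdw_softening = vdw_softening,
    vdw_cutoff = 10,
    bond = data.frame(
      type = c("N-CA", "CA-C", "C-N", "C-O", "CA-CB"),
      r0 = c(g$b_n_ca, g$b_ca_c, g$b_c_n, g$b_c_o, g$b_ca_cb),
      k = c(337, 317, 490, 570, 310)
    ),
    angle = data.frame(
      type = c("N-CA-C", "CA-C-N", "C-N-CA", "CA-C-O", "O-C-N",
               "N-CA-CB", "CB-CA-C"),
      theta0 = c(g$a_n_ca_c, g$a_ca_c_n, g$a_c_n_ca, g$a_ca_c_o,
                 a_o_c_n, g$a_n_ca_cb, a_cb_ca_c),
      k = c(63, 70, 50, 80, 80, 63, 63)
    ),
    ## per-atom-class VdW: rstar = rmin/2 (Angstrom), eps (kcal/mol)
    vdw = data.frame(
      class = c("N", "CA", "C", "O", "CB"),
      rstar = c(1.824, 1.908, 1.908, 1.661, 1.908),
      eps = c(0.17, 0.1094, 0.086, 0.21, 0.1094)
    ),
    hbond = list(minsep = 3, dmin = 2.5, dmax = 3.5, angle_min = 90,
                 eps = 1.0),
    burial = list(radius = 7.5, n_half = 4, slope = 1, weight = 1.0),
    water = list(dmin = 6.5, dmax = 9.5, minsep = 2, weight = 0.05)
  )
  class(p) <- "pw_energy_params"
  p
}

#' Load energy parameters from a YAML config file
#'
#' Top-level keys override the corresponding entries of
#' [default_energy_params()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pw_energy_params` list.
#' @export
load_energy_params <- function(path) {
  p <- default_energy_params()
  cfg <- yaml::read_yaml(path)
  for (k in names(cfg)) {
    if (!k %in% names(p)) stop("unknown energy parameter: ", k)
    if (is.list(p[[k]]) && !is.data.frame(p[[k]])) {
      for (k2 in names(cfg[[k]])) {
        if (!k2 %in% names(p[[k]])) stop("unknown energy parameter: ", k, "$", k2)
        p[[k]][[k2]] <- cfg[[k]][[k2]]
      }
    } else {
      p[[k]] <- cfg[[k]]
    }
  }
  p
}

## Kyte-Doolittle-flavoured hydrophobicity weights used by the burial term
## (positive = rewarded when buried); polar/charged residues get 0.
HYDRO_WEIGHT <- c(ALA = 0.3, VAL = 0.6, LEU = 0.6, ILE = 0.7, MET = 0.4,
                  PHE = 0.6, TRP = 0.3, PRO = 0.2, CYS = 0.4, TYR = 0.2)

## Residue classes forming hydrophobic constraint-graph contacts.
HYDROPHOBIC_SET <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

## Bonded topology and the nonbonded pair list (bond-path separation >= 3)
## for a structure.  Pure function of topology, cached on first use per
## conformation lineage by the search driver.
build_topology <- function(structure, params = default_energy_params()) {
  s <- as_structure(structure)
  n <- n_residues(s)
  ra <- s$res_atoms
  bonds <- list(); btype <- character(0)
  angles <- list(); atype <- character(0)
  add_bond <- function(i, j, type) {
    if (!is.na(i) && !is.na(j)) {
      bonds[[length(bonds) + 1]] <<- c(i, j); btype[length(btype) + 1] <<- type
    }
  }
  add_angle <- function(i, j, k, type) {
    if (!is.na(i) && !is.na(j) && !is.na(k)) {
      angles[[length(angles) + 1]] <<- c(i, j, k); atype[length(atype) + 1] <<- type
    }
  }
  for (i in seq_len(n)) {
    add_bond(ra[i, "N"], ra[i, "CA"], "N-CA")
    add_bond(ra[i, "CA"], ra[i, "C"], "CA-C")
    add_bond(ra[i, "C"], ra[i, "O"], "C-O")
    add_bond(ra[i, "CA"], ra[i, "CB"], "CA-CB")
    add_angle(ra[i, "N"], ra[i, "CA"], ra[i, "C"], "N-CA-C")
    add_angle(ra[i, "CA"], ra[i, "C"], ra[i, "O"], "CA-C-O")
    add_angle(ra[i, "N"], ra[i, "CA"], ra[i, "CB"], "N-CA-CB")
    add_angle(ra[i, "CB"], ra[i, "CA"], ra[i, "C"], "CB-CA-C")
    if (i < n && !s$gap_after[i]) {
      add_bond(ra[i, "C"], ra[i + 1, "N"], "C-N")
      add_angle(ra[i, "CA"], ra[i, "C"], ra[i + 1, "N"], "CA-C-N")
      add_angle(ra[i, "O"], ra[i, "C"], ra[i + 1, "N"], "O-C-N")
      add_angle(ra[i, "C"], ra[i + 1, "N"], ra[i + 1, "CA"], "C-N-CA")
    }
  }
  bonds <- do.call(rbind, bonds)
  angles <- do.call(rbind, angles)

  ## nonbonded pairs: bond-path distance >= 3 (exclude 1-2 and 1-3)
  na <- nrow(s$atoms)
  adj <- vector("list", na)
  for (m in seq_len(nrow(bonds))) {
    i <- bonds[m, 1]; j <- bonds[m, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env()
  for (i in seq_len(na)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    for (j in unique(c(one, two))) {
      if (j > i) assign(paste(i, j), TRUE, envir = excl)
    }
  }
  pr <- t(utils::combn(na, 2))
  keep <- !vapply(seq_len(nrow(pr)),
                  function(m) exists(paste(pr[m, 1], pr[m, 2]), envir = excl),
                  logical(1))
  pairs <- pr[keep, , drop = FALSE]

  vdwtab <- params$vdw
  cls <- match(s$atoms$name, vdwtab$class)
  rmin <- vdwtab$rstar[cls[pairs[, 1]]] + vdwtab$rstar[cls[pairs[, 2]]]
  eps <- sqrt(vdwtab$eps[cls[pairs[, 1]]] * vdwtab$eps[cls[pairs[, 2]]])

  btab <- params$bond[match(btype, params$bond$type), ]
  atab <- params$angle[match(atype, params$angle$type), ]
  list(bonds = bonds, bond_r0 = btab$r0, bond_k = btab$k,
       angles = angles, angle_th0 = atab$theta0 * pi / 180, angle_k = atab$k,
       pairs = pairs, pair_rmin = rmin, pair_eps = eps)
}

## Detect backbone hydrogen bonds (shared by the energy term and the
## rigidity constraint graph).
detect_hbonds <- function(structure, minsep = 3, dmin = 0, dmax = 3.5,
                          angle_min = 90) {
  s <- as_structure(structure)
  .cpp_hbonds(s$xyz, s$res_atoms[, "O"], s$res_atoms[, "N"],
              s$res_atoms[, "CA"], as.integer(minsep), dmin, dmax, angle_min)
}

#' Composite coarse-grained energy of a conformation
#'
#' @param conformation A `pw_conformation` (or `pw_structure`).
#' @param params Energy parameters, see [default_energy_params()].
#' @param topology Optional precomputed topology (internal use).
#' @return A `pw_energy_breakdown`: list with `e_hb`, `e_burial`, `e_water`,
#'   `e_bond`, `e_angle`, `e_vdw` and `total` (their sum, fixed accumulation
#'   order).
#' @export
total_energy <- function(conformation, params = default_energy_params(),
                         topology = NULL) {
  s <- as_structure(conformation)
  if (is.null(topology)) topology <- build_topology(s, params)
  xyz <- s$xyz
  bd <- .cpp_bonded(xyz, topology$bonds, topology$bond_r0, topology$bond_k,
                    topology$angles, topology$angle_th0, topology$angle_k,
                    FALSE)
  vd <- .cpp_vdw(xyz, topology$pairs, topology$pair_rmin, topology$pair_eps,
                 params$vdw_softening, params$vdw_cutoff, FALSE)
  hb <- detect_hbonds(s, params$hbond$minsep, params$hbond$dmin,
                      params$hbond$dmax, params$hbond$angle_min)
  e_hb <- -params$hbond$eps * length(hb$res_o)

  ## burial: hydrophobicity-weighted sigmoid of CB contact counts
  cb <- s$res_atoms[, "CB"]
  has_cb <- which(!is.na(cb))
  e_burial <- 0
  e_water <- 0
  if (length(has_cb) >= 2) {
    cbx <- xyz[cb[has_cb], , drop = FALSE]
    D <- as.matrix(stats::dist(cbx))
    diag(D) <- Inf
    counts <- rowSums(D < params$burial$radius)
    w <- HYDRO_WEIGHT[s$res$resname[has_cb]]
    w[is.na(w)] <- 0
    e_burial <- -params$burial$weight *
      sum(w / (1 + exp(-(counts - params$burial$n_half) / params$burial$slope)))
    sep <- abs(outer(has_cb, has_cb, `-`))
    shell <- D >= params$water$dmin & D <= params$water$dmax &
      sep >= params$water$minsep
    e_water <- -params$water$weight * sum(shell[upper.tri(shell)])
  }
  breakdown(e_hb, e_burial, e_water, bd$e_bond, bd$e_angle, vd$e_vdw)
}

breakdown <- function(e_hb, e_burial, e_water, e_bond, e_angle, e_vdw) {
  structure(list(e_hb = e_hb, e_burial = e_burial, e_water = e_water,
                 e_bond = e_bond, e_angle = e_angle, e_vdw = e_vdw,
                 total = e_hb + e_burial + e_water + e_bond + e_angle + e_vdw),
            class = "pw_energy_breakdown")
}

#' @export
print.pw_energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy breakdown (kcal/mol):\n  HB %8.3f  burial %8.3f",
                     "  water %8.3f\n  bond %7.3f  angle %8.3f  VdW %10.3f",
                     "\n  total %.3f\n"),
              x$e_hb, x$e_burial, x$e_water, x$e_bond, x$e_angle, x$e_vdw,
              x$total))
  invisible(x)
}

#' Bounded steepest-descent relaxation
#'
#' Runs at most `max_steps` steepest-descent steps in Cartesian space on the
#' bond + angle + VdW terms only (the clash-relaxation target; the H-bond,
#' burial and water terms are excluded).  Step size starts at 0.01 Angstrom
#' along the normalized negative gradient and is halved on energy increase;
#' a step is rejected (and the descent stops) after 5 halvings.  The target
#' energy is non-increasing across accepted steps.
#'
#' @param conformation A `pw_conformation`.
#' @param params Energy parameters.
#' @param max_steps Maximum number of descent steps (default 10).
#' @param topology Optional precomputed topology (internal use).
#' @return A new `pw_conformation` with refreshed dihedral cache.
#' @export
minimize_energy <- function(conformation, params = default_energy_params(),
                            max_steps = 10, topology = NULL) {
  stopifnot(inherits(conformation, "pw_conformation"))
  s <- conformation$structure
  if (is.null(topology)) topology <- build_topology(s, params)
  out <- .cpp_minimize(s$xyz, topology$bonds, topology$bond_r0,
                       topology$bond_k, topology$angles, topology$angle_th0,
                       topology$angle_k, topology$pairs, topology$pair_rmin,
                       topology$pair_eps, params$vdw_softening,
                       params$vdw_cutoff, as.integer(max_steps),
                       0.01, 5L)
  if (!out$moved) return(conformation)
  s$xyz <- out$xyz
  new_conformation(s)
}

#' Energy acceptance gate
#'
#' A candidate conformation is admitted to the pool only if its total energy
#' is strictly below `k` times the residue count.
#'
#' @param e A `pw_energy_breakdown` (or a numeric total).
#' @param n_residues Number of residues (>= 1).
#' @param k Per-residue threshold (default 5).
#' @return TRUE iff `total < k * n_residues`.
#' @export
energy_gate <- function(e, n_residues, k = 5) {
  stopifnot(n_residues >= 1)
  total <- if (inherits(e, "pw_energy_breakdown")) e$total else as.numeric(e)
  total < k * n_residues
}
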
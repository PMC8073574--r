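## Body-bar rigidity analysis.  Atoms are 6-DOF bodies; covalent bonds,
## hydrogen bonds and hydrophobic contacts become multi-bars; the (6,6)
## pebble game decomposes the multigraph into maximal rigid clusters, from
## which the flexible-residue set is derived with a minimum-cluster-size
## filter.
##
## Bar multiplicities (standard molecular body-bar convention): rotatable
## covalent single bonds (N-CA, CA-C) 5 bars, locked covalent bonds 6 bars
## (the partial-double peptide C-N, the C=O double bond, and CA-CB: a bond to
## a terminal body carries no usable spin freedom), hydrogen bonds 5 bars,
## hydrophobic contacts 2 bars.
##
## Note this analysis runs on the same coarse-grained model as the search (no
## hydrogens, no side chain beyond CB), NOT on an all-atom model as external
## rigidity servers do; it reproduces hinge-versus-domain behavior, not
## all-atom cluster boundaries.  A user-supplied flexible-residue list (see
## read_flexible_list) can override it.

#' Build the body-bar constraint multigraph of a conformation
#'
#' Edges carry an integer bar multiplicity in 1..6 and a provenance tag
#' (`covalent_rotatable`, `covalent_locked`, `hbond`, `hydrophobic`).
#' Hydrogen bonds are detected geometrically (O(i)...N(j) distance below
#' `hb_dist_max`, CA-O...N angle above `hb_angle_min`, sequence separation
#' >= 3); hydrophobic contacts are CB-CB pairs below `hp_dist_max` between
#' hydrophobic residues at sequence separation >= 2.
#'
#' @param conformation A `pw_conformation` or `pw_structure`.
#' @param hb_dist_max,hb_angle_min Hydrogen-bond geometric cutoffs
#'   (Angstrom, degrees).
#' @param hp_dist_max Hydrophobic CB-CB distance cutoff (Angstrom).
#' @return A `pw_constraint_graph`: list with `n_bodies` and `edges`
#'   (data frame: i, j, bars, type).
#' @export
build_constraint_graph <- function(conformation, hb_dist_max = 3.5,
                                   hb_angle_min = 90, hp_dist_max = 6.0) {
  s <- as_structure(conformation)
  n <- n_residues(s)
  ra <- s$res_atoms
  ii <- integer(0); jj <- integer(0); bars <- integer(0); type <- character(0)
  add <- function(i, j, b, t) {
    if (!is.na(i) && !is.na(j)) {
      ii <<- c(ii, i); jj <<- c(jj, j); bars <<- c(bars, b); type <<- c(type, t)
    }
  }
  for (r in seq_len(n)) {
    add(ra[r, "N"], ra[r, "CA"], 5L, "covalent_rotatable")
    add(ra[r, "CA"], ra[r, "C"], 5L, "covalent_rotatable")
    add(ra[r, "C"], ra[r, "O"], 6L, "covalent_locked")
    add(ra[r, "CA"], ra[r, "CB"], 6L, "covalent_locked")
    if (r < n && !s$gap_after[r]) add(ra[r, "C"], ra[r + 1, "N"], 6L, "covalent_locked")
  }
  hb <- detect_hbonds(s, minsep = 3, dmin = 0, dmax = hb_dist_max,
                      angle_min = hb_angle_min)
  for (k in seq_along(hb$atom_o)) add(hb$atom_o[k], hb$atom_n[k], 5L, "hbond")
  cb <- ra[, "CB"]
  hydro <- which(!is.na(cb) & s$res$resname %in% HYDROPHOBIC_SET)
  if (length(hydro) >= 2) {
    cbx <- s$xyz[cb[hydro], , drop = FALSE]
    D <- as.matrix(stats::dist(cbx))
    for (a in seq_along(hydro)) for (b in seq_along(hydro)) {
      if (b > a && abs(hydro[b] - hydro[a]) >= 2 && D[a, b] < hp_dist_max) {
        add(cb[hydro[a]], cb[hydro[b]], 2L, "hydrophobic")
      }
    }
  }
  new_constraint_graph(nrow(s$atoms),
                       data.frame(i = ii, j = jj, bars = bars, type = type,
                                  stringsAsFactors = FALSE))
}

#' Construct a constraint graph from an edge table
#'
#' @param n_bodies Number of bodies.
#' @param edges Data frame with integer columns `i`, `j`, `bars` (1..6) and
#'   optionally `type`.
#' @return A `pw_constraint_graph`.
#' @export
new_constraint_graph <- function(n_bodies, edges) {
  if (is.null(edges$type))
    edges$type <- rep("bar", nrow(edges))
  stopifnot(all(edges$bars >= 1), all(edges$bars <= 6),
            all(edges$i != edges$j),
            all(edges$i >= 1), all(edges$j >= 1),
            all(edges$i <= n_bodies), all(edges$j <= n_bodies))
  structure(list(n_bodies = as.integer(n_bodies), edges = edges),
            class = "pw_constraint_graph")
}

#' @export
print.pw_constraint_graph <- function(x, ...) {
  cat(sprintf("pw_constraint_graph: %d bodies, %d edges (%d bars)\n",
              x$n_bodies, nrow(x$edges), sum(x$edges$bars)))
  print(table(x$edges$type))
  invisible(x)
}

#' (6,6) body-bar pebble game rigid-cluster decomposition
#'
#' Every body starts with 6 pebbles; a bar is independent iff 7 pebbles can
#' be gathered on its endpoints, in which case it is inserted and paid for
#' with one pebble.  After all bars are processed, maximal rigid clusters are
#' the equivalence classes of mutual rigidity: an adjacent pair of bodies on
#' which 7 pebbles cannot be gathered has no residual relative freedom.
#' Every body lies in exactly one cluster; singletons are allowed.
#'
#' @param graph A `pw_constraint_graph`.
#' @return List of integer vectors, each a rigid cluster of body indices,
#'   in order of their smallest member.
#' @export
pebble_game <- function(graph) {
  stopifnot(inherits(graph, "pw_constraint_graph"))
  n <- graph$n_bodies
  pebbles <- rep(6L, n)
  D <- matrix(0L, n, n)   # D[u,v]: bars currently oriented u -> v

  ## depth-first search for a free pebble reachable from `roots` along
  ## oriented bars; on success the path is reversed and the pebble moved to
  ## the first root on the path.
  gather_one <- function(roots) {
    seen <- rep(FALSE, n)
    seen[roots] <- TRUE
    parent <- rep(NA_integer_, n)
    stack <- roots
    while (length(stack) > 0) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in which(D[u, ] > 0L)) {
        if (seen[w]) next
        seen[w] <- TRUE
        parent[w] <- u
        if (pebbles[w] > 0L) {
          ## reverse the path root -> ... -> w and move the pebble
          v <- w
          while (!is.na(parent[v])) {
            p <- parent[v]
            D[p, v] <<- D[p, v] - 1L
            D[v, p] <<- D[v, p] + 1L
            v <- p
          }
          pebbles[w] <<- pebbles[w] - 1L
          pebbles[v] <<- pebbles[v] + 1L
          return(TRUE)
        }
        stack <- c(stack, w)
      }
    }
    FALSE
  }

  gather_pair <- function(u, v, want = 7L) {
    while (pebbles[u] + pebbles[v] < want) {
      if (!gather_one(c(u, v))) return(FALSE)
    }
    TRUE
  }

  for (m in seq_len(nrow(graph$edges))) {
    u <- graph$edges$i[m]; v <- graph$edges$j[m]
    for (b in seq_len(graph$edges$bars[m])) {
      if (gather_pair(u, v, 7L)) {
        if (pebbles[u] > 0L) {
          pebbles[u] <- pebbles[u] - 1L
          D[u, v] <- D[u, v] + 1L
        } else {
          pebbles[v] <- pebbles[v] - 1L
          D[v, u] <- D[v, u] + 1L
        }
      }
      ## dependent bars are redundant and simply not inserted
    }
  }

  ## mutual-rigidity union-find over adjacent pairs
  uf <- as.integer(seq_len(n))
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  pairs <- unique(cbind(as.integer(pmin(graph$edges$i, graph$edges$j)),
                        as.integer(pmax(graph$edges$i, graph$edges$j))))
  for (m in seq_len(nrow(pairs))) {
    u <- pairs[m, 1]; v <- pairs[m, 2]
    if (find(u) == find(v)) next
    if (!gather_pair(u, v, 7L)) uf[find(u)] <- find(v)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  cl <- split(seq_len(n), comp)
  cl <- cl[order(vapply(cl, min, integer(1)))]
  unname(cl)
}

#' Derive the flexible-residue set from a cluster decomposition
#'
#' Clusters smaller than `min_cluster_atoms` are disregarded (tiny clusters
#' carry no useful rigidity signal); a residue is flexible iff at least one
#' of its atoms belongs to no retained cluster.
#'
#' @param clusters List of integer atom-index vectors from [pebble_game()].
#' @param conformation The analyzed `pw_conformation`/`pw_structure`.
#' @param min_cluster_atoms Minimum retained cluster size (>= 1); default 6.
#' @return A `pw_rigidity_report`: list with `clusters` (retained, as atom
#'   index vectors), `cluster_serials`, `min_cluster_atoms`,
#'   `flexible_residues` (1-based residue indices) and `flexible_resno`
#'   (PDB numbering).
#' @export
derive_flexible_residues <- function(clusters, conformation,
                                     min_cluster_atoms = 6) {
  if (min_cluster_atoms < 1) stop("min_cluster_atoms must be >= 1")
  s <- as_structure(conformation)
  retained <- clusters[vapply(clusters, length, 1L) >= min_cluster_atoms]
  covered <- rep(FALSE, nrow(s$atoms))
  for (cl in retained) covered[cl] <- TRUE
  flex <- which(vapply(seq_len(n_residues(s)), function(r) {
    idx <- s$res_atoms[r, ]
    any(!covered[idx[!is.na(idx)]])
  }, logical(1)))
  structure(list(clusters = retained,
                 cluster_serials = lapply(retained, function(cl) s$atoms$serial[cl]),
                 min_cluster_atoms = as.integer(min_cluster_atoms),
                 flexible_residues = flex,
                 flexible_resno = s$res$resno[flex]),
            class = "pw_rigidity_report")
}

#' @export
print.pw_rigidity_report <- function(x, ...) {
  cat(sprintf(paste0("pw_rigidity_report: %d retained cluster(s)",
                     " (>= %d atoms), %d flexible residue(s)\n"),
              length(x$clusters), x$min_cluster_atoms,
              length(x$flexible_residues)))
  invisible(x)
}

#' Run the full rigidity analysis of a conformation
#'
#' Convenience wrapper: constraint graph, pebble game, flexible residues.
#'
#' @inheritParams build_constraint_graph
#' @inheritParams derive_flexible_residues
#' @return A `pw_rigidity_report`.
#' @export
rigidity_analysis <- function(conformation, min_cluster_atoms = 6,
                              hb_dist_max = 3.5, hb_angle_min = 90,
                              hp_dist_max = 6.0) {
  g <- build_constraint_graph(conformation, hb_dist_max, hb_angle_min,
                              hp_dist_max)
  derive_flexible_residues(pebble_game(g), conformation, min_cluster_atoms)
}

#' Read a flexible-residue override file
#'
#' Plain text, one PDB residue number per line, `#` comments allowed.  The
#' resulting report overrides the built-in rigidity analysis (e.g., to use
#' output of an external all-atom rigidity server).
#'
#' @param path Path to the list file.
#' @param structure The structure the numbers refer to.
#' @return A `pw_rigidity_report` with empty cluster list.
#' @export
read_flexible_list <- function(path, structure) {
  s <- as_structure(structure)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  resno <- suppressWarnings(as.integer(lines))
  if (any(is.na(resno))) stop("malformed flexible-residue list: ",
                              lines[which(is.na(resno))[1]])
  flex <- which(s$res$resno %in% resno)
  structure(list(clusters = list(), cluster_serials = list(),
                 min_cluster_atoms = NA_integer_,
                 flexible_residues = flex,
                 flexible_resno = s$res$resno[flex]),
            class = "pw_rigidity_report")
}

#' Export a rigidity report as text
#'
#' Writes a tab-separated cluster table (cluster_id, size, atom serials)
#' followed by the flexible-residue list.
#'
#' @param report A `pw_rigidity_report`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_rigidity_report <- function(report, path) {
  lines <- c("cluster_id\tsize\tatom_serials")
  for (k in seq_along(report$cluster_serials)) {
    lines <- c(lines, sprintf("%d\t%d\t%s", k,
                              length(report$cluster_serials[[k]]),
                              paste(report$cluster_serials[[k]],
                                    collapse = ",")))
  }
  lines <- c(lines, "", "# flexible residues (PDB numbering)",
             as.character(report$flexible_resno))
  writeLines(lines, path)
  invisible(path)
}
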
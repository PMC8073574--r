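## Coarse-grained structure model: parse PDB ATOM records into a
## backbone + C-beta representation, write single- and multi-model PDB text,
## and pair residues between two conformations of the same protein.

RETAINED_ATOMS <- c("N", "CA", "C", "O", "CB")

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## Maximum C(i)-N(i+1) distance still treated as a peptide bond; anything
## longer marks a chain gap that blocks torsion propagation.
PEPTIDE_BOND_MAX <- 1.8

#' Parse a PDB file into the coarse-grained model
#'
#' Retains the backbone atoms N, CA, C, O and the side-chain C-beta of the
#' standard amino acids of one chain.  Alternate locations are resolved to
#' the highest-occupancy copy; residues missing any required atom (N, CA, C,
#' O, and CB for non-glycine) are dropped with a warning.  Heteroatoms,
#' waters, hydrogens and non-standard residues are discarded.  For
#' multi-model files (NMR ensembles) only the first MODEL is read.
#'
#' @param pdb_text Character: either PDB-format text (single string or vector
#'   of lines) or the path to a PDB file.
#' @param chain_id Single-character chain identifier.
#' @return A `pw_structure`: list with `atoms` (data frame of atom records),
#'   `xyz` (N x 3 coordinate matrix, Angstrom), `res` (residue table),
#'   `res_atoms` (residue x atom-name index matrix), `gap_after` (logical,
#'   chain break after residue i), `sequence` (1-letter string) and
#'   `chain_id`.
#' @export
read_structure <- function(pdb_text, chain_id) {
  stopifnot(is.character(chain_id), nchar(chain_id) == 1)
  lines <- pdb_lines(pdb_text)
  ## keep first model only
  mdl <- grep("^ENDMDL", lines)
  if (length(mdl) > 0) lines <- lines[seq_len(mdl[1] - 1)]
  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom)) stop("empty chain: no ATOM records in input")
  recs <- parse_atom_records(lines[is_atom], which(is_atom))
  recs <- recs[recs$chain == chain_id &
               recs$name %in% RETAINED_ATOMS &
               recs$resname %in% STANDARD_AA, , drop = FALSE]
  if (nrow(recs) == 0) stop(sprintf("empty chain: no ATOM records for chain '%s'", chain_id))
  ## resolve alternate locations: highest occupancy wins, first on ties
  key <- paste(recs$resno, recs$icode, recs$name, sep = "|")
  ord <- order(match(key, unique(key)), -recs$occ)
  recs <- recs[ord, , drop = FALSE]
  recs <- recs[!duplicated(paste(recs$resno, recs$icode, recs$name, sep = "|")), , drop = FALSE]
  build_structure(recs, chain_id)
}

pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    readLines(pdb_text, warn = FALSE)
  } else {
    unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  }
}

## Fixed-column parse per wwPDB v3.3.  `line_no` carries original line
## numbers so malformed fields can be reported usefully.
parse_atom_records <- function(lines, line_no) {
  lines <- formatC(lines, width = 80, flag = "-")
  f <- function(from, to) substr(lines, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & trimws(s) != "")
    bad2 <- which(trimws(s) == "" & what %in% c("x", "y", "z"))
    bad <- sort(unique(c(bad, bad2)))
    if (length(bad) > 0)
      stop(sprintf("parse error at line %d: malformed %s field '%s'",
                   line_no[bad[1]], what[1], trimws(s[bad[1]])))
    v
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    serial  = suppressWarnings(as.integer(f(7, 11))),
    name    = trimws(f(13, 16)),
    alt     = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain   = f(22, 22),
    resno   = num(f(23, 26), "residue number"),
    icode   = trimws(f(27, 27)),
    x       = num(f(31, 38), "x"),
    y       = num(f(39, 46), "y"),
    z       = num(f(47, 54), "z"),
    occ     = occ,
    element = trimws(f(77, 78)),
    stringsAsFactors = FALSE
  )
}

build_structure <- function(recs, chain_id) {
  rkey <- paste(recs$resno, recs$icode, sep = "|")
  rtab <- unique(data.frame(resno = recs$resno, icode = recs$icode,
                            resname = recs$resname[match(rkey, rkey)],
                            key = rkey, stringsAsFactors = FALSE))
  rtab <- rtab[order(rtab$resno, rtab$icode), , drop = FALSE]
  ## drop residues missing a required atom
  keep <- logical(nrow(rtab))
  for (i in seq_len(nrow(rtab))) {
    names_i <- recs$name[rkey == rtab$key[i]]
    required <- if (rtab$resname[i] == "GLY") c("N", "CA", "C", "O") else RETAINED_ATOMS
    keep[i] <- all(required %in% names_i)
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d residue(s) missing required atoms: %s",
                    sum(!keep),
                    paste(rtab$resno[!keep], collapse = ", ")))
    rtab <- rtab[keep, , drop = FALSE]
  }
  if (nrow(rtab) == 0) stop("empty chain: no complete residues")

  nres <- nrow(rtab)
  atoms <- NULL
  res_atoms <- matrix(NA_integer_, nres, 5, dimnames = list(NULL, RETAINED_ATOMS))
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    sub <- recs[rkey == rtab$key[i], , drop = FALSE]
    wanted <- if (rtab$resname[i] == "GLY") c("N", "CA", "C", "O") else RETAINED_ATOMS
    sub <- sub[match(wanted, sub$name), , drop = FALSE]
    rows[[i]] <- sub
  }
  atoms <- do.call(rbind, rows)
  offs <- c(0, cumsum(vapply(rows, nrow, 1L)))
  for (i in seq_len(nres)) {
    nm <- rows[[i]]$name
    res_atoms[i, nm] <- offs[i] + seq_along(nm)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  if (!all(is.finite(xyz))) stop("non-finite coordinates in input")
  atoms_df <- data.frame(serial = seq_len(nrow(atoms)), name = atoms$name,
                         resno = atoms$resno, icode = atoms$icode,
                         resname = atoms$resname, chain = chain_id,
                         element = ifelse(atoms$name == "N", "N",
                                   ifelse(atoms$name == "O", "O", "C")),
                         stringsAsFactors = FALSE)
  gap_after <- rep(FALSE, nres)
  if (nres > 1) {
    for (i in seq_len(nres - 1)) {
      ci <- res_atoms[i, "C"]; ni <- res_atoms[i + 1, "N"]
      d <- sqrt(sum((xyz[ci, ] - xyz[ni, ])^2))
      gap_after[i] <- !is.finite(d) || d > PEPTIDE_BOND_MAX ||
        (rtab$resno[i + 1] - rtab$resno[i] > 1 && d > PEPTIDE_BOND_MAX)
    }
  }
  structure(
    list(atoms = atoms_df, xyz = xyz,
         res = data.frame(resno = rtab$resno, icode = rtab$icode,
                          resname = rtab$resname, stringsAsFactors = FALSE),
         res_atoms = res_atoms,
         gap_after = gap_after,
         sequence = paste(AA_321[rtab$resname], collapse = ""),
         chain_id = chain_id),
    class = "pw_structure"
  )
}

#' @export
print.pw_structure <- function(x, ...) {
  cat(sprintf("pw_structure: %d residues, %d atoms, chain %s\n",
              nrow(x$res), nrow(x$atoms), x$chain_id))
  cat(" sequence:", x$sequence, "\n")
  if (any(x$gap_after)) cat(" chain gaps after residue index:",
                            which(x$gap_after), "\n")
  invisible(x)
}

n_residues <- function(structure) nrow(structure$res)

#' Write a structure as PDB text
#'
#' @param structure A `pw_structure`.
#' @return Single character string of PDB-format text (ATOM records with
#'   3-decimal coordinates, TER, END).
#' @export
write_structure <- function(structure) {
  check_structure(structure)
  paste(c(atom_lines(structure), ter_line(structure), "END"), collapse = "\n")
}

check_structure <- function(structure) {
  if (!inherits(structure, "pw_structure") || nrow(structure$atoms) == 0)
    stop("invalid or empty structure")
  invisible(TRUE)
}

atom_lines <- function(structure, serial_offset = 0) {
  a <- structure$atoms
  xyz <- structure$xyz
  name_fmt <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), a$name)
  sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial + serial_offset, name_fmt, a$resname, a$chain, a$resno,
          ifelse(a$icode == "", " ", a$icode),
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
}

ter_line <- function(structure) {
  a <- structure$atoms
  n <- nrow(a)
  sprintf("TER   %5d      %3s %1s%4d%1s",
          a$serial[n] + 1, a$resname[n], a$chain[n], a$resno[n],
          ifelse(a$icode[n] == "", " ", a$icode[n]))
}

#' Write a conformational path as multi-model PDB text
#'
#' @param conformations List of `pw_structure` or `pw_conformation` objects
#'   sharing the same topology (same residues and atoms), in path order.
#' @return Character string of multi-model PDB text (MODEL/ENDMDL blocks,
#'   1-based model numbers).
#' @export
write_path <- function(conformations) {
  if (length(conformations) == 0) stop("empty path")
  structs <- lapply(conformations, as_structure)
  ref <- structs[[1]]
  for (s in structs) {
    if (nrow(s$atoms) != nrow(ref$atoms) ||
        !identical(s$atoms$name, ref$atoms$name) ||
        !identical(s$atoms$resno, ref$atoms$resno))
      stop("topology mismatch between path models")
  }
  blocks <- vapply(seq_along(structs), function(k) {
    paste(c(sprintf("MODEL     %4d", k), atom_lines(structs[[k]]),
            ter_line(structs[[k]]), "ENDMDL"), collapse = "\n")
  }, character(1))
  paste(c(blocks, "END"), collapse = "\n")
}

as_structure <- function(x) {
  if (inherits(x, "pw_conformation")) x$structure else x
}

#' Pair residues between two conformations of the same protein
#'
#' Residues are paired by identical PDB residue number (and insertion code)
#' where the residue names agree; if fewer than 3 residues pair that way the
#' longest common ungapped block of identical residue names is used instead.
#' Unpaired residues are excluded from lRMSD and from perturbation
#' eligibility.
#'
#' @param start,goal `pw_structure` (or `pw_conformation`) objects.
#' @return A `pw_pairing`: list with `mapping`, a two-column integer matrix
#'   of (start residue index, goal residue index) pairs, 1-based and
#'   order-preserving.
#' @export
pair_residues <- function(start, goal) {
  s <- as_structure(start); g <- as_structure(goal)
  ks <- paste(s$res$resno, s$res$icode, sep = "|")
  kg <- paste(g$res$resno, g$res$icode, sep = "|")
  gi <- match(ks, kg)
  ok <- !is.na(gi) & s$res$resname == g$res$resname[ifelse(is.na(gi), 1, gi)]
  mapping <- cbind(start = which(ok), goal = gi[ok])
  if (nrow(mapping) < 3) {
    mapping <- longest_common_block(s$res$resname, g$res$resname)
  }
  if (is.null(mapping) || nrow(mapping) < 3)
    stop("incompatible structures: fewer than 3 paired residues")
  ## enforce order preservation (number-based pairing could cross if files
  ## renumber; keep the longest increasing run)
  if (is.unsorted(mapping[, 2])) {
    keep <- longest_increasing(mapping[, 2])
    mapping <- mapping[keep, , drop = FALSE]
  }
  structure(list(mapping = mapping), class = "pw_pairing")
}

## longest common contiguous block of identical residue names
longest_common_block <- function(a, b) {
  na <- length(a); nb <- length(b)
  best <- 0; bi <- 0; bj <- 0
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j > 1) prev[j - 1] + 1 else 1
        if (cur[j] > best) { best <- cur[j]; bi <- i; bj <- j }
      }
    }
    prev <- cur
  }
  if (best == 0) return(NULL)
  cbind(start = (bi - best + 1):bi, goal = (bj - best + 1):bj)
}

longest_increasing <- function(x) {
  n <- length(x)
  len <- rep(1L, n); pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (x[j] < x[i] && len[j] + 1L > len[i]) { len[i] <- len[j] + 1L; pred[i] <- j }
  }
  i <- which.max(len); out <- integer(0)
  while (!is.na(i)) { out <- c(i, out); i <- pred[i] }
  out
}
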
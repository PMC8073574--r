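## Independent oracles used across the suite.  These deliberately avoid the
## code paths they check: the rigidity oracle works on the numeric rank of a
## generic body-bar rigidity matrix, the superposition oracle searches
## rotation space directly, and the cost/prune oracles recompute quantities
## from first principles with lrmsd()/superpose() only.

## ---- generic body-bar rigidity-matrix oracle -------------------------------

## One bar between generic points a (on body u) and b (on body v) constrains
## the relative point velocity along the bar: rows over (v_u, w_u, v_v, w_v)
## are (d, a x d, -d, -(b x d)) with d = b - a.
oracle_bar_row <- function(n, u, v, pos) {
  a <- pos[u, ] + stats::rnorm(3, sd = 2)
  b <- pos[v, ] + stats::rnorm(3, sd = 2)
  d <- b - a
  d <- d / sqrt(sum(d^2))
  cx <- function(p, q) c(p[2] * q[3] - p[3] * q[2],
                         p[3] * q[1] - p[1] * q[3],
                         p[1] * q[2] - p[2] * q[1])
  r <- numeric(6 * n)
  r[(6 * (u - 1) + 1):(6 * (u - 1) + 3)] <- d
  r[(6 * (u - 1) + 4):(6 * (u - 1) + 6)] <- cx(a, d)
  r[(6 * (v - 1) + 1):(6 * (v - 1) + 3)] <- -d
  r[(6 * (v - 1) + 4):(6 * (v - 1) + 6)] <- -cx(b, d)
  r
}

## Rigid-cluster decomposition by rank: bodies u, v are mutually rigid iff
## generic extra bars between them add no rank.
oracle_clusters <- function(n_bodies, edges) {
  pos <- matrix(stats::rnorm(n_bodies * 3, sd = 3), n_bodies, 3)
  rows <- list()
  for (m in seq_len(nrow(edges))) {
    for (k in seq_len(edges$bars[m])) {
      rows[[length(rows) + 1]] <- oracle_bar_row(n_bodies, edges$i[m],
                                                 edges$j[m], pos)
    }
  }
  M <- do.call(rbind, rows)
  ## numeric rank via singular values with a relative tolerance; rows are
  ## unit-direction bars so scales are comparable
  rk <- function(X) {
    if (is.null(X) || nrow(X) == 0) return(0L)
    d <- svd(X, nu = 0, nv = 0)$d
    sum(d > d[1] * 1e-9)
  }
  r0 <- rk(M)
  uf <- seq_len(n_bodies)
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  prs <- unique(cbind(pmin(edges$i, edges$j), pmax(edges$i, edges$j)))
  for (m in seq_len(nrow(prs))) {
    u <- prs[m, 1]; v <- prs[m, 2]
    if (find(u) == find(v)) next
    extra <- rbind(oracle_bar_row(n_bodies, u, v, pos),
                   oracle_bar_row(n_bodies, u, v, pos),
                   oracle_bar_row(n_bodies, u, v, pos))
    if (rk(rbind(M, extra)) == r0) uf[find(u)] <- find(v)
  }
  comp <- vapply(seq_len(n_bodies), find, numeric(1))
  cl <- split(seq_len(n_bodies), comp)
  unname(cl[order(vapply(cl, min, numeric(1)))])
}

## canonical string form of a cluster decomposition, for set equality
canon_clusters <- function(cl) {
  paste(sort(vapply(cl, function(x) paste(sort(x), collapse = ","),
                    character(1))), collapse = ";")
}

## ---- rotation-space superposition oracle -----------------------------------

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## brute-force minimum RMSD: random quaternion sweep + Nelder-Mead polish
oracle_min_rmsd <- function(a, b, n_grid = 20000) {
  A <- sweep(a, 2, colMeans(a))
  B <- sweep(b, 2, colMeans(b))
  f_q <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, f_q)
  q0 <- qs[which.min(vals), ]
  opt <- stats::optim(q0, f_q, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

## ---- search-tree oracles ----------------------------------------------------

## recompute every node's accumulated cost g along its parent chain
oracle_recompute_g <- function(tree, g_mode = "paper") {
  start <- tree$conf[[1]]
  g <- numeric(tree$n)
  for (i in seq_len(tree$n)) {
    chain <- i
    p <- tree$parent[i]
    while (!is.na(p)) { chain <- c(p, chain); p <- tree$parent[p] }
    acc <- 0
    for (k in seq_along(chain)[-1]) {
      node <- chain[k]
      acc <- acc + if (g_mode == "paper") {
        lrmsd(tree$conf[[node]], start, tree$pairing)
      } else {
        lrmsd(tree$conf[[node]], tree$conf[[chain[k - 1]]], tree$pairing)
      }
    }
    g[i] <- acc
  }
  g
}

## brute-force replay of the pool-pruning rule
oracle_prune <- function(tree_before_pool, h, conf_list, pairing,
                         fraction = 0.10) {
  in_pool <- tree_before_pool
  ord <- which(in_pool)[order(h[which(in_pool)])]
  for (k in seq_along(ord)) {
    u <- ord[k]
    if (!in_pool[u]) next
    for (v in ord[-seq_len(k)]) {
      if (!in_pool[v]) next
      d <- lrmsd(conf_list[[u]], conf_list[[v]], pairing)
      if (d <= fraction * min(h[u], h[v])) in_pool[v] <- FALSE
    }
  }
  in_pool
}

## ---- shared tiny fixtures ---------------------------------------------------

## minimal hand-written single-alanine PDB text
minimal_ala_pdb <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.760  -1.200  1.00  0.00           C",
    "TER       6      ALA A   1",
    "END"), collapse = "\n")
}

## small helical conformation used across tests
helix_conf <- function(n = 10, seq = "A") {
  build_peptide(fixture_spec(n, sequence = seq, phi = -57, psi = -47))
}

## an 8-residue single-hinge transition pair
hinge_pair <- function(delta = 40) {
  spec <- fixture_spec(8, hinge_residues = 4L)
  make_transition_pair(spec, list(`4` = c(psi = delta)))
}

## a search tree preloaded with nodes made by hinge rotations of the start
seeded_tree <- function(n_nodes = 30, seed = 1) {
  set.seed(seed)
  pair <- hinge_pair()
  tree <- new_search_tree(pair$start, pair$goal)
  for (k in seq_len(n_nodes - 1)) {
    conf <- set_dihedral(pair$start, 4, "psi",
                         pair$start$psi[4] + stats::runif(1, -40, 40))
    conf <- set_dihedral(conf, 3, "phi",
                         conf$phi[3] + stats::runif(1, -15, 15))
    h <- lrmsd(conf, pair$goal, tree$pairing)
    d0 <- lrmsd(conf, pair$start, tree$pairing)
    par <- sample.int(tree$n, 1)
    pathweaver:::tree_insert(tree, conf, par, h, d0, tree$g[par] + d0)
  }
  list(tree = tree, pair = pair)
}
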
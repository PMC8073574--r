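## The RRT*/Monte-Carlo search engine.  A tree of conformations grows from
## the start conformation: biased node selection, dihedral perturbation
## restricted to flexible residues, bounded minimization, an energy gate, a
## Monte-Carlo acceptance test, least-cost parent choice with rewiring
## (RRT*), pool pruning, and optional adaptive recomputation of the rigidity
## analysis as the best conformation drifts.

#' Search configuration
#'
#' @param bias_fraction Probability of drawing the node to perturb from the
#'   k-best pool (closest to the goal); otherwise it is drawn from the rest
#'   of the pool. Default 1/3.
#' @param k_best Size of the best pool. Default 20.
#' @param angle_diff_min Degrees: only torsions differing from their goal
#'   counterpart by more than this are eligible for perturbation. Default 5.
#' @param neighbor_radius Angstrom: near-neighbor radius for parent choice
#'   and rewiring. Default 1.0.
#' @param minimize_steps Maximum steepest-descent steps per candidate.
#'   Default 10.
#' @param energy_k Energy gate: total energy must be below
#'   `energy_k * n_residues`. Default 5.
#' @param mc_a Monte-Carlo acceptance constant `a`. Default 0.01.
#' @param stall_limit Stop after this many iterations without improvement of
#'   the best lRMSD (M). Default 500.
#' @param goal_threshold Angstrom: stop when the best lRMSD to the goal falls
#'   to or below this. Default NULL: 0.25 x initial lRMSD clamped to
#'   [1.7, 3.65].
#' @param prune_growth Pool-size pruning trigger multiplier: pruning fires at
#'   pool sizes n_residues, then n_residues * prune_growth, ... Default 3.
#' @param rigidity_mode `"off"` (perturb any residue), `"once"` (rigidity
#'   analysis of the start only) or `"adaptive"` (recompute when the best
#'   conformation drifts). Default `"adaptive"`.
#' @param rigidity_recompute_drift Angstrom of best-conformation drift that
#'   triggers recomputation in adaptive mode. Default 2.0.
#' @param min_cluster_atoms Minimum rigid-cluster size retained. Default 6.
#' @param max_iterations Hard iteration cap. Default 20000.
#' @param perturb_max_angles Maximum number of torsions changed per move.
#'   Default NULL: max(2, ceiling(0.05 * n_residues)).
#' @param perturb_step_max Degrees: per-torsion perturbation is uniform in
#'   +/- this. Default 10.
#' @param g_mode Accumulated-cost recurrence: `"paper"` adds the node's lRMSD
#'   from the start at every hop (g(n) = g(parent) + lrmsd(n, start));
#'   `"edge"` adds the parent-child edge length instead. Default `"paper"`.
#' @param rng_seed Integer seed for the single RNG threading all stochastic
#'   choices. Default 1.
#' @return A `pw_search_config` list.
#' @export
search_config <- function(bias_fraction = 1 / 3, k_best = 20,
                          angle_diff_min = 5, neighbor_radius = 1.0,
                          minimize_steps = 10, energy_k = 5, mc_a = 0.01,
                          stall_limit = 500, goal_threshold = NULL,
                          prune_growth = 3, rigidity_mode = "adaptive",
                          rigidity_recompute_drift = 2.0,
                          min_cluster_atoms = 6, max_iterations = 20000,
                          perturb_max_angles = NULL, perturb_step_max = 10,
                          g_mode = "paper", rng_seed = 1L) {
  rigidity_mode <- match.arg(rigidity_mode, c("off", "once", "adaptive"))
  g_mode <- match.arg(g_mode, c("paper", "edge"))
  stopifnot(bias_fraction > 0, bias_fraction < 1, k_best >= 1,
            angle_diff_min > 0, neighbor_radius > 0, minimize_steps >= 0,
            energy_k > 0, mc_a > 0, stall_limit >= 1, prune_growth > 1,
            rigidity_recompute_drift > 0, min_cluster_atoms >= 1,
            max_iterations >= 1, perturb_step_max > 0)
  structure(list(bias_fraction = bias_fraction, k_best = as.integer(k_best),
                 angle_diff_min = angle_diff_min,
                 neighbor_radius = neighbor_radius,
                 minimize_steps = as.integer(minimize_steps),
                 energy_k = energy_k, mc_a = mc_a,
                 stall_limit = as.integer(stall_limit),
                 goal_threshold = goal_threshold,
                 prune_growth = prune_growth, rigidity_mode = rigidity_mode,
                 rigidity_recompute_drift = rigidity_recompute_drift,
                 min_cluster_atoms = as.integer(min_cluster_atoms),
                 max_iterations = as.integer(max_iterations),
                 perturb_max_angles = perturb_max_angles,
                 perturb_step_max = perturb_step_max, g_mode = g_mode,
                 rng_seed = as.integer(rng_seed)),
            class = "pw_search_config")
}

#' Load a search configuration from a YAML file
#'
#' Keys are [search_config()] argument names; unknown keys are rejected.
#' `overrides` (a named list, e.g. parsed CLI flags) take precedence over
#' file values.
#'
#' @param path Path to a YAML file, or NULL for defaults.
#' @param overrides Named list of overriding values.
#' @return A `pw_search_config`.
#' @export
load_search_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), names(formals(search_config)))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(search_config, vals)
}

## ---- search tree -----------------------------------------------------------

#' Create a search tree rooted at the start conformation
#'
#' @param start,goal `pw_conformation` objects.
#' @param pairing A `pw_pairing`; computed if NULL.
#' @return A `pw_tree` environment.
#' @export
new_search_tree <- function(start, goal, pairing = NULL) {
  if (is.null(pairing)) pairing <- pair_residues(start, goal)
  tr <- new.env(parent = emptyenv())
  tr$pairing <- pairing
  tr$m <- nrow(pairing$mapping)
  tr$start_ca <- ca_coords(start, pairing$mapping[, 1])
  tr$goal_ca <- ca_coords(goal, pairing$mapping[, 2])
  tr$conf <- list()
  tr$parent <- integer(0)
  tr$g <- numeric(0)
  tr$h <- numeric(0)
  tr$d_start <- numeric(0)
  tr$in_pool <- logical(0)
  tr$epoch <- integer(0)
  tr$ca_stack <- matrix(NA_real_, 0, 3)
  tr$n <- 0L
  class(tr) <- c("pw_tree", "environment")
  h0 <- .cpp_rmsd_batch(tr$goal_ca, tr$start_ca)[1]
  tree_insert(tr, start, parent = NA_integer_, h = h0, d_start = 0,
              g = 0, epoch = 0L)
  tr
}

#' @export
print.pw_tree <- function(x, ...) {
  cat(sprintf("pw_tree: %d nodes (%d in pool), best h = %.3f A\n",
              x$n, sum(x$in_pool), min(x$h)))
  invisible(x)
}

node_ca <- function(tree, conf) ca_coords(conf, tree$pairing$mapping[, 1])

tree_insert <- function(tree, conf, parent, h, d_start, g, epoch = 0L) {
  i <- tree$n + 1L
  tree$conf[[i]] <- conf
  tree$parent[i] <- parent
  tree$g[i] <- g
  tree$h[i] <- h
  tree$d_start[i] <- d_start
  tree$in_pool[i] <- TRUE
  tree$epoch[i] <- epoch
  tree$ca_stack <- rbind(tree$ca_stack, node_ca(tree, conf))
  tree$n <- i
  i
}

## lRMSD of an arbitrary conformation against a set of tree nodes
tree_rmsd_to <- function(tree, conf, nodes = seq_len(tree$n)) {
  q <- node_ca(tree, conf)
  all_d <- .cpp_rmsd_batch(q, tree$ca_stack)
  all_d[nodes]
}

rmsd_between_nodes <- function(tree, i, nodes) {
  m <- tree$m
  q <- tree$ca_stack[((i - 1) * m + 1):(i * m), , drop = FALSE]
  .cpp_rmsd_batch(q, tree$ca_stack)[nodes]
}

## ---- individual search operations ------------------------------------------

#' Biased node selection
#'
#' With probability `bias_fraction` draws uniformly from the `k_best` pool
#' nodes closest to the goal, otherwise uniformly from the rest of the pool
#' (the whole pool when it has at most `k_best` members).  Only nodes still
#' in the pool are eligible.
#'
#' @param tree A `pw_tree`.
#' @param config A `pw_search_config`.
#' @return The selected node index.
#' @export
select_node <- function(tree, config = search_config()) {
  pool <- which(tree$in_pool)
  if (length(pool) == 0) stop("empty pool")
  if (length(pool) == 1) return(pool)
  ord <- pool[order(tree$h[pool])]
  k <- min(config$k_best, length(ord))
  best <- ord[seq_len(k)]
  rest <- if (length(ord) > k) ord[(k + 1):length(ord)] else best
  from <- if (stats::runif(1) < config$bias_fraction) best else rest
  from[sample.int(length(from), 1)]
}

no_eligible_angles <- function() {
  stop(structure(class = c("pw_no_eligible_angles", "error", "condition"),
                 list(message = "no eligible angles", call = NULL)))
}

#' Enumerate perturbation-eligible torsions
#'
#' A torsion is eligible when it is defined in both conformations, its
#' residue is paired, its circular difference from the goal counterpart
#' exceeds `angle_diff_min`, and (when a rigidity report is supplied) its
#' residue is flexible.
#'
#' @param conformation,goal `pw_conformation` objects.
#' @param pairing A `pw_pairing`.
#' @param flexible Optional `pw_rigidity_report` restricting residues.
#' @param angle_diff_min Degrees.
#' @return Data frame with columns `residue` (start-side index) and `kind`.
#' @export
eligible_angles <- function(conformation, goal, pairing, flexible = NULL,
                            angle_diff_min = 5) {
  map <- pairing$mapping
  res <- integer(0); kind <- character(0)
  for (r in seq_len(nrow(map))) {
    si <- map[r, 1]; gi <- map[r, 2]
    if (!is.null(flexible) && !(si %in% flexible$flexible_residues)) next
    for (kk in c("phi", "psi")) {
      a <- conformation[[kk]][si]; b <- goal[[kk]][gi]
      if (!is.na(a) && !is.na(b) && circular_diff(a, b) > angle_diff_min) {
        res <- c(res, si); kind <- c(kind, kk)
      }
    }
  }
  data.frame(residue = res, kind = kind, stringsAsFactors = FALSE)
}

#' Perturb a conformation at randomly chosen eligible torsions
#'
#' Draws `m` torsions uniformly without replacement from the eligible set
#' (`m` itself uniform in 1..perturb_max_angles, capped at the set size) and
#' offsets each by a step uniform in +/- `perturb_step_max` degrees.
#'
#' @param conformation The node conformation to perturb.
#' @param goal Goal conformation.
#' @param pairing A `pw_pairing`.
#' @param config A `pw_search_config` (with resolved `perturb_max_angles`).
#' @param flexible Optional `pw_rigidity_report`.
#' @return The new `pw_conformation`.  Signals a `pw_no_eligible_angles`
#'   error when nothing is eligible.
#' @export
perturb <- function(conformation, goal, pairing, config = search_config(),
                    flexible = NULL) {
  elig <- eligible_angles(conformation, goal, pairing, flexible,
                          config$angle_diff_min)
  if (nrow(elig) == 0) no_eligible_angles()
  maxa <- config$perturb_max_angles
  if (is.null(maxa)) maxa <- max(2, ceiling(0.05 * length(conformation$phi)))
  m <- min(sample.int(maxa, 1), nrow(elig))
  pick <- elig[sample.int(nrow(elig), m), , drop = FALSE]
  out <- conformation
  for (r in seq_len(nrow(pick))) {
    i <- pick$residue[r]; kk <- pick$kind[r]
    cur <- out[[kk]][i]
    step <- stats::runif(1, -config$perturb_step_max, config$perturb_step_max)
    out <- set_dihedral(out, i, kk, cur + step)
  }
  out
}

#' Near neighbors of a conformation in the pool
#'
#' All pool nodes within `neighbor_radius` lRMSD (inclusive); when none are,
#' the single nearest pool node.
#'
#' @param tree A `pw_tree`.
#' @param conf Candidate conformation.
#' @param radius Angstrom (default 1.0).
#' @return Integer node indices with attribute `"dist"` (lRMSD to `conf`).
#' @export
near_neighbors <- function(tree, conf, radius = 1.0) {
  pool <- which(tree$in_pool)
  d <- tree_rmsd_to(tree, conf, pool)
  sel <- d <= radius
  if (!any(sel)) sel <- seq_along(pool) == which.min(d)
  out <- pool[sel]
  attr(out, "dist") <- d[sel]
  out
}

#' A*-style node cost
#'
#' cost(n) = g(n) + h(n): the accumulated cost plus the lRMSD to the goal.
#'
#' @param tree A `pw_tree`.
#' @param node Node index.
#' @return Numeric cost.
#' @export
node_cost <- function(tree, node) tree$g[node] + tree$h[node]

#' Choose the least-cost parent among near neighbors
#'
#' Minimizes the prospective cost of the candidate when parented to each
#' neighbor (g(neighbor) + lrmsd(candidate, start) + lrmsd(candidate, goal));
#' ties break to the neighbor nearest the candidate in lRMSD, then to
#' insertion order.
#'
#' @param tree A `pw_tree`.
#' @param neighbors Node indices (as from [near_neighbors()], whose `"dist"`
#'   attribute is reused when present).
#' @param conf Candidate conformation.
#' @return The chosen parent node index.
#' @export
choose_parent <- function(tree, neighbors, conf) {
  if (length(neighbors) == 0) stop("choose_parent: no neighbors")
  d <- attr(neighbors, "dist")
  if (is.null(d)) d <- tree_rmsd_to(tree, conf, neighbors)
  cost <- tree$g[neighbors]   # + lrmsd(conf,start) + lrmsd(conf,goal), equal for all
  ord <- order(cost, d, seq_along(neighbors))
  neighbors[ord[1]]
}

tree_children <- function(tree, node) which(tree$parent == node)

tree_descendants <- function(tree, node) {
  out <- integer(0)
  frontier <- tree_children(tree, node)
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, tree_children, tree = tree))
  }
  out
}

tree_ancestors <- function(tree, node) {
  out <- integer(0)
  p <- tree$parent[node]
  while (!is.na(p)) { out <- c(out, p); p <- tree$parent[p] }
  out
}

#' Rewire neighbors through a newly inserted node
#'
#' For each neighbor, if routing through `new_node` gives a strictly smaller
#' accumulated cost g, its parent becomes `new_node` and the g values of its
#' entire subtree are updated.  The new node's own ancestor chain is excluded
#' so no cycle can form.
#'
#' @param tree A `pw_tree`.
#' @param new_node Index of the just-inserted node.
#' @param neighbors Candidate node indices.
#' @param g_mode `"paper"` or `"edge"` (see [search_config()]).
#' @return Number of reparented nodes.
#' @export
rewire <- function(tree, new_node, neighbors, g_mode = "paper") {
  neighbors <- setdiff(neighbors, c(new_node, tree_ancestors(tree, new_node)))
  count <- 0L
  for (nb in neighbors) {
    hop <- if (g_mode == "paper") tree$d_start[nb]
           else rmsd_between_nodes(tree, nb, new_node)
    g_alt <- tree$g[new_node] + hop
    if (g_alt < tree$g[nb]) {
      delta <- g_alt - tree$g[nb]
      tree$parent[nb] <- new_node
      tree$g[nb] <- g_alt
      sub <- tree_descendants(tree, nb)
      if (length(sub) > 0) tree$g[sub] <- tree$g[sub] + delta
      count <- count + 1L
    }
  }
  count
}

#' Monte-Carlo acceptance rule
#'
#' A candidate closer to the goal than the node it was perturbed from is
#' always accepted; otherwise it is accepted with probability
#' exp(-(lrmsd_new - lrmsd_parent) / (lrmsd_new * a)), allowing occasional
#' uphill moves to escape local minima.
#'
#' @param lrmsd_new,lrmsd_parent Candidate and source lRMSD to the goal (A).
#' @param a Scale constant (default 0.01).
#' @return Logical.
#' @export
mc_accept <- function(lrmsd_new, lrmsd_parent, a = 0.01) {
  stopifnot(lrmsd_new >= 0, lrmsd_parent >= 0, a > 0)
  if (lrmsd_new < lrmsd_parent) return(TRUE)
  if (lrmsd_new == 0) return(TRUE)
  stats::runif(1) < exp(-(lrmsd_new - lrmsd_parent) / (lrmsd_new * a))
}

#' Prune redundant nodes from the selection pool
#'
#' For every pool pair whose mutual lRMSD is at most 10% of the smaller of
#' their goal distances, the node farther from the goal leaves the pool.
#' Tree edges and parent links are never broken: pruned nodes remain as path
#' waypoints.  Pairs are processed in increasing order of goal distance.
#'
#' @param tree A `pw_tree`.
#' @param fraction Redundancy fraction (default 0.10).
#' @return Number of nodes removed from the pool.
#' @export
prune_pool <- function(tree, fraction = 0.10) {
  pool <- which(tree$in_pool)
  pool <- pool[order(tree$h[pool])]
  removed <- 0L
  for (k in seq_along(pool)) {
    u <- pool[k]
    if (!tree$in_pool[u]) next
    later <- pool[-seq_len(k)]
    later <- later[tree$in_pool[later]]
    if (length(later) == 0) next
    d <- rmsd_between_nodes(tree, u, later)
    out <- later[d <= fraction * tree$h[u]]
    if (length(out) > 0) {
      tree$in_pool[out] <- FALSE
      removed <- removed + length(out)
    }
  }
  removed
}

#' Should the rigidity analysis be recomputed?
#'
#' True iff the current conformation has drifted more than `drift` Angstrom
#' (lRMSD, strict) from the conformation of the previous rigidity run.
#'
#' @param current,last_rigidity_conf `pw_conformation` objects.
#' @param drift Angstrom threshold (default 2.0).
#' @param pairing Optional `pw_pairing` (identity if omitted).
#' @return Logical.
#' @export
should_recompute_rigidity <- function(current, last_rigidity_conf,
                                      drift = 2.0, pairing = NULL) {
  lrmsd(current, last_rigidity_conf, pairing) > drift
}

## ---- the full search -------------------------------------------------------

#' Run the rigidity-guided RRT*/MC pathway search
#'
#' Grows an RRT* tree from `start` towards `goal` in phi/psi space and
#' extracts the parent-chain path to the node closest to the goal.  Stops
#' when the best lRMSD reaches `goal_threshold`, when it has not improved for
#' `stall_limit` consecutive iterations, or at `max_iterations`.
#'
#' @param start,goal `pw_conformation` (or `pw_structure`) objects of the
#'   same protein.
#' @param config A `pw_search_config`.
#' @param flexible_override Optional `pw_rigidity_report` (e.g. from
#'   [read_flexible_list()]) that replaces the built-in rigidity analysis;
#'   it is never recomputed.
#' @return A `pw_path_result`: `path` (list of conformations, start first),
#'   `best_lrmsd`, `iterations_used`, `tree_size`, `lrmsd_trace` (running
#'   pool-minimum lRMSD per iteration), `pool_trace`, `size_trace`,
#'   `epoch_trace`, `prune_events` (pool size at each pruning pass),
#'   `rigidity_runs`, `flexible_residues` (last report), `config`, `seed`.
#' @export
run_search <- function(start, goal, config = search_config(),
                       flexible_override = NULL) {
  if (inherits(start, "pw_structure")) start <- new_conformation(start)
  if (inherits(goal, "pw_structure")) goal <- new_conformation(goal)
  pairing <- pair_residues(start, goal)
  nres <- n_residues(start$structure)
  set.seed(config$rng_seed)
  if (is.null(config$perturb_max_angles))
    config$perturb_max_angles <- max(2, ceiling(0.05 * nres))

  params <- default_energy_params()
  topo <- build_topology(start$structure, params)
  tree <- new_search_tree(start, goal, pairing)
  h0 <- tree$h[1]
  if (is.null(config$goal_threshold))
    config$goal_threshold <- min(max(0.25 * h0, 1.7), 3.65)

  report <- NULL
  rigidity_runs <- 0L
  epoch <- 0L
  last_rig <- start
  if (config$rigidity_mode != "off") {
    report <- if (!is.null(flexible_override)) flexible_override
              else rigidity_analysis(start, config$min_cluster_atoms)
    rigidity_runs <- 1L
  }

  best_h <- h0; best_idx <- 1L
  trace_h <- numeric(0); trace_pool <- integer(0)
  trace_size <- integer(0); trace_epoch <- integer(0)
  stall <- 0L
  next_trigger <- nres
  prune_events <- integer(0)   # pool size at each pruning pass (pre-prune)
  it <- 0L

  while (best_h > config$goal_threshold && stall < config$stall_limit &&
         it < config$max_iterations) {
    it <- it + 1L
    improved <- FALSE
    sel <- select_node(tree, config)
    cand <- tryCatch(
      perturb(tree$conf[[sel]], goal, pairing, config, report),
      pw_no_eligible_angles = function(e) NULL
    )
    if (!is.null(cand)) {
      cand <- minimize_energy(cand, params, config$minimize_steps, topo)
      e <- total_energy(cand, params, topo)
      if (energy_gate(e, nres, config$energy_k)) {
        ca_cand <- node_ca(tree, cand)
        h_new <- .cpp_rmsd_batch(ca_cand, tree$goal_ca)[1]
        if (mc_accept(h_new, tree$h[sel], config$mc_a)) {
          nb <- near_neighbors(tree, cand, config$neighbor_radius)
          par <- choose_parent(tree, nb, cand)
          d_start <- .cpp_rmsd_batch(ca_cand, tree$start_ca)[1]
          hop <- if (config$g_mode == "paper") d_start
                 else tree_rmsd_to(tree, cand, par)
          idx <- tree_insert(tree, cand, par, h_new, d_start,
                             tree$g[par] + hop, epoch)
          rewire(tree, idx, nb, config$g_mode)
          if (sum(tree$in_pool) >= next_trigger) {
            prune_events <- c(prune_events, sum(tree$in_pool))
            prune_pool(tree)
            next_trigger <- next_trigger * config$prune_growth
          }
          if (h_new < best_h) {
            best_h <- h_new; best_idx <- idx; improved <- TRUE
          }
        }
      }
    }
    stall <- if (improved) 0L else stall + 1L
    trace_h[it] <- best_h
    trace_pool[it] <- sum(tree$in_pool)
    trace_size[it] <- tree$n
    trace_epoch[it] <- epoch
    if (config$rigidity_mode == "adaptive" && is.null(flexible_override) &&
        should_recompute_rigidity(tree$conf[[best_idx]], last_rig,
                                  config$rigidity_recompute_drift, pairing)) {
      report <- rigidity_analysis(tree$conf[[best_idx]],
                                  config$min_cluster_atoms)
      rigidity_runs <- rigidity_runs + 1L
      epoch <- epoch + 1L
      last_rig <- tree$conf[[best_idx]]
    }
  }

  chain <- rev(c(best_idx, tree_ancestors(tree, best_idx)))
  structure(list(path = tree$conf[chain],
                 path_nodes = chain,
                 best_lrmsd = best_h,
                 iterations_used = it,
                 tree_size = tree$n,
                 lrmsd_trace = trace_h,
                 pool_trace = trace_pool,
                 size_trace = trace_size,
                 epoch_trace = trace_epoch,
                 prune_events = prune_events,
                 rigidity_runs = rigidity_runs,
                 flexible_residues = if (is.null(report)) integer(0)
                                     else report$flexible_residues,
                 tree = tree,
                 config = config,
                 seed = config$rng_seed),
            class = "pw_path_result")
}

#' @export
print.pw_path_result <- function(x, ...) {
  cat(sprintf(paste0("pw_path_result: best lRMSD %.3f A after %d iterations",
                     "\n  path length %d, tree size %d, rigidity runs %d\n"),
              x$best_lrmsd, x$iterations_used, length(x$path), x$tree_size,
              x$rigidity_runs))
  invisible(x)
}
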
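test_that("node selection is biased toward the k best at the stated rate", {
  st <- seeded_tree(100, seed = 4)
  tree <- st$tree
  cfg <- search_config()
  expect_equal(select_node(new_search_tree(st$pair$start, st$pair$goal), cfg), 1)
  best20 <- which(tree$in_pool)[order(tree$h[which(tree$in_pool)])][1:20]
  set.seed(1234)
  draws <- replicate(30000, select_node(tree, cfg))
  frac <- mean(draws %in% best20)
  expect_lt(abs(frac - 1 / 3), 0.02)
  ## a pool smaller than k is still well-defined
  small <- seeded_tree(8, seed = 5)$tree
  set.seed(1)
  expect_true(all(replicate(50, select_node(small, cfg)) %in% 1:8))
})

test_that("perturbation honors the goal-difference and flexibility filters", {
  pair <- hinge_pair()
  pairing <- pair_residues(pair$start, pair$goal)
  cfg <- search_config(rng_seed = 1)
  cfg$perturb_max_angles <- 2
  ## only the hinge psi differs from the goal by > 5 degrees
  el <- eligible_angles(pair$start, pair$goal, pairing, NULL, 5)
  expect_equal(el$residue, 4)
  expect_equal(el$kind, "psi")
  ## everything within 5 degrees -> no eligible angles
  expect_error(perturb(pair$goal, pair$goal, pairing, cfg),
               class = "pw_no_eligible_angles")
  ## with a rigidity report, perturbed angles stay within flexible residues
  fx <- two_domain_fixture()
  fpairing <- pair_residues(fx$start, fx$goal)
  rep <- rigidity_analysis(fx$start)
  set.seed(7)
  for (t in 1:1000) {
    out <- perturb(fx$start, fx$goal, fpairing, cfg, rep)
    changed <- which(abs(out$psi - fx$start$psi) > 1e-12 |
                     abs(out$phi - fx$start$phi) > 1e-12)
    expect_true(all(changed %in% rep$flexible_residues))
  }
  ## with rigidity off the eligible set is the unrestricted one
  el_off <- eligible_angles(fx$start, fx$goal, fpairing, NULL, 5)
  el_all <- eligible_angles(fx$start, fx$goal, fpairing,
                            list(flexible_residues = 1:20), 5)
  expect_equal(el_off, el_all)
  ## decoys are eligible without rigidity, filtered out with it
  expect_true(all(c(4, 16) %in% el_off$residue))
  el_rig <- eligible_angles(fx$start, fx$goal, fpairing, rep, 5)
  expect_false(any(c(4, 16) %in% el_rig$residue))
})

test_that("near_neighbors matches a brute-force scan and keeps its fallback", {
  st <- seeded_tree(200, seed = 8)
  tree <- st$tree
  probe <- set_dihedral(st$pair$start, 4, "psi", st$pair$start$psi[4] + 21)
  d_all <- vapply(seq_len(tree$n),
                  function(i) lrmsd(probe, tree$conf[[i]], tree$pairing),
                  numeric(1))
  pool <- which(tree$in_pool)
  nb <- near_neighbors(tree, probe, radius = 1.0)
  expect_setequal(nb, pool[d_all[pool] <= 1.0])
  ## the radius is inclusive: use an exact observed distance as the radius
  ## (distances from the same kernel near_neighbors uses, so equality is
  ## bit-exact)
  d_kern <- pathweaver:::tree_rmsd_to(tree, probe, pool)
  r_edge <- sort(d_kern)[2]
  nb2 <- near_neighbors(tree, probe, radius = r_edge)
  expect_true(pool[which(d_kern == r_edge)[1]] %in% nb2)
  expect_equal(length(nb2), 2)
  ## no node within a tiny radius -> single nearest node
  nb3 <- near_neighbors(tree, probe, radius = 1e-9)
  expect_equal(length(nb3), 1)
  expect_equal(nb3[1], pool[which.min(d_all[pool])])
})

test_that("cost recurrence, parent choice and tie-breaks follow the A* rule", {
  pair <- hinge_pair()
  tree <- new_search_tree(pair$start, pair$goal)
  a <- set_dihedral(pair$start, 4, "psi", pair$start$psi[4] + 15)
  b <- set_dihedral(pair$start, 4, "psi", pair$start$psi[4] + 30)
  da <- lrmsd(a, pair$start, tree$pairing)
  db <- lrmsd(b, pair$start, tree$pairing)
  ia <- pathweaver:::tree_insert(tree, a, 1L, lrmsd(a, pair$goal, tree$pairing),
                                 da, 0 + da)
  ib <- pathweaver:::tree_insert(tree, b, ia, lrmsd(b, pair$goal, tree$pairing),
                                 db, tree$g[ia] + db)
  ## root: g = 0, cost = h
  expect_equal(tree$g[1], 0)
  expect_equal(node_cost(tree, 1), tree$h[1])
  ## chained recurrence g(b) = g(a) + lrmsd(b, start)
  expect_equal(tree$g[ib], da + db, tolerance = 1e-12)
  expect_equal(node_cost(tree, ib), da + db + tree$h[ib], tolerance = 1e-12)
  ## choose_parent minimizes prospective cost = g(neighbor) + constants
  probe <- set_dihedral(pair$start, 4, "psi", pair$start$psi[4] + 28)
  expect_equal(choose_parent(tree, c(1L, ia, ib), probe), 1L)  # g = 0 wins
  ## exact g tie breaks to the neighbor nearest in lRMSD
  tree$g[ia] <- tree$g[ib] <- 0
  d_ia <- lrmsd(probe, a, tree$pairing)
  d_ib <- lrmsd(probe, b, tree$pairing)
  expect_equal(choose_parent(tree, c(ia, ib), probe),
               if (d_ia < d_ib) ia else ib)
})

test_that("rewiring reparents strictly-improving neighbors and updates subtrees", {
  st <- seeded_tree(40, seed = 10)
  tree <- st$tree
  ## no neighbor improves through a node with huge g
  worst <- which.max(tree$g)
  expect_equal(rewire(tree, worst, setdiff(seq_len(tree$n), worst)), 0)
  ## an engineered shortcut: a root child that sits very near the start has
  ## tiny g and undercuts the deepest chain
  conf <- set_dihedral(st$pair$start, 4, "psi", st$pair$start$psi[4] + 0.5)
  d0 <- lrmsd(conf, st$pair$start, tree$pairing)
  idx <- pathweaver:::tree_insert(tree, conf, 1L,
                                  lrmsd(conf, st$pair$goal, tree$pairing),
                                  d0, 0 + d0)
  deep <- vapply(seq_len(tree$n), function(i)
    length(pathweaver:::tree_ancestors(tree, i)), integer(1))
  cand_victims <- which(deep >= 2)
  victim <- cand_victims[which.max(tree$g[cand_victims])]
  old_g <- tree$g[victim]
  n_re <- rewire(tree, idx, victim, g_mode = "paper")
  expect_equal(n_re, 1)
  expect_equal(tree$parent[victim], idx)
  expect_lt(tree$g[victim], old_g)
  ## stored g equals the recurrence recomputed along every parent chain
  expect_equal(tree$g, oracle_recompute_g(tree), tolerance = 1e-9)
  ## ancestors of the new node are never rewired (no cycles)
  for (i in seq_len(tree$n)) {
    seen <- integer(0); p <- i
    while (!is.na(p)) {
      expect_false(p %in% seen)
      seen <- c(seen, p); p <- tree$parent[p]
    }
  }
})

test_that("the Monte-Carlo rule accepts downhill always, uphill at exp rate", {
  expect_true(mc_accept(1.0, 2.0))
  set.seed(2)
  expect_true(all(replicate(100, mc_accept(5, 5))))  # exponent 0, r < 1
  expect_true(mc_accept(0, 0))
})

test_that("pool pruning drops the farther node of redundant pairs only", {
  st <- seeded_tree(120, seed = 12)
  tree <- st$tree
  before <- tree$in_pool
  removed <- prune_pool(tree)
  expected <- oracle_prune(before, tree$h, tree$conf, tree$pairing)
  expect_equal(tree$in_pool, expected)
  expect_equal(removed, sum(before) - sum(expected))
  ## tree edges are untouched
  expect_true(all(is.na(tree$parent[1]) | tree$parent[1] >= 1))
  expect_equal(length(tree$parent), tree$n)
  ## well-separated nodes are never pruned
  iso <- seeded_tree(5, seed = 13)$tree
  iso_before <- iso$in_pool
  ## distances among these few nodes exceed 10% of their goal distances
  d_ok <- TRUE
  pool <- which(iso$in_pool)
  for (u in pool) for (v in pool) {
    if (v <= u) next
    if (lrmsd(iso$conf[[u]], iso$conf[[v]], iso$pairing) <=
        0.1 * min(iso$h[u], iso$h[v])) d_ok <- FALSE
  }
  if (d_ok) {
    prune_pool(iso)
    expect_equal(iso$in_pool, iso_before)
  }
})

test_that("rigidity recomputation triggers on strict drift only", {
  pair <- hinge_pair()
  moved <- set_dihedral(pair$start, 4, "psi", pair$start$psi[4] + 25)
  d <- lrmsd(moved, pair$start)
  expect_false(should_recompute_rigidity(moved, pair$start, drift = d))
  expect_true(should_recompute_rigidity(moved, pair$start, drift = d - 1e-9))
  expect_false(should_recompute_rigidity(pair$start, pair$start, drift = 2))
})

test_that("run_search terminates immediately when start equals goal", {
  conf <- helix_conf(6)
  res <- run_search(conf, conf, search_config(max_iterations = 10))
  expect_equal(res$iterations_used, 0)
  expect_equal(length(res$path), 1)
  expect_equal(res$best_lrmsd, 0, tolerance = 1e-10)
})

test_that("run_search is deterministic and keeps its invariants", {
  fx <- two_domain_fixture()
  cfg <- search_config(rigidity_mode = "off", goal_threshold = 1.6,
                       max_iterations = 400, rng_seed = 21)
  r1 <- run_search(fx$start, fx$goal, cfg)
  r2 <- run_search(fx$start, fx$goal, cfg)
  expect_equal(r1$best_lrmsd, r2$best_lrmsd)
  expect_identical(r1$lrmsd_trace, r2$lrmsd_trace)
  expect_equal(r1$tree_size, r2$tree_size)
  ## best-lRMSD trace is non-increasing
  expect_true(all(diff(r1$lrmsd_trace) <= 0))
  ## tree property: acyclic parent chains ending at the root
  tree <- r1$tree
  for (i in seq_len(tree$n)) {
    seen <- integer(0); p <- i
    while (!is.na(tree$parent[p])) {
      expect_false(tree$parent[p] %in% seen)
      seen <- c(seen, p)
      p <- tree$parent[p]
    }
    expect_equal(p, 1L)
  }
  ## stored g matches the recurrence along every parent chain
  expect_equal(tree$g, oracle_recompute_g(tree), tolerance = 1e-8)
  ## extracted path follows parent-child edges from the root
  expect_equal(r1$path_nodes[1], 1L)
  for (k in seq_along(r1$path_nodes)[-1]) {
    expect_equal(tree$parent[r1$path_nodes[k]], r1$path_nodes[k - 1])
  }
  ## pruning fires on the n, 3n, 9n, ... pool-size schedule
  if (length(r1$prune_events) > 0) {
    expect_equal(r1$prune_events,
                 20 * 3^(seq_along(r1$prune_events) - 1))
  }
})

test_that("adaptive mode recomputes rigidity and records epochs", {
  fx <- two_domain_fixture(hinge_delta = 60)
  cfg <- search_config(rigidity_mode = "adaptive", goal_threshold = 1.0,
                       rigidity_recompute_drift = 0.8,
                       max_iterations = 1500, rng_seed = 3)
  res <- run_search(fx$start, fx$goal, cfg)
  expect_gte(res$rigidity_runs, 2)
  expect_true(any(res$epoch_trace > 0))
  ## a user override disables recomputation
  ovr <- read_flexible_list({
    f <- tempfile(); writeLines(c("9", "10", "11"), f); f
  }, fx$start$structure)
  res2 <- run_search(fx$start, fx$goal, cfg, flexible_override = ovr)
  expect_equal(res2$rigidity_runs, 1)
})
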
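test_that("constraint graph covalent topology is correct for one residue", {
  conf <- build_peptide(fixture_spec(1))
  g <- build_constraint_graph(conf)
  expect_equal(nrow(g$edges), 4)
  expect_setequal(g$edges$type[g$edges$type != "covalent_rotatable"],
                  "covalent_locked")
  expect_equal(sum(g$edges$type == "covalent_rotatable"), 2)  # N-CA, CA-C
})

test_that("an ideal helix carries i -> i+4 hydrogen-bond edges", {
  conf <- helix_conf(12)
  g <- build_constraint_graph(conf)
  hb <- g$edges[g$edges$type == "hbond", ]
  s <- conf$structure
  reso <- s$atoms$resno[hb$i]
  resn <- s$atoms$resno[hb$j]
  for (i in 1:8) expect_true(any(reso == i & resn == i + 4))
})

test_that("edge counts decompose by provenance and match a brute-force scan", {
  conf <- two_domain_fixture()$start
  g <- build_constraint_graph(conf)
  s <- conf$structure
  n <- nrow(s$res)
  ## covalent: 4 per residue minus missing CB (GLY), plus peptide bonds
  n_gly <- sum(s$res$resname == "GLY")
  expect_equal(sum(startsWith(g$edges$type, "covalent")),
               4 * n - n_gly + (n - 1))
  ## hydrogen bonds by direct geometric re-scan
  ra <- s$res_atoms
  hb_count <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3) next
    o <- s$xyz[ra[i, "O"], ]; nn <- s$xyz[ra[j, "N"], ]; ca <- s$xyz[ra[i, "CA"], ]
    d <- sqrt(sum((o - nn)^2))
    if (d >= 3.5) next
    u <- ca - o; v <- nn - o
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    if (ang > 90) hb_count <- hb_count + 1
  }
  expect_equal(sum(g$edges$type == "hbond"), hb_count)
  ## hydrophobic contacts by direct re-scan
  hp_count <- 0
  hydro <- which(s$res$resname %in% pathweaver:::HYDROPHOBIC_SET &
                 !is.na(ra[, "CB"]))
  for (a in hydro) for (b in hydro) {
    if (b <= a || abs(b - a) < 2) next
    if (sqrt(sum((s$xyz[ra[a, "CB"], ] - s$xyz[ra[b, "CB"], ])^2)) < 6.0)
      hp_count <- hp_count + 1
  }
  expect_equal(sum(g$edges$type == "hydrophobic"), hp_count)
  expect_equal(nrow(g$edges),
               sum(startsWith(g$edges$type, "covalent")) + hb_count + hp_count)
})

test_that("pebble game resolves canonical two-body and ring cases", {
  one <- new_constraint_graph(1, data.frame(i = integer(0), j = integer(0),
                                            bars = integer(0)))
  expect_equal(pebble_game(one), list(1L))
  six <- new_constraint_graph(2, data.frame(i = 1, j = 2, bars = 6))
  expect_equal(canon_clusters(pebble_game(six)), "1,2")
  five <- new_constraint_graph(2, data.frame(i = 1, j = 2, bars = 5))
  expect_equal(canon_clusters(pebble_game(five)), "1;2")
  ring <- data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 1), bars = 5)
  set.seed(5)
  expect_equal(canon_clusters(pebble_game(new_constraint_graph(4, ring))),
               canon_clusters(oracle_clusters(4, ring)))
})

test_that("pebble game equals the rigidity-matrix-rank oracle on small graphs", {
  ## exhaustive over all multigraphs on <= 4 bodies with bar multiplicities
  ## in {0, 2, 5, 6} (4^6 = 4096 instances); 5- and 6-body instances are
  ## covered by a seeded random sample (full enumeration is astronomically
  ## large).
  set.seed(99)
  prs4 <- t(utils::combn(4, 2))
  mult <- c(0L, 2L, 5L, 6L)
  grid <- expand.grid(rep(list(mult), nrow(prs4)))
  for (r in seq_len(nrow(grid))) {
    bars <- as.integer(unlist(grid[r, ]))
    keep <- bars > 0
    if (!any(keep)) next
    ed <- data.frame(i = prs4[keep, 1], j = prs4[keep, 2], bars = bars[keep])
    expect_equal(canon_clusters(pebble_game(new_constraint_graph(4, ed))),
                 canon_clusters(oracle_clusters(4, ed)),
                 label = paste("bars:", paste(bars, collapse = ",")))
  }
  for (t in 1:150) {
    n <- sample(5:6, 1)
    prs <- t(utils::combn(n, 2))
    sel <- prs[stats::runif(nrow(prs)) < 0.5, , drop = FALSE]
    if (nrow(sel) == 0) next
    ed <- data.frame(i = sel[, 1], j = sel[, 2],
                     bars = sample(c(2L, 5L, 6L), nrow(sel), TRUE))
    expect_equal(canon_clusters(pebble_game(new_constraint_graph(n, ed))),
                 canon_clusters(oracle_clusters(n, ed)),
                 label = paste("random instance", t))
  }
})

test_that("cluster decomposition is independent of edge insertion order", {
  conf <- two_domain_fixture()$start
  g <- build_constraint_graph(conf)
  ref <- canon_clusters(pebble_game(g))
  set.seed(17)
  for (t in 1:10) {
    g2 <- g
    g2$edges <- g$edges[sample.int(nrow(g$edges)), ]
    expect_equal(canon_clusters(pebble_game(g2)), ref)
  }
})

test_that("adding a bar never shrinks any rigid cluster", {
  set.seed(23)
  for (t in 1:20) {
    n <- sample(4:7, 1)
    prs <- t(utils::combn(n, 2))
    sel <- prs[stats::runif(nrow(prs)) < 0.5, , drop = FALSE]
    if (nrow(sel) < 2) next
    ed <- data.frame(i = sel[, 1], j = sel[, 2],
                     bars = sample(c(2L, 5L, 6L), nrow(sel), TRUE))
    before <- pebble_game(new_constraint_graph(n, ed))
    ed2 <- ed
    grow <- sample.int(nrow(ed2), 1)
    ed2$bars[grow] <- pmin(ed2$bars[grow] + 1L, 6L)
    after <- pebble_game(new_constraint_graph(n, ed2))
    ## each old cluster must be contained in a single new cluster
    for (cl in before) {
      containing <- Filter(function(x) all(cl %in% x), after)
      expect_equal(length(containing), 1)
    }
  }
})

test_that("flexible-residue derivation applies the cluster-size filter", {
  conf <- helix_conf(3)   # 15 atoms
  ## one 5-atom cluster below a min size of 6 is discarded entirely
  rep5 <- derive_flexible_residues(list(1:5, 6:15), conf, min_cluster_atoms = 6)
  expect_equal(length(rep5$clusters), 1)
  expect_true(1 %in% rep5$flexible_residues)
  ## the whole protein in one retained cluster leaves nothing flexible
  rep_all <- derive_flexible_residues(list(1:15), conf, min_cluster_atoms = 6)
  expect_equal(length(rep_all$flexible_residues), 0)
  expect_error(derive_flexible_residues(list(1:15), conf, 0),
               "min_cluster_atoms")
})

test_that("a lower cluster-size threshold yields a subset of flexible residues", {
  conf <- two_domain_fixture()$start
  cl <- pebble_game(build_constraint_graph(conf))
  f1 <- derive_flexible_residues(cl, conf, 1)$flexible_residues
  for (thr in c(6, 7, 8)) {
    fthr <- derive_flexible_residues(cl, conf, thr)$flexible_residues
    expect_true(all(f1 %in% fthr))
  }
})

test_that("the engineered hinge is detected and the domain cores are rigid", {
  fx <- two_domain_fixture()
  rep <- rigidity_analysis(fx$start, min_cluster_atoms = 6)
  ## at least one hinge residue flagged flexible (all three, in fact)
  expect_gte(length(intersect(fx$hinge_residues, rep$flexible_residues)), 1)
  ## fewer than 20% of domain-core residues flexible (cores exclude the
  ## domain ends adjacent to the hinge and the chain termini)
  core <- c(2:7, 13:19)
  frac <- length(intersect(core, rep$flexible_residues)) / length(core)
  expect_lt(frac, 0.20)
})

test_that("flexible-list overrides parse PDB numbering with comments", {
  conf <- two_domain_fixture()$start
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c("# hinge picked by an external tool", "9", "10 ", "", "11"), f)
  rep <- read_flexible_list(f, conf$structure)
  expect_equal(rep$flexible_residues, 9:11)
  writeLines("not-a-number", f)
  expect_error(read_flexible_list(f, conf$structure), "malformed")
})

test_that("rigidity reports export a parseable cluster table", {
  fx <- two_domain_fixture()
  rep <- rigidity_analysis(fx$start)
  f <- tempfile()
  on.exit(unlink(f))
  write_rigidity_report(rep, f)
  lines <- readLines(f)
  expect_equal(lines[1], "cluster_id\tsize\tatom_serials")
  expect_equal(sum(grepl("^\\d+\t", lines)), length(rep$clusters))
})
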
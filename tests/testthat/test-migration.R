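test_that("migration counts tally pairs by destination and origin", {
  pairs <- tibble::tibble(
    offspring = c("o1", "o2", "o3"), offspring_pop = c("FJ", "FJ", "FJ"),
    parent = c("p1", "p2", "p3"), parent_pop = c("YN", "YN", "FJ"),
    lod = 1, n_loci_compared = 15L, n_mismatch = 0L)
  m <- migration_counts(pairs, c("FJ", "YN"))
  expect_equal(unname(m["FJ", "YN"]), 2L)
  expect_equal(unname(m["FJ", "FJ"]), 1L)
  expect_equal(sum(m), 3L)

  empty <- migration_counts(pairs[0, ], c("FJ", "YN"))
  expect_true(all(empty == 0))
  expect_error(migration_counts(pairs, c("FJ")), "unknown population")
})

test_that("counts conserve pairs and isolate migration in the simulator", {
  sim <- simulate_metapopulation(sim_config(
    n_demes = 3, deme_size = 60, sample_per_deme = 20,
    parent_sampling_fraction = 1, n_time_slices = 1,
    error_rate = 0, missing_rate = 0,
    migration = diag(3), seed = 41))
  sl <- time_slice(sim$data, 1)
  pairs <- assign_parentage(sl, error = 1e-4, seed = 11, n_sim = 2000)
  m <- migration_counts(pairs, sl)
  expect_equal(sum(m), nrow(pairs))
  expect_equal(sum(m) - sum(diag(unclass(m))),
               sum(pairs$offspring_pop != pairs$parent_pop))
  # closed demes: cross-population counts are only the multiple-comparison
  # residue of thresholding (best-of-n tests per offspring), and stay small
  cross <- sum(m) - sum(diag(unclass(m)))
  expect_lte(cross / sum(m), 0.06)
  # and the realized migration matrix is strictly diagonal
  rm <- realized_migration(sim$truth)
  expect_true(all(unclass(rm)[upper.tri(rm) | lower.tri(rm)] == 0))
})

test_that("migration rates are row-normalised with Wilson intervals", {
  m <- counts_from_edges(2, list())
  m["a", "a"] <- 6L; m["a", "b"] <- 2L
  r <- migration_rates(m)
  ra <- r[r$destination == "a", ]
  expect_equal(unname(sort(ra$m)), c(0.25, 0.75))
  expect_true(all(ra$ci_low <= ra$m & ra$m <= ra$ci_high))
  expect_equal(sum(ra$m), 1)
  # all-resident row: zero off-diagonal rate but positive upper CI
  m2 <- counts_from_edges(2, list()); m2["a", "a"] <- 10L
  r2 <- migration_rates(m2)
  off <- r2[r2$destination == "a" & r2$origin == "b", ]
  expect_equal(unname(off$m), 0)
  expect_gt(off$ci_high, 0)
  # undefined rows flagged as NA
  expect_true(all(is.na(r2$m[r2$destination == "b"])))
})

test_that("network edges, degrees and source/sink labels follow counts", {
  # star of immigration into f from 5 populations
  star <- counts_from_edges(6, lapply(1:5, function(i) c(i, 6)))
  net <- build_network(star)
  d <- network_degrees(net)
  expect_equal(unname(d$in_degree[d$population == "f"]), 5)
  expect_equal(unname(d$out_degree[d$population == "f"]), 0)
  expect_equal(unname(d$degree[d$population == "f"]), 5)
  roles <- classify_source_sink(net)
  expect_equal(roles$role[roles$population == "f"], "sink")
  expect_true(all(roles$role[roles$population != "f"] == "source"))

  # zero off-diagonal counts -> edgeless
  none <- counts_from_edges(3, list())
  none["a", "a"] <- 4L
  expect_equal(igraph::ecount(build_network(none)), 0)

  # cycle a -> b -> c -> a
  cyc <- counts_from_edges(3, list(c(1, 2), c(2, 3), c(3, 1)))
  netc <- build_network(cyc)
  expect_equal(igraph::ecount(netc), 3)
  expect_true(all(classify_source_sink(netc)$role == "mixed"))
  # labels invariant to node relabelling
  cyc2 <- cyc[c(2, 1, 3), c(2, 1, 3)]
  class(cyc2) <- class(cyc)
  r1 <- dplyr::arrange(classify_source_sink(build_network(cyc2)), population)
  r2 <- dplyr::arrange(classify_source_sink(netc), population)
  expect_equal(r1, r2)
})

test_that("edge betweenness matches brute-force path counting", {
  # canonical cases
  path3 <- counts_from_edges(3, list(c(1, 2), c(2, 3)))
  eb <- edge_betweenness_undirected(build_network(path3))
  expect_equal(eb$betweenness, c(2, 2))
  tri <- counts_from_edges(3, list(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(edge_betweenness_undirected(build_network(tri))$betweenness,
               c(1, 1, 1))
  barbell <- counts_from_edges(6, list(c(1, 2), c(2, 3), c(3, 1),
                                       c(4, 5), c(5, 6), c(6, 4), c(1, 4)))
  ebb <- edge_betweenness_undirected(build_network(barbell))
  bridge <- ebb[ebb$from == "a" & ebb$to == "d", ]
  expect_equal(bridge$betweenness, 9)
  expect_equal(max(ebb$betweenness), 9)

  # random graphs vs the BFS oracle
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    edges <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.45) edges[[length(edges) + 1]] <- c(i, j)
    }
    if (length(edges) == 0) next
    cnt <- counts_from_edges(n, edges)
    ours <- dplyr::arrange(
      edge_betweenness_undirected(build_network(cnt)), from, to)
    oracle <- dplyr::arrange(brute_edge_betweenness(adj_from_counts(cnt)),
                             from, to)
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("fast-greedy clustering attains the exhaustive optimum", {
  # disconnected triangles
  tri2 <- counts_from_edges(6, list(c(1, 2), c(2, 3), c(3, 1),
                                    c(4, 5), c(5, 6), c(6, 4)))
  cl <- cluster_migration(build_network(tri2), weights = "none")
  expect_equal(cl$n_clusters, 2)
  expect_equal(cl$Q, 0.5, tolerance = 1e-12)
  # bridged triangles
  tri2b <- counts_from_edges(6, list(c(1, 2), c(2, 3), c(3, 1),
                                     c(4, 5), c(5, 6), c(6, 4), c(1, 4)))
  clb <- cluster_migration(build_network(tri2b), weights = "none")
  expect_equal(clb$n_clusters, 2)
  expect_equal(clb$Q, 5 / 14, tolerance = 1e-12)
  # single edge: merging beats splitting
  k2 <- counts_from_edges(2, list(c(1, 2)))
  clk <- cluster_migration(build_network(k2), weights = "none")
  expect_equal(clk$n_clusters, 1)
  expect_equal(clk$Q, 0)
  # exhaustive-search confirmation on clique families
  for (cnt in list(tri2, tri2b)) {
    adj <- adj_from_counts(cnt)
    opt <- best_partition_modularity(adj)
    ours <- cluster_migration(build_network(cnt), weights = "none")
    expect_equal(ours$Q, opt$Q, tolerance = 1e-12)
  }
  # Q reported equals Q recomputed from the partition
  clw <- cluster_migration(build_network(tri2b), weights = "betweenness")
  w <- igraph::E(clw$graph)$weight
  memb <- clw$membership$cluster[
    match(igraph::V(clw$graph)$name, clw$membership$population)]
  expect_equal(clw$Q, igraph::modularity(clw$graph, memb, weights = w),
               tolerance = 1e-12)
  # edgeless graph: singletons with Q = 0
  e0 <- cluster_migration(build_network(counts_from_edges(4, list())))
  expect_equal(e0$n_clusters, 4)
  expect_equal(e0$Q, 0)
})

test_that("key nodes combine degree maxima and cluster bridges", {
  # hub and spokes, single cluster
  hub <- counts_from_edges(5, lapply(2:5, function(i) c(1, i)))
  neth <- build_network(hub)
  kh <- key_nodes(neth, cluster_migration(neth, weights = "none"))
  expect_equal(kh$global$population, "a")
  # barbell: two clusters, both bridge endpoints reported
  barbell <- counts_from_edges(6, list(c(1, 2), c(2, 3), c(3, 1),
                                       c(4, 5), c(5, 6), c(6, 4), c(1, 4)))
  netb <- build_network(barbell)
  kb <- key_nodes(netb, cluster_migration(netb, weights = "none"))
  expect_setequal(kb$bridges$population, c("a", "d"))
  expect_true(all(kb$bridges$clusters_touched >= 2))
  # edgeless network: empty report
  nete <- build_network(counts_from_edges(3, list()))
  ke <- key_nodes(nete, cluster_migration(nete))
  expect_equal(nrow(ke$global), 0)
  expect_equal(nrow(ke$bridges), 0)
})

test_that("migration distance summaries use geodesic edges and t intervals", {
  # three edges of known length along the equator: 1, 2, 3 degrees
  deg_km <- 2 * pi * 6371.0088 / 360
  coords <- tibble::tibble(population = letters[1:4],
                           latitude = 0, longitude = c(0, 1, 2, 3))
  cnt <- counts_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  # edges a->b (1 deg), a->c (2 deg), a->d (3 deg)
  net <- build_network(cnt, coords)
  s <- migration_distance_summary(net)
  d <- sort(s$edges$distance_km)
  expect_equal(d, deg_km * 1:3, tolerance = 1e-6)
  m <- mean(d); half <- stats::qt(0.975, 2) * stats::sd(d) / sqrt(3)
  expect_equal(s$summary$mean_km, m, tolerance = 1e-9)
  expect_equal(s$summary$ci_low_km, m - half, tolerance = 1e-9)
  expect_equal(s$summary$ci_high_km, m + half, tolerance = 1e-9)

  # single edge: CI flagged undefined
  one <- build_network(counts_from_edges(2, list(c(1, 2))),
                       coords[1:2, ])
  s1 <- migration_distance_summary(one)
  expect_false(s1$summary$ci_defined)
  expect_true(is.na(s1$summary$ci_low_km))

  # missing coordinates error names the node
  bad <- coords; bad$latitude[2] <- NA
  expect_error(migration_distance_summary(build_network(cnt, bad)), "b")
})

test_that("source/sink persistence is stable under constant migration", {
  M <- matrix(c(0.4, 0.3, 0.3,
                0.0, 1.0, 0.0,
                0.0, 0.0, 1.0), 3, byrow = TRUE)
  # deme A receives migrant parents from B and C every generation while B
  # and C are closed: A is a persistent sink, B and C persistent sources
  sim <- simulate_metapopulation(sim_config(
    n_demes = 3, deme_size = 150, sample_per_deme = 40,
    parent_sampling_fraction = 1, n_time_slices = 3,
    error_rate = 0, missing_rate = 0, migration = M, seed = 47))
  labels <- list()
  for (tc in 1:3) {
    rm <- realized_migration(sim$truth, slice = tc)
    rownames(rm) <- colnames(rm) <- LETTERS[1:3]
    labels[[paste0("t", tc)]] <- classify_source_sink(build_network(rm))
  }
  per <- source_sink_persistence(labels)
  a <- per[per$site == "A", ]
  expect_true(a$persistent)
  expect_match(a$roles, "^sink")
})
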
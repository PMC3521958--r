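test_that("weighted betweenness reproduces hand-derived fixtures", {
  # star K_{1,4}: centre mediates all 6 leaf pairs
  star <- reference_graph("star", 5)
  expect_equal(weighted_betweenness(star),
               c(g1 = 6, g2 = 0, g3 = 0, g4 = 0, g5 = 0))
  # clique: every pair adjacent, direct edge strictly shortest
  expect_true(all(weighted_betweenness(reference_graph("clique", 4)) == 0))
  # weighted triangle: the cheap two-hop route beats the heavy direct edge
  tri <- distance_network(c("a", "b", "c"),
                          data.frame(source = c("a", "b", "a"),
                                     target = c("b", "c", "c"),
                                     weight = c(1, 1, 3)))
  expect_equal(weighted_betweenness(tri), c(a = 0, b = 1, c = 0))
})

test_that("weighted betweenness matches exhaustive path enumeration", {
  set.seed(13)
  for (rep in 1:40) {
    net <- random_connected_graph(sample(4:8, 1))
    expect_equal(weighted_betweenness(net), oracle_betweenness(net),
                 tolerance = 1e-9)
  }
  # degree-1 nodes in connected graphs carry no load
  set.seed(14)
  for (rep in 1:10) {
    net <- random_connected_graph(6, p_extra = 0.2)
    deg <- table(c(net$edges$source, net$edges$target))
    b <- weighted_betweenness(net)
    expect_true(all(b[names(deg)[deg == 1]] == 0))
    expect_true(all(b >= 0))
  }
})

test_that("capacities are proportional to initial load and fixed", {
  loads <- c(a = 6, b = 0, c = 1.5)
  p0 <- initial_capacities(loads, 0)
  expect_identical(p0$capacity, loads)
  expect_equal(initial_capacities(loads, 1)$capacity[["a"]], 12)
  expect_equal(initial_capacities(loads, 7)$capacity[["b"]], 0)
  expect_error(initial_capacities(loads, -0.1), ">= 0")
})

test_that("hand-traced cascades on star, clique and cycle are exact", {
  star <- reference_graph("star", 5)
  res <- cascade_all(star, alpha = 0, t_cf = 0.5)
  expect_equal(unname(res$d), c(1, 0.2, 0.2, 0.2, 0.2))
  expect_equal(res$R, 0.36)
  expect_equal(res$P, 0.2)
  # seed = centre: all leaves isolated in one round
  ev <- cascade_from_node(star, initial_capacities(weighted_betweenness(star)),
                          "g1")
  expect_equal(ev$s, 5L)
  expect_equal(ev$d, 1)
  expect_length(ev$rounds, 2L)
  # seed = leaf: centre load drops 6 -> 3, nothing fails
  ev2 <- cascade_from_node(star, initial_capacities(weighted_betweenness(star)),
                           "g2")
  expect_equal(ev2$s, 1L)
  expect_equal(ev2$d, 0.2)

  clique <- cascade_all(reference_graph("clique", 4))
  expect_equal(unname(clique$d), rep(0.25, 4))
  expect_equal(clique$P, 0)
  expect_equal(clique$R, 0.25)

  cyc <- cascade_all(reference_graph("cycle", 4))
  expect_equal(unname(cyc$d), rep(1, 4))
  expect_equal(cyc$P, 1)
  expect_equal(cyc$R, 1)
})

test_that("single-edge network with an isolated bystander follows the trace", {
  net <- distance_network(c("g1", "g2", "g3"),
                          data.frame(source = "g1", target = "g2", weight = 1))
  res <- cascade_all(net)
  expect_equal(res$d, c(g1 = 2 / 3, g2 = 2 / 3, g3 = 1 / 3))
  # the initially isolated node never fails by isolation, and as a seed
  # removes only itself
  ev <- cascade_from_node(net, initial_capacities(weighted_betweenness(net)),
                          "g3")
  expect_identical(ev$failed, "g3")
})

test_that("cascade events have disjoint rounds, seed membership and bounded d", {
  set.seed(23)
  for (rep in 1:10) {
    net <- random_connected_graph(sample(5:9, 1))
    prof <- initial_capacities(weighted_betweenness(net))
    for (seed_node in net$nodes) {
      ev <- cascade_from_node(net, prof, seed_node)
      all_failed <- unlist(ev$rounds)
      expect_identical(sort(all_failed), sort(ev$failed))
      expect_false(anyDuplicated(all_failed) > 0)
      expect_true(seed_node %in% ev$failed)
      expect_lte(length(ev$rounds), length(net$nodes))
      expect_gte(ev$d, 1 / length(net$nodes))
      expect_lte(ev$d, 1)
    }
  }
  expect_error(cascade_from_node(net, prof, "nope"), "not in network")
})

test_that("on trees, cascades are isolation-only and independent of alpha", {
  # Tree paths are unique, so removing nodes can only delete load
  # contributions: no overload occurs at any alpha >= 0, failures reduce to
  # the isolation criterion, and s_i equals 1 plus the seed's degree-1
  # neighbour count at every tolerance.
  set.seed(31)
  for (rep in 1:8) {
    net <- random_connected_graph(sample(5:10, 1), p_extra = 0)  # tree
    exp_s <- 1 + vapply(net$nodes, isolation_count, 0, net = net)
    for (a in c(0, 0.5, 5, 1e12)) {
      s <- cascade_all(net, alpha = a)$s
      expect_equal(unname(s), unname(exp_s))
    }
  }
})

test_that("capacities are not recomputed mid-cascade", {
  # star with a pendant chain: g1-g2..g5 star plus g2-g6.
  # Removing g1 isolates g3..g5; g2 keeps g6: its load (1 path g6-? none) ...
  # capacity was fixed at the intact-network value; mutate survivor graph
  # by hand and verify the event is identical to a fresh profile copy.
  net <- distance_network(paste0("g", 1:6),
    data.frame(source = c("g1", "g1", "g1", "g1", "g2"),
               target = c("g2", "g3", "g4", "g5", "g6"),
               weight = 1))
  prof <- initial_capacities(weighted_betweenness(net))
  before <- prof$capacity
  ev <- cascade_from_node(net, prof, "g1")
  expect_identical(prof$capacity, before)
  expect_true(all(c("g3", "g4", "g5") %in% ev$failed))
})

test_that("cumulative curve is a proper survivor function anchored at P", {
  res <- cascade_all(reference_graph("star", 5))
  cc <- cumulative_curve(res, grid = seq(0, 1, by = 0.05))
  expect_equal(cc$cum_prob[cc$d == 0], 1)
  expect_equal(cc$cum_prob[cc$d == 0.5], res$P)
  expect_equal(cc$cum_prob[cc$d == 0.5], 0.2)
  expect_equal(cc$cum_prob[cc$d == 1], 0.2)   # the centre reaches d = 1
  expect_true(all(diff(cc$cum_prob) <= 0))
  expect_error(cumulative_curve(res, grid = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("threshold sweep uses the standard 18 thresholds and handles edge cases", {
  expect_identical(default_thresholds(),
                   c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45,
                     0.5, 0.55, 0.6, 0.65, 0.7, 0.8, 0.9, 0.99))
  # an edgeless network: every seed fails alone
  lab <- rbind(g1 = c(1, 2, 1, 2), g2 = c(1, 1, 2, 2), g3 = c(2, 1, 2, 1))
  attr(lab, "n_bins") <- 2L
  net <- nmi_matrix(lab)
  net$nmi[] <- 0
  sw <- threshold_sweep(net, thresholds = c(0, 0.5))
  expect_true(all(sw$summary$P == 0))
  expect_true(all(abs(sw$summary$R - 1 / 3) < 1e-12))
  expect_error(threshold_sweep(net, thresholds = numeric()), "non-empty")
})
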
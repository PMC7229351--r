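# Temporal variability, temporal correlation coefficient, temporal path
# length: worked examples, oracle equivalence on small networks, and the
# metric-family invariants.

test_that("temporal variability hits its limits: 0 for frozen, 2 for anticorrelated", {
  set.seed(1)
  L <- rand_weighted_net(5, 1)$layers[[1]]
  frozen <- weighted_dynamic_network(list(L, L, L, L))
  expect_equal(unname(nodal_temporal_variability(frozen)), rep(0, 5))
  expect_equal(global_temporal_variability(frozen), 0)

  flipped <- weighted_dynamic_network(list(L, -L))
  expect_equal(unname(nodal_temporal_variability(flipped)), rep(2, 5))
  expect_equal(global_temporal_variability(flipped), 2)
})

test_that("nodal temporal variability matches direct formula evaluation", {
  set.seed(42)
  for (rep in 1:10) {
    rw <- rand_weighted_net(sample(4:6, 1), sample(3:5, 1))
    v <- nodal_temporal_variability(rw$net)
    expect_equal(unname(v), oracle_variability(rw$layers), tolerance = 1e-12)
    expect_true(all(v >= 0 & v <= 2))
    expect_equal(global_temporal_variability(rw$net), mean(v))
  }
})

test_that("variability flags constant connectivity profiles", {
  L1 <- rand_weighted_net(4, 1)$layers[[1]]
  L2 <- L1
  L2[2, -2] <- 0.5; L2[-2, 2] <- 0.5   # node 2 profile constant in layer 2
  net <- weighted_dynamic_network(list(L1, L2))
  expect_error(nodal_temporal_variability(net), "n2.*layer 2")
})

test_that("whole-matrix variability variant agrees on the frozen / flipped limits", {
  set.seed(2)
  L <- rand_weighted_net(5, 1)$layers[[1]]
  frozen <- weighted_dynamic_network(list(L, L, L))
  expect_equal(global_temporal_variability(frozen, method = "whole_matrix"), 0)
  flipped <- weighted_dynamic_network(list(L, -L))
  expect_equal(global_temporal_variability(flipped, method = "whole_matrix"), 2)
})

edge_layers <- function(N, ...) {
  # build binary layers from edge lists given as list(c(i, j), ...)
  lapply(list(...), function(edges) {
    A <- matrix(0L, N, N)
    for (e in edges) { A[e[1], e[2]] <- 1L; A[e[2], e[1]] <- 1L }
    A
  })
}

test_that("temporal correlation: worked 5-node example and limits", {
  # layer1 edges {(1,2),(1,3)}, layer2 edges {(1,2),(1,4)}
  ls <- edge_layers(5, list(c(1, 2), c(1, 3)), list(c(1, 2), c(1, 4)))
  net <- binary_dynamic_network(ls)
  ci <- nodal_temporal_correlation(net)
  expect_equal(unname(ci), c(1 / 2, 1, 0, 0, 0))
  expect_equal(global_temporal_correlation(net), 0.3)

  # constant network without isolates: C_i = 1
  ring <- edge_layers(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))[[1]]
  cn <- binary_dynamic_network(list(ring, ring, ring))
  expect_equal(unname(nodal_temporal_correlation(cn)), rep(1, 4))

  # disjoint neighbor sets between consecutive layers: C_i = 0
  dj <- binary_dynamic_network(edge_layers(4, list(c(1, 2)), list(c(1, 3))))
  expect_equal(nodal_temporal_correlation(dj)[["n1"]], 0)

  # empty network: all terms zero by convention
  empty <- binary_dynamic_network(edge_layers(4, list(), list()))
  expect_equal(global_temporal_correlation(empty), 0)
})

test_that("latency: chain example is asymmetric and waiting is allowed", {
  # layer1 = {(1,2)}, layer2 = {(2,3)}
  net <- binary_dynamic_network(edge_layers(3, list(c(1, 2)), list(c(2, 3))))
  d <- latency_matrix(net)$d
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 2)   # 1 -> 2 in layer 1, wait, 2 -> 3 in layer 2
  expect_equal(d[2, 3], 2)
  expect_equal(d[2, 1], 1)
  expect_equal(d[3, 1], Inf) # reversing would need decreasing layers
  expect_equal(d[3, 2], 2)
})

test_that("latency: complete first layer gives distance 1 everywhere", {
  K <- matrix(1L, 4, 4); diag(K) <- 0L
  net <- binary_dynamic_network(list(K, matrix(0L, 4, 4)))
  d <- latency_matrix(net)$d
  expect_equal(unname(d[row(d) != col(d)]), rep(1, 12))
  cp <- characteristic_temporal_path_length(latency_matrix(net))
  expect_equal(cp$value, 1)
  expect_equal(cp$unreachable_fraction, 0)
})

test_that("latency: edge only in layer 3 forces distance 3 both ways", {
  Z <- matrix(0L, 2, 2)
  E <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  net <- binary_dynamic_network(list(Z, Z, E))
  d <- latency_matrix(net)$d
  expect_equal(d[1, 2], 3)
  expect_equal(d[2, 1], 3)
})

test_that("path-length summaries follow from the latency matrix", {
  net <- binary_dynamic_network(edge_layers(3, list(c(1, 2)), list(c(2, 3))))
  lat <- latency_matrix(net)
  # enumeration oracle: d(1,2)=1, d(2,1)=1, d(1,3)=2, d(2,3)=2,
  # d(3,2)=2 (wait at layer 1, edge (2,3) in layer 2), d(3,1)=Inf
  expect_equal(unname(lat$d), oracle_latency(edge_layers(3, list(c(1, 2)),
                                                         list(c(2, 3)))))
  L <- nodal_temporal_path_length(lat)
  expect_equal(L[["n1"]], 1.5)              # (1 + 2) / 2
  expect_equal(L[["n3"]], 2)                # only 3 -> 2 is reachable
  expect_equal(attr(L, "n_unreachable")[3], 1L)
  cp <- characteristic_temporal_path_length(lat)
  expect_equal(cp$value, (1 + 1 + 2 + 2 + 2) / 5)
  expect_equal(cp$unreachable_fraction, 1 / 6)

  empty <- binary_dynamic_network(edge_layers(3, list(), list()))
  expect_true(all(nodal_temporal_path_length(latency_matrix(empty)) == Inf))
  expect_error(characteristic_temporal_path_length(latency_matrix(empty)),
               "all ordered node pairs")
})

test_that("latency and temporal correlation match enumeration oracles on random nets", {
  set.seed(99)
  for (rep in 1:60) {
    rb <- rand_binary_net(sample(3:6, 1), sample(2:4, 1), p = runif(1, 0.15, 0.6))
    expect_equal(unname(latency_matrix(rb$net)$d), oracle_latency(rb$layers))
    expect_equal(unname(nodal_temporal_correlation(rb$net)),
                 oracle_temporal_correlation(rb$layers), tolerance = 1e-12)
  }
})

test_that("metric ranges hold on random networks", {
  set.seed(123)
  for (rep in 1:20) {
    rb <- rand_binary_net(6, 4, p = runif(1, 0.2, 0.7))
    ci <- nodal_temporal_correlation(rb$net)
    expect_true(all(ci >= 0 & ci <= 1))
    d <- latency_matrix(rb$net)$d
    fin <- d[is.finite(d) & row(diag(6)) != col(diag(6))]
    if (length(fin)) expect_true(all(fin >= 1 & fin <= 4))
  }
})

test_that("metrics are node-permutation equivariant", {
  set.seed(17)
  rb <- rand_binary_net(6, 3, p = 0.4)
  perm <- sample(6)
  permuted <- binary_dynamic_network(lapply(rb$layers, function(A) A[perm, perm]))
  expect_equal(unname(nodal_temporal_correlation(permuted)),
               unname(nodal_temporal_correlation(rb$net))[perm])
  expect_equal(unname(latency_matrix(permuted)$d),
               unname(latency_matrix(rb$net)$d)[perm, perm])

  rw <- rand_weighted_net(6, 3)
  wperm <- weighted_dynamic_network(lapply(rw$layers, function(A) A[perm, perm]))
  expect_equal(unname(nodal_temporal_variability(wperm)),
               unname(nodal_temporal_variability(rw$net))[perm])
})

test_that("layer reversal preserves temporal correlation but not latency", {
  set.seed(31)
  rb <- rand_binary_net(6, 4, p = 0.3)
  rev_net <- binary_dynamic_network(rev(rb$layers))
  expect_equal(nodal_temporal_correlation(rev_net),
               nodal_temporal_correlation(rb$net))
  # counterexample fixture: the 3-node chain has no 1 -> 3 path after reversal
  chain <- binary_dynamic_network(edge_layers(3, list(c(1, 2)), list(c(2, 3))))
  chain_rev <- binary_dynamic_network(edge_layers(3, list(c(2, 3)), list(c(1, 2))))
  expect_equal(latency_matrix(chain)$d[1, 3], 2)
  expect_equal(latency_matrix(chain_rev)$d[1, 3], Inf)
})

test_that("adding edges never increases temporal distances; denser is faster", {
  set.seed(57)
  for (rep in 1:10) {
    rb <- rand_binary_net(6, 3, p = 0.25)
    d0 <- latency_matrix(rb$net)$d
    layers2 <- rb$layers
    t_add <- sample(3, 1)
    zeros <- which(layers2[[t_add]] == 0 & upper.tri(layers2[[t_add]]))
    if (!length(zeros)) next
    e <- zeros[sample(length(zeros), 1)]
    layers2[[t_add]][e] <- 1L
    layers2[[t_add]] <- pmax(layers2[[t_add]],
                             t(layers2[[t_add]]))
    d1 <- latency_matrix(binary_dynamic_network(layers2))$d
    expect_true(all(d1 <= d0))
  }

  # nested edge sets over sparsity imply shorter characteristic path
  rw <- rand_weighted_net(10, 4)
  cps <- vapply(c(0.15, 0.3, 0.5), function(s) {
    characteristic_temporal_path_length(
      latency_matrix(binarize_by_sparsity(rw$net, s)))$value
  }, numeric(1))
  expect_true(all(diff(cps) <= 1e-12))
})

test_that("subject_metrics composes the per-metric pieces consistently", {
  expect_length(default_sparsity_grid(), 41)

  set.seed(8)
  X <- matrix(rnorm(40 * 8), 40, 8)
  ts <- roi_time_series(X, tr_s = 2)
  sch <- make_windows(40, 2, 20, 10)
  grid <- c(0.2, 0.3, 0.4)
  sm <- subject_metrics(ts, sch, sparsity_grid = grid)
  expect_equal(sm$global$temporal_correlation_avg,
               mean(sm$global$temporal_correlation))
  expect_equal(sm$global$temporal_path_length_avg,
               mean(sm$global$temporal_path_length))
  expect_equal(sm$global$temporal_variability,
               mean(sm$nodal$variability))
  # per-sparsity values equal the directly computed ones
  net <- window_fc(ts, sch)
  bn <- binarize_by_sparsity(net, 0.3)
  expect_equal(sm$global$temporal_correlation[["0.30"]],
               global_temporal_correlation(bn))
  expect_equal(sm$global$temporal_path_length[["0.30"]],
               characteristic_temporal_path_length(latency_matrix(bn))$value)

  # a subject whose layers are all identical: variability 0, correlation 1
  Xc <- matrix(rnorm(10 * 5), 10, 5)
  Xrep <- rbind(Xc, Xc, Xc)
  tsc <- roi_time_series(Xrep, tr_s = 1)
  schc <- make_windows(30, 1, 10, 10)  # 3 windows, identical data
  smc <- subject_metrics(tsc, schc, sparsity_grid = 0.3)
  expect_equal(smc$global$temporal_variability, 0)
  # identical layers: every non-isolated node keeps its neighbors perfectly
  bnc <- binarize_by_sparsity(window_fc(tsc, schc), 0.3)
  deg <- rowSums(bnc$layers[, , 1])
  expect_equal(unname(smc$nodal$correlation[1, ]), as.numeric(deg > 0))
})
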
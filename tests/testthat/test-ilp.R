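test_that("discordance score matches hand-evaluated cases", {
  # perfect agreement scores 0
  g <- tiny_deletion_graph(cn = c(1, 0, 1), support = 5)
  f0 <- c(1, 0, 1, 0, 0, 1)  # 3 interval, 2 reference, 1 bridge
  expect_equal(discordance_score(g, f0, alpha = 0.1), 0)

  # single interval, l = L, w = 2, f = 3, no bridges -> 1.0
  seg1 <- reference_segmentation(list(chr1 = 7))
  g1 <- build_bridge_graph(seg1, observed_data(seg1, 2))
  expect_equal(discordance_score(g1, 3, alpha = 0.1), 1.0)

  # two unused bridges with supports 3 and 1 (mu = 4), perfect CN -> alpha
  seg2 <- reference_segmentation(list(chr1 = c(1, 1, 1, 1)))
  obs2 <- observed_data(seg2, c(2, 2, 2, 2),
                        bridge_set(c(ext_head(1), ext_head(2)),
                                   c(ext_tail(3), ext_tail(4)),
                                   support = c(3, 1)))
  g2 <- build_bridge_graph(seg2, obs2)
  f2 <- c(2, 2, 2, 2, 2, 2, 2, 0, 0)  # 4 interval, 3 reference, 2 bridges
  for (alpha in c(0.1, 0.5, 2)) {
    expect_equal(discordance_score(g2, f2, alpha), alpha)
  }
  expect_error(discordance_score(g2, -f2, 0.1), "nonnegative")
})

test_that("the deletion-style instance is solved exactly: bridge used, middle interval empty", {
  g <- tiny_deletion_graph(cn = c(1, 0, 1), support = 5)
  mult <- formulate_and_solve(g, alpha = 0.1)
  expect_equal(mult$objective, 0, tolerance = 1e-9)
  expect_equal(mult$f[1:3], c(1L, 0L, 1L))
  expect_equal(mult$f[6], 1L)  # the bridge
  expect_true(karyograph:::check_flow_balance(g, mult))
})

test_that("all-zero CN with no bridges solves to the empty karyotype", {
  seg <- reference_segmentation(list(chr1 = c(2, 3)))
  g <- build_bridge_graph(seg, observed_data(seg, c(0, 0)))
  mult <- formulate_and_solve(g, alpha = 0.1)
  expect_equal(mult$f, c(0L, 0L, 0L))
  expect_equal(mult$objective, 0)
})

test_that("clean telomere-bounded simulations are recovered with score exactly 0", {
  set.seed(51)
  p <- scenario_params(eps = 0, p = 0)
  for (rep in 1:5) {
    truth <- simulate_tumor(p)
    while (!is_telomere_bounded(truth$tumor, truth$seg))
      truth <- simulate_tumor(p)
    obs <- add_noise(truth, p)
    g <- build_bridge_graph(truth$seg, obs)
    mult <- formulate_and_solve(g, alpha = 0.1)
    expect_equal(mult$objective, 0, tolerance = 1e-9)
    # score 0 forces the true CN profile and every bridge used
    n_int <- nrow(truth$seg$intervals)
    expect_equal(mult$f[seq_len(n_int)], truth$cn)
    br <- g$connections$type == "bridge"
    expect_true(all(mult$f[br] >= 1L))
    expect_true(karyograph:::check_flow_balance(g, mult))
  }
})

test_that("a chromosome clipped at its end is outside the valid-path space", {
  # suffix deletion: the rearranged copy ends at an interior breakpoint,
  # so even noiseless data cannot be matched exactly: the flow couples
  # the flanking intervals and the optimum pays for the clipped tail
  fx <- deletion_example(300L, 291L, 300L)
  truth <- derive_truth(fx$reference, fx$tumor)
  expect_false(is_telomere_bounded(truth$tumor, truth$seg))
  obs <- observed_data(truth$seg, as.numeric(truth$cn), truth$bridges)
  g <- build_bridge_graph(truth$seg, obs)
  mult <- formulate_and_solve(g, alpha = 0.1)
  expect_equal(mult$objective, 10 / 300, tolerance = 1e-9)
  expect_equal(mult$f[1:2], c(2L, 2L))
})

test_that("brute-force enumeration agrees with the MIP on small graphs", {
  for (case in small_oracle_graphs(n = 8L, seed = 5L)) {
    g <- case$graph
    bf <- brute_force_solve(g, alpha = 0.1, bound = 3L)
    mip <- formulate_and_solve(g, alpha = 0.1)
    expect_gt(bf$n_feasible, 0)
    # the MIP searches a larger box; it can only do at least as well
    expect_lte(mip$objective, bf$objective + 1e-9)
    if (all(mip$f <= 3L))
      expect_equal(mip$objective, bf$objective, tolerance = 1e-9)
  }
})

test_that("brute force agrees with the MIP on the hand-built deletion instance", {
  g <- tiny_deletion_graph(cn = c(2, 1, 2), support = 5)
  bf <- brute_force_solve(g, alpha = 0.1, bound = 3L)
  mip <- formulate_and_solve(g, alpha = 0.1)
  expect_equal(bf$objective, 0, tolerance = 1e-12)
  expect_equal(mip$objective, 0, tolerance = 1e-9)
  expect_equal(bf$f[1:3], c(2L, 1L, 2L))
})

test_that("increasing alpha never decreases the number of bridges used", {
  for (case in small_oracle_graphs(n = 6L, seed = 6L)) {
    g <- case$graph
    br <- which(g$connections$type == "bridge")
    if (!length(br)) next
    used <- vapply(c(0, 0.05, 0.1, 0.5, 1), function(a) {
      sum(formulate_and_solve(g, alpha = a)$f[br] >= 1L)
    }, numeric(1L))
    expect_true(all(diff(used) >= 0))
  }
})

test_that("flow balance holds at every non-telomeric vertex after solving", {
  set.seed(52)
  p <- scenario_params()
  for (rep in 1:4) {
    truth <- simulate_tumor(p)
    g <- build_bridge_graph(truth$seg, add_noise(truth, p))
    mult <- formulate_and_solve(g, alpha = 0.1)
    expect_true(karyograph:::check_flow_balance(g, mult))
  }
})

test_that("score terms stay within their design ranges for unit deviations", {
  set.seed(53)
  p <- scenario_params()
  truth <- simulate_tumor(p)
  obs <- add_noise(truth, p)
  g <- build_bridge_graph(truth$seg, obs)
  n_int <- nrow(truth$seg$intervals)
  # f within 1 of the (integralized) weights, no bridge used
  f <- integer(nrow(g$connections))
  f[seq_len(n_int)] <- pmax(0L, as.integer(round(obs$cn)))
  dev <- abs(f[seq_len(n_int)] - obs$cn)
  stopifnot(all(dev <= 1))
  s <- discordance_score(g, f, alpha = 0.7)
  expect_lte(s, 1 + 0.7 + 1e-12)
})

test_that("karyotype_multiplicities threads the truth through the graph", {
  fx <- deletion_example(30L, 10L, 19L)
  tr <- derive_truth(fx$reference, fx$tumor)
  obs <- observed_data(tr$seg, as.numeric(tr$cn), {
    b <- tr$bridges; b$support <- 4; b
  })
  g <- build_bridge_graph(tr$seg, obs)
  mult <- karyotype_multiplicities(g, tr$tumor)
  n_int <- nrow(tr$seg$intervals)
  expect_equal(mult$f[seq_len(n_int)], tr$cn)
  expect_equal(mult$f[g$connections$type == "bridge"], 1L)
  expect_equal(discordance_score(g, mult$f, 0.1), 0)
  expect_true(karyograph:::check_flow_balance(g, mult))
})
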
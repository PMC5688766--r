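test_that("deterministic operation cores match their textbook definitions", {
  # (A,B,C) with B deleted -> (A,C); B inverted -> (A,-B,C)
  ch <- c(1L, 2L, 3L)
  expect_equal(karyograph:::op_delete(ch, 2L, 1L), c(1L, 3L))
  expect_equal(karyograph:::op_invert(ch, 2L, 1L), c(1L, -2L, 3L))
  expect_equal(karyograph:::op_tandem_dup(ch, 2L, 1L), c(1L, 2L, 2L, 3L))
  # inversion of a multi-segment run flips order and signs
  expect_equal(karyograph:::op_invert(1:4, 2L, 2L), c(1L, -3L, -2L, 4L))
  # (A,B),(C,D) -> (A,D),(C,B)
  res <- karyograph:::op_translocate(c(1L, 2L), c(3L, 4L), 1L, 1L)
  expect_equal(res, list(c(1L, 4L), c(3L, 2L)))
})

test_that("atomic-segment count is conserved or changed as the operation dictates", {
  set.seed(31)
  p <- scenario_params(C = 2L, segments_per_chromosome = 50L, max_span = 10L)
  k <- karyotype(list(1:50, 51:100, 1:50, 51:100))
  n_atoms <- function(k) sum(lengths(unclass(k)))
  for (rep in 1:20) {
    expect_equal(n_atoms(apply_operation(k, "inversion", p)), 200L)
    expect_equal(n_atoms(apply_operation(k, "translocation", p)), 200L)
    expect_lt(n_atoms(apply_operation(k, "deletion", p)), 200L)
    expect_gt(n_atoms(apply_operation(k, "tandem_duplication", p)), 200L)
  }
})

test_that("impossible operations are resampled and degenerate karyotypes error", {
  set.seed(32)
  p <- scenario_params()
  one <- karyotype(list(1:10))
  # translocation impossible with a single chromosome: resampled
  res <- apply_operation(one, "translocation", p)
  expect_s3_class(res, "karyotype")
  p_only_tl <- scenario_params(op_weights = c(deletion = 0, inversion = 0,
                                              tandem_duplication = 0,
                                              translocation = 1))
  expect_error(apply_operation(one, "translocation", p_only_tl),
               class = "degenerate_karyotype")
})

test_that("simulate_tumor with N = 0 returns the unrearranged diploid reference", {
  p <- scenario_params(N = 0L, seed = 7L)
  truth <- simulate_tumor(p)
  expect_equal(nrow(truth$seg$intervals), 5L)
  expect_equal(truth$cn, rep(2L, 5L))
  expect_equal(nrow(truth$bridges), 0L)
  expect_equal(length(truth$tumor), 10L)
})

test_that("a single forced deletion leaves one cn-1 interval, one bridge, <= 3 intervals", {
  set.seed(33)
  p <- scenario_params(N = 1L, op_weights = c(deletion = 1, inversion = 0,
                                              tandem_duplication = 0,
                                              translocation = 0))
  for (rep in 1:5) {
    truth <- simulate_tumor(p)
    expect_equal(sum(truth$cn == 1L), 1L)
    expect_lte(nrow(truth$bridges), 1L)  # 0 when the deletion hits an end
    per_chrom <- table(truth$seg$intervals$chrom)
    expect_lte(max(per_chrom), 3L)
  }
})

test_that("simulation is deterministic given the seed", {
  p <- scenario_params(seed = 99L)
  a <- simulate_tumor(p)
  b <- simulate_tumor(p)
  expect_identical(unclass(a$tumor), unclass(b$tumor))
  expect_identical(a$cn, b$cn)
})

test_that("noise-free observation equals the truth and p = 1 drops every bridge", {
  set.seed(34)
  p0 <- scenario_params(eps = 0, p = 0)
  truth <- simulate_tumor(p0)
  obs <- add_noise(truth, p0)
  expect_equal(obs$cn, as.numeric(truth$cn))
  expect_equal(nrow(obs$bridges), nrow(truth$bridges))
  p1 <- scenario_params(eps = 0, p = 1)
  expect_equal(nrow(add_noise(truth, p1)$bridges), 0L)
})

test_that("observed bridges are a subset of true bridges", {
  set.seed(35)
  p <- scenario_params(p = 0.4)
  truth <- simulate_tumor(p)
  obs <- add_noise(truth, p)
  expect_true(all(karyograph:::bridge_key(obs$bridges) %in%
                    karyograph:::bridge_key(truth$bridges)))
})

test_that("CN noise has the declared moments on unit-length intervals", {
  # 10,000 unit intervals: scaled and flat modes coincide at l = 1
  set.seed(36)
  ref <- as.list(setNames(rep(1, 100), paste0("c", 1:100)))
  seg <- reference_segmentation(lapply(ref, function(x) rep(1, 100)))
  truth <- structure(list(seg = seg, cn = rep(2L, 10000L),
                          bridges = bridge_set()),
                     class = "karyotype_truth")
  p <- scenario_params(eps = 0.28)
  obs <- add_noise(truth, p)
  delta <- obs$cn - 2
  n <- length(delta)
  expect_lt(abs(mean(delta)), 3 * 0.28 / sqrt(n))
  se_sd <- 0.28 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(delta) - 0.28), 3 * se_sd)
})

test_that("scaled noise shrinks with interval length", {
  set.seed(37)
  seg <- reference_segmentation(list(chr1 = rep(100, 2000)))
  truth <- structure(list(seg = seg, cn = rep(2L, 2000L),
                          bridges = bridge_set()),
                     class = "karyotype_truth")
  obs <- add_noise(truth, scenario_params(eps = 0.28))
  expect_lt(abs(sd(obs$cn - 2) - 0.028), 0.004)
})

test_that("observed bridge support has mean about 1 / lambda = 5.36", {
  set.seed(38)
  n <- 4000L
  seg <- reference_segmentation(list(chr1 = rep(1, n + 2L)))
  b <- bridge_set(ext_head(seq_len(n)), ext_tail(seq_len(n) + 2L))
  truth <- structure(list(seg = seg, cn = rep(2L, n + 2L), bridges = b),
                     class = "karyotype_truth")
  obs <- add_noise(truth, scenario_params(eps = 0, p = 0, lambda = 0.1866))
  m <- 1 / 0.1866
  expect_lt(abs(mean(obs$bridges$support) - m), 3 * m / sqrt(n))
})

test_that("normal contamination shifts the observed CN toward the ploidy", {
  fx <- deletion_example(100L, 40L, 49L)
  truth <- derive_truth(fx$reference, fx$tumor)
  p <- scenario_params(eps = 0, p = 0, normal_fraction = 0.5)
  obs <- add_noise(truth, p)
  expect_equal(obs$cn, (truth$cn + 2) / 2)
})
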
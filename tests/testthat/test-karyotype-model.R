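test_that("identity tumor yields a single interval per chromosome and no bridges", {
  ref <- list(chr1 = 1:300)
  tum <- karyotype(list(1:300, 1:300))
  seg <- derive_breakpoints(ref, tum)
  expect_equal(nrow(seg$intervals), 1L)
  expect_equal(seg$intervals$length, 300)
  expect_equal(seg$L, 300)
  expect_equal(length(seg$telomeres), 2L)
  k <- rethread_karyotype(ref, tum, seg)
  expect_equal(derive_cn_profile(k, seg), 2L)
  expect_equal(nrow(derive_bridges(k, seg)), 0L)
})

test_that("the rearranged four-segment chromosome produces all three internal breakpoints", {
  fx <- fig_example(diploid = FALSE)
  seg <- derive_breakpoints(fx$reference, fx$tumor)
  expect_equal(nrow(seg$intervals), 4L)
  expect_equal(seg$intervals$length, rep(1, 4))
  k <- rethread_karyotype(fx$reference, fx$tumor, seg)
  expect_equal(unclass(k)[[1]], c(1L, 4L, -4L, -3L, 2L, -1L))
  # occurrence counts over intervals 1..4
  expect_equal(derive_cn_profile(k, seg), c(2L, 1L, 1L, 2L))
  # bridges {h1,t4}, {h4,h4}, {t3,t2}, {h2,h1}; {t4,h3} is NOT a bridge
  b <- derive_bridges(k, seg)
  got <- karyograph:::bridge_key(b)
  want <- karyograph:::bridge_key(bridge_set(
    e1 = c(ext_head(1), ext_head(4), ext_tail(3), ext_head(2)),
    e2 = c(ext_tail(4), ext_head(4), ext_tail(2), ext_head(1))))
  expect_setequal(got, want)
  expect_false(paste(ext_head(3), ext_tail(4), sep = "|") %in% got)
})

test_that("an interior deletion partitions the chromosome into three intervals", {
  fx <- deletion_example(300L, 10L, 19L)
  tr <- derive_truth(fx$reference, fx$tumor)
  expect_equal(tr$seg$intervals$length, c(9, 10, 281))
  expect_equal(tr$cn, c(2L, 1L, 2L))
  expect_equal(nrow(tr$bridges), 1L)
  expect_equal(tr$bridges$e1, ext_head(1))
  expect_equal(tr$bridges$e2, ext_tail(3))
  # re-threading reproduces the tumor structure
  expect_same_karyotype(tr$tumor, karyotype(list(c(1, 3), c(1, 2, 3))))
})

test_that("tandem duplication yields the fold-forward bridge {h, t} of the repeated interval", {
  ref <- list(chr1 = 1:4)
  tum <- karyotype(list(c(1L, 2L, 2L, 3L, 4L)))
  tr <- derive_truth(ref, tum)
  i2 <- which(tr$cn == max(tr$cn))  # the duplicated interval
  expect_equal(nrow(tr$bridges), 1L)
  expect_equal(sort(c(tr$bridges$e1, tr$bridges$e2)),
               sort(c(ext_head(i2), ext_tail(i2))))
})

test_that("unknown atomic segments are rejected", {
  expect_error(derive_breakpoints(list(chr1 = 1:4),
                                  karyotype(list(c(1L, 9L)))),
               "absent")
})

test_that("bridges cannot duplicate reference adjacencies in observed data", {
  seg <- reference_segmentation(list(chr1 = c(2, 3)))
  expect_error(observed_data(seg, c(2, 2),
                             bridge_set(ext_head(1), ext_tail(2))),
               "reference adjacency")
})

test_that("round trip: derived truth is reproduced by re-threading random tumors", {
  set.seed(21)
  for (rep in 1:10) {
    p <- scenario_params(C = 2L, N = 4L, segments_per_chromosome = 40L,
                         max_span = 10L)
    truth <- simulate_tumor(p)
    k2 <- rethread_karyotype(truth$reference, truth$tumor_atomic, truth$seg)
    expect_identical(unclass(k2), unclass(truth$tumor))
    expect_identical(derive_cn_profile(k2, truth$seg), truth$cn)
    expect_identical(karyograph:::bridge_key(derive_bridges(k2, truth$seg)),
                     karyograph:::bridge_key(truth$bridges))
  }
})

test_that("reversing every tumor chromosome changes neither CN profile nor bridges", {
  set.seed(22)
  p <- scenario_params(C = 2L, N = 4L, segments_per_chromosome = 40L,
                       max_span = 10L)
  truth <- simulate_tumor(p)
  flipped <- karyotype(lapply(unclass(truth$tumor), function(ch) -rev(ch)))
  expect_identical(derive_cn_profile(flipped, truth$seg), truth$cn)
  expect_identical(karyograph:::bridge_key(derive_bridges(flipped, truth$seg)),
                   karyograph:::bridge_key(truth$bridges))
})

test_that("segmentation invariants hold", {
  seg <- reference_segmentation(list(a = c(5, 2), b = 7))
  expect_equal(seg$L, 14)
  expect_equal(length(seg$telomeres), 4L)
  expect_equal(seg$intervals$index, c(1L, 2L, 1L))
  expect_error(reference_segmentation(list(a = c(1, 0))), "positive")
  expect_error(reference_segmentation(list(1:3)), "named")
})

test_that("extremity encoding is self-consistent", {
  ids <- c(1L, 5L, 12L)
  expect_equal(ext_interval(ext_tail(ids)), ids)
  expect_equal(ext_interval(ext_head(ids)), ids)
  expect_equal(ext_side(ext_tail(ids)), rep("tail", 3))
  expect_equal(ext_side(ext_head(ids)), rep("head", 3))
})
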
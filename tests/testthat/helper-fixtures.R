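# Shared fixtures: small genomes built in code.

# single reference chromosome of four unit atomic segments and the
# rearranged tumor chromosome 1,4,-4,-3,2,-1 (plus one intact copy)
fig_example <- function(diploid = TRUE) {
  ref <- list(chr1 = 1:4)
  chroms <- list(c(1L, 4L, -4L, -3L, 2L, -1L))
  if (diploid) chroms <- c(chroms, list(1:4))
  list(reference = ref, tumor = karyotype(chroms))
}

# diploid chromosome of `n` atomic segments with one deletion of
# segments del_start..del_end on one copy
deletion_example <- function(n = 300L, del_start = 10L, del_end = 19L) {
  ref <- list(chr1 = seq_len(n))
  kept <- setdiff(seq_len(n), del_start:del_end)
  list(reference = ref,
       tumor = karyotype(list(kept, seq_len(n))))
}

# a tiny graph: one chromosome of three intervals, cn (1, 0, 1) and a
# single deletion-like bridge {h1, t3}
tiny_deletion_graph <- function(cn = c(1, 0, 1), support = 5,
                                lengths = c(1, 1, 1)) {
  seg <- reference_segmentation(list(chr1 = lengths))
  obs <- observed_data(seg, cn,
                       bridge_set(ext_head(1), ext_tail(3), support = support))
  build_bridge_graph(seg, obs)
}

# random small simulated instances whose bridge graphs have at most
# `max_conn` connections (for the brute-force oracle)
small_oracle_graphs <- function(n = 8L, seed = 5L, max_conn = 6L) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    p <- scenario_params(C = 1L, N = 1L, segments_per_chromosome = 8L,
                         max_span = 3L, ploidy = 1L, eps = 0.3, p = 0,
                         op_weights = c(deletion = 0.4, inversion = 0.3,
                                        tandem_duplication = 0.3,
                                        translocation = 0))
    truth <- simulate_tumor(p)
    obs <- add_noise(truth, p)
    g <- build_bridge_graph(truth$seg, obs)
    if (nrow(g$connections) <= max_conn)
      out <- c(out, list(list(graph = g, truth = truth)))
  }
  out
}

expect_same_karyotype <- function(a, b) {
  ca <- karyograph:::canonical_karyotype(a)
  cb <- karyograph:::canonical_karyotype(b)
  expect_identical(lapply(ca, as.integer), lapply(cb, as.integer))
}
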
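# Structural-variant simulator: random rearrangement operations on a
# diploid reference, Gaussian CN noise, exponentially distributed bridge
# support, and random bridge dropout.

#' Simulation scenario parameters
#'
#' Defaults correspond to a medium-complexity tumor with realistic noise:
#' 5 chromosomes of 300 atomic segments, 5 uniformly chosen operations
#' with intra-chromosomal span at most 30 segments, CN noise standard
#' deviation 0.28, a 5% chance for each bridge to go unobserved, and
#' observed bridge support drawn from an exponential distribution with
#' rate 0.1866 (mean about 5.4 supporting read pairs).
#'
#' @param C number of reference chromosomes.
#' @param N number of rearrangement operations applied.
#' @param eps standard deviation of the Gaussian noise added to each
#'   interval's copy number.
#' @param p probability that a bridge is dropped from the observed data.
#' @param lambda rate of the exponential distribution of bridge support.
#' @param cn_noise noise granularity. `"scaled"` (default) emulates
#'   coverage-based CN estimation: every atomic unit of an interval
#'   carries an independent `N(0, eps)` measurement error and the
#'   observed interval CN is their mean, so an interval of length `l`
#'   has noise sd `eps / sqrt(l)` — longer intervals get more accurate
#'   estimates, the same assumption that motivates length-weighting in
#'   the discordance score. `"flat"` adds `N(0, eps)` to every interval
#'   regardless of its length.
#' @param segments_per_chromosome atomic segments per chromosome.
#' @param max_span largest number of atomic segments a deletion,
#'   inversion or tandem duplication may affect.
#' @param op_weights named probability vector over operation types
#'   `deletion`, `inversion`, `tandem_duplication`, `translocation`
#'   (optionally also `chromosome_gain`, `chromosome_loss`, disabled by
#'   default); must sum to 1.
#' @param ploidy copies of each reference chromosome in the starting
#'   karyotype (2 = diploid).
#' @param normal_fraction contamination: fraction of normal (ploidy-CN)
#'   cells mixed into the observed CN signal before noise.
#' @param round_support round bridge support to the nearest positive
#'   integer (off by default; support is conceptually a read count but
#'   kept real-valued).
#' @param seed optional integer seed; when non-NULL, [simulate_tumor()]
#'   seeds the R RNG before drawing.
#' @return a list of class `scenario_params`.
#' @export
scenario_params <- function(C = 5L, N = 5L, eps = 0.28, p = 0.05,
                            lambda = 0.1866,
                            cn_noise = c("scaled", "flat"),
                            segments_per_chromosome = 300L,
                            max_span = 30L,
                            op_weights = NULL,
                            ploidy = 2L,
                            normal_fraction = 0,
                            round_support = FALSE,
                            seed = NULL) {
  default_w <- c(deletion = 0.25, inversion = 0.25,
                 tandem_duplication = 0.25, translocation = 0.25)
  if (is.null(op_weights)) op_weights <- default_w
  all_ops <- c(names(default_w), "chromosome_gain", "chromosome_loss")
  if (is.null(names(op_weights)) || !all(names(op_weights) %in% all_ops))
    stop("op_weights must be named with known operation types")
  if (abs(sum(op_weights) - 1) > 1e-9) stop("op_weights must sum to 1")
  stopifnot(C >= 1, N >= 0, eps >= 0, p >= 0, p <= 1, lambda > 0,
            segments_per_chromosome >= 1, max_span >= 1, ploidy >= 1,
            normal_fraction >= 0, normal_fraction < 1)
  cn_noise <- match.arg(cn_noise)
  structure(list(
    C = as.integer(C), N = as.integer(N), eps = eps, p = p, lambda = lambda,
    cn_noise = cn_noise,
    segments_per_chromosome = as.integer(segments_per_chromosome),
    max_span = as.integer(max_span), op_weights = op_weights,
    ploidy = as.integer(ploidy), normal_fraction = normal_fraction,
    round_support = round_support, seed = seed
  ), class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Scenario: C=", x$C, " N=", x$N, " eps=", x$eps, " p=", x$p,
      " lambda=", x$lambda, " ploidy=", x$ploidy,
      if (x$normal_fraction > 0) paste0(" normal_fraction=", x$normal_fraction),
      "\n", sep = "")
  invisible(x)
}

# ---- individual operations (deterministic cores) ----------------------------

op_delete <- function(ch, start, span) ch[-(start:(start + span - 1L))]

op_invert <- function(ch, start, span) {
  idx <- start:(start + span - 1L)
  ch[idx] <- -rev(ch[idx])
  ch
}

op_tandem_dup <- function(ch, start, span) {
  idx <- start:(start + span - 1L)
  append(ch, ch[idx], after = start + span - 1L)
}

# suffix swap after cut positions i, j: (A,B),(C,D) -> (A,D),(C,B)
op_translocate <- function(ch1, ch2, i, j) {
  list(c(ch1[seq_len(i)], ch2[-seq_len(j)]),
       c(ch2[seq_len(j)], ch1[-seq_len(i)]))
}

#' Apply one random rearrangement operation to a karyotype
#'
#' Positions are drawn uniformly at random: a chromosome is chosen
#' uniformly among the karyotype's chromosomes, the start uniformly over
#' valid starts and the span uniformly in `[1, min(max_span, room)]` for
#' intra-chromosomal operations. Translocations pick two distinct
#' chromosomes and interior cut points, swapping suffixes. If the
#' requested operation is impossible on the current karyotype (for
#' example a translocation with a single chromosome), the operation type
#' is resampled from `params$op_weights`; if no operation at all is
#' possible, an error of class `degenerate_karyotype` is raised.
#'
#' Uses the R random number generator; seed management is up to the
#' caller.
#'
#' @param k a [karyotype()] over atomic segments.
#' @param op_type one of `"deletion"`, `"inversion"`,
#'   `"tandem_duplication"`, `"translocation"`, `"chromosome_gain"`,
#'   `"chromosome_loss"`.
#' @param params a [scenario_params()] (supplies `max_span` and the
#'   resampling weights).
#' @return the rearranged [karyotype()].
#' @export
apply_operation <- function(k, op_type, params = scenario_params()) {
  chroms <- unclass(k)
  feasible <- function(op) {
    switch(op,
      deletion = ,
      inversion = ,
      tandem_duplication = length(chroms) >= 1L,
      translocation = sum(lengths(chroms) >= 2L) >= 2L,
      chromosome_gain = length(chroms) >= 1L,
      chromosome_loss = length(chroms) >= 1L,
      stop("unknown operation type: ", op))
  }
  if (!feasible(op_type)) {
    w <- params$op_weights
    ok <- vapply(names(w), feasible, logical(1L)) & w > 0
    if (!any(ok))
      stop(errorCondition("no rearrangement operation is possible",
                          class = "degenerate_karyotype"))
    op_type <- sample(names(w)[ok], 1L, prob = w[ok])
  }
  if (op_type %in% c("deletion", "inversion", "tandem_duplication")) {
    ci <- sample.int(length(chroms), 1L)
    ch <- chroms[[ci]]
    start <- sample.int(length(ch), 1L)
    room <- min(params$max_span, length(ch) - start + 1L)
    span <- if (room == 1L) 1L else sample.int(room, 1L)
    chroms[[ci]] <- switch(op_type,
      deletion = op_delete(ch, start, span),
      inversion = op_invert(ch, start, span),
      tandem_duplication = op_tandem_dup(ch, start, span))
  } else if (op_type == "translocation") {
    elig <- which(lengths(chroms) >= 2L)
    pair <- sample(elig, 2L)
    l1 <- length(chroms[[pair[1L]]]); l2 <- length(chroms[[pair[2L]]])
    i <- sample.int(l1 - 1L, 1L); j <- sample.int(l2 - 1L, 1L)
    res <- op_translocate(chroms[[pair[1L]]], chroms[[pair[2L]]], i, j)
    chroms[[pair[1L]]] <- res[[1L]]
    chroms[[pair[2L]]] <- res[[2L]]
  } else if (op_type == "chromosome_gain") {
    ci <- sample.int(length(chroms), 1L)
    chroms <- c(chroms, chroms[ci])
  } else if (op_type == "chromosome_loss") {
    ci <- sample.int(length(chroms), 1L)
    chroms <- chroms[-ci]
  }
  karyotype(chroms)
}

#' Simulate a rearranged tumor karyotype and its noiseless truth
#'
#' Starts from `ploidy` copies of `C` chromosomes of
#' `segments_per_chromosome` atomic segments, applies `N` operations
#' with types drawn from `op_weights`, then derives the exact
#' segmentation, integer CN profile and bridge set by comparing tumor
#' and reference (see [derive_truth()]).
#'
#' @param params a [scenario_params()].
#' @return a `karyotype_truth` (see [derive_truth()]) with the scenario
#'   parameters attached as attribute `params`.
#' @export
simulate_tumor <- function(params = scenario_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- params$segments_per_chromosome
  reference <- lapply(seq_len(params$C) - 1L, function(c0) c0 * m + seq_len(m))
  names(reference) <- paste0("chr", seq_len(params$C))
  tumor <- karyotype(rep(reference, params$ploidy))
  w <- params$op_weights
  for (i in seq_len(params$N)) {
    op <- sample(names(w), 1L, prob = w)
    tumor <- apply_operation(tumor, op, params)
  }
  truth <- derive_truth(reference, tumor)
  attr(truth, "params") <- params
  truth
}

#' Add measurement noise to a simulated truth
#'
#' Independent Gaussian noise `N(0, eps)` is added to every interval's
#' copy number (values are not clipped at zero: the discordance score
#' uses absolute deviations and clipping would bias it). Each bridge is
#' dropped independently with probability `p`; surviving bridges receive
#' a support value drawn from `Exp(lambda)`. With
#' `normal_fraction = m > 0` the noiseless CN is first mixed with the
#' normal ploidy: `(1 - m) * cn + m * ploidy`.
#'
#' Uses the R random number generator; seed management is up to the
#' caller.
#'
#' @param truth a `karyotype_truth` from [simulate_tumor()] /
#'   [derive_truth()].
#' @param params a [scenario_params()].
#' @return an [observed_data()] over `truth$seg`.
#' @export
add_noise <- function(truth, params = scenario_params()) {
  cn <- as.numeric(truth$cn)
  if (params$normal_fraction > 0)
    cn <- (1 - params$normal_fraction) * cn +
      params$normal_fraction * params$ploidy
  sd_i <- if (identical(params$cn_noise, "flat")) rep(params$eps, length(cn))
          else params$eps / sqrt(truth$seg$intervals$length)
  cn_obs <- cn + stats::rnorm(length(cn), mean = 0, sd = sd_i)
  b <- truth$bridges
  if (nrow(b)) {
    keep <- stats::runif(nrow(b)) >= params$p
    b <- b[keep, , drop = FALSE]
    supp <- stats::rexp(nrow(b), rate = params$lambda)
    if (params$round_support) supp <- pmax(1, round(supp))
    b$support <- supp
    rownames(b) <- NULL
    class(b) <- c("bridge_set", "data.frame")
  }
  observed_data(truth$seg, cn_obs, b)
}
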
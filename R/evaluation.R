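# The five solution-quality measures comparing a reconstruction S
# against the simulated truth T and the noisy observation it was
# computed from.

# core: all measures from edge multiplicities on the observed graph
evaluate_multiplicities <- function(g, mult, truth, alpha) {
  conns <- g$connections
  n_int <- n_intervals(truth$seg)
  if (!identical(g$seg$intervals$id, truth$seg$intervals$id) ||
      !isTRUE(all.equal(g$seg$intervals$length, truth$seg$intervals$length)))
    stop("solution and truth are over different segmentations")
  # interval connections are built first, in interval id order
  cn_S <- mult$f[seq_len(n_int)]
  cn_T <- truth$cn
  br_rows <- which(conns$type == "bridge")
  observed_keys <- paste(pmin(conns$u[br_rows], conns$v[br_rows]),
                         pmax(conns$u[br_rows], conns$v[br_rows]), sep = "|")
  used_keys <- observed_keys[mult$f[br_rows] >= 1L]
  true_keys <- bridge_key(truth$bridges)

  ecn <- all(cn_S == cn_T)
  correct <- ecn && setequal(used_keys, true_keys) &&
    length(used_keys) == length(true_keys)

  score_S <- discordance_score(g, mult$f, alpha)
  score_T <- discordance_score(g, karyotype_multiplicities(g, truth$tumor)$f,
                               alpha)
  ebs <- score_S <= score_T + 1e-9

  dropped <- setdiff(true_keys, observed_keys)
  affected <- integer()
  if (length(dropped)) {
    # intervals owning an extremity of a dropped bridge are exempt from
    # the CN check
    parts <- do.call(rbind, strsplit(dropped, "|", fixed = TRUE))
    affected <- unique(ext_interval(as.integer(c(parts[, 1L], parts[, 2L]))))
  }
  unaffected <- setdiff(seq_len(n_int), affected)
  eob <- all(observed_keys %in% used_keys) &&
    all(cn_S[unaffected] == cn_T[unaffected])

  len <- truth$seg$intervals$length
  cn_sc <- sum(len[cn_S == cn_T]) / truth$seg$L

  structure(list(correct = correct, ecn = ecn, ebs = ebs, eob = eob,
                 cn_score = cn_sc, score_S = score_S, score_T = score_T),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("correct=", x$correct, " ECN=", x$ecn, " EBS=", x$ebs,
      " EOB=", x$eob, " CN-score=", format(x$cn_score),
      " (score S=", format(x$score_S), ", T=", format(x$score_T), ")\n",
      sep = "")
  invisible(x)
}

#' Evaluate a reconstructed karyotype against the simulated truth
#'
#' Computes the five correctness measures:
#' \describe{
#'   \item{correct}{S is *equivalent* to T: identical integer CN
#'     profile and the same set of bridges used (orientation and
#'     chromosome order are ignored).}
#'   \item{ecn}{*Equal Copy Number*: identical integer CN profiles.}
#'   \item{ebs}{*Equal or Better Score*: the discordance of S on the
#'     noisy graph is at most that of T (tolerance 1e-9). T is scored
#'     by its edge usage restricted to observed connections.}
#'   \item{eob}{*Equivalent for Observed Bridges*: S uses every
#'     observed bridge and matches T's CN on every interval not owning
#'     an extremity of a dropped bridge.}
#'   \item{cn_score}{length-weighted fraction of intervals with the
#'     correct CN, in `[0, 1]`.}
#' }
#'
#' @param sol a `karyo_solution` from [reconstruct_karyotype()] (or a
#'   pair of bridge graph + `edge_multiplicities`).
#' @param truth a `karyotype_truth` from [simulate_tumor()] over the
#'   same segmentation.
#' @param alpha score weight used for `ebs` (defaults to the solution's
#'   own alpha, else 0.1).
#' @return an `eval_report` list with the five measures plus `score_S`
#'   and `score_T`.
#' @export
evaluate_solution <- function(sol, truth, alpha = NULL) {
  if (is.null(alpha)) alpha <- if (!is.null(sol$alpha)) sol$alpha else 0.1
  evaluate_multiplicities(sol$graph, sol$multiplicities, truth, alpha)
}

#' Individual solution-quality measures
#'
#' Thin accessors over [evaluate_solution()]; see there for the
#' definitions.
#'
#' @inheritParams evaluate_solution
#' @return a logical (or a real in `[0, 1]` for [cn_score()]).
#' @name quality_measures
NULL

#' @rdname quality_measures
#' @export
is_equivalent <- function(sol, truth) evaluate_solution(sol, truth)$correct

#' @rdname quality_measures
#' @export
equal_cn_profile <- function(sol, truth) evaluate_solution(sol, truth)$ecn

#' @rdname quality_measures
#' @export
equal_or_better_score <- function(sol, truth, alpha = NULL)
  evaluate_solution(sol, truth, alpha)$ebs

#' @rdname quality_measures
#' @export
equivalent_observed_bridges <- function(sol, truth)
  evaluate_solution(sol, truth)$eob

#' @rdname quality_measures
#' @export
cn_score <- function(sol, truth) evaluate_solution(sol, truth)$cn_score
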
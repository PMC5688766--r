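# Simulation study drivers: batches of simulate -> add noise ->
# reconstruct -> evaluate, with per-batch success fractions and
# cross-batch summary statistics.

#' Run a simulation scenario
#'
#' Simulates `n_karyotypes` tumors under `params`, adds noise,
#' reconstructs each with the ILP at weight `alpha` (all instances are
#' solved in one batched backend call) and evaluates the five quality
#' measures. Runs are grouped into batches; per-batch mean fractions
#' and cross-batch medians/IQRs are reported, both for the raw
#' per-measure indicators and cumulatively (correct, correct-or-ECN,
#' ...-or-EBS, ...-or-EOB), the latter matching how success categories
#' build on each other from strictest to laxest.
#'
#' @param params a [scenario_params()] (its `seed` field is ignored
#'   here; use the `seed` argument).
#' @param n_karyotypes total number of simulated karyotypes.
#' @param batch_size runs per batch; must divide `n_karyotypes`.
#' @param alpha bridge-term weight for reconstruction and scoring.
#' @param seed integer seed; the full experiment is reproducible from
#'   it.
#' @return a `batch_summary` object: `per_run` (data frame of measures
#'   per run), `per_batch` (fractions per batch), `medians`, `means`,
#'   `iqr`, `sd` (named vectors over
#'   correct/ecn/ebs/eob/correct_cum/ecn_cum/ebs_cum/eob_cum),
#'   `cn_score_mean`, `cn_score_median`, `n_failed`.
#' @export
run_scenario <- function(params = scenario_params(), n_karyotypes = 100L,
                         batch_size = n_karyotypes, alpha = 0.1,
                         seed = 1L) {
  if (n_karyotypes %% batch_size != 0L)
    stop("'n_karyotypes' must be divisible by 'batch_size'")
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_karyotypes)
  params$seed <- NULL
  truths <- vector("list", n_karyotypes)
  graphs <- vector("list", n_karyotypes)
  for (i in seq_len(n_karyotypes)) {
    set.seed(run_seeds[i])
    truths[[i]] <- simulate_tumor(params)
    obs <- add_noise(truths[[i]], params)
    graphs[[i]] <- build_bridge_graph(truths[[i]]$seg, obs)
  }
  built <- lapply(graphs, build_milp, alpha = alpha)
  res <- milp_solve_batch(lapply(built, `[[`, "problem"))
  rows <- vector("list", n_karyotypes)
  n_failed <- 0L
  for (i in seq_len(n_karyotypes)) {
    rep_i <- tryCatch({
      mult <- decode_milp(graphs[[i]], built[[i]], res[[i]])
      evaluate_multiplicities(graphs[[i]], mult, truths[[i]], alpha)
    }, error = function(e) {
      message("run ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rep_i)) {
      n_failed <- n_failed + 1L
      rows[[i]] <- data.frame(run = i, batch = NA_integer_, correct = NA,
                              ecn = NA, ebs = NA, eob = NA,
                              cn_score = NA_real_, score_S = NA_real_,
                              score_T = NA_real_, failed = TRUE)
    } else {
      rows[[i]] <- data.frame(run = i, batch = (i - 1L) %/% batch_size + 1L,
                              correct = rep_i$correct, ecn = rep_i$ecn,
                              ebs = rep_i$ebs, eob = rep_i$eob,
                              cn_score = rep_i$cn_score,
                              score_S = rep_i$score_S,
                              score_T = rep_i$score_T, failed = FALSE)
    }
  }
  per_run <- do.call(rbind, rows)
  ok <- per_run[!per_run$failed, , drop = FALSE]
  ok$correct_cum <- ok$correct
  ok$ecn_cum <- ok$correct | ok$ecn
  ok$ebs_cum <- ok$ecn_cum | ok$ebs
  ok$eob_cum <- ok$ebs_cum | ok$eob
  meas <- c("correct", "ecn", "ebs", "eob",
            "correct_cum", "ecn_cum", "ebs_cum", "eob_cum")
  per_batch <- do.call(rbind, lapply(split(ok, ok$batch), function(b) {
    out <- as.data.frame(lapply(b[meas], mean))
    out$batch <- b$batch[1L]
    out$cn_score_mean <- mean(b$cn_score)
    out
  }))
  rownames(per_batch) <- NULL
  stat <- function(fn) vapply(per_batch[meas], fn, numeric(1L))
  structure(list(
    per_run = per_run, per_batch = per_batch,
    medians = stat(stats::median), means = stat(mean),
    iqr = stat(stats::IQR), sd = stat(stats::sd),
    cn_score_mean = mean(ok$cn_score),
    cn_score_median = stats::median(ok$cn_score),
    n_failed = n_failed, params = params, alpha = alpha, seed = seed
  ), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("Scenario summary over", nrow(x$per_run), "runs (",
      nrow(x$per_batch), "batch(es);", x$n_failed, "failed):\n")
  cat("  cross-batch medians (cumulative): correct=",
      round(100 * x$medians[["correct_cum"]], 1), "% ECN=",
      round(100 * x$medians[["ecn_cum"]], 1), "% EBS=",
      round(100 * x$medians[["ebs_cum"]], 1), "% EOB=",
      round(100 * x$medians[["eob_cum"]], 1), "%\n", sep = "")
  cat("  CN score: mean=", round(x$cn_score_mean, 4),
      " median=", round(x$cn_score_median, 4), "\n", sep = "")
  invisible(x)
}

#' Parameter sweep around a base scenario
#'
#' Alters one parameter over a grid of values, keeping the others at
#' their values in `fixed`, and runs [run_scenario()] for each value.
#'
#' @param param_name one of `"N"`, `"eps"`, `"p"`, `"C"`, `"ploidy"`,
#'   `"normal_fraction"`, `"alpha"`.
#' @param values numeric vector of parameter values.
#' @param fixed the base [scenario_params()].
#' @param n_per_value simulated karyotypes per value.
#' @param alpha reconstruction weight (ignored when sweeping `alpha`).
#' @param seed integer seed; each value gets an independent substream.
#' @return data frame with one row per value: the parameter value, raw
#'   and cumulative success fractions, CN-score mean/median; the full
#'   `batch_summary` objects are attached as attribute `summaries`.
#' @export
sweep_parameter <- function(param_name, values, fixed = scenario_params(),
                            n_per_value = 100L, alpha = 0.1, seed = 1L) {
  fields <- c(N = "N", eps = "eps", p = "p", C = "C", ploidy = "ploidy",
              normal_fraction = "normal_fraction")
  if (!param_name %in% c(names(fields), "alpha"))
    stop("unknown sweep parameter: ", param_name)
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, length(values))
  summaries <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (k in seq_along(values)) {
    pk <- fixed
    ak <- alpha
    if (param_name == "alpha") ak <- values[k]
    else pk[[fields[[param_name]]]] <- values[k]
    pk <- do.call(scenario_params, pk[setdiff(names(pk), "seed")])
    s <- run_scenario(pk, n_karyotypes = n_per_value,
                      batch_size = n_per_value, alpha = ak,
                      seed = sub_seeds[k])
    summaries[[k]] <- s
    rows[[k]] <- data.frame(
      param = param_name, value = values[k],
      correct = s$means[["correct"]], ecn = s$means[["ecn"]],
      ebs = s$means[["ebs"]], eob = s$means[["eob"]],
      correct_cum = s$means[["correct_cum"]], ecn_cum = s$means[["ecn_cum"]],
      ebs_cum = s$means[["ebs_cum"]], eob_cum = s$means[["eob_cum"]],
      cn_score_mean = s$cn_score_mean, cn_score_median = s$cn_score_median,
      n_failed = s$n_failed
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "summaries") <- summaries
  out
}
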
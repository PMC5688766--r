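# ILP formulation of the karyotype reconstruction problem.
#
# For every connection e there are two integer variables x_fwd, x_rev
# (one for fold-back self-loops) counting traversals per direction;
# f(e) = x_fwd + x_rev. At every non-telomeric vertex v the alternation
# of interval and non-interval edges imposes two balance equalities:
#   sum of interval-edge traversals leaving v  = sum of reference/bridge
#     traversals entering v, and
#   sum of interval-edge traversals entering v = sum of reference/bridge
#     traversals leaving v.
# A fold-back bridge at v counts once on each equality: one traversal
# pairs one incoming with one outgoing interval visit.
#
# The objective is the discordance score
#   d_G = sum_{e in E_I} (l_e / L) |f(e) - w(e)|
#       + alpha * sum_{e in E_V} (w(e) / mu) (1 - min(1, f(e))),
# linearized with a slack t_e >= |f(e) - w(e)| per interval connection
# and a binary y_e <= f(e) per bridge connection.

# directed edge incidence tables for a graph's connections
directed_edges <- function(g) {
  conns <- g$connections
  loop <- connection_is_loop(conns)
  fwd <- data.frame(conn = conns$id, dir = "fwd", from = conns$u,
                    to = conns$v, type = conns$type,
                    stringsAsFactors = FALSE)
  rev <- data.frame(conn = conns$id[!loop], dir = "rev",
                    from = conns$v[!loop], to = conns$u[!loop],
                    type = conns$type[!loop], stringsAsFactors = FALSE)
  rbind(fwd, rev)
}

# Build the MILP for a bridge graph. Returns the problem plus the
# variable layout needed to decode a solution.
build_milp <- function(g, alpha, time_limit = NULL) {
  conns <- g$connections
  n_conn <- nrow(conns)
  loop <- connection_is_loop(conns)
  is_int <- conns$type == "interval"
  is_br <- conns$type == "bridge"

  # variable layout: x_fwd per connection, x_rev for non-loops, then
  # interval slacks t, then bridge binaries y
  x_fwd <- seq_len(n_conn)
  x_rev <- rep(NA_integer_, n_conn)
  x_rev[!loop] <- n_conn + seq_len(sum(!loop))
  nx <- n_conn + sum(!loop)
  t_var <- rep(NA_integer_, n_conn)
  t_var[is_int] <- nx + seq_len(sum(is_int))
  y_var <- rep(NA_integer_, n_conn)
  y_var[is_br] <- nx + sum(is_int) + seq_len(sum(is_br))
  n_vars <- nx + sum(is_int) + sum(is_br)

  # bound on traversal counts: generous enough to never cut the optimum
  # at realistic noise levels, finite for the solver
  ub_x <- ceiling(max(c(conns$weight[is_int], 0))) + sum(is_br) + 2

  cvec <- numeric(n_vars)
  cvec[t_var[is_int]] <- conns$length[is_int] / g$seg$L
  mu <- g$mu
  if (any(is_br) && mu > 0)
    cvec[y_var[is_br]] <- -alpha * conns$weight[is_br] / mu
  const <- if (any(is_br) && mu > 0) alpha * sum(conns$weight[is_br]) / mu else 0

  lb <- numeric(n_vars)
  ub <- rep(MILP_BIG, n_vars)
  ub[seq_len(nx)] <- ub_x
  ub[y_var[is_br]] <- 1
  integrality <- integer(n_vars)
  integrality[seq_len(nx)] <- 1L
  integrality[y_var[is_br]] <- 1L

  ai <- integer(); aj <- integer(); ax <- numeric()
  rlb <- numeric(); rub <- numeric()
  nr <- 0L
  add_row <- function(j, x, lo, hi) {
    nr <<- nr + 1L
    ai <<- c(ai, rep(nr, length(j))); aj <<- c(aj, j); ax <<- c(ax, x)
    rlb <<- c(rlb, lo); rub <<- c(rub, hi)
  }

  # balance equalities at non-telomeric vertices
  de <- directed_edges(g)
  de$var <- ifelse(de$dir == "fwd", x_fwd[de$conn], x_rev[de$conn])
  non_tel <- setdiff(seq_len(g$n_vertices), g$telomeres)
  verts <- unique(c(conns$u, conns$v))
  for (v in intersect(non_tel, verts)) {
    iv_out <- de$var[de$type == "interval" & de$from == v]
    iv_in <- de$var[de$type == "interval" & de$to == v]
    ni_out <- de$var[de$type != "interval" & de$from == v]
    ni_in <- de$var[de$type != "interval" & de$to == v]
    # a self-loop's single edge appears with from == to == v; it must
    # count once per equality, which the two rows below already do
    # (fwd-only edges appear once in each of ni_out and ni_in)
    add_row(c(iv_out, ni_in), c(rep(1, length(iv_out)), rep(-1, length(ni_in))),
            0, 0)
    add_row(c(iv_in, ni_out), c(rep(1, length(iv_in)), rep(-1, length(ni_out))),
            0, 0)
  }

  # |f - w| slack rows for interval connections
  for (i in which(is_int)) {
    xs <- c(x_fwd[i], x_rev[i]); xs <- xs[!is.na(xs)]
    add_row(c(xs, t_var[i]), c(rep(1, length(xs)), -1), -MILP_BIG,
            conns$weight[i])
    add_row(c(xs, t_var[i]), c(rep(1, length(xs)), 1), conns$weight[i],
            MILP_BIG)
  }

  # y_e <= f(e) for bridge connections
  for (i in which(is_br)) {
    xs <- c(x_fwd[i], x_rev[i]); xs <- xs[!is.na(xs)]
    add_row(c(y_var[i], xs), c(1, rep(-1, length(xs))), -MILP_BIG, 0)
  }

  list(problem = milp_problem(cvec, lb, ub, integrality, ai, aj, ax,
                              rlb, rub, nr, time_limit),
       layout = list(x_fwd = x_fwd, x_rev = x_rev, t_var = t_var,
                     y_var = y_var, constant = const))
}

decode_milp <- function(g, built, res) {
  if (!isTRUE(res$success))
    stop("MIP solver did not reach a proven optimum: ", res$message)
  x <- unlist(res$x)
  lay <- built$layout
  x_fwd <- as.integer(round(x[lay$x_fwd]))
  x_rev <- ifelse(is.na(lay$x_rev), 0L, as.integer(round(x[lay$x_rev])))
  f <- x_fwd + x_rev
  structure(list(x_fwd = x_fwd, x_rev = x_rev, f = f,
                 objective = res$objective + lay$constant),
            class = "edge_multiplicities")
}

#' Discordance score of an edge-multiplicity assignment
#'
#' Computes
#' \deqn{d_G = \sum_{e \in E_I} \frac{l_e}{L} |f(e) - w(e)| +
#'   \alpha \sum_{e \in E_V} \frac{w(e)}{\mu} (1 - \min(1, f(e)))}
#' the length-weighted absolute copy-number deviation plus the
#' support-weighted penalty for unused bridges. If the graph has no
#' bridges (or zero total support) the second term is 0.
#'
#' @param g a [build_bridge_graph()] result.
#' @param f nonnegative integer traversal counts, one per connection of
#'   `g` (in `g$connections` order); or an `edge_multiplicities` object.
#' @param alpha relative weight of the bridge term.
#' @return the score, a nonnegative real.
#' @export
discordance_score <- function(g, f, alpha) {
  if (inherits(f, "edge_multiplicities")) f <- f$f
  conns <- g$connections
  if (length(f) != nrow(conns))
    stop("'f' must assign a traversal count to every connection")
  if (any(f < 0)) stop("traversal counts must be nonnegative")
  is_int <- conns$type == "interval"
  is_br <- conns$type == "bridge"
  score <- sum(conns$length[is_int] / g$seg$L *
                 abs(f[is_int] - conns$weight[is_int]))
  if (any(is_br) && g$mu > 0)
    score <- score + alpha * sum(conns$weight[is_br] / g$mu *
                                   (1 - pmin(1, f[is_br])))
  score
}

#' Solve the reconstruction ILP on one or more bridge graphs
#'
#' Finds nonnegative integer traversal counts per directed edge
#' minimizing the discordance score subject to the valid-path balance
#' constraints (telomeric vertices unconstrained), to proven optimality
#' (zero MIP gap). `solve_graphs()` solves a list of graphs in one
#' backend call; `formulate_and_solve()` is the single-graph wrapper.
#'
#' @param graphs list of [build_bridge_graph()] objects.
#' @param g one bridge graph.
#' @param alpha bridge-term weight (0.1 for the simulation studies, 0.5
#'   recommended for real tumor data).
#' @param time_limit optional per-problem solver time limit in seconds.
#' @return an `edge_multiplicities` object (or a list of them): integer
#'   vectors `x_fwd`, `x_rev`, their per-connection sum `f`, and the
#'   optimal `objective` (the discordance score).
#' @export
solve_graphs <- function(graphs, alpha = 0.1, time_limit = NULL) {
  built <- lapply(graphs, build_milp, alpha = alpha, time_limit = time_limit)
  res <- milp_solve_batch(lapply(built, `[[`, "problem"))
  mapply(decode_milp, graphs, built, res, SIMPLIFY = FALSE)
}

#' @rdname solve_graphs
#' @export
formulate_and_solve <- function(g, alpha = 0.1, time_limit = NULL) {
  solve_graphs(list(g), alpha, time_limit)[[1L]]
}

#' @export
print.edge_multiplicities <- function(x, ...) {
  cat("Edge multiplicities over", length(x$f), "connections; objective",
      format(x$objective), "\n")
  invisible(x)
}

# verify the balance constraints for an f assignment (used in tests and
# as a post-solve assertion)
check_flow_balance <- function(g, mult) {
  de <- directed_edges(g)
  x <- ifelse(de$dir == "fwd", mult$x_fwd[de$conn], mult$x_rev[de$conn])
  non_tel <- setdiff(seq_len(g$n_vertices), g$telomeres)
  for (v in non_tel) {
    iv_out <- sum(x[de$type == "interval" & de$from == v])
    iv_in <- sum(x[de$type == "interval" & de$to == v])
    ni_out <- sum(x[de$type != "interval" & de$from == v])
    ni_in <- sum(x[de$type != "interval" & de$to == v])
    if (iv_out != ni_in || iv_in != ni_out) return(FALSE)
  }
  TRUE
}

#' Traversal counts induced by a known karyotype
#'
#' Threads a karyotype through a bridge graph and counts how often each
#' connection is traversed (per direction). Adjacencies of the
#' karyotype that use a bridge absent from the graph (for example a
#' bridge dropped from the observed data) are skipped; the result is
#' then the truth's edge usage restricted to observed connections,
#' which is how the true karyotype is scored on a noisy graph even when
#' it is not a feasible path system there.
#'
#' @param g a [build_bridge_graph()] result.
#' @param k a [karyotype()] over the graph's segmentation.
#' @return an `edge_multiplicities` object (objective `NA`).
#' @export
karyotype_multiplicities <- function(g, k) {
  conns <- g$connections
  n <- nrow(conns)
  x_fwd <- integer(n); x_rev <- integer(n)
  # directed (from, to) -> connection lookups, kept separate for
  # interval and non-interval connections: a bridge may share its
  # unordered vertex pair with an interval edge
  key <- function(a, b) paste(a, b, sep = ">")
  int_env <- new.env(parent = emptyenv())
  non_env <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    env <- if (conns$type[i] == "interval") int_env else non_env
    assign(key(conns$u[i], conns$v[i]), c(i, 1L), envir = env)
    if (conns$u[i] != conns$v[i] &&
        !exists(key(conns$v[i], conns$u[i]), envir = env))
      assign(key(conns$v[i], conns$u[i]), c(i, 2L), envir = env)
  }
  bump <- function(a, b, env) {
    k2 <- key(a, b)
    if (exists(k2, envir = env)) {
      hit <- get(k2, envir = env)
      if (hit[2L] == 1L) x_fwd[hit[1L]] <<- x_fwd[hit[1L]] + 1L
      else x_rev[hit[1L]] <<- x_rev[hit[1L]] + 1L
      TRUE
    } else FALSE
  }
  for (ch in unclass(k)) {
    for (j in seq_along(ch)) {
      s <- ch[j]
      bump(ext_entry(s), ext_exit(s), int_env)  # interval edge
      if (j < length(ch)) bump(ext_exit(s), ext_entry(ch[j + 1L]), non_env)
    }
  }
  structure(list(x_fwd = x_fwd, x_rev = x_rev, f = x_fwd + x_rev,
                 objective = NA_real_),
            class = "edge_multiplicities")
}
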
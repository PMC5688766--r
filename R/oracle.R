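#' Brute-force optimum of the reconstruction problem on a small graph
#'
#' Enumerates every integer assignment of the directed traversal
#' variables in `[0, bound]`, filters by the balance constraints and
#' minimizes the discordance score evaluated directly (with the true
#' `min(1, f)` bridge term, independent of the MIP linearization).
#' Intended as an independent oracle for graphs with few connections;
#' the search space grows as `(bound + 1)^(2 * connections)`.
#'
#' @param g a [build_bridge_graph()] result.
#' @param alpha bridge-term weight.
#' @param bound upper bound on each directed traversal count.
#' @return list with `objective` (optimal score), `f` (per-connection
#'   totals of one optimum) and `n_feasible` (number of assignments
#'   satisfying the constraints).
#' @export
brute_force_solve <- function(g, alpha = 0.1, bound = 3L) {
  conns <- g$connections
  n_conn <- nrow(conns)
  if (n_conn > 8L)
    stop("brute force is limited to graphs with at most 8 connections")
  loop <- connection_is_loop(conns)
  var1 <- seq_len(n_conn)
  var2 <- rep(NA_integer_, n_conn)
  var2[!loop] <- n_conn + seq_len(sum(!loop))
  n_vars <- n_conn + sum(!loop)

  de <- directed_edges(g)
  de$var <- ifelse(de$dir == "fwd", var1[de$conn], var2[de$conn])
  non_tel <- setdiff(seq_len(g$n_vertices), g$telomeres)
  row_var <- list(); row_coef <- list()
  for (v in intersect(non_tel, unique(c(conns$u, conns$v)))) {
    iv_out <- de$var[de$type == "interval" & de$from == v]
    iv_in <- de$var[de$type == "interval" & de$to == v]
    ni_out <- de$var[de$type != "interval" & de$from == v]
    ni_in <- de$var[de$type != "interval" & de$to == v]
    row_var <- c(row_var, list(c(iv_out, ni_in)), list(c(iv_in, ni_out)))
    row_coef <- c(row_coef,
                  list(c(rep(1, length(iv_out)), rep(-1, length(ni_in)))),
                  list(c(rep(1, length(iv_in)), rep(-1, length(ni_out)))))
  }
  type_code <- match(conns$type, c("interval", "reference", "bridge")) - 1L
  res <- .brute_force_cpp(
    n_vars, as.integer(bound),
    lapply(row_var, function(v) as.integer(v - 1L)),
    row_coef,
    as.integer(ifelse(is.na(var1), -1L, var1 - 1L)),
    as.integer(ifelse(is.na(var2), -1L, var2 - 1L)),
    type_code,
    ifelse(is.na(conns$weight), 0, conns$weight),
    ifelse(is.na(conns$length), 0, conns$length / g$seg$L),
    alpha, g$mu
  )
  x <- res$x
  f <- x[var1] + ifelse(is.na(var2), 0L, x[ifelse(is.na(var2), 1L, var2)])
  list(objective = res$objective, f = as.integer(f),
       n_feasible = res$n_feasible)
}
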
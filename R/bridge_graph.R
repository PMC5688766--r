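# The bridge graph: a directed weighted graph over interval extremities.
# Every undirected "connection" (interval, reference or bridge) is
# realized as a pair of antiparallel directed edges; fold-back bridges
# degenerate to a single self-loop edge.

#' Build the bridge graph for an observed data set
#'
#' Vertices are the interval extremities of the segmentation. For each
#' interval there is one *interval connection* (tail to head) weighted
#' by the observed copy number; consecutive intervals of a reference
#' chromosome are joined by unweighted *reference connections* (head of
#' `i` to tail of `i+1`); every observed bridge becomes a *bridge
#' connection* weighted by its support. Each connection stands for a
#' pair of antiparallel directed edges. The telomere set `S` holds the
#' outermost extremities of every reference chromosome; valid paths
#' start and end only there.
#'
#' @param seg a [reference_segmentation()].
#' @param obs an [observed_data()] over `seg`.
#' @return an object of class `bridge_graph` with components
#'   `connections` (data frame: `id`, `type` in
#'   interval/reference/bridge, `u`, `v` extremity ids, `weight`,
#'   `length`), `telomeres`, `mu` (total bridge support), `n_vertices`
#'   and `seg`.
#' @examples
#' seg <- reference_segmentation(list(chr1 = c(1, 1, 1, 1)))
#' obs <- observed_data(seg, c(2, 1, 1, 2),
#'                      bridge_set(c(ext_head(1), ext_head(4), ext_tail(3),
#'                                   ext_head(2)),
#'                                 c(ext_tail(4), ext_head(4), ext_tail(2),
#'                                   ext_head(1)),
#'                                 support = c(5, 3, 4, 2)))
#' g <- build_bridge_graph(seg, obs)
#' table(g$connections$type)
#' @export
build_bridge_graph <- function(seg, obs) {
  n <- n_intervals(seg)
  if (length(obs$cn) != n)
    stop("observed CN profile does not cover the segmentation")
  iv <- seg$intervals
  conn_i <- data.frame(type = "interval", u = ext_tail(iv$id),
                       v = ext_head(iv$id), weight = obs$cn,
                       length = iv$length, stringsAsFactors = FALSE)
  pre <- which(iv$index[-1L] > 1L)  # rows i where i+1 continues the chromosome
  conn_r <- data.frame(type = rep("reference", length(pre)),
                       u = ext_head(iv$id[pre]),
                       v = ext_tail(iv$id[pre] + 1L),
                       weight = rep(NA_real_, length(pre)),
                       length = rep(NA_real_, length(pre)),
                       stringsAsFactors = FALSE)
  b <- obs$bridges
  if (nrow(b) && any(is_reference_adjacency(b$e1, b$e2, seg)))
    stop("bridge coincides with a reference adjacency")
  conn_b <- data.frame(type = rep("bridge", nrow(b)), u = b$e1, v = b$e2,
                       weight = b$support, length = rep(NA_real_, nrow(b)),
                       stringsAsFactors = FALSE)
  conns <- rbind(conn_i, conn_r, conn_b)
  conns$id <- seq_len(nrow(conns))
  conns <- conns[, c("id", "type", "u", "v", "weight", "length")]
  structure(list(
    connections = conns,
    telomeres = seg$telomeres,
    mu = obs$mu,
    n_vertices = 2L * n,
    seg = seg
  ), class = "bridge_graph")
}

#' @export
print.bridge_graph <- function(x, ...) {
  tb <- table(x$connections$type)
  cat("Bridge graph: ", x$n_vertices, " vertices; ",
      paste(names(tb), tb, sep = "=", collapse = ", "),
      "; |S|=", length(x$telomeres), "\n", sep = "")
  invisible(x)
}

#' Split a bridge graph into connected components
#'
#' Components are maximal sets of connections linked through shared
#' vertices (antiparallel edge pairs collapse to their undirected
#' connection). Because reference connections chain all intervals of a
#' chromosome, every component contains whole reference chromosomes and
#' can be analyzed independently.
#'
#' @param g a [build_bridge_graph()] result.
#' @return a list of `bridge_graph` objects. Each keeps the global
#'   vertex/connection numbering of `g` plus a `component_of` attribute
#'   on `g`'s vertices is not retained; the subgraphs carry their own
#'   `connections`, `telomeres` and per-component `mu` equal to the full
#'   graph's `mu` (the discordance normalization is global).
#' @export
graph_components <- function(g) {
  ig <- igraph::graph_from_edgelist(
    as.matrix(g$connections[, c("u", "v")]), directed = FALSE)
  if (igraph::vcount(ig) < g$n_vertices)
    ig <- igraph::add_vertices(ig, g$n_vertices - igraph::vcount(ig))
  memb <- igraph::components(ig)$membership
  comp_of_conn <- memb[g$connections$u]
  lapply(sort(unique(comp_of_conn)), function(cc) {
    sub <- g
    sub$connections <- g$connections[comp_of_conn == cc, , drop = FALSE]
    verts <- unique(c(sub$connections$u, sub$connections$v))
    sub$telomeres <- intersect(g$telomeres, verts)
    sub
  })
}

# per-vertex incidence of directed edges, used by the ILP and the
# decomposer; for each connection, the forward edge runs u -> v and the
# reverse edge v -> u; a self-loop has a single edge counted once as
# outgoing and once as incoming at its vertex.
connection_is_loop <- function(conns) conns$u == conns$v
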
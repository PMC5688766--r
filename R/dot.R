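# Graphviz DOT export. Interval, reference and bridge connections are
# drawn as black solid, dotted and red arcs respectively; bridge labels
# carry the observed support, and a solution overlay annotates every
# connection with its traversal count (unused bridges turn dashed
# grey).

#' Render a bridge graph (optionally with a solution) as DOT
#'
#' @param g a [build_bridge_graph()] result.
#' @param sol optional `karyo_solution` over `g`; when given, every
#'   connection is annotated with its traversal count `f` and bridges
#'   with `f = 0` are drawn dashed grey.
#' @return character vector of DOT lines (one element per line).
#' @examples
#' seg <- reference_segmentation(list(chr1 = c(1, 1, 1)))
#' obs <- observed_data(seg, c(2, 1, 2),
#'                      bridge_set(ext_head(1), ext_tail(3), support = 5))
#' cat(to_dot(build_bridge_graph(seg, obs)), sep = "\n")
#' @export
to_dot <- function(g, sol = NULL) {
  conns <- g$connections
  f <- if (!is.null(sol)) sol$multiplicities$f else NULL
  lines <- c("graph bridge_graph {",
             "  rankdir=LR;",
             "  node [shape=circle, fontsize=10];")
  iv <- g$seg$intervals
  # align interval extremities along each chromosome
  for (ch in unique(iv$chrom)) {
    ids <- iv$id[iv$chrom == ch]
    verts <- as.vector(rbind(ext_tail(ids), ext_head(ids)))
    lines <- c(lines, paste0("  { rank=same; ",
                             paste0("\"", ext_label(verts), "\"",
                                    collapse = "; "), " }"))
  }
  for (i in seq_len(nrow(conns))) {
    u <- ext_label(conns$u[i]); v <- ext_label(conns$v[i])
    attrs <- switch(conns$type[i],
      interval = sprintf("color=black, penwidth=2, label=\"%s\"",
                         format_num(round(conns$weight[i], 3))),
      reference = "style=dotted, color=black",
      bridge = sprintf("color=red, fontcolor=red, label=\"%s\"",
                       format_num(round(conns$weight[i], 3))))
    if (!is.null(f)) {
      if (conns$type[i] == "bridge" && f[i] == 0L)
        attrs <- "style=dashed, color=grey, fontcolor=grey, label=\"unused\""
      else
        attrs <- paste0(attrs, sprintf(", xlabel=\"f=%d\"", f[i]))
    }
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [%s];", u, v, attrs))
  }
  c(lines, "}")
}
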
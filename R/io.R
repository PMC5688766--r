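# Plain-text interchange formats.
#
# CN profile: BED-like TSV  chrom  start  end  interval_id  cn
#   (0-based half-open; cn real-valued; no header).
# Bridges: BEDPE-like TSV  chrom1 pos1 side1 chrom2 pos2 side2 support
#   where pos is the interval-boundary coordinate of the extremity and
#   side is H (head) or T (tail). Standard BEDPE has no extremity-side
#   semantics; the side columns are the minimal extension needed here.
# Karyotypes: one line per chromosome, comma-separated signed interval
#   ids ('#' lines are comments).

#' Write / read an observed data set
#'
#' @param seg a [reference_segmentation()].
#' @param obs an [observed_data()] over `seg`.
#' @param cn_path path of the BED-like CN profile.
#' @param bridges_path path of the BEDPE-like bridge table.
#' @return `read_observed()` returns `list(seg, obs)`;
#'   `write_observed()` returns the paths, invisibly.
#' @export
write_observed <- function(seg, obs, cn_path, bridges_path) {
  iv <- seg$intervals
  cn_df <- data.frame(chrom = iv$chrom, start = format_num(iv$start),
                      end = format_num(iv$end), interval_id = iv$id,
                      cn = format_num(obs$cn))
  utils::write.table(cn_df, cn_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  b <- obs$bridges
  coord <- function(e) {
    i <- ext_interval(e)
    ifelse(ext_side(e) == "tail", iv$start[i], iv$end[i])
  }
  b_df <- data.frame(
    chrom1 = iv$chrom[ext_interval(b$e1)], pos1 = format_num(coord(b$e1)),
    side1 = toupper(substr(ext_side(b$e1), 1L, 1L)),
    chrom2 = iv$chrom[ext_interval(b$e2)], pos2 = format_num(coord(b$e2)),
    side2 = toupper(substr(ext_side(b$e2), 1L, 1L)),
    support = format_num(b$support)
  )
  utils::write.table(b_df, bridges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(cn_path, bridges_path))
}

format_num <- function(x) {
  ifelse(x == round(x), format(round(x), scientific = FALSE, trim = TRUE),
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}

#' @rdname write_observed
#' @export
read_observed <- function(cn_path, bridges_path) {
  cn_raw <- utils::read.table(cn_path, sep = "\t", header = FALSE,
                              col.names = c("chrom", "start", "end",
                                            "interval_id", "cn"),
                              colClasses = c("character", "numeric",
                                             "numeric", "integer", "numeric"))
  if (!nrow(cn_raw)) stop("empty CN profile: ", cn_path)
  # contiguity per chromosome, in file order
  lengths <- list()
  for (ch in unique(cn_raw$chrom)) {
    rows <- cn_raw[cn_raw$chrom == ch, , drop = FALSE]
    bad <- which(rows$end <= rows$start)
    if (length(bad))
      stop(cn_path, ": non-positive interval on line ",
           which(cn_raw$chrom == ch)[bad[1L]])
    gap <- which(rows$start[-1L] != rows$end[-nrow(rows)])
    if (length(gap))
      stop(cn_path, ": intervals of ", ch,
           " are not contiguous at line ",
           which(cn_raw$chrom == ch)[gap[1L] + 1L])
    if (rows$start[1L] != 0)
      stop(cn_path, ": ", ch, " does not start at coordinate 0")
    lengths[[ch]] <- rows$end - rows$start
  }
  seg <- reference_segmentation(lengths)
  iv <- seg$intervals
  br_raw <- tryCatch(
    utils::read.table(bridges_path, sep = "\t", header = FALSE,
                      col.names = c("chrom1", "pos1", "side1", "chrom2",
                                    "pos2", "side2", "support"),
                      colClasses = c("character", "numeric", "character",
                                     "character", "numeric", "character",
                                     "numeric")),
    error = function(e) NULL)  # empty file -> zero bridges
  to_ext <- function(chrom, pos, side, line) {
    if (!side %in% c("H", "T"))
      stop(bridges_path, " line ", line, ": side must be H or T, got '",
           side, "'")
    rows <- which(iv$chrom == chrom &
                    (if (side == "T") iv$start == pos else iv$end == pos))
    if (length(rows) != 1L)
      stop(bridges_path, " line ", line,
           ": no interval boundary at ", chrom, ":", pos, " (side ", side,
           ")")
    if (side == "T") ext_tail(iv$id[rows]) else ext_head(iv$id[rows])
  }
  if (is.null(br_raw) || !nrow(br_raw)) {
    obs <- observed_data(seg, cn_raw$cn, bridge_set())
  } else {
    e1 <- mapply(to_ext, br_raw$chrom1, br_raw$pos1, br_raw$side1,
                 seq_len(nrow(br_raw)))
    e2 <- mapply(to_ext, br_raw$chrom2, br_raw$pos2, br_raw$side2,
                 seq_len(nrow(br_raw)))
    obs <- observed_data(seg, cn_raw$cn, bridge_set(e1, e2, br_raw$support))
  }
  list(seg = seg, obs = obs)
}

#' Write / read karyotypes as signed-interval lines
#'
#' One line per chromosome: comma-separated signed interval ids, e.g.
#' `1,4,-4,-3,2,-1`. Lines starting with `#` are comments.
#'
#' @param k a [karyotype()].
#' @param path file path.
#' @param header optional comment line(s) written before the data.
#' @return `read_karyotype()` returns a [karyotype()].
#' @export
write_karyotype <- function(k, path, header = NULL) {
  lines <- format(k)
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_karyotype
#' @export
read_karyotype <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  karyotype(lapply(strsplit(lines, ","), as.integer))
}

#' Write a reconstruction to a directory
#'
#' Writes `karyotype.txt` (paths), `cycles.txt` (if any),
#' `multiplicities.tsv`, `score.json` (score to full precision, alpha,
#' run metadata) and `graph.dot`.
#'
#' @param sol a `karyo_solution`.
#' @param out_dir output directory (created if missing).
#' @param meta optional named list merged into `score.json`.
#' @return `read_solution()` returns a list with `paths`, `cycles`,
#'   `multiplicities` (data frame), `score`, `alpha`, `meta`.
#' @export
write_solution <- function(sol, out_dir, meta = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_karyotype(sol$paths, file.path(out_dir, "karyotype.txt"))
  if (length(sol$cycles))
    write_karyotype(karyotype(sol$cycles), file.path(out_dir, "cycles.txt"))
  conns <- sol$graph$connections
  mult_df <- data.frame(conns[, c("id", "type", "u", "v")],
                        weight = conns$weight,
                        x_fwd = sol$multiplicities$x_fwd,
                        x_rev = sol$multiplicities$x_rev,
                        f = sol$multiplicities$f)
  utils::write.table(mult_df, file.path(out_dir, "multiplicities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  info <- c(list(score = sol$score, alpha = sol$alpha,
                 objective = sol$multiplicities$objective,
                 n_paths = length(sol$paths), n_cycles = length(sol$cycles),
                 solver = "scipy-highs",
                 package_version = as.character(utils::packageVersion("karyograph"))),
            meta)
  jsonlite::write_json(info, file.path(out_dir, "score.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(to_dot(sol$graph, sol), file.path(out_dir, "graph.dot"))
  invisible(out_dir)
}

#' @rdname write_solution
#' @export
read_solution <- function(out_dir) {
  paths <- read_karyotype(file.path(out_dir, "karyotype.txt"))
  cyc_path <- file.path(out_dir, "cycles.txt")
  cycles <- if (file.exists(cyc_path)) unclass(read_karyotype(cyc_path))
            else list()
  mult <- utils::read.table(file.path(out_dir, "multiplicities.tsv"),
                            sep = "\t", header = TRUE)
  info <- jsonlite::read_json(file.path(out_dir, "score.json"),
                              simplifyVector = TRUE)
  list(paths = paths, cycles = cycles, multiplicities = mult,
       score = info$score, alpha = info$alpha, meta = info)
}

#' Serialize a bridge graph as JSON (debugging aid)
#'
#' @param g a [build_bridge_graph()] result.
#' @return a JSON string.
#' @export
graph_json <- function(g) {
  jsonlite::toJSON(list(n_vertices = g$n_vertices,
                        telomeres = g$telomeres, mu = g$mu,
                        connections = g$connections),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA)
}
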
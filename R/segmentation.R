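#' Reference segmentation of a genome into intervals
#'
#' A reference segmentation partitions each reference chromosome into
#' consecutively indexed intervals. Intervals are the atomic units over
#' which copy numbers are measured and over which rearranged karyotypes
#' are expressed. Every interval has two *extremities*: its `tail`
#' (start) and `head` (end). Extremities are encoded internally as
#' integers: interval `i` has tail `2i - 1` and head `2i`, with `i` a
#' global interval id running over all chromosomes.
#'
#' @param lengths a named list; one numeric vector of strictly positive
#'   interval lengths per chromosome, in chromosome order.
#' @return an object of class `ref_segmentation` with components:
#'   \describe{
#'     \item{intervals}{data frame with one row per interval: `id`
#'       (global), `chrom`, `index` (1-based within chromosome),
#'       `length`, `start`, `end` (cumulative, 0-based half-open).}
#'     \item{chroms}{character vector of chromosome names.}
#'     \item{L}{total length of all intervals.}
#'     \item{telomeres}{integer extremity ids of the outermost
#'       extremities of each chromosome (tail of the first interval and
#'       head of the last; two per chromosome).}
#'   }
#' @examples
#' seg <- reference_segmentation(list(chr1 = c(9, 10, 281)))
#' seg$L
#' @export
reference_segmentation <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("'lengths' must be a named list with unique chromosome names")
  chroms <- names(lengths)
  n_per <- vapply(lengths, length, integer(1L))
  if (any(n_per == 0L)) stop("every chromosome needs at least one interval")
  len <- unlist(lengths, use.names = FALSE)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("interval lengths must be strictly positive")
  n <- length(len)
  chrom <- rep(chroms, n_per)
  index <- unlist(lapply(n_per, seq_len), use.names = FALSE)
  start <- unlist(lapply(lengths, function(l) cumsum(c(0, l[-length(l)]))),
                  use.names = FALSE)
  intervals <- data.frame(
    id = seq_len(n), chrom = chrom, index = index,
    length = as.numeric(len), start = start, end = start + len,
    stringsAsFactors = FALSE
  )
  first <- intervals$id[intervals$index == 1L]
  last <- intervals$id[c(which(intervals$index == 1L)[-1] - 1L, n)]
  seg <- list(
    intervals = intervals,
    chroms = chroms,
    L = sum(len),
    telomeres = sort(c(ext_tail(first), ext_head(last)))
  )
  class(seg) <- "ref_segmentation"
  seg
}

#' @export
print.ref_segmentation <- function(x, ...) {
  cat("Reference segmentation: ", length(x$chroms), " chromosome(s), ",
      nrow(x$intervals), " interval(s), total length ", x$L, "\n", sep = "")
  invisible(x)
}

n_intervals <- function(seg) nrow(seg$intervals)

# ---- extremity encoding -----------------------------------------------------

#' Extremity encoding helpers
#'
#' Extremities (interval tails and heads) are encoded as integers:
#' interval `i` owns tail `2i - 1` and head `2i`.
#'
#' @param i interval id(s).
#' @param e extremity id(s).
#' @name extremities
#' @export
ext_tail <- function(i) 2L * as.integer(i) - 1L

#' @rdname extremities
#' @export
ext_head <- function(i) 2L * as.integer(i)

#' @rdname extremities
#' @export
ext_interval <- function(e) (as.integer(e) + 1L) %/% 2L

#' @rdname extremities
#' @export
ext_side <- function(e) ifelse(as.integer(e) %% 2L == 1L, "tail", "head")

# the extremity at which a signed interval traversal begins / ends
ext_entry <- function(s) ifelse(s > 0, ext_tail(abs(s)), ext_head(abs(s)))
ext_exit  <- function(s) ifelse(s > 0, ext_head(abs(s)), ext_tail(abs(s)))

ext_label <- function(e) {
  paste0(ifelse(ext_side(e) == "tail", "t", "h"), ext_interval(e))
}

# ---- karyotype --------------------------------------------------------------

#' Construct a karyotype
#'
#' A karyotype is a multiset of chromosomes, each an ordered sequence of
#' signed interval ids. A negative id means the interval is traversed
#' reversed (head to tail). Empty chromosomes are dropped.
#'
#' @param chromosomes list of integer vectors of signed interval ids.
#' @return an object of class `karyotype` (a list of integer vectors).
#' @examples
#' karyotype(list(c(1, 4, -4, -3, 2, -1)))
#' @export
karyotype <- function(chromosomes) {
  chromosomes <- lapply(chromosomes, function(ch) {
    ch <- as.integer(ch)
    if (any(ch == 0L)) stop("interval ids are signed and non-zero")
    ch
  })
  chromosomes <- chromosomes[lengths(chromosomes) > 0L]
  structure(chromosomes, class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype with", length(x), "chromosome(s):\n")
  for (ch in x) cat(" ", paste(ch, collapse = ","), "\n")
  invisible(x)
}

#' @export
format.karyotype <- function(x, ...) {
  vapply(unclass(x), function(ch) paste(ch, collapse = ","), character(1L))
}

# validate that a karyotype only references intervals of a segmentation
validate_karyotype <- function(k, seg) {
  ids <- abs(unlist(unclass(k), use.names = FALSE))
  if (length(ids) && (max(ids) > n_intervals(seg) || min(ids) < 1L))
    stop("karyotype references intervals absent from the segmentation")
  invisible(TRUE)
}

# canonical form for equivalence up to chromosome order and orientation
canonical_karyotype <- function(k) {
  norm <- lapply(unclass(k), function(ch) {
    rev_ch <- -rev(ch)
    a <- paste(ch, collapse = ","); b <- paste(rev_ch, collapse = ",")
    if (b < a) rev_ch else ch
  })
  norm[order(vapply(norm, paste, character(1L), collapse = ","))]
}

# ---- bridges ----------------------------------------------------------------

#' Construct a set of bridges
#'
#' A bridge is an unordered pair of interval extremities that are
#' adjacent in the tumor genome but not adjacent on the reference.
#' Fold-back bridges (an extremity paired with itself) are allowed.
#' Pairs are stored canonically with `e1 <= e2` so duplicates collapse.
#'
#' @param e1,e2 integer extremity ids (recycled to common length).
#' @param support numeric support values (default 0).
#' @return data frame of class `bridge_set` with columns `e1`, `e2`,
#'   `support`.
#' @export
bridge_set <- function(e1 = integer(), e2 = integer(),
                       support = numeric(length(e1))) {
  e1 <- as.integer(e1); e2 <- as.integer(e2)
  swap <- e1 > e2
  tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  b <- data.frame(e1 = e1, e2 = e2, support = as.numeric(support))
  o <- order(b$e1, b$e2)
  b <- b[o, , drop = FALSE]
  rownames(b) <- NULL
  class(b) <- c("bridge_set", "data.frame")
  b
}

bridge_key <- function(b) paste(b$e1, b$e2, sep = "|")

# TRUE for extremity pairs that form a reference adjacency {h_i, t_{i+1}}
is_reference_adjacency <- function(e1, e2, seg) {
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  i <- ext_interval(lo); j <- ext_interval(hi)
  iv <- seg$intervals
  ext_side(lo) == "head" & ext_side(hi) == "tail" &
    j == i + 1L & iv$chrom[i] == iv$chrom[j]
}

# ---- observed data ----------------------------------------------------------

#' Bundle an observed CN profile and bridge set
#'
#' @param seg a [reference_segmentation()].
#' @param cn numeric vector of observed (real-valued) copy numbers, one
#'   per interval of `seg`, in interval id order.
#' @param bridges a [bridge_set()].
#' @return object of class `observed_data` with fields `cn`, `bridges`
#'   and `mu` (total bridge support).
#' @export
observed_data <- function(seg, cn, bridges = bridge_set()) {
  if (length(cn) != n_intervals(seg))
    stop("'cn' must have one value per interval of the segmentation")
  if (any(!is.finite(cn))) stop("'cn' must be finite")
  if (nrow(bridges)) {
    if (max(bridges$e2) > 2L * n_intervals(seg))
      stop("bridge extremity outside the segmentation")
    if (any(is_reference_adjacency(bridges$e1, bridges$e2, seg)))
      stop("a bridge must not coincide with a reference adjacency")
    if (any(bridges$support < 0)) stop("bridge support must be >= 0")
  }
  structure(list(cn = as.numeric(cn), bridges = bridges,
                 mu = sum(bridges$support)),
            class = "observed_data")
}

#' @export
print.observed_data <- function(x, ...) {
  cat("Observed data: ", length(x$cn), " interval CN value(s), ",
      nrow(x$bridges), " bridge(s), total support ",
      format(x$mu), "\n", sep = "")
  invisible(x)
}
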
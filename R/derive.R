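# Derivation of breakpoints, CN profiles and bridges by comparing a tumor
# karyotype against its reference genome. In simulation mode the reference
# is a set of chromosomes made of unit-length "atomic segments": the
# smallest unit at which a breakpoint can occur.

# map atomic segment ids to (chromosome, position); atoms are globally unique
atom_index <- function(reference) {
  atoms <- unlist(reference, use.names = FALSE)
  if (anyDuplicated(atoms))
    stop("atomic segment ids must be unique across reference chromosomes")
  n_per <- lengths(reference)
  data.frame(
    atom = atoms,
    chrom = rep(names(reference), n_per),
    pos = unlist(lapply(n_per, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Detect breakpoints by comparing a tumor karyotype to its reference
#'
#' Compares a tumor genome, expressed over atomic segments, with the
#' reference it was derived from, and returns the coarsest partition of
#' each reference chromosome into intervals such that every tumor
#' adjacency either lies inside one interval or falls exactly on an
#' interval boundary. Tumor chromosome ends that do not coincide with
#' reference chromosome ends also induce breakpoints, so that the tumor
#' can be re-expressed over whole intervals.
#'
#' @param reference named list of integer vectors: each reference
#'   chromosome as an ordered sequence of globally unique atomic segment
#'   ids (unit length each).
#' @param tumor a [karyotype()] whose signed entries are atomic segment
#'   ids of `reference`.
#' @return a [reference_segmentation()].
#' @examples
#' ref <- list(chr1 = 1:4)
#' tum <- karyotype(list(c(1, 4, -4, -3, 2, -1)))
#' derive_breakpoints(ref, tum)
#' @export
derive_breakpoints <- function(reference, tumor) {
  ai <- atom_index(reference)
  look <- match(abs(unlist(unclass(tumor), use.names = FALSE)), ai$atom)
  if (anyNA(look))
    stop("tumor references atomic segments absent from the reference")
  chrom_of <- function(a) ai$chrom[match(abs(a), ai$atom)]
  pos_of <- function(a) ai$pos[match(abs(a), ai$atom)]
  len_of <- vapply(reference, length, integer(1L))

  cuts <- lapply(reference, function(x) integer())
  add_cut <- function(chrom, c, len) {
    keep <- c >= 1L & c <= len - 1L
    if (any(keep)) {
      for (ch in unique(chrom[keep]))
        cuts[[ch]] <<- c(cuts[[ch]], c[keep][chrom[keep] == ch])
    }
  }
  for (ch in unclass(tumor)) {
    p <- pos_of(ch); cr <- chrom_of(ch); sgn <- sign(ch)
    n <- length(ch)
    # boundary left of the first and right of the last tumor segment
    add_cut(cr[1L], if (sgn[1L] > 0) p[1L] - 1L else p[1L], len_of[cr[1L]])
    add_cut(cr[n], if (sgn[n] > 0) p[n] else p[n] - 1L, len_of[cr[n]])
    if (n > 1L) {
      a <- ch[-n]; b <- ch[-1L]
      pa <- p[-n]; pb <- p[-1L]
      concordant <- sgn[-n] == sgn[-1L] & cr[-n] == cr[-1L] &
        ifelse(sgn[-n] > 0, pb == pa + 1L, pb == pa - 1L)
      disc <- which(!concordant)
      if (length(disc)) {
        # right end of a in tumor orientation
        ca <- ifelse(sgn[-n][disc] > 0, pa[disc], pa[disc] - 1L)
        cb <- ifelse(sgn[-1L][disc] > 0, pb[disc] - 1L, pb[disc])
        add_cut(cr[-n][disc], ca, len_of[cr[-n][disc]])
        add_cut(cr[-1L][disc], cb, len_of[cr[-1L][disc]])
      }
    }
  }
  lengths <- lapply(names(reference), function(ch) {
    b <- sort(unique(cuts[[ch]]))
    diff(c(0L, b, len_of[[ch]]))
  })
  names(lengths) <- names(reference)
  reference_segmentation(lengths)
}

# For a segmentation derived from `reference`, the global interval id and
# within-interval offset of every atomic segment.
atom_to_interval <- function(reference, seg) {
  ai <- atom_index(reference)
  iv <- seg$intervals
  res_iv <- integer(nrow(ai)); res_off <- integer(nrow(ai))
  for (ch in names(reference)) {
    rows <- which(ai$chrom == ch)
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    idx <- findInterval(ai$pos[rows] - 1L, ivc$start)  # positions are 1-based
    res_iv[rows] <- ivc$id[idx]
    res_off[rows] <- ai$pos[rows] - ivc$start[idx]
  }
  data.frame(atom = ai$atom, interval = res_iv, offset = res_off)
}

#' Re-express an atomic-segment tumor karyotype over segmentation intervals
#'
#' Each interval's atomic run must appear in the tumor either intact or
#' fully reversed; otherwise the segmentation is not a valid partition
#' for this tumor and an error is raised.
#'
#' @inheritParams derive_breakpoints
#' @param seg a [reference_segmentation()] produced by
#'   [derive_breakpoints()] for the same reference.
#' @return a [karyotype()] over the intervals of `seg`.
#' @export
rethread_karyotype <- function(reference, tumor, seg) {
  a2i <- atom_to_interval(reference, seg)
  ilen <- seg$intervals$length
  out <- lapply(unclass(tumor), function(ch) {
    m <- match(abs(ch), a2i$atom)
    if (anyNA(m)) stop("tumor references unknown atomic segments")
    ivs <- a2i$interval[m]; off <- as.integer(a2i$offset[m]); sgn <- sign(ch)
    n <- length(ch)
    signed <- integer(); r_iv <- 0L; r_sgn <- 0L; r_start_off <- 0L
    r_len <- 0L
    close_run <- function() {
      m_j <- as.integer(ilen[r_iv])
      ok <- r_len == m_j &&
        ((r_sgn > 0L && r_start_off == 1L) ||
           (r_sgn < 0L && r_start_off == m_j))
      if (!ok)
        stop("interval ", r_iv, " does not appear intact in the tumor; ",
             "segmentation is inconsistent with this karyotype")
      signed <<- c(signed, r_sgn * r_iv)
    }
    for (t in seq_len(n)) {
      continues <- r_len > 0L && ivs[t] == r_iv && sgn[t] == r_sgn &&
        off[t] == r_start_off + r_sgn * r_len
      if (continues) {
        r_len <- r_len + 1L
      } else {
        if (r_len > 0L) close_run()
        r_iv <- ivs[t]; r_sgn <- sgn[t]; r_start_off <- off[t]; r_len <- 1L
      }
    }
    if (r_len > 0L) close_run()
    signed
  })
  karyotype(out)
}

#' Integer copy-number profile of a karyotype
#'
#' Counts, for every interval of the segmentation, how many times it
#' occurs in the karyotype (in either orientation).
#'
#' @param k a [karyotype()] expressed over the intervals of `seg`.
#' @param seg a [reference_segmentation()].
#' @return integer vector of length `nrow(seg$intervals)`.
#' @export
derive_cn_profile <- function(k, seg) {
  validate_karyotype(k, seg)
  ids <- abs(unlist(unclass(k), use.names = FALSE))
  as.integer(tabulate(ids, nbins = n_intervals(seg)))
}

#' Bridges of a karyotype
#'
#' Returns the set of extremity pairs that are adjacent in the karyotype
#' but not adjacent on the reference. Each bridge is reported once,
#' regardless of how many times or in which orientation it is traversed.
#' Reference adjacencies traversed in reverse are not bridges.
#'
#' @inheritParams derive_cn_profile
#' @return a [bridge_set()] (support initialized to 0).
#' @export
derive_bridges <- function(k, seg) {
  validate_karyotype(k, seg)
  e1 <- integer(); e2 <- integer()
  for (ch in unclass(k)) {
    if (length(ch) < 2L) next
    u <- ch[-length(ch)]; v <- ch[-1L]
    e1 <- c(e1, ext_exit(u)); e2 <- c(e2, ext_entry(v))
  }
  if (length(e1)) {
    keep <- !is_reference_adjacency(e1, e2, seg)
    b <- bridge_set(e1[keep], e2[keep])
    b <- b[!duplicated(bridge_key(b)), , drop = FALSE]
    rownames(b) <- NULL
    class(b) <- c("bridge_set", "data.frame")
    b
  } else {
    bridge_set()
  }
}

#' Does every chromosome of a karyotype run telomere to telomere?
#'
#' The reconstruction model represents chromosomes as alternating paths
#' between telomeric extremities of the reference. A rearrangement that
#' clips a chromosome end (for example a deletion reaching the last
#' segment) leaves a tumor chromosome ending at an interior breakpoint;
#' such a karyotype lies outside the valid-path space and cannot be
#' recovered exactly even from noiseless data.
#'
#' @param k a [karyotype()] over the intervals of `seg`.
#' @param seg a [reference_segmentation()].
#' @return TRUE if every chromosome starts and ends at a telomeric
#'   extremity.
#' @export
is_telomere_bounded <- function(k, seg) {
  all(vapply(unclass(k), function(ch) {
    ext_entry(ch[1L]) %in% seg$telomeres &&
      ext_exit(ch[length(ch)]) %in% seg$telomeres
  }, logical(1L)))
}

#' Full noiseless truth for a simulated tumor
#'
#' Convenience wrapper running [derive_breakpoints()],
#' [rethread_karyotype()], [derive_cn_profile()] and [derive_bridges()].
#'
#' @inheritParams derive_breakpoints
#' @return a list of class `karyotype_truth` with fields `reference`,
#'   `tumor_atomic`, `seg`, `tumor` (interval karyotype), `cn` (integer
#'   profile) and `bridges`.
#' @export
derive_truth <- function(reference, tumor) {
  seg <- derive_breakpoints(reference, tumor)
  tum_iv <- rethread_karyotype(reference, tumor, seg)
  structure(list(
    reference = reference,
    tumor_atomic = tumor,
    seg = seg,
    tumor = tum_iv,
    cn = derive_cn_profile(tum_iv, seg),
    bridges = derive_bridges(tum_iv, seg)
  ), class = "karyotype_truth")
}

#' @export
print.karyotype_truth <- function(x, ...) {
  cat("Simulated truth: ", length(x$seg$chroms), " reference chromosome(s), ",
      n_intervals(x$seg), " interval(s), ", length(x$tumor),
      " tumor chromosome(s), ", nrow(x$bridges), " bridge(s)\n", sep = "")
  invisible(x)
}
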
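#' Anchor-centred signal matrix (computeMatrix reference-point analog)
#'
#' One row per anchor holding the track signal over `[anchor - flank,
#' anchor + flank)` resampled to `out_bin` bp by averaging the covered fine
#' bins. Rows of minus-strand anchors are reversed so columns read upstream
#' to downstream in gene direction. Anchors without full flank room on their
#' chromosome are dropped; the count is kept in the `n_dropped` attribute.
#'
#' @param track A `binned_track`.
#' @param anchors Width-1 `GRanges` (stranded; `*` treated as `+`).
#' @param flank bp each side of the anchor (default 3000); must be a
#'   multiple of `out_bin`.
#' @param out_bin Output bin width in bp (default 50); must share a common
#'   grid with the track (one a multiple of the other).
#' @return Numeric matrix of class `signal_matrix` with attributes
#'   `offsets` (column-centre offsets in bp) and `n_dropped`.
#' @export
signal_matrix <- function(track, anchors, flank = 3000, out_bin = 50) {
  bs <- track$bin_size
  if (flank %% out_bin != 0) stop("flank must be a multiple of out_bin")
  if (out_bin %% bs != 0 && bs %% out_bin != 0) {
    stop("out_bin and track bin_size must be nested")
  }
  lens <- assembly_lengths(track$assembly)
  chr <- as.character(GenomeInfoDb::seqnames(anchors))
  pos0 <- GenomicRanges::start(anchors) - 1L  # 0-based anchor base
  ok <- pos0 - flank >= 0 & pos0 + flank <= lens[chr]
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no anchor has full flank room")
  anchors <- anchors[ok]; chr <- chr[ok]; pos0 <- pos0[ok]
  strand <- as.character(GenomicRanges::strand(anchors))

  ncol <- 2L * flank %/% out_bin
  m <- matrix(NA_real_, nrow = length(anchors), ncol = ncol)
  for (i in seq_along(anchors)) {
    v <- track$values[[chr[i]]]
    lo <- pos0[i] - flank + (seq_len(ncol) - 1L) * out_bin
    row <- vapply(lo, function(s) {
      b0 <- s %/% bs + 1L
      b1 <- ceiling((s + out_bin) / bs)
      w <- v[b0:min(b1, length(v))]
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, 0)
    if (strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  rownames(m) <- if (!is.null(anchors$name)) anchors$name else NULL
  attr(m, "offsets") <- -flank + (seq_len(ncol) - 0.5) * out_bin
  attr(m, "n_dropped") <- n_dropped
  class(m) <- c("signal_matrix", class(m))
  m
}

#' Column-mean summary of a signal matrix
#'
#' @param mat A `signal_matrix`.
#' @return A `position_profile` (per-offset mean ignoring missing cells,
#'   `n` = contributing anchors per offset; mean is `NA` where no cell is
#'   defined).
#' @export
summary_profile <- function(mat) {
  if (nrow(mat) == 0) stop("empty signal matrix")
  n <- colSums(!is.na(mat))
  mean <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
  position_profile(attr(mat, "offsets"), mean, n, "signal")
}
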
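#' Per-offset profile around a set of anchors
#'
#' @param offsets Integer offsets (bp) relative to the anchor, negative =
#'   upstream in reading direction; strictly increasing.
#' @param mean Per-offset mean statistic.
#' @param n Number of anchors contributing at each offset.
#' @param stat_name Label: `"gc_skew"`, `"g4_score"` or `"signal"`.
#' @return A data.frame of class `position_profile` with columns
#'   `offset`, `mean`, `n`.
#' @export
position_profile <- function(offsets, mean, n, stat_name = "signal") {
  stopifnot(length(offsets) == length(mean), length(mean) == length(n))
  if (is.unsorted(offsets, strictly = TRUE)) {
    stop("offsets must be strictly increasing")
  }
  out <- data.frame(offset = offsets, mean = mean, n = n)
  attr(out, "stat_name") <- stat_name
  class(out) <- c("position_profile", "data.frame")
  out
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("position_profile (%s): %d offsets in [%d, %d], max n = %d\n",
              attr(x, "stat_name"), nrow(x), min(x$offset), max(x$offset),
              max(x$n)))
  invisible(x)
}

#' @export
plot.position_profile <- function(x, ...) {
  plot(x$offset, x$mean, type = "l",
       xlab = "offset from anchor (bp)", ylab = attr(x, "stat_name"), ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

# Uppercase character vector of single bases.
#' @noRd
seq_chars <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from both
#' numerator and denominator. `NA` when no unambiguous base remains.
#'
#' @param seq Character scalar or `DNAString`.
#' @return Numeric in `[0, 1]`, or `NA`.
#' @export
gc_fraction <- function(seq) {
  s <- seq_chars(seq)
  acgt <- sum(s %in% c("A", "C", "G", "T"))
  if (acgt == 0) return(NA_real_)
  sum(s %in% c("G", "C")) / acgt
}

#' GC skew of a sequence
#'
#' `(G - C) / (G + C)`; `NA` when the sequence has no G or C.
#'
#' @param seq Character scalar or `DNAString`.
#' @return Numeric in `[-1, 1]`, or `NA`.
#' @export
gc_skew <- function(seq) {
  s <- seq_chars(seq)
  g <- sum(s == "G"); c <- sum(s == "C")
  if (g + c == 0) return(NA_real_)
  (g - c) / (g + c)
}

#' Per-base G-quadruplex propensity scores
#'
#' G4Hunter-style rule: every base inside a maximal run of `k` consecutive Gs
#' scores `+min(k, 4)`, inside a run of `k` Cs `-min(k, 4)`, all other bases
#' (including ambiguity codes) score 0. Window means of this vector are the
#' G4 propensity statistic.
#'
#' @param seq Character scalar or `DNAString`.
#' @return Numeric vector, one score per base, each in `[-4, 4]`.
#' @export
g4_base_scores <- function(seq) {
  s <- seq_chars(seq)
  r <- rle(s)
  sc <- numeric(length(r$lengths))
  isg <- r$values == "G"; isc <- r$values == "C"
  sc[isg] <- pmin(r$lengths[isg], 4)
  sc[isc] <- -pmin(r$lengths[isc], 4)
  rep(sc, r$lengths)
}

#' Parameters for TSS GC-skew profiling
#'
#' Defaults scan a 10 kb span around each TSS with 200 bp windows sliding
#' by 1 bp.
#'
#' @param flank bp on each side of the TSS (default 5000).
#' @param window Window width in bp (default 200).
#' @param step Slide step in bp (default 1).
#' @export
skew_params <- function(flank = 5000, window = 200, step = 1) {
  if (window > 2 * flank) stop("window must fit inside the flank span")
  if (step < 1) stop("step must be >= 1")
  list(flank = as.integer(flank), window = as.integer(window),
       step = as.integer(step))
}

#' Parameters for TSS G4-propensity profiling
#'
#' Defaults score 25 bp windows across 2 kb around each TSS with no score
#' threshold, the standard G4Hunter setting.
#'
#' @param flank bp on each side of the TSS (default 1000).
#' @param window Window width in bp (default 25).
#' @param threshold Windows with |score| below this are reported as 0
#'   (default 0, i.e. all windows reported).
#' @export
g4_params <- function(flank = 1000, window = 25, threshold = 0) {
  if (window < 1) stop("window must be >= 1")
  if (flank < window) stop("flank must be >= window")
  list(flank = as.integer(flank), window = as.integer(window),
       threshold = threshold)
}

# Shared profile driver: fn maps a (2*flank)-length base vector (already in
# reading direction) to one value per window start; returns per-offset mean
# and n over anchors, skipping anchors without full flank room.
#' @noRd
profile_over_anchors <- function(genome, tss, flank, window, step, per_anchor,
                                 stat_name) {
  if (length(tss) == 0) stop("tss set is empty")
  if (any(GenomicRanges::width(tss) != 1L)) stop("TSS anchors must be 1 bp")
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  chr <- as.character(GenomeInfoDb::seqnames(tss))
  pos <- GenomicRanges::start(tss)
  ok <- pos - flank >= 1L & pos + flank <= lens[chr]
  n_skipped <- sum(!ok)
  if (!any(ok)) stop("no TSS has full flank room on both sides")
  tss <- tss[ok]; chr <- chr[ok]; pos <- pos[ok]
  strand <- as.character(GenomicRanges::strand(tss))

  starts <- seq(1L, 2L * flank - window + 1L, by = step)
  # window center offset relative to the TSS (base flank+1 of the span)
  offsets <- starts + window %/% 2L - flank - 1L
  acc <- numeric(length(starts))
  cnt <- integer(length(starts))
  for (i in seq_along(tss)) {
    # window carries `flank` bases upstream of the TSS base in reading
    # direction, the TSS base, and `flank - 1` downstream, on either strand
    rng <- if (strand[i] == "-") {
      IRanges::IRanges(pos[i] - flank + 1L, pos[i] + flank)
    } else {
      IRanges::IRanges(pos[i] - flank, pos[i] + flank - 1L)
    }
    win <- GenomicRanges::GRanges(chr[i], rng, strand = strand[i])
    s <- seq_chars(extract_sequence(genome, win)[[1]])
    v <- per_anchor(s, starts, window)
    def <- !is.na(v)
    acc[def] <- acc[def] + v[def]
    cnt <- cnt + def
  }
  mean <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  p <- position_profile(offsets, mean, cnt, stat_name)
  attr(p, "n_anchors") <- length(tss)
  attr(p, "n_skipped") <- n_skipped
  p
}

# Windowed sums via cumulative sums: x numeric per-base, window w, returns
# one sum per window start in `starts`.
#' @noRd
window_sums <- function(x, starts, w) {
  cs <- c(0, cumsum(x))
  cs[starts + w] - cs[starts]
}

#' Sliding-window GC-skew profile around TSSs
#'
#' Each window is scored on the gene-reading-direction strand (minus-strand
#' TSSs use the reverse complement, so offsets always read upstream to
#' downstream); the per-offset mean is taken over all anchors with a defined
#' skew (windows with no G/C are ignored). TSSs without full flank room are
#' skipped; their count is kept in the `n_skipped` attribute.
#'
#' @param genome Named `DNAStringSet`.
#' @param tss Width-1 stranded `GRanges` of TSS anchors.
#' @param params From [skew_params()].
#' @return A `position_profile` with `stat_name = "gc_skew"`.
#' @export
skew_profile <- function(genome, tss, params = skew_params()) {
  per_anchor <- function(s, starts, w) {
    g <- window_sums(as.numeric(s == "G"), starts, w)
    c_ <- window_sums(as.numeric(s == "C"), starts, w)
    ifelse(g + c_ > 0, (g - c_) / (g + c_), NA_real_)
  }
  profile_over_anchors(genome, tss, params$flank, params$window, params$step,
                       per_anchor, "gc_skew")
}

#' Sliding-window G4-propensity profile around TSSs
#'
#' Per TSS and offset, the mean of [g4_base_scores()] over the window whose
#' middle sits at that offset, computed on the reading-direction strand.
#' Across anchors the default aggregates the absolute window score (a G4 can
#' form on either strand); `aggregate = "signed"` keeps the sign.
#'
#' @param genome Named `DNAStringSet`.
#' @param tss Width-1 stranded `GRanges` of TSS anchors.
#' @param params From [g4_params()].
#' @param aggregate `"absolute"` (default) or `"signed"`.
#' @return A `position_profile` with `stat_name = "g4_score"`.
#' @export
g4_profile <- function(genome, tss, params = g4_params(),
                       aggregate = c("absolute", "signed")) {
  aggregate <- match.arg(aggregate)
  thr <- params$threshold
  per_anchor <- function(s, starts, w) {
    v <- window_sums(g4_base_scores(paste(s, collapse = "")), starts, w) / w
    if (thr > 0) v[abs(v) < thr] <- 0
    if (aggregate == "absolute") abs(v) else v
  }
  profile_over_anchors(genome, tss, params$flank, params$window, 1L,
                       per_anchor, "g4_score")
}
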
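#' Stranded Okazaki-fragment counts per bin
#'
#' @param watson Named list of per-bin Watson (forward-strand) counts.
#' @param crick Named list of per-bin Crick counts, same shape.
#' @param bin_size Bin width in bp.
#' @param assembly `Seqinfo`.
#' @return List of class `stranded_counts`.
#' @export
stranded_counts <- function(watson, crick, bin_size, assembly) {
  if (!identical(names(watson), names(crick))) {
    stop("watson and crick must cover the same chromosomes")
  }
  for (chr in names(watson)) {
    if (length(watson[[chr]]) != length(crick[[chr]])) {
      stop("watson/crick length mismatch on ", chr)
    }
    if (any(watson[[chr]] < 0) || any(crick[[chr]] < 0)) {
      stop("counts must be non-negative")
    }
  }
  structure(list(watson = watson, crick = crick,
                 bin_size = as.integer(bin_size), assembly = assembly),
            class = "stranded_counts")
}

#' Read stranded OK-seq counts from a 4-column TSV
#'
#' Columns: chrom, bin_start (0-based, multiple of `bin_size`), watson,
#' crick. Bins absent from the file get zero counts.
#'
#' @param path TSV path (with header).
#' @param assembly `Seqinfo`.
#' @param bin_size Bin width in bp.
#' @export
read_okseq_tsv <- function(path, assembly, bin_size) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          col.names = c("chrom", "bin_start", "watson", "crick"))
  lens <- assembly_lengths(assembly)
  if (any(df$bin_start %% bin_size != 0)) stop("bin_start off the bin grid")
  w <- lapply(names(lens), function(chr) {
    n <- ceiling(lens[[chr]] / bin_size)
    v <- integer(n)
    d <- df[df$chrom == chr, ]
    v[d$bin_start %/% bin_size + 1L] <- d$watson
    v
  })
  k <- lapply(names(lens), function(chr) {
    n <- ceiling(lens[[chr]] / bin_size)
    v <- integer(n)
    d <- df[df$chrom == chr, ]
    v[d$bin_start %/% bin_size + 1L] <- d$crick
    v
  })
  names(w) <- names(k) <- names(lens)
  stranded_counts(w, k, bin_size, assembly)
}

#' Write stranded OK-seq counts as 4-column TSV
#'
#' @param counts A `stranded_counts`.
#' @param path Output path.
#' @export
write_okseq_tsv <- function(counts, path) {
  rows <- lapply(names(counts$watson), function(chr) {
    n <- length(counts$watson[[chr]])
    data.frame(chrom = chr,
               bin_start = (seq_len(n) - 1L) * counts$bin_size,
               watson = counts$watson[[chr]], crick = counts$crick[[chr]])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Centered moving average with window truncated at chromosome ends.
#' @noRd
rolling_mean <- function(x, half) {
  if (half == 0) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Replication fork directionality from stranded counts
#'
#' RFD per bin is `(C - W) / (C + W)` on the (optionally smoothed) Watson
#' and Crick counts: +1 means purely rightward-moving forks (Crick excess),
#' -1 purely leftward. Bins whose smoothed total `C + W` falls below
#' `min_total` are undefined (`NA`).
#'
#' @param counts A `stranded_counts`.
#' @param min_total Minimum smoothed per-bin total for a defined RFD
#'   (default 10).
#' @param smooth_bins Half-width of the centred moving average applied to W
#'   and C before the ratio (default 2; 0 disables smoothing).
#' @return A `binned_track` with `normalization = "RFD"`.
#' @export
compute_rfd <- function(counts, min_total = 10, smooth_bins = 2) {
  values <- lapply(names(counts$watson), function(chr) {
    w <- rolling_mean(counts$watson[[chr]], smooth_bins)
    k <- rolling_mean(counts$crick[[chr]], smooth_bins)
    tot <- w + k
    ifelse(tot >= min_total, (k - w) / tot, NA_real_)
  })
  names(values) <- names(counts$watson)
  binned_track(values, counts$bin_size, counts$assembly, "RFD")
}

#' Parameters for TRC-site discovery
#'
#' Defaults implement the published geometry: |RFD| > 0.75 regions, TRC
#' windows of +/- 10 kb around the R-loop overlap centre, and 20 kb control
#' windows 1 Mb up- and downstream.
#'
#' @param rfd_threshold Strict |RFD| cutoff (default 0.75).
#' @param min_region_bins Minimum qualifying bins per region (default 5).
#' @param merge_gap_bins Interior non-qualifying bins tolerated inside a
#'   region (default 1).
#' @param flank TRC half-window in bp (default 10000).
#' @param control_distance Distance from TRC centre to each control centre
#'   (default 1e6).
#' @param control_length Control window length in bp (default 20000).
#' @param min_total,smooth_bins Passed to [compute_rfd()].
#' @export
trc_params <- function(rfd_threshold = 0.75, min_region_bins = 5,
                       merge_gap_bins = 1, flank = 10000,
                       control_distance = 1e6, control_length = 20000,
                       min_total = 10, smooth_bins = 2) {
  if (rfd_threshold <= 0 || rfd_threshold > 1) stop("rfd_threshold in (0, 1]")
  if (control_length <= 0) stop("control_length must be > 0")
  if (control_distance <= flank) stop("control_distance must exceed flank")
  list(rfd_threshold = rfd_threshold,
       min_region_bins = as.integer(min_region_bins),
       merge_gap_bins = as.integer(merge_gap_bins),
       flank = as.integer(flank),
       control_distance = as.integer(control_distance),
       control_length = as.integer(control_length),
       min_total = min_total, smooth_bins = as.integer(smooth_bins))
}

# Run-calling on one signed qualifying vector (+1/-1/0); returns matrix of
# (first, last) qualifying bin indices for the given sign.
#' @noRd
call_runs_one_sign <- function(qual, sign, min_bins, gap_bins) {
  idx <- which(qual == sign)
  if (length(idx) == 0) return(NULL)
  # split where the gap is too wide or an opposite-sign bin intervenes
  brk <- logical(length(idx))
  if (length(idx) > 1) {
    for (j in 2:length(idx)) {
      interior <- qual[(idx[j - 1] + 1):(idx[j] - 1)]
      brk[j] <- (idx[j] - idx[j - 1] - 1L) > gap_bins ||
        any(interior == -sign)
    }
  }
  grp <- cumsum(brk)
  out <- lapply(split(idx, grp), function(ix) {
    if (length(ix) >= min_bins) c(ix[1], ix[length(ix)]) else NULL
  })
  do.call(rbind, out)
}

#' Call high-|RFD| regions
#'
#' Maximal runs of bins with `RFD > threshold` (sign `+`) or
#' `RFD < -threshold` (sign `-`), strict inequality, tolerating up to
#' `merge_gap_bins` interior undefined or sub-threshold bins, never bridging
#' bins of the opposite sign, and requiring at least `min_region_bins`
#' qualifying bins.
#'
#' @param rfd An RFD `binned_track` from [compute_rfd()].
#' @param params From [trc_params()].
#' @return `GRanges` with a `sign` column (`"+"`/`"-"`), sorted.
#' @export
call_high_rfd_regions <- function(rfd, params = trc_params()) {
  bs <- rfd$bin_size
  lens <- assembly_lengths(rfd$assembly)
  out <- list()
  for (chr in names(rfd$values)) {
    v <- rfd$values[[chr]]
    qual <- integer(length(v))
    qual[!is.na(v) & v > params$rfd_threshold] <- 1L
    qual[!is.na(v) & v < -params$rfd_threshold] <- -1L
    for (s in c(1L, -1L)) {
      runs <- call_runs_one_sign(qual, s, params$min_region_bins,
                                 params$merge_gap_bins)
      if (is.null(runs)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = (runs[, 1] - 1L) * bs + 1L,
        end = pmin(runs[, 2] * bs, lens[[chr]]),
        sign = if (s > 0) "+" else "-")
    }
  }
  if (length(out) == 0) {
    gr <- GenomicRanges::GRanges(seqinfo = rfd$assembly)
    gr$sign <- character(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               seqinfo = rfd$assembly)
  gr$sign <- df$sign
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Genes fully contained in high-RFD regions
#'
#' A gene is kept when its body lies entirely inside a single region; kept
#' genes are tagged with that region's RFD sign. `mode = "overlap"` relaxes
#' containment to any overlap (tagging with the region of largest overlap).
#'
#' @param genes Stranded `GRanges` with `gene_id`.
#' @param regions Output of [call_high_rfd_regions()].
#' @param mode `"within"` (default) or `"overlap"`.
#' @return Subset of `genes` with an added `rfd_sign` column.
#' @export
genes_in_regions <- function(genes, regions, mode = c("within", "overlap")) {
  mode <- match.arg(mode)
  if (length(genes) == 0 || length(regions) == 0) {
    g <- genes[integer(0)]
    g$rfd_sign <- character(0)
    return(g)
  }
  hit <- GenomicRanges::findOverlaps(genes, regions, type =
    if (mode == "within") "within" else "any", ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hit)
  if (mode == "overlap" && anyDuplicated(q)) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      genes[q], regions[S4Vectors::subjectHits(hit)]))
    keep <- unlist(lapply(split(seq_along(q), q), function(ix) {
      ix[which.max(ov[ix])]
    }))
    hit <- hit[keep]
    q <- S4Vectors::queryHits(hit)
  }
  g <- genes[q]
  g$rfd_sign <- regions$sign[S4Vectors::subjectHits(hit)]
  g
}

#' Define TRC sites from sign-tagged genes and R-loop peaks
#'
#' For each gene overlapping at least one DRIPc peak, the overlap span runs
#' from the leftmost to the rightmost bp of all gene-by-peak intersections;
#' the TRC window is the span centre +/- `flank`, and each control window is
#' `control_length` bp centred `control_distance` bp up- or downstream of
#' that centre. Sites whose window or either control leaves the chromosome
#' are dropped (their count is kept in the `n_dropped` attribute).
#'
#' @param genes Sign-tagged genes from [genes_in_regions()].
#' @param dripc `GRanges` of DRIPc (R-loop) peaks; intersection is
#'   strand-agnostic.
#' @param params From [trc_params()].
#' @param assembly `Seqinfo`.
#' @return data.frame of class `trc_sites`; coordinate columns are 0-based
#'   half-open (BED-like): `window_start/end`, `overlap_start/end`,
#'   `ctrl_up_start/end`, `ctrl_down_start/end`, plus `gene_id`,
#'   `gene_strand`, `rfd_sign`, `orientation`.
#' @export
define_trc_sites <- function(genes, dripc, params = trc_params(), assembly) {
  lens <- assembly_lengths(assembly)
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      gene_strand = character(0), rfd_sign = character(0),
                      overlap_start = integer(0), overlap_end = integer(0),
                      center = integer(0),
                      window_start = integer(0), window_end = integer(0),
                      ctrl_up_start = integer(0), ctrl_up_end = integer(0),
                      ctrl_down_start = integer(0), ctrl_down_end = integer(0),
                      orientation = character(0))
  class(empty) <- c("trc_sites", "data.frame")
  if (length(genes) == 0 || length(dripc) == 0) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  hit <- GenomicRanges::findOverlaps(genes, dripc, ignore.strand = TRUE)
  if (length(hit) == 0) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  q <- S4Vectors::queryHits(hit)
  inter <- IRanges::pintersect(genes[q], dripc[S4Vectors::subjectHits(hit)],
                               ignore.strand = TRUE)
  os <- tapply(GenomicRanges::start(inter), q, min) - 1L  # 0-based
  oe <- tapply(GenomicRanges::end(inter), q, max)         # exclusive
  gi <- as.integer(names(os))
  chrom <- as.character(GenomeInfoDb::seqnames(genes))[gi]
  center <- (os + oe) %/% 2L
  half_ctrl <- params$control_length %/% 2L
  df <- data.frame(
    gene_id = genes$gene_id[gi], chrom = chrom,
    gene_strand = as.character(GenomicRanges::strand(genes))[gi],
    rfd_sign = genes$rfd_sign[gi],
    overlap_start = as.integer(os), overlap_end = as.integer(oe),
    center = as.integer(center),
    window_start = as.integer(center - params$flank),
    window_end = as.integer(center + params$flank),
    ctrl_up_start = as.integer(center - params$control_distance - half_ctrl),
    ctrl_up_end = as.integer(center - params$control_distance + half_ctrl),
    ctrl_down_start = as.integer(center + params$control_distance - half_ctrl),
    ctrl_down_end = as.integer(center + params$control_distance + half_ctrl))
  inb <- df$ctrl_up_start >= 0 & df$window_start >= 0 &
    df$ctrl_down_end <= lens[df$chrom] & df$window_end <= lens[df$chrom]
  n_dropped <- sum(!inb)
  df <- df[inb, , drop = FALSE]
  rownames(df) <- NULL
  df$orientation <- classify_orientation(df$gene_strand, df$rfd_sign)
  class(df) <- c("trc_sites", "data.frame")
  attr(df, "n_dropped") <- n_dropped
  df
}

#' @export
print.trc_sites <- function(x, ...) {
  cat(sprintf("trc_sites: %d site(s) (%d head-on, %d co-directional), %d dropped at bounds\n",
              nrow(x), sum(x$orientation == "head_on"),
              sum(x$orientation == "co_directional"),
              attr(x, "n_dropped") %||% 0L))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transcription-replication conflict orientation
#'
#' Head-on when transcription opposes the predominant fork direction:
#' a `+` gene in a leftward-fork (`-` RFD sign) region or a `-` gene in a
#' rightward-fork (`+`) region; co-directional otherwise.
#'
#' @param gene_strand `"+"`/`"-"` per site.
#' @param rfd_sign `"+"`/`"-"` per site.
#' @return Character vector, `"head_on"` or `"co_directional"`.
#' @export
classify_orientation <- function(gene_strand, rfd_sign) {
  ifelse(gene_strand != rfd_sign, "head_on", "co_directional")
}

#' Write TRC sites as TSV
#' @param sites A `trc_sites` data.frame.
#' @param path Output path.
#' @export
write_trc_sites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
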
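#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges] at this boundary, the only place a
#' conversion happens. Records are validated against the assembly and the
#' result is returned sorted.
#'
#' @param path Path to a BED3 or BED6 file.
#' @param assembly A [GenomeInfoDb::Seqinfo] from [genome_assembly()].
#' @return A sorted `GRanges`; strand is `*` where the file has no strand
#'   column (rendered as `.` on write).
#' @export
read_bed <- function(path, assembly) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges(seqinfo = assembly))
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 bad[1], path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  check_in_assembly(gr, assembly, what = "BED record")
  gr <- with_assembly(gr, assembly)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' Emits BED6 when `name`, `score` or strand information is present,
#' otherwise BED3. Inverse of [read_bed()] on the retained fields.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  has6 <- !is.null(gr$name) || !is.null(gr$score) ||
    any(as.character(GenomicRanges::strand(gr)) != "*")
  if (has6) {
    if (is.null(gr$name)) gr$name <- "."
    if (is.null(gr$score)) gr$score <- 0
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Collapses intervals whose gap is at most `max_gap` bp, the operation used
#' to merge peak-call replicates into a single peak set.
#'
#' @param gr A `GRanges`.
#' @param max_gap Maximum gap (bp) bridged by a merge; 0 merges only
#'   overlapping or book-ended intervals.
#' @param ignore.strand Merge across strands (default TRUE, as peak sets are
#'   unstranded).
#' @return A `GRanges` whose intervals are pairwise separated by more than
#'   `max_gap` bp.
#' @export
merge_overlapping <- function(gr, max_gap = 0, ignore.strand = TRUE) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                        ignore.strand = ignore.strand)
}

#' TSS anchors of a gene set
#'
#' The TSS of a gene is its 5' base in reading direction: the leftmost base
#' for `+` genes, the rightmost for `-` genes, kept as a 1 bp stranded anchor.
#'
#' @param genes Stranded `GRanges` of gene bodies.
#' @return A width-1 `GRanges` of TSS anchors (names/gene_id carried over).
#' @export
tss_anchors <- function(genes) {
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("genes must be stranded to define a TSS")
  }
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' Signed distance from interval midpoints to the nearest TSS
#'
#' Distance is measured from the query midpoint to the nearest TSS anchor on
#' the same chromosome; the sign reads in the gene's direction (negative =
#' upstream of the TSS, positive = downstream). Ties are broken by the
#' leftmost TSS.
#'
#' @param query `GRanges` of query intervals (e.g. peaks).
#' @param tss Width-1 stranded `GRanges` of TSS anchors.
#' @return A data.frame with columns `tss_index`, `distance` (signed bp);
#'   `NA` rows where the query chromosome carries no TSS.
#' @export
signed_tss_distance <- function(query, tss) {
  if (length(tss) == 0) stop("tss set is empty")
  if (any(GenomicRanges::width(tss) != 1L)) stop("TSS anchors must be 1 bp")
  qchr <- as.character(GenomeInfoDb::seqnames(query))
  qmid <- GenomicRanges::start(query) +
    floor((GenomicRanges::width(query) - 1L) / 2)
  tchr <- as.character(GenomeInfoDb::seqnames(tss))
  tpos <- GenomicRanges::start(tss)
  tstr <- as.character(GenomicRanges::strand(tss))
  idx <- rep(NA_integer_, length(query))
  dist <- rep(NA_real_, length(query))
  for (chr in unique(qchr)) {
    ti <- which(tchr == chr)
    qi <- which(qchr == chr)
    if (length(ti) == 0) next
    ord <- ti[order(tpos[ti], ti)]
    pos <- tpos[ord]
    lo <- findInterval(qmid[qi], pos)
    for (k in seq_along(qi)) {
      cand <- unique(pmin(pmax(c(lo[k], lo[k] + 1L), 1L), length(pos)))
      ad <- abs(qmid[qi[k]] - pos[cand])
      best <- cand[order(ad, pos[cand])][1]
      idx[qi[k]] <- ord[best]
    }
  }
  ok <- !is.na(idx)
  sgn <- ifelse(tstr[idx[ok]] == "-", -1, 1)
  dist[ok] <- sgn * (qmid[ok] - tpos[idx[ok]])
  data.frame(tss_index = idx, distance = dist)
}

#' Extract genomic sequence for an interval
#'
#' Returns the uppercase sequence of the interval, reverse-complemented when
#' the interval is on the `-` strand. Out-of-bounds intervals error rather
#' than clip.
#'
#' @param genome A named [Biostrings::DNAStringSet] (one entry per chromosome)
#'   as returned by [Biostrings::readDNAStringSet()] or [make_genome()].
#' @param interval A `GRanges` (may hold several intervals).
#' @return A `DNAStringSet`, one sequence per interval.
#' @export
extract_sequence <- function(genome, interval) {
  chr <- as.character(GenomeInfoDb::seqnames(interval))
  bad <- !(chr %in% names(genome))
  if (any(bad)) stop(sprintf("chromosome '%s' not in genome", chr[bad][1]))
  lens <- Biostrings::width(genome)[match(chr, names(genome))]
  if (any(GenomicRanges::start(interval) < 1L) ||
      any(GenomicRanges::end(interval) > lens)) {
    stop("interval exceeds chromosome bounds")
  }
  out <- Biostrings::DNAStringSet(lapply(seq_along(interval), function(i) {
    Biostrings::subseq(genome[[chr[i]]],
                       start = GenomicRanges::start(interval)[i],
                       end = GenomicRanges::end(interval)[i])
  }))
  neg <- as.character(GenomicRanges::strand(interval)) == "-"
  if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])
  names(out) <- if (!is.null(interval$name)) interval$name else NULL
  out
}
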
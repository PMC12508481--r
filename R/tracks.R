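#' Fixed-bin genomic signal track
#'
#' A `binned_track` stores one numeric vector per chromosome at a fixed bin
#' size; element `i` covers the half-open bp span `[(i-1)*bin, i*bin)`.
#' `NA` marks bins with no defined value (e.g. RFD at zero coverage); window
#' means ignore `NA` bins.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin width in bp.
#' @param assembly `Seqinfo` governing the coordinates.
#' @param normalization One of `"raw"`, `"CPM"`, `"RPKM"`, `"RFD"`, `"other"`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, assembly,
                         normalization = c("raw", "CPM", "RPKM", "RFD", "other")) {
  normalization <- match.arg(normalization)
  if (bin_size <= 0) stop("bin_size must be > 0")
  lens <- assembly_lengths(assembly)
  if (!all(names(values) %in% names(lens))) {
    stop("track chromosome not in assembly")
  }
  for (chr in names(values)) {
    expect_n <- ceiling(lens[[chr]] / bin_size)
    if (length(values[[chr]]) != expect_n) {
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chr, expect_n, length(values[[chr]])))
    }
    v <- values[[chr]]
    if (any(!is.finite(v) & !is.na(v))) stop("non-finite track value")
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 assembly = assembly, normalization = normalization),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- sum(lengths(x$values))
  cat(sprintf("binned_track: %d chromosome(s), bin %d bp, %d bins, %s\n",
              length(x$values), x$bin_size, nb, x$normalization))
  invisible(x)
}

#' Bin point positions into a raw count track
#'
#' @param positions data.frame with columns `chrom` and `pos` (0-based bp).
#' @param assembly `Seqinfo`.
#' @param bin_size Bin width in bp.
#' @return A raw-count `binned_track`; total over all bins equals the number
#'   of positions.
#' @export
bin_counts <- function(positions, assembly, bin_size) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  lens <- assembly_lengths(assembly)
  bad <- !(positions$chrom %in% names(lens))
  if (any(bad)) stop("position on unknown chromosome")
  if (any(positions$pos < 0) ||
      any(positions$pos >= lens[positions$chrom])) {
    stop("position outside chromosome bounds")
  }
  values <- lapply(names(lens), function(chr) {
    n <- ceiling(lens[[chr]] / bin_size)
    p <- positions$pos[positions$chrom == chr]
    tabulate(floor(p / bin_size) + 1L, nbins = n)
  })
  names(values) <- names(lens)
  binned_track(values, bin_size, assembly, "raw")
}

# Mean track value over a 0-based half-open window [start0, end0); NA bins
# ignored; NA when every overlapped bin is NA.
#' @noRd
track_window_mean <- function(track, chrom, start0, end0) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(NA_real_)
  i0 <- floor(start0 / track$bin_size) + 1L
  i1 <- ceiling(end0 / track$bin_size)
  i0 <- max(i0, 1L); i1 <- min(i1, length(v))
  if (i1 < i0) return(NA_real_)
  w <- v[i0:i1]
  if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
}

#' Write a binned track as bedGraph
#'
#' Adjacent bins with equal values are collapsed into one record; `NA` bins
#' are omitted (bedGraph has no missing-value representation).
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lens <- assembly_lengths(track$assembly)
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    r <- rle(ifelse(is.na(v), NA, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values)
    if (!any(keep)) next
    s0 <- starts[keep] * track$bin_size
    e0 <- pmin(ends[keep] * track$bin_size, lens[[chr]])
    writeLines(sprintf("%s\t%d\t%d\t%s", chr, s0, e0,
                       formatC(r$values[keep], format = "g", digits = 15)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph into a binned track
#'
#' Record boundaries must align to the bin grid (multiples of `bin_size`,
#' except a final record truncated at the chromosome end). Uncovered bins
#' become `NA`.
#'
#' @param path bedGraph file.
#' @param assembly `Seqinfo`.
#' @param bin_size Bin width in bp.
#' @param normalization Label recorded on the returned track.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, assembly, bin_size,
                          normalization = "other") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  check_in_assembly(gr, assembly, what = "bedGraph record")
  lens <- assembly_lengths(assembly)
  values <- lapply(names(lens), function(chr) {
    rep(NA_real_, ceiling(lens[[chr]] / bin_size))
  })
  names(values) <- names(lens)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  if (any(s0 %% bin_size != 0)) {
    stop("bedGraph record start not aligned to bin grid")
  }
  ok_end <- e0 %% bin_size == 0 | e0 == lens[chr]
  if (!all(ok_end)) stop("bedGraph record end not aligned to bin grid")
  for (i in seq_along(gr)) {
    b0 <- s0[i] %/% bin_size + 1L
    b1 <- ceiling(e0[i] / bin_size)
    values[[chr[i]]][b0:b1] <- gr$score[i]
  }
  binned_track(values, bin_size, assembly, normalization)
}

#' Read gene records from a minimal GTF
#'
#' Only `gene` feature rows are kept; each must carry a `gene_id` attribute.
#'
#' @param path GTF file.
#' @param assembly `Seqinfo`.
#' @return Sorted stranded `GRanges` with a `gene_id` column.
#' @export
read_gtf_genes <- function(path, assembly) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("GTF gene records must carry gene_id")
  }
  gr <- with_assembly(gr, assembly)
  check_in_assembly(gr, assembly, what = "gene")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = gr$gene_id)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write gene records as minimal GTF
#'
#' @param genes Stranded `GRanges` with a `gene_id` column.
#' @param path Output path.
#' @export
write_gtf_genes <- function(genes, path) {
  if (is.null(genes$gene_id)) stop("genes must carry gene_id")
  lines <- sprintf('%s\ttrcatlas\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   as.character(GenomeInfoDb::seqnames(genes)),
                   GenomicRanges::start(genes), GenomicRanges::end(genes),
                   as.character(GenomicRanges::strand(genes)),
                   genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}
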
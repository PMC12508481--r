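#' Gene annotation model for peak classification
#'
#' @param genes Stranded `GRanges` with `gene_id`.
#' @param exons Optional `GRanges` with `gene_id`, each exon inside its gene.
#' @param promoter_window bp upstream/downstream of the TSS counting as
#'   promoter (default 1000).
#' @param downstream_window bp past the gene 3' end counting as downstream
#'   (default 3000).
#' @return A list of class `annotation_model`.
#' @export
annotation_model <- function(genes, exons = NULL, promoter_window = 1000,
                             downstream_window = 3000) {
  if (length(genes) == 0) stop("genes must be non-empty")
  if (promoter_window <= 0) stop("promoter_window must be > 0")
  if (!is.null(exons) && length(exons) > 0) {
    hit <- GenomicRanges::findOverlaps(exons, genes, type = "within",
                                       ignore.strand = TRUE)
    ok <- genes$gene_id[S4Vectors::subjectHits(hit)] ==
      exons$gene_id[S4Vectors::queryHits(hit)]
    if (!all(seq_along(exons) %in% S4Vectors::queryHits(hit)[ok])) {
      stop("every exon must lie within its gene")
    }
  }
  structure(list(genes = genes, exons = exons,
                 tss = tss_anchors(genes),
                 promoter_window = as.integer(promoter_window),
                 downstream_window = as.integer(downstream_window)),
            class = "annotation_model")
}

#' Classify peaks against a gene annotation
#'
#' Category is decided by the peak midpoint with priority
#' promoter > exon > intron > downstream > intergenic, so categories
#' partition the peak set. Promoter means within `promoter_window` bp of a
#' TSS on either side; downstream means within `downstream_window` bp past a
#' gene's 3' end.
#'
#' @param peaks `GRanges` of peaks.
#' @param model An [annotation_model()].
#' @return data.frame with one row per peak: `chrom`, `start0`, `end0`
#'   (BED coordinates), `category`, `nearest_gene`, `tss_distance` (signed).
#' @export
classify_peaks <- function(peaks, model) {
  if (length(peaks) == 0) stop("peaks must be non-empty")
  mid1 <- GenomicRanges::start(peaks) +
    floor((GenomicRanges::width(peaks) - 1L) / 2)
  midgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                  IRanges::IRanges(mid1, width = 1L))
  sd <- signed_tss_distance(peaks, model$tss)
  category <- rep("intergenic", length(peaks))

  # downstream: within downstream_window past the 3' end, strand-aware
  dw <- GenomicRanges::flank(model$genes, model$downstream_window,
                             start = FALSE)
  category[IRanges::overlapsAny(midgr, dw, ignore.strand = TRUE)] <- "downstream"
  in_gene <- IRanges::overlapsAny(midgr, model$genes, ignore.strand = TRUE)
  category[in_gene] <- "intron"
  if (!is.null(model$exons) && length(model$exons) > 0) {
    in_exon <- IRanges::overlapsAny(midgr, model$exons, ignore.strand = TRUE)
    category[in_gene & in_exon] <- "exon"
  }
  category[!is.na(sd$distance) &
             abs(sd$distance) <= model$promoter_window] <- "promoter"

  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start0 = GenomicRanges::start(peaks) - 1L,
    end0 = GenomicRanges::end(peaks),
    category = factor(category, levels = c("promoter", "exon", "intron",
                                           "downstream", "intergenic")),
    nearest_gene = ifelse(is.na(sd$tss_index), NA_character_,
                          model$genes$gene_id[sd$tss_index]),
    tss_distance = sd$distance)
}

#' Annotate a peak set: per-peak table and category fractions
#'
#' @inheritParams classify_peaks
#' @return List with `table` (per-peak data.frame from [classify_peaks()])
#'   and `fractions` (named numeric summing to 1 over the five categories).
#' @export
annotate_peakset <- function(peaks, model) {
  tab <- classify_peaks(peaks, model)
  fr <- table(tab$category) / nrow(tab)
  list(table = tab, fractions = c(fr))
}

#' Fraction of peaks within given distances of the nearest TSS
#'
#' @param peaks `GRanges` of peaks.
#' @param tss Width-1 stranded `GRanges` of TSS anchors.
#' @param thresholds Ascending positive distances in bp.
#' @return Named numeric vector, fraction of peaks with
#'   `|midpoint-to-TSS distance| <= t` for each threshold; monotone
#'   non-decreasing.
#' @export
tss_proximity_fractions <- function(peaks, tss, thresholds) {
  if (length(peaks) == 0 || length(tss) == 0) stop("empty input set")
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be positive and strictly ascending")
  }
  d <- abs(signed_tss_distance(peaks, tss)$distance)
  out <- vapply(thresholds, function(t) mean(d <= t, na.rm = FALSE), 0)
  names(out) <- paste0("<=", thresholds)
  out
}

#' Select TSSs bound by (proximal to) at least one peak
#'
#' A TSS is bound when its distance to the nearest peak edge is strictly
#' less than `max_distance` bp (0 for a TSS inside a peak).
#'
#' @param tss Width-1 stranded `GRanges`.
#' @param peaks `GRanges` of peaks.
#' @param max_distance Strict upper bound in bp (default 3000).
#' @return The bound subset of `tss`, original order preserved.
#' @export
select_bound_tss <- function(tss, peaks, max_distance = 3000) {
  if (length(tss) == 0 || length(peaks) == 0) stop("empty input set")
  hit <- GenomicRanges::distanceToNearest(tss, peaks, ignore.strand = TRUE)
  keep <- rep(FALSE, length(tss))
  keep[S4Vectors::queryHits(hit)] <-
    S4Vectors::mcols(hit)$distance < max_distance
  tss[keep]
}
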
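#' Parameters for GC-matched control TSS sampling
#'
#' @param gc_window Total bp around the TSS over which GC\% is computed
#'   (default 2000, i.e. +/- 1 kb).
#' @param gc_bin_width GC\% histogram bin used for stratified matching
#'   (default 0.01).
#' @param exclusion_distance A candidate closer than this to any peak is
#'   ineligible (default 3000 bp, mirroring the bound-TSS definition).
#' @param n_sets Number of independent control sets (default 2).
#' @param seed RNG seed for the draw.
#' @export
matching_params <- function(gc_window = 2000, gc_bin_width = 0.01,
                            exclusion_distance = 3000, n_sets = 2, seed = 1) {
  if (gc_bin_width <= 0 || gc_bin_width > 1) stop("gc_bin_width in (0, 1]")
  if (n_sets < 1) stop("n_sets must be >= 1")
  list(gc_window = as.integer(gc_window), gc_bin_width = gc_bin_width,
       exclusion_distance = as.integer(exclusion_distance),
       n_sets = as.integer(n_sets), seed = as.integer(seed))
}

# GC% per TSS over +/- gc_window/2, forward strand (GC% is strand-symmetric).
# NA for TSSs without room or with no unambiguous base.
#' @noRd
tss_gc_percent <- function(tss, genome, gc_window) {
  half <- gc_window %/% 2L
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  chr <- as.character(GenomeInfoDb::seqnames(tss))
  pos <- GenomicRanges::start(tss)
  out <- rep(NA_real_, length(tss))
  ok <- pos - half >= 1L & pos + half - 1L <= lens[chr]
  if (!any(ok)) return(out)
  win <- GenomicRanges::GRanges(chr[ok], IRanges::IRanges(
    pos[ok] - half, pos[ok] + half - 1L))
  seqs <- extract_sequence(genome, win)
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  tot <- rowSums(freq)
  out[ok] <- ifelse(tot > 0, (freq[, "C"] + freq[, "G"]) / tot, NA_real_)
  out
}

#' @noRd
gc_bin_index <- function(gc, width) pmin(floor(gc / width), floor(1 / width))

#' Sample GC-matched, unbound control TSS sets
#'
#' Builds `n_sets` pairwise-disjoint control sets, each the same size as the
#' bound set and matching its GC\% histogram bin-for-bin (stratified sampling
#' without replacement). Candidates within `exclusion_distance` of any peak,
#' or present in the bound set, are ineligible. Fully reproducible under the
#' seed in `params`.
#'
#' @param bound Bound TSS set (width-1 `GRanges`).
#' @param candidates Candidate TSS universe (width-1 `GRanges`).
#' @param peaks Peak `GRanges` defining "bound" to be excluded.
#' @param genome Named `DNAStringSet`.
#' @param params From [matching_params()].
#' @return List of `n_sets` `GRanges`, each sorted.
#' @export
select_matched_tss <- function(bound, candidates, peaks, genome,
                               params = matching_params()) {
  if (length(candidates) == 0) stop("candidate set is empty")
  if (length(bound) == 0) stop("bound set is empty")

  # drop candidates that are bound TSSs or near a peak
  self <- IRanges::overlapsAny(candidates, bound, ignore.strand = TRUE)
  hit <- GenomicRanges::distanceToNearest(candidates, peaks,
                                          ignore.strand = TRUE)
  near <- rep(FALSE, length(candidates))
  near[S4Vectors::queryHits(hit)] <-
    S4Vectors::mcols(hit)$distance < params$exclusion_distance
  eligible <- candidates[!self & !near]

  gc_b <- tss_gc_percent(bound, genome, params$gc_window)
  gc_e <- tss_gc_percent(eligible, genome, params$gc_window)
  if (anyNA(gc_b)) stop("bound TSS without computable GC% (flank room?)")
  keep <- !is.na(gc_e)
  eligible <- eligible[keep]; gc_e <- gc_e[keep]

  bb <- gc_bin_index(gc_b, params$gc_bin_width)
  be <- gc_bin_index(gc_e, params$gc_bin_width)
  need <- table(bb)
  avail <- table(factor(be, levels = names(need)))
  short <- avail < as.integer(need) * params$n_sets
  if (any(short)) {
    i <- which(short)
    stop(sprintf(
      "deficient GC bin(s): %s",
      paste(sprintf("bin %s needs %d, has %d", names(need)[i],
                    as.integer(need)[i] * params$n_sets,
                    as.integer(avail)[i]), collapse = "; ")))
  }

  withr::with_seed(params$seed, {
    sets <- replicate(params$n_sets, integer(0), simplify = FALSE)
    for (b in names(need)) {
      pool <- which(be == as.numeric(b))
      pick <- pool[sample.int(length(pool), as.integer(need[[b]]) * params$n_sets)]
      for (k in seq_len(params$n_sets)) {
        take <- pick[seq_len(need[[b]]) + (k - 1L) * need[[b]]]
        sets[[k]] <- c(sets[[k]], take)
      }
    }
    lapply(sets, function(ix) {
      GenomicRanges::sort(eligible[ix], ignore.strand = TRUE)
    })
  })
}
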
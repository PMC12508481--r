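#' @noRd
resolve_genome <- function(x) {
  if (is.character(x)) Biostrings::readDNAStringSet(x) else x
}

#' @noRd
resolve_bed <- function(x, assembly) {
  if (is.character(x)) read_bed(x, assembly) else x
}

#' @noRd
write_manifest <- function(outdir, stage, params, counts) {
  manifest <- list(stage = stage, params = params, counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the promoter secondary-structure analysis end to end
#'
#' Selects TSSs bound by a peak set, draws GC-matched unbound control TSS
#' sets, and profiles all sets identically: sliding-window GC skew, G4
#' propensity, and (when a signal track is supplied) a signal metaprofile.
#'
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param tss Width-1 stranded `GRanges` (or BED path) of all TSSs.
#' @param peaks `GRanges` or BED path of binding peaks.
#' @param assembly `Seqinfo`.
#' @param track Optional `binned_track` (or bedGraph path at `track_bin`)
#'   for the metaprofile.
#' @param track_bin Bin size used when reading `track` from a path.
#' @param bound_max_distance Peak-to-TSS bound cutoff in bp (default 3000).
#' @param skew,g4,matching Parameter lists from [skew_params()],
#'   [g4_params()], [matching_params()].
#' @param meta_flank,meta_bin Metaprofile geometry (bp).
#' @param outdir Optional directory; when given, BED files for the anchor
#'   sets, profile TSVs and a JSON manifest are written there.
#' @return List: `bound`, `controls` (list of `GRanges`), `profiles` (per
#'   set: `skew`, `g4`, optional `signal` position_profiles), `counts`.
#' @export
run_tss_structure_analysis <- function(genome, tss, peaks, assembly,
                                       track = NULL, track_bin = 50,
                                       bound_max_distance = 3000,
                                       skew = skew_params(),
                                       g4 = g4_params(),
                                       matching = matching_params(),
                                       meta_flank = 3000, meta_bin = 50,
                                       outdir = NULL) {
  genome <- resolve_genome(genome)
  tss <- resolve_bed(tss, assembly)
  peaks <- resolve_bed(peaks, assembly)
  if (is.character(track)) {
    track <- read_bedgraph(track, assembly, track_bin)
  }
  bound <- select_bound_tss(tss, peaks, bound_max_distance)
  if (length(bound) == 0) stop("tss_structure: no bound TSS found")
  controls <- select_matched_tss(bound, tss, peaks, genome, matching)
  sets <- c(list(bound = bound),
            stats::setNames(controls, paste0("control", seq_along(controls))))
  profiles <- lapply(sets, function(anchors) {
    p <- list(skew = skew_profile(genome, anchors, skew),
              g4 = g4_profile(genome, anchors, g4))
    if (!is.null(track)) {
      p$signal <- summary_profile(
        signal_matrix(track, anchors, meta_flank, meta_bin))
    }
    p
  })
  counts <- c(list(n_tss = length(tss), n_peaks = length(peaks),
                   n_bound = length(bound)),
              stats::setNames(lapply(controls, length),
                              paste0("n_control", seq_along(controls))))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sets)) {
      write_bed(sets[[nm]], file.path(outdir, paste0(nm, "_tss.bed")))
      for (st in names(profiles[[nm]])) {
        utils::write.table(as.data.frame(profiles[[nm]][[st]]),
                           file.path(outdir, sprintf("%s_%s.tsv", nm, st)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_manifest(outdir, "tss_structure",
                   list(bound_max_distance = bound_max_distance,
                        skew = skew, g4 = g4, matching = matching,
                        meta_flank = meta_flank, meta_bin = meta_bin),
                   counts)
  }
  list(bound = bound, controls = controls, profiles = profiles,
       counts = counts)
}

#' Run the TRC-site discovery and factor-enrichment analysis end to end
#'
#' Computes RFD from stranded OK-seq counts, calls high-|RFD| regions,
#' keeps genes contained in them, intersects with DRIPc peaks to define TRC
#' sites with distal controls, and scores each supplied factor track by its
#' TRC/control enrichment ratio.
#'
#' @param okseq A `stranded_counts` (or 4-column TSV path at `okseq_bin`).
#' @param genes Stranded `GRanges` with `gene_id` (or GTF path).
#' @param dripc `GRanges` or BED path of DRIPc peaks.
#' @param factors Named list; each element either a normalized
#'   `binned_track`, or `list(track = raw binned_track, total_mapped = n)`
#'   to be normalized here.
#' @param assembly `Seqinfo`.
#' @param trc From [trc_params()].
#' @param norm From [normalization_params()].
#' @param okseq_bin Bin size used when reading `okseq` from a path.
#' @param outdir Optional output directory (site table, per-factor TSVs,
#'   manifest).
#' @return List: `rfd` track, `regions`, `sites`, `enrichment` (list of
#'   `enrichment_result`), `summary` (data.frame ordered by decreasing
#'   `factor_log2`), `status` (`"ok"` or `"no_sites"`).
#' @export
run_trc_enrichment_analysis <- function(okseq, genes, dripc, factors,
                                        assembly,
                                        trc = trc_params(),
                                        norm = normalization_params(),
                                        okseq_bin = 1000,
                                        outdir = NULL) {
  if (is.character(okseq)) okseq <- read_okseq_tsv(okseq, assembly, okseq_bin)
  if (is.character(genes)) genes <- read_gtf_genes(genes, assembly)
  dripc <- resolve_bed(dripc, assembly)
  rfd <- compute_rfd(okseq, trc$min_total, trc$smooth_bins)
  regions <- call_high_rfd_regions(rfd, trc)
  contained <- genes_in_regions(genes, regions)
  sites <- define_trc_sites(contained, dripc, trc, assembly)
  if (nrow(sites) == 0) {
    return(list(rfd = rfd, regions = regions, sites = sites,
                enrichment = list(),
                summary = data.frame(factor = character(0),
                                     factor_log2 = numeric(0),
                                     n_sites = integer(0)),
                status = "no_sites"))
  }
  enrichment <- lapply(names(factors), function(nm) {
    f <- factors[[nm]]
    track <- if (inherits(f, "binned_track")) {
      f
    } else {
      normalize_track(f$track, f$total_mapped, norm)
    }
    score_trc_enrichment(track, sites, norm, factor_label = nm)
  })
  names(enrichment) <- names(factors)
  summary <- data.frame(
    factor = names(enrichment),
    factor_log2 = vapply(enrichment, function(e) e$factor_log2, 0),
    n_sites = vapply(enrichment, function(e) nrow(e$per_site), 0L))
  summary <- summary[order(-summary$factor_log2), , drop = FALSE]
  rownames(summary) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_trc_sites(sites, file.path(outdir, "trc_sites.tsv"))
    write_bedgraph(rfd, file.path(outdir, "rfd.bedgraph"))
    utils::write.table(summary, file.path(outdir, "enrichment_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(outdir, "trc_enrichment", list(trc = trc, norm = norm),
                   list(n_genes = length(genes),
                        n_regions = length(regions),
                        n_contained = length(contained),
                        n_sites = nrow(sites)))
  }
  list(rfd = rfd, regions = regions, sites = sites,
       enrichment = enrichment, summary = summary, status = "ok")
}
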
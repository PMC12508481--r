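#' Coverage normalization parameters
#'
#' @param bin_size Bin width in bp (default 100, the published setting for
#'   factor tracks at TRC sites).
#' @param mode `"RPKM"` or `"CPM"`.
#' @param pseudocount Added to window means before the TRC/control ratio
#'   (default 0.01), guarding zero-coverage controls.
#' @export
normalization_params <- function(bin_size = 100, mode = c("RPKM", "CPM"),
                                 pseudocount = 0.01) {
  mode <- match.arg(mode)
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  list(bin_size = as.integer(bin_size), mode = mode,
       pseudocount = pseudocount)
}

#' Depth-normalize a raw count track
#'
#' RPKM: `count / ((bin_size/1000) * (total_mapped/1e6))`;
#' CPM: `count / (total_mapped/1e6)`.
#'
#' @param raw A raw-count `binned_track`.
#' @param total_mapped Total mapped reads (> 0).
#' @param params From [normalization_params()].
#' @return A `binned_track` with the chosen normalization.
#' @export
normalize_track <- function(raw, total_mapped, params = normalization_params()) {
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  if (raw$normalization != "raw") stop("input track must be raw counts")
  denom <- if (params$mode == "RPKM") {
    (raw$bin_size / 1000) * (total_mapped / 1e6)
  } else {
    total_mapped / 1e6
  }
  values <- lapply(raw$values, function(v) v / denom)
  binned_track(values, raw$bin_size, raw$assembly, params$mode)
}

#' Element-wise average of replicate tracks
#'
#' Missing bins are excluded from the per-bin mean; a bin missing in every
#' replicate stays missing.
#'
#' @param tracks List of `binned_track`s on the same grid, assembly and
#'   normalization.
#' @return A `binned_track`.
#' @export
average_tracks <- function(tracks) {
  if (length(tracks) == 0) stop("no tracks given")
  t1 <- tracks[[1]]
  for (t in tracks[-1]) {
    if (t$bin_size != t1$bin_size ||
        !identical(lengths(t$values), lengths(t1$values)) ||
        !identical(names(t$values), names(t1$values)) ||
        t$normalization != t1$normalization) {
      stop("tracks must share grid, assembly and normalization")
    }
  }
  values <- lapply(names(t1$values), function(chr) {
    m <- do.call(rbind, lapply(tracks, function(t) t$values[[chr]]))
    n <- colSums(!is.na(m))
    ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  })
  names(values) <- names(t1$values)
  binned_track(values, t1$bin_size, t1$assembly, t1$normalization)
}

#' Factor enrichment at TRC sites versus distal controls
#'
#' Per site: the mean normalized signal over the TRC window and over each
#' control window, then
#' `ratio = (trc + pc) / (mean(ctrl_up, ctrl_down) + pc)`.
#' The per-factor summary is `log2(mean(ratio))` across sites (the
#' `"mean_of_log2"` alternative averages `log2(ratio)` instead). Sites whose
#' window has no defined signal are dropped with a count.
#'
#' @param track Normalized `binned_track`.
#' @param sites A `trc_sites` table from [define_trc_sites()].
#' @param params From [normalization_params()] (only `pseudocount` is used).
#' @param factor_label Label carried into the result.
#' @param summary `"log2_of_mean"` (default) or `"mean_of_log2"`.
#' @return List of class `enrichment_result`: `factor`, `per_site`
#'   (data.frame with site means and ratio), `factor_log2`, `n_dropped`.
#' @export
score_trc_enrichment <- function(track, sites,
                                 params = normalization_params(),
                                 factor_label = "factor",
                                 summary = c("log2_of_mean", "mean_of_log2")) {
  summary <- match.arg(summary)
  if (nrow(sites) == 0) stop("no TRC sites given")
  pc <- params$pseudocount
  trc <- mapply(track_window_mean, sites$chrom, sites$window_start,
                sites$window_end, MoreArgs = list(track = track))
  up <- mapply(track_window_mean, sites$chrom, sites$ctrl_up_start,
               sites$ctrl_up_end, MoreArgs = list(track = track))
  dn <- mapply(track_window_mean, sites$chrom, sites$ctrl_down_start,
               sites$ctrl_down_end, MoreArgs = list(track = track))
  keep <- !is.na(trc) & !is.na(up) & !is.na(dn)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("every site window lacks defined signal")
  ratio <- (trc[keep] + pc) / ((up[keep] + dn[keep]) / 2 + pc)
  per_site <- data.frame(
    gene_id = sites$gene_id[keep], trc_mean = trc[keep],
    ctrl_up_mean = up[keep], ctrl_down_mean = dn[keep], ratio = ratio)
  factor_log2 <- if (summary == "log2_of_mean") {
    log2(mean(ratio))
  } else {
    mean(log2(ratio))
  }
  structure(list(factor = factor_label, per_site = per_site,
                 factor_log2 = factor_log2, n_dropped = n_dropped,
                 summary = summary),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result [%s]: %d site(s), factor_log2 = %.3f (%s)\n",
              x$factor, nrow(x$per_site), x$factor_log2, x$summary))
  invisible(x)
}
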
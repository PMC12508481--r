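#' Configuration for the synthetic-data generators
#'
#' One object drives every generator, making each a pure, seeded function of
#' the configuration. Defaults describe the standard toy study: a 5 Mb
#' chromosome, 30 non-overlapping genes kept clear of replication-origin
#' transitions and of chromosome ends (so TRC control geometry always fits),
#' two origins, OK-seq depth 200 reads/bin at 1 kb bins, ChIP background 50
#' reads/bin at 100 bp bins, and DRIPc peaks over half the genes.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   from it.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param gc Background GC fraction of the genome.
#' @param skew_amplitude Excess of G over C planted on the coding strand in
#'   the first kb downstream of designated TSSs (0 = no skew).
#' @param n_genes Number of genes.
#' @param gene_length Length range (bp), sampled uniformly.
#' @param cgg_repeat_counts CGG tract lengths (units of one CGG) available
#'   for planting at designated promoters.
#' @param origin_positions Replication origins: named list of bp vectors per
#'   chromosome, or a plain vector for a single-chromosome assembly.
#' @param okseq_depth Expected Okazaki reads per OK-seq bin.
#' @param chip_background_depth Expected ChIP reads per ChIP bin.
#' @param dripc_gene_fraction Fraction of genes given a DRIPc peak.
#' @param okseq_bin OK-seq bin size (bp).
#' @param chip_bin ChIP bin size (bp).
#' @param gene_margin Genes are placed at least this far from chromosome
#'   ends (default 1.02 Mb so 1 Mb-distant controls always fit) and at least
#'   `transition_margin` from RFD transitions.
#' @param transition_margin Clearance (bp) around origins/termination
#'   midpoints when placing genes (default 5000).
#' @param gene_spacing Minimum gap between placed genes in bp (default
#'   1000).
#' @param promoter_gc Optional length-2 range; when set, each promoter
#'   (+/- 1 kb of the TSS) is resampled at its own GC fraction drawn
#'   uniformly from this range, giving the TSS universe a broad GC spectrum
#'   for stratified matching. `NULL` keeps the background composition.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrS = 5e6),
                       gc = 0.45,
                       skew_amplitude = 0.3,
                       n_genes = 30,
                       gene_length = c(5000, 20000),
                       cgg_repeat_counts = integer(0),
                       origin_positions = c(1.5e6, 3.5e6),
                       okseq_depth = 200,
                       chip_background_depth = 50,
                       dripc_gene_fraction = 0.5,
                       okseq_bin = 1000,
                       chip_bin = 100,
                       gene_margin = 1.02e6,
                       transition_margin = 5000,
                       gene_spacing = 1000,
                       promoter_gc = NULL) {
  stopifnot(gc >= 0, gc <= 1, skew_amplitude >= 0, skew_amplitude <= 1,
            okseq_depth >= 0, chip_background_depth >= 0,
            dripc_gene_fraction >= 0, dripc_gene_fraction <= 1)
  if (is.numeric(origin_positions) && !is.list(origin_positions)) {
    origin_positions <- stats::setNames(
      list(sort(origin_positions)), names(chrom_lengths)[1])
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 gc = gc, skew_amplitude = skew_amplitude,
                 n_genes = as.integer(n_genes), gene_length = gene_length,
                 cgg_repeat_counts = as.integer(cgg_repeat_counts),
                 origin_positions = origin_positions,
                 okseq_depth = okseq_depth,
                 chip_background_depth = chip_background_depth,
                 dripc_gene_fraction = dripc_gene_fraction,
                 okseq_bin = as.integer(okseq_bin),
                 chip_bin = as.integer(chip_bin),
                 gene_margin = gene_margin,
                 transition_margin = transition_margin,
                 gene_spacing = as.integer(gene_spacing),
                 promoter_gc = promoter_gc,
                 assembly = genome_assembly(chrom_lengths)),
            class = "sim_config")
}

# RFD breakpoints (0-based bp) on one chromosome: origins plus termination
# midpoints between consecutive origins.
#' @noRd
rfd_breakpoints <- function(origins, chrom_len) {
  o <- sort(origins)
  mids <- if (length(o) > 1) (o[-length(o)] + o[-1]) / 2 else numeric(0)
  sort(c(o, mids))
}

# True RFD at 0-based position x: -1 left of the first origin, +1 from an
# origin to the following termination midpoint, -1 from there to the next
# origin, +1 right of the last origin.
#' @noRd
true_rfd_at <- function(x, origins, chrom_len) {
  b <- rfd_breakpoints(origins, chrom_len)
  seg <- findInterval(x, b)
  ifelse(seg %% 2 == 1, 1, -1)
}

#' Generate a synthetic gene annotation
#'
#' Genes are non-overlapping, with seeded random strands and lengths, placed
#' uniformly but excluding chromosome ends (`gene_margin`) and a clearance
#' around every RFD transition (`transition_margin`), so each gene body sits
#' inside one fork-direction plateau and TRC control windows always fit.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (stranded `GRanges` + `gene_id`) and `tss`
#'   (width-1 anchors).
#' @export
make_annotation <- function(cfg) {
  withr::with_seed(cfg$seed + 1L, {
    lens <- cfg$chrom_lengths
    out <- list()
    per_chr <- table(factor(
      sample(names(lens), cfg$n_genes, replace = TRUE,
             prob = lens / sum(lens)), levels = names(lens)))
    for (chr in names(lens)) {
      n <- per_chr[[chr]]
      if (n == 0) next
      len <- lens[[chr]]
      origins <- cfg$origin_positions[[chr]]
      brk <- if (is.null(origins)) numeric(0) else rfd_breakpoints(origins, len)
      placed <- IRanges::IRanges()
      starts <- integer(n); widths <- integer(n)
      for (i in seq_len(n)) {
        okpos <- FALSE
        for (try in 1:2000) {
          w <- round(stats::runif(1, cfg$gene_length[1], cfg$gene_length[2]))
          s <- round(stats::runif(1, cfg$gene_margin, len - cfg$gene_margin - w))
          cand <- IRanges::IRanges(s + 1L, s + w)
          near_brk <- length(brk) > 0 &&
            any(brk > s - cfg$transition_margin &
                brk < s + w + cfg$transition_margin)
          if (!near_brk &&
              !any(IRanges::overlapsAny(cand, placed,
                                        maxgap = cfg$gene_spacing))) {
            placed <- c(placed, cand)
            starts[i] <- s; widths[i] <- w
            okpos <- TRUE
            break
          }
        }
        if (!okpos) stop("could not place genes: chromosome too crowded")
      }
      out[[chr]] <- data.frame(chrom = chr, start = starts + 1L,
                               width = widths,
                               strand = sample(c("+", "-"), n,
                                               replace = TRUE))
    }
    df <- do.call(rbind, unname(out))
    genes <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, width = df$width),
      strand = df$strand, seqinfo = cfg$assembly)
    genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
    genes$gene_id <- sprintf("gene%03d", seq_along(genes))
    list(genes = genes, tss = tss_anchors(genes))
  })
}

#' Generate a synthetic genome sequence
#'
#' Background bases are i.i.d. at GC fraction `gc`. For genes named in
#' `skewed_gene_ids`, the first kb downstream of the TSS gets a planted GC
#' skew of `skew_amplitude` on the coding (non-template) strand. For genes
#' named in `cgg_gene_ids`, a `(CGG)_n` tract (n drawn from
#' `cgg_repeat_counts`) is written on the coding strand just downstream of
#' the TSS. A truth record lists every planted feature.
#'
#' @param cfg A [sim_config()].
#' @param annotation From [make_annotation()].
#' @param skewed_gene_ids Genes whose promoters get planted skew
#'   (default none).
#' @param cgg_gene_ids Genes whose promoters get a CGG tract (default none).
#' @return List with `genome` (named `DNAStringSet`) and `truth`
#'   (data.frames `skew` and `cgg` of planted features, 0-based half-open).
#' @export
make_genome <- function(cfg, annotation, skewed_gene_ids = character(0),
                        cgg_gene_ids = character(0)) {
  withr::with_seed(cfg$seed + 2L, {
    lens <- cfg$chrom_lengths
    p_bg <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
              G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
    chars <- lapply(names(lens), function(chr) {
      sample(names(p_bg), lens[[chr]], replace = TRUE, prob = p_bg)
    })
    names(chars) <- names(lens)

    genes <- annotation$genes
    tss <- annotation$tss
    chr_of <- as.character(GenomeInfoDb::seqnames(tss))
    pos0 <- GenomicRanges::start(tss) - 1L
    strand <- as.character(GenomicRanges::strand(tss))

    # optional per-promoter GC spectrum: resample +/- 1 kb of every TSS at
    # a gene-specific GC fraction (G = C, so no skew is introduced here)
    gene_gc <- rep(cfg$gc, length(genes))
    names(gene_gc) <- genes$gene_id
    if (!is.null(cfg$promoter_gc)) {
      gene_gc[] <- stats::runif(length(genes), cfg$promoter_gc[1],
                                cfg$promoter_gc[2])
      for (i in seq_along(genes)) {
        s0 <- max(pos0[i] - 1000L, 0L)
        e0 <- min(pos0[i] + 1000L, lens[[chr_of[i]]])
        gci <- gene_gc[[i]]
        p <- c(A = (1 - gci) / 2, C = gci / 2, G = gci / 2, T = (1 - gci) / 2)
        ix <- (s0 + 1L):e0
        chars[[chr_of[i]]][ix] <- sample(names(p), length(ix),
                                         replace = TRUE, prob = p)
      }
    }

    # Skew is planted by reassigning the existing G/C positions in the first
    # kb downstream of the TSS: each becomes coding-strand G with
    # probability (1 + amp)/2. GC content is untouched, so planted skew
    # cannot leak into GC-based matching.
    skew_rows <- list()
    amp <- cfg$skew_amplitude
    for (gid in skewed_gene_ids) {
      i <- match(gid, genes$gene_id)
      if (is.na(i)) stop("unknown gene_id: ", gid)
      span <- 1000L
      if (strand[i] == "+") {
        s0 <- pos0[i]; e0 <- min(pos0[i] + span, lens[[chr_of[i]]])
        p_g_fwd <- (1 + amp) / 2  # coding strand is the forward strand
      } else {
        s0 <- max(pos0[i] + 1L - span, 0L); e0 <- pos0[i] + 1L
        p_g_fwd <- (1 - amp) / 2  # coding-strand G reads as forward C
      }
      ix <- (s0 + 1L):e0
      gcpos <- ix[chars[[chr_of[i]]][ix] %in% c("G", "C")]
      chars[[chr_of[i]]][gcpos] <- ifelse(
        stats::runif(length(gcpos)) < p_g_fwd, "G", "C")
      skew_rows[[gid]] <- data.frame(gene_id = gid, chrom = chr_of[i],
                                     start0 = s0, end0 = e0,
                                     strand = strand[i])
    }

    cgg_rows <- list()
    for (gid in cgg_gene_ids) {
      i <- match(gid, genes$gene_id)
      if (is.na(i)) stop("unknown gene_id: ", gid)
      n_rep <- if (length(cfg$cgg_repeat_counts) == 1) {
        cfg$cgg_repeat_counts
      } else {
        sample(cfg$cgg_repeat_counts, 1)
      }
      tract <- strsplit(strrep("CGG", n_rep), "")[[1]]
      if (strand[i] == "+") {
        s0 <- pos0[i] + 10L
        bases <- tract
      } else {
        s0 <- pos0[i] - 10L - length(tract) + 1L
        bases <- rev(c(A = "T", C = "G", G = "C", T = "A")[tract])
      }
      e0 <- s0 + length(tract)
      if (s0 < 0 || e0 > lens[[chr_of[i]]]) stop("CGG tract out of bounds")
      chars[[chr_of[i]]][(s0 + 1L):e0] <- bases
      cgg_rows[[gid]] <- data.frame(gene_id = gid, chrom = chr_of[i],
                                    start0 = s0, end0 = e0, n = n_rep)
    }

    genome <- Biostrings::DNAStringSet(vapply(chars, paste,
                                              collapse = "", ""))
    names(genome) <- names(lens)
    list(genome = genome,
         truth = list(skew = do.call(rbind, unname(skew_rows)),
                      cgg = do.call(rbind, unname(cgg_rows)),
                      gene_gc = gene_gc))
  })
}

#' Simulate stranded OK-seq counts with a step-function true RFD
#'
#' The true RFD is +1 from each origin to the termination midpoint before
#' the next origin and -1 elsewhere (leftward forks before the first and
#' after each midpoint). Per bin, total reads are Poisson(`okseq_depth`)
#' and Crick reads Binomial(total, (1 + r)/2).
#'
#' @param cfg A [sim_config()] (must carry origin positions).
#' @return List with `counts` (`stranded_counts`) and `truth_rfd`
#'   (a `binned_track` of the planted RFD).
#' @export
simulate_okseq <- function(cfg) {
  if (length(cfg$origin_positions) == 0 ||
      all(lengths(cfg$origin_positions) == 0)) {
    stop("config has no replication origins")
  }
  withr::with_seed(cfg$seed + 3L, {
    lens <- cfg$chrom_lengths
    bs <- cfg$okseq_bin
    w <- k <- truth <- list()
    for (chr in names(lens)) {
      n <- ceiling(lens[[chr]] / bs)
      centers <- (seq_len(n) - 0.5) * bs
      origins <- cfg$origin_positions[[chr]]
      r <- if (is.null(origins) || length(origins) == 0) {
        rep(0, n)
      } else {
        true_rfd_at(centers, origins, lens[[chr]])
      }
      tot <- stats::rpois(n, cfg$okseq_depth)
      crick <- stats::rbinom(n, tot, (1 + r) / 2)
      w[[chr]] <- tot - crick
      k[[chr]] <- crick
      truth[[chr]] <- r
    }
    list(counts = stranded_counts(w, k, bs, cfg$assembly),
         truth_rfd = binned_track(truth, bs, cfg$assembly, "RFD"))
  })
}

#' Simulate a raw ChIP coverage track with planted enrichment
#'
#' Per-bin counts are Poisson with mean `chip_background_depth * fold`,
#' where `fold` is the planted fold for bins overlapping a planted site and
#' 1 elsewhere.
#'
#' @param cfg A [sim_config()].
#' @param planted_sites Optional data.frame with `chrom`, `start0`, `end0`
#'   (0-based half-open) and `fold` (>= 1).
#' @param stream Extra seed offset so multiple factors drawn from one config
#'   are independent (default 0).
#' @return List with `track` (raw `binned_track`) and `total_mapped`.
#' @export
simulate_chip <- function(cfg, planted_sites = NULL, stream = 0) {
  if (!is.null(planted_sites) && any(planted_sites$fold < 1)) {
    stop("planted folds must be >= 1")
  }
  withr::with_seed(cfg$seed + 4L + as.integer(stream), {
    lens <- cfg$chrom_lengths
    bs <- cfg$chip_bin
    values <- list()
    for (chr in names(lens)) {
      n <- ceiling(lens[[chr]] / bs)
      fold <- rep(1, n)
      if (!is.null(planted_sites)) {
        ps <- planted_sites[planted_sites$chrom == chr, , drop = FALSE]
        for (j in seq_len(nrow(ps))) {
          b0 <- ps$start0[j] %/% bs + 1L
          b1 <- min(ceiling(ps$end0[j] / bs), n)
          fold[b0:b1] <- ps$fold[j]
        }
      }
      values[[chr]] <- stats::rpois(n, cfg$chip_background_depth * fold)
    }
    names(values) <- names(lens)
    track <- binned_track(values, bs, cfg$assembly, "raw")
    list(track = track, total_mapped = sum(vapply(values, sum, 0)))
  })
}

#' Simulate DRIPc (R-loop) peaks over a gene subset
#'
#' A seeded choice of `round(dripc_gene_fraction * n_genes)` genes each
#' receives one peak placed uniformly inside the gene body with length
#' drawn from 500-2000 bp (capped by the gene).
#'
#' @param cfg A [sim_config()].
#' @param genes Stranded `GRanges` with `gene_id`.
#' @return List with `peaks` (`GRanges`, unstranded, named by gene) and
#'   `truth_gene_ids` (the chosen genes).
#' @export
simulate_dripc <- function(cfg, genes) {
  withr::with_seed(cfg$seed + 5L, {
    n_pick <- round(cfg$dripc_gene_fraction * length(genes))
    if (n_pick == 0) {
      peaks <- GenomicRanges::GRanges(seqinfo = cfg$assembly)
      peaks$name <- character(0)
      return(list(peaks = peaks, truth_gene_ids = character(0)))
    }
    pick <- sort(sample.int(length(genes), n_pick))
    g <- genes[pick]
    len <- pmin(round(stats::runif(n_pick, 500, 2000)),
                GenomicRanges::width(g) - 2L)
    off <- floor(stats::runif(n_pick) * (GenomicRanges::width(g) - len))
    peaks <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(g),
      IRanges::IRanges(GenomicRanges::start(g) + off, width = len))
    peaks$name <- g$gene_id
    peaks <- with_assembly(peaks, cfg$assembly)
    list(peaks = GenomicRanges::sort(peaks, ignore.strand = TRUE),
         truth_gene_ids = g$gene_id)
  })
}

#' Simulate a binding-peak set at designated promoters
#'
#' One peak per designated gene, centred on its TSS.
#'
#' @param cfg A [sim_config()].
#' @param annotation From [make_annotation()].
#' @param bound_gene_ids Genes whose promoters carry a peak.
#' @param peak_halfwidth Half-width in bp (default 150).
#' @return `GRanges` of peaks (named by gene), sorted.
#' @export
simulate_peaks <- function(cfg, annotation, bound_gene_ids,
                           peak_halfwidth = 150) {
  tss <- annotation$tss
  i <- match(bound_gene_ids, annotation$genes$gene_id)
  if (anyNA(i)) stop("unknown gene_id in bound_gene_ids")
  pos <- GenomicRanges::start(tss)[i]
  peaks <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(tss)[i],
    IRanges::IRanges(pmax(pos - peak_halfwidth, 1L), pos + peak_halfwidth))
  peaks$name <- bound_gene_ids
  peaks <- with_assembly(peaks, cfg$assembly)
  GenomicRanges::sort(peaks, ignore.strand = TRUE)
}

#' Choose a bound gene set with guaranteed GC-matching support
#'
#' Draws `n_bound` genes at random subject to the stratified-matching
#' feasibility constraint: within every GC bin, the bound count never
#' exceeds `floor(candidates_in_bin / (n_sets + 1))`, so the remaining
#' unbound TSSs in each bin always suffice for `n_sets` disjoint control
#' sets. This mirrors real promoter universes, where bound promoters are a
#' small minority of each GC stratum.
#'
#' @param cfg A [sim_config()] (its seed drives the draw).
#' @param annotation From [make_annotation()].
#' @param genome From [make_genome()] (`$genome`).
#' @param n_bound Number of bound genes.
#' @param params From [matching_params()] (`gc_window`, `gc_bin_width`,
#'   `n_sets`).
#' @return Character vector of bound `gene_id`s, sorted.
#' @export
choose_bound_genes <- function(cfg, annotation, genome, n_bound,
                               params = matching_params()) {
  gc <- tss_gc_percent(annotation$tss, genome, params$gc_window)
  if (anyNA(gc)) stop("TSS without computable GC%")
  bin <- gc_bin_index(gc, params$gc_bin_width)
  cap <- floor(table(bin) / (params$n_sets + 1))
  withr::with_seed(cfg$seed + 6L, {
    ord <- sample.int(length(gc))
    taken <- integer(0)
    used <- stats::setNames(rep(0L, length(cap)), names(cap))
    for (i in ord) {
      b <- as.character(bin[i])
      if (used[[b]] < cap[[b]]) {
        taken <- c(taken, i)
        used[[b]] <- used[[b]] + 1L
        if (length(taken) == n_bound) break
      }
    }
    if (length(taken) < n_bound) {
      stop("TSS universe too small for a feasible bound set of this size")
    }
    sort(annotation$genes$gene_id[taken])
  })
}
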
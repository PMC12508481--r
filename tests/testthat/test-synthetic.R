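test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 81, chrom_lengths = c(c1 = 3e5),
                    n_genes = 4, gene_margin = 5000,
                    origin_positions = c(1.5e5))
  a1 <- make_annotation(cfg)
  a2 <- make_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  g1 <- make_genome(cfg, a1)
  g2 <- make_genome(cfg, a1)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  o1 <- simulate_okseq(cfg)
  o2 <- simulate_okseq(cfg)
  expect_identical(o1$counts$crick, o2$counts$crick)
  # a different seed changes the draw
  cfg2 <- sim_config(seed = 82, chrom_lengths = c(c1 = 3e5),
                     n_genes = 4, gene_margin = 5000,
                     origin_positions = c(1.5e5))
  expect_false(identical(make_annotation(cfg2)$genes, a1$genes))
})

test_that("genome composition matches the configured GC and skew is planted cleanly", {
  cfg <- sim_config(seed = 83, chrom_lengths = c(c1 = 1e6), gc = 0.5,
                    n_genes = 10, gene_margin = 6000, gene_spacing = 3500,
                    gene_length = c(2000, 4000), origin_positions = c(5e5),
                    skew_amplitude = 0.4)
  ann <- make_annotation(cfg)
  gen0 <- make_genome(cfg, ann)
  s <- as.character(gen0$genome[[1]])
  expect_equal(gc_fraction(s), 0.5, tolerance = 0.01)
  expect_lt(abs(gc_skew(s)), 0.02)

  # planting skew at half the genes leaves GC untouched base-for-base
  ids <- ann$genes$gene_id[1:5]
  gen1 <- make_genome(cfg, ann, skewed_gene_ids = ids)
  ch0 <- strsplit(s, "")[[1]]
  ch1 <- strsplit(as.character(gen1$genome[[1]]), "")[[1]]
  expect_identical(ch0 %in% c("G", "C"), ch1 %in% c("G", "C"))
  # and the planted span shows the configured coding-strand skew
  tr <- gen1$truth$skew
  expect_equal(nrow(tr), 5)
  for (i in 1:5) {
    span <- GenomicRanges::GRanges(tr$chrom[i],
                                   IRanges::IRanges(tr$start0[i] + 1,
                                                    tr$end0[i]),
                                   strand = tr$strand[i])
    sk <- gc_skew(as.character(extract_sequence(gen1$genome, span)))
    expect_lt(abs(sk - 0.4), 0.13)  # ~3 sd at ~500 G/C bases per span
  }
})

test_that("CGG tracts are written at the recorded coordinates on the coding strand", {
  cfg <- sim_config(seed = 84, chrom_lengths = c(c1 = 2e5), n_genes = 4,
                    gene_margin = 5000, gene_spacing = 3500,
                    gene_length = c(2000, 4000),
                    cgg_repeat_counts = 8, origin_positions = c(1e5))
  ann <- make_annotation(cfg)
  gen <- make_genome(cfg, ann, cgg_gene_ids = ann$genes$gene_id[1:2])
  tr <- gen$truth$cgg
  expect_equal(nrow(tr), 2)
  for (i in 1:2) {
    strand <- as.character(GenomicRanges::strand(
      ann$genes[match(tr$gene_id[i], ann$genes$gene_id)]))
    span <- GenomicRanges::GRanges(tr$chrom[i],
                                   IRanges::IRanges(tr$start0[i] + 1,
                                                    tr$end0[i]),
                                   strand = strand)
    expect_equal(as.character(extract_sequence(gen$genome, span)),
                 strrep("CGG", 8))
  }
})

test_that("OK-seq truth follows the origin step profile and is recoverable", {
  cfg <- sim_config(seed = 85, chrom_lengths = c(c1 = 1e6),
                    origin_positions = c(5e5), okseq_depth = 200,
                    n_genes = 2, gene_margin = 5000)
  ok <- simulate_okseq(cfg)
  r <- ok$truth_rfd$values$c1
  expect_equal(unique(r[1:499]), -1)  # leftward forks before the origin
  expect_equal(unique(r[501:1000]), 1)
  rfd <- compute_rfd(ok$counts)
  expect_lte(mean(abs(rfd$values$c1 - r), na.rm = TRUE), 0.05)
  # counts are consistent: watson + crick ~ Poisson(depth)
  tot <- ok$counts$watson$c1 + ok$counts$crick$c1
  expect_equal(mean(tot), 200, tolerance = 0.05)
  expect_error(simulate_okseq(sim_config(origin_positions = numeric(0))),
               "origins")
})

test_that("ChIP simulation plants fold enrichment over Poisson background", {
  cfg <- sim_config(seed = 86, chrom_lengths = c(c1 = 2e6), n_genes = 2,
                    chip_background_depth = 50, origin_positions = c(1e6))
  site <- data.frame(chrom = "c1", start0 = 1e6, end0 = 1.02e6, fold = 4)
  sim <- simulate_chip(cfg, site)
  v <- sim$track$values$c1
  inside <- (1e6 / 100 + 1):(1.02e6 / 100)
  ratio <- mean(v[inside]) / mean(v[-inside])
  expect_gt(ratio, 3.6)
  expect_lt(ratio, 4.4)
  expect_equal(sim$total_mapped, sum(v))
  expect_error(simulate_chip(cfg, transform(site, fold = 0.5)), "fold")
  # zero depth: all-zero track whose normalization then fails by contract
  cfg0 <- sim_config(seed = 86, chrom_lengths = c(c1 = 1e5), n_genes = 2,
                     chip_background_depth = 0, origin_positions = c(5e4))
  sim0 <- simulate_chip(cfg0)
  expect_equal(sim0$total_mapped, 0)
  expect_error(normalize_track(sim0$track, sim0$total_mapped),
               "total_mapped")
})

test_that("DRIPc peaks land inside their genes at the configured fraction", {
  cfg <- sim_config(seed = 87)
  ann <- make_annotation(cfg)
  for (frac in c(0, 0.5, 1)) {
    cfgf <- sim_config(seed = 87, dripc_gene_fraction = frac)
    dr <- simulate_dripc(cfgf, ann$genes)
    expect_length(dr$peaks, round(frac * length(ann$genes)))
    expect_equal(length(dr$truth_gene_ids), length(dr$peaks))
    if (frac > 0) {
      hit <- GenomicRanges::findOverlaps(dr$peaks, ann$genes,
                                         type = "within",
                                         ignore.strand = TRUE)
      expect_length(unique(S4Vectors::queryHits(hit)), length(dr$peaks))
    }
  }
})

test_that("generated datasets survive their on-disk formats", {
  cfg <- sim_config(seed = 88, chrom_lengths = c(c1 = 4e5), n_genes = 6,
                    gene_margin = 5000, gene_spacing = 3500,
                    gene_length = c(2000, 4000), origin_positions = c(2e5))
  ann <- make_annotation(cfg)
  gen <- make_genome(cfg, ann)
  dir <- withr::local_tempdir()

  fa <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(gen$genome, fa)
  expect_identical(as.character(Biostrings::readDNAStringSet(fa)$c1),
                   as.character(gen$genome$c1))

  gtf <- file.path(dir, "genes.gtf")
  write_gtf_genes(ann$genes, gtf)
  back <- read_gtf_genes(gtf, cfg$assembly)
  expect_equal(GenomicRanges::ranges(back), GenomicRanges::ranges(ann$genes))
  expect_equal(back$gene_id, ann$genes$gene_id)

  tsv <- file.path(dir, "okseq.tsv")
  ok <- simulate_okseq(cfg)
  write_okseq_tsv(ok$counts, tsv)
  back_ok <- read_okseq_tsv(tsv, cfg$assembly, cfg$okseq_bin)
  expect_identical(back_ok$watson, ok$counts$watson)
  expect_identical(back_ok$crick, ok$counts$crick)

  dr <- simulate_dripc(cfg, ann$genes)
  bed <- file.path(dir, "dripc.bed")
  write_bed(dr$peaks, bed)
  back_dr <- read_bed(bed, cfg$assembly)
  expect_equal(GenomicRanges::ranges(back_dr), GenomicRanges::ranges(dr$peaks))
})
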
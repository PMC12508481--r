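counts1 <- function(w, k, bin = 1000) {
  asm <- genome_assembly(c(chr = length(w) * bin))
  stranded_counts(list(chr = w), list(chr = k), bin, asm)
}

test_that("RFD follows (C - W)/(C + W) with the missing-data contract", {
  sc <- counts1(w = c(10, 5, 4, 0, 0), k = c(90, 5, 5, 0, 20))
  rfd <- compute_rfd(sc, min_total = 10, smooth_bins = 0)
  # equal strands -> 0; total below min_total or zero -> undefined
  expect_equal(rfd$values$chr, c(0.8, 0, NA, NA, 1))
  expect_equal(rfd$normalization, "RFD")
  # antisymmetry under swapping Watson and Crick
  sc2 <- counts1(w = c(90, 5, 5, 0, 20), k = c(10, 5, 4, 0, 0))
  rfd2 <- compute_rfd(sc2, min_total = 10, smooth_bins = 0)
  expect_equal(rfd2$values$chr, -rfd$values$chr)
})

test_that("RFD recovers a planted per-bin directionality as depth grows", {
  set.seed(61)
  n <- 2000
  r_true <- stats::runif(n, -0.9, 0.9)
  for (depth in c(200)) {
    tot <- stats::rpois(n, depth)
    crick <- stats::rbinom(n, tot, (1 + r_true) / 2)
    rfd <- compute_rfd(counts1(tot - crick, crick), min_total = 10,
                       smooth_bins = 0)
    v <- rfd$values$chr
    expect_true(all(abs(v) <= 1, na.rm = TRUE))
    expect_lte(mean(abs(v - r_true), na.rm = TRUE), 0.05)
  }
})

test_that("high-RFD region calling is strict, sign-aware and matches a run-scan oracle", {
  p <- trc_params(min_region_bins = 5, merge_gap_bins = 1)
  asm <- genome_assembly(c(chr = 100 * 1000))
  mk_rfd <- function(v) binned_track(list(chr = v), 1000, asm, "RFD")

  regs <- call_high_rfd_regions(mk_rfd(rep(0.9, 100)), p)
  expect_length(regs, 1)
  expect_equal(GenomicRanges::width(regs), 100000)
  expect_equal(regs$sign, "+")

  expect_length(call_high_rfd_regions(mk_rfd(rep(0.75, 100)), p), 0)

  # gap tolerance: a single interior sub-threshold bin is bridged,
  # two are not; opposite-sign bins always break
  v <- rep(0, 100)
  v[11:20] <- 0.9; v[21] <- 0.5; v[22:31] <- 0.9
  v[41:50] <- 0.9; v[51:52] <- 0.5; v[53:62] <- 0.9
  v[71:80] <- 0.9; v[81] <- -0.9; v[82:91] <- 0.9
  regs <- call_high_rfd_regions(mk_rfd(v), p)
  df <- data.frame(start = GenomicRanges::start(regs),
                   end = GenomicRanges::end(regs), sign = regs$sign)
  expect_equal(nrow(df), 5)
  expect_true(any(df$start == 10001 & df$end == 31000))       # bridged
  expect_true(any(df$start == 40001 & df$end == 50000))       # split
  expect_true(any(df$start == 52001 & df$end == 62000))
  expect_true(any(df$start == 70001 & df$end == 80000))       # broken by -
  expect_true(any(df$start == 81001 & df$end == 91000))
  expect_true(all(df$sign == "+"))  # the lone - bin is below min_region_bins

  # randomized blocky profile against an rle-based run-scan oracle
  set.seed(62)
  v <- rep(stats::runif(20, -1, 1), each = 5)
  p0 <- trc_params(min_region_bins = 3, merge_gap_bins = 0)
  regs <- call_high_rfd_regions(mk_rfd(v), p0)
  qual <- ifelse(v > 0.75, 1L, ifelse(v < -0.75, -1L, 0L))
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values != 0 & r$lengths >= 3
  expect_gt(sum(keep), 0)
  expect_equal(GenomicRanges::start(regs), (starts[keep] - 1) * 1000 + 1)
  expect_equal(GenomicRanges::end(regs), ends[keep] * 1000)
  expect_equal(regs$sign, as.character(ifelse(r$values[keep] > 0, "+", "-")))
})

test_that("gene retention requires full containment and tags the region sign", {
  asm <- genome_assembly(c(chr = 200000))
  regions <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(10001, 100001), c(50000, 150000)),
    seqinfo = asm)
  regions$sign <- c("+", "-")
  set.seed(63)
  s <- sample(1:180000, 50)
  genes <- GenomicRanges::GRanges("chr", IRanges::IRanges(s, s + 9999),
                                  strand = sample(c("+", "-"), 50, TRUE),
                                  seqinfo = asm)
  genes$gene_id <- sprintf("g%02d", 1:50)
  kept <- genes_in_regions(genes, regions)
  inside <- (s >= 10001 & s + 9999 <= 50000) |
    (s >= 100001 & s + 9999 <= 150000)
  expect_equal(kept$gene_id, genes$gene_id[inside])
  expect_equal(kept$rfd_sign, ifelse(GenomicRanges::start(kept) < 60000,
                                     "+", "-"))
  # straddling gene is dropped under containment but kept under overlap mode
  straddle <- GenomicRanges::GRanges("chr", IRanges::IRanges(45001, 55000),
                                     seqinfo = asm)
  straddle$gene_id <- "gx"
  expect_length(genes_in_regions(straddle, regions), 0)
  expect_equal(genes_in_regions(straddle, regions, mode = "overlap")$gene_id,
               "gx")
})

test_that("TRC window and control geometry follows the published layout", {
  asm <- genome_assembly(c(chr = 5e6))
  # a 10 kb gene whose single DRIPc overlap spans [2054k, 2056k)
  gene <- GenomicRanges::GRanges("chr", IRanges::IRanges(2050001, 2060000),
                                 strand = "+", seqinfo = asm)
  gene$gene_id <- "g1"
  gene$rfd_sign <- "-"
  dripc <- GenomicRanges::GRanges("chr", IRanges::IRanges(2054001, 2056000),
                                  seqinfo = asm)
  p <- trc_params()
  sites <- define_trc_sites(gene, dripc, p, asm)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$overlap_start, 2054000)
  expect_equal(sites$overlap_end, 2056000)
  expect_equal(sites$center, 2055000)
  expect_equal(c(sites$window_start, sites$window_end),
               c(2045000, 2065000))
  expect_equal(sites$window_end - sites$window_start, 2 * p$flank)
  expect_equal(c(sites$ctrl_up_start, sites$ctrl_up_end),
               2055000 - 1e6 + c(-1e4, 1e4))
  expect_equal(c(sites$ctrl_down_start, sites$ctrl_down_end),
               2055000 + 1e6 + c(-1e4, 1e4))
  expect_equal(sites$orientation, "head_on")

  # no DRIPc overlap -> no site
  far <- GenomicRanges::GRanges("chr", IRanges::IRanges(90001, 91000),
                                seqinfo = asm)
  expect_equal(nrow(define_trc_sites(gene, far, p, asm)), 0)

  # out-of-bounds controls are dropped, not clipped
  gene2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(500001, 510000),
                                  strand = "+", seqinfo = asm)
  gene2$gene_id <- "g2"
  gene2$rfd_sign <- "+"
  dripc2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(504001, 506000),
                                   seqinfo = asm)
  s2 <- define_trc_sites(gene2, dripc2, p, asm)
  expect_equal(nrow(s2), 0)
  expect_equal(attr(s2, "n_dropped"), 1L)
})

test_that("orientation enumerates strand-by-fork-direction combinations", {
  expect_equal(
    classify_orientation(c("+", "+", "-", "-"), c("+", "-", "+", "-")),
    c("co_directional", "head_on", "head_on", "co_directional"))
})

test_that("multi-peak overlap spans run leftmost start to rightmost end", {
  asm <- genome_assembly(c(chr = 5e6))
  gene <- GenomicRanges::GRanges("chr", IRanges::IRanges(2000001, 2050000),
                                 strand = "-", seqinfo = asm)
  gene$gene_id <- "g1"
  gene$rfd_sign <- "-"
  dripc <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    c(1990001, 2010001, 2040001), c(2005000, 2012000, 2060000)),
    seqinfo = asm)
  sites <- define_trc_sites(gene, dripc, trc_params(), asm)
  # peaks clipped to the gene body: [2000000, 2050000) in BED coordinates
  expect_equal(sites$overlap_start, 2000000)
  expect_equal(sites$overlap_end, 2050000)
  expect_equal(sites$center, 2025000)
  expect_equal(sites$orientation, "co_directional")
})
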
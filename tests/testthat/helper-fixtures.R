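# Shared study configurations and a per-session cache for the heavier
# synthetic datasets (built once, reused across test files).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_assembly <- function() genome_assembly(c(chrA = 100000, chrB = 50000))

# Promoter-structure study: one 3.5 Mb chromosome, 300 short well-spaced
# genes with a broad promoter GC spectrum, 20 bound promoters.
tss_structure_config <- function(seed, skew_amplitude = 0.3) {
  sim_config(seed = seed, chrom_lengths = c(chrT = 3.5e6), n_genes = 300,
             gene_length = c(2000, 4000), gene_margin = 6000,
             gene_spacing = 3500, origin_positions = c(1.75e6),
             promoter_gc = c(0.35, 0.65), skew_amplitude = skew_amplitude)
}

build_tss_structure_data <- function(seed, skew_amplitude = 0.3,
                                     n_bound = 20) {
  cfg <- tss_structure_config(seed, skew_amplitude)
  ann <- make_annotation(cfg)
  base <- make_genome(cfg, ann)
  bound_ids <- choose_bound_genes(cfg, ann, base$genome, n_bound)
  gen <- make_genome(cfg, ann, skewed_gene_ids = bound_ids)
  peaks <- simulate_peaks(cfg, ann, bound_ids)
  list(cfg = cfg, ann = ann, genome = gen$genome, truth = gen$truth,
       bound_ids = bound_ids, peaks = peaks)
}

tss_structure_data <- function(seed = 101, skew_amplitude = 0.3) {
  cached(sprintf("tss_%d_%g", seed, skew_amplitude),
         function() build_tss_structure_data(seed, skew_amplitude))
}

# Factor-enrichment study: 25 chromosomes of 3 Mb (so 1 Mb-distant controls
# can never touch another site's window), one origin each, 50 genes all
# carrying a DRIPc peak.
enrichment_config <- function(seed) {
  lens <- stats::setNames(rep(3e6, 25), sprintf("chr%02d", 1:25))
  sim_config(seed = seed, chrom_lengths = lens, n_genes = 50,
             origin_positions = stats::setNames(as.list(rep(5e5, 25)),
                                                names(lens)),
             dripc_gene_fraction = 1, chip_background_depth = 50)
}

enrichment_sites <- function(seed = 202) {
  cached(sprintf("enr_%d", seed), function() {
    cfg <- enrichment_config(seed)
    ann <- make_annotation(cfg)
    ok <- simulate_okseq(cfg)
    rfd <- compute_rfd(ok$counts)
    regions <- call_high_rfd_regions(rfd)
    contained <- genes_in_regions(ann$genes, regions)
    dripc <- simulate_dripc(cfg, ann$genes)
    sites <- define_trc_sites(contained, dripc$peaks, trc_params(),
                              cfg$assembly)
    list(cfg = cfg, ann = ann, okseq = ok, rfd = rfd, regions = regions,
         dripc = dripc, sites = sites)
  })
}

planted_site_frame <- function(sites, fold) {
  data.frame(chrom = sites$chrom, start0 = sites$window_start,
             end0 = sites$window_end, fold = fold)
}
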
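# Shared fixtures.  Expensive objects (synthetic bundles, corpora, encoded
# datasets) are built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

# random interval sets in 0-based half-open coordinates, for oracle tests
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 60) {
  start0 <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  gr(sample(chroms, n, replace = TRUE), start0, start0 + len)
}

# brute-force >=1 bp overlap between two 0-based half-open intervals
overlaps_1bp <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & pmax(s1, s2) < pmin(e1, e2)
}

# per-pair brute-force overlap of a query GRanges against a subject GRanges
brute_any_overlap <- function(query, subject) {
  qs <- GenomicRanges::start(query) - 1L; qe <- GenomicRanges::end(query)
  qc <- as.character(GenomicRanges::seqnames(query))
  ss <- GenomicRanges::start(subject) - 1L; se <- GenomicRanges::end(subject)
  sc <- as.character(GenomicRanges::seqnames(subject))
  vapply(seq_along(query), function(i)
    any(overlaps_1bp(qc[i], qs[i], qe[i], sc, ss, se)), logical(1))
}

# a tiny in-memory hybrid_dataset
toy_dataset <- function(tokens, signal, label) {
  structure(list(tokens = tokens, signal = signal, label = label,
                 meta = data.frame(
                   cell_type = "toy", chrom = "chr1",
                   win_start = seq_len(ncol(tokens)) - 1L,
                   win_end = seq_len(ncol(tokens)) - 1L + nrow(tokens),
                   tss_overlap = FALSE,
                   mean_atac_signal = colMeans(signal))),
            class = "hybrid_dataset")
}

# small study-shaped synthetic configuration for unit tests: same structure
# as the defaults but scaled down so generation takes seconds
small_config <- function(seed = 11L, ...) {
  synthetic_config(
    chromosome_lengths = stats::setNames(rep(30000L, 14),
                                         c(paste0("chr", c(1:13)), "chrX")),
    n_ocrs_per_cell_type = 120L,
    total_reads = 2e6,
    seed = seed, ...)
}

small_bundle <- function() {
  cache_get("small_bundle", function()
    generate_dataset(small_config(),
                     out_dir = file.path(tempdir(), "peaktx_small_bundle")))
}

small_corpora <- function() {
  cache_get("small_corpora", function()
    suppressMessages(load_bundle_corpora(small_bundle())))
}

# full default-condition bundle shared by the acceptance tests
default_bundle <- function() {
  cache_get("default_bundle", function()
    generate_dataset(synthetic_config(),
                     out_dir = file.path(tempdir(), "peaktx_default_bundle")))
}

default_corpora <- function() {
  cache_get("default_corpora", function()
    suppressMessages(load_bundle_corpora(default_bundle())))
}

# encoded LOOT datasets for the default bundle (held out cellA)
default_loot_encoded <- function() {
  cache_get("default_loot_encoded", function() {
    bundle <- default_bundle()
    corpora <- default_corpora()
    split <- suppressMessages(loot_split(corpora, held_out = "cellA",
                                         validation_cell_type = "cellV"))
    list(train = combine_datasets(lapply(split$train, encode_windows,
                                         genome = bundle$genome)),
         validation = encode_windows(split$validation, bundle$genome),
         test = encode_windows(split$test, bundle$genome))
  })
}
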
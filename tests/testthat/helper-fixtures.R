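# Shared fixtures, built in code at test time.

# Hand-built 4-probe, 3-pair matrix with known values.
tiny_em <- function(values = NULL) {
  probes <- data.frame(probe_id = paste0("P", 1:4),
                       gene_symbol = c("GA", "GB", "GC", "GD"),
                       biotype = c("mRNA", "mRNA", "lncRNA", "mRNA"),
                       stringsAsFactors = FALSE)
  design <- data.frame(sample_id = c("S1T", "S2T", "S3T", "S1N", "S2N", "S3N"),
                       condition = rep(c("tumor", "normal"), each = 3),
                       pair_id = rep(c("PA", "PB", "PC"), 2),
                       stringsAsFactors = FALSE)
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(rnorm(24, 8, 1), 4, 6)
  }
  expression_matrix(values, probes, design)
}

# Downsized generator settings for fast unit tests.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_pairs = 26L, n_probes = 800L, n_de = 80L, n_sets = 40L,
         set_size_range = c(10L, 30L), n_enriched_sets = 2L,
         n_modules = 2L, module_size = 10L, n_hubs = 2L, hub_degree = 27L,
         n_background_edges = 300L, seed = 11L),
    list(...))
  do.call(synth_config, args)
}

# Null generator: no planted structure at all.
null_config <- function(...) {
  quick_config(n_de = 0L, n_modules = 0L, n_hubs = 0L, n_enriched_sets = 0L,
               n_background_edges = 100L, ...)
}

expect_same_file_bytes <- function(path_a, path_b) {
  expect_identical(unname(tools::md5sum(path_a)), unname(tools::md5sum(path_b)))
}
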
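# Fixtures are built in code; larger cohorts are generated once per test run
# and cached, so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

# small 5-species cohort for structural checks
small_cohort <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "cdiv_small_cohort")
    cfg <- cohort_config(n_orthogroups = 150L, n_duplicate_pairs = 60L,
                         seed = 11L)
    .fixture_cache$small <- generate_cohort(cfg, dir)
  }
  .fixture_cache$small
}

# full-size cohort at the default study conditions (2000 orthogroups)
default_cohort <- function() {
  if (is.null(.fixture_cache$default)) {
    dir <- file.path(tempdir(), "cdiv_default_cohort")
    .fixture_cache$default <- generate_cohort(cohort_config(seed = 101L), dir)
  }
  .fixture_cache$default
}

worked_example <- function() {
  if (is.null(.fixture_cache$we)) {
    dir <- file.path(tempdir(), "cdiv_worked_example")
    .fixture_cache$we <- worked_example_cohort(dir)
  }
  .fixture_cache$we
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# quick peak data.frame constructor
make_peaks <- function(start, end, summit_offset = (end - start) %/% 2L,
                       signal_fc = 1, idr = NA_real_, chrom = "chr1",
                       name = sprintf("pk%03d", seq_along(start))) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = 0, strand = ".",
             signal_fc = signal_fc, pvalue_neglog10 = -1,
             qvalue_neglog10 = -1, summit_offset = as.integer(summit_offset),
             idr = idr, stringsAsFactors = FALSE)
}

make_genes <- function(tss, strand = "+", chrom = "chr1",
                       gene_id = sprintf("g%03d", seq_along(tss))) {
  data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
             strand = strand, stringsAsFactors = FALSE)
}
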
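test_that("summit regions are fixed-width windows around the summit", {
  pk <- make_peaks(start = 100L, end = 600L, summit_offset = 400L)
  rg <- resize_summit_regions(pk, 75L)
  expect_equal(c(rg$start, rg$end), c(425L, 575L))
  expect_equal(rg$end - rg$start, 150L)
  # clipping at the chromosome start
  pk2 <- make_peaks(start = 0L, end = 100L, summit_offset = 30L)
  expect_warning(rg2 <- resize_summit_regions(pk2, 75L), "clipped")
  expect_equal(c(rg2$start, rg2$end), c(0L, 105L))
  expect_error(resize_summit_regions(pk, 0L), "positive")
  pk$summit_offset <- -1L
  expect_error(resize_summit_regions(pk, 75L), "without summit")
})

test_that("peak filtering applies IDR and signal cut-offs conjunctively", {
  pk <- make_peaks(start = (0:4) * 1000L, end = (0:4) * 1000L + 200L,
                   signal_fc = c(3, 1, 9, 9, 9),
                   idr = c(.001, .005, .02, .05, .2))
  expect_message(kept <- filter_peaks(pk, idr_max = 0.01, signal_min = 2),
                 "4 of 5")
  expect_equal(nrow(kept), 1L)           # hand enumeration: only peak 1
  expect_equal(kept$name, "pk001")
  # signal_min = 0 leaves only the IDR criterion
  expect_equal(nrow(suppressMessages(filter_peaks(pk, 0.01, 0))), 2L)
  # raising idr_max never decreases the survivor count
  counts <- vapply(c(.001, .005, .02, .05, .2, 1),
                   function(th) nrow(suppressMessages(filter_peaks(pk, th, 0))),
                   0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("summit-to-gene assignment honours upstream windows, strand and ties", {
  genes <- make_genes(tss = 10000L, strand = "+")
  pk <- make_peaks(start = 9100L, end = 9300L, summit_offset = 100L)  # summit 9200
  asn <- assign_peaks_to_genes(pk, genes, 1500L)
  expect_equal(asn$distance_to_tss, 800L)
  # downstream summit of a + gene is never assigned
  pk2 <- make_peaks(start = 9901L, end = 10101L, summit_offset = 100L)  # summit 10001
  expect_equal(nrow(assign_peaks_to_genes(pk2, genes, 100000L)), 0L)
  # a summit eligible for two genes goes to the nearer one
  g2 <- make_genes(tss = c(5300L, 5900L), strand = "+",
                   gene_id = c("near", "far"))
  pk3 <- make_peaks(start = 4900L, end = 5100L, summit_offset = 100L)  # summit 5000
  asn3 <- assign_peaks_to_genes(pk3, g2, 1500L)
  expect_equal(asn3$gene_id, "near")
  # equidistant tie broken by lexicographically smallest gene id
  g3 <- make_genes(tss = c(5300L, 5300L), strand = "+", gene_id = c("b", "a"))
  expect_equal(assign_peaks_to_genes(pk3, g3, 1500L)$gene_id, "a")
})

test_that("assignment equals the quadratic brute force on random cohorts", {
  for (seed in 1:3) {
    set.seed(seed)
    n_pk <- 150L; n_g <- 60L
    starts <- sort(sample.int(200000L, n_pk))
    pk <- make_peaks(start = starts, end = starts + 200L)
    genes <- make_genes(tss = sample.int(200000L, n_g),
                        strand = sample(c("+", "-"), n_g, TRUE))
    asn <- assign_peaks_to_genes(pk, genes, 1500L)
    ora <- oracle_assign(pk, genes, 1500L)
    expect_equal(nrow(asn), nrow(ora))
    m <- merge(asn, ora, by = "peak")
    expect_equal(m$gene_id.x, m$gene_id.y)
    expect_equal(m$distance_to_tss, m$distance)
  }
})

test_that("every planted target gene and no other is recovered on a synthetic cohort", {
  co <- small_cohort()
  s <- co$config$species[[1]]
  pk <- read_narrowpeak(co$paths[[paste0("tf1_", s)]])
  genes <- read_gene_table(co$paths[[paste0("genes_", s)]])
  asn <- assign_peaks_to_genes(pk, genes,
                               co$config$promoter_window_bp[[s]])
  expect_setequal(unique(asn$gene_id), co$truth$targets_by_species[[s]])
})

test_that("peak overlap counts match an interval-sweep check and edge cases", {
  a <- make_peaks(start = c(0L, 1000L), end = c(100L, 1100L))
  expect_equal(peak_overlap(a, a), list(a_overlap = 2L, a_only = 0L,
                                        b_overlap = 2L, b_only = 0L))
  b <- make_peaks(start = c(5000L, 6000L), end = c(5100L, 6100L))
  expect_equal(peak_overlap(a, b)$a_overlap, 0L)
  expect_equal(peak_overlap(a, b)$b_only, 2L)
  # 1 bp shared counts at the default, not at min_overlap = 2
  a1 <- make_peaks(start = 0L, end = 100L)
  b1 <- make_peaks(start = 99L, end = 200L)
  expect_equal(peak_overlap(a1, b1)$a_overlap, 1L)
  expect_equal(peak_overlap(a1, b1, min_overlap = 2L)$a_overlap, 0L)
})

test_that("signal correlation over the union of summit regions behaves", {
  sig <- c(2, 4, 8, 16)
  a <- make_peaks(start = c(0L, 1000L, 2000L, 3000L) + 100L,
                  end = c(0L, 1000L, 2000L, 3000L) + 300L, signal_fc = sig)
  b <- a; b$signal_fc <- sig * 3          # proportional -> r = 1 on log scale
  out <- signal_correlation_in_union(a, b)
  expect_equal(out$n, 4L)
  expect_equal(out$r, 1)
  b2 <- a; b2$signal_fc <- rev(sig)       # anti-ordered -> r = -1 on log scale
  expect_equal(signal_correlation_in_union(a, b2)$r, -1)
  expect_error(signal_correlation_in_union(a[1:2, ], b[1:2, ]), "fewer than 3")
})
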
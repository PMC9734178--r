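test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_orthogroups = 60L, n_duplicate_pairs = 30L, seed = 1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- generate_cohort(cfg, d1)
  c2 <- generate_cohort(cfg, d2)
  for (k in names(c1$paths))
    expect_identical(unname(tools::md5sum(c1$paths[[k]])),
                     unname(tools::md5sum(c2$paths[[k]])),
                     label = paste("checksum of", k))
})

test_that("config validation rejects out-of-range fractions", {
  expect_error(cohort_config(frac_target = 1.4), "fractions")
  expect_error(cohort_config(pi_constraint_factor = 0), "pi_constraint_factor")
  expect_error(cohort_config(n_species = 1L), "at least 2|n_species - 1")
})

test_that("generator ground truth is self-consistent with the emitted files", {
  co <- small_cohort()
  # planted targets are exactly the genes with a TF peak in their promoter
  for (s in co$config$species) {
    pk <- read_narrowpeak(co$paths[[paste0("tf1_", s)]])
    genes <- read_gene_table(co$paths[[paste0("genes_", s)]])
    asn <- assign_peaks_to_genes(pk, genes, co$config$promoter_window_bp[[s]])
    expect_setequal(unique(asn$gene_id), co$truth$targets_by_species[[s]])
  }
  # bound summit regions contain at least one planted consensus instance
  focal <- co$config$species[[1]]
  genome <- Biostrings::readDNAStringSet(co$paths[[paste0("genome_", focal)]])
  names(genome) <- sub("\\s.*$", "", names(genome))
  tf <- read_narrowpeak(co$paths[[paste0("tf1_", focal)]])
  regions <- resize_summit_regions(tf, 75L)
  win <- extract_windows(tf, 150L, genome)
  hits_per_region <- vapply(win, function(s)
    nrow(scan_iupac(s, co$config$motif_consensus)), 0L)
  expect_true(all(hits_per_region >= 1L))
})

test_that("conserved sites carry a stronger planted signal", {
  co <- default_cohort()
  focal <- co$config$species[[1]]
  tf <- read_narrowpeak(co$paths[[paste0("tf1_", focal)]])
  genes <- read_gene_table(co$paths[[paste0("genes_", focal)]])
  asn <- assign_peaks_to_genes(tf, genes, co$config$promoter_window_bp[[focal]])
  lev <- co$truth$focal_target_levels
  sig <- asn$signal_fc[asn$closest]
  names(sig) <- asn$gene_id[asn$closest]
  s_cons <- sig[names(lev)[lev == co$config$n_species]]
  s_spec <- sig[names(lev)[lev == 1L]]
  expect_gt(mean(s_cons), mean(s_spec))
  mw <- stats::wilcox.test(s_cons, s_spec, alternative = "greater")
  expect_lt(mw$p.value, 0.01)
})

test_that("bound-motif diversity is shrunk relative to the background", {
  for (seed in c(2L, 9L)) {
    d <- withr::local_tempdir()
    co <- generate_cohort(cohort_config(n_orthogroups = 120L,
                                        n_duplicate_pairs = 30L,
                                        seed = seed), d)
    focal <- co$config$species[[1]]
    genome <- Biostrings::readDNAStringSet(co$paths[[paste0("genome_", focal)]])
    names(genome) <- sub("\\s.*$", "", names(genome))
    hits <- scan_iupac(genome, co$config$motif_consensus)
    hits <- classify_motif_sites(hits,
                                 read_narrowpeak(co$paths[[paste0("tf1_", focal)]]),
                                 read_narrowpeak(co$paths[[paste0("atac_", focal)]]))
    sd_tab <- motif_diversity(hits[hits$klass != "excluded", , drop = FALSE],
                              read_variant_table(co$paths$variants))
    ct <- diversity_contrast(sd_tab, exact = FALSE)
    expect_lt(ct$mean_a, ct$mean_b)
  }
})

test_that("a zero-coefficient DEG model yields chance-level prediction", {
  d <- withr::local_tempdir()
  cfg <- cohort_config(n_orthogroups = 400L, n_duplicate_pairs = 60L,
                       deg_coefficients = c(intercept = -0.7, signal = 0,
                                            distance = 0, expression = 0,
                                            cobinding = 0),
                       seed = 8L)
  co <- generate_cohort(cfg, d)
  expr <- utils::read.delim(co$paths$expression)
  p <- co$truth$p_deg
  expect_true(all(abs(p - p[1]) < 1e-12))   # constant DEG probability
  # empirical DEG rate independent of conservation level
  lev <- co$truth$focal_target_levels
  is_deg <- stats::setNames(expr$is_deg, expr$gene_id)[names(lev)]
  r_hi <- mean(is_deg[lev >= 4]); r_lo <- mean(is_deg[lev <= 2])
  expect_lt(abs(r_hi - r_lo), 0.15)
})

test_that("the worked example reproduces its hand-computed expectations", {
  we <- worked_example()
  orth <- read_orthogroups(we$paths$orthogroups, we$config$species)
  targets <- lapply(we$config$species, function(s) {
    pk <- read_narrowpeak(we$paths[[paste0("tf1_", s)]])
    genes <- read_gene_table(we$paths[[paste0("genes_", s)]])
    unique(assign_peaks_to_genes(pk, genes, we$config$windows[[s]])$gene_id)
  })
  names(targets) <- we$config$species
  cl <- conservation_levels(targets, orth, "speciesA")
  expect_equal(cl$levels[names(we$expected$levels)], we$expected$levels)
  expect_equal(as.integer(cl$groups), unname(we$expected$groups))
  # motif diversity of the planted bound and background instances
  genome <- Biostrings::readDNAStringSet(we$paths$genome_speciesA)
  names(genome) <- sub("\\s.*$", "", names(genome))
  hits <- scan_iupac(genome, "RGATTYY")
  hits <- classify_motif_sites(hits,
                               read_narrowpeak(we$paths$tf1_speciesA),
                               read_narrowpeak(we$paths$atac_speciesA))
  sd_tab <- motif_diversity(hits, read_variant_table(we$paths$variants))
  expect_equal(
    sd_tab$motif_pi[sd_tab$start == we$expected$bound_motif_start &
                    sd_tab$strand == "+"],
    we$expected$bound_motif_pi)
  expect_equal(
    sd_tab$motif_pi[sd_tab$start == we$expected$background_motif_start &
                    sd_tab$strand == "+"],
    we$expected$background_motif_pi)
  # DEG summary: both target DEGs are down-regulated
  expr <- utils::read.delim(we$paths$expression)
  ov <- summarize_deg_overlap(targets$speciesA, expr)
  expect_equal(ov$pct_down, we$expected$pct_down)
  # duplicate pair retention
  pairs <- utils::read.delim(we$paths$duplicate_pairs)
  pairs <- classify_retention(pairs, targets$speciesA)
  expect_equal(pairs$retention, we$expected$retention)
})
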